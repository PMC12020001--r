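#' A 2D periodic configuration
#'
#' Positions, one orientation angle per molecule, and a rectangular periodic
#' box. Positions are wrapped into `[0, box)`.
#'
#' @param positions N x 2 matrix of positions.
#' @param orientations Length-N vector of orientation angles, radians.
#' @param box Length-2 vector of box edge lengths.
#' @return Object of class `configuration`.
#' @export
configuration <- function(positions, orientations, box) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 1,
            length(orientations) == nrow(positions),
            length(box) == 2, all(box > 0))
  structure(list(positions = wrap_positions(positions, box),
                 orientations = as.numeric(orientations),
                 box = as.numeric(box),
                 n = nrow(positions)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d molecules, box %.4g x %.4g (area %.4g)\n",
              x$n, x$box[1], x$box[2], prod(x$box)))
  invisible(x)
}

#' Wrap positions into the periodic box
#'
#' @param positions N x 2 matrix.
#' @param box Length-2 box vector.
#' @return Wrapped N x 2 matrix.
#' @export
wrap_positions <- function(positions, box) {
  positions[, 1] <- positions[, 1] %% box[1]
  positions[, 2] <- positions[, 2] %% box[2]
  positions
}

#' Minimum-image displacement vectors from one molecule to all others
#'
#' @param config A [configuration()].
#' @param i Molecule index.
#' @return (N-1) x 2 matrix of displacements to the other molecules.
#' @export
min_image_disp <- function(config, i) {
  d <- sweep(config$positions[-i, , drop = FALSE], 2,
             config$positions[i, ])
  d[, 1] <- d[, 1] - config$box[1] * round(d[, 1] / config$box[1])
  d[, 2] <- d[, 2] - config$box[2] * round(d[, 2] / config$box[2])
  d
}

#' Minimum pairwise minimum-image distance
#'
#' @param config A [configuration()].
#' @return Scalar distance.
#' @export
min_pair_distance <- function(config) {
  if (config$n < 2) return(Inf)
  d <- cpp_pair_distances(config$positions, config$box,
                          max(config$box))
  if (length(d) == 0) Inf else min(d)
}

#' Read and write extended XYZ snapshots
#'
#' One frame per call: a count line, a comment line carrying the box
#' (`Lattice="Lx 0 0 Ly"`-style shorthand `box="Lx Ly"`), then one line per
#' molecule with columns `x y theta`. Round-trips exactly at full double
#' precision.
#'
#' @param config A [configuration()].
#' @param path File path.
#' @param append Append a frame instead of overwriting.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a list
#'   of `configuration` objects (one per frame).
#' @export
write_xyz <- function(config, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(config$n), con)
  writeLines(sprintf('box="%.17g %.17g"', config$box[1], config$box[2]), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     config$positions[, 1], config$positions[, 2],
                     config$orientations), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    box <- as.numeric(strsplit(sub('.*box="([^"]*)".*', "\\1",
                                   lines[i + 1]), " ")[[1]])
    dat <- do.call(rbind, lapply(strsplit(lines[(i + 2):(i + 1 + n)], " "),
                                 as.numeric))
    frames[[length(frames) + 1]] <-
      configuration(dat[, 1:2, drop = FALSE], dat[, 3], box)
    i <- i + 2 + n
  }
  frames
}
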