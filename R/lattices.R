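#' Ideal honeycomb hydrogen-bond network
#'
#' Generates the low-pressure solid of the model: a honeycomb lattice in
#' which every molecule's three arms point exactly at its three neighbors.
#' The two sublattices carry orientations -30 and +30 degrees (rotated 60
#' degrees from each other); with the body-frame arm convention of
#' [arm_angles()] this aligns every arm with a bond. Built from a
#' rectangular 4-molecule cell of size `sqrt(3) b x 3 b`, replicated
#' `n_cells x n_cells` times (N = 4 n_cells^2).
#'
#' @param n_cells Number of rectangular cells per direction.
#' @param bond_length Nearest-neighbor (hydrogen-bond) distance `b`.
#' @return A [configuration()].
#' @export
make_honeycomb <- function(n_cells, bond_length = 1) {
  stopifnot(n_cells >= 1)
  b <- bond_length
  base_pos <- rbind(c(0, 0),
                    c(sqrt(3) * b / 2, b / 2),
                    c(sqrt(3) * b / 2, 3 * b / 2),
                    c(0, 2 * b))
  base_ori <- c(-pi / 6, pi / 6, -pi / 6, pi / 6)
  cell <- c(sqrt(3) * b, 3 * b)
  shifts <- as.matrix(expand.grid(ix = seq_len(n_cells) - 1,
                                  iy = seq_len(n_cells) - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    sweep(base_pos, 2, shifts[k, ] * cell, "+")))
  ori <- rep(base_ori, nrow(shifts))
  configuration(pos, ori, cell * n_cells)
}

#' Ideal triangular close packing
#'
#' The high-pressure hexagonally close-packed solid: a triangular lattice
#' with 6-fold coordination, built from a rectangular 2-molecule cell of
#' size `a x sqrt(3) a` (N = 2 n_cells^2). Number density is
#' `2 / (sqrt(3) a^2)`.
#'
#' @param n_cells Number of rectangular cells per direction.
#' @param spacing Nearest-neighbor distance `a`.
#' @param orientation Common orientation angle of all molecules.
#' @return A [configuration()].
#' @export
make_triangular <- function(n_cells, spacing = 1, orientation = 0) {
  stopifnot(n_cells >= 1)
  a <- spacing
  base_pos <- rbind(c(0, 0), c(a / 2, sqrt(3) * a / 2))
  cell <- c(a, sqrt(3) * a)
  shifts <- as.matrix(expand.grid(ix = seq_len(n_cells) - 1,
                                  iy = seq_len(n_cells) - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    sweep(base_pos, 2, shifts[k, ] * cell, "+")))
  configuration(pos, rep(orientation, nrow(pos)), cell * n_cells)
}

#' Random non-overlapping gas configuration
#'
#' Uniform random positions with a hard minimum-separation constraint
#' (rejection sampling) and uniform random orientations.
#'
#' @param n Number of molecules.
#' @param box Length-2 box vector.
#' @param min_sep Minimum allowed pair distance.
#' @param seed RNG seed (the result is reproducible for a fixed seed).
#' @param max_tries Placement attempts per molecule before giving up.
#' @return A [configuration()].
#' @export
make_gas <- function(n, box, min_sep, seed = 1, max_tries = 2000) {
  stopifnot(n >= 1, length(box) == 2)
  set.seed(seed)
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(runif(1, 0, box[1]), runif(1, 0, box[2]))
      if (i == 1) { ok <- TRUE } else {
        d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, cand)
        d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
        d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
        ok <- all(d[, 1]^2 + d[, 2]^2 >= min_sep^2)
      }
      if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("make_gas: could not place molecule %d of %d at min_sep %g",
                   i, n, min_sep))
  }
  configuration(pos, runif(n, 0, 2 * pi), box)
}

#' Random initial configuration for MD
#'
#' A square box sized to the requested number density, filled with
#' non-overlapping molecules (no pair closer than `0.85 * sigma_lj`).
#'
#' @param n Number of molecules.
#' @param density_guess Target number density (1/area).
#' @param seed RNG seed.
#' @param params A [rose_params()] object (sets the overlap distance).
#' @return A [configuration()].
#' @export
make_initial_configuration <- function(n, density_guess, seed = 1,
                                       params = rose_params("mb")) {
  stopifnot(n >= 1, density_guess > 0)
  L <- sqrt(n / density_guess)
  make_gas(n, c(L, L), min_sep = 0.85 * params$sigma_lj, seed = seed)
}
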