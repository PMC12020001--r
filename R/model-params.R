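#' Rose water model parameter sets
#'
#' Builds the full parameter set of the 2D rose water model: a Lennard-Jones
#' disc term plus an orientation-dependent hydrogen-bond term whose angular
#' shape is a normalized 3-petal rose function and whose radial extent is a
#' double-sided cubic switching window around the hydrogen-bond distance.
#'
#' Two presets are shipped. `"mb"` mimics the Mercedes-Benz water model
#' (`eps_lj = 0.1`, `sigma_lj = 0.7`, `eps_hb = 1`, `r_hb = 1`,
#' `r_fwhm = 0.2`, `a1 = 0.6`, `a2 = -0.4`). `"real"` softens the model's
#' exaggerations: `eps_lj = 0.2`, `sigma_lj = 0.890899` (the LJ minimum then
#' coincides with the hydrogen-bond distance) and a wider bond,
#' `r_fwhm = 0.41666`; all other values as in `"mb"`.
#'
#' Derived fields: `r_l = r_hb - r_fwhm` and `r_u = r_hb + r_fwhm` (the
#' switching window, with `r_fwhm` its full width at half maximum), `a_max`
#' (the maximum magnitude of the unnormalized rose function over one period,
#' used to normalize the orientational term so its global minimum is exactly
#' -1), and the cut-and-shift constant of the LJ term at `lj_cutoff`
#' (default `4 * sigma_lj`; the shift keeps the truncated potential
#' continuous so that microcanonical energy conservation is testable).
#'
#' @param preset `"mb"`, `"real"`, or `"custom"`.
#' @param eps_lj,sigma_lj LJ well depth and contact distance.
#' @param eps_hb Hydrogen-bond well depth (the best possible full bond has
#'   pair energy `-eps_hb`; each molecule contributes at most `-eps_hb / 2`).
#' @param r_hb,r_fwhm Hydrogen-bond distance and full width at half maximum
#'   of the switching window.
#' @param a1,a2 Rose-function coefficients.
#' @param lj_cutoff LJ truncation radius; defaults to `4 * sigma_lj`.
#' @return An object of class `rose_params` (a named list).
#' @examples
#' p <- rose_params("mb")
#' p$r_l; p$r_u
#' @export
rose_params <- function(preset = c("mb", "real", "custom"),
                        eps_lj = NULL, sigma_lj = NULL, eps_hb = 1,
                        r_hb = 1, r_fwhm = NULL, a1 = 0.6, a2 = -0.4,
                        lj_cutoff = NULL) {
  preset <- match.arg(preset)
  if (preset == "mb") {
    eps_lj <- eps_lj %||% 0.1; sigma_lj <- sigma_lj %||% 0.7
    r_fwhm <- r_fwhm %||% 0.2
  } else if (preset == "real") {
    eps_lj <- eps_lj %||% 0.2; sigma_lj <- sigma_lj %||% 0.890899
    r_fwhm <- r_fwhm %||% 0.41666
  } else {
    if (is.null(eps_lj) || is.null(sigma_lj) || is.null(r_fwhm))
      stop("custom parameters require eps_lj, sigma_lj and r_fwhm")
  }
  stopifnot(sigma_lj > 0 || eps_lj == 0, r_hb > 0, r_fwhm > 0, r_fwhm < r_hb)
  lj_cutoff <- lj_cutoff %||% (4 * sigma_lj)
  p <- list(preset = preset,
            eps_lj = eps_lj, sigma_lj = sigma_lj, eps_hb = eps_hb,
            r_hb = r_hb, r_fwhm = r_fwhm,
            r_l = r_hb - r_fwhm, r_u = r_hb + r_fwhm,
            a1 = a1, a2 = a2,
            a_max = rose_a_max(a1, a2),
            lj_cutoff = lj_cutoff,
            lj_shift = lj_unshifted(lj_cutoff, eps_lj, sigma_lj))
  class(p) <- "rose_params"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lj_unshifted <- function(r, eps, sigma) {
  if (eps == 0) return(0)
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6)
}

# Maximum magnitude of the unnormalized rose function over one period,
# located numerically (dense scan + golden-section polish). For the shipped
# coefficient sets this is exactly a1 - a2 = 1.
rose_a_max <- function(a1, a2) {
  f <- function(t) abs(a1 * cos(3 * t) + a2 * cos(6 * t))
  grid <- seq(0, 2 * pi / 3, length.out = 2001)
  t0 <- grid[which.max(f(grid))]
  h <- pi / 3000
  opt <- optimize(f, lower = t0 - h, upper = t0 + h, maximum = TRUE,
                  tol = 1e-14)
  max(opt$objective, f(t0))
}

#' Body-frame arm directions
#'
#' The three hydrogen-bond arms of a molecule, in its body frame. They sit at
#' the minima of the rose orientational term: 60, 180 and 300 degrees.
#'
#' @param params A `rose_params` object (the arm geometry is coefficient-sign
#'   dependent in general; for the shipped presets the minima are at these
#'   angles).
#' @return Numeric vector of three angles in radians.
#' @export
arm_angles <- function(params = rose_params("mb")) {
  pi / 3 + c(0, 1, 2) * 2 * pi / 3
}

#' @export
print.rose_params <- function(x, ...) {
  cat("Rose water model parameters (preset: ", x$preset, ")\n", sep = "")
  cat(sprintf("  LJ:  eps = %g, sigma = %g, cutoff = %g (cut-and-shift)\n",
              x$eps_lj, x$sigma_lj, x$lj_cutoff))
  cat(sprintf("  HB:  eps = %g, r_hb = %g, window [%g, %g] (fwhm %g)\n",
              x$eps_hb, x$r_hb, x$r_l, x$r_u, x$r_fwhm))
  cat(sprintf("  rose: a1 = %g, a2 = %g, a_max = %g\n", x$a1, x$a2, x$a_max))
  invisible(x)
}

#' Read or write model parameters as JSON
#'
#' Round-trip exact serialization of a `rose_params` object.
#'
#' @param params A `rose_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `rose_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "rose_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(p, function(v) if (is.numeric(v)) as.numeric(v) else v)
  out <- rose_params(preset = "custom",
                     eps_lj = p$eps_lj, sigma_lj = p$sigma_lj,
                     eps_hb = p$eps_hb, r_hb = p$r_hb, r_fwhm = p$r_fwhm,
                     a1 = p$a1, a2 = p$a2, lj_cutoff = p$lj_cutoff)
  out$preset <- p$preset
  out
}
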