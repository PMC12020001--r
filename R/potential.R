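#' Lennard-Jones disc energy
#'
#' The 12-6 pair term of the model, truncated by cut-and-shift at
#' `params$lj_cutoff` so the potential is continuous at the cutoff. Beyond
#' the cutoff the energy is exactly 0; the shift displaces the in-range
#' values by the (tiny) unshifted value at the cutoff.
#'
#' @param r Center-center distance(s), `r > 0`.
#' @param params A [rose_params()] object.
#' @return Energy, vectorized over `r`.
#' @export
lj_energy <- function(r, params) {
  if (any(r <= 0)) stop("lj_energy: r must be positive")
  if (params$eps_lj == 0) return(rep(0, length(r)))
  sr6 <- (params$sigma_lj / r)^6
  e <- 4 * params$eps_lj * (sr6^2 - sr6) - params$lj_shift
  e[r >= params$lj_cutoff] <- 0
  e
}

#' Normalized rose orientational term
#'
#' The angular factor of the hydrogen-bond energy: a 3-petal rose,
#' `(a1 cos(3 theta) + a2 cos(6 theta)) / a_max`, periodic with period
#' 2 pi / 3 and normalized by `a_max` so that its global minimum is exactly
#' -1. The minimum is attained when the connecting vector points along one
#' of the molecule's arms ([arm_angles()]).
#'
#' @param theta Orientation angle(s) of the connecting vector in the body
#'   frame of the molecule, radians.
#' @param params A [rose_params()] object.
#' @return Dimensionless value(s) in `[-1, a_max'/a_max]`.
#' @export
rose_orientational <- function(theta, params) {
  (params$a1 * cos(3 * theta) + params$a2 * cos(6 * theta)) / params$a_max
}

#' @rdname rose_orientational
#' @param x,y Cartesian coordinates of the partner molecule in the body
#'   frame (the same value as `rose_orientational(atan2(y, x))`, written
#'   without trigonometric calls: `cos(3t) = (x^3 - 3 x y^2) / r^3` and
#'   `cos(6t) = 2 cos(3t)^2 - 1`).
#' @export
rose_orientational_xy <- function(x, y, params) {
  r3 <- (x^2 + y^2)^1.5
  if (any(r3 == 0)) stop("rose_orientational_xy: zero-length vector")
  c3 <- (x^3 - 3 * x * y^2) / r3
  (params$a1 * c3 + params$a2 * (2 * c3^2 - 1)) / params$a_max
}

#' Double-sided cubic switching function
#'
#' Radial window of the hydrogen-bond term: two mirrored smoothstep cubics
#' meeting at `r_hb` with zero slope, `s = 1 - 3u^2 + 2u^3` with
#' `u = |r - r_hb| / r_fwhm`. Equal to 1 at `r_hb`, 0 at and beyond the
#' window limits `r_l`, `r_u`, 0.5 at `r_hb +/- r_fwhm / 2` (so `r_fwhm` is
#' the full width at half maximum), and continuously differentiable
#' everywhere (required for forces).
#'
#' @param r Distance(s), `r >= 0`.
#' @param params A [rose_params()] object.
#' @return Value(s) in `[0, 1]`.
#' @export
switching <- function(r, params) {
  u <- abs(r - params$r_hb) / params$r_fwhm
  s <- ifelse(u >= 1, 0, 1 - 3 * u^2 + 2 * u^3)
  s
}

#' Pair geometry in a molecule's body frame
#'
#' Describes the connecting vector from molecule i to molecule j as seen
#' from i's body frame: components `dx`, `dy`, length `r` and orientation
#' angle `theta = atan2(dy, dx)`.
#'
#' @param ri,rj Positions (length-2 vectors), minimum image already applied.
#' @param phi_i Orientation angle of molecule i, radians.
#' @return A list of class `pair_geometry` with fields `r`, `dx`, `dy`,
#'   `theta`.
#' @export
pair_geometry <- function(ri, rj, phi_i) {
  d <- rj - ri
  co <- cos(phi_i); si <- sin(phi_i)
  dx <- co * d[1] + si * d[2]
  dy <- -si * d[1] + co * d[2]
  structure(list(r = sqrt(dx^2 + dy^2), dx = dx, dy = dy,
                 theta = atan2(dy, dx)),
            class = "pair_geometry")
}

#' Hydrogen-bond pair energy
#'
#' The orientation-dependent term of the pair potential: the sum of the two
#' per-molecule contributions, each the product of the molecule's normalized
#' rose orientational value and the distance switching function, scaled by
#' `eps_hb / 2`. A perfectly aligned pair at `r = r_hb` therefore has energy
#' exactly `-eps_hb`; each one-sided ("half bond") contribution is bounded
#' below by `-eps_hb / 2` and is independent of the partner's orientation.
#'
#' @param geom_ij Geometry of j seen from i's body frame ([pair_geometry()]).
#' @param geom_ji Geometry of i seen from j's body frame. Must describe the
#'   same physical pair (`r` equal).
#' @param params A [rose_params()] object.
#' @return Energy (scalar).
#' @export
hb_pair_energy <- function(geom_ij, geom_ji, params) {
  if (abs(geom_ij$r - geom_ji$r) > 1e-9 * max(1, geom_ij$r))
    stop("hb_pair_energy: geometries describe different pairs")
  s <- switching(geom_ij$r, params)
  if (s == 0) return(0)
  0.5 * params$eps_hb * s *
    (rose_orientational(geom_ij$theta, params) +
     rose_orientational(geom_ji$theta, params))
}

#' Full pair energy
#'
#' Lennard-Jones plus hydrogen-bond energy of one pair of molecules, with
#' the additive decomposition exposed (used for hydrogen-bond counting).
#'
#' @param ri,rj Positions (length-2), minimum image already applied.
#' @param phi_i,phi_j Orientation angles, radians.
#' @param params A [rose_params()] object.
#' @return A list with `total`, `lj` and `hb` components.
#' @export
pair_energy <- function(ri, rj, phi_i, phi_j, params) {
  gij <- pair_geometry(ri, rj, phi_i)
  gji <- pair_geometry(rj, ri, phi_j)
  if (gij$r == 0) stop("pair_energy: coincident molecular centers")
  lj <- lj_energy(gij$r, params)
  hb <- hb_pair_energy(gij, gji, params)
  list(total = lj + hb, lj = lj, hb = hb)
}

#' Total potential energy of a configuration
#'
#' Sum of all pair energies under periodic boundary conditions (minimum
#' image). Computed by the compiled kernel.
#'
#' @param config A [configuration()].
#' @param params A [rose_params()] object.
#' @return Energy (scalar).
#' @export
config_energy <- function(config, params) {
  cpp_total_energy(config$positions, config$orientations, config$box,
                   unclass(params))
}

#' Forces and torques
#'
#' Negative gradients of the total potential energy with respect to the
#' molecular positions and orientation angles, plus the radial pair virial
#' (only the distance derivative of the orientational term does virial
#' work; the angular gradients are perpendicular to the connecting vector).
#' Pairwise forces obey action-reaction, so the total force is zero.
#'
#' @param config A [configuration()].
#' @param params A [rose_params()] object.
#' @return A list with `energy`, `forces` (N x 2), `torques` (length N) and
#'   `virial` (scalar, `sum over pairs of -dU/dr * r`).
#' @export
forces_and_torques <- function(config, params) {
  out <- cpp_energy_forces(config$positions, config$orientations,
                           config$box, unclass(params))
  if (!all(is.finite(out$forces)))
    stop("forces_and_torques: non-finite force (overlapping molecules?)")
  out
}
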