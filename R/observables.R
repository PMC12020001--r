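#' Angular distribution function
#'
#' For every ordered pair of molecules whose minimum-image distance lies in
#' `r_target +/- r_halfwidth`, the angle between molecule i's nearest
#' hydrogen-bond arm and the line connecting the centers is histogrammed.
#' The 3-fold arm symmetry folds all angles into `[-60, 60)` degrees. The
#' density is normalized to unit integral over the window whenever any pair
#' was counted.
#'
#' @param frames A list of [configuration()] frames, or a single one.
#' @param r_target Shell radius.
#' @param r_halfwidth Shell half-width (default `0.05 * r_hb`).
#' @param bin_width Angular bin width in degrees. The default 1.6 gives 75
#'   bins over the window, chosen so that taking every third bin yields the
#'   25 descriptor points per distance.
#' @param params A [rose_params()] object (sets the default half-width).
#' @return Object of class `adf`: list with `angle` (bin centers, degrees),
#'   `density`, `counts`, `n_pairs`, `r_target`, `r_halfwidth`.
#' @export
compute_adf <- function(frames, r_target, r_halfwidth = NULL,
                        bin_width = 1.6, params = rose_params("mb")) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  stopifnot(length(frames) >= 1, r_target > 0)
  r_halfwidth <- r_halfwidth %||% (0.05 * params$r_hb)
  breaks <- seq(-60, 60, by = bin_width)
  if (abs(tail(breaks, 1) - 60) > 1e-9)
    stop("compute_adf: bin_width must divide the 120-degree window")
  counts <- numeric(length(breaks) - 1)
  n_pairs <- 0
  for (fr in frames) {
    pp <- cpp_adf_pairs(fr$positions, fr$orientations, fr$box,
                        r_target + r_halfwidth)
    sel <- abs(pp$r - r_target) <= r_halfwidth
    if (!any(sel)) next
    a <- pp$angle[sel]
    a[a >= 60] <- a[a >= 60] - 120   # guard the seam
    idx <- pmin(pmax(floor((a + 60) / bin_width) + 1, 1), length(counts))
    tab <- tabulate(idx, nbins = length(counts))
    counts <- counts + tab
    n_pairs <- n_pairs + sum(sel)
  }
  density <- if (n_pairs > 0) counts / (n_pairs * bin_width) else counts
  structure(list(angle = breaks[-length(breaks)] + bin_width / 2,
                 density = density, counts = counts, n_pairs = n_pairs,
                 r_target = r_target, r_halfwidth = r_halfwidth,
                 bin_width = bin_width),
            class = "adf")
}

#' Count peaks of an angular distribution function
#'
#' Interior local maxima above a prominence floor, with periodic wrap
#' across the +/-60 degree seam (the window is topologically a circle).
#'
#' @param adf An `adf` object.
#' @param prominence_floor Minimum height above the adjacent valleys,
#'   in density units.
#' @return Integer peak count.
#' @export
count_adf_peaks <- function(adf, prominence_floor = 0.1 * max(adf$density)) {
  d <- adf$density
  n <- length(d)
  if (all(d == 0) || n < 3) return(0L)
  ext <- c(d, d, d)  # periodic extension
  peaks <- integer(0)
  for (i in seq_len(n) + n) {
    if (ext[i] > ext[i - 1] && ext[i] >= ext[i + 1]) {
      # walk out to the nearest valleys
      l <- i; while (l > 1 && ext[l - 1] <= ext[l]) l <- l - 1
      r <- i; while (r < length(ext) && ext[r + 1] <= ext[r]) r <- r + 1
      prom <- ext[i] - max(ext[l], ext[r])
      if (prom >= prominence_floor) peaks <- c(peaks, i - n)
    }
  }
  length(unique(peaks))
}

#' Diffusion coefficient from mean-squared displacement
#'
#' 2D Einstein relation: `D = slope(MSD(t)) / 4`, the slope fitted over the
#' middle of the lag window (default lags between 10% and 50% of the
#' trajectory length). Per-series slopes give the block standard error when
#' `blocks > 1`.
#'
#' @param unwrapped List of N x 2 unwrapped position frames.
#' @param times Frame times (equal spacing assumed).
#' @param fit_window Fractions of the maximum lag to fit over.
#' @param blocks Number of contiguous trajectory blocks for the error bar.
#' @return List with `D` and `se`.
#' @export
diffusion_coefficient <- function(unwrapped, times,
                                  fit_window = c(0.1, 0.5), blocks = 1) {
  stopifnot(length(unwrapped) >= 2, length(times) == length(unwrapped))
  est <- function(idx) {
    nf <- length(idx)
    max_lag <- nf - 1
    lags <- seq_len(max_lag)
    msd <- vapply(lags, function(l) {
      d <- mapply(function(a, b) sum((unwrapped[[b]] - unwrapped[[a]])^2) /
                    nrow(unwrapped[[a]]),
                  idx[seq_len(nf - l)], idx[seq_len(nf - l) + l])
      mean(d)
    }, numeric(1))
    t_lag <- lags * (times[idx[2]] - times[idx[1]])
    sel <- lags >= max(1, floor(fit_window[1] * max_lag)) &
      lags <= ceiling(fit_window[2] * max_lag)
    if (!any(sel)) sel <- rep(TRUE, max_lag)
    fit <- stats::lm.fit(cbind(1, t_lag[sel]), msd[sel])
    unname(fit$coefficients[2]) / 4
  }
  if (blocks > 1 && length(unwrapped) >= 2 * blocks) {
    cuts <- split(seq_along(unwrapped),
                  cut(seq_along(unwrapped), blocks, labels = FALSE))
    Ds <- vapply(cuts, est, numeric(1))
    list(D = mean(Ds), se = sd(Ds) / sqrt(length(Ds)))
  } else {
    list(D = est(seq_along(unwrapped)), se = NA_real_)
  }
}

#' Hydrogen-bond statistics
#'
#' A pair counts as hydrogen bonded when its pair HB energy (both halves)
#' is below `hb_energy_cut`; the criterion is energetic because the model
#' defines the bond energetically. Per-molecule bond counts are clipped at
#' 3 for the fractions.
#'
#' @param frame A [configuration()].
#' @param params A [rose_params()] object.
#' @param hb_energy_cut Bond threshold (default `-0.5 * eps_hb`).
#' @return List with `mean_hb` and `frac_hb` (length 4, molecules with 0,
#'   1, 2, >=3 bonds; sums to 1).
#' @export
hb_statistics <- function(frame, params,
                          hb_energy_cut = -0.5 * params$eps_hb) {
  cnt <- cpp_hb_counts(frame$positions, frame$orientations, frame$box,
                       unclass(params), hb_energy_cut)
  clipped <- pmin(cnt, 3L)
  frac <- tabulate(clipped + 1L, nbins = 4L) / frame$n
  list(mean_hb = mean(cnt), frac_hb = frac)
}

#' Bond-orientational order parameter psi_k
#'
#' `|mean_j exp(i k phi_ij)|` over each molecule's neighbors within
#' `neighbor_cutoff`, averaged over molecules: the standard measure of
#' k-fold orientational order (k = 3 for the honeycomb network, k = 6 for
#' triangular close packing). Molecules without neighbors contribute 0 and
#' are counted in a warning.
#'
#' @param frame A [configuration()].
#' @param k Symmetry order (3 or 6).
#' @param neighbor_cutoff Neighbor distance; the standard choice is the
#'   first minimum of g(r), fallback `1.35 * r_hb`.
#' @return psi_k in `[0, 1]`.
#' @export
bond_order <- function(frame, k = 6, neighbor_cutoff = 1.35) {
  stopifnot(frame$n >= 2, k %in% c(3L, 6L))
  out <- cpp_bond_order(frame$positions, frame$box, as.integer(k),
                        neighbor_cutoff)
  if (out$n_neighborless > 0)
    warning(sprintf("bond_order: %d molecule(s) without neighbors",
                    out$n_neighborless))
  out$psi
}

#' Radial distribution function
#'
#' Standard 2D g(r) histogram over minimum-image pair distances, averaged
#' over frames.
#'
#' @param frames List of [configuration()] frames (or one).
#' @param r_max Maximum distance (default: a little under half the box).
#' @param bin_width Radial bin width.
#' @return data.frame with `r` (bin centers) and `g`.
#' @export
radial_distribution <- function(frames, r_max = NULL, bin_width = 0.02) {
  if (inherits(frames, "configuration")) frames <- list(frames)
  r_max <- r_max %||% (0.45 * min(frames[[1]]$box))
  breaks <- seq(0, r_max, by = bin_width)
  if (length(breaks) < 3) stop("radial_distribution: r_max too small")
  r_max <- tail(breaks, 1)  # histogram must span every counted pair
  counts <- numeric(length(breaks) - 1)
  norm <- 0
  for (fr in frames) {
    d <- cpp_pair_distances(fr$positions, fr$box, r_max)
    counts <- counts + graphics::hist(d, breaks = breaks,
                                      plot = FALSE)$counts
    rho <- fr$n / prod(fr$box)
    norm <- norm + fr$n * (fr$n - 1) / 2 / (fr$n) * rho  # per-frame factor
  }
  shell <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  g <- counts / (shell * norm)
  data.frame(r = breaks[-length(breaks)] + bin_width / 2, g = g)
}

#' Height of the first structure peak of g(r)
#'
#' The "radial structure factor" descriptor: the height of the first local
#' maximum of g(r) beyond `0.5 * sigma_lj`.
#'
#' @param frames List of [configuration()] frames (or one).
#' @param params A [rose_params()] object.
#' @param bin_width Radial bin width.
#' @return Scalar peak height (0 when no pairs are in range).
#' @export
radial_structure_factor <- function(frames, params, bin_width = 0.05) {
  gr <- radial_distribution(frames, bin_width = bin_width)
  sel <- gr$r > 0.5 * params$sigma_lj
  g <- gr$g[sel]
  if (!length(g) || all(g == 0)) return(0)
  # first interior local maximum; fallback to the overall maximum
  im <- which(diff(sign(diff(g))) == -2) + 1
  if (length(im)) g[im[1]] else max(g)
}

#' First minimum of g(r) (psi_k neighbor cutoff helper)
#'
#' @inheritParams radial_structure_factor
#' @param fallback Cutoff returned when no interior minimum is found.
#' @return Scalar distance.
#' @export
first_gr_minimum <- function(frames, params, bin_width = 0.05,
                             fallback = 1.35 * params$r_hb) {
  gr <- radial_distribution(frames, bin_width = bin_width)
  sel <- gr$r > 0.5 * params$sigma_lj
  r <- gr$r[sel]; g <- gr$g[sel]
  ip <- which(diff(sign(diff(g))) == -2) + 1  # first peak
  if (!length(ip)) return(fallback)
  after <- seq(ip[1], length(g))
  im <- which(diff(sign(diff(g[after]))) == 2) + ip[1]
  if (!length(im)) fallback else r[im[1]]
}

#' Mean orientational cosine
#'
#' `mean(cos(3 theta))` over molecules: the 3-fold molecular symmetry makes
#' the plain cosine non-invariant under the arm relabeling
#' `theta -> theta + 120 degrees`, so the third harmonic is used.
#'
#' @param frame A [configuration()].
#' @return Value in `[-1, 1]`.
#' @export
mean_orientation_cosine <- function(frame) {
  mean(cos(3 * frame$orientations))
}

#' Fluctuation response functions from block statistics
#'
#' NPT fluctuation formulas evaluated within each sampling block and
#' averaged across blocks: `C_p = Var(H) / (k_B T^2)` (the kinetic part of
#' H is included in the sampled H), `kappa_T = Var(V) / (k_B T <V>)`,
#' `alpha_P = Cov(V, H) / (k_B T^2 <V>)`.
#'
#' @param blocks data.frame with columns `H_var`, `V_var`, `HV_cov`,
#'   `V_mean` (one row per block), as produced by [run_npt()].
#' @param T Temperature.
#' @return List with `c_p`, `kappa_T`, `alpha_P`, each with a `_se` block
#'   standard error.
#' @export
response_functions <- function(blocks, T) {
  stopifnot(nrow(blocks) >= 2, T > 0)
  cp <- blocks$H_var / (.kB * T^2)
  kt <- blocks$V_var / (.kB * T * blocks$V_mean)
  ap <- blocks$HV_cov / (.kB * T^2 * blocks$V_mean)
  se <- function(x) sd(x) / sqrt(length(x))
  list(c_p = mean(cp), c_p_se = se(cp),
       kappa_T = mean(kt), kappa_T_se = se(kt),
       alpha_P = mean(ap), alpha_P_se = se(ap))
}

#' The per-phase-point observable set
#'
#' Condenses an NPT run into the 15 quantities used as machine-learning
#' descriptors: enthalpy (per molecule), number density, isothermal
#' compressibility, thermal expansion coefficient, heat capacity (per
#' molecule), diffusion coefficient, radial structure factor, mean
#' orientational cosine, mean hydrogen bonds per molecule and the fractions
#' of molecules with 0/1/2/3 bonds, and the psi_3 and psi_6
#' bond-orientational order parameters.
#'
#' @param run An `md_run` from [run_npt()] (must contain frames).
#' @return Named list of class `observable_set` with a `se` attribute
#'   carrying available block standard errors.
#' @export
observable_set <- function(run) {
  stopifnot(inherits(run, "md_run"), length(run$frames) >= 2)
  n <- run$protocol$n
  b <- run$blocks
  resp <- if (nrow(b) >= 2) response_functions(b, run$T) else
    list(c_p = NA, c_p_se = NA, kappa_T = NA, kappa_T_se = NA,
         alpha_P = NA, alpha_P_se = NA)
  dif <- diffusion_coefficient(run$unwrapped, run$frame_times,
                               blocks = min(4, length(run$unwrapped) %/% 4))
  cutoff <- first_gr_minimum(run$frames, run$params)
  per_frame <- lapply(run$frames, function(fr) {
    hb <- hb_statistics(fr, run$params)
    c(mean_hb = hb$mean_hb, frac0 = hb$frac_hb[1], frac1 = hb$frac_hb[2],
      frac2 = hb$frac_hb[3], frac3 = hb$frac_hb[4],
      cos3 = mean_orientation_cosine(fr),
      psi3 = suppressWarnings(bond_order(fr, 3, cutoff)),
      psi6 = suppressWarnings(bond_order(fr, 6, cutoff)))
  })
  pf <- do.call(rbind, per_frame)
  pfm <- colMeans(pf)
  pfse <- apply(pf, 2, function(x) sd(x) / sqrt(length(x)))
  se_b <- function(x) sd(x) / sqrt(length(x))
  obs <- list(
    enthalpy = mean(b$H_mean) / n,
    density = n / mean(b$V_mean),
    kappa_T = resp$kappa_T,
    alpha_P = resp$alpha_P,
    c_p = resp$c_p / n,
    diffusion = dif$D,
    radial_structure_factor = radial_structure_factor(run$frames,
                                                      run$params),
    mean_orientation_cosine = unname(pfm["cos3"]),
    mean_hb = unname(pfm["mean_hb"]),
    frac_hb_0 = unname(pfm["frac0"]),
    frac_hb_1 = unname(pfm["frac1"]),
    frac_hb_2 = unname(pfm["frac2"]),
    frac_hb_3 = unname(pfm["frac3"]),
    psi3 = unname(pfm["psi3"]),
    psi6 = unname(pfm["psi6"]))
  attr(obs, "se") <- list(
    enthalpy = se_b(b$H_mean) / n, density = NA,
    kappa_T = resp$kappa_T_se, alpha_P = resp$alpha_P_se,
    c_p = resp$c_p_se / n, diffusion = dif$se,
    mean_orientation_cosine = unname(pfse["cos3"]),
    mean_hb = unname(pfse["mean_hb"]))
  class(obs) <- "observable_set"
  obs
}

#' Names of the observable-set quantities, in canonical column order
#' @return Character vector of length 15.
#' @export
observable_names <- function() {
  c("enthalpy", "density", "kappa_T", "alpha_P", "c_p", "diffusion",
    "radial_structure_factor", "mean_orientation_cosine", "mean_hb",
    "frac_hb_0", "frac_hb_1", "frac_hb_2", "frac_hb_3", "psi3", "psi6")
}
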