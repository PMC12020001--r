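#' Nested-sampling configuration
#'
#' Settings for constant-pressure nested sampling. Production values follow
#' the study protocol (32 particles, K = 500 live configurations, walk
#' length L = 5000, 500,000 iterations); tests use desk-scale values.
#'
#' @param n_particles Number of molecules.
#' @param K Live-set size (>= 2).
#' @param L Walk length: each replacement walks `L * N` single-particle
#'   sub-steps, with one volume attempt per `N` sub-steps.
#' @param n_iter Number of enthalpy levels to record.
#' @param pressure Reduced pressure of the run.
#' @param V0 Upper volume bound; defaults to `100 * N * r_hb^2` so that
#'   `k_B T << p V0` for all analysis temperatures `T* <= 1`.
#' @param seed RNG seed.
#' @return Object of class `ns_config`.
#' @export
ns_config <- function(n_particles = 32, K = 500, L = 5000, n_iter = 500000,
                      pressure = 1, V0 = NULL, seed = 1) {
  stopifnot(K >= 2, L >= 1, n_iter >= 1, n_particles >= 1, pressure > 0)
  structure(list(n_particles = n_particles, K = K, L = L, n_iter = n_iter,
                 pressure = pressure,
                 V0 = V0 %||% (100 * n_particles), seed = seed),
            class = "ns_config")
}

#' Constant-pressure nested sampling
#'
#' Builds a decreasing sequence of configurational enthalpy levels
#' `H_i = U + pV`. A live set of `K` configurations (uniform positions and
#' orientations in an isotropically rescalable square cell, volume uniform
#' with the `V^N` configuration-space measure on `(0, V0]`) is iteratively
#' compressed: at each iteration the highest-enthalpy member sets the new
#' limit `H_lim` and is replaced by a clone of a random survivor walked
#' `L * N` single-particle sub-steps (plus one volume attempt per `N`
#' sub-steps), every move accepted only below `H_lim`. The enclosed
#' phase-space volume obeys `log chi_i = i * log(K / (K + 1))` exactly by
#' construction. Move sizes are auto-tuned toward ~50% acceptance.
#'
#' @param cfg An [ns_config()].
#' @param params A [rose_params()] object.
#' @return Object of class `ns_run` with `enthalpy_levels`, `volumes`,
#'   `log_chi`, `pressure`, `n_particles` and `meta`.
#' @export
ns_sample <- function(cfg, params) {
  set.seed(cfg$seed)
  N <- cfg$n_particles
  p <- cfg$pressure
  par <- unclass(params)
  live <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    V <- runif(1)^(1 / (N + 1)) * cfg$V0   # V^N measure on (0, V0]
    L <- sqrt(V)
    pos <- cbind(runif(N, 0, L), runif(N, 0, L))
    ori <- runif(N, 0, 2 * pi)
    U <- cpp_total_energy(pos, ori, c(L, L), par)
    live[[k]] <- list(pos = pos, ori = ori, V = V, U = U, H = U + p * V)
  }
  H_levels <- V_levels <- numeric(cfg$n_iter)
  step <- 0.3 * sqrt(cfg$V0 / N)  # particle move size, auto-tuned
  vstep <- 0.3                    # ln-volume move size
  n_acc <- n_try <- 0
  Hs <- vapply(live, `[[`, numeric(1), "H")
  for (i in seq_len(cfg$n_iter)) {
    worst <- which.max(Hs)
    H_lim <- Hs[worst]
    H_levels[i] <- H_lim
    V_levels[i] <- live[[worst]]$V
    seed_idx <- if (cfg$K > 1) {
      cand <- sample.int(cfg$K, 1)
      if (cand == worst) setdiff(seq_len(cfg$K), worst)[
        sample.int(cfg$K - 1, 1)] else cand
    } else worst
    w <- live[[seed_idx]]
    res <- cpp_ns_walk(w$pos, w$ori, w$V, w$U, H_lim, p,
                       as.integer(cfg$L), step, vstep, cfg$V0, par)
    w <- list(pos = res$pos, ori = res$ori, V = res$V, U = res$U,
              H = res$U + p * res$V)
    n_acc <- n_acc + res$acc
    n_try <- n_try + res$tries
    live[[worst]] <- w
    Hs[worst] <- w$H
    if (i %% 20 == 0) {  # gentle auto-tuning toward ~50% acceptance
      acc <- if (n_try > 0) n_acc / n_try else 0.5
      if (acc < 0.35) step <- step * 0.8
      if (acc > 0.65) step <- min(step * 1.2, sqrt(cfg$V0))
      if (acc == 0)
        warning(sprintf("ns_sample: walk stalled at iteration %d", i))
      n_acc <- n_try <- 0
    }
  }
  structure(list(enthalpy_levels = H_levels,
                 volumes = V_levels,
                 log_chi = seq_len(cfg$n_iter) * log(cfg$K / (cfg$K + 1)),
                 pressure = p, n_particles = N, meta = cfg),
            class = "ns_run")
}

#' Thermodynamics from a nested-sampling run
#'
#' Evaluates the constant-pressure partition function on a temperature grid
#' from the recorded enthalpy levels and phase-space volumes, using
#' log-sum-exp-stable weights `w_i proportional to
#' (chi_{i-1} - chi_{i+1}) / 2 * exp(-H_i / T)`. The kinetic prefactor of
#' the partition function only adds a temperature-smooth constant to
#' `log Delta` and cancels in all response functions; it is absorbed into
#' the kinetic heat-capacity term. Returns the mean enthalpy, heat
#' capacity (configurational enthalpy variance over `T^2` plus the
#' `dof/2` kinetic contribution), isothermal compressibility
#' `Var(V) / (k_B T <V>)` and thermal expansion coefficient
#' `Cov(V, H) / (k_B T^2 <V>)` (the per-level volume record enables the
#' latter two).
#'
#' @param run An `ns_run`.
#' @param T_grid Positive temperature grid.
#' @return Object of class `thermo_curves`: a data.frame with columns
#'   `T`, `H_mean`, `c_p`, `kappa_T`, `alpha_P`, plus a `truncated` logical
#'   column flagging temperatures whose weight concentrates on the last
#'   recorded level (below the resolvable range).
#' @export
partition_thermo <- function(run, T_grid) {
  stopifnot(length(run$enthalpy_levels) > 0, all(T_grid > 0))
  H <- run$enthalpy_levels
  V <- run$volumes
  n <- length(H)
  K <- run$meta$K
  lf <- log(K / (K + 1))
  # (chi_{i-1} - chi_{i+1})/2 = chi_0 f^i (1/f - f)/2: constant in i up to f^i
  log_shell <- seq_len(n) * lf
  dof_kin <- 3 * run$n_particles / 2
  out <- lapply(T_grid, function(Tt) {
    lw <- log_shell - H / Tt
    lw <- lw - max(lw)
    w <- exp(lw)
    w <- w / sum(w)
    Hm <- sum(w * H)
    Hv <- sum(w * (H - Hm)^2)
    Vm <- sum(w * V)
    Vv <- sum(w * (V - Vm)^2)
    HVc <- sum(w * (H - Hm) * (V - Vm))
    data.frame(T = Tt,
               H_mean = Hm + dof_kin * .kB * Tt,
               c_p = Hv / Tt^2 + dof_kin * .kB,
               kappa_T = Vv / (.kB * Tt * Vm),
               alpha_P = HVc / (.kB * Tt^2 * Vm),
               truncated = w[n] > 0.5)
  })
  structure(do.call(rbind, out), class = c("thermo_curves", "data.frame"))
}

#' Nested-sampling error estimate by compression resampling
#'
#' The phase-space compression per level is stochastic: each ratio
#' `chi_i / chi_{i-1}` is Beta(K, 1)-distributed rather than exactly
#' `K / (K + 1)`. Resampling the compression sequence and re-evaluating
#' the thermodynamics yields the standard error of any nested-sampling
#' estimate.
#'
#' @param run An `ns_run`.
#' @param T_grid Temperature grid.
#' @param n_resample Number of resampled compression sequences.
#' @param seed RNG seed for the resampling.
#' @return data.frame with `T`, `H_se`, `c_p_se`.
#' @export
ns_thermo_se <- function(run, T_grid, n_resample = 32, seed = 1) {
  set.seed(seed)
  H <- run$enthalpy_levels
  n <- length(H)
  K <- run$meta$K
  dof_kin <- 3 * run$n_particles / 2
  draws <- replicate(n_resample, {
    log_t <- log(stats::rbeta(n, K, 1))
    log_shell <- cumsum(log_t)
    vapply(T_grid, function(Tt) {
      lw <- log_shell - H / Tt
      lw <- lw - max(lw)
      w <- exp(lw); w <- w / sum(w)
      Hm <- sum(w * H)
      c(Hm + dof_kin * .kB * Tt,
        sum(w * (H - Hm)^2) / Tt^2 + dof_kin * .kB)
    }, numeric(2))
  })
  data.frame(T = T_grid,
             H_se = apply(draws[1, , , drop = FALSE], 2, sd),
             c_p_se = apply(draws[2, , , drop = FALSE], 2, sd))
}

#' Locate response-function extrema
#'
#' Interior local maxima of a thermodynamic curve (e.g. the heat capacity),
#' the standard indicators of candidate phase transitions. Prominence is
#' measured down to the deepest valley separating a peak from a higher
#' point (or the grid edge).
#'
#' @param T Grid of temperatures (>= 5 points).
#' @param values Curve values on the grid.
#' @param prominence_floor Minimum prominence for a peak to be reported.
#' @return data.frame with columns `T`, `value`, `prominence`, sorted by
#'   `T`; zero rows for a monotone curve.
#' @export
find_extrema <- function(T, values, prominence_floor = 0) {
  stopifnot(length(T) >= 5, length(values) == length(T))
  o <- order(T)
  T <- T[o]; v <- values[o]
  n <- length(v)
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  if (length(peaks) == 0)
    return(data.frame(T = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(peaks, function(i) {
    left <- v[seq_len(i - 1)]
    right <- v[seq(i + 1, n)]
    hi_l <- which(left >= v[i])
    hi_r <- which(right >= v[i])
    base_l <- min(left[seq(if (length(hi_l)) max(hi_l) else 1, i - 1)])
    base_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) else n - i)])
    v[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence_floor
  data.frame(T = T[peaks[keep]], value = v[peaks[keep]],
             prominence = prom[keep])
}

#' Persist and reload a nested-sampling run
#'
#' The level sequence goes to CSV (`i, H_i, V_i, log_chi_i`) with a JSON
#' sidecar holding the [ns_config()].
#'
#' @param run An `ns_run`.
#' @param path CSV path (sidecar gets extension `.json`).
#' @return `write_ns_run` returns `path` invisibly; `read_ns_run` the
#'   restored `ns_run`.
#' @export
write_ns_run <- function(run, path) {
  df <- data.frame(i = seq_along(run$enthalpy_levels),
                   H = run$enthalpy_levels, V = run$volumes,
                   log_chi = run$log_chi)
  write.csv(df, path, row.names = FALSE)
  side <- c(unclass(run$meta), list(pressure = run$pressure))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ns_run
#' @export
read_ns_run <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  cfg <- ns_config(n_particles = side$n_particles, K = side$K, L = side$L,
                   n_iter = side$n_iter, pressure = side$pressure,
                   V0 = side$V0, seed = side$seed)
  structure(list(enthalpy_levels = df$H, volumes = df$V,
                 log_chi = df$log_chi, pressure = side$pressure,
                 n_particles = side$n_particles, meta = cfg),
            class = "ns_run")
}
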