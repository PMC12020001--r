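#' MD state of translating-rotating discs
#'
#' Bundles a [configuration()] with velocities, angular velocities, masses
#' and the force cache. Unwrapped positions are carried alongside the
#' wrapped ones so mean-squared displacements can cross periodic images.
#'
#' @param config A [configuration()].
#' @param velocities N x 2 matrix; if `NULL`, drawn from the
#'   Maxwell-Boltzmann distribution at `T0` with the center-of-mass motion
#'   removed.
#' @param ang_velocities Length-N vector; if `NULL`, Maxwell-Boltzmann at
#'   `T0`.
#' @param T0 Temperature used to draw missing velocities.
#' @param mass Molecular mass (reduced units; default 1).
#' @param inertia Moment of inertia. The model never states one; the default
#'   `m r_hb^2 / 4 = 0.25` only sets the rotational timescale, not any
#'   equilibrium average.
#' @param params A [rose_params()] for the initial force evaluation.
#' @return Object of class `md_state`.
#' @export
md_state <- function(config, velocities = NULL, ang_velocities = NULL,
                     T0 = 0.2, mass = 1, inertia = 0.25,
                     params = rose_params("mb")) {
  n <- config$n
  if (is.null(velocities)) {
    velocities <- matrix(rnorm(2 * n, sd = sqrt(.kB * T0 / mass)), n, 2)
    if (n > 1) {
      velocities <- sweep(velocities, 2, colMeans(velocities))
      # exact equipartition start: K_trans = (N - 1) k_B T after COM
      # removal (global rescaling thermostats preserve the trans/rot
      # split, so an unlucky initial draw would otherwise persist in
      # weakly coupled systems)
      kt <- 0.5 * mass * sum(velocities^2)
      if (kt > 0)
        velocities <- velocities * sqrt((n - 1) * .kB * T0 / kt)
    }
  }
  if (is.null(ang_velocities)) {
    ang_velocities <- rnorm(n, sd = sqrt(.kB * T0 / inertia))
    kr <- 0.5 * inertia * sum(ang_velocities^2)
    if (kr > 0)
      ang_velocities <- ang_velocities * sqrt(n * .kB * T0 / (2 * kr))
  }
  st <- list(config = config,
             velocities = velocities,
             ang_velocities = as.numeric(ang_velocities),
             mass = mass, inertia = inertia,
             unwrapped = config$positions,
             time = 0,
             force_cache = NULL)
  class(st) <- "md_state"
  st$force_cache <- forces_and_torques(config, params)
  st
}

#' Degrees of freedom of the thermostatted system
#'
#' 2N translational + N rotational, minus 2 for the frozen center-of-mass
#' momentum (rotational motion is thermostatted along with translation).
#'
#' @param state An `md_state`.
#' @return Integer count.
#' @export
md_dof <- function(state) max(1L, 3L * state$config$n - 2L)

#' Kinetic energy and temperature
#'
#' @param state An `md_state`.
#' @return `kinetic_energy`: list with `translational`, `rotational`,
#'   `total`. `kinetic_temperature`: instantaneous temperature
#'   `2 K / (dof k_B)`.
#' @export
kinetic_energy <- function(state) {
  kt <- 0.5 * state$mass * sum(state$velocities^2)
  kr <- 0.5 * state$inertia * sum(state$ang_velocities^2)
  list(translational = kt, rotational = kr, total = kt + kr)
}

#' @rdname kinetic_energy
#' @export
kinetic_temperature <- function(state) {
  2 * kinetic_energy(state)$total / (md_dof(state) * .kB)
}

#' Instantaneous virial pressure
#'
#' 2D virial pressure `(K_trans + W/2) / A` where `W = sum over pairs of
#' -dU/dr * r` (only the distance derivative of the pair potential does
#' virial work; torques do none).
#'
#' @param state An `md_state` (force cache must be current).
#' @return Scalar pressure.
#' @export
virial_pressure <- function(state) {
  kt <- 0.5 * state$mass * sum(state$velocities^2)
  (kt + 0.5 * state$force_cache$virial) / prod(state$config$box)
}

#' One velocity-Verlet step
#'
#' Advances positions, orientations, velocities and angular velocities by
#' `dt` using the cached forces; recomputes forces once per step.
#'
#' @param state An `md_state`.
#' @param params A [rose_params()] object.
#' @param dt Time step.
#' @return Updated `md_state`.
#' @export
vv_step <- function(state, params, dt) {
  f <- state$force_cache
  if (is.null(f)) f <- forces_and_torques(state$config, params)
  inv_m <- 1 / state$mass
  inv_i <- 1 / state$inertia
  v_half <- state$velocities + 0.5 * dt * inv_m * f$forces
  w_half <- state$ang_velocities + 0.5 * dt * inv_i * f$torques
  disp <- dt * v_half
  state$unwrapped <- state$unwrapped + disp
  state$config$positions <-
    wrap_positions(state$config$positions + disp, state$config$box)
  state$config$orientations <- state$config$orientations +
    dt * w_half
  f2 <- forces_and_torques(state$config, params)
  state$velocities <- v_half + 0.5 * dt * inv_m * f2$forces
  state$ang_velocities <- w_half + 0.5 * dt * inv_i * f2$torques
  state$force_cache <- f2
  state$time <- state$time + dt
  state
}

#' Thermostats
#'
#' `"rescale"` scales all velocities so the kinetic temperature equals
#' `target_T` exactly. `"stochastic_rescale"` is the canonical-sampling
#' stochastic velocity rescaling: the kinetic energy is propagated toward
#' its canonical distribution with relaxation time `tau`, so long-run
#' kinetic temperature averages to `target_T` while its fluctuations remain
#' canonical. In the `tau -> Inf` limit the stochastic mode leaves
#' velocities unchanged.
#'
#' @param state An `md_state`.
#' @param target_T Target temperature (> 0).
#' @param mode `"rescale"` or `"stochastic_rescale"`.
#' @param tau Coupling time constant (stochastic mode).
#' @param dt Time step (stochastic mode).
#' @return Updated `md_state`.
#' @export
apply_thermostat <- function(state, target_T,
                             mode = c("rescale", "stochastic_rescale"),
                             tau = 0.01, dt = 0.001) {
  mode <- match.arg(mode)
  stopifnot(target_T > 0)
  K <- kinetic_energy(state)$total
  if (K == 0) {
    if (mode == "rescale") warning("apply_thermostat: zero kinetic energy")
    return(state)
  }
  dof <- md_dof(state)
  Kbar <- 0.5 * dof * .kB * target_T
  if (mode == "rescale") {
    lambda <- sqrt(Kbar / K)
  } else {
    c1 <- exp(-dt / tau)
    r1 <- rnorm(1)
    rsum <- if (dof > 1) rchisq(1, df = dof - 1) else 0
    a2 <- c1 +
      (1 - c1) * Kbar * (r1^2 + rsum) / (dof * K) +
      2 * r1 * sqrt(c1 * (1 - c1) * Kbar / (dof * K))
    lambda <- sqrt(max(a2, 0))
  }
  state$velocities <- state$velocities * lambda
  state$ang_velocities <- state$ang_velocities * lambda
  state
}

#' Barostats
#'
#' Isotropic area rescaling toward the target pressure. `"berendsen"` uses
#' the weak-coupling rule `A' = A (1 + dt * kappa / tau * (p - p0))`;
#' `"stochastic_cell_rescale"` integrates the overdamped ln-area Langevin
#' equation whose stationary distribution is the NPT area distribution,
#' adding the noise term `sqrt(2 k_B T kappa / (A tau) dt)`. Positions (and
#' unwrapped positions) are scaled with the box; velocities are untouched.
#'
#' @param state An `md_state`.
#' @param target_p Target pressure (> 0).
#' @param mode `"berendsen"` or `"stochastic_cell_rescale"`.
#' @param tau Coupling time constant.
#' @param dt Time step.
#' @param target_T Temperature entering the noise amplitude (stochastic
#'   mode).
#' @param kappa Dimensionless effective compressibility of the coupling.
#' @return Updated `md_state`.
#' @export
apply_barostat <- function(state, target_p,
                           mode = c("berendsen", "stochastic_cell_rescale"),
                           tau = 0.1, dt = 0.001, target_T = 1,
                           kappa = 1) {
  mode <- match.arg(mode)
  stopifnot(target_p > 0)
  A <- prod(state$config$box)
  p_inst <- virial_pressure(state)
  if (mode == "berendsen") {
    scale_A <- 1 + dt * kappa / tau * (p_inst - target_p)
    if (scale_A <= 0) {
      warning("apply_barostat: negative proposed area rejected")
      return(state)
    }
  } else {
    deps <- -(kappa / tau) * (target_p - p_inst) * dt +
      sqrt(2 * .kB * target_T * kappa * dt / (A * tau)) * rnorm(1)
    scale_A <- exp(deps)
  }
  s <- sqrt(scale_A)
  state$config$box <- state$config$box * s
  state$config$positions <-
    wrap_positions(state$config$positions * s, state$config$box)
  state$unwrapped <- state$unwrapped * s
  state
}

#' MD protocol
#'
#' Simulation schedule and couplings for [run_npt()]. Defaults follow the
#' production protocol (time step 0.001, 100,000 equilibration steps, 20
#' sampling series of 100,000 steps, thermostat coupling 0.01, barostat
#' coupling 0.1); tests and desk-scale runs pass smaller counts.
#'
#' @param n Number of molecules (production default 200).
#' @param dt Time step.
#' @param n_equil Equilibration steps (velocity rescale + Berendsen).
#' @param n_series Number of sampling series.
#' @param series_len Steps per series (stochastic rescaling + stochastic
#'   cell rescale).
#' @param tau_T,tau_P Thermostat/barostat coupling constants.
#' @param kappa Barostat effective compressibility.
#' @param sample_interval Steps between scalar samples (H, A, T_kin).
#' @param frame_interval Steps between stored frames (0 = none).
#' @param density_guess Initial number density for random initialization.
#' @param init `"random"`, `"honeycomb"`, `"triangular"`, or `"auto"`
#'   (lattice seeds at low temperature, random otherwise; shortens
#'   equilibration at desk scale).
#' @param seed RNG seed for the whole run.
#' @return Object of class `md_protocol`.
#' @export
md_protocol <- function(n = 200, dt = 0.001, n_equil = 100000,
                        n_series = 20, series_len = 100000,
                        tau_T = 0.01, tau_P = 0.1, kappa = 1,
                        sample_interval = 10, frame_interval = 500,
                        density_guess = 0.4,
                        init = c("random", "honeycomb", "triangular", "auto"),
                        seed = 1) {
  stopifnot(dt > 0, n_equil >= 0, n_series >= 1, series_len >= 1, n >= 1)
  structure(list(n = n, dt = dt, n_equil = n_equil, n_series = n_series,
                 series_len = series_len, tau_T = tau_T, tau_P = tau_P,
                 kappa = kappa, sample_interval = sample_interval,
                 frame_interval = frame_interval,
                 density_guess = density_guess,
                 init = match.arg(init), seed = seed),
            class = "md_protocol")
}

initial_config_for <- function(protocol, params, T, p) {
  init <- protocol$init
  if (init == "auto")
    init <- if (T < 0.15) (if (p < 4) "honeycomb" else "triangular")
            else "random"
  n <- protocol$n
  if (init == "honeycomb") {
    nc <- max(1L, round(sqrt(n / 4)))
    make_honeycomb(nc, bond_length = params$r_hb)
  } else if (init == "triangular") {
    nc <- max(1L, round(sqrt(n / 2)))
    make_triangular(nc, spacing = 2^(1 / 6) * params$sigma_lj)
  } else {
    make_initial_configuration(n, protocol$density_guess,
                               seed = protocol$seed, params = params)
  }
}

#' NPT molecular dynamics run
#'
#' Equilibrates with velocity rescaling and the Berendsen barostat, then
#' samples in `n_series` blocks under stochastic velocity rescaling and the
#' stochastic cell rescale barostat. Per block, the means, variances and
#' covariance of the instantaneous enthalpy `H = U + K + pA` and area `A`
#' are retained (basis for error bars and fluctuation response functions),
#' along with kinetic temperature and virial pressure means. Frames
#' (wrapped and unwrapped positions plus orientations) are stored every
#' `frame_interval` steps of the sampling phase.
#'
#' @param protocol An [md_protocol()].
#' @param params A [rose_params()] object.
#' @param T,p Target reduced temperature and pressure.
#' @return Object of class `md_run`: `blocks` (one row per series),
#'   `frames`, `frame_times`, `unwrapped`, `final_state`, plus the inputs.
#' @export
run_npt <- function(protocol, params, T, p) {
  stopifnot(T > 0, p > 0)
  set.seed(protocol$seed)
  cfg <- initial_config_for(protocol, params, T, p)
  st <- md_state(cfg, T0 = T, params = params)
  dt <- protocol$dt
  for (k in seq_len(protocol$n_equil)) {
    st <- vv_step(st, params, dt)
    st <- apply_thermostat(st, T, "rescale")
    st <- apply_barostat(st, p, "berendsen", tau = protocol$tau_P,
                         dt = dt, target_T = T, kappa = protocol$kappa)
    if (!all(is.finite(st$velocities)))
      stop("run_npt: integration blow-up during equilibration")
  }
  blocks <- vector("list", protocol$n_series)
  frames <- list(); frame_times <- numeric(0); unwrapped <- list()
  for (b in seq_len(protocol$n_series)) {
    Hs <- As <- Ts <- Ps <- numeric(0)
    for (k in seq_len(protocol$series_len)) {
      st <- vv_step(st, params, dt)
      st <- apply_thermostat(st, T, "stochastic_rescale",
                             tau = protocol$tau_T, dt = dt)
      st <- apply_barostat(st, p, "stochastic_cell_rescale",
                           tau = protocol$tau_P, dt = dt, target_T = T,
                           kappa = protocol$kappa)
      if (k %% protocol$sample_interval == 0) {
        A <- prod(st$config$box)
        H <- st$force_cache$energy + kinetic_energy(st)$total + p * A
        Hs <- c(Hs, H); As <- c(As, A)
        Ts <- c(Ts, kinetic_temperature(st))
        Ps <- c(Ps, virial_pressure(st))
      }
      if (protocol$frame_interval > 0 &&
          k %% protocol$frame_interval == 0) {
        frames[[length(frames) + 1]] <- st$config
        unwrapped[[length(unwrapped) + 1]] <- st$unwrapped
        frame_times <- c(frame_times, st$time)
      }
    }
    if (!all(is.finite(Hs)))
      stop("run_npt: integration blow-up during sampling")
    blocks[[b]] <- data.frame(series = b,
                              H_mean = mean(Hs), H_var = var_or0(Hs),
                              V_mean = mean(As), V_var = var_or0(As),
                              HV_cov = cov_or0(Hs, As),
                              T_mean = mean(Ts), p_mean = mean(Ps))
  }
  structure(list(blocks = do.call(rbind, blocks),
                 frames = frames, frame_times = frame_times,
                 unwrapped = unwrapped,
                 final_state = st,
                 T = T, p = p, params = params, protocol = protocol),
            class = "md_run")
}

var_or0 <- function(x) if (length(x) > 1) var(x) else 0
cov_or0 <- function(x, y) if (length(x) > 1) cov(x, y) else 0

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("NPT run: N = %d, T* = %g, p* = %g; %d series\n",
              x$protocol$n, x$T, x$p, nrow(x$blocks)))
  cat(sprintf("  <T_kin> = %.4g, <p_virial> = %.4g, <A> = %.4g\n",
              mean(x$blocks$T_mean), mean(x$blocks$p_mean),
              mean(x$blocks$V_mean)))
  invisible(x)
}
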