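# Generative fixtures and independent oracles shared across tests.

mb <- rose_params("mb")
real_par <- rose_params("real")
ideal_par <- rose_params("custom", eps_lj = 0, sigma_lj = 1, eps_hb = 0,
                         r_fwhm = 0.2)
lj_only <- rose_params("custom", eps_lj = 0.1, sigma_lj = 0.7, eps_hb = 0,
                       r_fwhm = 0.2)

# Dimer configuration at given separation/orientations in a large box.
make_dimer <- function(r, phi_i = 0, phi_j = 0, box = 20) {
  configuration(rbind(c(box / 2, box / 2), c(box / 2 + r, box / 2)),
                c(phi_i, phi_j), c(box, box))
}

# Orientations that make the i->j bond ideal for both molecules: molecule i's
# arm (body-frame pi/3) points along +x, molecule j's along -x.
ideal_pair_oris <- function() c(-pi / 3, pi - pi / 3)

# --- planted-partition fixtures ------------------------------------------

# Three ADF-template "phases": distinct smooth 125-dim templates plus noise.
planted_adf_table <- function(n_per_phase = 20, noise = 0.01, seed = 42) {
  set.seed(seed)
  grid <- seq_len(125)
  bump <- function(mu, s) exp(-(grid - mu)^2 / (2 * s^2))
  templates <- rbind(bump(20, 6) + bump(80, 10),
                     bump(50, 8) + 0.6 * bump(110, 6),
                     0.8 * bump(35, 12) + bump(95, 5))
  rows <- do.call(rbind, lapply(1:3, function(k)
    templates[rep(k, n_per_phase), ] +
      matrix(rnorm(n_per_phase * 125, sd = noise), n_per_phase)))
  pts <- data.frame(T = rep(seq_len(n_per_phase), 3) / 100,
                    p = rep(1:3, each = n_per_phase))
  list(table = feature_table(pts, rows, paste0("adf_", grid)),
       truth = rep(0:2, each = n_per_phase))
}

# Diffusion mixture (gas broad and high, two narrow liquid bands, tight
# near-zero solid band) with 4 planted solid sub-populations in the other
# 14 property dimensions.
planted_property_table <- function(seed = 42, n_gas = 20, n_liq_a = 24,
                                   n_liq_b = 28, n_solid_each = 16) {
  set.seed(seed)
  n_solid <- 4 * n_solid_each
  n <- n_gas + n_liq_a + n_liq_b + n_solid
  state <- rep(0:3, c(n_gas, n_liq_a, n_liq_b, n_solid))
  diffusion <- c(runif(n_gas, 0.5, 1.5),
                 rnorm(n_liq_a, 0.25, 0.01),
                 rnorm(n_liq_b, 0.12, 0.004),
                 abs(rnorm(n_solid, 0.001, 0.0002)))
  other_names <- setdiff(observable_names(), "diffusion")
  x <- matrix(rnorm(n * 14, sd = 0.3), n, 14)
  centers <- matrix(rnorm(4 * 14, sd = 3), 4, 14)  # well-separated solids
  sub <- rep(0:3, each = n_solid_each)
  solid_rows <- which(state == 3)
  x[solid_rows, ] <- centers[sub + 1, ] +
    matrix(rnorm(n_solid * 14, sd = 0.05), n_solid, 14)
  raw <- cbind(diffusion = diffusion, x)
  colnames(raw) <- c("diffusion", other_names)
  raw <- raw[, observable_names()]
  pts <- data.frame(T = seq_len(n) / 100, p = rep(1, n))
  list(table = feature_table(pts, standardize_columns(raw),
                             observable_names(), standardized = TRUE),
       diffusion = diffusion, state = state,
       solid_sub = ifelse(state == 3, sub[match(seq_len(n), solid_rows)],
                          NA))
}

# --- independent oracles --------------------------------------------------

# NPT Monte Carlo for the 2D ideal gas: volume sampled by Metropolis in ln V
# with the V^N configuration-space weight. Returns sampled areas.
ideal_gas_npt_mc <- function(n_particles, T, p, n_steps = 20000,
                             V_init = NULL, seed = 1) {
  set.seed(seed)
  V <- V_init %||% (n_particles * T / p)
  out <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    Vn <- V * exp(runif(1, -0.1, 0.1))
    log_acc <- -(p / T) * (Vn - V) + (n_particles + 1) * log(Vn / V)
    if (log(runif(1)) < log_acc) V <- Vn
    out[i] <- V
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NPT Metropolis Monte Carlo oracle for a small interacting system, using
# the scalar R pair energies (independent of the compiled kernel and of
# nested sampling). Returns configurational enthalpy samples U + pV.
npt_mc_enthalpy <- function(params, n_particles, T, p, n_steps = 30000,
                            V0 = 200, seed = 1) {
  set.seed(seed)
  L <- sqrt(V0) / 2
  pos <- matrix(runif(2 * n_particles, 0, L), ncol = 2)
  ori <- runif(n_particles, 0, 2 * pi)
  tot_U <- function(pos, ori, L) {
    e <- 0
    for (i in seq_len(n_particles - 1))
      for (j in seq(i + 1, n_particles)) {
        d <- pos[j, ] - pos[i, ]
        d <- d - L * round(d / L)
        e <- e + pair_energy(c(0, 0), d, ori[i], ori[j], params)$total
      }
    e
  }
  U <- tot_U(pos, ori, L)
  H_out <- numeric(0)
  step <- 0.5
  for (s in seq_len(n_steps)) {
    i <- sample.int(n_particles, 1)
    old_p <- pos[i, ]; old_o <- ori[i]
    pos[i, ] <- (pos[i, ] + runif(2, -step, step)) %% L
    ori[i] <- ori[i] + runif(1, -pi, pi)
    U_new <- tot_U(pos, ori, L)
    if (log(runif(1)) < -(U_new - U) / T) U <- U_new
    else { pos[i, ] <- old_p; ori[i] <- old_o }
    # volume move
    Ln <- L * exp(runif(1, -0.05, 0.05))
    if (Ln^2 <= V0) {
      pos_n <- pos * (Ln / L)
      U_n <- tot_U(pos_n, ori, Ln)
      log_acc <- -(U_n - U + p * (Ln^2 - L^2)) / T +
        (n_particles + 1) * 2 * log(Ln / L)
      if (log(runif(1)) < log_acc) { pos <- pos_n; L <- Ln; U <- U_n }
    }
    if (s > n_steps / 4 && s %% 10 == 0)
      H_out <- c(H_out, U + p * L^2)
  }
  H_out
}

# Exhaustive label-matching oracle: best total agreement over all injective
# assignments of predicted labels to reference labels.
exhaustive_agreement <- function(pred, ref) {
  up <- unique(pred); ur <- unique(ref)
  if (length(up) > length(ur)) return(exhaustive_agreement(ref, pred))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (target in perms(ur)) {
    m <- 0
    for (k in seq_along(up))
      m <- m + sum(pred == up[k] & ref == target[k])
    best <- max(best, m)
  }
  best / length(pred)
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (v in 0:next_max)
      rec(c(labels, v), max(next_max, v + 1))
  }
  rec(integer(0), 0)
  out
}
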