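test_that("honeycomb ADF shows the hydrogen-bond peaks at the right angles", {
  hc <- make_honeycomb(4)
  a_bond <- compute_adf(hc, 1.0, params = mb)
  expect_equal(count_adf_peaks(a_bond), 1)
  expect_lt(abs(a_bond$angle[which.max(a_bond$density)]), a_bond$bin_width)
  a_second <- compute_adf(hc, 1.73, params = mb)
  expect_equal(count_adf_peaks(a_second), 2)
  pk <- a_second$angle[a_second$density > 0]
  expect_true(all(abs(abs(pk) - 30) < 2 * a_second$bin_width))
  # normalization: unit integral over the window
  expect_equal(sum(a_bond$density) * a_bond$bin_width, 1)
})

test_that("ADF of a random gas is flat within Poisson noise", {
  frames <- lapply(1:40, function(s) make_gas(600, c(30, 30), 0.01,
                                              seed = 100 + s))
  adf <- compute_adf(frames, 1.0, r_halfwidth = 0.5, params = mb)
  expect_gt(adf$n_pairs, 1e5)
  expect_lt(max(adf$density) / min(adf$density), 1.2)
  # empty shell: zero density, zero counted pairs
  empty <- compute_adf(make_gas(20, c(40, 40), 5, seed = 1), 1.0,
                       r_halfwidth = 0.05, params = mb)
  expect_equal(empty$n_pairs, 0)
  expect_true(all(empty$density == 0))
  expect_equal(count_adf_peaks(empty), 0)
})

test_that("ADF is invariant under global rotation and relabeling", {
  g <- make_gas(150, c(12, 12), 0.5, seed = 6)
  a0 <- compute_adf(g, 1.0, r_halfwidth = 0.3, params = mb)
  perm <- sample(g$n)
  a1 <- compute_adf(configuration(g$positions[perm, ],
                                  g$orientations[perm], g$box),
                    1.0, r_halfwidth = 0.3, params = mb)
  expect_equal(a1$density, a0$density)
  # rotation by 90 degrees maps the square periodic box onto itself
  rot <- cbind(-g$positions[, 2], g$positions[, 1])
  a2 <- compute_adf(configuration(rot, g$orientations + pi / 2, g$box),
                    1.0, r_halfwidth = 0.3, params = mb)
  # identical up to at most a couple of pairs whose folded angle sits on a
  # bin boundary within floating-point rounding
  expect_lt(sum(abs(a2$counts - a0$counts)), 3)
})

test_that("diffusion: frozen is zero, Brownian slope is recovered, unwrapping works", {
  frames <- replicate(30, matrix(1, 5, 2), simplify = FALSE)
  expect_equal(diffusion_coefficient(frames, seq(0, 2.9, by = 0.1))$D, 0)
  # planted 2D random walk: per-axis step sd s => D = s^2 / (2 dt)
  set.seed(7)
  s <- 0.05; dt <- 0.1; nf <- 400; np <- 200
  steps_x <- matrix(rnorm(nf * np, sd = s), nf, np)
  steps_y <- matrix(rnorm(nf * np, sd = s), nf, np)
  walks <- lapply(seq_len(nf), function(i)
    cbind(colSums(steps_x[seq_len(i), , drop = FALSE]),
          colSums(steps_y[seq_len(i), , drop = FALSE])))
  est <- diffusion_coefficient(walks, seq_len(nf) * dt)
  expect_lt(abs(est$D - s^2 / (2 * dt)) / (s^2 / (2 * dt)), 0.05)
  # a particle drifting across the periodic boundary: the integrator's
  # unwrapped positions keep the ballistic MSD of the unbounded copy
  cfg <- configuration(matrix(c(4.9, 2.5), 1), 0, c(5, 5))
  st <- md_state(cfg, velocities = matrix(c(1, 0), 1),
                 ang_velocities = 0, params = ideal_par)
  un <- list(st$unwrapped)
  for (k in 1:200) {
    st <- vv_step(st, ideal_par, 0.01)
    un[[k + 1]] <- st$unwrapped
  }
  expect_lt(st$config$positions[1, 1], 5)   # wrapped back into the box
  expect_equal(st$unwrapped[1, 1], 4.9 + 2, tolerance = 1e-9)
  est2 <- diffusion_coefficient(un, seq(0, 2, by = 0.01))
  # ballistic motion: MSD = v^2 t^2; the fitted slope over the window is
  # positive and large compared to any wrapping artifact
  expect_gt(est2$D, 0)
})

test_that("hydrogen-bond statistics on reference structures", {
  hc <- make_honeycomb(3)
  hb <- hb_statistics(hc, mb)
  expect_equal(hb$mean_hb, 3)
  expect_equal(hb$frac_hb, c(0, 0, 0, 1))
  oris <- ideal_pair_oris()
  pair <- make_dimer(1, oris[1], oris[2])
  expect_equal(hb_statistics(pair, mb)$mean_hb, 1)
  dilute <- make_gas(30, c(40, 40), mb$r_u * 1.05, seed = 2)
  hb3 <- hb_statistics(dilute, mb)
  expect_equal(hb3$mean_hb, 0)
  expect_equal(hb3$frac_hb[1], 1)
})

test_that("bond-orientational order distinguishes the lattices from gas", {
  expect_equal(bond_order(make_triangular(5), 6, 1.2), 1, tolerance = 1e-9)
  expect_equal(bond_order(make_honeycomb(4), 3, 1.2), 1, tolerance = 1e-9)
  # null value scales like 1/sqrt(neighbors); use a wide enough shell that
  # the random-gas expectation sits clearly below 0.2
  g <- make_gas(200, c(12, 12), 0.3, seed = 3)
  expect_lt(bond_order(g, 6, 3.0), 0.2)
})

test_that("response functions match the ideal-gas oracle and scale correctly", {
  N <- 100; Tt <- 0.3; p <- 0.1
  V <- ideal_gas_npt_mc(N, Tt, p, n_steps = 60000, seed = 5)
  V <- V[-(1:5000)]
  idx <- cut(seq_along(V), 10, labels = FALSE)
  blocks <- do.call(rbind, lapply(split(V, idx), function(v)
    data.frame(H_mean = mean(p * v), H_var = var(p * v), V_mean = mean(v),
               V_var = var(v), HV_cov = cov(v, p * v))))
  resp <- response_functions(blocks, Tt)
  expect_lt(abs(resp$kappa_T * p - 1), 0.1)
  # duplicated identical blocks leave the estimates unchanged
  resp2 <- response_functions(rbind(blocks, blocks), Tt)
  expect_equal(resp2$kappa_T, resp$kappa_T)
  # doubling T with the same raw fluctuations scales C_p by 1/4
  resp3 <- response_functions(blocks, 2 * Tt)
  expect_equal(resp3$c_p, resp$c_p / 4)
})

test_that("mean orientational cosine honors the 3-fold symmetry", {
  box <- c(10, 10)
  pos <- matrix(runif(20, 0, 10), 10, 2)
  expect_equal(mean_orientation_cosine(configuration(pos, rep(0, 10), box)),
               1)
  expect_equal(mean_orientation_cosine(
    configuration(pos, rep(pi / 3, 10), box)), -1)
  set.seed(8)
  big <- configuration(matrix(runif(2e4, 0, 10), 1e4, 2),
                       runif(1e4, 0, 2 * pi), box)
  expect_lt(abs(mean_orientation_cosine(big)), 0.05)
})

test_that("observable sets from a short run are finite and simplex-valued", {
  run <- run_npt(md_protocol(n = 36, n_equil = 500, n_series = 3,
                             series_len = 600, frame_interval = 100,
                             init = "honeycomb", seed = 21),
                 mb, T = 0.1, p = 0.05)
  obs <- observable_set(run)
  v <- unlist(obs[observable_names()])
  expect_true(all(is.finite(v)))
  expect_equal(sum(v[c("frac_hb_0", "frac_hb_1", "frac_hb_2",
                       "frac_hb_3")]), 1, tolerance = 1e-9)
  expect_gte(obs$kappa_T, 0)
  expect_gte(obs$c_p, 0)
  expect_true(obs$psi3 >= 0 && obs$psi3 <= 1)
  expect_true(obs$psi6 >= 0 && obs$psi6 <= 1)
})
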