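test_that("MDS preserves distances of intrinsically 3D data", {
  set.seed(1)
  y <- matrix(rnorm(40 * 3), 40, 3)
  mix <- matrix(rnorm(18), 3, 6)
  tab <- feature_table(data.frame(T = 1:40 / 100, p = 1), y %*% mix,
                       paste0("f", 1:6))
  emb <- reduce(tab, "mds")
  expect_equal(dim(emb$coords), c(40, 3))
  d0 <- dist(feature_matrix(tab))
  d1 <- dist(emb$coords)
  stress <- sqrt(sum((d1 - d0)^2) / sum(d0^2))
  expect_lt(stress, 0.01)
})

test_that("duplicated rows embed to coincident points (mds, isomap)", {
  set.seed(2)
  x <- matrix(rnorm(10 * 4), 10, 4)
  x <- rbind(x, x[1:3, ])
  tab <- feature_table(data.frame(T = 1:13 / 100, p = 1), x,
                       paste0("f", 1:4))
  for (m in c("mds", "isomap")) {
    emb <- reduce(tab, m, hyperparams = list(n_neighbors = 5))
    for (k in 1:3)
      expect_lt(sqrt(sum((emb$coords[10 + k, ] - emb$coords[k, ])^2)),
                1e-6)
  }
})

test_that("embeddings are deterministic under a fixed seed (t-SNE included)", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40 * 3, 0, 0.1), 40), matrix(rnorm(40 * 3, 2, 0.1), 40))
  tab <- feature_table(data.frame(T = 1:80 / 100, p = 1), x,
                       paste0("f", 1:3))
  e1 <- reduce(tab, "tsne", hyperparams = list(max_iter = 400), seed = 9)
  e2 <- reduce(tab, "tsne", hyperparams = list(max_iter = 400), seed = 9)
  expect_identical(e1$coords, e2$coords)
  # spectral embedding needs a connected neighbor graph: one cloud here,
  # and an explicit error on fragmented data
  one <- feature_table(data.frame(T = 1:40 / 100, p = 1),
                       matrix(rnorm(120), 40, 3), paste0("f", 1:3))
  expect_identical(reduce(one, "spectral", seed = 1)$coords,
                   reduce(one, "spectral", seed = 2)$coords)
  expect_error(reduce(tab, "spectral", seed = 1), "disconnected")
})

test_that("clustering recovers separated blobs and handles degenerate input", {
  set.seed(4)
  cen <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(90, 0, 0.01), 30, 3), 2, cen[i, ], "+")))
  truth <- rep(0:2, each = 30)
  pts <- data.frame(T = 1:90, p = 0)
  for (alg in c("kmeans", "ward")) {
    lab <- cluster(x, alg, params = list(n_clusters = 3), seed = 5)$label
    expect_equal(fraction_of_agreement(phase_label_grid(pts, lab),
                                       phase_label_grid(pts, truth)), 1)
  }
  same <- matrix(1, 10, 3)
  lab1 <- cluster(same, "ward", params = list(n_clusters = 1), seed = 1)
  expect_true(all(lab1$label == 0))
  # dbscan with eps below the minimum pairwise distance: everything noise
  spread <- matrix(seq_len(20), 20, 3)
  labn <- cluster(spread, "dbscan",
                  params = list(eps = 0.1, min_pts = 2), seed = 1)
  expect_true(all(labn$label == -1))
  expect_error(cluster(x, "kmeans", params = list(n_clusters = 99)),
               "more clusters than points")
})

test_that("k-distance elbow lands between the density scales", {
  set.seed(5)
  two <- matrix(c(rnorm(30, 0, 0.01), rnorm(30, 10, 0.01)), ncol = 1)
  eps <- eps_from_kdistance(two, 5)
  expect_gt(eps, 1e-4)        # at least the within-cluster scale
  expect_lt(eps, 5)           # well below the between-cluster scale
  labs <- dbscan_fit(two, eps, 5)
  expect_equal(length(unique(labs[labs >= 0])), 2)
  # equally spaced 1D points: eps close to the spacing
  xs <- matrix(seq(0, 1, length.out = 21), ncol = 1)
  eps_u <- eps_from_kdistance(xs, 2)
  expect_gt(eps_u, 0.05 / 2)
  expect_lt(eps_u, 0.05 * 2)
  # k = n - 1 on a tiny set: finite, no crash
  tiny <- matrix(rnorm(5), ncol = 1)
  expect_true(is.finite(eps_from_kdistance(tiny, 4)))
  expect_error(eps_from_kdistance(tiny, 5), "more points than k")
})

test_that("sequential diffusion peeling separates the planted states of matter", {
  set.seed(9)
  dif <- c(runif(25, 0.5, 1.5), rnorm(30, 0.25, 0.01),
           rnorm(40, 0.12, 0.004), abs(rnorm(60, 0.001, 0.0002)))
  truth <- rep(0:3, c(25, 30, 40, 60))
  pts <- data.frame(T = seq_along(dif), p = 0)
  g <- sequential_diffusion_dbscan(pts, dif, min_pts = 8, n_rounds = 3)
  expect_true(attr(g, "complete"))
  expect_identical(attr(g, "groups"),
                   c("gas", "liquid_a", "liquid_b", "solid"))
  expect_equal(length(unique(g$label)), 4)
  agree <- fraction_of_agreement(g, phase_label_grid(pts, truth))
  expect_gte(agree, 0.95)
  # groups ordered by descending mean diffusion
  means <- vapply(0:3, function(l) mean(dif[g$label == l]), numeric(1))
  expect_true(all(diff(means) < 0))
  # degenerate input: one group plus a warning
  expect_warning(
    g1 <- sequential_diffusion_dbscan(pts, rep(0.5, nrow(pts)),
                                      min_pts = 8),
    "no outliers")
  expect_equal(length(unique(g1$label)), 1)
})

test_that("agreement fraction equals the exhaustive assignment oracle", {
  pts3 <- data.frame(T = 1:3, p = 0)
  expect_equal(fraction_of_agreement(phase_label_grid(pts3, c(1, 1, 1)),
                                     phase_label_grid(pts3, c(0, 0, 1))),
               2 / 3)
  # all partition pairs of up to 5 points
  for (n in 3:5) {
    pts <- data.frame(T = seq_len(n), p = 0)
    parts <- all_partitions(n)
    for (a in parts) for (b in parts) {
      expect_equal(
        fraction_of_agreement(phase_label_grid(pts, a),
                              phase_label_grid(pts, b)),
        exhaustive_agreement(a, b))
    }
  }
  # partitions of 6 points against a fixed reference set
  set.seed(6)
  pts6 <- data.frame(T = 1:6, p = 0)
  refs <- list(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 1, 1, 2), rep(0, 6))
  for (a in all_partitions(6)) for (b in refs)
    expect_equal(fraction_of_agreement(phase_label_grid(pts6, a),
                                       phase_label_grid(pts6, b)),
                 exhaustive_agreement(a, b))
})

test_that("agreement is symmetric, permutation invariant, and penalizes noise", {
  set.seed(7)
  pts <- data.frame(T = 1:40, p = 0)
  a <- sample(0:3, 40, replace = TRUE)
  b <- sample(0:2, 40, replace = TRUE)
  ga <- phase_label_grid(pts, a); gb <- phase_label_grid(pts, b)
  expect_equal(fraction_of_agreement(ga, gb),
               fraction_of_agreement(gb, ga))
  perm <- c(2L, 0L, 3L, 1L)
  expect_equal(fraction_of_agreement(phase_label_grid(pts, perm[a + 1]),
                                     ga), 1)
  withnoise <- a; withnoise[1:4] <- -1L
  expect_equal(fraction_of_agreement(phase_label_grid(pts, withnoise), ga),
               36 / 40)
  expect_equal(fraction_of_agreement(phase_label_grid(pts, withnoise), ga,
                                     count_noise = FALSE), 1)
  # merge map: two labels scored as one phase
  m <- merge_map(c(0L, 1L))
  merged <- ifelse(a == 1L, 0L, a)
  expect_equal(fraction_of_agreement(phase_label_grid(pts, merged), ga,
                                     merge = m), 1)
  expect_error(merge_map(c(0L, 1L), c(1L, 2L)), "disjoint")
})

test_that("ADF-template phases are recovered perfectly by isomap + ward", {
  fx <- planted_adf_table()
  lab <- adf_phase_pipeline(fx$table, "isomap", "ward", n_clusters = 3,
                            seed = 1)
  ref <- phase_label_grid(fx$table[, c("T", "p")], fx$truth)
  expect_equal(fraction_of_agreement(lab, ref), 1)
  # reruns are identical; provenance travels with the labels
  lab2 <- adf_phase_pipeline(fx$table, "isomap", "ward", n_clusters = 3,
                             seed = 1)
  expect_identical(lab$label, lab2$label)
  expect_equal(attr(lab, "provenance")$cluster_algo, "ward")
  # k = 1 puts everything in one phase
  one <- adf_phase_pipeline(fx$table, "mds", "ward", n_clusters = 1)
  expect_true(all(one$label == 0))
})

test_that("intelligent pipeline recovers the planted solid sub-phases", {
  fx <- planted_property_table()
  grid <- intelligent_phase_pipeline(
    fx$table, reduce_method = "tsne", cluster_algo = "dbscan",
    params = list(min_pts_peel = 8, min_pts = 8), seed = 2)
  s1 <- attr(grid, "stage1")
  ref_state <- phase_label_grid(fx$table[, c("T", "p")], fx$state)
  expect_gte(fraction_of_agreement(s1, ref_state), 0.95)
  # the four planted solid sub-phases come out of t-SNE + DBSCAN
  in_solid_stage <- s1$label == max(s1$label)
  stage2_labels <- grid$label[in_solid_stage]
  expect_equal(length(unique(stage2_labels[stage2_labels >= 0])), 4)
  solid <- fx$state == 3
  sub_pred <- grid$label[solid]
  sub_ref <- fx$solid_sub[solid]
  pts_s <- data.frame(T = seq_len(sum(solid)), p = 0)
  expect_gte(fraction_of_agreement(phase_label_grid(pts_s, sub_pred),
                                   phase_label_grid(pts_s, sub_ref)),
             0.95)
  # stage-1 labels identical whether or not stage 2 runs
  s1_only <- sequential_diffusion_dbscan(fx$table[, c("T", "p")],
                                         feature_matrix(fx$table)[, "diffusion"],
                                         min_pts = 8, n_rounds = 3)
  expect_identical(s1$label, s1_only$label)
})

test_that("a single solid population is not split spuriously", {
  fx <- planted_property_table()
  # collapse the four solid centers into one
  raw <- feature_matrix(fx$table)
  solid <- fx$state == 3
  set.seed(3)
  raw[solid, setdiff(observable_names(), "diffusion")] <-
    matrix(rnorm(sum(solid) * 14, sd = 0.05), sum(solid))
  tab <- feature_table(fx$table[, c("T", "p")], standardize_columns(raw),
                       observable_names(), standardized = TRUE)
  grid <- intelligent_phase_pipeline(
    tab, reduce_method = "mds", cluster_algo = "dbscan",
    params = list(min_pts_peel = 8, min_pts = 8), seed = 4)
  s1 <- attr(grid, "stage1")
  sub_pred <- grid$label[s1$label == max(s1$label)]
  expect_lte(length(unique(sub_pred[sub_pred >= 0])), 1)
})

test_that("label grids round-trip through CSV with provenance", {
  pts <- data.frame(T = c(0.1, 0.2), p = c(1, 2))
  g <- phase_label_grid(pts, c(0L, -1L),
                        provenance = list(method = "manual", seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_labels(g, f)
  back <- read_labels(f)
  expect_equal(back$label, g$label)
  expect_equal(attr(back, "provenance")$method, "manual")
})
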