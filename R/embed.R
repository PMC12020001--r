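#' Dimensionality reduction to three components
#'
#' Projects a feature table onto 3 dimensions by one of four methods:
#' classical metric MDS (`stats::cmdscale`), Isomap (`vegan::isomap`,
#' default 100 neighbors), Laplacian-eigenmap spectral embedding, or exact
#' t-SNE with defaults perplexity 20, early exaggeration 12, learning rate
#' 100 and 3000 iterations. Three dimensions are the standard working
#' compromise here: cheap, visualizable, and sufficient to separate the
#' phases. All stochastic stages are seeded, so the embedding is
#' deterministic given `seed`.
#'
#' @param table A `feature_table` (or plain numeric matrix).
#' @param method One of `"mds"`, `"isomap"`, `"spectral"`, `"tsne"`.
#' @param hyperparams Named list overriding the method defaults
#'   (`n_neighbors` for isomap/spectral; `perplexity`,
#'   `early_exaggeration`, `learning_rate`, `max_iter` for t-SNE).
#' @param seed RNG seed (used by t-SNE initialization).
#' @return Object of class `embedding`: `coords` (points x 3), `method`,
#'   `hyperparams`, `seed`, `phase_points`.
#' @export
reduce <- function(table, method = c("mds", "isomap", "spectral", "tsne"),
                   hyperparams = list(), seed = 1) {
  method <- match.arg(method)
  if (inherits(table, "feature_table")) {
    x <- feature_matrix(table)
    pts <- table[, c("T", "p")]
  } else {
    x <- as.matrix(table)
    pts <- data.frame(T = seq_len(nrow(x)), p = 0)
  }
  n <- nrow(x)
  if (n < 4) stop("reduce: need at least 4 points")
  hp <- switch(method,
    mds = list(),
    isomap = list(n_neighbors = 100),
    spectral = list(n_neighbors = 10),
    tsne = list(perplexity = 20, early_exaggeration = 12,
                learning_rate = 100, max_iter = 3000))
  hp[names(hyperparams)] <- hyperparams
  coords <- switch(method,
    mds = {
      y <- cmdscale(dist(x), k = 3)
      if (ncol(y) < 3) y <- cbind(y, matrix(0, n, 3 - ncol(y)))
      y
    },
    isomap = {
      k <- min(hp$n_neighbors, n - 1)
      y <- tryCatch(
        vegan::isomap(dist(x), ndim = 3, k = k)$points,
        error = function(e)
          stop(sprintf("reduce: isomap failed (%s)", conditionMessage(e))))
      if (ncol(y) < 3) y <- cbind(y, matrix(0, n, 3 - ncol(y)))
      y[, 1:3, drop = FALSE]
    },
    spectral = spectral_embed(x, k = min(hp$n_neighbors, n - 1)),
    tsne = tsne_embed(x, perplexity = hp$perplexity,
                      exaggeration = hp$early_exaggeration,
                      eta = hp$learning_rate, max_iter = hp$max_iter,
                      seed = seed))
  if (!all(is.finite(coords)))
    stop(sprintf("reduce: %s produced non-finite coordinates", method))
  structure(list(coords = unname(as.matrix(coords)), method = method,
                 hyperparams = hp, seed = seed, phase_points = pts),
            class = "embedding")
}

# Laplacian eigenmaps on a symmetrized kNN graph (binary weights,
# generalized eigenproblem L u = lambda D u via the normalized Laplacian).
spectral_embed <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  # connectivity check (breadth-first)
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("reduce: spectral embedding failed (disconnected neighbor graph)")
  deg <- rowSums(adj)
  dis <- 1 / sqrt(deg)
  lsym <- diag(n) - (dis * adj) %*% diag(dis)
  e <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  idx <- order(e$values)[2:4]
  dis * e$vectors[, idx, drop = FALSE]
}

# Exact t-SNE (Student-t embedding of perplexity-calibrated Gaussian
# affinities), gradient descent with momentum and adaptive gains.
tsne_embed <- function(x, perplexity = 20, exaggeration = 12, eta = 100,
                       max_iter = 3000, seed = 1) {
  n <- nrow(x)
  perplexity <- min(perplexity, max(1, floor((n - 1) / 3)))
  d2 <- as.matrix(dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    di <- d2[i, -i]
    for (it in seq_len(50)) {
      pj <- exp(-di * beta)
      sp <- sum(pj)
      if (sp == 0) { pj <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * pj) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else { bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- pj / sum(pj)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(rnorm(n * 3, sd = 1e-4), n, 3)
  dY <- matrix(0, n, 3)
  gains <- matrix(1, n, 3)
  stop_exag <- 250
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= stop_exag) P * exaggeration else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter < 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2,
                         gains * 0.8), 0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter > stop_exag && max(abs(grad)) < 1e-7) break
  }
  Y
}
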