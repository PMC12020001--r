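#' Phase label grids
#'
#' Cluster label per phase point. Labels are contiguous integers from 0;
#' the reserved value -1 marks noise / unassigned points (the "white
#' spots" of a density-based clustering).
#'
#' @param phase_points data.frame with columns `T`, `p`.
#' @param labels Integer labels (use -1 for noise).
#' @param provenance Optional list recording method, hyperparameters and
#'   seed.
#' @return Object of class `phase_label_grid` (a data.frame with columns
#'   `T`, `p`, `label`).
#' @export
phase_label_grid <- function(phase_points, labels, provenance = NULL) {
  stopifnot(nrow(phase_points) == length(labels))
  out <- data.frame(T = phase_points$T, p = phase_points$p,
                    label = as.integer(labels))
  attr(out, "noise_label") <- -1L
  attr(out, "provenance") <- provenance
  class(out) <- c("phase_label_grid", "data.frame")
  out
}

relabel_contiguous <- function(labels) {
  keep <- labels != -1L
  u <- sort(unique(labels[keep]))
  labels[keep] <- match(labels[keep], u) - 1L
  labels
}

#' Cluster an embedding into candidate phases
#'
#' k-means (k-means++-style multiple starts via `nstart`), Ward
#' agglomerative clustering on standardized Euclidean distances, or DBSCAN
#' on the raw embedding coordinates.
#'
#' @param embedding An [reduce()] result (or plain matrix).
#' @param algo `"kmeans"`, `"ward"`, or `"dbscan"`.
#' @param params List: `n_clusters` (kmeans/ward), `eps` (dbscan; `"auto"`
#'   selects it from the k-distance elbow) and `min_pts` (dbscan, default
#'   80).
#' @param seed RNG seed (k-means initialization).
#' @return A [phase_label_grid()] with provenance attached.
#' @export
cluster <- function(embedding, algo = c("kmeans", "ward", "dbscan"),
                    params = list(), seed = 1) {
  algo <- match.arg(algo)
  if (inherits(embedding, "embedding")) {
    x <- embedding$coords
    pts <- embedding$phase_points
    prov_embed <- list(reduce_method = embedding$method,
                       reduce_hyperparams = embedding$hyperparams,
                       reduce_seed = embedding$seed)
  } else {
    x <- as.matrix(embedding)
    pts <- data.frame(T = seq_len(nrow(x)), p = 0)
    prov_embed <- NULL
  }
  n <- nrow(x)
  labels <- switch(algo,
    kmeans = {
      k <- params$n_clusters %||% stop("cluster: kmeans needs n_clusters")
      if (k > n) stop("cluster: more clusters than points")
      set.seed(seed)
      if (nrow(unique(x)) < k) {
        # degenerate duplicates: fall back to unique-point assignment
        as.integer(factor(apply(round(x, 10), 1, paste,
                                collapse = ","))) - 1L
      } else {
        kmeans(x, centers = k, nstart = 10, iter.max = 200)$cluster - 1L
      }
    },
    ward = {
      k <- params$n_clusters %||% stop("cluster: ward needs n_clusters")
      if (k > n) stop("cluster: more clusters than points")
      xs <- standardize_columns(x)
      cutree(hclust(dist(xs), method = "ward.D2"), k = k) - 1L
    },
    dbscan = {
      min_pts <- params$min_pts %||% 80
      eps <- params$eps %||% "auto"
      if (identical(eps, "auto"))
        eps <- eps_from_kdistance(x, k = min(min_pts, n - 1))
      dbscan_fit(x, eps = eps, min_pts = min_pts)
    })
  labels <- relabel_contiguous(as.integer(labels))
  prov <- c(prov_embed,
            list(cluster_algo = algo, cluster_params = params, seed = seed,
                 package_version =
                   as.character(utils::packageVersion("rosewater"))))
  phase_label_grid(pts, labels, provenance = prov)
}

#' DBSCAN (density-based clustering with noise)
#'
#' Classic DBSCAN on a Euclidean distance matrix: points with at least
#' `min_pts` neighbors within `eps` (the point itself included) are cores;
#' clusters are the connected components of the core graph plus their
#' border points; everything else is noise (-1).
#'
#' @param x Numeric matrix or vector of observations.
#' @param eps Neighborhood radius.
#' @param min_pts Minimum neighborhood size for a core point.
#' @return Integer labels, 0-based, noise = -1.
#' @export
dbscan_fit <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(-1L, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Epsilon from the k-distance elbow
#'
#' Sorts the distance to each point's k-th nearest neighbor in decreasing
#' order and returns the value at the elbow where the curve falls toward
#' zero and flattens. The elbow is located, after light smoothing, as the
#' point of maximum deviation below the chord joining the ends of the
#' sorted curve (the standard knee criterion; it is far more robust on
#' ragged curves than a raw second difference). Deterministic.
#'
#' @param x Numeric matrix or vector of observations.
#' @param k Neighbor rank (`n_points > k`).
#' @return Scalar eps.
#' @export
eps_from_kdistance <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k) stop("eps_from_kdistance: need more points than k")
  d <- as.matrix(dist(x))
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
  s <- sort(kd, decreasing = TRUE)
  if (n < 4) return(max(s))
  w <- max(3L, n %/% 50L)
  sm <- as.numeric(stats::filter(s, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- s[is.na(sm)]
  i <- seq_len(n)
  chord <- sm[1] + (sm[n] - sm[1]) * (i - 1) / (n - 1)
  elbow <- which.max(chord - sm)
  max(sm[elbow], sm[n])
}

#' Sequential diffusion peeling into states of matter
#'
#' Separates gas, liquid and solid phase points from the diffusion
#' coefficient alone by repeated DBSCAN on the (standardized) diffusion
#' values: at each round `eps` is chosen from the k-distance elbow and the
#' points that fall outside the dense cluster(s) - the group with the
#' lower diffusion point density - are peeled off as one state-of-matter
#' group. Three successful rounds leave four groups (gas, two parts of the
#' liquid, solid), ordered and labeled by descending mean diffusion:
#' gas = 0, liquid-a = 1, liquid-b = 2, solid = 3. Rounds that find no
#' outliers end the peeling early with a warning (fewer groups).
#'
#' @param phase_points data.frame with columns `T`, `p`.
#' @param diffusion Diffusion coefficient per phase point.
#' @param min_pts DBSCAN core-neighbor count (default 60; scale down with
#'   the grid).
#' @param n_rounds Number of peeling rounds (default 3).
#' @return A [phase_label_grid()]; attribute `groups` holds the group
#'   names, attribute `complete` whether all rounds peeled.
#' @export
sequential_diffusion_dbscan <- function(phase_points, diffusion,
                                        min_pts = 60, n_rounds = 3) {
  stopifnot(nrow(phase_points) == length(diffusion))
  n <- length(diffusion)
  z <- if (sd(diffusion) > 0) (diffusion - mean(diffusion)) / sd(diffusion)
       else diffusion * 0
  remaining <- seq_len(n)
  peeled <- list()
  complete <- TRUE
  for (round in seq_len(n_rounds)) {
    if (length(remaining) <= min_pts) {
      warning("sequential_diffusion_dbscan: too few points to keep peeling")
      complete <- FALSE
      break
    }
    zr <- matrix(z[remaining], ncol = 1)
    eps <- eps_from_kdistance(zr, k = min(min_pts, length(remaining) - 1))
    labs <- dbscan_fit(zr, eps = eps, min_pts = min_pts)
    out <- labs == -1L
    if (!any(out) || all(out)) {
      warning(sprintf(
        "sequential_diffusion_dbscan: round %d found no outliers", round))
      complete <- FALSE
      break
    }
    peeled[[length(peeled) + 1]] <- remaining[out]
    remaining <- remaining[!out]
  }
  groups <- c(peeled, list(remaining))
  means <- vapply(groups, function(i) mean(diffusion[i]), numeric(1))
  ord <- order(means, decreasing = TRUE)
  labels <- integer(n)
  for (g in seq_along(ord)) labels[groups[[ord[g]]]] <- g - 1L
  nm <- if (length(groups) == 4) c("gas", "liquid_a", "liquid_b", "solid")
        else paste0("group_", seq_along(groups) - 1L)
  out <- phase_label_grid(phase_points, labels,
                          provenance = list(method = "diffusion_peeling",
                                            min_pts = min_pts,
                                            n_rounds = n_rounds))
  attr(out, "groups") <- nm
  attr(out, "complete") <- complete
  out
}

#' Read/write phase label grids
#'
#' CSV with columns `T`, `p`, `label`, plus a JSON provenance sidecar.
#'
#' @param grid A `phase_label_grid`.
#' @param path CSV path.
#' @return `write_labels` returns `path` invisibly; `read_labels` a
#'   `phase_label_grid`.
#' @export
write_labels <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  prov <- attr(grid, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  prov <- if (file.exists(side)) jsonlite::read_json(side,
                                                     simplifyVector = TRUE)
          else NULL
  phase_label_grid(df[, c("T", "p")], df$label, provenance = prov)
}
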