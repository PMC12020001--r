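#' ADF phase pipeline
#'
#' The descriptor-driven route to a phase diagram: reduce the 125-dim ADF
#' feature table to 3 components, then cluster. The full provenance
#' (methods, hyperparameters, seed, package version) travels with the
#' result, so a run can be reproduced exactly.
#'
#' @param table A `feature_table` of ADF descriptors.
#' @param reduce_method,cluster_algo See [reduce()] and [cluster()].
#' @param n_clusters Number of phases for kmeans/ward.
#' @param seed RNG seed for all stochastic stages.
#' @param reduce_hyperparams,cluster_params Optional overrides.
#' @return A [phase_label_grid()].
#' @export
adf_phase_pipeline <- function(table, reduce_method = "isomap",
                               cluster_algo = "ward", n_clusters = 7,
                               seed = 1, reduce_hyperparams = list(),
                               cluster_params = list()) {
  emb <- reduce(table, reduce_method, hyperparams = reduce_hyperparams,
                seed = seed)
  cluster_params$n_clusters <- cluster_params$n_clusters %||% n_clusters
  cluster(emb, cluster_algo, params = cluster_params, seed = seed)
}

#' Intelligent phase pipeline (diffusion first, then solids)
#'
#' Two-stage phase classification of the 15-quantity property table.
#' Stage 1 separates the states of matter from the diffusion coefficient
#' alone via [sequential_diffusion_dbscan()] (gas, two liquid parts,
#' solid). Stage 2 takes the solid points only, drops the diffusion
#' column (already spent), re-standardizes the remaining 14 features on
#' the solid subset, reduces to 3 components and clusters into solid
#' sub-phases. Stage-1 labels are unchanged by stage 2.
#'
#' @param table A standardized 15-column property `feature_table`
#'   including a `diffusion` column.
#' @param reduce_method,cluster_algo Stage-2 methods.
#' @param params List: `min_pts_peel` (stage-1 DBSCAN core count, default
#'   60), `n_rounds` (default 3), `n_clusters` (stage-2 kmeans/ward),
#'   `min_pts` and `eps` (stage-2 DBSCAN, defaults 80 and `"auto"`),
#'   `min_solid` (smallest solid subset worth splitting, default 8).
#' @param seed RNG seed.
#' @param diffusion Optional raw diffusion values (defaults to the table's
#'   `diffusion` column, whose standardization does not affect peeling).
#' @return A [phase_label_grid()]: gas = 0, liquid groups next, solid
#'   sub-phases after; stage-2 DBSCAN noise = -1. Attributes `stage1`
#'   (the peeling grid) and `groups`.
#' @export
intelligent_phase_pipeline <- function(table, reduce_method = "tsne",
                                       cluster_algo = "dbscan",
                                       params = list(), seed = 1,
                                       diffusion = NULL) {
  stopifnot(inherits(table, "feature_table"))
  nm <- attr(table, "feature_names")
  if (!"diffusion" %in% nm)
    stop("intelligent_phase_pipeline: table lacks a diffusion column")
  diffusion <- diffusion %||% feature_matrix(table)[, "diffusion"]
  min_pts_peel <- params$min_pts_peel %||% 60
  n_rounds <- params$n_rounds %||% 3
  min_solid <- params$min_solid %||% 8
  stage1 <- sequential_diffusion_dbscan(table[, c("T", "p")], diffusion,
                                        min_pts = min_pts_peel,
                                        n_rounds = n_rounds)
  groups <- attr(stage1, "groups")
  solid_label <- max(stage1$label)
  solid_idx <- which(stage1$label == solid_label)
  labels <- stage1$label
  if (length(solid_idx) < max(min_solid, 4)) {
    warning("intelligent_phase_pipeline: solid subset too small to split")
    out <- phase_label_grid(table[, c("T", "p")], labels,
                            provenance = list(method = "intelligent",
                                              stage2 = "skipped",
                                              seed = seed))
    attr(out, "stage1") <- stage1
    attr(out, "groups") <- groups
    return(out)
  }
  sub <- table[solid_idx, , drop = FALSE]
  x <- feature_matrix(table)[solid_idx, setdiff(nm, "diffusion"),
                             drop = FALSE]
  solid_table <- feature_table(sub[, c("T", "p")],
                               standardize_columns(x),
                               setdiff(nm, "diffusion"),
                               standardized = TRUE)
  emb <- reduce(solid_table, reduce_method, seed = seed)
  cp <- list(n_clusters = params$n_clusters %||% 4,
             min_pts = params$min_pts %||% 80,
             eps = params$eps %||% "auto")
  sub_labels <- cluster(emb, cluster_algo, params = cp, seed = seed)$label
  offset <- solid_label
  labels[solid_idx] <- ifelse(sub_labels == -1L, -1L,
                              offset + sub_labels)
  out <- phase_label_grid(table[, c("T", "p")], labels,
                          provenance = list(
                            method = "intelligent",
                            reduce_method = reduce_method,
                            cluster_algo = cluster_algo,
                            params = params, seed = seed,
                            package_version =
                              as.character(utils::packageVersion("rosewater"))))
  attr(out, "stage1") <- stage1
  attr(out, "groups") <- groups
  out
}
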