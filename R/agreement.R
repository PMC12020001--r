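#' Merge map for scoring
#'
#' Declares groups of reference/predicted labels that count as a single
#' phase when computing the fraction of agreement (e.g. the two parts of
#' the liquid phase, or the split high-pressure solid).
#'
#' @param ... Integer vectors, one per group; groups must be disjoint.
#' @return Object of class `merge_map`.
#' @export
merge_map <- function(...) {
  groups <- list(...)
  all_labels <- unlist(groups)
  if (anyDuplicated(all_labels))
    stop("merge_map: groups must be disjoint")
  structure(list(groups = groups), class = "merge_map")
}

apply_merge <- function(labels, merge) {
  if (is.null(merge)) return(labels)
  for (g in merge$groups) {
    rep_label <- min(g)
    labels[labels %in% g] <- rep_label
  }
  labels
}

#' Fraction of agreement between phase diagrams
#'
#' The proportion of phase points whose predicted phase matches the
#' reference diagram. Predicted clusters are identified with reference
#' phases by the one-to-one assignment that maximizes the total number of
#' matches (Hungarian algorithm on the contingency table); a merge map is
#' applied to both sides first. Noise / unassigned points always count as
#' disagreement (they stay in the denominator unless `count_noise =
#' FALSE`).
#'
#' @param predicted,reference [phase_label_grid()]s over identical phase
#'   points.
#' @param merge Optional [merge_map()].
#' @param count_noise Keep noise points in the denominator (default TRUE).
#' @return Agreement fraction in `[0, 1]`.
#' @export
fraction_of_agreement <- function(predicted, reference, merge = NULL,
                                  count_noise = TRUE) {
  if (nrow(predicted) != nrow(reference) ||
      any(abs(predicted$T - reference$T) > 1e-9) ||
      any(abs(predicted$p - reference$p) > 1e-9))
    stop("fraction_of_agreement: phase-point grids differ")
  pl <- apply_merge(predicted$label, merge)
  rl <- apply_merge(reference$label, merge)
  noise <- pl == -1L | rl == -1L
  total <- if (count_noise) length(pl) else sum(!noise)
  if (total == 0) return(0)
  if (!any(!noise)) return(0)
  matches <- max_assignment_matches(pl[!noise], rl[!noise])
  matches / total
}

# Maximum total contingency count under a one-to-one label assignment.
max_assignment_matches <- function(a, b) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  tab <- table(factor(a, levels = ua), factor(b, levels = ub))
  m <- matrix(as.numeric(tab), nrow = length(ua))
  transposed <- FALSE
  if (nrow(m) > ncol(m)) { m <- t(m); transposed <- TRUE }
  assign <- cpp_hungarian(-m)
  sum(m[cbind(seq_len(nrow(m)), assign)])
}
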