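## Clustering quality metrics: normalized mutual information between two
## labelings and the total convex-hull area of a labeled point set.

#' Normalized mutual information between two labelings
#'
#' NMI(C, C') = I(C, C') / sqrt(En(C) En(C')), computed from the
#' contingency table with natural logarithms (the ratio is base-invariant).
#' 1 means the partitions are identical, 0 means no mutual information.
#' When either labeling has zero entropy (a single cluster) the formula is
#' 0/0; by convention the value is 1 if both partitions are the trivial
#' single cluster (identical partitions) and 0 otherwise.
#'
#' @param true_labels,pred_labels equal-length label vectors (any atomic
#'   type; only the induced partitions matter).
#' @return Numeric in [0, 1].
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
nmi <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have the same length")
  if (length(true_labels) < 1L)
    stop("label vectors must be non-empty")
  n <- length(true_labels)
  tab <- table(true_labels, pred_labels)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(ifelse(pu > 0, pu * log(pu), 0))
  hv <- -sum(ifelse(pv > 0, pv * log(pv), 0))
  if (hu < 1e-15 || hv < 1e-15) {
    # zero-entropy convention: identical trivial partitions score 1
    return(if (hu < 1e-15 && hv < 1e-15) 1 else 0)
  }
  p <- tab / n
  ratio <- p / (pu %o% pv)
  mi <- sum(ifelse(p > 0, p * log(ratio), 0))
  max(0, min(1, mi / sqrt(hu * hv)))
}

#' Total convex-hull area of a labeled clustering
#'
#' The K-area clustering objective evaluated on any labeling: the sum of
#' per-cluster convex hull areas. Degenerate clusters (single points,
#' collinear sets) contribute 0.
#'
#' @param ps a [point_set()].
#' @param labels per-point cluster labels (length N).
#' @return Non-negative numeric scalar.
#' @export
total_convex_area <- function(ps, labels) {
  stopifnot(inherits(ps, "point_set"))
  if (length(labels) != ps$n)
    stop("labels must have one entry per point")
  groups <- split(seq_len(ps$n), labels)
  sum(vapply(groups, function(idx) convex_hull(ps, idx)$area, numeric(1)))
}
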