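## Synthetic fixture generator. Emulates the geometry of a 2D PCA embedding
## of well-annotated cells: compact clusters (Gaussian blobs, uniform convex
## patches, or degenerate collinear sets) with a controlled ratio of
## between-center distance to within-cluster radius, optional planted
## outliers in the inflated bounding box, and optional nested (hierarchical)
## center placement. Everything is driven by a single seed.

#' Generate a synthetic labeled 2D point set
#'
#' Cluster shapes are sampled first (unit scale), the largest within-cluster
#' radius is measured, and the cluster centers are then placed so that the
#' minimum inter-center distance divided by that radius is at least
#' `separation` — so the requested separation ratio holds by construction on
#' the generated output. With `depth > 1` centers are placed by recursive
#' bisection with geometrically growing spacing, producing a nested
#' hierarchy (recorded as an attribute). Outliers are planted uniformly in
#' the bounding box of the clustered points inflated by 50% and carry the
#' label of the nearest cluster center, with an `outlier` attribute marking
#' them.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param points_per_cluster points in each cluster (>= 1).
#' @param shape `"gaussian"` (isotropic unit-sd blob), `"convex-polygon"`
#'   (uniform in a randomly rotated regular hexagon), or `"collinear"`
#'   (exactly collinear segment, a zero-area degenerate cluster).
#' @param separation required minimum ratio of inter-center distance to the
#'   maximum within-cluster radius (> 0).
#' @param outlier_fraction fraction of the output points that are planted
#'   outliers, in [0, 1).
#' @param depth hierarchy depth of center placement (1 = flat).
#' @param seed integer seed; the only source of randomness.
#' @return A [point_set()] with true `labels`, and attributes `centers`
#'   (cluster centers), `outlier` (logical per point), `hierarchy` (nested
#'   grouping of cluster ids) and `spec` (the arguments).
#' @examples
#' ps <- generate_points(n_clusters = 4, points_per_cluster = 50,
#'                       separation = 10, seed = 1)
#' table(ps$labels)
#' @export
generate_points <- function(n_clusters = 4L, points_per_cluster = 50L,
                            shape = c("gaussian", "convex-polygon", "collinear"),
                            separation = 10, outlier_fraction = 0,
                            depth = 1L, seed = 1L) {
  shape <- match.arg(shape)
  if (n_clusters < 1L || points_per_cluster < 1L || depth < 1L)
    stop("counts and depth must be at least 1")
  if (separation <= 0) stop("separation must be positive")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")

  with_seed(seed, {
    offsets <- lapply(seq_len(n_clusters), function(j)
      sample_shape(shape, points_per_cluster))
    r_max <- max(1e-9, vapply(offsets, function(o)
      max(sqrt(rowSums(o^2))), numeric(1)))
    sep_dist <- separation * r_max * 1.0001

    placed <- place_centers(n_clusters, 1L, depth, sep_dist)
    centers <- placed$centers

    xs <- numeric(0); ys <- numeric(0); labels <- integer(0)
    for (j in seq_len(n_clusters)) {
      xs <- c(xs, centers[j, 1L] + offsets[[j]][, 1L])
      ys <- c(ys, centers[j, 2L] + offsets[[j]][, 2L])
      labels <- c(labels, rep(j, points_per_cluster))
    }

    base_n <- length(xs)
    n_out <- round(outlier_fraction / (1 - outlier_fraction) * base_n)
    outlier <- rep(FALSE, base_n)
    if (n_out > 0) {
      rx <- range(xs); ry <- range(ys)
      padx <- 0.25 * max(diff(rx), 1e-9)
      pady <- 0.25 * max(diff(ry), 1e-9)
      ox <- stats::runif(n_out, rx[1L] - padx, rx[2L] + padx)
      oy <- stats::runif(n_out, ry[1L] - pady, ry[2L] + pady)
      d2 <- dist_to_centers(ox, oy, centers[, 1L], centers[, 2L])
      olab <- max.col(-d2, ties.method = "first")
      xs <- c(xs, ox); ys <- c(ys, oy)
      labels <- c(labels, olab)
      outlier <- c(outlier, rep(TRUE, n_out))
    }

    ps <- point_set(xs, ys, labels = labels)
    attr(ps, "centers") <- centers
    attr(ps, "outlier") <- outlier
    attr(ps, "hierarchy") <- placed$tree
    attr(ps, "spec") <- list(n_clusters = n_clusters,
                             points_per_cluster = points_per_cluster,
                             shape = shape, separation = separation,
                             outlier_fraction = outlier_fraction,
                             depth = depth, seed = seed)
    ps
  })
}

# Unit-scale within-cluster offsets for one cluster.
sample_shape <- function(shape, n) {
  if (shape == "gaussian") {
    cbind(stats::rnorm(n), stats::rnorm(n))
  } else if (shape == "convex-polygon") {
    # uniform in a randomly rotated regular hexagon of circumradius 1
    rot <- stats::runif(1, 0, 2 * pi)
    vth <- rot + 2 * pi * (0:5) / 6
    vx <- cos(vth); vy <- sin(vth)
    out <- matrix(0, n, 2L)
    got <- 0L
    while (got < n) {
      cx <- stats::runif(n, -1, 1)
      cy <- stats::runif(n, -1, 1)
      keep <- in_convex_ring(vx, vy, cx, cy)
      take <- min(n - got, sum(keep))
      if (take > 0) {
        idx <- which(keep)[seq_len(take)]
        out[got + seq_len(take), ] <- cbind(cx[idx], cy[idx])
        got <- got + take
      }
    }
    out
  } else {  # collinear
    th <- stats::runif(1, 0, pi)
    t <- stats::runif(n, -1, 1)
    cbind(t * cos(th), t * sin(th))
  }
}

# point-in-convex-polygon for a counterclockwise coordinate ring
in_convex_ring <- function(vx, vy, px, py) {
  m <- length(vx)
  ok <- rep(TRUE, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ok <- ok & (cross_sign(vx[i], vy[i], vx[j], vy[j], px, py) >= 0)
  }
  ok
}

# Place n cluster centers. Flat (level == depth): evenly on a circle whose
# adjacent chord equals sep_dist. Hierarchical: recursive bisection with
# spacing growing 3x per level so between-group gaps dominate within-group
# gaps. Returns centers and the nested grouping over cluster ids.
place_centers <- function(n, level, depth, sep_dist) {
  if (n == 1L)
    return(list(centers = matrix(0, 1L, 2L), tree = 1L))
  if (level >= depth) {
    R <- sep_dist / (2 * sin(pi / n))
    th <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n) - 1L) / n
    return(list(centers = cbind(R * cos(th), R * sin(th)),
                tree = as.list(seq_len(n))))
  }
  nl <- ceiling(n / 2); nr <- n - nl
  left <- place_centers(nl, level + 1L, depth, sep_dist)
  right <- place_centers(nr, level + 1L, depth, sep_dist)
  span <- function(cm) if (nrow(cm) == 1L) 0 else max(sqrt(rowSums(cm^2)))
  gap <- span(left$centers) + span(right$centers) +
    sep_dist * 3^(depth - level)
  th <- stats::runif(1, 0, 2 * pi)
  dir <- c(cos(th), sin(th))
  lc <- sweep(left$centers, 2L, -gap / 2 * dir)
  rc <- sweep(right$centers, 2L, gap / 2 * dir)
  rtree <- relabel_tree(right$tree, nl)
  list(centers = rbind(lc, rc), tree = list(left$tree, rtree))
}

relabel_tree <- function(tr, offset) {
  if (is.list(tr)) lapply(tr, relabel_tree, offset = offset)
  else tr + offset
}
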