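## The three comparison algorithms: K-center by farthest-first traversal,
## K-median by Lloyd iterations with geometric-median (Weiszfeld) centers,
## and K-means by Lloyd iterations, each reporting its own objective.
## All randomness is confined to an explicit seed; given the same seed the
## result is identical.

new_baseline_result <- function(labels, centers, objective, iterations, seed,
                                algorithm, trace = NULL) {
  structure(
    list(labels = labels, centers = centers, objective = objective,
         iterations = iterations, seed = seed, algorithm = algorithm,
         objective_trace = trace),
    class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s: K = %d, objective = %.6g (%d iterations)\n",
              x$algorithm, nrow(x$centers), x$objective, x$iterations))
  invisible(x)
}

#' K-center clustering by farthest-first traversal
#'
#' The classical greedy 2-approximation for the K-center objective: the
#' first center is point 1 (deterministic default) or a seeded uniform
#' choice; each subsequent center is the point farthest from its nearest
#' already-chosen center. Points are assigned to the nearest center.
#' The objective is the largest distance from any point to its assigned
#' center (the quantity K-center minimizes).
#'
#' @param ps a [point_set()].
#' @param K number of clusters, 1 <= K <= N.
#' @param seed `NULL` (default) starts from point 1; an integer seed draws
#'   the first center uniformly at random.
#' @return A `baseline_result`: `labels` (1..K per point), `centers`
#'   (K x 2 matrix of chosen points), `objective` (max radius),
#'   `iterations`, `seed`.
#' @export
k_center <- function(ps, K, seed = NULL) {
  stopifnot(inherits(ps, "point_set"))
  K <- check_K(K, ps$n)
  first <- if (is.null(seed)) 1L else
    with_seed(seed, sample.int(ps$n, 1L))
  centers <- integer(K)
  centers[1L] <- first
  d2near <- (ps$x - ps$x[first])^2 + (ps$y - ps$y[first])^2
  if (K > 1L) for (j in 2:K) {
    nxt <- which.max(d2near)  # deterministic: first max wins ties
    centers[j] <- nxt
    d2new <- (ps$x - ps$x[nxt])^2 + (ps$y - ps$y[nxt])^2
    d2near <- pmin(d2near, d2new)
  }
  d2 <- dist_to_centers(ps$x, ps$y, ps$x[centers], ps$y[centers])
  labels <- max.col(-d2, ties.method = "first")
  objective <- sqrt(max(d2[cbind(seq_len(ps$n), labels)]))
  new_baseline_result(labels, cbind(x = ps$x[centers], y = ps$y[centers]),
                      objective, iterations = K, seed = seed,
                      algorithm = "k_center")
}

check_K <- function(K, n) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > n || K != round(K))
    stop("K must be an integer between 1 and N")
  as.integer(K)
}

# Geometric median of a 2D point cloud by the modified Weiszfeld iteration
# (handles iterates that land on a data point). Minimizes sum of Euclidean
# distances.
geometric_median <- function(x, y, tol = 1e-8, max_iter = 100L) {
  if (length(x) == 1L) return(c(x, y))
  cx <- mean(x); cy <- mean(y)
  for (it in seq_len(max_iter)) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    on_pt <- d < 1e-12 * max(1, max(d))
    w <- ifelse(on_pt, 0, 1 / pmax(d, .Machine$double.xmin))
    sw <- sum(w)
    if (sw == 0) break  # all points coincide with the iterate
    tx <- sum(w * x) / sw
    ty <- sum(w * y) / sw
    eta <- sum(on_pt)
    if (eta > 0) {
      # Vardi-Zhang correction when the iterate sits on eta data points
      rx <- sum(w * (x - cx)); ry <- sum(w * (y - cy))
      r <- sqrt(rx^2 + ry^2)
      if (r <= eta) break  # current point is the median
      gamma <- min(1, eta / r)
      tx <- (1 - gamma) * tx + gamma * cx
      ty <- (1 - gamma) * ty + gamma * cy
    }
    if (sqrt((tx - cx)^2 + (ty - cy)^2) <= tol * max(1, sqrt(cx^2 + cy^2))) {
      cx <- tx; cy <- ty
      break
    }
    cx <- tx; cy <- ty
  }
  c(cx, cy)
}

# Seeded k-means++ style initialization: first center uniform, each next
# center drawn with probability proportional to weight_fun(distance to the
# nearest chosen center). Returns K distinct point indices.
seeded_init <- function(ps, K, seed, weight_fun) {
  with_seed(seed, {
    centers <- integer(K)
    centers[1L] <- sample.int(ps$n, 1L)
    d2near <- (ps$x - ps$x[centers[1L]])^2 + (ps$y - ps$y[centers[1L]])^2
    if (K > 1L) for (j in 2:K) {
      w <- weight_fun(d2near)
      if (sum(w) <= 0) {  # all remaining points coincide with a center
        cand <- setdiff(seq_len(ps$n), centers[seq_len(j - 1L)])
        centers[j] <- cand[1L]
      } else {
        centers[j] <- sample.int(ps$n, 1L, prob = w)
      }
      d2new <- (ps$x - ps$x[centers[j]])^2 + (ps$y - ps$y[centers[j]])^2
      d2near <- pmin(d2near, d2new)
    }
    centers
  })
}

# Shared Lloyd-style alternation. center_fun(x, y) -> c(cx, cy);
# cost_fun(d2_assigned) -> scalar objective (d2 = squared distances).
lloyd_iterate <- function(ps, K, init_centers, center_fun, cost_fun,
                          max_iter = 300L) {
  cx <- init_centers[, 1L]; cy <- init_centers[, 2L]
  labels <- rep(0L, ps$n)
  trace <- numeric(0)
  reseeds <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- dist_to_centers(ps$x, ps$y, cx, cy)
    new_labels <- max.col(-d2, ties.method = "first")
    # revive empty clusters at the point farthest from its current center
    for (j in which(tabulate(new_labels, K) == 0L)) {
      far <- which.max(d2[cbind(seq_len(ps$n), new_labels)])
      new_labels[far] <- j
      cx[j] <- ps$x[far]; cy[j] <- ps$y[far]
      d2 <- dist_to_centers(ps$x, ps$y, cx, cy)
      reseeds <- reseeds + 1L
    }
    trace <- c(trace, cost_fun(d2[cbind(seq_len(ps$n), new_labels)]))
    if (identical(new_labels, labels)) {
      labels <- new_labels
      break
    }
    labels <- new_labels
    for (j in seq_len(K)) {
      idx <- labels == j
      cc <- center_fun(ps$x[idx], ps$y[idx])
      cx[j] <- cc[1L]; cy[j] <- cc[2L]
    }
  }
  d2 <- dist_to_centers(ps$x, ps$y, cx, cy)
  objective <- cost_fun(d2[cbind(seq_len(ps$n), labels)])
  list(labels = labels, centers = cbind(x = cx, y = cy),
       objective = objective, iterations = it, trace = trace,
       reseeds = reseeds)
}

#' K-median clustering (Lloyd-style with geometric-median centers)
#'
#' Alternates nearest-center assignment (Euclidean distance) with updating
#' each center to the geometric median of its cluster (modified Weiszfeld
#' iteration, tolerance 1e-8, at most 100 inner iterations), until the
#' assignment is stable or 300 outer iterations. The objective is the total
#' distance of points to their assigned centers. Initialization draws seeded
#' centers with probability proportional to the distance to the nearest
#' chosen center. An emptied cluster is re-seeded at the point farthest from
#' its current center.
#'
#' @inheritParams k_center
#' @param seed integer RNG seed for initialization (default 1).
#' @param median_type `"geometric"` (Weiszfeld, the true planar minimizer of
#'   the objective) or `"coordinate"` (independent per-axis medians).
#' @return A `baseline_result` with objective = sum of distances.
#' @export
k_median <- function(ps, K, seed = 1L, median_type = c("geometric", "coordinate")) {
  stopifnot(inherits(ps, "point_set"))
  K <- check_K(K, ps$n)
  median_type <- match.arg(median_type)
  init <- seeded_init(ps, K, seed, weight_fun = function(d2) sqrt(d2))
  center_fun <- if (median_type == "geometric") geometric_median else
    function(x, y) c(stats::median(x), stats::median(y))
  res <- lloyd_iterate(ps, K,
                       cbind(ps$x[init], ps$y[init]),
                       center_fun,
                       cost_fun = function(d2) sum(sqrt(d2)))
  new_baseline_result(res$labels, res$centers, res$objective,
                      res$iterations, seed, "k_median", res$trace)
}

#' K-means clustering (Lloyd's algorithm)
#'
#' Seeded k-means++ style initialization (next center drawn with probability
#' proportional to the squared distance to the nearest chosen center),
#' followed by Lloyd iterations: assign to the nearest center, update each
#' center to its cluster mean; stops on a stable assignment or after 300
#' iterations. The objective is the within-cluster sum of squared distances.
#' The per-iteration objective trace is retained so the Lloyd monotonicity
#' guarantee can be inspected.
#'
#' @inheritParams k_median
#' @return A `baseline_result` with objective = sum of squared distances and
#'   `objective_trace` per iteration.
#' @export
k_means <- function(ps, K, seed = 1L) {
  stopifnot(inherits(ps, "point_set"))
  K <- check_K(K, ps$n)
  init <- seeded_init(ps, K, seed, weight_fun = identity)
  res <- lloyd_iterate(ps, K,
                       cbind(ps$x[init], ps$y[init]),
                       center_fun = function(x, y) c(mean(x), mean(y)),
                       cost_fun = sum)
  new_baseline_result(res$labels, res$centers, res$objective,
                      res$iterations, seed, "k_means", res$trace)
}
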