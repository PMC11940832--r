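## The greedy K-area clusterer. Clusters live in a flat node table (a binary
## divisive tree); each round the leaf x hull-chord split with the largest
## area reduction delta = A(C) - [A(C1)+A(C2)] is applied, until the cluster
## count cap K or the depth cap H is reached or no leaf can be split.

#' Enumerate candidate splits of one cluster
#'
#' A bipartition of a cluster into two convex children is always induced by
#' a separating line, and any separating line can be slid until it passes
#' through two of the cluster's points; the candidate lines are therefore
#' all unordered pairs of member points — m (m-1) / 2 lines before
#' filtering. Each candidate line partitions the members with
#' [split_by_line()] (points on the line, including the two defining
#' points, go to the closed side 1); both child hulls are computed and the
#' area reduction delta = A(C) - [A(C1) + A(C2)] recorded. Lines with an
#' empty open side cannot produce two clusters and are discarded — in
#' particular a 2-point cluster, or a fully collinear one, has no valid
#' candidate. Enumeration order is deterministic (pairs in member order).
#'
#' @param ps a [point_set()].
#' @param members integer member indices of the cluster.
#' @param hull optional precomputed `hull_polygon` for the members.
#' @return List of candidates, each a list with `a_idx`, `b_idx`, `delta`,
#'   `members1`, `members2`, `hull1`, `hull2`. Empty list when the cluster
#'   cannot be split.
#' @export
enumerate_candidates <- function(ps, members, hull = NULL) {
  members <- check_members(ps, members)
  if (is.null(hull)) hull <- convex_hull(ps, members)
  m <- length(members)
  if (m < 2L) return(list())

  xs <- ps$x[members]; ys <- ps$y[members]
  tol <- orient_tol(xs, ys)
  out <- vector("list", m * (m - 1L) %/% 2L)
  cnt <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- members[i]; b <- members[j]
      if (xs[i] == xs[j] && ys[i] == ys[j]) next  # coincident: no line
      side <- side_of_line(xs, ys, xs[i], ys[i], xs[j], ys[j], tol = tol)
      m2 <- members[side == 2L]
      if (length(m2) == 0L) next
      m1 <- members[side == 1L]
      h1 <- convex_hull(ps, m1)
      h2 <- convex_hull(ps, m2)
      delta <- clamp_delta(hull$area - (h1$area + h2$area), hull$area)
      cnt <- cnt + 1L
      out[[cnt]] <- list(a_idx = a, b_idx = b, delta = delta,
                         members1 = m1, members2 = m2,
                         hull1 = h1, hull2 = h2)
    }
  }
  out[seq_len(cnt)]
}

# sub-additivity makes delta >= 0 up to roundoff; clamp the dust, trap bugs
clamp_delta <- function(delta, parent_area) {
  if (delta < 0) {
    if (delta < -1e-9 * max(parent_area, .Machine$double.eps))
      stop("negative area reduction beyond tolerance: geometry error")
    delta <- 0
  }
  delta
}

#' Best split of one cluster
#'
#' The candidate line (over all member pairs, see
#' [enumerate_candidates()]) with the largest area reduction. Ties (within
#' a small relative tolerance) are broken deterministically: prefer the
#' more balanced split (larger smaller-side size), then the
#' lexicographically smallest sorted index pair. The scan runs in compiled
#' code; its result is identical to taking the delta-maximum of
#' [enumerate_candidates()].
#'
#' @inheritParams enumerate_candidates
#' @return A single candidate list (`a_idx`, `b_idx`, `delta`, `members1`,
#'   `members2`, `hull1`, `hull2`), or `NULL` when the cluster has no
#'   valid split.
#' @export
best_split <- function(ps, members, hull = NULL) {
  members <- check_members(ps, members)
  if (length(members) < 2L) return(NULL)
  if (is.null(hull)) hull <- convex_hull(ps, members)
  xs <- ps$x[members]; ys <- ps$y[members]
  scan <- kac_best_split_scan(xs, ys, members, hull$area,
                              orient_tol(xs, ys))
  if (!scan$found) return(NULL)
  m1 <- members[scan$side1]
  m2 <- members[!scan$side1]
  h1 <- convex_hull(ps, m1)
  h2 <- convex_hull(ps, m2)
  list(a_idx = scan$a_idx, b_idx = scan$b_idx,
       delta = clamp_delta(hull$area - (h1$area + h2$area), hull$area),
       members1 = m1, members2 = m2, hull1 = h1, hull2 = h2)
}

new_node <- function(id, members, hull, depth, parent) {
  list(id = id, members = members, hull = hull, depth = depth,
       parent = parent, children = NULL, split = NULL)
}

#' Greedy divisive K-area clustering
#'
#' Starts from the convex hull of all points as a single cluster and
#' repeatedly bisects the leaf whose best hull-chord split removes the most
#' total area, growing a binary cluster tree. Stops when the number of leaf
#' clusters reaches `K`, when the tree depth reaches `H`, or when no leaf
#' admits a valid split (fewer leaves than requested; recorded as a
#' warning in the round log). Fully deterministic: no randomness anywhere.
#'
#' @param ps a [point_set()].
#' @param K target number of clusters (cap); `Inf` for unlimited.
#' @param H hierarchy depth cap (root has depth 1); `Inf` for unlimited.
#'   At least one of `K`, `H` must be finite.
#' @return An object of class `cluster_tree`: `nodes` (flat list of tree
#'   nodes), `root` (id 1), `leaves` (leaf node ids in creation order),
#'   `rounds` (per-round data.frame: round, k, h, total_area, ratio,
#'   cluster_split, delta), `n`, `params`, and `stopped_early` (TRUE when
#'   fewer than K leaves could be produced).
#' @examples
#' ps <- point_set(c(0, 1, 0, 10, 11, 10), c(0, 0, 1, 0, 0, 1))
#' tr <- kac_cluster(ps, K = 2)
#' cluster_labels(tr)
#' @export
kac_cluster <- function(ps, K = Inf, H = Inf) {
  stopifnot(inherits(ps, "point_set"))
  if (!is.numeric(K) || !is.numeric(H) || length(K) != 1L || length(H) != 1L)
    stop("K and H must be numeric scalars")
  if (is.infinite(K) && is.infinite(H))
    stop("at least one of K and H must be finite")
  if (K < 1 || H < 1)
    stop("K and H must be at least 1")
  if (is.finite(K) && K > ps$n) {
    warning(sprintf("K = %d exceeds the number of points; capped at N = %d",
                    as.integer(K), ps$n))
    K <- ps$n
  }

  root <- new_node(1L, seq_len(ps$n), convex_hull(ps), 1L, NA_integer_)
  nodes <- list(root)
  leaves <- 1L
  best <- list()   # cached best split per leaf id (list or "none")
  k <- 1L
  h <- 1L
  total <- root$hull$area
  rounds <- data.frame(round = 1L, k = 1L, h = 1L, total_area = total,
                       ratio = 0, cluster_split = NA_integer_,
                       delta = NA_real_)
  stopped_early <- FALSE

  # continue only while both caps have room: the first cap reached stops
  while (k < K && h < H) {
    # refresh best-split cache for new leaves
    for (id in leaves) {
      key <- as.character(id)
      if (is.null(best[[key]])) {
        nd <- nodes[[id]]
        bs <- best_split(ps, nd$members, nd$hull)
        best[[key]] <- if (is.null(bs)) "none" else bs
      }
    }
    splittable <- leaves[vapply(leaves, function(id)
      !identical(best[[as.character(id)]], "none"), logical(1))]
    if (length(splittable) == 0L) {
      stopped_early <- TRUE
      warning("no cluster admits a valid split; stopping with ",
              length(leaves), " clusters")
      break
    }
    deltas <- vapply(splittable, function(id)
      best[[as.character(id)]]$delta, numeric(1))
    eps <- 1e-12 * max(1, max(deltas))
    tied <- splittable[deltas >= max(deltas) - eps]
    i_star <- min(tied)  # earliest-created cluster wins ties
    cand <- best[[as.character(i_star)]]
    parent <- nodes[[i_star]]

    id1 <- length(nodes) + 1L
    id2 <- length(nodes) + 2L
    nodes[[id1]] <- new_node(id1, cand$members1, cand$hull1,
                             parent$depth + 1L, i_star)
    nodes[[id2]] <- new_node(id2, cand$members2, cand$hull2,
                             parent$depth + 1L, i_star)
    nodes[[i_star]]$children <- c(id1, id2)
    nodes[[i_star]]$split <- list(a_idx = cand$a_idx, b_idx = cand$b_idx,
                                  delta = cand$delta)
    leaves <- c(setdiff(leaves, i_star), id1, id2)
    best[[as.character(i_star)]] <- NULL

    k <- k + 1L
    h <- max(h, parent$depth + 1L)
    prev_total <- total
    total <- total - cand$delta
    rounds <- rbind(rounds, data.frame(
      round = k, k = k, h = h, total_area = total,
      ratio = if (prev_total > 0) total / prev_total else 1,
      cluster_split = i_star, delta = cand$delta))
  }

  structure(
    list(nodes = nodes, root = 1L, leaves = leaves, rounds = rounds,
         n = ps$n, params = list(K = K, H = H),
         stopped_early = stopped_early),
    class = "cluster_tree"
  )
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf(
    "cluster_tree: %d points, %d clusters, depth %d, total area %.6g\n",
    x$n, length(x$leaves), max(x$rounds$h),
    x$rounds$total_area[nrow(x$rounds)]))
  invisible(x)
}

#' Per-point cluster labels from a cluster tree
#'
#' Leaves are numbered 1..k in creation order (the order the divisive
#' algorithm produced them), matching the `C1..Ck` names used in tree
#' exports. Because the tree records the full divisive history, the
#' clustering at any intermediate round can be recovered by replaying the
#' splits: `k` asks for the state when the tree had `k` leaves.
#'
#' @param tree a `cluster_tree` from [kac_cluster()].
#' @param k optional intermediate leaf count (1 <= k <= number of leaves);
#'   default: the final clustering.
#' @return Integer vector of length N with values in 1..k.
#' @export
cluster_labels <- function(tree, k = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (is.null(k)) {
    leaves <- tree$leaves
  } else {
    if (k < 1L || k > length(tree$leaves))
      stop("k must be between 1 and the number of leaves")
    leaves <- 1L
    r <- 1L
    while (length(leaves) < k) {
      r <- r + 1L
      sp <- tree$rounds$cluster_split[r]
      leaves <- c(setdiff(leaves, sp), tree$nodes[[sp]]$children)
    }
  }
  lab <- integer(tree$n)
  for (j in seq_along(leaves))
    lab[tree$nodes[[leaves[j]]]$members] <- j
  lab
}

#' Total-area profile across divisive rounds
#'
#' Runs the divisive clusterer once up to `k_max` leaves and reports, for
#' each round r (= number of clusters), the total convex-hull area and the
#' neighboring-round ratio total_area(r) / total_area(r-1). The first
#' round's ratio is 0 by convention. Ratios near 1 signal that further
#' splitting removes little area.
#'
#' @param ps a [point_set()].
#' @param k_max largest cluster count to profile (1 <= k_max <= N).
#' @return An object of class `k_selection_profile`: data.frame with columns
#'   `k`, `total_area`, `ratio`, plus the full `cluster_tree` as attribute
#'   `"tree"`.
#' @export
area_profile <- function(ps, k_max) {
  stopifnot(inherits(ps, "point_set"))
  if (k_max < 1 || k_max > ps$n)
    stop("k_max must be between 1 and N")
  tree <- kac_cluster(ps, K = k_max)
  prof <- data.frame(k = tree$rounds$k,
                     total_area = tree$rounds$total_area,
                     ratio = tree$rounds$ratio)
  class(prof) <- c("k_selection_profile", "data.frame")
  attr(prof, "tree") <- tree
  prof
}

#' Choose the number of clusters from an area-ratio profile
#'
#' Returns the smallest k such that every later neighboring-round area ratio
#' is at least `tau`: beyond k, each additional split retains at least a
#' fraction `tau` of the previous total area, i.e. splitting has stopped
#' paying off. Returns the profile's largest k when no such k exists.
#'
#' @param profile a `k_selection_profile` from [area_profile()].
#' @param tau stabilization threshold in (0, 1); default 0.8.
#' @return Integer: the selected number of clusters.
#' @examples
#' prof <- structure(
#'   data.frame(k = 1:5, total_area = c(10, 1, .9, .85, .83),
#'              ratio = c(0, .1, .9, .94, .98)),
#'   class = c("k_selection_profile", "data.frame"))
#' select_k(prof)  # 2
#' @export
select_k <- function(profile, tau = 0.8) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 2L)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  k_max <- nrow(profile)
  for (k in seq_len(k_max - 1L)) {
    if (all(profile$ratio[(k + 1L):k_max] >= tau))
      return(profile$k[k])
  }
  profile$k[k_max]
}
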