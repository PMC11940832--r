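test_that("enumerate_candidates evaluates every two-sided line", {
  # strictly convex pentagon: every point is a hull vertex
  th <- 2 * pi * (0:4) / 5
  ps <- point_set(cos(th), sin(th))
  cands <- enumerate_candidates(ps, 1:5)
  expect_lte(length(cands), 10)  # m(m-1)/2 lines before filtering
  expect_gt(length(cands), 0)
  for (cc in cands) {
    expect_gt(length(cc$members1), 0)
    expect_gt(length(cc$members2), 0)
    expect_setequal(c(cc$members1, cc$members2), 1:5)
  }

  # 2-point cluster: the only line holds both points on the closed side
  expect_length(enumerate_candidates(point_set(c(0, 1), c(0, 0)), 1:2), 0)
  # fully collinear cluster: every candidate line contains all points
  expect_length(
    enumerate_candidates(point_set(c(0, 1, 2, 3), c(0, 0, 0, 0)), 1:4), 0)
})

test_that("candidate deltas match independent brute-force recomputation", {
  th <- 2 * pi * (0:5) / 6
  ps <- point_set(2 * cos(th), 2 * sin(th))
  h <- convex_hull(ps)
  cands <- enumerate_candidates(ps, 1:6, h)
  for (cc in cands) {
    a1 <- chull_area(ps$x[cc$members1], ps$y[cc$members1])
    a2 <- chull_area(ps$x[cc$members2], ps$y[cc$members2])
    expect_equal(cc$delta, max(0, h$area - a1 - a2), tolerance = 1e-12)
    expect_equal(cc$hull1$area, a1, tolerance = 1e-12)
    expect_equal(cc$hull2$area, a2, tolerance = 1e-12)
  }
})

test_that("best_split maximizes the area reduction", {
  # two unit squares far apart: the best split separates them and removes
  # exactly the joint hull area minus 2
  pp <- square_pair(10)
  h <- convex_hull(pp)
  bs <- best_split(pp, 1:8, h)
  expect_setequal(bs$members1, setdiff(1:8, bs$members2))
  grp <- sort(unique(pp$labels[bs$members1]))
  expect_length(grp, 1)  # one full square per side
  expect_equal(bs$delta, h$area - 2, tolerance = 1e-9)

  # equilateral triangle: only one candidate line survives the closed-side
  # rule; it isolates the apex and removes the whole area
  tri <- point_set(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  bs2 <- best_split(tri, 1:3)
  expect_equal(bs2$delta, convex_hull(tri)$area, tolerance = 1e-12)
  expect_identical(bs2$members2, 3L)
  expect_equal(bs2$hull1$area + bs2$hull2$area, 0)

  # consistency: the compiled scan equals the delta-max over the R
  # enumeration on random input
  for (seed in c(11, 22)) {
    ps <- random_points(30, seed)
    bs3 <- best_split(ps, 1:30)
    cands <- enumerate_candidates(ps, 1:30)
    expect_equal(bs3$delta, max(vapply(cands, `[[`, numeric(1), "delta")),
                 tolerance = 1e-9)
  }

  expect_null(best_split(point_set(c(0, 1), c(0, 0)), 1:2))
})

test_that("kac_cluster implements the greedy divisive loop", {
  # K = 1: the hull of all points is the single cluster
  ps <- random_points(20, 1)
  tr1 <- kac_cluster(ps, K = 1)
  expect_length(tr1$leaves, 1)
  expect_identical(cluster_labels(tr1), rep(1L, 20))

  # three well-separated triangles are recovered exactly at K = 3
  trio <- triangle_trio()
  tr3 <- kac_cluster(trio, K = 3)
  expect_length(tr3$leaves, 3)
  expect_equal(nmi(trio$labels, cluster_labels(tr3)), 1)
  planted_total <- sum(vapply(1:3, function(g)
    chull_area(trio$x[trio$labels == g], trio$y[trio$labels == g]),
    numeric(1)))
  expect_equal(tr3$rounds$total_area[3], planted_total, tolerance = 1e-9)
  expect_true(all(diff(tr3$rounds$total_area) <= 1e-9))

  # invalid parameters
  expect_error(kac_cluster(ps, K = 0), "at least 1")
  expect_error(kac_cluster(ps), "finite")
  # K above N is capped, and the 2-point child is unsplittable under the
  # closed-side rule, so the run also stops early
  expect_warning(
    expect_warning(tcap <- kac_cluster(point_set(c(0, 1, 2), c(0, 1, 0)),
                                       K = 10), "capped"),
    "no cluster admits")
  expect_lte(length(tcap$leaves), 3)
  expect_true(tcap$stopped_early)
})

test_that("the depth cap stops the loop as soon as it is reached", {
  ps <- generate_points(4, 10, separation = 8, seed = 5)
  tr <- kac_cluster(ps, K = Inf, H = 2)
  expect_equal(max(tr$rounds$h), 2)
  expect_length(tr$leaves, 2)  # first split reaches depth 2
})

test_that("leaves always partition the input and the objective is monotone", {
  for (seed in 1:8) {
    ps <- random_points(25 + seed, seed * 7)
    tr <- kac_cluster(ps, K = 5)
    members <- sort(unlist(lapply(tr$leaves, function(id)
      tr$nodes[[id]]$members)))
    expect_identical(members, seq_len(ps$n))
    expect_true(all(tr$rounds$delta[-1] >= 0))
    expect_true(all(diff(tr$rounds$total_area) <= 1e-9))
    expect_true(all(tr$rounds$ratio >= 0 & tr$rounds$ratio <= 1 + 1e-9))
    expect_identical(tr$rounds$ratio[1], 0)
  }
})

test_that("clustering is deterministic and rigid-motion invariant", {
  ps <- generate_points(3, 15, separation = 6, seed = 9)
  tr_a <- kac_cluster(ps, K = 3)
  tr_b <- kac_cluster(ps, K = 3)
  expect_identical(cluster_labels(tr_a), cluster_labels(tr_b))
  expect_identical(tr_a$rounds, tr_b$rounds)

  th <- 0.41
  ps_rot <- point_set(cos(th) * ps$x - sin(th) * ps$y + 17,
                      sin(th) * ps$x + cos(th) * ps$y - 3)
  tr_rot <- kac_cluster(ps_rot, K = 3)
  expect_equal(nmi(cluster_labels(tr_a), cluster_labels(tr_rot)), 1)
})

test_that("intermediate cuts of one run equal separate shorter runs", {
  ps <- generate_points(4, 12, separation = 8, seed = 21)
  tr8 <- kac_cluster(ps, K = 8)
  for (k in c(2, 4, 6)) {
    expect_identical(cluster_labels(tr8, k = k),
                     cluster_labels(kac_cluster(ps, K = k)))
  }
})

test_that("area_profile reports totals and neighboring-round ratios", {
  ps <- generate_points(4, 20, separation = 10, seed = 2)
  prof <- area_profile(ps, 8)
  expect_identical(prof$k, 1:8)
  expect_identical(prof$ratio[1], 0)
  expect_true(all(prof$ratio >= 0 & prof$ratio <= 1 + 1e-9))
  expect_true(all(diff(prof$total_area) <= 1e-9))
  # splitting within a blob removes little area: the ratio jumps after
  # the true cluster count
  expect_gt(prof$ratio[5] / max(prof$ratio[4], 1e-12), 2)
  expect_error(area_profile(ps, 0), "between")
})

test_that("select_k picks the smallest k after which ratios stabilize", {
  mk <- function(r) structure(
    data.frame(k = seq_along(r), total_area = rev(cumsum(rev(1 - r))),
               ratio = r),
    class = c("k_selection_profile", "data.frame"))
  expect_identical(select_k(mk(c(0, 0.1, 0.1, 0.95, 0.97)), tau = 0.8), 3L)
  expect_identical(select_k(mk(c(0, 0.9, 0.85, 0.95)), tau = 0.8), 1L)
  expect_identical(select_k(mk(c(0, 0.1, 0.2, 0.3)), tau = 0.8), 4L)
  expect_error(select_k(mk(c(0, 0.5)), tau = 2), "tau")
})

test_that("runtime grows no faster than the cubic-log model (coarse)", {
  ps1 <- generate_points(4, 20, separation = 10, seed = 3)   # N = 80
  ps2 <- generate_points(4, 40, separation = 10, seed = 3)   # N = 160
  t1 <- min(replicate(3, system.time(kac_cluster(ps1, K = 4))[["elapsed"]]))
  t2 <- min(replicate(3, system.time(kac_cluster(ps2, K = 4))[["elapsed"]]))
  model_ratio <- (160^3 * log(160)) / (80^3 * log(80))  # ~8.8
  expect_lt(t2 / max(t1, 0.01), 6 * model_ratio)
})
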