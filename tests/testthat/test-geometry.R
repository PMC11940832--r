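test_that("convex_hull handles simple, degenerate and duplicated input", {
  ps <- point_set(c(0, 1, 0), c(0, 0, 1))
  h <- convex_hull(ps)
  expect_setequal(h$vertices, 1:3)
  expect_length(h$interior, 0)
  expect_equal(h$area, 0.5)

  # collinear sets degrade to a two-vertex ring with area 0, not an error
  ps2 <- point_set(c(0, 1, 2, 3), c(0, 1, 2, 3))
  h2 <- convex_hull(ps2)
  expect_length(h2$vertices, 2)
  expect_equal(h2$area, 0)
  expect_setequal(c(h2$vertices, h2$interior), 1:4)

  # single point
  h3 <- convex_hull(point_set(2, 3))
  expect_equal(h3$vertices, 1L)
  expect_equal(h3$area, 0)

  # exact duplicates collapse to one vertex (smallest index), duplicates
  # stay members in the interior list
  ps4 <- point_set(c(0, 1, 0, 0, 1), c(0, 0, 1, 0, 0))
  h4 <- convex_hull(ps4)
  expect_setequal(h4$vertices, 1:3)
  expect_setequal(h4$interior, 4:5)
  expect_equal(h4$area, 0.5)

  expect_error(convex_hull(ps, integer(0)), "non-empty")
})

test_that("hull ring is clockwise and starts at the lexicographic minimum", {
  for (seed in 1:20) {
    ps <- random_points(40, seed)
    h <- convex_hull(ps)
    v <- h$vertices
    lex <- order(ps$x[v], ps$y[v])[1]
    expect_identical(v[1], v[lex])
    # clockwise ring: signed shoelace sum is negative
    xs <- ps$x[v]; ys <- ps$y[v]
    nxt <- c(seq_along(v)[-1], 1L)
    expect_lt(sum(xs * ys[nxt] - ys * xs[nxt]), 0)
    # strict convexity: no three consecutive ring vertices collinear
    if (length(v) > 2) {
      m <- length(v)
      for (i in seq_len(m)) {
        a <- v[i]; b <- v[i %% m + 1L]; cc <- v[(i + 1L) %% m + 1L]
        cr <- (ps$x[b] - ps$x[a]) * (ps$y[cc] - ps$y[a]) -
          (ps$y[b] - ps$y[a]) * (ps$x[cc] - ps$x[a])
        expect_gt(abs(cr), 0)
      }
    }
  }
})

test_that("convex_hull matches an independent gift-wrapping oracle", {
  for (seed in 1:60) {
    n <- 5 + (seed %% 40)
    ps <- random_points(n, seed + 1000)
    expect_setequal(convex_hull(ps)$vertices,
                    gift_wrap_vertices(ps$x, ps$y))
  }
})

test_that("every member lies inside or on its hull", {
  for (seed in c(3, 14, 159)) {
    ps <- random_points(50, seed)
    h <- convex_hull(ps)
    expect_true(all(kareaclust:::point_in_hull(ps, h, ps$x, ps$y)))
  }
})

test_that("polygon_area implements the shoelace convention", {
  sq <- point_set(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(convex_hull(sq)$area, 1)
  expect_equal(polygon_area(convex_hull(sq), sq), 1)

  expect_equal(convex_hull(point_set(0, 0))$area, 0)
  expect_equal(convex_hull(point_set(c(0, 2), c(0, 1)))$area, 0)

  # random strictly convex 7-gon: area equals fan triangulation
  set.seed(42)
  th <- sort(runif(7, 0, 2 * pi))
  r <- 2 + runif(7, 0, 0.3)
  ps <- point_set(r * cos(th), r * sin(th))
  h <- convex_hull(ps)
  expect_length(h$vertices, 7)
  expect_equal(h$area, fan_area(ps$x[h$vertices], ps$y[h$vertices]),
               tolerance = 1e-12)
})

test_that("area is rigid-motion invariant and scales quadratically", {
  ps <- random_points(30, 7)
  a0 <- convex_hull(ps)$area
  th <- 0.73
  rx <- cos(th) * ps$x - sin(th) * ps$y + 100
  ry <- sin(th) * ps$x + cos(th) * ps$y - 55
  expect_equal(convex_hull(point_set(rx, ry))$area, a0,
               tolerance = 1e-9)
  s <- 3.7
  expect_equal(convex_hull(point_set(s * ps$x, s * ps$y))$area, s^2 * a0,
               tolerance = 1e-9)
})

test_that("side_of_line follows the closed >= rule and the slope form", {
  # opposite sides of the x axis
  expect_identical(side_of_line(c(0.5, 0.5), c(1, -1), 0, 0, 1, 0),
                   c(2L, 1L))
  # a point on the line, and the endpoints themselves, are side 1
  expect_identical(side_of_line(0, 0, 0, 0, 1, 0), 1L)
  expect_identical(side_of_line(0.5, 0, 0, 0, 1, 0), 1L)
  # argument order does not change the classification
  expect_identical(side_of_line(c(0.3, 0.9), c(2, -4), 0, 0, 1, 1),
                   side_of_line(c(0.3, 0.9), c(2, -4), 1, 1, 0, 0))
  expect_error(side_of_line(1, 1, 2, 3, 2, 3), "distinct")

  # oracle equivalence with the slope form on non-vertical lines
  set.seed(99)
  for (rep in 1:1000) {
    a <- runif(2, -5, 5); b <- runif(2, -5, 5); p <- runif(2, -5, 5)
    if (abs(a[1] - b[1]) < 1e-3) next
    expect_identical(side_of_line(p[1], p[2], a[1], a[2], b[1], b[2]),
                     slope_form_side(p[1], p[2], a[1], a[2], b[1], b[2]))
  }

  # vertical line: closed right half-plane is side 1
  expect_identical(side_of_line(c(1, -1, 0), c(5, 5, 5), 0, 0, 0, 1),
                   c(1L, 2L, 1L))
})

test_that("split_by_line partitions exactly and respects hull nesting", {
  sq <- point_set(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sp <- split_by_line(sq, 1:4, 1L, 3L)  # diagonal (0,0)-(1,1)
  expect_setequal(sp$members1, c(1L, 2L, 3L))
  expect_identical(sp$members2, 4L)

  # conservation on random splits
  for (seed in 1:10) {
    ps <- random_points(35, seed + 500)
    h <- convex_hull(ps)
    v <- h$vertices
    sp <- split_by_line(ps, seq_len(ps$n), v[1], v[ceiling(length(v) / 2)])
    expect_identical(sort(c(sp$members1, sp$members2)), seq_len(ps$n))
    expect_length(intersect(sp$members1, sp$members2), 0)
    # sub-additivity of child areas
    a1 <- convex_hull(ps, sp$members1)$area
    a2 <- if (length(sp$members2)) convex_hull(ps, sp$members2)$area else 0
    expect_lte(a1 + a2, h$area * (1 + 1e-9))
  }

  # two separated squares split by a line between them
  pp <- square_pair(10)
  sp2 <- split_by_line(
    point_set(c(pp$x, 5, 5), c(pp$y, -1, 2)), 1:10, 9L, 10L)
  # vertical split line: the closed side 1 is the right half-plane
  expect_setequal(setdiff(sp2$members1, 9:10), 5:8)
  expect_setequal(setdiff(sp2$members2, 9:10), 1:4)

  expect_error(split_by_line(sq, 1:3, 1L, 4L), "belong")
})
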