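# Independent oracles used to cross-check the implementation. These share
# no code with the package: gift-wrapping instead of a sorted chain, fan
# triangulation instead of the shoelace ring sum, chull()-based hulls for
# brute-force split scans, and a direct term-by-term NMI formula.

# Jarvis-march (gift wrapping) hull: returns the vertex index set.
gift_wrap_vertices <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(1L)
  start <- order(x, y)[1L]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      d2r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      d2q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      if (cr < 0 || (cr == 0 && d2r > d2q)) q <- r
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) stop("gift wrap failed to close")
  }
  sort(unique(hull))
}

# Fan triangulation area over an ordered vertex ring.
fan_area <- function(xs, ys) {
  m <- length(xs)
  if (m < 3L) return(0)
  s <- 0
  for (i in 2:(m - 1L)) {
    s <- s + ((xs[i] - xs[1L]) * (ys[i + 1L] - ys[1L]) -
                (ys[i] - ys[1L]) * (xs[i + 1L] - xs[1L])) / 2
  }
  abs(s)
}

# Convex hull area via grDevices::chull (independent of the package's
# chain) with a cross-product ring sum.
chull_area <- function(xx, yy) {
  if (length(xx) < 3L) return(0)
  h <- grDevices::chull(xx, yy)
  if (length(h) < 3L) return(0)
  xs <- xx[h]; ys <- yy[h]
  nxt <- c(seq_along(h)[-1L], 1L)
  abs(sum(xs * ys[nxt] - ys * xs[nxt])) / 2
}

# Literal slope-form classification of Eq-(2)/(3) type for non-vertical
# lines: side 1 iff the line's value at x_p is >= y_p.
slope_form_side <- function(px, py, ax, ay, bx, by) {
  stopifnot(ax != bx)
  m <- (ay - by) / (ax - bx)
  lv <- m * (px - ax) + ay
  ifelse(lv >= py, 1L, 2L)
}

# Brute-force best area reduction over every candidate line (all pairs of
# member points, on-line points to the closed side) — the exhaustive
# oracle for greedy-step optimality.
brute_best_delta <- function(x, y) {
  m <- length(x)
  if (m < 2L) return(NULL)
  dx <- diff(range(x)); dy <- diff(range(y))
  tol <- 1e-12 * max(dx * dx + dy * dy, .Machine$double.xmin)
  parent <- chull_area(x, y)
  best <- NULL
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]
      if (ax == bx && ay == by) next
      if (ax > bx || (ax == bx && ay > by)) {
        t <- ax; ax <- bx; bx <- t
        t <- ay; ay <- by; by <- t
      }
      cr <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
      s1 <- cr <= tol
      if (all(s1)) next
      delta <- parent - chull_area(x[s1], y[s1]) - chull_area(x[!s1], y[!s1])
      if (is.null(best) || delta > best) best <- delta
    }
  }
  best
}

# Direct term-by-term NMI in log base 2 (the ratio is base-invariant, so
# this must agree with the natural-log implementation).
nmi_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  pa <- vapply(ua, function(u) sum(a == u) / n, numeric(1))
  pb <- vapply(ub, function(v) sum(b == v) / n, numeric(1))
  ha <- -sum(pa * log2(pa))
  hb <- -sum(pb * log2(pb))
  if (ha == 0 || hb == 0) return(if (ha == 0 && hb == 0) 1 else 0)
  mi <- 0
  for (u in ua) for (v in ub) {
    puv <- sum(a == u & b == v) / n
    if (puv > 0)
      mi <- mi + puv * log2(puv / (pa[match(u, ua)] * pb[match(v, ub)]))
  }
  mi / sqrt(ha * hb)
}
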