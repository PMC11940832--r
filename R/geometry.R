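## Exact-ish 2D computational geometry used by the divisive clusterer:
## convex hulls (Graham-scan family), shoelace areas, and line-based
## bipartition of a point set. All predicates share one orientation
## tolerance so classification is deterministic under roundoff.

# Squared-cross-product tolerance: |cross| below this is "on the line".
# scale is the bounding-box diagonal of the coordinates in play, so the
# threshold follows the data's units (cross products scale as length^2).
orient_tol <- function(xs, ys) {
  dx <- diff(range(xs))
  dy <- diff(range(ys))
  1e-12 * max(dx * dx + dy * dy, .Machine$double.xmin)
}

# Signed cross product (b - a) x (p - a); vectorized over p.
cross_sign <- function(ax, ay, bx, by, px, py) {
  (bx - ax) * (py - ay) - (by - ay) * (px - ax)
}

#' Convex hull of a member subset
#'
#' Computes the minimal convex polygon enclosing the selected points, using a
#' monotone-chain scan (the sort-then-scan Graham family). The vertex ring is
#' returned in clockwise order starting from the lexicographically smallest
#' vertex (smallest x, then smallest y); collinear points on hull edges are
#' not vertices, so the ring is strictly convex. Points sharing identical
#' coordinates collapse to a single vertex (the one with the smallest index);
#' all remaining members are reported as interior.
#'
#' Degenerate inputs follow the zero-area convention: a single point yields a
#' one-vertex ring, a collinear set yields the two extreme points as a
#' two-vertex ring, and both have area 0.
#'
#' @param ps a [point_set()].
#' @param members integer vector of point indices (defaults to all points).
#' @return An object of class `hull_polygon`: list with `vertices` (point
#'   indices, clockwise ring), `interior` (non-vertex members), `area`
#'   (non-negative), and `members`.
#' @examples
#' ps <- point_set(c(0, 1, 0, 0.2), c(0, 0, 1, 0.2))
#' h <- convex_hull(ps)
#' h$area  # 0.5
#' @export
convex_hull <- function(ps, members = seq_len(ps$n)) {
  members <- check_members(ps, members)
  members <- sort(members)
  xs <- ps$x[members]
  ys <- ps$y[members]

  # collapse exact duplicate coordinates; first occurrence (smallest index)
  # is the representative
  dup <- duplicated(cbind(xs, ys))
  ux <- xs[!dup]; uy <- ys[!dup]; uidx <- members[!dup]

  if (length(ux) == 1L) {
    ring <- uidx
  } else {
    tol <- orient_tol(ux, uy)
    ord <- order(ux, uy)
    px <- ux[ord]; py <- uy[ord]; pid <- uidx[ord]
    m <- length(px)

    build_chain <- function(idx) {
      stack <- integer(length(idx))
      top <- 0L
      for (i in idx) {
        while (top >= 2L) {
          a <- stack[top - 1L]; b <- stack[top]
          if (cross_sign(px[a], py[a], px[b], py[b], px[i], py[i]) <= tol)
            top <- top - 1L
          else break
        }
        top <- top + 1L
        stack[top] <- i
      }
      stack[seq_len(top)]
    }

    lower <- build_chain(seq_len(m))
    upper <- build_chain(rev(seq_len(m)))
    ring_pos <- c(lower[-length(lower)], upper[-length(upper)])
    if (length(ring_pos) < 2L) ring_pos <- unique(c(lower, upper))
    ring_ccw <- pid[ring_pos]
    # monotone chain emits counterclockwise; flip to clockwise keeping the
    # lexicographically smallest vertex first
    ring <- if (length(ring_ccw) > 2L)
      c(ring_ccw[1L], rev(ring_ccw[-1L]))
    else ring_ccw
  }

  area <- shoelace_area(ps$x[ring], ps$y[ring])
  structure(
    list(vertices = ring,
         interior = setdiff(members, ring),
         area = area,
         members = members),
    class = "hull_polygon"
  )
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat(sprintf("hull_polygon: %d vertices, %d interior, area %.6g\n",
              length(x$vertices), length(x$interior), x$area))
  invisible(x)
}

# Shoelace formula over a closed ring: 1/2 |sum_i (x_i y_{i+1} - y_i x_{i+1})|.
shoelace_area <- function(xs, ys) {
  m <- length(xs)
  if (m < 3L) return(0)
  nxt <- c(2:m, 1L)
  abs(sum(xs * ys[nxt] - ys * xs[nxt])) / 2
}

#' Area of a hull polygon
#'
#' Shoelace (surveyor's) formula over the hull's closed vertex ring:
#' \eqn{\frac{1}{2}\left|\sum_i (x_i y_{i+1} - y_i x_{i+1})\right|}. Rings
#' with fewer than three vertices (single points, collinear segments) have
#' area 0 by convention.
#'
#' @param h a `hull_polygon` from [convex_hull()].
#' @param ps the [point_set()] that `h` was computed from.
#' @return Non-negative numeric scalar.
#' @export
polygon_area <- function(h, ps) {
  stopifnot(inherits(h, "hull_polygon"))
  shoelace_area(ps$x[h$vertices], ps$y[h$vertices])
}

#' Classify points against a separating line
#'
#' Classifies each query point relative to the line through `a` and `b` by
#' the sign of the cross product, after canonicalizing the pair so the
#' result does not depend on argument order. Side 1 is the closed side: it
#' contains the line itself, so `a`, `b` and any point within the orientation
#' tolerance of the line are assigned to side 1. For non-vertical lines this
#' reproduces the slope-form comparison "line value at x_p >= y_p" exactly;
#' for vertical lines (where the slope form is undefined) the orientation
#' test extends the rule continuously (side 1 is the closed right half-plane).
#'
#' @param px,py numeric vectors: query point coordinates.
#' @param ax,ay,bx,by scalars: two distinct points defining the line.
#' @param tol optional orientation tolerance; defaults to one derived from
#'   the bounding box of all coordinates supplied.
#' @return Integer vector of 1 (closed side) and 2 (open side).
#' @examples
#' side_of_line(c(0.5, 0.5), c(1, -1), 0, 0, 1, 0)  # 2 1
#' @export
side_of_line <- function(px, py, ax, ay, bx, by, tol = NULL) {
  if (ax == bx && ay == by)
    stop("line endpoints must be distinct")
  # canonical lexicographic order (x, then y) so both argument orders and
  # the vertical-line case classify identically
  if (ax > bx || (ax == bx && ay > by)) {
    tmp <- ax; ax <- bx; bx <- tmp
    tmp <- ay; ay <- by; by <- tmp
  }
  if (is.null(tol))
    tol <- orient_tol(c(px, ax, bx), c(py, ay, by))
  cr <- cross_sign(ax, ay, bx, by, px, py)
  ifelse(cr <= tol, 1L, 2L)
}

#' Bipartition a member set by a line through two of its points
#'
#' Splits the members into the two sides of the line through points `a_idx`
#' and `b_idx` using [side_of_line()]; on-line points (including the two
#' endpoints) land on side 1. When `check = TRUE` the hull-nesting guarantee
#' is verified: every hull vertex of the parent must reappear as a hull
#' vertex of one of the children.
#'
#' @param ps a [point_set()].
#' @param members integer vector of point indices to split.
#' @param a_idx,b_idx point indices (within `members`) defining the line;
#'   intended to be hull vertices of the member set.
#' @param check verify the parent-hull-vertex nesting property (default TRUE).
#' @return List with `members1` and `members2` (disjoint, union = members).
#' @export
split_by_line <- function(ps, members, a_idx, b_idx, check = TRUE) {
  members <- check_members(ps, members)
  a_idx <- as.integer(a_idx); b_idx <- as.integer(b_idx)
  if (!(a_idx %in% members) || !(b_idx %in% members))
    stop("a_idx and b_idx must belong to the member set")
  if (ps$x[a_idx] == ps$x[b_idx] && ps$y[a_idx] == ps$y[b_idx])
    stop("line endpoints must have distinct coordinates")

  xs <- ps$x[members]; ys <- ps$y[members]
  tol <- orient_tol(xs, ys)
  side <- side_of_line(xs, ys, ps$x[a_idx], ps$y[a_idx],
                       ps$x[b_idx], ps$y[b_idx], tol = tol)
  out <- list(members1 = members[side == 1L], members2 = members[side == 2L])

  if (check && length(out$members1) && length(out$members2)) {
    parent_v <- convex_hull(ps, members)$vertices
    child_v <- c(convex_hull(ps, out$members1)$vertices,
                 convex_hull(ps, out$members2)$vertices)
    if (!all(parent_v %in% child_v))
      stop("hull nesting violated: a parent hull vertex is not a child hull vertex")
  }
  out
}

# Boundary-inclusive point-in-convex-polygon test against a clockwise ring.
# Used by tests and by the containment invariant; vectorized over p.
point_in_hull <- function(ps, h, px, py) {
  v <- h$vertices
  m <- length(v)
  if (m == 1L)
    return(abs(px - ps$x[v]) < 1e-9 & abs(py - ps$y[v]) < 1e-9)
  xs <- ps$x[v]; ys <- ps$y[v]
  tol <- orient_tol(c(xs, px), c(ys, py))
  if (m == 2L) {
    on_line <- abs(cross_sign(xs[1], ys[1], xs[2], ys[2], px, py)) <= tol
    within <- px >= min(xs) - 1e-9 & px <= max(xs) + 1e-9 &
      py >= min(ys) - 1e-9 & py <= max(ys) + 1e-9
    return(on_line & within)
  }
  inside <- rep(TRUE, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # clockwise ring: interior is on the right of each directed edge
    inside <- inside &
      cross_sign(xs[i], ys[i], xs[j], ys[j], px, py) <= tol
  }
  inside
}
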