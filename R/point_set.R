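#' Construct a 2D point set
#'
#' A `point_set` is the basic container for all clustering operations: an
#' ordered collection of N points in the plane, optionally carrying a true
#' (reference) label per point. Point indices 1..N are stable identities:
#' every cluster, hull and tree refers to points by these indices.
#'
#' @param x,y numeric vectors of equal length with finite coordinates.
#' @param labels optional vector of per-point category labels (length N).
#' @param ids optional character vector of point identifiers (e.g. cell ids).
#' @return An object of class `point_set` with fields `x`, `y`, `n`,
#'   `labels` (or `NULL`) and `ids` (or `NULL`).
#' @examples
#' ps <- point_set(c(0, 1, 0), c(0, 0, 1))
#' ps$n
#' @export
point_set <- function(x, y, labels = NULL, ids = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (length(x) < 1L)
    stop("a point_set needs at least one point")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  if (!is.null(labels) && length(labels) != length(x))
    stop("labels must have one entry per point")
  if (!is.null(ids) && length(ids) != length(x))
    stop("ids must have one entry per point")
  structure(
    list(x = x, y = y, n = length(x), labels = labels, ids = ids),
    class = "point_set"
  )
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set with %d points%s\n", x$n,
              if (is.null(x$labels)) "" else
                sprintf(" (%d labelled groups)", length(unique(x$labels)))))
  invisible(x)
}

#' @export
as.data.frame.point_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  d <- data.frame(x = x$x, y = x$y)
  if (!is.null(x$labels)) d$label <- x$labels
  if (!is.null(x$ids)) d$id <- x$ids
  d
}

# Validate a member-index subset against a point set.
check_members <- function(ps, members) {
  members <- as.integer(members)
  if (length(members) < 1L)
    stop("member set must be non-empty")
  if (anyNA(members) || any(members < 1L) || any(members > ps$n))
    stop("member indices out of range")
  if (anyDuplicated(members))
    stop("member indices must be unique")
  members
}
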