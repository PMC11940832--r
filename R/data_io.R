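## File formats and the PCA front end. Points travel as CSV (x, y, optional
## label); expression matrices as dense CSV or MatrixMarket MTX with row/
## column name sidecars. Orientation (cells x genes vs genes x cells) is
## always declared explicitly, never guessed from shape.

#' Read a 2D point set from CSV
#'
#' Expects a header row. Coordinate columns are taken by name (`x`, `y`)
#' when present, otherwise by position (first two columns); a `label`
#' column (or any remaining third column named `label`) supplies true
#' labels. Row order defines the point indices.
#'
#' @param path CSV file path.
#' @return A [point_set()].
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("point CSV needs at least two columns (x, y)")
  nm <- tolower(names(d))
  xi <- if ("x" %in% nm) which(nm == "x")[1L] else 1L
  yi <- if ("y" %in% nm) which(nm == "y")[1L] else setdiff(1:2, xi)[1L]
  xs <- suppressWarnings(as.numeric(d[[xi]]))
  ys <- suppressWarnings(as.numeric(d[[yi]]))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop(sprintf("non-numeric coordinate at data row %d of %s", bad[1L], path))
  labels <- if ("label" %in% nm) d[[which(nm == "label")[1L]]] else NULL
  point_set(xs, ys, labels = labels)
}

#' Write a 2D point set to CSV
#'
#' Emits columns `x,y` plus `label` when labels are present; numbers are
#' formatted so [read_points()] round-trips coordinates and labels exactly.
#'
#' @param ps a [point_set()].
#' @param path output CSV path.
#' @export
write_points <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  d <- data.frame(x = sprintf("%.17g", ps$x), y = sprintf("%.17g", ps$y))
  if (!is.null(ps$labels)) d$label <- ps$labels
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Dense CSV (first column = row ids, header = column ids) or MatrixMarket
#' MTX with two sidecar text files naming rows and columns (one id per
#' line). The `orientation` flag declares how the file is laid out; the
#' returned matrix is always cells x genes.
#'
#' @param path CSV or MTX file.
#' @param format `"csv"` or `"mtx"`.
#' @param orientation `"cells_x_genes"` (default) or `"genes_x_cells"`
#'   describing the file on disk.
#' @param row_names,col_names sidecar files for MTX (required).
#' @return An `expression_matrix`: list with `values` (cells x genes dense
#'   matrix), `cell_ids`, `gene_ids`.
#' @export
read_expression <- function(path, format = c("csv", "mtx"),
                            orientation = c("cells_x_genes", "genes_x_cells"),
                            row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "csv") {
    d <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(d)
    rid <- rownames(m); cid <- colnames(m)
  } else {
    if (is.null(row_names) || is.null(col_names))
      stop("MTX input requires row_names and col_names sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rid <- readLines(row_names)
    cid <- readLines(col_names)
    if (length(rid) != nrow(m) || length(cid) != ncol(m))
      stop("sidecar name files do not match the MTX dimensions")
    rownames(m) <- rid; colnames(m) <- cid
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty expression matrix")
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("expression values must be finite")
  if (orientation == "genes_x_cells") m <- t(m)
  structure(list(values = m, cell_ids = rownames(m), gene_ids = colnames(m)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Project an expression matrix to 2D by PCA
#'
#' The clustering front end: optional library-size normalization (counts
#' per 10,000 then log1p), column centering, and projection onto the top
#' two principal components via a deterministic singular value
#' decomposition. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the embedding
#' reproducible across runs and platforms.
#'
#' @param em an `expression_matrix` from [read_expression()].
#' @param transform `"log1p-cpm"` (default; counts per 1e4, then log1p) or
#'   `"none"`.
#' @return A [point_set()] of the cells (PC1 = x, PC2 = y) with cell ids.
#' @export
embed_2d <- function(em, transform = c("log1p-cpm", "none")) {
  stopifnot(inherits(em, "expression_matrix"))
  transform <- match.arg(transform)
  m <- em$values
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 cells and 2 genes")
  if (transform == "log1p-cpm") {
    libs <- rowSums(m)
    if (any(libs <= 0)) stop("cells with zero total counts cannot be normalized")
    m <- log1p(m / libs * 1e4)
  }
  m <- sweep(m, 2L, colMeans(m))
  if (max(abs(m)) == 0) stop("matrix is constant: no variance to embed")

  if (ncol(m) > nrow(m)) {
    # wide matrices: eigen-decompose the n x n Gram matrix
    eg <- eigen(tcrossprod(m), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[1:2], 0))
    u <- eg$vectors[, 1:2, drop = FALSE]
    scores <- u %*% diag(d, 2L)
    loadings <- crossprod(m, u) %*% diag(ifelse(d > 0, 1 / d, 0), 2L)
  } else {
    sv <- svd(m, nu = 2L, nv = 2L)
    scores <- sv$u %*% diag(sv$d[1:2], 2L)
    loadings <- sv$v
  }
  for (j in 1:2) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  point_set(scores[, 1L], scores[, 2L], ids = em$cell_ids)
}
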