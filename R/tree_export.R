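## Serialization of the divisive cluster tree: a JSON document that
## round-trips exactly, a Newick string for tree viewers, and the per-round
## log as TSV.

#' Serialize a cluster tree to JSON
#'
#' Emits the complete tree: for every node its id, parent, depth, member
#' indices, hull vertex ring, interior members, area, children and (for
#' internal nodes) the split line and its area reduction delta; plus the
#' per-round log. [tree_from_json()] reconstructs an identical tree, so
#' serialize-parse-serialize is the identity.
#'
#' @param tree a `cluster_tree` from [kac_cluster()].
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, parent = nd$parent, depth = nd$depth,
                members = nd$members,
                hull_vertices = nd$hull$vertices,
                interior = nd$hull$interior,
                area = nd$hull$area)
    if (!is.null(nd$children)) {
      out$children <- nd$children
      out$split <- list(a_idx = nd$split$a_idx, b_idx = nd$split$b_idx,
                        delta = nd$split$delta)
    }
    out
  })
  doc <- list(n = tree$n, root = tree$root, leaves = tree$leaves,
              params = list(K = unbox_cap(tree$params$K),
                            H = unbox_cap(tree$params$H)),
              stopped_early = tree$stopped_early,
              nodes = nodes,
              rounds = as.list(tree$rounds))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

# Inf is not representable in JSON; encode unlimited caps as the string "Inf".
unbox_cap <- function(v) if (is.infinite(v)) "Inf" else v
rebox_cap <- function(v) if (identical(v, "Inf")) Inf else as.numeric(v)

#' Parse a cluster tree from JSON
#'
#' Inverse of [tree_to_json()].
#'
#' @param x a JSON string or a path to a JSON file.
#' @return A `cluster_tree`.
#' @export
tree_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- lapply(doc$nodes, function(nd) {
    hull <- structure(
      list(vertices = as.integer(nd$hull_vertices),
           interior = as.integer(nd$interior %||% integer(0)),
           area = as.numeric(nd$area),
           members = sort(as.integer(nd$members))),
      class = "hull_polygon")
    node <- new_node(as.integer(nd$id), as.integer(nd$members), hull,
                     as.integer(nd$depth),
                     if (is.null(nd$parent)) NA_integer_ else as.integer(nd$parent))
    if (!is.null(nd$children)) {
      node$children <- as.integer(nd$children)
      node$split <- list(a_idx = as.integer(nd$split$a_idx),
                         b_idx = as.integer(nd$split$b_idx),
                         delta = as.numeric(nd$split$delta))
    }
    node
  })
  rounds <- as.data.frame(lapply(doc$rounds, function(col) {
    if (is.null(col)) return(NA)  # single-round tree, all-null column
    if (is.list(col))
      col <- lapply(col, function(v) if (is.null(v)) NA else v)
    unlist(col)
  }))
  rounds$round <- as.integer(rounds$round)
  rounds$k <- as.integer(rounds$k)
  rounds$h <- as.integer(rounds$h)
  rounds$cluster_split <- as.integer(rounds$cluster_split)
  rounds$delta <- as.numeric(rounds$delta)
  structure(
    list(nodes = nodes, root = as.integer(doc$root),
         leaves = as.integer(doc$leaves), rounds = rounds,
         n = as.integer(doc$n),
         params = list(K = rebox_cap(doc$params$K), H = rebox_cap(doc$params$H)),
         stopped_early = isTRUE(doc$stopped_early)),
    class = "cluster_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Newick export of a cluster tree
#'
#' Leaves are named `C1..Ck` in creation order (matching
#' [cluster_labels()]); each child edge carries, as its branch length, the
#' area reduction delta of the split that created it. A single-leaf tree is
#' `"C1;"`.
#'
#' @param tree a `cluster_tree`.
#' @param path optional file to write.
#' @return The Newick string, invisibly when written to a file.
#' @export
tree_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  leaf_name <- stats::setNames(paste0("C", seq_along(tree$leaves)),
                               tree$leaves)
  walk <- function(id) {
    nd <- tree$nodes[[id]]
    if (is.null(nd$children)) return(leaf_name[[as.character(id)]])
    kids <- vapply(nd$children, function(ch)
      sprintf("%s:%s", walk(ch), format(nd$split$delta, digits = 15)),
      character(1))
    sprintf("(%s)", paste(kids, collapse = ","))
  }
  nwk <- paste0(walk(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write the per-round log as TSV
#'
#' Columns: round, k, h, total_area, ratio, cluster_split, delta — one row
#' per divisive round, the first row being the single-cluster state with
#' ratio 0.
#'
#' @param tree a `cluster_tree`.
#' @param path output TSV path.
#' @param header_lines optional character vector of comment lines (prefixed
#'   `#`) to place above the column header.
#' @export
write_round_log <- function(tree, path, header_lines = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  df <- tree$rounds
  df$total_area <- sprintf("%.10g", df$total_area)
  df$ratio <- sprintf("%.10g", df$ratio)
  df$delta <- ifelse(is.na(df$delta), "NA", sprintf("%.10g", df$delta))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
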