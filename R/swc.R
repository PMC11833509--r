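#' Construct a neurite tree
#'
#' A rooted tree of 3D nodes with radii, following the SWC convention:
#' 1-based integer ids, `parent = -1` for the single root, coordinates in
#' micrometres, radii required and positive.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `radius`,
#'   `parent` (optional `type`, defaulting to 0).
#' @return object of class `neurite_tree`: the validated node table plus
#'   precomputed children lists and edge lengths.
#' @export
neurite_tree <- function(nodes) {
  need <- c("id", "x", "y", "z", "radius", "parent")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"type" %in% names(nodes)) nodes$type <- 0L
  nodes <- nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(nodes$radius <= 0)) stop("radii must be positive")
  root <- which(nodes$parent == -1L)
  if (length(root) != 1L)
    stop("tree must have exactly one root (parent = -1); found ", length(root))
  idx <- match(nodes$parent, nodes$id)
  if (any(is.na(idx[-root])))
    stop("parent id(s) not present in the node table")
  # connectivity/acyclicity: walking parents from every node must reach root
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    todo <- which(is.na(depth) & !is.na(idx) & !is.na(depth[idx]))
    if (!length(todo)) break
    depth[todo] <- depth[idx[todo]] + 1L
  }
  if (anyNA(depth)) stop("tree is disconnected or cyclic")
  ord <- order(depth)              # topological order, root first
  children <- split(seq_len(nrow(nodes))[-root], idx[-root])
  elen <- rep(0, nrow(nodes))
  nr <- which(seq_len(nrow(nodes)) != root)
  elen[nr] <- sqrt((nodes$x[nr] - nodes$x[idx[nr]])^2 +
                   (nodes$y[nr] - nodes$y[idx[nr]])^2 +
                   (nodes$z[nr] - nodes$z[idx[nr]])^2)
  structure(list(nodes = nodes, root = root, parent_idx = idx,
                 children = children, edge_length = elen,
                 depth = depth, topo = ord),
            class = "neurite_tree")
}

#' @export
print.neurite_tree <- function(x, ...) {
  cat(sprintf("neurite_tree: %d nodes, %d leaves, total cable %.1f um\n",
              nrow(x$nodes), length(tree_leaves(x)), sum(x$edge_length)))
  invisible(x)
}

#' Row indices of the children of a node (by row index)
#' @keywords internal
child_rows <- function(tree, row) {
  ch <- tree$children[[as.character(row)]]
  if (is.null(ch)) integer() else ch
}

#' Leaf node row indices of a tree
#' @param tree a [neurite_tree()].
#' @return integer vector of row indices.
#' @export
tree_leaves <- function(tree) {
  has_child <- rep(FALSE, nrow(tree$nodes))
  has_child[unique(tree$parent_idx[!is.na(tree$parent_idx)])] <- TRUE
  which(!has_child)
}

#' Root-to-node path as row indices
#' @keywords internal
path_to_root <- function(tree, row) {
  p <- integer()
  while (!is.na(row)) {
    p <- c(row, p)
    row <- tree$parent_idx[row]
  }
  p
}

#' All row indices in the subtree rooted at `row` (inclusive)
#' @keywords internal
subtree_rows <- function(tree, row) {
  out <- integer()
  stack <- row
  while (length(stack)) {
    r <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, r)
    stack <- c(stack, child_rows(tree, r))
  }
  out
}

#' Node coordinates as a matrix
#' @param tree a [neurite_tree()].
#' @param rows optional row indices.
#' @return numeric matrix with columns x, y, z.
#' @export
node_coords <- function(tree, rows = seq_len(nrow(tree$nodes))) {
  as.matrix(tree$nodes[rows, c("x", "y", "z")])
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent; `#` comments.
#'
#' @param path path to an SWC file.
#' @return a [neurite_tree()].
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  neurite_tree(tab)
}

#' Write a neurite tree to SWC
#'
#' @param tree a [neurite_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export", con)
  utils::write.table(n, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
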