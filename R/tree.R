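#' Rooted-tree tables
#'
#' A tree is represented as a tibble with one row per node, class
#' `"tree_tbl"`. Node ids are assigned in preorder (root = 1), so a parent's
#' id is always smaller than its children's ids and sibling order equals id
#' order. This flat form keeps every traversal iterative and vectorised, so
#' trees with millions of leaves are handled without recursion.
#'
#' Columns:
#' \describe{
#'   \item{node}{integer node id, `1:n` in preorder}
#'   \item{parent}{integer id of the parent; `NA` for the root}
#'   \item{label}{leaf name, or inner-node label (e.g. bootstrap support);
#'     `NA` when absent}
#'   \item{branch_length}{length of the edge above the node; `NA` when the
#'     input carried none}
#'   \item{is_leaf}{`TRUE` for terminal nodes}
#' }
#'
#' Attributes: `n_leaves` (number of leaves) and `has_lengths` (`TRUE` iff
#' every non-root node has a branch length).
#'
#' @param parent integer vector of parent ids (`NA` for the root, which must
#'   be node 1).
#' @param label character vector of node labels (`NA` allowed).
#' @param branch_length numeric vector of edge lengths (`NA` allowed).
#' @return A `tree_tbl` tibble.
#' @examples
#' tr <- parse_newick("((A:1,B:2)95:0.5,C:3);")
#' tr
#' attr(tr, "n_leaves")
#' @export
new_tree_tbl <- function(parent, label, branch_length) {
  n <- length(parent)
  stopifnot(length(label) == n, length(branch_length) == n, n >= 1L)
  parent <- as.integer(parent)
  branch_length <- as.numeric(branch_length)
  label <- as.character(label)
  if (!is.na(parent[1L])) {
    rlang::abort("node 1 must be the root (parent NA)", class = "phylopaint_error")
  }
  if (n > 1L && any(is.na(parent[-1L]))) {
    rlang::abort("only the root may have a missing parent", class = "phylopaint_error")
  }
  if (n > 1L && any(parent[-1L] >= seq_len(n)[-1L])) {
    rlang::abort("nodes must be numbered in preorder (parent id < child id)",
      class = "phylopaint_error")
  }
  bad_bl <- !is.na(branch_length) & (!is.finite(branch_length) | branch_length < 0)
  if (any(bad_bl)) {
    rlang::abort(
      sprintf("branch lengths must be finite and >= 0 (node %d)", which(bad_bl)[1L]),
      class = "phylopaint_error")
  }
  has_child <- logical(n)
  if (n > 1L) has_child[parent[-1L]] <- TRUE
  is_leaf <- !has_child
  out <- tibble::tibble(
    node = seq_len(n), parent = parent, label = label,
    branch_length = branch_length, is_leaf = is_leaf)
  attr(out, "n_leaves") <- sum(is_leaf)
  attr(out, "has_lengths") <- n > 1L && !anyNA(branch_length[-1L])
  class(out) <- c("tree_tbl", class(out))
  out
}

#' @export
`[.tree_tbl` <- function(x, ...) {
  out <- NextMethod()
  # subsetting generally breaks the preorder invariants; drop the class
  class(out) <- setdiff(class(out), "tree_tbl")
  attr(out, "n_leaves") <- NULL
  attr(out, "has_lengths") <- NULL
  out
}

is_tree_tbl <- function(x) inherits(x, "tree_tbl")

assert_tree <- function(tree, arg = "tree") {
  if (!is_tree_tbl(tree)) {
    rlang::abort(sprintf("`%s` must be a tree_tbl (see parse_newick())", arg),
      class = "phylopaint_error")
  }
  invisible(tree)
}

#' Number of leaves below a node
#'
#' Counts the leaf descendants of `node` (a leaf counts itself). Computed in
#' one vectorised reverse-preorder sweep, so it is safe on very deep trees.
#'
#' @param tree a `tree_tbl`.
#' @param node node id(s) to query; defaults to the root.
#' @return Integer vector of leaf counts, one per element of `node`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' count_leaves(tr)          # 3
#' count_leaves(tr, 1:5)     # per-node counts
#' @export
count_leaves <- function(tree, node = 1L) {
  assert_tree(tree)
  n_desc_leaves(tree)[node]
}

# leaf-descendant count for every node (reverse preorder accumulation)
n_desc_leaves <- function(tree) {
  n <- nrow(tree)
  parent <- tree$parent
  cnt <- as.integer(tree$is_leaf)
  if (n > 1L) {
    for (i in n:2L) cnt[parent[i]] <- cnt[parent[i]] + cnt[i]
  }
  cnt
}

# cumulative depth from the root; hops = TRUE counts edges instead of lengths.
# Missing branch lengths count as `unit` (used for cladogram fallbacks).
node_depths <- function(tree, hops = FALSE, unit = 1) {
  n <- nrow(tree)
  parent <- tree$parent
  step <- if (hops) rep(1, n) else {
    bl <- tree$branch_length
    bl[is.na(bl)] <- unit
    bl
  }
  depth <- numeric(n)
  if (n > 1L) {
    for (i in 2L:n) depth[i] <- depth[parent[i]] + step[i]
  }
  depth
}

# first and last child of every node (0 = none); sibling order is id order
child_extremes <- function(tree) {
  n <- nrow(tree)
  fc <- integer(n)
  lc <- integer(n)
  if (n > 1L) {
    ids <- 2L:n
    p <- tree$parent[ids]
    lc[p] <- ids                  # ascending: last write wins -> max child id
    fc[rev(p)] <- rev(ids)        # descending: last write wins -> min child id
  }
  list(first = fc, last = lc)
}

# children of every node as a list, in sibling order
children_list <- function(tree) {
  n <- nrow(tree)
  out <- vector("list", n)
  if (n > 1L) {
    ids <- 2L:n
    got <- split(ids, tree$parent[ids])
    out[as.integer(names(got))] <- got
  }
  out
}

# renumber an arbitrary parent-pointer forest (single root) to preorder,
# children visited in ascending original-id order; iterative DFS
renumber_preorder <- function(parent, label, branch_length) {
  n <- length(parent)
  root <- which(is.na(parent))
  stopifnot(length(root) == 1L)
  kids <- vector("list", n)
  idx <- which(!is.na(parent))
  got <- split(idx, parent[idx])
  kids[as.integer(names(got))] <- got
  new_id <- integer(n)
  stack <- integer(n)
  stack[1L] <- root
  top <- 1L
  nxt <- 0L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    nxt <- nxt + 1L
    new_id[v] <- nxt
    kv <- kids[[v]]
    nk <- length(kv)
    if (nk) {
      stack[(top + 1L):(top + nk)] <- kv[nk:1L]  # reversed: leftmost pops first
      top <- top + nk
    }
  }
  ord <- order(new_id)
  new_parent <- parent[ord]
  keep <- !is.na(new_parent)
  new_parent[keep] <- new_id[new_parent[keep]]
  new_tree_tbl(new_parent, label[ord], branch_length[ord])
}

leaf_ids <- function(tree) tree$node[tree$is_leaf]

#' @export
print.tree_tbl <- function(x, ...) {
  cat(sprintf("# A tree_tbl: %d nodes, %d leaves, %s\n",
    nrow(x), attr(x, "n_leaves"),
    if (isTRUE(attr(x, "has_lengths"))) "with branch lengths" else "cladogram (no lengths)"))
  NextMethod()
}
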