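#' Random tree generator
#'
#' Grows a rooted bifurcating tree by sequential random attachment: starting
#' from a two-leaf tree, each new leaf splits a uniformly chosen existing
#' edge. Branch lengths are i.i.d. uniform(0, 1) and leaves are named
#' `t1 ... tn` in order of creation. Generation is iterative, so
#' million-leaf trees are produced without recursion-depth limits, and the
#' result is a pure function of `(n_leaves, seed)`.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer RNG seed.
#' @return A `tree_tbl` with `2 * n_leaves - 1` nodes.
#' @examples
#' gen_tree(5, seed = 1)
#' @export
gen_tree <- function(n_leaves, seed = 1L) {
  if (!is.numeric(n_leaves) || n_leaves < 2) {
    rlang::abort("`n_leaves` must be >= 2", class = "phylopaint_error")
  }
  n_leaves <- as.integer(n_leaves)
  set.seed(seed)
  n_nodes <- 2L * n_leaves - 1L
  parent <- integer(n_nodes)
  parent[1L] <- NA_integer_
  parent[2L] <- 1L
  parent[3L] <- 1L
  cnt <- 3L
  if (n_leaves > 2L) {
    r <- stats::runif(n_leaves)
    for (k in 3:n_leaves) {
      u <- 2L + as.integer(r[k] * (cnt - 1L))   # uniform over nodes 2..cnt
      if (u > cnt) u <- cnt
      m <- cnt + 1L
      lf <- cnt + 2L
      parent[m] <- parent[u]
      parent[u] <- m
      parent[lf] <- m
      cnt <- lf
    }
  }
  has_child <- logical(n_nodes)
  has_child[parent[!is.na(parent)]] <- TRUE
  label <- rep(NA_character_, n_nodes)
  label[!has_child] <- paste0("t", seq_len(n_leaves))  # creation = id order
  bl <- stats::runif(n_nodes)
  bl[1L] <- NA_real_
  renumber_preorder(parent, label, bl)
}

#' Random count table matching a tree
#'
#' One row per leaf (in leaf order), `n_variables` columns of non-negative
#' integers drawn Poisson(`lambda`) by inverse-transform sampling on the
#' seeded uniform stream. Rows that come out all-zero are redrawn so that
#' every row sum is positive and evenness is defined.
#'
#' @param tree a `tree_tbl` (typically from [gen_tree()]).
#' @param n_variables number of numeric columns (>= 1).
#' @param seed integer RNG seed.
#' @param lambda Poisson mean of the counts.
#' @return A `count_tbl` tibble with columns `name`, `v1 ... vN`.
#' @export
gen_counts <- function(tree, n_variables, seed = 1L, lambda = 10) {
  assert_tree(tree)
  if (!is.numeric(n_variables) || n_variables < 1) {
    rlang::abort("`n_variables` must be >= 1", class = "phylopaint_error")
  }
  n_variables <- as.integer(n_variables)
  set.seed(seed)
  nm <- tree$label[tree$is_leaf]
  m <- length(nm)
  vals <- matrix(
    stats::qpois(stats::runif(m * n_variables), lambda),
    nrow = m, ncol = n_variables)
  repeat {
    zero <- rowSums(vals) == 0
    if (!any(zero)) break
    vals[zero, ] <- stats::qpois(stats::runif(sum(zero) * n_variables), lambda)
  }
  out <- tibble::tibble(name = nm)
  for (j in seq_len(n_variables)) out[[paste0("v", j)]] <- vals[, j]
  class(out) <- c("count_tbl", class(out))
  out
}

# preorder subtree sizes: the subtree of node v occupies ids v..v+size-1
subtree_sizes <- function(tree) {
  n <- nrow(tree)
  sz <- rep(1L, n)
  if (n > 1L) {
    for (i in n:2L) sz[tree$parent[i]] <- sz[tree$parent[i]] + sz[i]
  }
  sz
}

#' Random mapping file matching a tree
#'
#' Assigns each leaf one of `n_colors` random branch colors, then paints
#' one randomly chosen inner clade a single uniform color — a planted
#' positive case for style propagation: after [propagate_styles()] that
#' clade's ancestral node carries the color.
#'
#' @param tree a `tree_tbl`.
#' @param seed integer RNG seed.
#' @param n_colors size of the random color pool.
#' @return Mapping-file TSV text (parsable by [parse_mapping()]), with
#'   attributes `clade_node` (the painted clade's root id) and
#'   `clade_color`.
#' @export
gen_mapping <- function(tree, seed = 1L, n_colors = 4L) {
  assert_tree(tree)
  set.seed(seed)
  pool <- sprintf("#%06x", sample.int(16777216L, n_colors) - 1L)
  nm <- tree$label[tree$is_leaf]
  cols <- sample(pool, length(nm), replace = TRUE)
  inner <- tree$node[!tree$is_leaf]
  clade <- if (length(inner) > 1L) {
    sample(inner[-1L], 1L)  # avoid the root: keep a non-uniform remainder
  } else inner[1L]
  sz <- subtree_sizes(tree)
  in_clade <- tree$node >= clade & tree$node < clade + sz[clade]
  clade_color <- pool[1L]
  cols[in_clade[tree$is_leaf]] <- clade_color
  tsv <- paste(c("name\tbranch_color", paste0(nm, "\t", cols)), collapse = "\n")
  attr(tsv, "clade_node") <- clade
  attr(tsv, "clade_color") <- clade_color
  tsv
}
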