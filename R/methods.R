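#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tree table
#'
#' Returns the node table augmented with per-node summaries: cumulative
#' depth from the root and the number of descendant leaves.
#'
#' @param x a `tree_tbl`.
#' @param ... unused.
#' @return A plain tibble.
#' @export
tidy.tree_tbl <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$depth <- node_depths(x)
  out$n_leaves_below <- n_desc_leaves(x)
  out
}

#' One-row summary of a tree
#'
#' @param x a `tree_tbl`.
#' @param ... unused.
#' @return A one-row tibble: node/leaf counts, whether branch lengths are
#'   complete, the maximum root-to-tip depth, and the number of duplicated
#'   leaf names.
#' @export
glance.tree_tbl <- function(x, ...) {
  leaf_nm <- x$label[x$is_leaf]
  tibble::tibble(
    n_nodes = nrow(x),
    n_leaves = attr(x, "n_leaves"),
    n_inner = nrow(x) - attr(x, "n_leaves"),
    has_lengths = isTRUE(attr(x, "has_lengths")),
    max_depth = max(node_depths(x)),
    n_duplicated_leaf_names = sum(duplicated(leaf_nm[!is.na(leaf_nm)])))
}

#' One-row summary of a layout
#'
#' @param x a `tree_layout`.
#' @param ... unused.
#' @return A one-row tibble with the layout mode, node count, and extent.
#' @export
glance.tree_layout <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_nodes = nrow(x),
    n_leaves = attr(x, "n_leaves"),
    width = attr(x, "width"),
    height = attr(x, "height"))
}

#' One-row summary of a reduction
#'
#' @param x a `reduction_tbl`.
#' @param ... unused.
#' @return A one-row tibble with the reduction mode, the number of
#'   observations, and the raw-score range.
#' @export
glance.reduction_tbl <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_observations = nrow(x),
    min_score = min(x$raw_score),
    max_score = max(x$raw_score))
}

# edge segments of a layout for plotting: elbows in rectangular mode,
# straight connectors otherwise (a quick-look approximation of the SVG arcs)
layout_edge_segments <- function(layout) {
  n <- nrow(layout)
  tree_parent <- attr(layout, "parent")
  if (is.null(tree_parent)) {
    rlang::abort("layout lacks parent pointers; use autoplot(layout, tree = tree)",
      class = "phylopaint_error")
  }
  ids <- 2:n
  p <- tree_parent[ids]
  if (attr(layout, "mode") == "rectangular") {
    tibble::tibble(
      x = c(layout$x[ids], layout$x[p]),
      y = c(layout$y[ids], layout$y[ids]),
      xend = c(layout$x[p], layout$x[p]),
      yend = c(layout$y[ids], layout$y[p]))
  } else {
    tibble::tibble(x = layout$x[ids], y = layout$y[ids],
      xend = layout$x[p], yend = layout$y[p])
  }
}

#' Quick ggplot of a tree layout
#'
#' Draws the layout's edges as segments (right-angle elbows in rectangular
#' mode, straight connectors otherwise — a quick-look approximation of the
#' SVG output) plus leaf labels. For publication-quality styled output use
#' [render_svg()].
#'
#' @param object a `tree_layout`.
#' @param tree the `tree_tbl` the layout was computed from.
#' @param show_labels draw leaf labels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tree_layout <- function(object, tree, show_labels = TRUE, ...) {
  attr(object, "parent") <- tree$parent
  seg <- layout_edge_segments(object)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      linewidth = 0.3) +
    ggplot2::theme_void()
  if (show_labels) {
    leaves <- object[object$is_leaf, ]
    p <- p + ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = 0, size = 3)
  }
  if (attr(object, "mode") != "rectangular") p <- p + ggplot2::coord_equal()
  p
}

#' Quick ggplot of a reduction
#'
#' Bar chart of per-observation raw scores, filled with the gradient colors
#' when present (see [apply_gradient()]).
#'
#' @param object a `reduction_tbl`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.reduction_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$name <- factor(df$name, levels = df$name)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$raw_score))
  if (!is.null(df$color)) {
    p <- p + ggplot2::geom_col(fill = df$color)
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = NULL, y = paste0(attr(object, "mode"), " score")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @importFrom rlang .data
NULL
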