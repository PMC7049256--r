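#' Tree layouts
#'
#' [layout_rectangular()], [layout_circular()] and [layout_radial()] compute
#' per-node drawing coordinates for the three supported layouts and return a
#' `tree_layout` tibble with one row per node:
#'
#' \describe{
#'   \item{x, y}{Cartesian coordinates in abstract units (the renderer
#'     scales them to the canvas). For the rectangular layout `x` is the
#'     longitudinal (root-to-tip) axis and `y` the transverse axis.}
#'   \item{angle, radius}{polar coordinates where meaningful (`NA` in the
#'     rectangular layout). In the circular layout
#'     `(x, y) = (radius * cos(angle), radius * sin(angle))`.}
#'   \item{depth}{cumulative branch length from the root (edges with no
#'     length count as 1).}
#' }
#'
#' All layouts are deterministic: the same tree always yields bit-identical
#' coordinates. Traversals are iterative, so million-leaf trees lay out
#' without recursion-depth failures.
#'
#' @section Conventions:
#' Angles are radians; angle 0 points along the positive x axis and
#' increases counterclockwise. Leaves are placed in depth-first (sibling
#' id) order. An inner node's transverse position is the midpoint of its
#' first and last child (the cluster-layout convention); set
#' `midpoint_extremes = FALSE` for the mean of all children instead.
#'
#' @name tree-layouts
NULL

new_tree_layout <- function(df, mode, tree) {
  bounds <- c(
    xmin = min(df$x), xmax = max(df$x),
    ymin = min(df$y), ymax = max(df$y))
  attr(df, "mode") <- mode
  attr(df, "bounds") <- bounds
  attr(df, "width") <- unname(bounds["xmax"] - bounds["xmin"])
  attr(df, "height") <- unname(bounds["ymax"] - bounds["ymin"])
  attr(df, "n_leaves") <- attr(tree, "n_leaves")
  class(df) <- c("tree_layout", class(df))
  df
}

# transverse coordinate: leaves 0,1,2,... in depth-first order, inner nodes
# at the midpoint of their extreme children (or mean of all children)
transverse_coords <- function(tree, midpoint_extremes = TRUE) {
  n <- nrow(tree)
  y <- numeric(n)
  y[tree$is_leaf] <- seq_len(attr(tree, "n_leaves")) - 1
  if (any(!tree$is_leaf)) {
    if (midpoint_extremes) {
      ce <- child_extremes(tree)
      for (i in n:1L) {
        if (!tree$is_leaf[i]) y[i] <- (y[ce$first[i]] + y[ce$last[i]]) / 2
      }
    } else {
      kids <- children_list(tree)
      for (i in n:1L) {
        if (!tree$is_leaf[i]) y[i] <- mean(y[kids[[i]]])
      }
    }
  }
  y
}

# longitudinal coordinate; cladogram mode aligns every leaf at the maximum
# hop depth and puts inner nodes at their hop depth
longitudinal_coords <- function(tree, use_branch_lengths) {
  phylogram <- use_branch_lengths && isTRUE(attr(tree, "has_lengths"))
  if (use_branch_lengths && !phylogram) {
    rlang::warn("tree has no (complete) branch lengths; using cladogram layout",
      class = "phylopaint_warning")
  }
  if (phylogram) {
    list(x = node_depths(tree), phylogram = TRUE)
  } else {
    hop <- node_depths(tree, hops = TRUE)
    x <- hop
    x[tree$is_leaf] <- max(hop)
    list(x = x, phylogram = FALSE)
  }
}

#' @param tree a `tree_tbl`.
#' @param use_branch_lengths draw edges proportional to branch length
#'   (phylogram). When the tree lacks complete lengths this falls back to a
#'   cladogram (leaves aligned at the maximum hop depth) with a warning.
#' @param midpoint_extremes inner-node transverse rule; see Conventions.
#' @return A `tree_layout` tibble (see [tree-layouts]).
#' @rdname tree-layouts
#' @examples
#' tr <- parse_newick("((A:1,B:2)90:1,C:3);")
#' layout_rectangular(tr)
#' layout_circular(tr, sweep_degrees = 360)
#' layout_radial(tr)
#' @export
layout_rectangular <- function(tree, use_branch_lengths = TRUE,
                               midpoint_extremes = TRUE) {
  assert_tree(tree)
  lon <- longitudinal_coords(tree, use_branch_lengths)
  df <- tibble::tibble(
    node = tree$node, is_leaf = tree$is_leaf, label = tree$label,
    x = lon$x, y = transverse_coords(tree, midpoint_extremes),
    angle = NA_real_, radius = NA_real_,
    depth = node_depths(tree))
  new_tree_layout(df, "rectangular", tree)
}

#' @param sweep_degrees angular span of the circle actually used, in
#'   (0, 360]. Values below 360 leave a gap (helpful for reading labels).
#' @rdname tree-layouts
#' @export
layout_circular <- function(tree, sweep_degrees = 360,
                            use_branch_lengths = TRUE,
                            midpoint_extremes = TRUE) {
  assert_tree(tree)
  if (!is.numeric(sweep_degrees) || length(sweep_degrees) != 1L ||
      !is.finite(sweep_degrees) || sweep_degrees <= 0 || sweep_degrees > 360) {
    rlang::abort("`sweep_degrees` must be in (0, 360]", class = "phylopaint_error")
  }
  lon <- longitudinal_coords(tree, use_branch_lengths)
  trans <- transverse_coords(tree, midpoint_extremes)
  n_leaves <- attr(tree, "n_leaves")
  angle <- trans * (sweep_degrees * pi / 180) / n_leaves
  radius <- lon$x
  df <- tibble::tibble(
    node = tree$node, is_leaf = tree$is_leaf, label = tree$label,
    x = radius * cos(angle), y = radius * sin(angle),
    angle = angle, radius = radius,
    depth = node_depths(tree))
  out <- new_tree_layout(df, "circular", tree)
  attr(out, "sweep_degrees") <- sweep_degrees
  out
}

#' @description
#' The radial layout places the root at the origin with the full-circle
#' wedge `[0, 2*pi)`. In preorder, each child is allocated a consecutive
#' sub-wedge of its parent's wedge with angular width
#' `2*pi * count_leaves(child) / count_leaves(root)`, starting at the
#' parent's wedge start, and sits at its parent's position displaced by its
#' branch length along the wedge's midpoint angle. Sibling wedges therefore
#' exactly partition the parent wedge, and each parent-child distance equals
#' the child's branch length.
#' @rdname tree-layouts
#' @export
layout_radial <- function(tree) {
  assert_tree(tree)
  n <- nrow(tree)
  if (!isTRUE(attr(tree, "has_lengths")) && n > 1L) {
    rlang::warn("tree has no (complete) branch lengths; using unit lengths",
      class = "phylopaint_warning")
  }
  bl <- tree$branch_length
  bl[is.na(bl)] <- 1
  nl <- n_desc_leaves(tree)
  wedge <- 2 * pi * nl / nl[1L]
  wstart <- numeric(n)
  nxt <- numeric(n)          # next free wedge start below each node
  x <- numeric(n); y <- numeric(n); tau <- rep(NA_real_, n)
  parent <- tree$parent
  if (n > 1L) {
    for (i in 2L:n) {
      p <- parent[i]
      wstart[i] <- nxt[p]
      nxt[p] <- nxt[p] + wedge[i]
      nxt[i] <- wstart[i]
      t_i <- wstart[i] + wedge[i] / 2
      tau[i] <- t_i
      x[i] <- x[p] + bl[i] * cos(t_i)
      y[i] <- y[p] + bl[i] * sin(t_i)
    }
  }
  df <- tibble::tibble(
    node = tree$node, is_leaf = tree$is_leaf, label = tree$label,
    x = x, y = y, angle = tau, radius = sqrt(x^2 + y^2),
    depth = node_depths(tree),
    wedge_start = wstart, wedge_width = wedge)
  new_tree_layout(df, "radial", tree)
}

#' @param mode which layout to compute.
#' @param ... passed to the specific layout function.
#' @rdname tree-layouts
#' @export
layout_tree <- function(tree, mode = c("rectangular", "circular", "radial"), ...) {
  mode <- match.arg(mode)
  switch(mode,
    rectangular = layout_rectangular(tree, ...),
    circular = layout_circular(tree, ...),
    radial = layout_radial(tree))
}

#' @export
print.tree_layout <- function(x, ...) {
  cat(sprintf("# A tree_layout: mode %s, %d nodes, extent %.4g x %.4g\n",
    attr(x, "mode"), nrow(x), attr(x, "width"), attr(x, "height")))
  NextMethod()
}
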