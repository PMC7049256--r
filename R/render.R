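#' Rendering options
#'
#' Bundles canvas geometry and toggles for the SVG renderer. All lengths
#' are in pixels.
#'
#' @param width,height canvas size.
#' @param margin padding between the drawing and the canvas edge.
#' @param show_labels,show_dots,show_bars,show_arcs,show_support toggles for
#'   the optional element classes.
#' @param bar_max_length length at which the observation with the largest
#'   absolute bar height in a series renders; other bars scale
#'   proportionally.
#' @param bar_padding gap between stacked bar series.
#' @param bar_offset gap between the label band and the first bar series.
#' @param bar_default_color fill used when a leaf has a bar height but no
#'   `bar<k>_color`.
#' @param bar_negative_color when set, bars with negative heights use this
#'   fill (two-color sign mode, e.g. for ratio bars); otherwise negative
#'   heights keep the series color and only their length (`|height|`) is
#'   drawn.
#' @param arc_thickness,arc_offset ring thickness for arcs and the gap
#'   before the arc band.
#' @param label_default_size,label_default_color,label_offset leaf-label
#'   font size (px), color, and distance from the leaf tip.
#' @param label_space room reserved beyond the tips for labels before bars
#'   start.
#' @param branch_default_color,branch_default_width edge stroke defaults.
#' @param leaf_dot_default_size default dot radius when a dot color is set
#'   without a size.
#' @param support_radius radius of support-decoration circles.
#' @param background canvas fill (hex) or `NULL` for none.
#' @return A `render_options` list.
#' @export
render_options <- function(width = 800, height = 800, margin = 20,
                           show_labels = TRUE, show_dots = TRUE,
                           show_bars = TRUE, show_arcs = TRUE,
                           show_support = TRUE,
                           bar_max_length = 80, bar_padding = 4,
                           bar_offset = 10,
                           bar_default_color = "#808080",
                           bar_negative_color = NULL,
                           arc_thickness = 10, arc_offset = 6,
                           label_default_size = 10,
                           label_default_color = "#000000",
                           label_offset = 4, label_space = 100,
                           branch_default_color = "#000000",
                           branch_default_width = 1,
                           leaf_dot_default_size = 3,
                           support_radius = 3,
                           background = NULL) {
  sizes <- c(width = width, height = height, bar_max_length = bar_max_length,
    label_default_size = label_default_size,
    branch_default_width = branch_default_width,
    leaf_dot_default_size = leaf_dot_default_size)
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    rlang::abort("render sizes must be positive", class = "phylopaint_error")
  }
  out <- as.list(environment())
  class(out) <- "render_options"
  out
}

# fixed 4-decimal float formatting for byte-stable output
fmt <- function(x) {
  s <- sprintf("%.4f", x)
  sub("^-(0\\.0000)$", "\\1", s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

or_default <- function(x, default) ifelse(is.na(x), default, x)

# annular sector path between radii r0 < r1 over angles [a0, a1] (drawing
# angles, y-down canvas); cx, cy = center
sector_path <- function(cx, cy, r0, r1, a0, a1) {
  p <- function(r, a) c(cx + r * cos(a), cy + r * sin(a))
  sw <- as.integer(a1 > a0)
  q00 <- p(r0, a0); q01 <- p(r0, a1); q11 <- p(r1, a1); q10 <- p(r1, a0)
  paste0(
    "M", fmt(q00[1]), " ", fmt(q00[2]),
    " A", fmt(r0), " ", fmt(r0), " 0 0 ", sw, " ", fmt(q01[1]), " ", fmt(q01[2]),
    " L", fmt(q11[1]), " ", fmt(q11[2]),
    " A", fmt(r1), " ", fmt(r1), " 0 0 ", 1L - sw, " ", fmt(q10[1]), " ", fmt(q10[2]),
    " Z")
}

bar_series_indices <- function(styles) {
  ks <- unique(as.integer(sub("^bar([0-9]+)_.*$", "\\1",
    grep("^bar[0-9]+_height$", names(styles), value = TRUE))))
  sort(ks)
}

#' Render a styled tree to SVG
#'
#' Emits a standalone SVG 1.1 document: one `<path class="branch">` per
#' non-root node (right-angle elbows in the rectangular layout, a radial
#' segment plus an arc in the circular layout, straight lines in the radial
#' layout), one `<text>` per leaf when labels are on, `<circle>` leaf dots
#' where styled, stacked bar series beyond the leaf tips (rectangles in the
#' rectangular layout, outward annular wedges in the circular layout), arc
#' bands spanning each styled leaf's slot, and filled/open support circles
#' at inner nodes. Identical inputs produce byte-identical output (fixed
#' element order, 4-decimal coordinates).
#'
#' Bars and arcs are drawn in the rectangular and circular layouts only;
#' the radial layout has no leaf-aligned band to attach them to.
#'
#' @param tree a `tree_tbl`.
#' @param layout a `tree_layout` computed from the same tree.
#' @param styles optional `resolved_styles` (leaf-level results are
#'   propagated to inner nodes automatically).
#' @param decorations optional support-decoration tibble from
#'   [support_decorations()].
#' @param options a [render_options()] list.
#' @param file optional path; the SVG text is also written there.
#' @return SVG document text (single string), invisibly when `file` is
#'   given.
#' @examples
#' tr <- parse_newick("((A:1,B:2)90:1,C:3);")
#' svg <- render_svg(tr, layout_rectangular(tr))
#' @export
render_svg <- function(tree, layout, styles = NULL, decorations = NULL,
                       options = render_options(), file = NULL) {
  assert_tree(tree)
  if (!inherits(layout, "tree_layout")) {
    rlang::abort("`layout` must come from a layout function", class = "phylopaint_error")
  }
  if (nrow(layout) != nrow(tree) || !identical(layout$is_leaf, tree$is_leaf)) {
    rlang::abort("mismatched tree/layout: recompute the layout from this tree",
      class = "phylopaint_error")
  }
  if (!inherits(options, "render_options")) {
    rlang::abort("`options` must come from render_options()", class = "phylopaint_error")
  }
  mode <- attr(layout, "mode")
  n <- nrow(tree)
  n_leaves <- attr(tree, "n_leaves")

  if (is.null(styles)) {
    styles <- tibble::tibble(node = tree$node, is_leaf = tree$is_leaf,
      label = tree$label)
    for (h in STYLE_COLOR_COLS) styles[[h]] <- NA_character_
    for (h in STYLE_NUMERIC_COLS) styles[[h]] <- NA_real_
    styles[["new_name"]] <- NA_character_
    styles$default <- TRUE
    class(styles) <- c("resolved_styles", class(styles))
  }
  if (!all(tree$node %in% styles$node)) {
    styles <- propagate_styles(tree, styles)
  }
  styles <- styles[order(styles$node), ]

  o <- options
  annot <- mode %in% c("rectangular", "circular")
  bar_ks <- if (o$show_bars && annot) bar_series_indices(styles) else integer(0)
  has_arcs <- annot && o$show_arcs && !is.null(styles$arc_color) &&
    any(!is.na(styles$arc_color[styles$is_leaf]))
  bars_extent <- if (annot && length(bar_ks)) {
    o$bar_offset + length(bar_ks) * o$bar_max_length +
      (length(bar_ks) - 1L) * o$bar_padding
  } else 0
  arcs_extent <- if (annot && has_arcs) o$arc_offset + o$arc_thickness else 0
  label_extent <- if (o$show_labels) o$label_space else 0
  reserve <- label_extent + bars_extent + arcs_extent

  # --- coordinate transforms ------------------------------------------------
  if (mode == "rectangular") {
    ext_x <- max(layout$x)
    sx <- (o$width - 2 * o$margin - reserve) / max(ext_x, .Machine$double.eps)
    sy <- (o$height - 2 * o$margin) / max(n_leaves, 1L)  # one slot per leaf
    px <- o$margin + layout$x * sx
    py <- o$margin + (layout$y + 0.5) * sy
    tip_x <- o$margin + ext_x * sx
    slot <- sy
  } else {
    cx <- o$width / 2; cy <- o$height / 2
    r_max <- max(layout$radius, na.rm = TRUE)
    s <- (min(o$width, o$height) / 2 - o$margin - reserve) /
      max(r_max, .Machine$double.eps)
    rot <- if (mode == "circular") -pi / 2 else 0
    ang <- layout$angle + rot
    rad <- layout$radius * s
    if (mode == "radial") {
      # radial node positions are cartesian; rotate not needed
      px <- cx + layout$x * s
      py <- cy + layout$y * s
      ang_draw <- layout$angle
    } else {
      px <- cx + rad * cos(ang)
      py <- cy + rad * sin(ang)
      ang_draw <- ang
    }
    slot_ang <- if (mode == "circular") {
      attr(layout, "sweep_degrees") * pi / 180 / n_leaves
    } else NA_real_
    tip_r <- if (mode == "circular") max(layout$radius) * s else NA_real_
  }

  parent <- tree$parent
  b_color <- or_default(styles$branch_color, o$branch_default_color)
  b_width <- or_default(styles$branch_width, o$branch_default_width)

  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))

  push('<?xml version="1.0" encoding="UTF-8" standalone="no"?>')
  push('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
    fmt(o$width), '" height="', fmt(o$height),
    '" viewBox="0 0 ', fmt(o$width), ' ', fmt(o$height), '">')
  if (!is.null(o$background)) {
    push('<rect class="background" x="0" y="0" width="', fmt(o$width),
      '" height="', fmt(o$height), '" fill="', o$background, '"/>')
  }

  # --- branches -------------------------------------------------------------
  push('<g class="branches" fill="none">')
  if (n > 1L) {
    for (i in 2L:n) {
      p <- parent[i]
      d <- if (mode == "rectangular") {
        paste0("M", fmt(px[i]), " ", fmt(py[i]),
          " H", fmt(px[p]), " V", fmt(py[p]))
      } else if (mode == "radial") {
        paste0("M", fmt(px[p]), " ", fmt(py[p]),
          " L", fmt(px[i]), " ", fmt(py[i]))
      } else {
        elbow_x <- cx + rad[p] * cos(ang[i])
        elbow_y <- cy + rad[p] * sin(ang[i])
        d0 <- paste0("M", fmt(px[i]), " ", fmt(py[i]),
          " L", fmt(elbow_x), " ", fmt(elbow_y))
        if (rad[p] > 1e-9 && abs(ang[p] - ang[i]) > 1e-12) {
          sw <- as.integer(ang[p] > ang[i])
          paste0(d0, " A", fmt(rad[p]), " ", fmt(rad[p]), " 0 0 ", sw,
            " ", fmt(px[p]), " ", fmt(py[p]))
        } else d0
      }
      push('<path class="branch" d="', d, '" stroke="', b_color[i],
        '" stroke-width="', fmt(b_width[i]), '"/>')
    }
  }
  push('</g>')

  # --- arcs -----------------------------------------------------------------
  if (has_arcs) {
    push('<g class="arcs">')
    arc0 <- label_extent + bars_extent + o$arc_offset
    for (i in which(tree$is_leaf)) {
      col <- styles$arc_color[i]
      if (is.na(col)) next
      if (mode == "rectangular") {
        push('<rect class="arc" x="', fmt(tip_x + arc0), '" y="',
          fmt(py[i] - slot / 2), '" width="', fmt(o$arc_thickness),
          '" height="', fmt(slot), '" fill="', col, '"/>')
      } else {
        r0 <- tip_r + arc0
        push('<path class="arc" d="',
          sector_path(cx, cy, r0, r0 + o$arc_thickness,
            ang_draw[i] - slot_ang / 2, ang_draw[i] + slot_ang / 2),
          '" fill="', col, '"/>')
      }
    }
    push('</g>')
  }

  # --- bars -----------------------------------------------------------------
  if (length(bar_ks)) {
    push('<g class="bars">')
    leaves <- which(tree$is_leaf)
    for (si in seq_along(bar_ks)) {
      k <- bar_ks[si]
      hts <- styles[[paste0("bar", k, "_height")]][leaves]
      cols <- styles[[paste0("bar", k, "_color")]]
      cols <- if (is.null(cols)) rep(NA_character_, n) else cols
      maxabs <- suppressWarnings(max(abs(hts), na.rm = TRUE))
      if (!is.finite(maxabs) || maxabs == 0) next
      scale_k <- o$bar_max_length / maxabs
      start <- label_extent + o$bar_offset +
        (si - 1L) * (o$bar_max_length + o$bar_padding)
      for (j in seq_along(leaves)) {
        i <- leaves[j]
        h <- hts[j]
        if (is.na(h) || h == 0) next
        col <- if (h < 0 && !is.null(o$bar_negative_color)) o$bar_negative_color
               else or_default(cols[i], o$bar_default_color)
        len <- abs(h) * scale_k
        if (mode == "rectangular") {
          push('<rect class="bar" x="', fmt(tip_x + start), '" y="',
            fmt(py[i] - 0.4 * slot), '" width="', fmt(len),
            '" height="', fmt(0.8 * slot), '" fill="', col, '"/>')
        } else {
          r0 <- tip_r + start
          push('<path class="bar" d="',
            sector_path(cx, cy, r0, r0 + len,
              ang_draw[i] - 0.45 * slot_ang, ang_draw[i] + 0.45 * slot_ang),
            '" fill="', col, '"/>')
        }
      }
    }
    push('</g>')
  }

  # --- leaf dots ------------------------------------------------------------
  if (o$show_dots) {
    dot_col <- styles$leaf_dot_color
    dot_size <- styles$leaf_dot_size
    draw <- tree$is_leaf & (!is.na(dot_col) | !is.na(dot_size))
    if (any(draw)) {
      push('<g class="dots">')
      for (i in which(draw)) {
        push('<circle class="leaf-dot" cx="', fmt(px[i]), '" cy="', fmt(py[i]),
          '" r="', fmt(or_default(dot_size[i], o$leaf_dot_default_size)),
          '" fill="', or_default(dot_col[i], "#000000"), '"/>')
      }
      push('</g>')
    }
  }

  # --- support decorations --------------------------------------------------
  if (o$show_support && !is.null(decorations) && nrow(decorations)) {
    dec <- decorations[decorations$decoration != "none", , drop = FALSE]
    if (nrow(dec)) {
      push('<g class="supports">')
      for (r in seq_len(nrow(dec))) {
        i <- dec$node[r]
        fill <- if (dec$decoration[r] == "filled") "#000000" else "#ffffff"
        push('<circle class="support" cx="', fmt(px[i]), '" cy="', fmt(py[i]),
          '" r="', fmt(o$support_radius), '" fill="', fill,
          '" stroke="#000000" stroke-width="1"/>')
      }
      push('</g>')
    }
  }

  # --- labels ---------------------------------------------------------------
  if (o$show_labels) {
    push('<g class="labels">')
    new_nm <- if (is.null(styles$new_name)) rep(NA_character_, n) else styles$new_name
    l_col <- or_default(styles$label_color, o$label_default_color)
    l_size <- or_default(styles$label_font_size, o$label_default_size)
    for (i in which(tree$is_leaf)) {
      txt <- if (!is.na(new_nm[i])) new_nm[i] else tree$label[i]
      txt <- xml_escape(ifelse(is.na(txt), "", txt))
      if (mode == "rectangular") {
        push('<text class="leaf-label" x="', fmt(px[i] + o$label_offset),
          '" y="', fmt(py[i]), '" dy="0.35em" font-size="', fmt(l_size[i]),
          '" fill="', l_col[i], '">', txt, '</text>')
      } else {
        a <- ang_draw[i]
        lx <- if (mode == "circular") cx + (rad[i] + o$label_offset) * cos(a)
              else px[i] + o$label_offset * cos(a)
        ly <- if (mode == "circular") cy + (rad[i] + o$label_offset) * sin(a)
              else py[i] + o$label_offset * sin(a)
        deg <- (a * 180 / pi) %% 360
        flip <- deg > 90 && deg < 270
        rot_deg <- if (flip) deg + 180 else deg
        anchor <- if (flip) "end" else "start"
        push('<text class="leaf-label" x="', fmt(lx), '" y="', fmt(ly),
          '" dy="0.35em" font-size="', fmt(l_size[i]), '" fill="', l_col[i],
          '" text-anchor="', anchor, '" transform="rotate(', fmt(rot_deg),
          ' ', fmt(lx), ' ', fmt(ly), ')">', txt, '</text>')
      }
    }
    push('</g>')
  }

  push('</svg>')
  svg <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file, useBytes = TRUE)
    return(invisible(svg))
  }
  svg
}
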