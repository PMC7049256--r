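#' Count tables
#'
#' The color gradient generator reads classic-style OTU tables: UTF-8
#' tab-separated text with a header row and one row per observation. With
#' `M` observations and `N` variables the file has `M + 1` rows and `N + 1`
#' columns; the first column holds observation names (typically leaf names
#' of the tree to be colored) and the remaining cells are numeric. Negative
#' values are accepted — the table is general numeric data — though the
#' evenness reduction requires non-negative rows.
#'
#' @name count-tables
NULL

count_error <- function(msg, row = NULL, col = NULL) {
  loc <- if (!is.null(row)) sprintf(" (row %d, column %d)", row, col) else ""
  rlang::abort(paste0("count table parse error", loc, ": ", msg),
    class = c("phylopaint_parse_error", "phylopaint_error"))
}

#' Parse a count table
#'
#' @param text tab-separated table text (string or lines); see
#'   [count-tables].
#' @return A `count_tbl` tibble: column `name` plus `N` numeric columns
#'   named from the header.
#' @examples
#' parse_count_table("otu\ts1\ts2\nA\t1\t2\nB\t3\t4")
#' @export
parse_count_table <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  lines <- sub("\r$", "", lines)
  if (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) < 2L) count_error("empty table (need a header and at least one row)")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) count_error("need at least one numeric column")
  n_var <- length(header) - 1L
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_var)
  nm <- character(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_var + 1L) {
      count_error(sprintf("ragged row: %d cells, expected %d",
        length(row), n_var + 1L), i, length(row))
    }
    nm[i] <- row[1L]
    num <- suppressWarnings(as.numeric(row[-1L]))
    bad <- is.na(num) | !is.finite(num)
    if (any(bad)) {
      j <- which(bad)[1L]
      count_error(sprintf("non-numeric cell '%s'", row[j + 1L]), i, j + 1L)
    }
    vals[i, ] <- num
  }
  out <- tibble::tibble(name = nm)
  for (j in seq_len(n_var)) out[[header[j + 1L]]] <- vals[, j]
  class(out) <- c("count_tbl", class(out))
  out
}

#' Read a count table from disk
#' @param file path to a tab-separated count table.
#' @return A `count_tbl` tibble; see [parse_count_table()].
#' @export
read_count_table <- function(file) {
  parse_count_table(readLines(file, warn = FALSE, encoding = "UTF-8"))
}

assert_count_tbl <- function(table) {
  if (!inherits(table, "count_tbl")) {
    if (is.data.frame(table) && "name" %in% names(table)) {
      class(table) <- unique(c("count_tbl", class(table)))
    } else {
      rlang::abort("`table` must be a count_tbl (see parse_count_table())",
        class = "phylopaint_error")
    }
  }
  table
}

count_matrix <- function(table) {
  m <- as.matrix(table[setdiff(names(table), "name")])
  rownames(m) <- table$name
  storage.mode(m) <- "double"
  m
}

new_reduction <- function(name, raw, mode) {
  out <- tibble::tibble(name = name, raw_score = raw,
    scaled = scale_unit_interval(raw))
  attr(out, "mode") <- mode
  class(out) <- c("reduction_tbl", class(out))
  out
}

#' Reduce each observation to its mean
#'
#' Scores observation `i` by the arithmetic mean of its row,
#' `mean_i = sum_j(c_ij) / N`. With `sum = TRUE` the row sum is used
#' instead (identical colors after min-max scaling, since the two differ by
#' the constant factor `N`).
#'
#' @param table a `count_tbl`.
#' @param sum score by the row sum instead of the row mean.
#' @return A `reduction_tbl` tibble: `name`, `raw_score`, `scaled`
#'   (min-max transform of `raw_score` into `[0, 1]`).
#' @examples
#' reduce_mean(parse_count_table("o\ta\tb\tc\nx\t2\t4\t6"))
#' @export
reduce_mean <- function(table, sum = FALSE) {
  table <- assert_count_tbl(table)
  m <- count_matrix(table)
  raw <- if (sum) rowSums(m) else rowMeans(m)
  new_reduction(table$name, unname(raw), if (sum) "sum" else "mean")
}

#' Reduce each observation to its Pielou evenness
#'
#' Scores observation `i` by Pielou's evenness index
#' `E_i = H_i / Hmax`, where `H_i = -sum_j p_ij log2 p_ij` is the Shannon
#' entropy of the row proportions `p_ij = c_ij / sum_j c_ij` (with
#' `0 * log 0 = 0`) and `Hmax = log2 N` is the entropy of a perfectly even
#' row. `E_i` is 1 for a uniform row and 0 when a single variable carries
#' all of the row's weight.
#'
#' @param table a `count_tbl` with `N >= 2` non-negative columns and no
#'   zero-sum row.
#' @return A `reduction_tbl` tibble (see [reduce_mean()]).
#' @examples
#' reduce_evenness(parse_count_table("o\ta\tb\tc\nx\t2\t1\t1\ny\t1\t1\t1"))
#' @export
reduce_evenness <- function(table) {
  table <- assert_count_tbl(table)
  m <- count_matrix(table)
  if (ncol(m) < 2L) {
    rlang::abort("evenness needs at least 2 variables (log2 N = 0 for N = 1)",
      class = "phylopaint_error")
  }
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1L]
    rlang::abort(sprintf("evenness needs non-negative values (observation '%s')",
      table$name[bad]), class = "phylopaint_error")
  }
  rs <- rowSums(m)
  if (any(rs == 0)) {
    rlang::abort(sprintf("zero-sum row: observation '%s'",
      table$name[which(rs == 0)[1L]]), class = "phylopaint_error")
  }
  p <- m / rs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(plogp)
  new_reduction(table$name, unname(h / log2(ncol(m))), "evenness")
}

#' Reduce each observation to its first principal-component score
#'
#' Performs a principal components analysis via the singular value
#' decomposition: the columns of `X` (observations as rows) are centered
#' and, when `scale_variables = TRUE`, divided by their sample standard
#' deviation (`M - 1` denominator; zero-variance columns are left centered,
#' with a warning). From `X = U S V'`, observation `i` is scored by row `i`
#' of the first column of `US` — its PC-1 score, the one-dimensional
#' projection holding as much of the variance as possible.
#'
#' The PC-1 sign is fixed so the loading of largest absolute value in the
#' first column of `V` is positive (earliest such entry on ties), making
#' scores reproducible across runs and row orderings.
#'
#' @param table a `count_tbl` with `M >= 2` observations.
#' @param scale_variables also scale columns to unit variance.
#' @return A `reduction_tbl` tibble (see [reduce_mean()]).
#' @export
reduce_projection <- function(table, scale_variables = FALSE) {
  table <- assert_count_tbl(table)
  m <- count_matrix(table)
  if (nrow(m) < 2L) {
    rlang::abort("projection needs at least 2 observations", class = "phylopaint_error")
  }
  x <- sweep(m, 2L, colMeans(m))
  if (scale_variables) {
    sds <- apply(x, 2L, stats::sd)
    zero <- sds == 0 | is.na(sds)
    if (any(zero)) {
      rlang::warn(sprintf("zero-variance column(s) left centered, not scaled: %s",
        paste(colnames(m)[zero], collapse = ", ")),
        class = "phylopaint_warning")
      sds[zero] <- 1
    }
    x <- sweep(x, 2L, sds, "/")
  }
  dec <- svd(x)
  scores <- dec$u[, 1L] * dec$d[1L]
  v1 <- dec$v[, 1L]
  if (v1[which.max(abs(v1))] < 0) scores <- -scores
  new_reduction(table$name, scores, "projection")
}

#' Min-max scale scores onto [0, 1]
#'
#' `(x - min) / (max - min)`; when all scores are equal every output is
#' 0.5 (the gradient midpoint).
#'
#' @param scores numeric vector of finite scores.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' scale_unit_interval(c(1, 2, 3))
#' @export
scale_unit_interval <- function(scores) {
  if (!length(scores) || anyNA(scores) || !all(is.finite(scores))) {
    rlang::abort("`scores` must be non-empty and finite", class = "phylopaint_error")
  }
  rng <- range(scores)
  if (rng[1L] == rng[2L]) return(rep(0.5, length(scores)))
  (scores - rng[1L]) / (rng[2L] - rng[1L])
}

# --- gradients --------------------------------------------------------------

#' Color gradients
#'
#' Two gradient kinds are supported. A *stops* gradient interpolates
#' linearly, per RGB channel, between ordered color stops at positions 0
#' through 1 (channel values are rounded half-up when quantised to 0-255).
#' A *cubehelix* gradient follows Green's helix through RGB space with
#' monotonically increasing intensity: with `phi = 2*pi*(start/3 +
#' rotations*lambda)`, `g = lambda^gamma` and `a = hue*g*(1-g)/2`,
#'
#' ```
#' R = g + a * (-0.14861 cos phi + 1.78277 sin phi)
#' G = g + a * (-0.29227 cos phi - 0.90649 sin phi)
#' B = g + a * ( 1.97294 cos phi)
#' ```
#'
#' each channel clamped to `[0, 1]` before quantisation (the helix can
#' leave the RGB cube). At `lambda = 0` the color is black; at
#' `lambda = 1` with `gamma = 1` it is white.
#'
#' Interpolation is in raw RGB for exact reproducibility; this is a known
#' perceptual tradeoff relative to Lab/HCL interpolation.
#'
#' @param colors character vector of at least two hex colors (`#RRGGBB` or
#'   `#RGB`).
#' @param positions stop positions: strictly increasing, first 0, last 1.
#'   Defaults to equally spaced.
#' @return A `gradient` object.
#' @examples
#' color_at(gradient_stops(c("#000000", "#ff0000")), 0.5)
#' color_at(gradient_cubehelix(), c(0, 0.5, 1))
#' @name gradients
#' @export
gradient_stops <- function(colors, positions = NULL) {
  colors <- normalize_hex(colors, "gradient stop")
  if (length(colors) < 2L || anyNA(colors)) {
    rlang::abort("a stops gradient needs >= 2 hex colors", class = "phylopaint_error")
  }
  if (is.null(positions)) positions <- seq(0, 1, length.out = length(colors))
  if (length(positions) != length(colors) || anyNA(positions) ||
      positions[1L] != 0 || positions[length(positions)] != 1 ||
      any(diff(positions) <= 0)) {
    rlang::abort("stop positions must be strictly increasing from 0 to 1",
      class = "phylopaint_error")
  }
  structure(list(kind = "stops", colors = colors, positions = positions),
    class = "gradient")
}

#' @param start start color of the helix (0 = blue, 1 = red, 2 = green,
#'   modulo 3).
#' @param rotations number (and direction) of helix rotations over the
#'   gradient.
#' @param hue hue saturation parameter; 0 gives pure grayscale.
#' @param gamma intensity gamma; values below 1 emphasise low intensities.
#' @rdname gradients
#' @export
gradient_cubehelix <- function(start = 0.5, rotations = -1.5, hue = 1, gamma = 1) {
  for (v in list(start, rotations, hue, gamma)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort("cubehelix parameters must be finite numbers",
        class = "phylopaint_error")
    }
  }
  structure(list(kind = "cubehelix", start = start, rotations = rotations,
    hue = hue, gamma = gamma), class = "gradient")
}

#' Built-in named palettes
#'
#' Each entry is an ordered list of hex color stops (data, not code) turned
#' into a stops gradient by [gradient_palette()].
#'
#' @format A named list of character vectors of hex colors.
#' @export
gradient_palettes <- list(
  viridis   = c("#440154", "#3b528b", "#21918c", "#5ec962", "#fde725"),
  rdylbu    = c("#fc8d59", "#ffffbf", "#91bfdb"),
  brbg      = c("#d8b365", "#f5f5f5", "#5ab4ac"),
  spectral  = c("#fc8d59", "#ffffbf", "#99d594"),
  bluered   = c("#0000ff", "#ff0000"),
  grayscale = c("#000000", "#ffffff")
)

#' @param name palette name; one of `names(gradient_palettes)` or
#'   `"cubehelix"`.
#' @rdname gradients
#' @export
gradient_palette <- function(name) {
  if (identical(name, "cubehelix")) return(gradient_cubehelix())
  if (!name %in% names(gradient_palettes)) {
    rlang::abort(sprintf("unknown palette '%s' (available: %s, cubehelix)",
      name, paste(names(gradient_palettes), collapse = ", ")),
      class = "phylopaint_error")
  }
  gradient_stops(gradient_palettes[[name]])
}

# round half-up to integer (sprintf/round use round-half-even)
round_half_up <- function(x) floor(x + 0.5)

hex_of_rgb01 <- function(r, g, b) {
  q <- function(v) round_half_up(pmin(pmax(v, 0), 1) * 255)
  sprintf("#%02x%02x%02x", q(r), q(g), q(b))
}

hex_channels <- function(hex) {
  list(
    r = strtoi(substr(hex, 2L, 3L), 16L),
    g = strtoi(substr(hex, 4L, 5L), 16L),
    b = strtoi(substr(hex, 6L, 7L), 16L))
}

#' Evaluate a gradient
#'
#' @param gradient a `gradient` object.
#' @param lambda numeric vector of positions in `[0, 1]`.
#' @return Character vector of `#rrggbb` hex colors, one per `lambda`.
#' @rdname gradients
#' @export
color_at <- function(gradient, lambda) {
  if (!inherits(gradient, "gradient")) {
    rlang::abort("`gradient` must be a gradient object", class = "phylopaint_error")
  }
  if (!length(lambda) || anyNA(lambda) || any(lambda < 0 | lambda > 1)) {
    rlang::abort("`lambda` must lie in [0, 1]", class = "phylopaint_error")
  }
  if (gradient$kind == "stops") {
    pos <- gradient$positions
    ch <- hex_channels(gradient$colors)
    k <- findInterval(lambda, pos, rightmost.closed = TRUE)
    f <- (lambda - pos[k]) / (pos[k + 1L] - pos[k])
    mix <- function(a) (a[k] + f * (a[k + 1L] - a[k])) / 255
    hex_of_rgb01(mix(ch$r), mix(ch$g), mix(ch$b))
  } else {
    phi <- 2 * pi * (gradient$start / 3 + gradient$rotations * lambda)
    g <- lambda^gradient$gamma
    a <- gradient$hue * g * (1 - g) / 2
    hex_of_rgb01(
      g + a * (-0.14861 * cos(phi) + 1.78277 * sin(phi)),
      g + a * (-0.29227 * cos(phi) - 0.90649 * sin(phi)),
      g + a * (1.97294 * cos(phi)))
  }
}

#' Attach gradient colors to a reduction
#'
#' @param reduction a `reduction_tbl` from one of the `reduce_*()`
#'   functions.
#' @param gradient a `gradient` object.
#' @return The reduction with a `color` column added; equal raw scores
#'   always receive identical colors.
#' @export
apply_gradient <- function(reduction, gradient) {
  if (!inherits(reduction, "reduction_tbl")) {
    rlang::abort("`reduction` must come from a reduce_*() function",
      class = "phylopaint_error")
  }
  reduction$color <- color_at(gradient, reduction$scaled)
  reduction
}

#' Emit a gradient mapping file
#'
#' Writes a two-column mapping file (`name` plus one style column) carrying
#' one hex color per observation; the output is valid input to
#' [parse_mapping()], closing the loop between the gradient generator and
#' the tree styler.
#'
#' @param reduction a `reduction_tbl` with a `color` column (see
#'   [apply_gradient()]).
#' @param target_field the style column to fill; one of the color style
#'   columns (`branch_color`, `label_color`, `leaf_dot_color`, `arc_color`,
#'   or `bar<k>_color`).
#' @param file optional output path.
#' @return The TSV text, invisibly when `file` is given.
#' @export
write_gradient_mapping <- function(reduction, target_field = "branch_color",
                                   file = NULL) {
  if (!inherits(reduction, "reduction_tbl") || is.null(reduction$color)) {
    rlang::abort("`reduction` must carry colors; see apply_gradient()",
      class = "phylopaint_error")
  }
  ok <- target_field %in% STYLE_COLOR_COLS ||
    grepl("^bar[0-9]+_color$", target_field)
  if (!ok) {
    rlang::abort(sprintf("unrecognized target_field '%s'", target_field),
      class = "phylopaint_error")
  }
  out <- paste(c(paste0("name\t", target_field),
    paste0(reduction$name, "\t", reduction$color)), collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
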