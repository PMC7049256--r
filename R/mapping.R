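#' Mapping files
#'
#' A mapping file is a UTF-8, tab-separated table whose first column
#' (header `name`) holds leaf-name patterns and whose remaining columns hold
#' style directives. Recognised style headers:
#'
#' * `branch_color`, `label_color`, `leaf_dot_color`, `arc_color` — hex
#'   colors, `#RRGGBB` (the 3-digit `#RGB` form is expanded on parse)
#' * `branch_width`, `label_font_size`, `leaf_dot_size` — positive numbers
#' * `new_name` — replacement leaf label, applied at render time only
#'   (matching always uses the original names)
#' * `bar1_height`, `bar1_color`, `bar2_height`, ... — one bar series per
#'   `k`, drawn beyond the leaf tips
#'
#' Empty cells mean "unspecified". Unrecognised headers are ignored with a
#' warning. Patterns are kept verbatim; no quoting or escaping of tabs is
#' supported.
#'
#' @name mapping-files
NULL

# canonical scalar style fields, in output order
STYLE_COLOR_COLS <- c("branch_color", "label_color", "leaf_dot_color", "arc_color")
STYLE_NUMERIC_COLS <- c("branch_width", "label_font_size", "leaf_dot_size")
STYLE_TEXT_COLS <- c("new_name")

style_field_names <- function(rules_or_styles) {
  setdiff(names(rules_or_styles),
    c("pattern", "node", "label", "is_leaf", "default"))
}

mapping_error <- function(msg, row = NULL, col = NULL) {
  loc <- if (!is.null(row)) sprintf(" (row %d, column '%s')", row, col) else ""
  rlang::abort(paste0("mapping parse error", loc, ": ", msg),
    class = c("phylopaint_parse_error", "phylopaint_error"))
}

# expand #RGB to #RRGGBB, validate, normalise to lowercase; NA passes through
normalize_hex <- function(x, colname = "color") {
  out <- ifelse(is.na(x) | x == "", NA_character_, x)
  short <- !is.na(out) & grepl("^#[0-9a-fA-F]{3}$", out)
  out[short] <- vapply(out[short], function(h) {
    d <- strsplit(substring(h, 2L), "")[[1L]]
    paste0("#", d[1L], d[1L], d[2L], d[2L], d[3L], d[3L])
  }, character(1L))
  ok <- is.na(out) | grepl("^#[0-9a-fA-F]{6}$", out)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    mapping_error(sprintf("invalid hex color '%s'", x[bad]), bad, colname)
  }
  tolower(out)
}

#' Parse a mapping file into style rules
#'
#' @param text the mapping file contents (a single string or a character
#'   vector of lines).
#' @return A `mapping_rules` tibble: column `pattern` plus one column per
#'   recognised style directive (see [mapping-files]). All scalar style
#'   columns are present (all-`NA` when the file omits them); bar columns
#'   appear only when the file has them.
#' @examples
#' parse_mapping("name\tbranch_color\nA\t#ff0000\nB\t")
#' @export
parse_mapping <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  lines <- sub("\r$", "", lines)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) mapping_error("missing header")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!length(header) || header[1L] != "name") {
    mapping_error("first column header must be 'name'")
  }
  style_headers <- header[-1L]
  known <- style_headers %in% c(STYLE_COLOR_COLS, STYLE_NUMERIC_COLS, STYLE_TEXT_COLS) |
    grepl("^bar[0-9]+_(height|color)$", style_headers)
  if (any(duplicated(style_headers[known]))) {
    mapping_error(sprintf("duplicate style header '%s'",
      style_headers[known][duplicated(style_headers[known])][1L]))
  }
  if (any(!known)) {
    rlang::warn(sprintf("ignoring unrecognized mapping column(s): %s",
      paste(style_headers[!known], collapse = ", ")),
      class = "phylopaint_warning")
  }

  body <- lines[-1L]
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_all <- length(header)
  mat <- matrix(NA_character_, nrow = length(body), ncol = ncol_all)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    if (length(row) > ncol_all) {
      mapping_error("more cells than headers", i, "")
    }
    if (length(row)) mat[i, seq_along(row)] <- row
  }
  mat[!is.na(mat) & mat == ""] <- NA_character_

  pattern <- mat[, 1L]
  if (any(is.na(pattern))) {
    mapping_error("empty name pattern", which(is.na(pattern))[1L], "name")
  }
  out <- tibble::tibble(pattern = pattern)
  keep <- which(known) + 1L
  for (j in keep) {
    h <- header[j]
    col <- mat[, j]
    if (h %in% STYLE_COLOR_COLS || grepl("^bar[0-9]+_color$", h)) {
      col <- tryCatch(normalize_hex(col, h), phylopaint_error = function(e) {
        mapping_error(conditionMessage(e), NULL, h)
      })
    } else if (h %in% STYLE_NUMERIC_COLS || grepl("^bar[0-9]+_height$", h)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad)) {
        mapping_error(sprintf("non-numeric value '%s'", col[which(bad)[1L]]),
          which(bad)[1L], h)
      }
      if (h != "bar_height" && !grepl("^bar", h) && any(!is.na(num) & num <= 0)) {
        mapping_error("value must be positive", which(!is.na(num) & num <= 0)[1L], h)
      }
      col <- num
    }
    out[[h]] <- col
  }
  # guarantee every scalar style column exists
  for (h in c(STYLE_COLOR_COLS, STYLE_NUMERIC_COLS, STYLE_TEXT_COLS)) {
    if (is.null(out[[h]])) {
      out[[h]] <- if (h %in% STYLE_NUMERIC_COLS) NA_real_ else NA_character_
    }
  }
  # order: pattern, canonical scalars, then bar columns by series index
  bars <- sort(grep("^bar[0-9]+_", names(out), value = TRUE))
  out <- out[c("pattern", STYLE_COLOR_COLS, STYLE_NUMERIC_COLS, STYLE_TEXT_COLS, bars)]
  class(out) <- c("mapping_rules", class(out))
  out
}

#' Read a mapping file from disk
#'
#' @param file path to a tab-separated mapping file.
#' @return A `mapping_rules` tibble; see [parse_mapping()].
#' @export
read_mapping <- function(file) {
  parse_mapping(readLines(file, warn = FALSE, encoding = "UTF-8"))
}

#' Match mapping rules against the leaves of a tree
#'
#' In `exact` mode a rule applies to a leaf iff its pattern equals the leaf
#' name; in `substring` mode, iff the pattern occurs anywhere in the name
#' (plain substring, not a regex). Matching is case-sensitive unless
#' `ignore_case = TRUE`. When several rules match one leaf they are applied
#' in file order and later rules override earlier ones field by field, so
#' complementary rules merge. Leaves matched by no rule keep the all-default
#' (all-`NA`) style. Duplicate leaf names are each styled independently.
#'
#' @param tree a `tree_tbl`.
#' @param rules a `mapping_rules` tibble from [parse_mapping()].
#' @param match `"exact"` or `"substring"`.
#' @param ignore_case match case-insensitively.
#' @return A `resolved_styles` tibble with one row per leaf: `node`,
#'   `label`, the style columns, and `default` (`TRUE` when no field is
#'   set). Attribute `report` lists `unmatched_leaves` and `unused_rules`.
#' @examples
#' tr <- parse_newick("((OTU_1,OTU_12),OTU_2);")
#' rules <- parse_mapping("name\tbranch_color\nOTU_1\t#ff0000")
#' resolve_leaf_styles(tr, rules, match = "substring")
#' @export
resolve_leaf_styles <- function(tree, rules, match = c("exact", "substring"),
                                ignore_case = FALSE) {
  assert_tree(tree)
  match <- match.arg(match)
  if (!inherits(rules, "mapping_rules")) {
    rlang::abort("`rules` must come from parse_mapping()/read_mapping()",
      class = "phylopaint_error")
  }
  leaves <- which(tree$is_leaf)
  nm <- tree$label[leaves]
  nm_cmp <- if (ignore_case) tolower(nm) else nm
  fields <- style_field_names(rules)

  out <- tibble::tibble(node = tree$node[leaves], label = nm)
  for (f in fields) {
    out[[f]] <- if (is.numeric(rules[[f]])) rep(NA_real_, length(leaves))
                else rep(NA_character_, length(leaves))
  }
  rule_used <- logical(nrow(rules))
  leaf_hit <- logical(length(leaves))
  for (r in seq_len(nrow(rules))) {
    pat <- rules$pattern[r]
    pat_cmp <- if (ignore_case) tolower(pat) else pat
    hit <- if (match == "exact") !is.na(nm_cmp) & nm_cmp == pat_cmp
           else !is.na(nm_cmp) & grepl(pat_cmp, nm_cmp, fixed = TRUE)
    if (!any(hit)) next
    rule_used[r] <- TRUE
    leaf_hit <- leaf_hit | hit
    for (f in fields) {
      v <- rules[[f]][r]
      if (!is.na(v)) out[[f]][hit] <- v
    }
  }
  out$default <- !Reduce(`|`, lapply(fields, function(f) !is.na(out[[f]])),
    logical(length(leaves)))
  attr(out, "report") <- list(
    unmatched_leaves = nm[!leaf_hit],
    unused_rules = rules$pattern[!rule_used],
    n_matched = sum(leaf_hit))
  class(out) <- c("resolved_styles", class(out))
  out
}

#' Propagate leaf styles to inner nodes
#'
#' For each style field independently, an inner node receives value `v` iff
#' every one of its descendant leaves has effective value `v` for that field
#' — where "no value set" (the default) counts as a value, so one unstyled
#' leaf in a clade keeps the clade's ancestors at the default. Otherwise the
#' inner node stays at the default. Computed in a single post-order pass;
#' propagating an already-propagated result is a no-op.
#'
#' @param tree a `tree_tbl`.
#' @param leaf_styles a `resolved_styles` tibble from
#'   [resolve_leaf_styles()] (leaf rows; any extra non-leaf rows are
#'   ignored).
#' @return A `resolved_styles` tibble over all nodes, ordered by node id,
#'   with an `is_leaf` column added.
#' @export
propagate_styles <- function(tree, leaf_styles) {
  assert_tree(tree)
  n <- nrow(tree)
  fields <- style_field_names(leaf_styles)
  kids <- children_list(tree)
  leaf_rows <- leaf_styles[leaf_styles$node %in% tree$node[tree$is_leaf], ]

  out <- tibble::tibble(node = tree$node, is_leaf = tree$is_leaf,
    label = tree$label)
  for (f in fields) {
    v <- if (is.numeric(leaf_rows[[f]])) rep(NA_real_, n) else rep(NA_character_, n)
    v[leaf_rows$node] <- leaf_rows[[f]]
    conflict <- logical(n)
    for (i in n:1L) {
      kv <- kids[[i]]
      if (!length(kv)) next
      if (any(conflict[kv])) { conflict[i] <- TRUE; next }
      vals <- v[kv]
      if (all(is.na(vals))) next                       # consensus: default
      if (!anyNA(vals) && all(vals == vals[1L])) {
        v[i] <- vals[1L]
      } else {
        conflict[i] <- TRUE                            # mixed -> default
      }
    }
    v[conflict] <- NA
    out[[f]] <- v
  }
  out$default <- !Reduce(`|`, lapply(fields, function(f) !is.na(out[[f]])),
    logical(n))
  class(out) <- c("resolved_styles", class(out))
  out
}

#' Support-value decorations for inner nodes
#'
#' Inner nodes whose label parses as a number `s` are decorated with a
#' filled circle when `s >= filled_min`, an open circle when
#' `open_min <= s < filled_min`, and nothing otherwise. Non-numeric or
#' absent labels get no decoration. Thresholds are on whatever scale the
#' tree's support values use (percent or proportions).
#'
#' @param tree a `tree_tbl`.
#' @param filled_min minimum support for a filled circle.
#' @param open_min minimum support for an open circle; must be
#'   `<= filled_min`.
#' @return A tibble over inner nodes: `node`, `support` (numeric or `NA`),
#'   `decoration` (`"filled"`, `"open"`, `"none"`).
#' @examples
#' tr <- parse_newick("((A,B)100,(C,D)80);")
#' support_decorations(tr, filled_min = 95, open_min = 70)
#' @export
support_decorations <- function(tree, filled_min = 95, open_min = 70) {
  assert_tree(tree)
  if (!is.numeric(filled_min) || !is.numeric(open_min) || open_min > filled_min) {
    rlang::abort("`open_min` must be <= `filled_min`", class = "phylopaint_error")
  }
  inner <- which(!tree$is_leaf)
  s <- suppressWarnings(as.numeric(tree$label[inner]))
  dec <- rep("none", length(inner))
  dec[!is.na(s) & s >= filled_min] <- "filled"
  dec[!is.na(s) & s >= open_min & s < filled_min] <- "open"
  tibble::tibble(node = tree$node[inner], support = s, decoration = dec)
}
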