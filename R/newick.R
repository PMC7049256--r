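#' Parse a Newick string into a tree table
#'
#' Accepts a single Newick statement terminated by `";"`. Single-quoted
#' labels (with `''` as the escaped quote) are unquoted; bracketed comments
#' `[...]` are discarded; the token between a `)` and the following `:` is
#' stored as that inner node's label (typically a support value). Underscores
#' are kept verbatim — they are not turned into spaces — so mapping-file
#' patterns can match leaf names exactly as written. Multifurcations and
#' single-child nodes are kept as parsed; no rerooting is performed.
#'
#' The parser is iterative (an explicit stack over a vectorised token
#' stream), so arbitrarily deep trees — e.g. a million-leaf caterpillar —
#' parse without hitting a recursion limit.
#'
#' @param text Newick string (may contain newlines; trailing whitespace after
#'   the `";"` is ignored).
#' @return A [new_tree_tbl()] `tree_tbl`. A warning of class
#'   `phylopaint_warning` is emitted when leaf names are duplicated.
#' @seealso [write_newick()], [read_newick()]
#' @examples
#' parse_newick("((A:1,B:2)95:0.5,C:3);")
#' parse_newick("('sp. one':0.5,B:0.5);")$label
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) {
    parse_error("empty input", 0L)
  }
  if (grepl("['\\[]", text)) {
    ev <- newick_tokens_quoted(text)
  } else {
    ev <- newick_tokens_plain(text)
  }
  tree <- newick_assemble(ev)
  dup <- duplicated(tree$label[tree$is_leaf]) & !is.na(tree$label[tree$is_leaf])
  if (any(dup)) {
    rlang::warn(
      sprintf("duplicate leaf names: %s",
        paste(unique(tree$label[tree$is_leaf][dup]), collapse = ", ")),
      class = "phylopaint_warning")
  }
  tree
}

#' Read a Newick file
#'
#' @param file path to a plain-text Newick file (UTF-8).
#' @return A `tree_tbl`.
#' @export
read_newick <- function(file) {
  parse_newick(readLines(file, warn = FALSE, encoding = "UTF-8"))
}

parse_error <- function(msg, offset) {
  rlang::abort(sprintf("newick parse error at character %d: %s", offset, msg),
    class = c("phylopaint_parse_error", "phylopaint_error"),
    offset = offset)
}

# --- tokenisers -------------------------------------------------------------
# Both produce a token stream: for each structural character ( ) , ; its
# offset, the character itself, and the label / branch-length text of the
# chunk immediately preceding it.

newick_tokens_plain <- function(text) {
  cp <- utf8ToInt(text)
  pos <- which(cp == 40L | cp == 41L | cp == 44L | cp == 59L)
  if (!length(pos) || !any(cp[pos] == 59L)) {
    parse_error("missing ';'", nchar(text))
  }
  semi <- pos[match(59L, cp[pos])]
  tail_txt <- substring(text, semi + 1L)
  if (nzchar(trimws(tail_txt))) {
    parse_error("text after ';'", semi + 1L)
  }
  pos <- pos[pos <= semi]
  chr <- intToUtf8(cp[pos], multiple = TRUE)
  starts <- c(1L, pos[-length(pos)] + 1L)
  chunks <- trimws(substring(text, starts, pos - 1L))
  colon <- regexpr(":", chunks, fixed = TRUE)
  lab <- ifelse(colon > 0L, substr(chunks, 1L, colon - 1L), chunks)
  lenstr <- ifelse(colon > 0L, substring(chunks, colon + 1L), NA_character_)
  list(pos = pos, chr = chr, lab = trimws(lab), lenstr = lenstr)
}

# slower character-level tokeniser for inputs with quotes or [] comments
newick_tokens_quoted <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  pos <- integer(0); chr <- character(0)
  lab <- character(0); lenstr <- character(0)
  buf_lab <- ""; buf_len <- NA_character_; after_colon <- FALSE
  i <- 1L
  done <- FALSE
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "'") {
      qtext <- ""
      i <- i + 1L
      repeat {
        if (i > n) parse_error("unterminated quote", i)
        if (ch[i] == "'") {
          if (i < n && ch[i + 1L] == "'") { qtext <- paste0(qtext, "'"); i <- i + 2L }
          else { i <- i + 1L; break }
        } else { qtext <- paste0(qtext, ch[i]); i <- i + 1L }
      }
      if (after_colon) buf_len <- paste0(ifelse(is.na(buf_len), "", buf_len), qtext)
      else buf_lab <- paste0(buf_lab, qtext)
      next
    }
    if (c0 == "[") {
      j <- i
      while (j <= n && ch[j] != "]") j <- j + 1L
      if (j > n) parse_error("unterminated '[' comment", i)
      i <- j + 1L
      next
    }
    if (c0 %in% c("(", ")", ",", ";")) {
      pos <- c(pos, i); chr <- c(chr, c0)
      lab <- c(lab, trimws(buf_lab)); lenstr <- c(lenstr, buf_len)
      buf_lab <- ""; buf_len <- NA_character_; after_colon <- FALSE
      if (c0 == ";") { done <- TRUE; i <- i + 1L; break }
      i <- i + 1L
      next
    }
    if (c0 == ":") {
      if (after_colon) parse_error("second ':' in one token", i)
      after_colon <- TRUE
      buf_len <- ""
      i <- i + 1L
      next
    }
    if (after_colon) buf_len <- paste0(buf_len, c0) else buf_lab <- paste0(buf_lab, c0)
    i <- i + 1L
  }
  if (!done) parse_error("missing ';'", n)
  if (i <= n && nzchar(trimws(paste(ch[i:n], collapse = "")))) {
    parse_error("text after ';'", i)
  }
  list(pos = pos, chr = chr, lab = trimws(lab), lenstr = lenstr)
}

# --- assembly ---------------------------------------------------------------

newick_assemble <- function(ev) {
  E <- length(ev$pos)
  lens <- suppressWarnings(as.numeric(ev$lenstr))
  bad <- !is.na(ev$lenstr) & (is.na(lens) | !is.finite(lens))
  if (any(bad)) {
    k <- which(bad)[1L]
    parse_error(sprintf("invalid branch length '%s'", ev$lenstr[k]), ev$pos[k])
  }
  neg <- !is.na(lens) & lens < 0
  if (any(neg)) {
    k <- which(neg)[1L]
    parse_error(sprintf("negative branch length '%s'", ev$lenstr[k]), ev$pos[k])
  }

  n_alloc <- E + 2L
  parent <- integer(n_alloc); labv <- character(n_alloc); blv <- rep(NA_real_, n_alloc)
  stack <- integer(n_alloc)
  top <- 0L; cnt <- 0L
  last_closed <- 0L
  prev <- "start"

  for (e in seq_len(E)) {
    c0 <- ev$chr[e]
    lab <- ev$lab[e]
    len <- lens[e]
    chunk_used <- FALSE

    if (prev == ")") {
      # chunk is the just-closed inner node's label / length
      labv[last_closed] <- lab
      blv[last_closed] <- len
      chunk_used <- TRUE
    }

    if (c0 == "(") {
      if (!chunk_used && (nzchar(lab) || !is.na(len))) {
        parse_error("unexpected label before '('", ev$pos[e])
      }
      if (prev == ")") parse_error("unexpected '(' after ')'", ev$pos[e])
      cnt <- cnt + 1L
      parent[cnt] <- if (top > 0L) stack[top] else NA_integer_
      labv[cnt] <- ""; blv[cnt] <- NA_real_
      top <- top + 1L
      stack[top] <- cnt
    } else {
      # ',' ')' ';' terminate a chunk; if the chunk belongs to no closed
      # node it is a leaf (possibly unnamed)
      if (!chunk_used && (prev %in% c("(", ",") ||
                          (prev == "start" && c0 == ";"))) {
        cnt <- cnt + 1L
        parent[cnt] <- if (top > 0L) stack[top] else NA_integer_
        labv[cnt] <- lab
        blv[cnt] <- len
      }
      if (c0 == ")") {
        if (top == 0L) parse_error("unbalanced ')'", ev$pos[e])
        last_closed <- stack[top]
        top <- top - 1L
      } else if (c0 == ";") {
        if (top != 0L) parse_error("unbalanced '(' (missing ')')", ev$pos[e])
      } else if (c0 == "," && top == 0L) {
        parse_error("',' outside parentheses", ev$pos[e])
      }
    }
    prev <- c0
  }
  if (cnt == 0L) parse_error("empty input", 1L)
  labv <- labv[seq_len(cnt)]
  labv[!nzchar(labv)] <- NA_character_
  new_tree_tbl(parent[seq_len(cnt)], labv, blv[seq_len(cnt)])
}

# --- writer -----------------------------------------------------------------

#' Serialise a tree table to Newick
#'
#' Labels containing Newick metacharacters (parentheses, brackets, commas,
#' colons, semicolons, quotes, or whitespace) are single-quoted with `''`
#' escaping. Branch lengths are written with 17 significant digits so that
#' `parse_newick(write_newick(t))` reproduces `t` exactly (topology, names,
#' lengths, inner labels).
#'
#' @param tree a `tree_tbl`.
#' @param file optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @examples
#' write_newick(parse_newick("(A:1,B:2);"))
#' @export
write_newick <- function(tree, file = NULL) {
  assert_tree(tree)
  n <- nrow(tree)
  lab <- quote_newick_label(tree$label)
  lenstr <- ifelse(is.na(tree$branch_length), "",
    paste0(":", sprintf("%.17g", tree$branch_length)))
  kids <- children_list(tree)
  part <- character(n)
  for (i in n:1L) {
    kv <- kids[[i]]
    if (length(kv)) {
      part[i] <- paste0("(", paste(part[kv], collapse = ","), ")", lab[i], lenstr[i])
    } else {
      part[i] <- paste0(lab[i], lenstr[i])
    }
  }
  out <- paste0(part[1L], ";")
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

quote_newick_label <- function(lab) {
  out <- ifelse(is.na(lab), "", lab)
  needs <- nzchar(out) & grepl("[][(),:;'[:space:]]", out)
  out[needs] <- paste0("'", gsub("'", "''", out[needs], fixed = TRUE), "'")
  out
}
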