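# shared independent oracles and small utilities for the suite

expect_tree_equal <- function(a, b) {
  expect_equal(a$parent, b$parent)
  expect_identical(a$label, b$label)
  expect_equal(a$branch_length, b$branch_length)
}

# leaves below each node, found by walking every leaf's ancestor chain --
# independent of the package's preorder/post-order machinery
leafsets_by_ancestor_walk <- function(tree) {
  sets <- rep(list(integer(0)), nrow(tree))
  for (lf in tree$node[tree$is_leaf]) {
    v <- lf
    while (!is.na(v)) {
      sets[[v]] <- c(sets[[v]], lf)
      v <- tree$parent[v]
    }
  }
  sets
}

# brute-force style propagation: a node gets value v iff every descendant
# leaf's value equals v (NA counting as a value)
propagate_brute_force <- function(tree, leaf_values) {
  vals <- rep(NA_character_, nrow(tree))
  vals[tree$node[tree$is_leaf]] <- leaf_values
  sets <- leafsets_by_ancestor_walk(tree)
  out <- vals
  for (i in which(!tree$is_leaf)) {
    lv <- vals[sets[[i]]]
    if (all(is.na(lv))) {
      out[i] <- NA_character_
    } else if (!anyNA(lv) && all(lv == lv[1L])) {
      out[i] <- lv[1L]
    } else {
      out[i] <- NA_character_
    }
  }
  out
}

# root-to-node path sum computed by explicit parent-chain walking
path_sum_walk <- function(tree, unit = 1) {
  vapply(tree$node, function(i) {
    s <- 0
    v <- i
    while (!is.na(tree$parent[v])) {
      bl <- tree$branch_length[v]
      s <- s + if (is.na(bl)) unit else bl
      v <- tree$parent[v]
    }
    s
  }, numeric(1L))
}

random_leaf_colors <- function(tree, k = 3L, seed = 1L) {
  set.seed(seed)
  pool <- sprintf("#%06x", sample.int(16777216L, k))
  sample(pool, attr(tree, "n_leaves"), replace = TRUE)
}

styles_from_colors <- function(tree, colors) {
  nwk_rules <- parse_mapping(paste(
    c("name\tbranch_color", paste0(tree$label[tree$is_leaf], "\t", colors)),
    collapse = "\n"))
  resolve_leaf_styles(tree, nwk_rules, match = "exact")
}

children_by_parent <- function(tree) {
  lapply(tree$node, function(v) tree$node[!is.na(tree$parent) & tree$parent == v])
}

count_svg_elements <- function(svg, xpath) {
  length(xml2::xml_find_all(xml2::read_xml(svg), xpath))
}
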