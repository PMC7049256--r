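test_that("mapping files parse into rules; empty cells mean unspecified", {
  rules <- parse_mapping("name\tbranch_color\nA\t#ff0000\nB\t")
  expect_s3_class(rules, "mapping_rules")
  expect_equal(rules$pattern, c("A", "B"))
  expect_equal(rules$branch_color, c("#ff0000", NA))
  expect_true(all(is.na(rules$label_color)))

  # 3-digit colors expand; case normalised
  rules2 <- parse_mapping("name\tlabel_color\nA\t#F00")
  expect_equal(rules2$label_color, "#ff0000")

  # numeric validation with location
  expect_equal(parse_mapping("name\tbar1_height\nA\t1.5")$bar1_height, 1.5)
  expect_error(parse_mapping("name\tbar1_height\nA\tx"), "bar1_height",
    class = "phylopaint_parse_error")
  expect_error(parse_mapping("name\tbranch_width\nA\t-2"),
    class = "phylopaint_parse_error")
})

test_that("header problems are errors; unknown headers warn and are ignored", {
  expect_error(parse_mapping(""), "header", class = "phylopaint_parse_error")
  expect_error(parse_mapping("taxon\tbranch_color\nA\t#fff"), "name",
    class = "phylopaint_parse_error")
  expect_error(parse_mapping("name\tbranch_color\tbranch_color\nA\t#fff\t#000"),
    "duplicate", class = "phylopaint_parse_error")
  expect_warning(rules <- parse_mapping("name\tshoe_size\nA\t42"),
    "unrecognized", class = "phylopaint_warning")
  expect_false("shoe_size" %in% names(rules))
})

test_that("exact vs substring matching; case sensitivity is optional", {
  tr <- parse_newick("((OTU_1,OTU_12),OTU_2);")
  rules <- parse_mapping("name\tbranch_color\nOTU_1\t#ff0000")
  ex <- resolve_leaf_styles(tr, rules, match = "exact")
  expect_equal(sum(!is.na(ex$branch_color)), 1L)
  expect_equal(ex$label[!is.na(ex$branch_color)], "OTU_1")
  sub <- resolve_leaf_styles(tr, rules, match = "substring")
  expect_equal(sort(sub$label[!is.na(sub$branch_color)]), c("OTU_1", "OTU_12"))

  rules_lc <- parse_mapping("name\tbranch_color\notu_1\t#ff0000")
  cs <- resolve_leaf_styles(tr, rules_lc, match = "exact")
  expect_equal(sum(!is.na(cs$branch_color)), 0L)
  ci <- resolve_leaf_styles(tr, rules_lc, match = "exact", ignore_case = TRUE)
  expect_equal(sum(!is.na(ci$branch_color)), 1L)
})

test_that("later rules override field-by-field; complementary rules merge", {
  tr <- parse_newick("(A,B);")
  rules <- parse_mapping(
    "name\tbranch_color\tlabel_color\nA\t#ff0000\t\nA\t#0000ff\t\nA\t\t#00ff00")
  st <- resolve_leaf_styles(tr, rules)
  a <- st[st$label == "A", ]
  expect_equal(a$branch_color, "#0000ff")  # later rule wins
  expect_equal(a$label_color, "#00ff00")   # merged from a different rule
  b <- st[st$label == "B", ]
  expect_true(b$default)
})

test_that("the run report lists unmatched leaves and unused rules", {
  tr <- parse_newick("(A,B);")
  rules <- parse_mapping("name\tbranch_color\nA\t#ff0000\nZ\t#00ff00")
  st <- resolve_leaf_styles(tr, rules)
  rep <- attr(st, "report")
  expect_equal(rep$unmatched_leaves, "B")
  expect_equal(rep$unused_rules, "Z")
  expect_equal(rep$n_matched, 1L)
})

test_that("duplicate leaf names are each styled independently", {
  suppressWarnings(tr <- parse_newick("(A,(A,B));"))
  rules <- parse_mapping("name\tbranch_color\nA\t#ff0000")
  st <- resolve_leaf_styles(tr, rules)
  expect_equal(sum(st$branch_color %in% "#ff0000"), 2L)
})

test_that("propagation: uniform clades color, mixed clades stay default", {
  tr <- parse_newick("((A,B),C);")
  rules <- parse_mapping("name\tbranch_color\nA\t#ff0000\nB\t#ff0000\nC\t#0000ff")
  ps <- propagate_styles(tr, resolve_leaf_styles(tr, rules))
  inner_ab <- ps$node[!ps$is_leaf][2]
  expect_equal(ps$branch_color[inner_ab], "#ff0000")
  expect_true(is.na(ps$branch_color[1]))   # root sees both colors -> default

  # the default counts as a value: one unstyled leaf blocks the clade
  rules2 <- parse_mapping("name\tbranch_color\nA\t#ff0000")
  ps2 <- propagate_styles(tr, resolve_leaf_styles(tr, rules2))
  expect_true(is.na(ps2$branch_color[inner_ab]))
})

test_that("propagation is idempotent and monochrome trees go fully colored", {
  tr <- gen_tree(30, seed = 5)
  st <- styles_from_colors(tr, rep("#123456", 30))
  ps <- propagate_styles(tr, st)
  expect_true(all(ps$branch_color == "#123456"))
  ps2 <- propagate_styles(tr, ps)
  expect_equal(ps2$branch_color, ps$branch_color)
})

test_that("fields propagate independently", {
  tr <- parse_newick("((A,B),C);")
  r1 <- parse_mapping(paste0("name\tbranch_color\tlabel_color\n",
    "A\t#ff0000\t#00ff00\nB\t#ff0000\t#0000ff\nC\t#ff0000\t#0000ff"))
  ps <- propagate_styles(tr, resolve_leaf_styles(tr, r1))
  expect_true(all(ps$branch_color == "#ff0000"))  # branch color unanimous
  expect_true(is.na(ps$label_color[1]))           # labels disagree at root
  # perturbing label colors leaves branch colors untouched
  r2 <- parse_mapping(paste0("name\tbranch_color\tlabel_color\n",
    "A\t#ff0000\t#ffffff\nB\t#ff0000\t#ffffff\nC\t#ff0000\t#ffffff"))
  ps2 <- propagate_styles(tr, resolve_leaf_styles(tr, r2))
  expect_equal(ps2$branch_color, ps$branch_color)
})

test_that("propagation equals the brute-force descendant oracle", {
  for (seed in 1:30) {
    tr <- gen_tree(sample(2:80, 1L), seed = seed)
    cols <- random_leaf_colors(tr, k = 3L, seed = seed + 1000L)
    ps <- propagate_styles(tr, styles_from_colors(tr, cols))
    expect_identical(ps$branch_color, propagate_brute_force(tr, cols))
  }
})

test_that("support decorations follow the thresholds on any scale", {
  tr <- parse_newick("((A,B)100,((C,D)80,(E,F)50)clade_x);")
  dec <- support_decorations(tr, filled_min = 95, open_min = 70)
  by_label <- function(l) dec$decoration[match(
    tr$node[match(l, tr$label)], dec$node)]
  expect_equal(by_label("100"), "filled")
  expect_equal(by_label("80"), "open")
  expect_equal(by_label("50"), "none")
  expect_equal(by_label("clade_x"), "none")

  tr2 <- parse_newick("((A,B)0.97,C);")
  dec2 <- support_decorations(tr2, filled_min = 0.95, open_min = 0.70)
  expect_equal(dec2$decoration[2], "filled")
  expect_error(support_decorations(tr, filled_min = 70, open_min = 95),
    class = "phylopaint_error")
})
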