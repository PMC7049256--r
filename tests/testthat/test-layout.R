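test_that("count_leaves matches explicit leaf enumeration", {
  expect_equal(count_leaves(parse_newick("A;")), 1L)
  tr <- parse_newick("((A,B),C);")
  expect_equal(count_leaves(tr), 3L)
  for (seed in 1:10) {
    tr <- gen_tree(sample(2:80, 1L), seed = seed)
    sets <- leafsets_by_ancestor_walk(tr)
    expect_equal(count_leaves(tr, tr$node), lengths(sets))
  }
})

test_that("rectangular phylogram follows the midpoint/cumulative rules", {
  tr <- parse_newick("(A:1,B:2);")
  lay <- layout_rectangular(tr)
  expect_equal(lay$x[lay$label %in% "A"], 1)
  expect_equal(lay$y[lay$label %in% "A"], 0)
  expect_equal(lay$x[lay$label %in% "B"], 2)
  expect_equal(lay$y[lay$label %in% "B"], 1)
  expect_equal(lay$x[1], 0)
  expect_equal(lay$y[1], 0.5)
})

test_that("cladogram aligns leaves at max hop depth, inner nodes at theirs", {
  tr <- parse_newick("((A,B),C);")
  expect_warning(lay <- layout_rectangular(tr, use_branch_lengths = TRUE),
    class = "phylopaint_warning")   # no lengths -> recorded fallback
  leaves <- lay[lay$is_leaf, ]
  expect_equal(leaves$x, c(2, 2, 2))           # all tips aligned
  expect_equal(leaves$y, c(0, 1, 2))           # A, B, C in traversal order
  expect_equal(lay$y[1], (0.5 + 2) / 2)        # root midpoint rule -> 1.25
  inner_ab <- lay[!lay$is_leaf, ][2, ]
  expect_equal(inner_ab$x, 1)
  expect_equal(inner_ab$y, 0.5)
})

test_that("mean-of-children transverse rule is available", {
  tr <- parse_newick("((A,B,C)x,D);")
  mid <- layout_rectangular(tr, use_branch_lengths = FALSE)
  avg <- layout_rectangular(tr, use_branch_lengths = FALSE,
    midpoint_extremes = FALSE)
  i <- which(!tr$is_leaf & tr$label %in% "x")
  expect_equal(mid$y[i], (0 + 2) / 2)
  expect_equal(avg$y[i], mean(c(0, 1, 2)))
})

test_that("longitudinal coordinate equals an independent root-path walk", {
  for (seed in 1:10) {
    tr <- gen_tree(sample(2:60, 1L), seed = seed)
    lay <- layout_rectangular(tr)
    expect_equal(lay$x, path_sum_walk(tr), tolerance = 1e-12)
    expect_true(all(diff(lay$y[lay$is_leaf]) > 0))  # strict traversal order
  }
})

test_that("circular layout maps transverse onto angle, longitudinal onto radius", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  lay <- layout_circular(tr, sweep_degrees = 360)
  leaves <- lay[lay$is_leaf, ]
  expect_equal(leaves$angle, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(lay$radius[1], 0)
  rect <- layout_rectangular(tr)
  expect_equal(lay$radius, rect$x)
  expect_equal(lay$x, lay$radius * cos(lay$angle))
  expect_equal(lay$y, lay$radius * sin(lay$angle))
  expect_error(layout_circular(tr, sweep_degrees = 0), class = "phylopaint_error")
  expect_error(layout_circular(tr, sweep_degrees = 361), class = "phylopaint_error")
})

test_that("radial layout: star-tree wedges and positions", {
  tr <- parse_newick("(A:1,B:1,C:1,D:1);")
  lay <- layout_radial(tr)
  kids <- lay[lay$is_leaf, ]
  expect_equal(kids$wedge_start, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(kids$wedge_width, rep(pi / 2, 4))
  expect_equal(kids$angle, c(pi / 4, 3 * pi / 4, 5 * pi / 4, 7 * pi / 4))
  expect_equal(sqrt(kids$x^2 + kids$y^2), rep(1, 4))
})

test_that("radial layout: edge lengths and wedge partition on random trees", {
  for (seed in 1:10) {
    tr <- gen_tree(sample(2:60, 1L), seed = seed)
    lay <- layout_radial(tr)
    d <- sqrt((lay$x - lay$x[tr$parent])^2 + (lay$y - lay$y[tr$parent])^2)
    expect_equal(d[-1], tr$branch_length[-1], tolerance = 1e-9)
    kids <- children_by_parent(tr)
    for (v in which(!tr$is_leaf)) {
      kv <- kids[[v]]
      starts <- lay$wedge_start[kv]
      widths <- lay$wedge_width[kv]
      expect_equal(starts[1], lay$wedge_start[v])
      if (length(kv) > 1) {
        expect_equal(starts[-1], (starts + widths)[-length(kv)], tolerance = 1e-9)
      }
      expect_equal(sum(widths), lay$wedge_width[v], tolerance = 1e-9)
    }
  }
})

test_that("radial layout substitutes unit lengths for cladograms, with warning", {
  tr <- parse_newick("((A,B),C);")
  expect_warning(lay <- layout_radial(tr), "unit lengths",
    class = "phylopaint_warning")
  d <- sqrt((lay$x - lay$x[tr$parent])^2 + (lay$y - lay$y[tr$parent])^2)
  expect_equal(d[-1], rep(1, nrow(tr) - 1))
})

test_that("layouts are deterministic", {
  tr <- gen_tree(40, seed = 9)
  expect_identical(layout_rectangular(tr), layout_rectangular(tr))
  expect_identical(layout_circular(tr), layout_circular(tr))
  expect_identical(layout_radial(tr), layout_radial(tr))
})

test_that("layout_tree dispatches on mode", {
  tr <- gen_tree(10, seed = 1)
  expect_equal(attr(layout_tree(tr, "circular"), "mode"), "circular")
  expect_equal(attr(layout_tree(tr, "radial"), "mode"), "radial")
})
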