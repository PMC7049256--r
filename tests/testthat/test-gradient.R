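test_that("count tables parse with names, shape, and located errors", {
  tab <- parse_count_table("otu\ts1\ts2\nA\t1\t2\nB\t3\t4\nC\t5\t6")
  expect_equal(nrow(tab), 3L)                     # M
  expect_equal(ncol(tab) - 1L, 2L)                # N
  expect_equal(tab$name, c("A", "B", "C"))
  # negative values are accepted (general numeric data)
  expect_silent(parse_count_table("o\ta\nx\t-3.5"))
  err <- tryCatch(parse_count_table("o\ta\tb\nx\t1\tabc"),
    condition = function(e) e)
  expect_s3_class(err, "phylopaint_parse_error")
  expect_match(conditionMessage(err), "row 1, column 3")
  expect_error(parse_count_table("o\ta\tb\nx\t1"), "ragged",
    class = "phylopaint_parse_error")
  expect_error(parse_count_table("o\ta"), "empty",
    class = "phylopaint_parse_error")
})

test_that("mean reduction averages rows; the sum variant scales by N", {
  tab <- parse_count_table("o\ta\tb\tc\nx\t2\t4\t6\ny\t0\t0\t0\nz\t1\t1\t1")
  r <- reduce_mean(tab)
  expect_equal(r$raw_score, c(4, 0, 1))
  expect_equal(reduce_mean(tab, sum = TRUE)$raw_score, c(12, 0, 3))
  one <- reduce_mean(parse_count_table("o\ta\nx\t7"))
  expect_equal(one$raw_score, 7)
  # same colors either way: the two scores differ by the constant N
  expect_equal(reduce_mean(tab)$scaled, reduce_mean(tab, sum = TRUE)$scaled)
})

test_that("evenness: endpoints and an independent Shannon-sum oracle", {
  tab <- parse_count_table("o\ta\tb\tc\td\nu\t1\t1\t1\t1\ns\t1\t0\t0\t0")
  r <- reduce_evenness(tab)
  expect_equal(r$raw_score, c(1, 0))

  r2 <- reduce_evenness(parse_count_table("o\ta\tb\tc\nx\t2\t1\t1"))
  p <- c(0.5, 0.25, 0.25)
  h_oracle <- -(p[1] * log2(p[1]) + p[2] * log2(p[2]) + p[3] * log2(p[3]))
  expect_equal(h_oracle, 1.5)
  expect_equal(r2$raw_score, h_oracle / log2(3), tolerance = 1e-9)
})

test_that("evenness agrees with vegan's Shannon entropy on random rows", {
  skip_if_not_installed("vegan")
  set.seed(11)
  m <- matrix(rpois(200, 8) + 1, nrow = 20)
  tab <- tibble::tibble(name = paste0("r", 1:20))
  for (j in 1:10) tab[[paste0("v", j)]] <- m[, j]
  class(tab) <- c("count_tbl", class(tab))
  ours <- reduce_evenness(tab)$raw_score
  theirs <- vegan::diversity(m, index = "shannon", base = 2) / log2(10)
  expect_equal(ours, unname(theirs), tolerance = 1e-12)
})

test_that("evenness is invariant to row scaling and column permutation", {
  set.seed(21)
  for (i in 1:50) {
    row <- rpois(6, 5) + c(1, rep(0, 5))
    tab <- function(v) {
      t <- tibble::tibble(name = "x")
      for (j in seq_along(v)) t[[paste0("v", j)]] <- v[j]
      class(t) <- c("count_tbl", class(t)); t
    }
    e0 <- reduce_evenness(tab(row))$raw_score
    expect_equal(reduce_evenness(tab(row * runif(1, 0.1, 90)))$raw_score, e0,
      tolerance = 1e-12)
    expect_equal(reduce_evenness(tab(sample(row)))$raw_score, e0,
      tolerance = 1e-12)
    if (length(unique(row)) > 1L) expect_lt(e0, 1 - 1e-12)
  }
})

test_that("evenness rejects N = 1, zero-sum rows, and negatives by name", {
  expect_error(reduce_evenness(parse_count_table("o\ta\nx\t3")), "N = 1",
    class = "phylopaint_error")
  expect_error(reduce_evenness(parse_count_table("o\ta\tb\nx\t1\t1\nbad\t0\t0")),
    "bad", class = "phylopaint_error")
  expect_error(reduce_evenness(parse_count_table("o\ta\tb\nneg\t-1\t2")),
    "neg", class = "phylopaint_error")
})

test_that("projection recovers the diagonal example and centers scores", {
  tab <- parse_count_table("o\ta\tb\np\t0\t0\nq\t2\t2\nr\t4\t4")
  r <- reduce_projection(tab)
  expect_equal(r$raw_score, c(-2 * sqrt(2), 0, 2 * sqrt(2)), tolerance = 1e-9)
  expect_equal(sum(r$raw_score), 0, tolerance = 1e-9)

  same <- parse_count_table("o\ta\tb\np\t1\t2\nq\t1\t2")
  expect_equal(reduce_projection(same)$raw_score, c(0, 0))
  expect_error(reduce_projection(parse_count_table("o\ta\nx\t1")),
    class = "phylopaint_error")
})

test_that("projection matches prcomp up to the documented sign convention", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rnorm(12 * 5), nrow = 12)
    tab <- tibble::tibble(name = paste0("r", 1:12))
    for (j in 1:5) tab[[paste0("v", j)]] <- m[, j]
    class(tab) <- c("count_tbl", class(tab))
    ours <- reduce_projection(tab)$raw_score
    ref <- stats::prcomp(m, center = TRUE, scale. = FALSE)$x[, 1]
    expect_equal(abs(ours), unname(abs(ref)), tolerance = 1e-9)
    # sign convention: the largest-magnitude loading is positive
    expect_true(cor(ours, ref) > 0.999 || cor(ours, -ref) > 0.999)
  }
})

test_that("projection scores are independent of row order", {
  set.seed(41)
  m <- matrix(rpois(40, 6), nrow = 8)
  tab <- tibble::tibble(name = paste0("r", 1:8))
  for (j in 1:5) tab[[paste0("v", j)]] <- m[, j]
  class(tab) <- c("count_tbl", class(tab))
  r1 <- reduce_projection(tab)
  perm <- sample(8)
  tab2 <- tab[perm, ]
  class(tab2) <- c("count_tbl", class(tab2))
  r2 <- reduce_projection(tab2)
  expect_equal(r2$raw_score[order(perm)], r1$raw_score, tolerance = 1e-9)
})

test_that("scaling to unit variance handles zero-variance columns", {
  tab <- parse_count_table("o\ta\tb\nx\t1\t5\ny\t2\t5\nz\t9\t5")
  expect_warning(r <- reduce_projection(tab, scale_variables = TRUE),
    "zero-variance", class = "phylopaint_warning")
  expect_equal(sum(r$raw_score), 0, tolerance = 1e-9)
})

test_that("min-max scaling follows the stated rules", {
  expect_equal(scale_unit_interval(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(scale_unit_interval(5), 0.5)
  expect_equal(scale_unit_interval(c(-2, 0, 2)), c(0, 0.5, 1))
  expect_error(scale_unit_interval(numeric(0)), class = "phylopaint_error")
  expect_error(scale_unit_interval(c(1, Inf)), class = "phylopaint_error")
})

test_that("cubehelix endpoints and stops interpolation round half-up", {
  expect_equal(color_at(gradient_cubehelix(), 0), "#000000")
  expect_equal(color_at(gradient_cubehelix(0.9, 2.5, 1.8, 1), 0), "#000000")
  expect_equal(color_at(gradient_cubehelix(gamma = 1), 1), "#ffffff")
  g <- gradient_stops(c("#000000", "#ff0000"))
  expect_equal(color_at(g, 0.5), "#800000")   # 127.5 rounds up to 128
  expect_equal(color_at(g, c(0, 1)), c("#000000", "#ff0000"))
  expect_error(color_at(g, 1.5), class = "phylopaint_error")
  expect_error(color_at(g, -0.1), class = "phylopaint_error")
})

test_that("stop lists validate; built-in palettes are valid gradients", {
  expect_error(gradient_stops("#000000"), class = "phylopaint_error")
  expect_error(gradient_stops(c("#000000", "#ffffff"), c(0.2, 1)),
    class = "phylopaint_error")
  expect_error(gradient_stops(c("#000000", "#ffffff", "#ff0000"), c(0, 1, 1)),
    class = "phylopaint_error")
  for (nm in names(gradient_palettes)) {
    g <- gradient_palette(nm)
    expect_s3_class(g, "gradient")
    expect_match(color_at(g, 0.37), "^#[0-9a-f]{6}$")
  }
  expect_error(gradient_palette("no_such"), class = "phylopaint_error")
})

test_that("equal raw scores always map to identical colors", {
  tab <- parse_count_table("o\ta\tb\nx\t1\t3\ny\t3\t1\nz\t0\t0")
  r <- apply_gradient(reduce_mean(tab), gradient_cubehelix())
  expect_equal(r$color[1], r$color[2])  # both means are 2
})

test_that("gradient mapping files round-trip through parse_mapping", {
  tab <- parse_count_table("o\ta\tb\nsp one\t1\t2\nB\t3\t4\nC\t5\t6")
  red <- apply_gradient(reduce_mean(tab), gradient_stops(c("#000000", "#ffffff")))
  tsv <- write_gradient_mapping(red, target_field = "branch_color")
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 4L)  # header + M rows
  rules <- parse_mapping(tsv)
  expect_equal(nrow(rules), 3L)
  expect_equal(rules$pattern, c("sp one", "B", "C"))  # names verbatim
  expect_error(write_gradient_mapping(red, target_field = "branch_width"),
    class = "phylopaint_error")
})
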