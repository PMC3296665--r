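test_that("find_repeats recovers a planted identical family", {
  g <- plant_repeats(make_genome(100000, gc = 0.5, seed = 81, id = "r"),
                     1, 500, 4, divergence = 0, seed = 82,
                     strands = "forward")
  fr <- find_repeats(g)
  expect_equal(length(unique(fr$family_id)), 1L)
  expect_equal(nrow(fr), 4L)
  expect_lt(abs(fr$unit_length[1] - 500) / 500, 0.05)
  # detected copies overlap the planted truth
  planted <- g$repeats[order(g$repeats$start), ]
  found <- fr[order(fr$start), ]
  expect_true(all(abs(found$start - planted$start) < 30))
})

test_that("an i.i.d. genome contains no detectable repeat families", {
  g <- make_genome(100000, gc = 0.5, seed = 83)
  expect_equal(nrow(find_repeats(g, k = 14, min_length = 300)), 0L)
})

test_that("distinct families are reported separately", {
  g <- make_genome(80000, gc = 0.5, seed = 84)
  g <- plant_repeats(g, 1, 600, 2, divergence = 0, strands = "forward")
  g <- plant_repeats(g, 1, 450, 3, divergence = 0, strands = "forward")
  fr <- find_repeats(g, min_length = 200)
  expect_equal(length(unique(fr$family_id)), 2L)
  expect_error(find_repeats(g, k = 25), "k")
})

test_that("summarize_repeats computes the class totals", {
  r <- tibble::tibble(start = c(1000L, 5000L), end = c(1500L, 5500L))
  s <- summarize_repeats(r, 100000)
  expect_equal(s$n_repeats, 2L)
  expect_equal(s$total_bp, 1000)
  expect_equal(s$total_bp_gt300, 1000)
  expect_equal(s$total_bp_gt700, 0)
  expect_equal(s$pct_total, 1)

  s2 <- summarize_repeats(tibble::tibble(start = 0L, end = 800L), 100000)
  expect_equal(s2$total_bp, 800)
  expect_equal(s2$total_bp_gt300, 800)
  expect_equal(s2$total_bp_gt700, 800)

  s0 <- summarize_repeats(r[0, ], 100000)
  expect_true(all(unlist(s0) == 0))

  # totals are invariant to copy order and relabeling
  s3 <- summarize_repeats(r[c(2, 1), ], 100000)
  expect_equal(s3, s)
  # nesting invariant
  expect_true(s$total_bp >= s$total_bp_gt300 &&
              s$total_bp_gt300 >= s$total_bp_gt700)
})

test_that("regress matches exact lines and the closed-form oracle", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  f <- regress(d, "x", "y")
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)

  # arbitrary 3-point data against hand formulas
  d3 <- data.frame(x = c(1, 4, 6), y = c(2.5, 3.1, 9.0))
  f3 <- regress(d3, "x", "y")
  o3 <- oracle_ols(d3$x, d3$y)
  expect_equal(f3$slope, o3$slope)
  expect_equal(f3$intercept, o3$intercept)
  expect_equal(f3$r_squared, o3$r_squared)
  expect_equal(f3$p_value, o3$p_value)

  expect_error(regress(d3[1:2, ], "x", "y"), "at least 3")
  expect_error(regress(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "variance")
})

test_that("independent response yields negligible r-squared", {
  set.seed(85)
  d <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(regress(d, "x", "y")$r_squared, 0.02)
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- data.frame(x = 1:8, y = c(1, 3, 2, 5, 4, 6, 7, 9))
  f <- regress(d, "x", "y")
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(f)
  expect_named(gl, c("r.squared", "slope", "p.value", "nobs"))
  expect_equal(gl$nobs, 8L)
})

test_that("regress_panel covers the indicator grid", {
  set.seed(86)
  panel <- data.frame(total_bp = runif(10, 0, 1e4),
                      total_bp_gt700 = runif(10, 0, 5e3),
                      CN = rpois(10, 20), SN = rpois(10, 4))
  tbl <- regress_panel(panel, predictors = c("total_bp", "total_bp_gt700"),
                       responses = c("CN", "SN"))
  expect_equal(nrow(tbl), 4L)
  expect_true(all(tbl$r_squared >= 0 & tbl$r_squared <= 1))
})
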