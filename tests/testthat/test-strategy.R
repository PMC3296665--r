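test_that("strategy labels round-trip and validate", {
  sp <- strategy_spec(10, 10)
  parsed <- parse_strategy_label(sp$label)
  expect_equal(parsed$se_depth, 10)
  expect_equal(parsed$pe_depth, 10)
  sp2 <- strategy_spec(6, 10, read_length = 100, insert_mean = 3000)
  expect_equal(parse_strategy_label(sp2$label)$se_depth, 6)
  expect_error(strategy_spec(0, 0), "positive")
  expect_error(parse_strategy_label("nonsense"), "label")
})

test_that("run_strategy produces labelled reports deterministically", {
  g <- plant_genes(make_genome(50000, gc = 0.5, seed = 91, id = "p1"),
                   10, seed = 92)
  spec <- strategy_spec(10, 10, read_length = 400, insert_mean = 8000)
  r1 <- run_strategy(list(g), spec, error_model(), seed = 7)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$strategy, spec$label)
  expect_true(is.na(r1$error))
  expect_gte(r1$GCE, 95)
  r2 <- run_strategy(list(g), spec, error_model(), seed = 7)
  expect_equal(r1[, c("GCE", "SBE", "CN", "NB", "SN")],
               r2[, c("GCE", "SBE", "CN", "NB", "SN")])
  expect_error(run_strategy(list(), spec), "empty")
})

test_that("failures are isolated per genome", {
  good <- plant_genes(make_genome(50000, gc = 0.5, seed = 93, id = "ok"),
                      5, seed = 94)
  # a genome shorter than the maximum read length fails in simulation
  bad <- good
  bad$sequence <- substr(bad$sequence, 1, 300)
  bad$length <- 300L
  bad$id <- "bad"
  bad$genes <- bad$genes[0, ]
  r <- run_strategy(list(bad, good),
                    strategy_spec(10, 10, insert_mean = 8000),
                    error_model(), seed = 9)
  expect_equal(nrow(r), 2L)
  expect_false(is.na(r$error[r$genome_id == "bad"]))
  expect_true(is.na(r$error[r$genome_id == "ok"]))
})

test_that("aggregate_reports averages and counts cumulative fractions", {
  reps <- tibble::tibble(
    strategy = "10 × SE + 10 × PE",
    GCE = c(98, 99), SBE = c(0.01, 0.03), IDR = c(0, 0),
    SBA = c(99.99, 99.97), FLT = c(0, 1), FDT = c(0, 0),
    CN = c(40, 60), NB = c(1e5, 2e5), SN = c(3, 12),
    genome_id = c("a", "b"), error = NA_character_)
  agg <- aggregate_reports(reps, cn_threshold = 150, sn_threshold = 10)
  expect_equal(agg$means$CN, 50)
  expect_equal(agg$means$NB, 1.5e5)
  expect_equal(agg$cumulative$frac_cn_below, 1)
  expect_equal(agg$cumulative$frac_sn_below, 0.5)
  expect_error(aggregate_reports(reps[0, ]), "no reports")
})

test_that("cumulative distributions are nondecreasing in the threshold", {
  reps <- tibble::tibble(strategy = "s",
                         CN = c(3, 5, 12, 40), SN = c(1, 2, 3, 9))
  cd <- cumulative_distribution(reps, "CN", thresholds = c(0, 4, 10, 50))
  expect_true(all(diff(cd$fraction) >= 0))
  expect_equal(cd$fraction[cd$threshold == 10], 0.5)
})

test_that("plots build without evaluation errors", {
  reps <- tibble::tibble(strategy = rep(c("A", "B"), each = 3),
                         CN = c(3, 10, 25, 5, 12, 30),
                         SN = c(1, 2, 4, 2, 3, 5),
                         GCE = 98, SBE = 0, IDR = 0, SBA = 100,
                         FLT = 0, FDT = 0, NB = 1e5,
                         genome_id = letters[1:6], error = NA_character_)
  p1 <- plot_cumulative(reps, "CN")
  expect_s3_class(p1, "ggplot")
  agg <- aggregate_reports(reps)
  p2 <- ggplot2::autoplot(agg, metric = "NB")
  expect_s3_class(p2, "ggplot")
})

test_that("quality reports serialise in the indicator column order", {
  rep <- tibble::tibble(strategy = "10 × SE + 10 × PE", GCE = 98.3,
                        SBE = 0.004, IDR = 3e-4, SBA = 99.9957,
                        FLT = 0.26, FDT = 0.56, CN = 45L, NB = 383794,
                        SN = 3.5)
  class(rep) <- c("quality_report", class(rep))
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "report.tsv")
  write_quality_report(rep, tsv)
  hdr <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_equal(hdr, c("ST", "GCE", "SBE", "IDR", "FLT", "FDT",
                      "CN", "NB", "SN", "SBA"))
})
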