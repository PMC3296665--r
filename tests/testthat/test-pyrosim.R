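test_that("zero-error shotgun reads are exact genomic substrings", {
  g <- make_genome(100000, gc = 0.5, seed = 31, id = "se")
  lib <- library_spec("se", read_length = 400, depth = 10,
                      length_dist = read_length_dist("fixed", mean = 400))
  rd <- simulate_shotgun(g, lib, zero_error_model(), seed = 32)
  expect_equal(nrow(rd), 2500L)  # 10 x 100,000 / 400
  expect_true(all(rd$n_sub == 0 & rd$n_ins == 0 & rd$n_del == 0))
  for (i in c(1, 50, 500, 2500)) {
    expect_identical(rd$sequence[i], read_truth_seq(g, rd[i, ]))
  }
  # emitted bases within 1% of request, and depth doubles with depth
  expect_lt(abs(estimate_depth(rd, g$length) - 10) / 10, 0.01)
  rd20 <- simulate_shotgun(g, library_spec("se", 400, depth = 20,
    length_dist = read_length_dist("fixed", mean = 400)),
    zero_error_model(), seed = 32)
  ratio <- sum(nchar(rd20$sequence)) / sum(nchar(rd$sequence))
  expect_lt(abs(ratio - 2), 0.02)
})

test_that("injected substitutions match the configured profile", {
  g <- make_genome(50000, gc = 0.5, seed = 33)
  m <- error_model()   # ramp 0.1% -> 0.5%, mean 0.3%
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 4), m,
                         seed = 34)
  emitted <- sum(nchar(rd$sequence))
  expected <- mean(m$profile) * emitted
  expect_lt(abs(sum(rd$n_sub) - expected), 3 * sqrt(expected))
})

test_that("homopolymer miscall frequency follows the rounded-normal oracle", {
  # each "read" is one homopolymer run of length 6; a large sigma0 makes
  # the miscall probability measurable
  L <- 6; sigma0 <- 0.4
  p_miscall <- 1 - (pnorm(0.5 / sigma0) - pnorm(-0.5 / sigma0))
  m <- error_model(0, 0, sigma0 = sigma0, sigma1 = 0,
                   background_indel = 0)
  set.seed(35)
  n <- 4000
  res <- pyroseval:::cpp_apply_errors(rep(strrep("A", L), n), m$profile,
                                      m$sigma0, m$sigma1, 0,
                                      rep(NA_integer_, n))
  miscalls <- sum(res$n_ins + res$n_del > 0)
  expect_lt(abs(miscalls - n * p_miscall),
            3 * sqrt(n * p_miscall * (1 - p_miscall)))
})

test_that("apply_errors honours the identity case and the length identity", {
  out <- apply_errors("ACGTACGTAAAC", zero_error_model())
  expect_identical(out$sequence, "ACGTACGTAAAC")
  expect_equal(c(out$n_sub, out$n_ins, out$n_del), c(0L, 0L, 0L))
  expect_error(apply_errors("ACGTN"), "A/C/G/T")

  # invariant: nchar(out) == nchar(in) - n_del + n_ins, any model
  set.seed(36)
  m <- error_model(0.02, 0.05, sigma0 = 0.3, sigma1 = 0.05,
                   background_indel = 0.01)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    out <- apply_errors(s, m)
    expect_equal(nchar(out$sequence), 300L - out$n_del + out$n_ins)
  }
})

test_that("paired-end geometry follows the fragment model", {
  g <- make_genome(100000, gc = 0.5, seed = 41, id = "pe")
  # sd = 0: outer truth coordinates exactly insert_mean apart
  lib0 <- library_spec("pe", 400, depth = 2, insert_mean = 8000,
                       insert_sd = 0,
                       length_dist = read_length_dist("fixed", mean = 400))
  pe0 <- simulate_paired(g, lib0, zero_error_model(), seed = 42)
  m1 <- pe0[pe0$mate == 1, ]; m2 <- pe0[pe0$mate == 2, ]
  expect_true(all(((m2$end - m1$start) %% g$length) == 8000))
  expect_true(all(m1$strand == "+" & m2$strand == "-"))
  for (i in c(1, 10)) {
    expect_identical(m1$sequence[i], read_truth_seq(g, m1[i, ]))
    expect_identical(m2$sequence[i], read_truth_seq(g, m2[i, ]))
  }

  # sd > 0: sample mean of spans within 3 standard errors
  lib <- library_spec("pe", 400, depth = 6, insert_mean = 8000,
                      insert_sd = 800)
  pe <- simulate_paired(g, lib, zero_error_model(), seed = 43)
  p1 <- pe[pe$mate == 1, ]; p2 <- pe[pe$mate == 2, ]
  spans <- (p2$end - p1$start) %% g$length
  expect_lt(abs(mean(spans) - 8000), 3 * 800 / sqrt(length(spans)))
  expect_lt(abs(estimate_depth(pe, g$length) - 6) / 6, 0.01)
})

test_that("error bookkeeping bounds the edit distance to the truth span", {
  g <- make_genome(50000, gc = 0.5, seed = 44)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 1),
                         error_model(), seed = 45)
  idx <- which(rd$n_sub + rd$n_ins + rd$n_del > 0)[1:20]
  for (i in idx) {
    truth <- read_truth_seq(g, rd[i, ])
    dist <- adist(truth, rd$sequence[i])[1, 1]
    expect_lte(dist, rd$n_sub[i] + rd$n_ins[i] + rd$n_del[i])
  }
})

test_that("reads wrap the circular origin at the expected frequency", {
  g <- make_genome(50000, gc = 0.5, seed = 46)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 20),
                         zero_error_model(), seed = 47)
  n_wrap <- sum(rd$end > g$length)
  p <- mean(nchar(rd$sequence)) / g$length
  expect_lt(abs(n_wrap - nrow(rd) * p),
            3 * sqrt(nrow(rd) * p * (1 - p)) + 3)
})

test_that("simulation is deterministic per seed and distinct across seeds", {
  g <- make_genome(20000, gc = 0.5, seed = 48)
  lib <- library_spec("se", 400, depth = 3)
  a <- simulate_shotgun(g, lib, error_model(), seed = 50)
  b <- simulate_shotgun(g, lib, error_model(), seed = 50)
  c <- simulate_shotgun(g, lib, error_model(), seed = 51)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$start, c$start))
})

test_that("estimate_depth contracts and merged additivity hold", {
  g <- make_genome(20000, gc = 0.5, seed = 52)
  se <- simulate_shotgun(g, library_spec("se", 400, depth = 5),
                         zero_error_model(), seed = 53)
  pe <- simulate_paired(g, library_spec("pe", 400, depth = 5,
                                        insert_mean = 8000),
                        zero_error_model(), seed = 54)
  merged <- merge_read_sets(se, pe, prefixes = c("se_", "pe_"))
  expect_lt(abs(estimate_depth(merged, g$length) - 10), 0.2)
  expect_error(estimate_depth(se, 0), "positive")
  expect_error(estimate_depth(se[0, ], g$length), "empty")
})

test_that("FASTQ and truth-table writers emit well-formed records", {
  g <- make_genome(20000, gc = 0.5, seed = 55)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 1),
                         zero_error_model(), seed = 56)
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  write_fastq(rd, fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 4 * nrow(rd))
  expect_true(all(startsWith(lines[seq(1, length(lines), 4)], "@")))
  expect_equal(nchar(lines[2]), nchar(rd$sequence[1]))
  expect_equal(nchar(lines[4]), nchar(rd$sequence[1]))

  tsv <- file.path(dir, "truth.tsv")
  write_read_truth(rd, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(rd))
  expect_equal(back$start, rd$start)
})
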