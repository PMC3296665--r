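test_that("align_assembly handles identity, substitution and strand", {
  g <- small_genome(5000, seed = 71)
  b <- align_assembly(setNames(g$sequence, "c"), g)
  expect_equal(nrow(b), 1L)
  expect_equal(b$ref_start, 0)
  expect_equal(b$ref_end, 5000)
  expect_equal(b$identity, 1)

  # one substitution, verified against an independent pairwise aligner
  mutated <- g$sequence
  substr(mutated, 2500, 2500) <- if (substr(mutated, 2500, 2500) == "A")
    "C" else "A"
  b1 <- align_assembly(setNames(mutated, "c"), g)
  expect_equal(sum(b1$n_mismatch), 1)
  expect_equal(sum(b1$n_ins) + sum(b1$n_del), 0)
  pa <- Biostrings::pairwiseAlignment(mutated, g$sequence,
                                      type = "global")
  expect_equal(sum(b1$n_mismatch),
               Biostrings::nmismatch(pa))

  # reverse-complement fragment reported on forward coordinates
  frag <- revcomp_chr(substr(g$sequence, 101, 200))
  # a 100 bp query needs a lenient anchor count
  b2 <- align_assembly(setNames(frag, "rc"), g, anchor_k = 15)
  expect_equal(b2$strand, "-")
  expect_equal(b2$ref_start, 100)
  expect_equal(b2$ref_end, 200)
})

test_that("alignment blocks satisfy the reference-span identity", {
  g <- small_genome(20000, seed = 72)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 2),
                         error_model(), seed = 73)
  b <- align_assembly(setNames(rd$sequence, rd$read_id), g)
  expect_true(all(b$n_match + b$n_mismatch + b$n_del ==
                    b$ref_end - b$ref_start))
  expect_true(all(b$identity >= 0 & b$identity <= 1))
})

test_that("genome_coverage equals the interval-union oracle", {
  expect_equal(genome_coverage(
    tibble::tibble(ref_start = 0, ref_end = 1000), 1000), 100)
  expect_equal(genome_coverage(
    tibble::tibble(ref_start = c(0, 400), ref_end = c(600, 1000)), 1000),
    100)  # union, not 120
  expect_equal(genome_coverage(
    tibble::tibble(ref_start = 0, ref_end = 500), 1000), 50)
  expect_error(genome_coverage(
    tibble::tibble(ref_start = 0, ref_end = 10), 0), "positive")

  set.seed(74)
  for (i in 1:200) {
    L <- sample(50:500, 1)
    n <- sample(1:12, 1)
    s <- sample(0:(L - 1), n, replace = TRUE)
    e <- pmin(L, s + sample(1:80, n, replace = TRUE))
    got <- genome_coverage(tibble::tibble(ref_start = s, ref_end = e), L)
    expect_equal(got, oracle_coverage(s, e, L))
    expect_lte(got, 100)
  }
})

test_that("base_accuracy decomposes exactly", {
  b <- tibble::tibble(n_match = 9999, n_mismatch = 1, n_ins = 0, n_del = 0)
  acc <- base_accuracy(b)
  expect_equal(acc$sbe, 0.01)
  expect_equal(acc$idr, 0)
  expect_equal(acc$sba, 100 - acc$sbe - acc$idr)
  b2 <- tibble::tibble(n_match = 100000 - 3, n_mismatch = 0,
                       n_ins = 2, n_del = 1)
  expect_equal(base_accuracy(b2)$idr, 100 * 3 / 100000)
  expect_error(base_accuracy(b[0, ]), "zero aligned")
})

test_that("n50 agrees with the brute-force accumulation oracle", {
  expect_equal(n50(c(5, 4, 3, 2, 1), denominator = 15), 4)
  expect_equal(n50(77, denominator = 77), 77)
  expect_warning(z <- n50(10, denominator = 100), "half")
  expect_equal(z, 0)
  expect_error(n50(numeric()), "non-empty")

  set.seed(75)
  for (i in 1:1000) {
    lens <- sample(1:1000, sample(1:30, 1), replace = TRUE)
    denom <- if (runif(1) < 0.5) sum(lens) else sample(1:3000, 1)
    expect_identical(
      suppressWarnings(n50(lens, denom)),
      suppressWarnings(oracle_n50(lens, denom)))
  }
})

test_that("count_units applies both reporting thresholds", {
  asm <- pyroseval:::new_assembly(
    tibble::tibble(contig_id = sprintf("c%d", 1:7),
                   sequence = strrep("A", c(rep(3000, 5), 5000, 5000)),
                   length = c(rep(3000L, 5), 5000L, 5000L)),
    tibble::tibble(scaffold_id = "s1", contig_id = sprintf("c%d", 1:5),
                   position = 1:5, orientation = "+",
                   gap_after = c(rep(10L, 4), NA)))
  u <- count_units(asm)
  expect_equal(u$cn, 7L)
  expect_equal(u$sn, 3L)  # one scaffold + two unplaced 5 kb contigs
  u2 <- count_units(asm, min_contig = 4000)
  expect_equal(u2$cn, 2L)
  empty <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = character(), sequence = character(), length = integer()))
  expect_equal(count_units(empty), list(cn = 0L, sn = 0L))
})

test_that("call_genes is threshold-monotone and finds verbatim genes", {
  g <- plant_genes(small_genome(40000, seed = 76), 10, seed = 77)
  asm <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = "c1", sequence = g$sequence, length = g$length))
  calls <- call_genes(g, asm)
  expect_true(all(calls$n_copies_found == 1L))
  expect_true(all(calls$best_identity == 1))

  stricter <- call_genes(g, asm, min_identity = 0.999,
                         min_coverage = 0.9)
  expect_true(all(stricter$n_copies_found <= calls$n_copies_found))
})

test_that("gene_dup_loss arithmetic follows the strict counting rules", {
  truth <- tibble::tibble(gene_id = sprintf("g%d", 1:200),
                          true_copy_number = 1L)
  calls <- tibble::tibble(gene_id = truth$gene_id, n_copies_found = 1L,
                          best_identity = 1, best_coverage = 1)
  expect_equal(gene_dup_loss(calls, truth), list(flt = 0, fdt = 0))
  calls$n_copies_found[1] <- 0L
  expect_equal(gene_dup_loss(calls, truth)$flt, 0.5)
  calls$n_copies_found[1] <- 1L
  calls$n_copies_found[2] <- 2L
  expect_equal(gene_dup_loss(calls, truth)$fdt, 0.5)
  expect_error(gene_dup_loss(calls, truth[0, ]), "empty")
})

test_that("evaluate is exact on the perfect assembly and order-invariant", {
  g <- plant_genes(small_genome(30000, seed = 78), 8, seed = 79)
  half <- 15000
  asm <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = c("c1", "c2"),
    sequence = c(substr(g$sequence, 1, half),
                 substr(g$sequence, half + 1, g$length)),
    length = c(half, g$length - half)))
  rep1 <- evaluate(asm, g, "perfect")
  expect_equal(rep1$GCE, 100)
  expect_equal(rep1$SBE, 0)
  expect_equal(rep1$IDR, 0)
  expect_equal(rep1$SBA, 100)

  # contig order and strand do not matter
  asm2 <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = c("c2", "c1"),
    sequence = c(revcomp_chr(substr(g$sequence, half + 1, g$length)),
                 substr(g$sequence, 1, half)),
    length = c(g$length - half, half)))
  rep2 <- evaluate(asm2, g, "perfect")
  expect_equal(rep2[, -1], rep1[, -1])

  junk <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = "j", sequence = strrep("ACGT", 500), length = 2000L))
  expect_error(evaluate(junk, g), "align")
})

test_that("external alignment formats load as blocks", {
  dir <- withr::local_tempdir()
  coords <- file.path(dir, "aln.coords")
  writeLines(c(
    "/ref /qry", "NUCMER", "",
    "    [S1]     [E1]  |     [S2]     [E2]  |  [LEN 1]  [LEN 2]  |  [% IDY]  | [TAGS]",
    "=====================================================================================",
    "       1     1000  |        1     1000  |     1000     1000  |    99.50  | ref\tctg1",
    "    2001     3000  |     1000        1  |     1000     1000  |   100.00  | ref\tctg2"),
    coords)
  b <- read_coords(coords)
  expect_equal(nrow(b), 2L)
  expect_equal(b$ref_start, c(0, 2000))
  expect_equal(b$strand, c("+", "-"))
  expect_equal(b$n_match[2], 1000)

  paf <- file.path(dir, "aln.paf")
  writeLines(paste(c("q1", 500, 0, 500, "+", "ref", 5000, 100, 601, 495,
                     505, 60, "cg:Z:250=1X100=5I100=5D45="),
                   collapse = "\t"), paf)
  p <- read_paf(paf)
  expect_equal(p$n_match, 495)
  expect_equal(p$n_mismatch, 1)
  expect_equal(p$n_ins, 5)
  expect_equal(p$n_del, 5)
})
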