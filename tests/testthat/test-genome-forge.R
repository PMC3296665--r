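test_that("make_genome length and GC behave as drawn i.i.d. bases", {
  g <- make_genome(100000, gc = 0.5, seed = 1)
  expect_equal(nchar(g$sequence), 100000L)
  expect_equal(g$length, 100000L)

  g3 <- make_genome(100000, gc = 0.3, seed = 1)
  obs_gc <- sum(strsplit(g3$sequence, "")[[1]] %in% c("G", "C"))
  # Binomial(1e5, 0.3) oracle: 3 s.d. band
  expect_lt(abs(obs_gc - 30000), 3 * sqrt(100000 * 0.3 * 0.7))

  expect_identical(make_genome(50000, gc = 0.4, seed = 7)$sequence,
                   make_genome(50000, gc = 0.4, seed = 7)$sequence)
  expect_error(make_genome(100), "length")
  expect_error(make_genome(10000, gc = 1.2), "gc")
})

test_that("plant_repeats places annotated near-identical copies", {
  g <- small_genome(60000, seed = 2)
  g0 <- plant_repeats(g, 0, 500, 4)
  expect_identical(g0$sequence, g$sequence)

  gi <- plant_repeats(g, 1, 500, 4, divergence = 0, seed = 3,
                      strands = "forward")
  expect_equal(nrow(gi$repeats), 4L)
  expect_equal(gi$length, g$length)
  copies <- vapply(seq_len(4), function(i)
    substr(gi$sequence, gi$repeats$start[i] + 1, gi$repeats$end[i]),
    character(1))
  expect_length(unique(copies), 1L)  # zero divergence: identical

  # copies never overlap
  r <- gi$repeats[order(gi$repeats$start), ]
  expect_true(all(head(r$end, -1) <= tail(r$start, -1)))
  expect_error(plant_repeats(g, 1, 500, 1), "copies_per_family")
  expect_error(plant_repeats(g, 1, 500, 2, divergence = 0.5), "divergence")
})

test_that("planted divergence matches the pairwise-identity oracle", {
  # brute-force oracle: simulate many consensus/copy pairs and measure the
  # expected pairwise identity of two independently mutated copies
  set.seed(11)
  d <- 0.02
  sim_ident <- replicate(300, {
    cons <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    mut <- function(x) {
      hit <- runif(length(x)) < d
      x[hit] <- vapply(x[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      x
    }
    mean(mut(cons) == mut(cons))
  })
  exp_ident <- mean(sim_ident)

  g <- plant_repeats(small_genome(80000, seed = 5), 1, 500, 4,
                     divergence = d, seed = 6, strands = "forward")
  copies <- vapply(seq_len(4), function(i)
    substr(g$sequence, g$repeats$start[i] + 1, g$repeats$end[i]),
    character(1))
  pairs <- combn(4, 2)
  obs <- mean(apply(pairs, 2, function(p) {
    a <- strsplit(copies[p[1]], "")[[1]]
    b <- strsplit(copies[p[2]], "")[[1]]
    mean(a == b)
  }))
  n_cols <- 500 * ncol(pairs)
  expect_lt(abs(obs - exp_ident),
            3 * sqrt(exp_ident * (1 - exp_ident) / n_cols))
})

test_that("plant_genes annotates disjoint genes and repeat-hosted copies", {
  g <- small_genome(250000, seed = 8)
  g <- plant_genes(g, 100, mean_length = 900, seed = 9)
  expect_equal(nrow(g$genes), 100L)
  o <- g$genes[order(g$genes$start), ]
  expect_true(all(head(o$end, -1) <= tail(o$start, -1)))
  expect_true(all(g$genes$true_copy_number == 1L))

  gr <- plant_repeats(small_genome(80000, seed = 10), 1, 2000, 4,
                      divergence = 0, seed = 11)
  gr <- plant_genes(gr, 3, mean_length = 600, seed = 12, n_in_repeats = 1)
  expect_equal(gr$genes$true_copy_number[1], 4L)
  expect_true(all(gr$genes$true_copy_number[-1] == 1L))
})

test_that("gene annotations round-trip through GFF3 and BED", {
  g <- plant_genes(small_genome(50000, seed = 13), 5, seed = 14)
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "genes.gff3")
  write_genes_gff3(g, gff)
  back <- read_genes_gff3(gff)
  expect_equal(back$start, g$genes$start)
  expect_equal(back$end, g$genes$end)
  expect_equal(back$gene_id, g$genes$gene_id)
  expect_equal(back$strand, g$genes$strand)

  bed <- file.path(dir, "genes.bed")
  write_bed(g$genes, g$id, bed, name_col = "gene_id")
  bb <- read_bed(bed)
  expect_equal(bb$start, g$genes$start)
  expect_equal(bb$end, g$genes$end)
})

test_that("make_panel spans the requested sizes and repeat content", {
  panel <- make_panel(10, size_range = c(1e5, 1e6),
                      repeat_content_range = c(0, 0.12), seed = 21)
  mf <- panel_manifest(panel)
  expect_true(all(mf$length >= 1e5 & mf$length <= 1e6))
  # the top of a range past 0.10 yields at least one repeat-dense genome
  expect_true(any(mf$repeat_bp_gt300 / mf$length > 0.10))

  panel2 <- make_panel(10, size_range = c(1e5, 1e6),
                       repeat_content_range = c(0, 0.12), seed = 21)
  expect_identical(panel_manifest(panel2), mf)
  expect_identical(panel[[3]]$sequence, panel2[[3]]$sequence)
  expect_error(make_panel(1), "n_genomes")
})
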