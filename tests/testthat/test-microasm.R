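test_that("three tiling error-free reads reconstruct the source", {
  set.seed(61)
  src <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  reads <- c(substr(src, 1, 500), substr(src, 301, 800),
             substr(src, 601, 1000))
  asm <- greedy_assemble(reads, min_overlap = 100)
  expect_equal(nrow(asm$contigs), 1L)
  ctg <- asm$contigs$sequence[1]
  expect_true(ctg == src || revcomp_chr(ctg) == src)
})

test_that("reads without qualifying overlaps stay singletons", {
  set.seed(62)
  reads <- replicate(5, paste(sample(c("A", "C", "G", "T"), 200,
                                     replace = TRUE), collapse = ""))
  asm <- greedy_assemble(reads, min_overlap = 40)
  expect_equal(nrow(asm$contigs), 5L)
  expect_setequal(asm$contigs$sequence, reads)
  expect_error(greedy_assemble(character()), "empty")
})

test_that("error-free high-depth reads of a repeat-free genome assemble", {
  g <- small_genome(30000, seed = 63)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 20),
                         zero_error_model(), seed = 64)
  asm <- greedy_assemble(rd)
  blocks <- align_assembly(asm, g)
  expect_gte(genome_coverage(blocks, g$length), 99)
  # perfect-input recovery: one contig equal to the reference up to
  # rotation and strand
  expect_equal(nrow(asm$contigs), 1L)
  ctg <- asm$contigs$sequence[1]
  tripled <- strrep(g$sequence, 3)
  expect_true(grepl(substr(ctg, 1, g$length), tripled, fixed = TRUE) ||
              grepl(substr(revcomp_chr(ctg), 1, g$length), tripled,
                    fixed = TRUE))
})

test_that("assembly is deterministic", {
  g <- small_genome(20000, seed = 65)
  rd <- simulate_shotgun(g, library_spec("se", 400, depth = 10),
                         error_model(), seed = 66)
  a <- greedy_assemble(rd)
  b <- greedy_assemble(rd)
  expect_identical(a$contigs$sequence, b$contigs$sequence)
})

test_that("paired links order two contigs and estimate the gap", {
  # contigs flanking an unassembled 3 kb region; the genome extends well
  # past the contigs so circular-junction pairs stay unplaced and only the
  # 3 kb junction contributes links
  g <- make_genome(60000, gc = 0.5, seed = 67, id = "sc")
  asm <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = c("c1", "c2"),
    sequence = c(substr(g$sequence, 1, 15000),
                 substr(g$sequence, 18001, 40000)),
    length = c(15000L, 22000L)))
  pe <- simulate_paired(g, library_spec("pe", 400, depth = 6,
                                        insert_mean = 8000,
                                        insert_sd = 400),
                        zero_error_model(), seed = 68)
  sc <- scaffold(asm, pe, 8000, 400)
  expect_equal(length(unique(sc$scaffolds$scaffold_id)), 1L)
  expect_setequal(sc$scaffolds$contig_id, c("c1", "c2"))
  gap <- sc$scaffolds$gap_after[!is.na(sc$scaffolds$gap_after)]
  expect_lt(abs(gap - 3000), 3 * 400)  # median-of-normals, generous band

  # below min_links nothing is scaffolded
  linkers <- pe[pe$mate == 1 & pe$start < 10000 & pe$end > 0, ]
  few <- pe[sub("/[12]$", "", pe$read_id) %in%
              sub("/[12]$", "", linkers$read_id[1:2]), ]
  expect_warning(sc2 <- scaffold(asm, few, 8000, 400, min_links = 3))
  expect_equal(nrow(sc2$scaffolds), 0L)
})

test_that("mates landing in a single contig create no self-edge", {
  g <- make_genome(30000, gc = 0.5, seed = 69, id = "one")
  asm <- pyroseval:::new_assembly(tibble::tibble(
    contig_id = "c1", sequence = g$sequence, length = g$length))
  pe <- simulate_paired(g, library_spec("pe", 400, depth = 4,
                                        insert_mean = 8000),
                        zero_error_model(), seed = 70)
  expect_warning(sc <- scaffold(asm, pe, 8000, 800), "link")
  expect_equal(nrow(sc$scaffolds), 0L)
})

test_that("ingest_assembly splits records at N runs and honours AGP", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "asm.fasta")
  write_fasta(c(rec1 = paste0("ACGTACGTACGT", strrep("N", 20), "GGCCGGCC"),
                rec2 = "TTTTACGTACGTAAAA"), fa)
  asm <- ingest_assembly(fa)
  expect_equal(nrow(asm$contigs), 3L)
  r1 <- asm$scaffolds[asm$scaffolds$scaffold_id == "rec1", ]
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$gap_after[1], 20L)
  expect_equal(
    nrow(asm$scaffolds[asm$scaffolds$scaffold_id == "rec2", ]), 1L)

  # AGP path
  fa2 <- file.path(dir, "contigs.fasta")
  write_fasta(c(c1 = "ACGTACGTACGT", c2 = "GGCCGGCC"), fa2)
  agp <- file.path(dir, "asm.agp")
  writeLines(c("##agp-version\t2.0",
               paste("scf1", 1, 12, 1, "W", "c1", 1, 12, "+", sep = "\t"),
               paste("scf1", 13, 62, 2, "N", 50, "scaffold", "yes",
                     "paired-ends", sep = "\t"),
               paste("scf1", 63, 70, 3, "W", "c2", 1, 8, "-", sep = "\t")),
             agp)
  a2 <- ingest_assembly(fa2, agp)
  expect_equal(a2$scaffolds$contig_id, c("c1", "c2"))
  expect_equal(a2$scaffolds$gap_after[1], 50L)
  expect_equal(a2$scaffolds$orientation, c("+", "-"))

  bad <- file.path(dir, "bad.agp")
  writeLines(c(paste("scf1", 1, 12, 1, sep = "\t")), bad)
  expect_error(ingest_assembly(fa2, bad), "line 1")
  bad2 <- file.path(dir, "bad2.agp")
  writeLines(paste("scf1", 1, 12, 1, "W", "cX", 1, 12, "+", sep = "\t"),
             bad2)
  expect_error(ingest_assembly(fa2, bad2), "absent contig")
})

test_that("scaffold sequences join oriented contigs with N gaps", {
  asm <- pyroseval:::new_assembly(
    tibble::tibble(contig_id = c("c1", "c2"),
                   sequence = c("ACGTACGTAC", "GGGGCCCCTT"),
                   length = c(10L, 10L)),
    tibble::tibble(scaffold_id = "s1", contig_id = c("c1", "c2"),
                   position = 1:2, orientation = c("+", "-"),
                   gap_after = c(5L, NA)))
  seqs <- scaffold_sequences(asm)
  expect_identical(unname(seqs["s1"]),
                   paste0("ACGTACGTAC", "NNNNN", "AAGGGGCCCC"))
})
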