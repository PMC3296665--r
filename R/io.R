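#' Read a FASTA file as a named character vector
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (70-column wrapped)
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

# genes tibble (0-based half-open) -> GRanges (1-based inclusive)
genes_to_granges <- function(genes, seqname) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  gr
}

#' Write gene annotations to GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention.
#' @param genome A `synth_genome`.
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genome, path) {
  rtracklayer::export(genes_to_granges(genome$genes, genome$id), path,
                      format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#' @param path Path to a GFF3 file with `gene` records.
#' @return Tibble with 0-based half-open `start`/`end`, `gene_id`, `strand`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write intervals to BED6
#'
#' @param tbl Tibble with `start`, `end`, `strand` and a name column.
#' @param seqname Chromosome name to use.
#' @param path Output path.
#' @param name_col Column holding the BED name field.
#' @export
write_bed <- function(tbl, seqname, path, name_col = "name") {
  df <- data.frame(
    chrom = seqname, start = tbl$start, end = tbl$end,
    name = tbl[[name_col]], score = 0L, strand = tbl$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[
      seq_len(min(6, ncol(df)))]
  as_tibble(df)
}

#' Write a genome with its annotations
#'
#' Writes `<id>.fasta`, `<id>.genes.gff3`, `<id>.genes.bed` and
#' `<id>.repeats.bed` into `dir`.
#' @param genome A `synth_genome`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, genome$id)
  write_fasta(setNames(genome$sequence, genome$id),
              paste0(base, ".fasta"))
  if (nrow(genome$genes) > 0) {
    write_genes_gff3(genome, paste0(base, ".genes.gff3"))
    write_bed(genome$genes, genome$id, paste0(base, ".genes.bed"),
              name_col = "gene_id")
  }
  if (nrow(genome$repeats) > 0) {
    write_bed(genome$repeats, genome$id, paste0(base, ".repeats.bed"),
              name_col = "family_id")
  }
  invisible(dir)
}

#' Write simulated reads to FASTQ
#'
#' Qualities are a constant (default Q30) because the error model is not
#' tied to quality strings.
#' @param reads A `read_set` tibble.
#' @param path Output FASTQ path (single file; mates are interleaved and
#'   named `<id>/1`, `<id>/2`).
#' @param quality Constant Phred quality to emit.
#' @export
write_fastq <- function(reads, path, quality = 30L) {
  qc <- rawToChar(as.raw(33L + quality))
  quals <- vapply(nchar(reads$sequence),
                  function(n) strrep(qc, n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", quals))
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-read truth table
#'
#' @param reads A `read_set`.
#' @param path Output TSV path (`read_id`, `start`, `end`, `strand`,
#'   `n_sub`, `n_ins`, `n_del`).
#' @export
write_read_truth <- function(reads, path) {
  write.table(
    reads[, c("read_id", "start", "end", "strand",
              "n_sub", "n_ins", "n_del")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read MUMmer show-coords output as alignment blocks
#'
#' Parses the tabular output of `show-coords -rcl`.  Base-level counts are
#' reconstructed from the reported block lengths and percent identity:
#' mismatches and indels cannot be separated without the delta file, so the
#' non-matching columns are apportioned to mismatches and the block length
#' difference to indels.
#' @param path Path to a show-coords listing.
#' @return Alignment-block tibble compatible with [genome_coverage()] and
#'   [base_accuracy()].
#' @export
read_coords <- function(path) {
  lines <- readLines(path)
  data <- grep("^\\s*[0-9]", lines, value = TRUE)
  if (length(data) == 0) abort("no alignment rows found in coords file")
  rows <- lapply(data, function(l) {
    f <- strsplit(gsub("\\|", " ", l), "\\s+")[[1]]
    f <- f[nzchar(f)]
    s1 <- as.numeric(f[1]); e1 <- as.numeric(f[2])
    s2 <- as.numeric(f[3]); e2 <- as.numeric(f[4])
    len1 <- as.numeric(f[5]); len2 <- as.numeric(f[6])
    idy <- as.numeric(f[7])
    qry <- f[length(f)]
    strand <- if (s2 <= e2) "+" else "-"
    qs <- min(s2, e2) - 1; qe <- max(s2, e2)
    n_match <- round(len1 * idy / 100)
    n_ins <- max(0, len2 - len1)
    n_del <- max(0, len1 - len2)
    n_mismatch <- max(0, len1 - n_del - n_match)
    tibble(qry_id = qry, ref_start = s1 - 1, ref_end = e1,
           qry_start = qs, qry_end = qe, strand = strand,
           n_match = n_match, n_mismatch = n_mismatch,
           n_ins = n_ins, n_del = n_del)
  })
  bind_rows(rows)
}

#' Read PAF alignments as alignment blocks
#'
#' Requires the `cg:Z` CIGAR tag to recover base-level counts; `M`
#' operations are counted as matches, `X` as mismatches.
#' @param path Path to a PAF file.
#' @return Alignment-block tibble.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty PAF file")
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) abort("malformed PAF line (fewer than 12 fields)")
    cg <- grep("^cg:Z:", f, value = TRUE)
    if (length(cg) == 0) {
      abort("PAF line lacks a cg:Z CIGAR tag; cannot recover base counts")
    }
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", sub("^cg:Z:", "", cg[1]))[[1]]
    cig <- regmatches(sub("^cg:Z:", "", cg[1]), list(ops))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", cig))
    op <- sub("^[0-9]+", "", cig)
    tibble(
      qry_id = f[1],
      ref_start = as.numeric(f[8]), ref_end = as.numeric(f[9]),
      qry_start = as.numeric(f[3]), qry_end = as.numeric(f[4]),
      strand = f[5],
      n_match = sum(n[op %in% c("M", "=")]),
      n_mismatch = sum(n[op == "X"]),
      n_ins = sum(n[op == "I"]),
      n_del = sum(n[op == "D"]))
  })
  bind_rows(rows)
}
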