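ref_sequence <- function(reference) {
  if (inherits(reference, "synth_genome")) reference$sequence
  else if (is.character(reference) && length(reference) == 1) reference
  else abort("`reference` must be a synth_genome or a single sequence")
}

#' Align an assembly to its reference genome
#'
#' Anchor-and-extend whole-genome alignment: k-mers unique in the
#' reference are matched in each contig (both strands), chained
#' co-linearly, the inter-anchor gaps are filled by banded global
#' alignment, and block ends are extended greedily.  Each block carries
#' exact base-level counts; blocks from reverse-strand contigs are
#' reported on forward reference coordinates.  Contigs without anchors
#' are reported unaligned (absent from the result), not an error.
#'
#' @param assembly An `assembly` (or named character vector of contigs).
#' @param reference A `synth_genome` or reference sequence string.
#' @param anchor_k Anchor k-mer size (default 21).
#' @return Tibble of alignment blocks: `qry_id`, `ref_start`, `ref_end`
#'   (0-based half-open), `qry_start`, `qry_end`, `strand`, `n_match`,
#'   `n_mismatch`, `n_ins`, `n_del`, `identity`.  Satisfies
#'   `n_match + n_mismatch + n_del == ref_end - ref_start` per block.
#' @export
align_assembly <- function(assembly, reference, anchor_k = 21) {
  if (inherits(assembly, "assembly")) {
    seqs <- assembly$contigs$sequence
    ids <- assembly$contigs$contig_id
  } else {
    seqs <- unname(assembly)
    ids <- names(assembly) %||% sprintf("ctg_%05d", seq_along(assembly))
  }
  if (length(seqs) == 0) abort("empty assembly")
  ref <- ref_sequence(reference)
  if (nchar(ref) == 0) abort("empty reference")
  df <- cpp_align_blocks(seqs, ids, ref, as.integer(anchor_k),
                         TRUE, 4L, 3L, FALSE)
  as_tibble(df) |>
    mutate(identity = .data$n_match /
             pmax(1, .data$n_match + .data$n_mismatch +
                    .data$n_ins + .data$n_del))
}

#' Genome coverage of alignment blocks
#'
#' Reference intervals are unioned (overlaps merged) before summing, so
#' the result never exceeds 100.
#' @param blocks Alignment-block tibble (one reference).
#' @param genome_length Reference length in bases.
#' @return Percent of the reference covered.
#' @export
genome_coverage <- function(blocks, genome_length) {
  if (genome_length <= 0) abort("`genome_length` must be positive")
  if (nrow(blocks) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = blocks$ref_start + 1,
                                         end = blocks$ref_end))
  100 * min(sum(IRanges::width(ir)), genome_length) / genome_length
}

#' Substitution and indel error rates of an assembly
#'
#' The identity denominator includes gap columns, so SBE + IDR + SBA
#' decompose exactly to 100.
#' @param blocks Alignment-block tibble with exact base counts.
#' @return One-row tibble: `sbe` (percent substitutions), `idr` (percent
#'   indels), `sba` (`100 - sbe - idr`).
#' @export
base_accuracy <- function(blocks) {
  denom <- sum(blocks$n_match + blocks$n_mismatch +
                 blocks$n_ins + blocks$n_del)
  if (!is.finite(denom) || denom == 0) {
    abort("zero aligned bases: accuracy undefined")
  }
  sbe <- 100 * sum(blocks$n_mismatch) / denom
  idr <- 100 * sum(blocks$n_ins + blocks$n_del) / denom
  tibble(sbe = sbe, idr = idr, sba = 100 - sbe - idr)
}

#' N50 (or NG50) of a set of lengths
#'
#' Sorts descending and accumulates until half of `denominator` is
#' reached; returns the length at which the threshold is crossed.  With
#' the genome length as denominator this is the NG50-style statistic (the
#' smallest contig size such that contigs at least that long hold 50% of
#' the genome); with `sum(lengths)` it is the classic assembly N50.
#'
#' @param lengths Positive contig/scaffold lengths.
#' @param denominator Defaults to `sum(lengths)`.
#' @return The N50 length, or 0 (with a warning) if the cumulative sum
#'   never reaches half the denominator.
#' @export
n50 <- function(lengths, denominator = sum(lengths)) {
  if (length(lengths) == 0 || any(lengths <= 0)) {
    abort("`lengths` must be non-empty and positive")
  }
  if (denominator <= 0) abort("`denominator` must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  idx <- which(cum >= denominator / 2)[1]
  if (is.na(idx)) {
    warn("assembly spans less than half the denominator; N50 undefined (0)")
    return(0)
  }
  s[idx]
}

#' Contig and scaffold counts above reporting thresholds
#'
#' @param assembly An `assembly`.
#' @param min_contig Contigs shorter than this are not counted
#'   (default 100).
#' @param min_scaffold Top-level units (multi-contig scaffolds plus
#'   unplaced contigs) shorter than this are not counted (default 2000).
#' @return Named list `cn`, `sn`.
#' @export
count_units <- function(assembly, min_contig = 100, min_scaffold = 2000) {
  ctg <- assembly$contigs
  cn <- sum(ctg$length >= min_contig)
  unit_lengths <- numeric()
  if (nrow(assembly$scaffolds) > 0) {
    sc <- assembly$scaffolds |>
      left_join(ctg |> select("contig_id", "length"), by = "contig_id") |>
      group_by(.data$scaffold_id) |>
      summarise(len = sum(.data$length) +
                  sum(.data$gap_after, na.rm = TRUE), .groups = "drop")
    unit_lengths <- sc$len
  }
  unplaced <- setdiff(ctg$contig_id, assembly$scaffolds$contig_id)
  unit_lengths <- c(unit_lengths,
                    ctg$length[ctg$contig_id %in% unplaced])
  sn <- sum(unit_lengths >= min_scaffold)
  list(cn = as.integer(cn), sn = as.integer(sn))
}

#' Map annotated genes onto an assembly
#'
#' Each gene sequence is aligned to every contig on both strands; an
#' alignment counts as a gene copy only if identity is strictly greater
#' than `min_identity` AND the aligned gene fraction is strictly greater
#' than `min_coverage`, within a single contig.  Loci on the same contig
#' overlapping by more than 50% are collapsed to one copy.
#'
#' @param genome A `synth_genome` with planted genes (or a named character
#'   vector of gene sequences).
#' @param assembly An `assembly`.
#' @param min_identity Identity threshold (strict >), default 0.99.
#' @param min_coverage Gene length coverage threshold (strict >),
#'   default 0.5.
#' @param k Anchor k-mer size for gene mapping.
#' @return Tibble of gene calls: `gene_id`, `n_copies_found`,
#'   `best_identity`, `best_coverage`.
#' @export
call_genes <- function(genome, assembly, min_identity = 0.99,
                       min_coverage = 0.5, k = 15) {
  gseqs <- if (inherits(genome, "synth_genome")) gene_sequences(genome)
           else genome
  if (length(gseqs) == 0) abort("no gene sequences to map")
  ref_len <- if (inherits(genome, "synth_genome")) genome$length else Inf
  if (any(nchar(gseqs) > ref_len)) {
    abort("gene longer than the reference")
  }
  glens <- setNames(nchar(gseqs), names(gseqs))

  hits <- bind_rows(lapply(seq_len(nrow(assembly$contigs)), function(ci) {
    df <- cpp_align_blocks(unname(gseqs), names(gseqs),
                           assembly$contigs$sequence[ci],
                           as.integer(k), FALSE, 64L, 2L, TRUE)
    if (nrow(df) == 0) return(NULL)
    as_tibble(df) |>
      mutate(contig_id = assembly$contigs$contig_id[ci])
  }))

  calls <- tibble(gene_id = names(gseqs)) |>
    mutate(n_copies_found = 0L, best_identity = 0, best_coverage = 0)
  if (nrow(hits) == 0) return(calls)

  hits <- hits |>
    mutate(
      identity = .data$n_match /
        pmax(1, .data$n_match + .data$n_mismatch +
               .data$n_ins + .data$n_del),
      coverage = (.data$qry_end - .data$qry_start) /
        glens[.data$qry_id]
    )

  best <- hits |>
    group_by(gene_id = .data$qry_id) |>
    summarise(best_identity = max(.data$identity),
              best_coverage = max(.data$coverage), .groups = "drop")

  passing <- hits |>
    filter(.data$identity > min_identity, .data$coverage > min_coverage)

  # collapse loci overlapping > 50% on the same contig
  copies <- passing |>
    group_by(gene_id = .data$qry_id, .data$contig_id) |>
    group_modify(function(d, key) {
      d <- d |> arrange(desc(.data$identity))
      kept <- list()
      for (i in seq_len(nrow(d))) {
        dup <- FALSE
        for (kp in kept) {
          ov <- min(d$ref_end[i], kp$ref_end) -
            max(d$ref_start[i], kp$ref_start)
          shorter <- min(d$ref_end[i] - d$ref_start[i],
                         kp$ref_end - kp$ref_start)
          if (ov > 0.5 * shorter) { dup <- TRUE; break }
        }
        if (!dup) kept[[length(kept) + 1]] <- d[i, ]
      }
      tibble(n_loci = length(kept))
    }) |>
    group_by(.data$gene_id) |>
    summarise(n_copies_found = as.integer(sum(.data$n_loci)),
              .groups = "drop")

  calls |>
    select("gene_id") |>
    left_join(copies, by = "gene_id") |>
    left_join(best, by = "gene_id") |>
    mutate(n_copies_found = coalesce(.data$n_copies_found, 0L),
           best_identity = coalesce(.data$best_identity, 0),
           best_coverage = coalesce(.data$best_coverage, 0))
}

#' False gene loss and duplication rates
#'
#' A gene found zero times is a false loss; copies beyond the true copy
#' number are false duplicates.  Both rates are percentages of the total
#' gene count.
#'
#' @param gene_calls Output of [call_genes()].
#' @param truth Gene annotation tibble with `gene_id` and
#'   `true_copy_number` (e.g. `genome$genes`).
#' @return Named list `flt`, `fdt` (percent).
#' @export
gene_dup_loss <- function(gene_calls, truth) {
  if (nrow(truth) == 0) abort("empty gene truth table")
  j <- truth |>
    select("gene_id", "true_copy_number") |>
    left_join(gene_calls, by = "gene_id") |>
    mutate(n_copies_found = coalesce(.data$n_copies_found, 0L))
  n <- nrow(j)
  list(
    flt = 100 * sum(j$n_copies_found == 0) / n,
    fdt = 100 * sum(pmax(0, j$n_copies_found - j$true_copy_number)) / n
  )
}

#' Evaluate an assembly against its reference
#'
#' Composes alignment, coverage, base accuracy, N50, unit counts and gene
#' mapping into one quality report with the study's indicator set.
#'
#' @param assembly An `assembly`.
#' @param genome The reference `synth_genome` (sequence + gene truth).
#' @param strategy_label Strategy label recorded in the report (e.g.
#'   `"10 x SE + 10 x PE"`).
#' @param anchor_k Anchor k-mer size for the whole-genome alignment.
#' @param min_contig,min_scaffold Reporting thresholds for CN/SN.
#' @param n50_denominator `"genome"` (default; NG50-style against the
#'   genome length) or `"assembly"` (classic N50).
#' @return A one-row `quality_report` tibble: `strategy`, `GCE`, `SBE`,
#'   `IDR`, `SBA`, `FLT`, `FDT`, `CN`, `NB`, `SN`.
#' @export
evaluate <- function(assembly, genome, strategy_label = "",
                     anchor_k = 21, min_contig = 100, min_scaffold = 2000,
                     n50_denominator = c("genome", "assembly")) {
  n50_denominator <- match.arg(n50_denominator)
  blocks <- align_assembly(assembly, genome, anchor_k = anchor_k)
  if (nrow(blocks) == 0) abort("assembly does not align to the reference")
  gce <- genome_coverage(blocks, genome$length)
  acc <- base_accuracy(blocks)
  denom <- if (n50_denominator == "genome") genome$length
           else sum(assembly$contigs$length)
  nb <- withCallingHandlers(
    n50(assembly$contigs$length, denom),
    warning = function(w) invokeRestart("muffleWarning"))
  units <- count_units(assembly, min_contig, min_scaffold)
  if (nrow(genome$genes) > 0) {
    calls <- call_genes(genome, assembly)
    gl <- gene_dup_loss(calls, genome$genes)
  } else {
    gl <- list(flt = NA_real_, fdt = NA_real_)
  }
  out <- tibble(
    strategy = strategy_label,
    GCE = gce, SBE = acc$sbe, IDR = acc$idr, SBA = acc$sba,
    FLT = gl$flt, FDT = gl$fdt,
    CN = units$cn, NB = nb, SN = units$sn
  )
  class(out) <- c("quality_report", class(out))
  out
}

#' Write quality reports as TSV or JSON
#'
#' Columns follow the study's table order (ST, GCE, SBE, IDR, FLT, FDT,
#' CN, NB, SN) with SBA appended for completeness.
#' @param reports One or more stacked `quality_report` rows.
#' @param path Output path; format from extension (`.json` or TSV).
#' @export
write_quality_report <- function(reports, path) {
  df <- reports |>
    transmute(ST = .data$strategy, GCE = .data$GCE, SBE = .data$SBE,
              IDR = .data$IDR, FLT = .data$FLT, FDT = .data$FDT,
              CN = .data$CN, NB = .data$NB, SN = .data$SN,
              SBA = .data$SBA)
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("jsonlite is required for JSON output")
    }
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
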