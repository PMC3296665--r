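#' Generate a synthetic circular prokaryotic genome
#'
#' Draws an i.i.d. base sequence with the requested GC content.  The result
#' starts with empty gene and repeat annotation tables; use
#' [plant_repeats()] and [plant_genes()] to add ground-truth features.
#' Coordinates throughout the package are 0-based, half-open.
#'
#' @param length Genome size in bases (1 kb to 10 Mb).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Optional integer seed; the same `(length, gc, seed)` always
#'   yields the same genome.
#' @param id Genome identifier used in FASTA/GFF3 output and read names.
#' @return A `synth_genome` object: a list with elements `id`, `sequence`,
#'   `length`, `circular`, `gc`, `genes` (tibble: `gene_id`, `start`, `end`,
#'   `strand`, `true_copy_number`) and `repeats` (tibble: `family_id`,
#'   `copy`, `start`, `end`, `strand`, `unit_length`, `divergence`).
#' @examples
#' g <- make_genome(5000, gc = 0.4, seed = 1)
#' g$length
#' @export
make_genome <- function(length, gc = 0.5, seed = NULL, id = "genome") {
  if (length < 1000 || length > 10e6) {
    abort("`length` must be between 1,000 and 10,000,000 bases")
  }
  if (gc <= 0 || gc >= 1) abort("`gc` must be strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(
      id = id,
      sequence = random_dna(length, gc),
      length = as.integer(length),
      circular = TRUE,
      gc = gc,
      genes = empty_genes(),
      repeats = empty_repeats(),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "synth_genome"
  )
}

empty_genes <- function() {
  tibble(gene_id = character(), start = integer(), end = integer(),
         strand = character(), true_copy_number = integer())
}

empty_repeats <- function() {
  tibble(family_id = character(), copy = integer(), start = integer(),
         end = integer(), strand = character(), unit_length = integer(),
         divergence = double())
}

#' @export
print.synth_genome <- function(x, ...) {
  cat(sprintf(
    "<synth_genome %s> %s bp circular, GC %.3f, %d genes, %d repeat copies\n",
    x$id, format(x$length, big.mark = ","), x$gc,
    nrow(x$genes), nrow(x$repeats)))
  invisible(x)
}

# occupied intervals (genes + repeat copies), as a two-column matrix
occupied_intervals <- function(genome, extra = NULL) {
  iv <- rbind(
    cbind(genome$genes$start, genome$genes$end),
    cbind(genome$repeats$start, genome$repeats$end),
    extra
  )
  if (is.null(iv)) matrix(numeric(0), ncol = 2) else iv
}

# find a free non-wrapping placement of `len` bases, or NA after max tries
place_interval <- function(genome_length, len, occupied, gap = 20,
                           max_tries = 400) {
  for (i in seq_len(max_tries)) {
    s <- floor(runif(1) * (genome_length - len))
    e <- s + len
    if (nrow(occupied) == 0 ||
        all(e + gap <= occupied[, 1] | s - gap >= occupied[, 2])) {
      return(s)
    }
  }
  NA_real_
}

#' Plant near-identical repeat families into a genome
#'
#' Each family is a random consensus of `unit_length` bases; every copy is
#' an independently mutated version of the consensus (substitution rate
#' `divergence`), written over the background sequence at a random
#' non-overlapping position and on a random strand.  Genome length is
#' unchanged.  Families span both sides of the >300 bp and >700 bp
#' long-repeat classes when called with the corresponding unit lengths.
#'
#' @param genome A `synth_genome`.
#' @param n_families Number of families to plant (0 returns the genome
#'   unchanged).
#' @param unit_length Consensus length in bases (scalar or one per family).
#' @param copies_per_family Copies per family, at least 2.
#' @param divergence Per-base substitution rate between each copy and the
#'   family consensus, in `[0, 0.2]`.
#' @param seed Optional seed.
#' @param strands `"both"` places copies on a random strand, `"forward"`
#'   keeps all copies on the plus strand.
#' @return The genome with updated `sequence` and `repeats` annotation.
#' @export
plant_repeats <- function(genome, n_families, unit_length,
                          copies_per_family, divergence = 0, seed = NULL,
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (n_families == 0) return(genome)
  if (copies_per_family < 2) abort("`copies_per_family` must be >= 2")
  if (divergence < 0 || divergence > 0.2) {
    abort("`divergence` must be in [0, 0.2]")
  }
  if (!is.null(seed)) set.seed(seed)
  unit_length <- rep_len(unit_length, n_families)
  n_existing <- length(unique(genome$repeats$family_id))

  for (f in seq_len(n_families)) {
    ul <- unit_length[f]
    if (ul * copies_per_family > 0.5 * genome$length) {
      abort("not enough space to place repeat copies without overlap")
    }
    consensus <- random_dna(ul, genome$gc)
    fam_id <- sprintf("fam_%03d", n_existing + f)
    occ <- occupied_intervals(genome)
    rows <- vector("list", copies_per_family)
    for (cp in seq_len(copies_per_family)) {
      s <- place_interval(genome$length, ul, occ)
      if (is.na(s)) abort("could not place repeat copy: insufficient space")
      strand <- if (strands == "forward") "+" else
        sample(c("+", "-"), 1)
      copy_seq <- mutate_seq(consensus, divergence)
      if (strand == "-") copy_seq <- cpp_revcomp(copy_seq)[[1]]
      substr(genome$sequence, s + 1, s + ul) <- copy_seq
      rows[[cp]] <- tibble(
        family_id = fam_id, copy = cp, start = as.integer(s),
        end = as.integer(s + ul), strand = strand,
        unit_length = as.integer(ul), divergence = divergence)
      occ <- rbind(occ, c(s, s + ul))
    }
    genome$repeats <- bind_rows(genome$repeats, bind_rows(rows))
  }
  genome
}

#' Plant gene annotations into a genome
#'
#' Genes are annotated intervals over the existing sequence (the interval
#' itself is the gene); they are placed without overlapping one another or
#' any repeat copy, and carry `true_copy_number = 1`.  Duplicated genes are
#' created by placing a gene inside a planted repeat unit
#' (`n_in_repeats > 0`), in which case the gene exists once per repeat copy
#' and `true_copy_number` equals the family copy count.
#'
#' @param genome A `synth_genome` (plant repeats first if `n_in_repeats`).
#' @param n_genes Number of ordinary (single-copy) genes, at least 1 in
#'   total including `n_in_repeats`.
#' @param mean_length Mean gene length in bases; lengths are drawn from a
#'   normal with sd `0.15 * mean_length`, truncated at 300 bases.
#' @param seed Optional seed.
#' @param n_in_repeats How many of the genes to place inside repeat copies.
#' @return The genome with an updated `genes` annotation table.
#' @export
plant_genes <- function(genome, n_genes, mean_length = 900, seed = NULL,
                        n_in_repeats = 0) {
  if (n_genes < 1) abort("`n_genes` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_plain <- n_genes - n_in_repeats
  if (n_plain < 0) abort("`n_in_repeats` cannot exceed `n_genes`")
  n_existing <- nrow(genome$genes)
  rows <- vector("list", n_genes)

  if (n_in_repeats > 0) {
    fams <- genome$repeats |>
      group_by(.data$family_id) |>
      summarise(unit_length = first(.data$unit_length),
                copies = max(.data$copy), .groups = "drop") |>
      filter(.data$unit_length >= 350)
    if (nrow(fams) == 0) {
      abort("no repeat family is long enough to host a gene")
    }
  }

  for (i in seq_len(n_genes)) {
    len <- max(300, round(rnorm(1, mean_length, 0.15 * mean_length)))
    gene_id <- sprintf("gene_%04d", n_existing + i)
    if (i <= n_in_repeats) {
      fam <- fams[1 + (i - 1) %% nrow(fams), ]
      copy1 <- genome$repeats |>
        filter(.data$family_id == fam$family_id, .data$copy == 1)
      len <- min(len, fam$unit_length - 40)
      s <- copy1$start + 20
      rows[[i]] <- tibble(
        gene_id = gene_id, start = as.integer(s),
        end = as.integer(s + len), strand = copy1$strand,
        true_copy_number = as.integer(fam$copies))
    } else {
      occ <- occupied_intervals(genome)
      s <- place_interval(genome$length, len, occ)
      if (is.na(s)) abort("could not place gene: insufficient space")
      rows[[i]] <- tibble(
        gene_id = gene_id, start = as.integer(s),
        end = as.integer(s + len), strand = sample(c("+", "-"), 1),
        true_copy_number = 1L)
    }
    genome$genes <- bind_rows(genome$genes, rows[[i]])
  }
  genome
}

#' Extract gene sequences from the reference
#'
#' @param genome A `synth_genome` with planted genes.
#' @return Named character vector of gene sequences (minus-strand genes are
#'   reverse-complemented).
#' @export
gene_sequences <- function(genome) {
  if (nrow(genome$genes) == 0) return(setNames(character(), character()))
  seqs <- vapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes[i, ]
    s <- seq_extract(genome$sequence, g$start, g$end - g$start,
                     genome$circular)
    if (g$strand == "-") cpp_revcomp(s)[[1]] else s
  }, character(1))
  setNames(seqs, genome$genes$gene_id)
}

#' Generate a panel of synthetic genomes with graded repeat content
#'
#' Sizes are drawn from `size_range` with 90% of the mass below `size_q90`
#' (mirroring a strongly right-skewed size distribution of sequenced
#' prokaryotes).  Long-repeat content (fraction of the genome in repeat
#' copies >300 bp) is spread evenly across `repeat_content_range`, so a
#' range reaching past 0.10 yields at least one repeat-dense genome.
#' Each genome is reproducible from `(seed, index)`.
#'
#' @param n_genomes Panel size, at least 2.
#' @param size_range Two-element range of genome sizes in bases.
#' @param repeat_content_range Range of the >300 bp repeat fraction.
#' @param seed Integer panel seed.
#' @param size_q90 Size below which 90% of genomes fall; default is the
#'   0.675 quantile point of `size_range`.
#' @param gc_range Per-genome GC is drawn uniformly from this range.
#' @param gene_density Genes per base (default one gene per 5 kb).
#' @param gene_mean_length Mean planted gene length in bases.
#' @param divergence Inter-copy divergence of planted repeat families.
#' @return List of `synth_genome` objects; see [panel_manifest()].
#' @export
make_panel <- function(n_genomes, size_range = c(1e5, 8e6),
                       repeat_content_range = c(0, 0.12), seed = 1,
                       size_q90 = NULL, gc_range = c(0.35, 0.65),
                       gene_density = 1 / 5000, gene_mean_length = 900,
                       divergence = 0.005) {
  if (n_genomes < 2) abort("`n_genomes` must be >= 2")
  if (diff(range(size_range)) < 0 || size_range[1] > size_range[2]) {
    abort("`size_range` must be a non-empty increasing range")
  }
  if (repeat_content_range[1] > repeat_content_range[2]) {
    abort("`repeat_content_range` must be a non-decreasing range")
  }
  if (is.null(size_q90)) {
    size_q90 <- size_range[1] + 0.675 * diff(size_range)
  }
  rc <- seq(repeat_content_range[1], repeat_content_range[2],
            length.out = n_genomes)
  # long (>300 bp) units follow the graded per-genome fraction; short units
  # are drawn independently so the two classes are not collinear across the
  # panel (otherwise read-length contrasts are unidentifiable)
  units_long <- c(350, 450, 700, 1000, 1500, 2500, 4000)
  units_long_w <- c(3, 3, 2, 2, 1, 1, 1)
  units_short <- c(150, 250)
  copies_opts <- c(2, 3, 4, 6, 8)
  copies_w <- c(0.3, 0.3, 0.2, 0.1, 0.1)

  lapply(seq_len(n_genomes), function(i) {
    gseed <- stable_hash(seed, sprintf("panel_%d", i))
    set.seed(gseed)
    u <- runif(1)
    size <- if (u < 0.9) runif(1, size_range[1], min(size_q90, size_range[2]))
            else runif(1, min(size_q90, size_range[2]), size_range[2])
    size <- round(size)
    gc <- runif(1, gc_range[1], gc_range[2])
    g <- make_genome(size, gc = gc, id = sprintf("g%03d", i))
    g$seed <- gseed
    target_bp <- rc[i] * size
    planted <- 0
    guard <- 0
    while (planted < target_bp && guard < 200) {
      guard <- guard + 1
      ul <- sample(units_long, 1, prob = units_long_w)
      cp <- sample(copies_opts, 1, prob = copies_w)
      if (ul * cp > 0.2 * size) next
      if (ul * cp > (target_bp - planted) + 2000) next
      g <- tryCatch(
        plant_repeats(g, 1, ul, cp, divergence = divergence),
        error = function(e) g)
      planted <- sum(with(g$repeats, pmax(0, end - start)[
        (end - start) > 300]))
    }
    short_target <- runif(1, 0, 0.03) * size
    planted_short <- 0
    guard <- 0
    while (planted_short < short_target && guard < 100) {
      guard <- guard + 1
      ul <- sample(units_short, 1)
      cp <- sample(copies_opts, 1, prob = copies_w)
      g <- tryCatch(
        plant_repeats(g, 1, ul, cp, divergence = divergence),
        error = function(e) g)
      planted_short <- sum(with(g$repeats, pmax(0, end - start)[
        (end - start) <= 300]))
    }
    n_genes <- max(5, round(size * gene_density))
    g <- plant_genes(g, n_genes, mean_length = gene_mean_length)
    g
  })
}

#' Summarise a genome panel
#'
#' @param panel List of `synth_genome` objects from [make_panel()].
#' @return Tibble with one row per genome: `genome_id`, `length`,
#'   `n_genes`, `repeat_bp_gt300`, `repeat_bp_gt700`, `seed`.
#' @export
panel_manifest <- function(panel) {
  bind_rows(lapply(panel, function(g) {
    lens <- g$repeats$end - g$repeats$start
    tibble(
      genome_id = g$id,
      length = g$length,
      n_genes = nrow(g$genes),
      repeat_bp_gt300 = sum(lens[lens > 300]),
      repeat_bp_gt700 = sum(lens[lens > 700]),
      seed = g$seed
    )
  }))
}
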