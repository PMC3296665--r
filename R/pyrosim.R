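#' Flow-cycle sequencing error model
#'
#' Parametric error model for 454-style pyrosequencing reads.  Indels are
#' dominated by homopolymer length miscalls: an observed run of true length
#' L is drawn from `round(Normal(L, sigma0 + sigma1 * L))`, truncated at 0.
#' Substitutions follow a per-relative-position probability profile
#' (linearly interpolated between `sub_start` at the 5' end and `sub_end`
#' at the 3' end unless an explicit `profile` is given).  A small
#' background indel rate applies outside homopolymers.  The defaults keep
#' the expected total per-base error under 2%.
#'
#' @param sub_start,sub_end Substitution probability at the first/last
#'   base of a read.
#' @param sigma0,sigma1 Homopolymer length-call noise: sd = sigma0 +
#'   sigma1 * L for a run of length L.
#' @param background_indel Per-base indel probability outside homopolymers.
#' @param profile Optional numeric vector of substitution probabilities
#'   sampled on relative read position (overrides `sub_start`/`sub_end`),
#'   e.g. an empirical profile measured from real data.
#' @return An `error_model` object.
#' @export
error_model <- function(sub_start = 0.001, sub_end = 0.005,
                        sigma0 = 0.03, sigma1 = 0.01,
                        background_indel = 1e-4, profile = NULL) {
  if (is.null(profile)) {
    profile <- seq(sub_start, sub_end, length.out = 512)
  }
  if (any(profile < 0 | profile > 1)) {
    abort("substitution probabilities must lie in [0, 1]")
  }
  if (sigma0 < 0 || sigma1 < 0 || background_indel < 0 ||
      background_indel > 1) {
    abort("sigma0, sigma1 must be >= 0 and background_indel in [0, 1]")
  }
  structure(
    list(profile = profile, sigma0 = sigma0, sigma1 = sigma1,
         background_indel = background_indel),
    class = "error_model")
}

#' Error-free model (identity transform)
#' @return An `error_model` injecting no errors.
#' @export
zero_error_model <- function() {
  error_model(0, 0, 0, 0, 0)
}

#' Read-length distribution
#'
#' @param kind One of `"fixed"`, `"truncated-normal"`,
#'   `"empirical-table"`.
#' @param mean,sd Mean and sd in bases (fixed and truncated-normal kinds).
#' @param table Data frame with columns `length` and `probability`
#'   (empirical-table kind); probabilities must sum to 1.
#' @param support Truncation bounds; defaults to `[30, 1.2 * mean]` for the
#'   truncated-normal kind, within the platform's global `[30, 1200]`.
#' @return A `read_length_dist` object.
#' @export
read_length_dist <- function(kind = c("fixed", "truncated-normal",
                                      "empirical-table"),
                             mean = NULL, sd = NULL, table = NULL,
                             support = NULL) {
  kind <- match.arg(kind)
  if (kind == "empirical-table") {
    if (is.null(table) || !all(c("length", "probability") %in% names(table))) {
      abort("empirical-table kind needs a table with length and probability")
    }
    if (abs(sum(table$probability) - 1) > 1e-6) {
      abort("empirical table probabilities must sum to 1")
    }
    if (any(table$length < 30 | table$length > 1200)) {
      abort("read lengths must lie in [30, 1200]")
    }
  } else {
    if (is.null(mean)) abort("`mean` is required")
    if (kind == "truncated-normal" && is.null(sd)) sd <- 0.1 * mean
    if (is.null(support)) support <- c(30, min(1200, 1.2 * mean))
    if (support[1] < 30 || support[2] > 1200) {
      abort("read-length support must lie within [30, 1200]")
    }
  }
  structure(list(kind = kind, mean = mean, sd = sd, table = table,
                 support = support),
            class = "read_length_dist")
}

# draw n read lengths from a read_length_dist
draw_lengths <- function(dist, n) {
  if (n == 0) return(integer())
  switch(dist$kind,
    "fixed" = rep(as.integer(round(dist$mean)), n),
    "truncated-normal" = {
      out <- round(rnorm(n, dist$mean, dist$sd))
      bad <- which(out < dist$support[1] | out > dist$support[2])
      guard <- 0
      while (length(bad) > 0 && guard < 50) {
        out[bad] <- round(rnorm(length(bad), dist$mean, dist$sd))
        bad <- which(out < dist$support[1] | out > dist$support[2])
        guard <- guard + 1
      }
      out[out < dist$support[1]] <- dist$support[1]
      out[out > dist$support[2]] <- dist$support[2]
      as.integer(out)
    },
    "empirical-table" = as.integer(sample(dist$table$length, n,
      replace = TRUE, prob = dist$table$probability)))
}

#' Sequencing library specification
#'
#' @param layout `"se"` (shotgun) or `"pe"` (paired-end).
#' @param read_length Target read length: 100, 200 or 400 bases.
#' @param depth Fold coverage (emitted bases / genome length), > 0.
#' @param insert_mean,insert_sd Paired-end fragment length distribution in
#'   bases (e.g. 3000 or 8000); `insert_sd` defaults to 10% of the mean.
#' @param extension Paired-end anchor extension in bases (default 500: a
#'   200 bp anchor is extended to 700 bp of source sequence before error
#'   injection and length trimming).
#' @param length_dist Optional [read_length_dist()]; defaults to a
#'   truncated normal with mean `read_length` and sd 10% of it.
#' @return A `library_spec` object.
#' @export
library_spec <- function(layout = c("se", "pe"), read_length = 400, depth,
                         insert_mean = NULL, insert_sd = NULL,
                         extension = 500, length_dist = NULL) {
  layout <- match.arg(layout)
  if (!read_length %in% c(100, 200, 400)) {
    abort("`read_length` must be one of 100, 200, 400")
  }
  if (depth <= 0) abort("`depth` must be > 0")
  if (layout == "pe") {
    if (is.null(insert_mean)) abort("paired-end layout needs `insert_mean`")
    if (insert_mean <= 2 * read_length) {
      abort("`insert_mean` must exceed twice the read length")
    }
    if (is.null(insert_sd)) insert_sd <- 0.1 * insert_mean
  }
  if (is.null(length_dist)) {
    length_dist <- read_length_dist("truncated-normal", mean = read_length)
  }
  structure(
    list(layout = layout, read_length = read_length, depth = depth,
         insert_mean = insert_mean, insert_sd = insert_sd,
         extension = extension, length_dist = length_dist),
    class = "library_spec")
}

new_read_set <- function(tbl, genome) {
  attr(tbl, "genome_id") <- genome$id
  attr(tbl, "genome_length") <- genome$length
  class(tbl) <- c("read_set", class(tbl))
  tbl
}

# Draw per-read tuples in fixed-size chunks until the base target is met.
# Chunked draws make the read stream *nested* across depths: with the same
# seed, a shallower library is a prefix of a deeper one (common random
# numbers), so depth ladders are compared on coupled read sets.
draw_shotgun_chunks <- function(dist, target_bases, genome_length,
                                chunk = 256L, min_len = 30L) {
  lens <- integer(); starts <- numeric(); strands <- character()
  total <- 0
  while (total < target_bases) {
    lc <- draw_lengths(dist, chunk)
    sc <- floor(runif(chunk) * genome_length)
    tc <- sample(c("+", "-"), chunk, replace = TRUE)
    lens <- c(lens, lc); starts <- c(starts, sc); strands <- c(strands, tc)
    total <- total + sum(lc)
  }
  cum <- cumsum(lens)
  m <- which(cum >= target_bases)[1]
  excess <- cum[m] - target_bases
  if (excess > 0 && lens[m] - excess >= min_len) {
    lens[m] <- lens[m] - as.integer(excess)
  } else if (excess > 0 && m > 1) {
    m <- m - 1  # tiny deficit, well within 1%
  }
  list(lens = lens[seq_len(m)], starts = starts[seq_len(m)],
       strands = strands[seq_len(m)])
}

#' Simulate single-end shotgun reads
#'
#' Reads are sampled uniformly over the circular genome on a uniform
#' strand; read lengths come from the library's length distribution; the
#' number of reads is chosen so emitted bases / genome length is within 1%
#' of the requested depth.  Errors are injected with [apply_errors()]
#' semantics and per-read truth coordinates (error-free source span on the
#' forward strand) are recorded.
#'
#' @param genome A `synth_genome`.
#' @param lib A single-end [library_spec()].
#' @param model An [error_model()].
#' @param seed Optional seed.
#' @return A `read_set` tibble: `read_id`, `sequence`, `mate`, `start`,
#'   `end`, `strand`, `n_sub`, `n_ins`, `n_del`.  `end` may exceed the
#'   genome length for reads wrapping the circular origin.
#' @export
simulate_shotgun <- function(genome, lib, model = error_model(),
                             seed = NULL) {
  if (lib$layout != "se") abort("`lib` must have layout \"se\"")
  if (!is.null(seed)) set.seed(seed)
  L <- genome$length
  max_len <- if (lib$length_dist$kind == "empirical-table")
    max(lib$length_dist$table$length) else lib$length_dist$support[2]
  if (is.null(max_len)) max_len <- lib$length_dist$mean
  if (L <= max_len) abort("genome shorter than the maximum read length")

  drawn <- draw_shotgun_chunks(lib$length_dist, lib$depth * L, L)
  lens <- drawn$lens
  n <- length(lens)
  starts <- drawn$starts
  strands <- drawn$strands
  doubled <- paste0(genome$sequence, genome$sequence)
  src <- substring(doubled, starts + 1, starts + lens)
  flip <- strands == "-"
  src[flip] <- cpp_revcomp(src[flip])

  res <- cpp_apply_errors(src, model$profile, model$sigma0, model$sigma1,
                          model$background_indel, rep(NA_integer_, n))
  new_read_set(tibble(
    read_id = sprintf("r%06d", seq_len(n)),
    sequence = unlist(res$sequence),
    mate = NA_integer_,
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = strands,
    n_sub = res$n_sub, n_ins = res$n_ins, n_del = res$n_del
  ), genome)
}

#' Simulate a paired-end library
#'
#' Implements the four-step Monte-Carlo paired-end procedure: (1) draw a
#' fragment length from `Normal(insert_mean, insert_sd)` and place it
#' uniformly on the circle; (2) take the two inward-facing anchor reads
#' (200 bp) at the fragment ends; (3) extend each anchor to
#' `200 + extension` bases of error-free source sequence, truncated at the
#' fragment midpoint; (4) inject errors, then trim each read to a length
#' drawn from the library's read-length distribution (draws longer than
#' the available extended sequence keep the full sequence).  Mates are
#' forward/reverse on opposite strands and named `<id>/1`, `<id>/2`.
#'
#' @inheritParams simulate_shotgun
#' @param lib A paired-end [library_spec()].
#' @param anchor Anchor read length in bases (default 200).
#' @return A `read_set` with `mate` 1/2.
#' @export
simulate_paired <- function(genome, lib, model = error_model(),
                            seed = NULL, anchor = 200L) {
  if (lib$layout != "pe") abort("`lib` must have layout \"pe\"")
  if (!is.null(seed)) set.seed(seed)
  L <- genome$length
  if (lib$insert_mean >= L) {
    abort("`insert_mean` must be smaller than the genome length")
  }

  target <- lib$depth * L
  chunk <- 256L
  frag <- numeric(); starts <- numeric(); l1 <- integer(); l2 <- integer()
  total <- 0
  while (total < target) {
    fc <- round(rnorm(chunk, lib$insert_mean, lib$insert_sd))
    fc <- pmin(pmax(fc, 2 * anchor), L - 1)
    sc <- floor(runif(chunk) * L)
    ac <- pmin(anchor + lib$extension, floor(fc / 2))
    l1c <- pmin(draw_lengths(lib$length_dist, chunk), ac)
    l2c <- pmin(draw_lengths(lib$length_dist, chunk), ac)
    frag <- c(frag, fc); starts <- c(starts, sc)
    l1 <- c(l1, l1c); l2 <- c(l2, l2c)
    total <- total + sum(l1c + l2c)
  }
  cum <- cumsum(l1 + l2)
  m <- which(cum >= target)[1]
  keep <- seq_len(m)
  frag <- frag[keep]; starts <- starts[keep]
  avail <- pmin(anchor + lib$extension, floor(frag / 2))
  l1 <- l1[keep]; l2 <- l2[keep]
  excess <- sum(l1 + l2) - target
  if (excess > 0 && l2[m] - excess >= 30) l2[m] <- l2[m] - as.integer(excess)
  doubled <- paste0(genome$sequence, genome$sequence)
  src1 <- substring(doubled, starts + 1, starts + avail)
  e2 <- starts + frag
  src2 <- substring(doubled, e2 - avail + 1, e2)
  over <- e2 > 2 * L  # fragment end wrapped past the doubled copy
  if (any(over)) {
    e2w <- ((e2[over] - 1) %% L) + 1
    src2[over] <- substring(doubled, e2w - avail[over] + 1, e2w)
  }
  src2 <- cpp_revcomp(src2)

  res1 <- cpp_apply_errors(src1, model$profile, model$sigma0, model$sigma1,
                           model$background_indel, as.integer(l1))
  res2 <- cpp_apply_errors(src2, model$profile, model$sigma0, model$sigma1,
                           model$background_indel, as.integer(l2))

  s1 <- starts
  span1 <- res1$src_used
  span2 <- res2$src_used
  s2 <- (starts + frag - span2) %% L

  ids <- sprintf("p%06d", seq_len(m))
  tbl <- bind_rows(
    tibble(read_id = paste0(ids, "/1"), sequence = unlist(res1$sequence),
           mate = 1L, start = as.integer(s1),
           end = as.integer(s1 + span1), strand = "+",
           n_sub = res1$n_sub, n_ins = res1$n_ins, n_del = res1$n_del),
    tibble(read_id = paste0(ids, "/2"), sequence = unlist(res2$sequence),
           mate = 2L, start = as.integer(s2),
           end = as.integer(s2 + span2), strand = "-",
           n_sub = res2$n_sub, n_ins = res2$n_ins, n_del = res2$n_del)
  ) |>
    arrange(.data$read_id)
  new_read_set(tbl, genome)
}

#' Inject sequencing errors into one sequence
#'
#' Homopolymer runs are re-called through the sigma model (over-calls
#' become insertions of the run base, under-calls deletions);
#' substitutions follow the positional profile; a background indel rate
#' applies outside homopolymers.  Counts are returned exactly and satisfy
#' `nchar(out) == nchar(in) - n_del + n_ins`.
#'
#' @param sequence A single A/C/G/T string.
#' @param model An [error_model()].
#' @param seed Optional seed.
#' @return List with `sequence`, `n_sub`, `n_ins`, `n_del`.
#' @export
apply_errors <- function(sequence, model = error_model(), seed = NULL) {
  if (!grepl("^[ACGT]+$", sequence)) {
    abort("`sequence` must be a non-empty A/C/G/T string")
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_apply_errors(sequence, model$profile, model$sigma0,
                          model$sigma1, model$background_indel,
                          NA_integer_)
  list(sequence = unlist(res$sequence), n_sub = res$n_sub[1],
       n_ins = res$n_ins[1], n_del = res$n_del[1])
}

#' Estimate fold coverage of a read set
#'
#' @param reads A `read_set` (or any tibble with a `sequence` column).
#' @param genome_length Genome length in bases.
#' @return Sum of read lengths divided by `genome_length`.
#' @export
estimate_depth <- function(reads, genome_length) {
  if (genome_length <= 0) abort("`genome_length` must be positive")
  if (nrow(reads) == 0) abort("empty read set")
  sum(nchar(reads$sequence)) / genome_length
}

#' Merge read sets (e.g. shotgun plus paired-end)
#'
#' Read ids are prefixed per set to stay unique.
#' @param ... `read_set` objects from the same genome.
#' @param prefixes Character prefixes, one per set.
#' @return A combined `read_set`.
#' @export
merge_read_sets <- function(..., prefixes = NULL) {
  sets <- list(...)
  if (length(sets) == 0) abort("no read sets given")
  if (is.null(prefixes)) prefixes <- sprintf("s%d_", seq_along(sets))
  out <- bind_rows(lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    s$read_id <- paste0(prefixes[i], s$read_id)
    s
  }))
  attr(out, "genome_id") <- attr(sets[[1]], "genome_id")
  attr(out, "genome_length") <- attr(sets[[1]], "genome_length")
  class(out) <- unique(c("read_set", class(out)))
  out
}
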