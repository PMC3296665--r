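#' De novo repeat detection by seeded consensus extension
#'
#' A simplified repeat finder: k-mers occurring at least `min_copies`
#' times (canonically, so inverted copies are found) seed families; each
#' seed is extended left and right while at least `min_copies` copies stay
#' within `min_identity` of the running consensus; families at least
#' `min_length` long are reported with per-copy coordinates.  Planted
#' annotations (`genome$repeats`) remain the primary ground truth for
#' repeat metrics; this detector supports genomes without truth.
#'
#' @param genome A `synth_genome` or a single sequence string.
#' @param k Seed k-mer size, in `[10, 20]`.
#' @param min_length Minimum reported copy length in bases.
#' @param min_copies Minimum copies per family (>= 2).
#' @param min_identity Extension identity threshold.
#' @return Tibble of repeat copies: `family_id`, `copy`, `start`, `end`,
#'   `strand`, `unit_length`.
#' @export
find_repeats <- function(genome, k = 14, min_length = 100,
                         min_copies = 2, min_identity = 0.9) {
  if (k < 10 || k > 20) abort("`k` must be in [10, 20]")
  if (min_copies < 2) abort("`min_copies` must be >= 2")
  seqs <- ref_sequence(genome)
  if (nchar(seqs) < k) abort("genome shorter than `k`")
  df <- as_tibble(cpp_find_repeats(seqs, as.integer(k),
                                   as.integer(min_length),
                                   as.integer(min_copies), min_identity,
                                   512L))
  if (nrow(df) == 0) {
    return(tibble(family_id = character(), copy = integer(),
                  start = integer(), end = integer(), strand = character(),
                  unit_length = integer()))
  }
  out <- df |>
    group_by(.data$family) |>
    mutate(copy = row_number(),
           unit_length = as.integer(max(.data$end - .data$start))) |>
    ungroup() |>
    mutate(family_id = sprintf("rf_%03d", .data$family)) |>
    select("family_id", "copy", "start", "end", "strand", "unit_length")

  # merge families by containment: drop a family whose copies lie almost
  # entirely within another family's footprint
  fams <- split(out, out$family_id)
  footprints <- lapply(fams, function(f)
    IRanges::reduce(IRanges::IRanges(f$start + 1, f$end)))
  sizes <- vapply(fams, function(f) sum(f$end - f$start), numeric(1))
  keep <- rep(TRUE, length(fams))
  ord <- order(sizes, decreasing = TRUE)
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in seq_along(ord)) {
      if (i == j || !keep[ord[j]]) next
      if (sizes[ord[j]] > sizes[ord[i]]) next
      ov <- sum(IRanges::width(IRanges::intersect(
        footprints[[ord[j]]], footprints[[ord[i]]])))
      if (ov >= 0.95 * sum(IRanges::width(footprints[[ord[j]]])) &&
          ord[j] != ord[i]) {
        keep[ord[j]] <- FALSE
      }
    }
  }
  bind_rows(fams[keep])
}

#' Summarise the repeat content of a genome
#'
#' Computes the study's repeat indicators: copy count, total repeat
#' length, and the long-repeat classes with copy length strictly greater
#' than 300 bp and 700 bp.  Overlapping copies are unioned before
#' totalling, so percentages are bounded by 100.
#'
#' @param repeats Repeat copy tibble with `start`/`end` (planted truth
#'   `genome$repeats` or [find_repeats()] output).
#' @param genome_length Genome length in bases.
#' @return One-row tibble: `n_repeats`, `total_bp`, `pct_total`,
#'   `total_bp_gt300`, `pct_gt300`, `total_bp_gt700`, `pct_gt700`.
#' @export
summarize_repeats <- function(repeats, genome_length) {
  union_bp <- function(tbl) {
    if (nrow(tbl) == 0) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(tbl$start + 1, tbl$end))))
  }
  lens <- repeats$end - repeats$start
  tibble(
    n_repeats = nrow(repeats),
    total_bp = union_bp(repeats),
    pct_total = 100 * union_bp(repeats) / genome_length,
    total_bp_gt300 = union_bp(repeats[lens > 300, ]),
    pct_gt300 = 100 * union_bp(repeats[lens > 300, ]) / genome_length,
    total_bp_gt700 = union_bp(repeats[lens > 700, ]),
    pct_gt700 = 100 * union_bp(repeats[lens > 700, ]) / genome_length
  )
}

#' Regress a quality indicator on a repeat indicator
#'
#' Ordinary least squares of `response` on `predictor` across a genome
#' panel, reporting the slope, intercept, R-squared and the two-sided
#' slope p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param panel Data frame with one row per genome holding both columns
#'   (e.g. a repeat summary joined to a quality report).
#' @param predictor,response Column names.
#' @return A `repeat_regression` object; see [tidy()] and [glance()].
#' @export
regress <- function(panel, predictor, response) {
  if (nrow(panel) < 3) abort("panel must have at least 3 genomes")
  x <- panel[[predictor]]
  y <- panel[[response]]
  if (is.null(x) || is.null(y)) abort("predictor/response column missing")
  if (var(x) == 0) abort("predictor has zero variance")
  d <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = d)
  # a perfect fit (e.g. y exactly linear in x) is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      predictor = predictor, response = response,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]),
      n = nrow(d), fit = fit
    ),
    class = "repeat_regression")
}

#' @export
print.repeat_regression <- function(x, ...) {
  cat(sprintf(
    "<repeat_regression> %s ~ %s: slope %.4g, R^2 %.3f, p %.3g (n = %d)\n",
    x$response, x$predictor, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @method tidy repeat_regression
#' @export
tidy.repeat_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @method glance repeat_regression
#' @export
glance.repeat_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope,
         p.value = x$p_value, nobs = x$n)
}

#' Regression table over predictor/response combinations
#'
#' One OLS fit per predictor x response pair, mirroring a panel-wide
#' correlation table between repeat-content and assembly-quality
#' indicators.
#'
#' @param panel Data frame with all columns present.
#' @param predictors,responses Character vectors of column names.
#' @return Tibble: `predictor`, `response`, `slope`, `intercept`,
#'   `r_squared`, `p_value`.
#' @export
regress_panel <- function(panel,
                          predictors = c("n_repeats", "total_bp",
                                         "pct_total", "total_bp_gt300",
                                         "pct_gt300", "total_bp_gt700",
                                         "pct_gt700"),
                          responses = c("CN", "SN", "NB", "GCE")) {
  grid <- expand.grid(predictor = predictors, response = responses,
                      stringsAsFactors = FALSE)
  bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    r <- regress(panel, grid$predictor[i], grid$response[i])
    tibble(predictor = r$predictor, response = r$response,
           slope = r$slope, intercept = r$intercept,
           r_squared = r$r_squared, p_value = r$p_value)
  }))
}
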