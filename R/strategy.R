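#' Sequencing strategy specification
#'
#' A strategy combines single-end shotgun depth with paired-end depth at a
#' given read length and insert size, labelled in the
#' `"<se> x SE + <pe> x PE"` convention.
#'
#' @param se_depth,pe_depth Fold coverages; both >= 0, not both zero.
#' @param read_length Read length in bases (100, 200 or 400).
#' @param insert_mean,insert_sd Paired-end insert size in bases.
#' @return A `strategy_spec`.
#' @export
strategy_spec <- function(se_depth, pe_depth, read_length = 400,
                          insert_mean = 8000,
                          insert_sd = 0.1 * insert_mean) {
  if (se_depth < 0 || pe_depth < 0) abort("depths must be >= 0")
  if (se_depth == 0 && pe_depth == 0) {
    abort("at least one of `se_depth`, `pe_depth` must be positive")
  }
  structure(
    list(se_depth = se_depth, pe_depth = pe_depth,
         read_length = read_length, insert_mean = insert_mean,
         insert_sd = insert_sd,
         label = sprintf("%g × SE + %g × PE", se_depth, pe_depth)),
    class = "strategy_spec")
}

#' Parse a strategy label back into depths
#'
#' @param label A label of the form `"10 x SE + 10 x PE"`.
#' @return Named list `se_depth`, `pe_depth`.
#' @export
parse_strategy_label <- function(label) {
  m <- regmatches(label,
    regexec("^\\s*([0-9.]+)\\s*[x×]\\s*SE\\s*\\+\\s*([0-9.]+)\\s*[x×]\\s*PE\\s*$",
            label))[[1]]
  if (length(m) != 3) abort("unparseable strategy label")
  list(se_depth = as.numeric(m[2]), pe_depth = as.numeric(m[3]))
}

#' Run a sequencing strategy over a genome panel
#'
#' For each genome: simulate single-end shotgun reads at `se_depth` and a
#' paired-end library at `pe_depth`, merge them, assemble with the greedy
#' assembler, scaffold with the paired-end links, and evaluate against the
#' reference.  Per-genome seeds are derived by a stable hash of
#' `(seed, genome_id)`, so adding genomes never perturbs existing
#' results.  A failure in one genome is recorded and the run continues.
#'
#' @param panel List of `synth_genome` objects (or a single genome).
#' @param spec A [strategy_spec()].
#' @param model An [error_model()].
#' @param seed Integer run seed.
#' @param min_overlap,min_identity Assembler thresholds.
#' @param min_links Scaffolder link threshold.
#' @param branch_margin Assembler repeat-branch margin in bases.
#' @return Tibble with one row per genome: `genome_id`, the
#'   `quality_report` columns, and `error` (NA on success).
#' @export
run_strategy <- function(panel, spec, model = error_model(), seed = 1,
                         min_overlap = 40, min_identity = 0.97,
                         min_links = 3, branch_margin = 30) {
  if (inherits(panel, "synth_genome")) panel <- list(panel)
  if (length(panel) == 0) abort("empty panel")
  bind_rows(lapply(panel, function(g) {
    gseed <- stable_hash(seed, g$id)
    out <- tryCatch({
      rep <- run_strategy_one(g, spec, model, gseed,
                              min_overlap, min_identity, min_links,
                              branch_margin)
      rep$genome_id <- g$id
      rep$error <- NA_character_
      rep
    }, error = function(e) {
      tibble(strategy = spec$label, GCE = NA_real_, SBE = NA_real_,
             IDR = NA_real_, SBA = NA_real_, FLT = NA_real_,
             FDT = NA_real_, CN = NA_integer_, NB = NA_real_,
             SN = NA_integer_, genome_id = g$id,
             error = conditionMessage(e))
    })
    out
  }))
}

run_strategy_one <- function(genome, spec, model, gseed,
                             min_overlap, min_identity, min_links,
                             branch_margin) {
  sets <- list(); prefixes <- character()
  if (spec$se_depth > 0) {
    lib_se <- library_spec("se", read_length = spec$read_length,
                           depth = spec$se_depth)
    sets <- c(sets, list(simulate_shotgun(genome, lib_se, model,
                                          seed = gseed)))
    prefixes <- c(prefixes, "se_")
  }
  pe <- NULL
  if (spec$pe_depth > 0) {
    lib_pe <- library_spec("pe", read_length = spec$read_length,
                           depth = spec$pe_depth,
                           insert_mean = spec$insert_mean,
                           insert_sd = spec$insert_sd)
    pe <- simulate_paired(genome, lib_pe, model,
                          seed = (gseed + 1L) %% 2147483647L)
    sets <- c(sets, list(pe))
    prefixes <- c(prefixes, "pe_")
  }
  reads <- if (length(sets) == 1) sets[[1]] else
    do.call(merge_read_sets, c(sets, list(prefixes = prefixes)))
  asm <- greedy_assemble(reads, min_overlap = min_overlap,
                         min_identity = min_identity,
                         branch_margin = branch_margin)
  if (!is.null(pe)) {
    asm <- withCallingHandlers(
      scaffold(asm, pe, spec$insert_mean, spec$insert_sd,
               min_links = min_links),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  evaluate(asm, genome, strategy_label = spec$label)
}

#' Aggregate per-genome quality reports into a panel summary
#'
#' @param reports Stacked [run_strategy()] output (one or more
#'   strategies).
#' @param cn_threshold,sn_threshold Thresholds for the cumulative
#'   fractions (defaults 150 contigs and 10 scaffolds).
#' @return A `panel_summary`: list with `means` (per-strategy arithmetic
#'   means of every indicator, table-ordered) and `cumulative` (fraction
#'   of genomes with CN/SN strictly below the thresholds).
#' @export
aggregate_reports <- function(reports, cn_threshold = 150,
                              sn_threshold = 10) {
  if (nrow(reports) == 0) abort("no reports to aggregate")
  ok <- reports |> filter(is.na(.data$error) | !nzchar(.data$error))
  if (!"error" %in% names(reports)) ok <- reports
  if (nrow(ok) == 0) abort("all reports failed")
  means <- ok |>
    group_by(ST = .data$strategy) |>
    summarise(across(c("GCE", "SBE", "IDR", "FLT", "FDT",
                       "CN", "NB", "SN", "SBA"),
                     ~ mean(.x, na.rm = TRUE)),
              n_genomes = n(), .groups = "drop")
  cumulative <- ok |>
    group_by(ST = .data$strategy) |>
    summarise(
      frac_cn_below = mean(.data$CN < cn_threshold, na.rm = TRUE),
      frac_sn_below = mean(.data$SN < sn_threshold, na.rm = TRUE),
      .groups = "drop") |>
    mutate(cn_threshold = cn_threshold, sn_threshold = sn_threshold)
  structure(list(means = means, cumulative = cumulative),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>\n")
  print(x$means)
  print(x$cumulative)
  invisible(x)
}

#' Cumulative distribution of an indicator over a panel
#'
#' Fraction of genomes whose indicator is strictly below each threshold;
#' nondecreasing in the threshold.
#'
#' @param reports [run_strategy()] output.
#' @param metric Indicator column (e.g. `"CN"` or `"SN"`).
#' @param thresholds Numeric thresholds.
#' @return Tibble: `strategy`, `threshold`, `fraction`.
#' @export
cumulative_distribution <- function(reports, metric = "CN",
                                    thresholds = NULL) {
  if (is.null(thresholds)) {
    hi <- max(reports[[metric]], na.rm = TRUE)
    thresholds <- unique(round(seq(0, hi * 1.1 + 1, length.out = 25)))
  }
  reports |>
    group_by(strategy = .data$strategy) |>
    reframe(threshold = thresholds,
            fraction = vapply(thresholds, function(t)
              mean(.data[[metric]] < t, na.rm = TRUE), numeric(1)))
}

#' Write a panel summary to TSV
#'
#' @param summary A `panel_summary`.
#' @param means_path,cumulative_path Output paths (NULL to skip).
#' @export
write_panel_summary <- function(summary, means_path,
                                cumulative_path = NULL) {
  write.table(summary$means, means_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cumulative_path)) {
    write.table(summary$cumulative, cumulative_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(means_path)
}

#' Step plot of the cumulative CN/SN distribution
#'
#' @param reports [run_strategy()] output for one or more strategies.
#' @param metric `"CN"` or `"SN"`.
#' @return A ggplot object.
#' @export
plot_cumulative <- function(reports, metric = c("CN", "SN")) {
  metric <- match.arg(metric)
  cd <- cumulative_distribution(reports, metric)
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$threshold,
                                   y = 100 * .data$fraction,
                                   colour = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = sprintf("%s threshold", metric),
      y = "Cumulative % of genomes",
      colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot panel means per strategy
#'
#' @param object A `panel_summary`.
#' @param metric Indicator column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot panel_summary
#' @export
autoplot.panel_summary <- function(object, metric = "NB", ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(x = .data$ST, y = .data[[metric]],
                               group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Strategy", y = metric) +
    ggplot2::theme_minimal()
}
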