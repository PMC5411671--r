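# ---- descriptive statistics ------------------------------------------------

#' Wald binomial 95% confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- 1.96 sqrt(p(1-p)/n)`, both reported in
#' percent — the convention that reproduces every count cell of the study
#' summary tables. Display rounding is percentage to the nearest integer and
#' half-width to one decimal.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @return A list with `percent`, `half_width` (both unrounded, in percent)
#'   and `label` (`"k (p±hw%)"` after display rounding).
#' @export
#' @examples
#' binomial_wald_ci(148, 195)$label  # "148 (76±6.0%)"
binomial_wald_ci <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  hw <- 1.96 * sqrt(p * (1 - p) / n)
  list(percent = 100 * p, half_width = 100 * hw,
       label = sprintf("%d (%.0f±%.1f%%)", k, 100 * p, 100 * hw))
}

#' Median, quartiles and range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the package's documented quantile rule.
#'
#' @param values Non-empty numeric vector.
#' @return A named list: `median`, `q1`, `q3`, `min`, `max`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty value list")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       min = min(values), max = max(values))
}

# ---- cohort summary --------------------------------------------------------

#' One analysis configuration
#'
#' The four definitional configurations of the analysis matrix: CCL counting
#' rule (separate | cumulative) crossed with the Gleason heterogeneity
#' criterion (grades | score).
#'
#' @param ccl_mode `"separate"` or `"cumulative"`.
#' @param criterion `"grades"` or `"score"`.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(ccl_mode = c("separate", "cumulative"),
                            criterion = c("grades", "score")) {
  structure(list(ccl_mode = match.arg(ccl_mode),
                 criterion = match.arg(criterion)),
            class = "analysis_config")
}

#' All four analysis configurations
#' @return List of [analysis_config()]s in table column order.
#' @export
all_configs <- function() {
  list(analysis_config("separate", "grades"),
       analysis_config("separate", "score"),
       analysis_config("cumulative", "grades"),
       analysis_config("cumulative", "score"))
}

#' Summarise per-lesion reports for one analysis configuration
#'
#' Aggregates lesion reports (from [lesion_reports()] / [analyze_cohort()])
#' into the study-style summary: lesion counts by Gleason score, volume
#' median/IQR/range, homogeneous and heterogeneous counts, concordant and
#' discordant counts among heterogeneous lesions, discordant hotspot
#' distances, and the total concordance — each count with its Wald 95% CI.
#' Homogeneous lesions (under the configuration's criterion) are inherently
#' concordant; heterogeneous lesions use the hotspot-intersection result, so
#' the identity `total concordant = homogeneous + heterogeneous-concordant`
#' holds by construction and is asserted.
#'
#' @param reports Lesion-report tibble carrying a `ccl_mode` column (as
#'   returned by [analyze_cohort()]).
#' @param config An [analysis_config()].
#' @return A list of class `cohort_summary` with fields `config`, `n_lesions`,
#'   `score_counts` (tibble: score label, k, percent, half_width, label),
#'   `volume` (median_iqr list), `n_homogeneous`, `n_heterogeneous`,
#'   `n_het_concordant`, `n_het_discordant`, `n_concordant_total` (each count
#'   paired with a `*_ci` list), and `discordant_distance` (median_iqr list or
#'   `NULL`).
#' @export
summarize_cohort <- function(reports, config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!"ccl_mode" %in% names(reports))
    stop("reports lack the ccl_mode column")
  empty_input <- !nrow(reports)
  reports <- reports[reports$ccl_mode == config$ccl_mode, ]
  if (!nrow(reports)) {
    if (!empty_input)
      stop("no reports computed under ccl_mode = ", config$ccl_mode)
    # an all-benign cohort has no lesions in any configuration
    return(structure(list(config = config, n_lesions = 0L,
                          score_counts = tibble::tibble(), volume = NULL,
                          n_homogeneous = 0L, homogeneous_ci = NULL,
                          n_heterogeneous = 0L, heterogeneous_ci = NULL,
                          n_het_concordant = 0L, het_concordant_ci = NULL,
                          n_het_discordant = 0L, het_discordant_ci = NULL,
                          discordant_distance = NULL,
                          n_concordant_total = 0L, concordant_total_ci = NULL),
                     class = "cohort_summary"))
  }
  het <- if (config$criterion == "grades") reports$het_grades else
    reports$het_score
  concordant <- ifelse(het, reports$concordant, TRUE)
  n <- nrow(reports)
  score_counts <- reports |>
    dplyr::count(score = .data$score, name = "k") |>
    dplyr::arrange(gleason_rank(.data$score)) |>
    dplyr::mutate(
      label = gleason_label(.data$score),
      percent = vapply(.data$k, function(k) binomial_wald_ci(k, n)$percent, 0),
      half_width = vapply(.data$k, function(k)
        binomial_wald_ci(k, n)$half_width, 0),
      display = vapply(.data$k, function(k) binomial_wald_ci(k, n)$label, ""))
  n_hom <- sum(!het); n_het <- sum(het)
  n_het_conc <- sum(het & concordant); n_het_disc <- sum(het & !concordant)
  n_conc <- sum(concordant)
  stopifnot(n_hom + n_het == n, n_het_conc + n_het_disc == n_het,
            n_conc == n_hom + n_het_conc)
  dist <- reports$distance_mm[het & !concordant]
  structure(list(
    config = config,
    n_lesions = n,
    score_counts = score_counts,
    volume = median_iqr(reports$volume_ml),
    n_homogeneous = n_hom,
    homogeneous_ci = binomial_wald_ci(n_hom, n),
    n_heterogeneous = n_het,
    heterogeneous_ci = binomial_wald_ci(n_het, n),
    n_het_concordant = n_het_conc,
    het_concordant_ci = if (n_het) binomial_wald_ci(n_het_conc, n_het),
    n_het_discordant = n_het_disc,
    het_discordant_ci = if (n_het) binomial_wald_ci(n_het_disc, n_het),
    discordant_distance = if (length(dist)) median_iqr(dist),
    n_concordant_total = n_conc,
    concordant_total_ci = binomial_wald_ci(n_conc, n)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cfg <- sprintf("%s count / Gleason %s", x$config$ccl_mode,
                 x$config$criterion)
  cat("Analysis configuration:", cfg, "\n")
  cat(sprintf("  independent lesions: %d\n", x$n_lesions))
  if (x$n_lesions == 0L) return(invisible(x))
  for (i in seq_len(nrow(x$score_counts)))
    cat(sprintf("  Gleason %s: %s\n", x$score_counts$label[i],
                x$score_counts$display[i]))
  v <- x$volume
  cat(sprintf("  lesion volume ml: median %.3f (IQR %.3f-%.3f, range %.3f-%.3f)\n",
              v$median, v$q1, v$q3, v$min, v$max))
  cat(sprintf("  homogeneous: %s | heterogeneous: %s\n",
              x$homogeneous_ci$label, x$heterogeneous_ci$label))
  if (x$n_heterogeneous) {
    cat(sprintf("  heterogeneous concordant: %s | discordant: %s\n",
                x$het_concordant_ci$label, x$het_discordant_ci$label))
  }
  if (!is.null(x$discordant_distance)) {
    d <- x$discordant_distance
    cat(sprintf("  discordant hotspot distance mm: median %.1f (IQR %.1f-%.1f)\n",
                d$median, d$q1, d$q3))
  }
  cat(sprintf("  total concordant: %s\n", x$concordant_total_ci$label))
  invisible(x)
}

#' Tabulate summaries across configurations
#'
#' @param summaries List of `cohort_summary` objects (e.g. one per
#'   configuration of [all_configs()]).
#' @return A tibble with one row per summary and the headline quantities as
#'   columns.
#' @export
summary_table <- function(summaries) {
  dplyr::bind_rows(lapply(summaries, function(s) {
    tibble::tibble(
      ccl_mode = s$config$ccl_mode,
      criterion = s$config$criterion,
      n_lesions = s$n_lesions,
      volume_median_ml = if (s$n_lesions) s$volume$median else NA_real_,
      n_homogeneous = s$n_homogeneous,
      homogeneous_pct = if (s$n_lesions) s$homogeneous_ci$percent else NA_real_,
      n_heterogeneous = s$n_heterogeneous,
      n_het_concordant = s$n_het_concordant,
      n_het_discordant = s$n_het_discordant,
      het_discordant_pct = if (s$n_heterogeneous)
        s$het_discordant_ci$percent else NA_real_,
      discordant_distance_median_mm = if (!is.null(s$discordant_distance))
        s$discordant_distance$median else NA_real_,
      n_concordant_total = s$n_concordant_total,
      concordant_total_pct = if (s$n_lesions)
        s$concordant_total_ci$percent else NA_real_)
  }))
}
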