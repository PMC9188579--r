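#' Run the full multimorbidity-pattern pipeline
#'
#' Cohort construction (inclusion criteria, stratification, transaction
#' building), per-stratum FP-growth mining, cross-race pattern
#' classification per (age band, obesity class) cell, and the accompanying
#' statistics (exact binomial CIs, per-pattern g-tests, per-cell
#' Kruskal-Wallis BMI sensitivity tests, per-stratum BMI medians).
#'
#' @param demographics,diagnoses input tables, see [apply_inclusion()].
#' @param window study window.
#' @param filter a [chapter_filter()].
#' @param race_mapping see [map_race()].
#' @param race_list configured analysis races.
#' @param min_support support threshold xi (default 0.05).
#' @param min_size smallest itemset size reported as a pattern (default 2,
#'   the multimorbidity definition).
#' @param max_size optional itemset size cap (default `Inf`).
#' @param level confidence level for prevalence intervals.
#' @param drop_empty see [build_transactions()].
#' @return object of class `mm_run`: list with `profiles`, `exclusions`,
#'   `cohort`, `transaction_sets`, `patterns` (size >= `min_size`),
#'   `comparison`, `summary`, `g_tests`, `bmi_tests`, `bmi_medians`, and
#'   the effective settings.
#' @export
run_pipeline <- function(demographics, diagnoses,
                         window = study_window(),
                         filter = chapter_filter(),
                         race_mapping = default_race_mapping(),
                         race_list = default_race_list(),
                         min_support = 0.05, min_size = 2L, max_size = Inf,
                         level = 0.95, drop_empty = FALSE) {
  profiles <- apply_inclusion(demographics, diagnoses, window, race_mapping)
  profiles <- assign_stratum(profiles)
  exclusions <- exclusion_summary(profiles)
  if (!any(profiles$included))
    stop("empty cohort after inclusion filters; exclusion counts: ",
         paste(sprintf("%s=%d", exclusions$reason, exclusions$n_patients),
               collapse = ", "), call. = FALSE)
  ts <- build_transactions(profiles, diagnoses, filter, window, drop_empty)
  message(sprintf("cohort: %d included / %d total patients, %d strata",
                  sum(profiles$included), nrow(profiles), length(ts)))
  patterns_all <- mine_strata(ts, min_support = min_support, min_size = 1L,
                              max_size = max_size)
  patterns <- patterns_all[patterns_all$size >= min_size, , drop = FALSE]
  rownames(patterns) <- NULL
  comparison <- classify_patterns(patterns, ts, race_list = race_list,
                                  min_support = min_support, level = level)
  structure(list(
    profiles = profiles, exclusions = exclusions,
    cohort = cohort_summary(profiles),
    transaction_sets = ts, patterns = patterns,
    comparison = comparison, summary = count_summary(comparison),
    g_tests = pattern_g_tests(comparison),
    bmi_tests = bmi_kruskal_tests(profiles),
    bmi_medians = median_bmi_summary(profiles),
    min_support = min_support, min_size = min_size, level = level,
    race_list = race_list, window = window),
    class = "mm_run")
}

#' @export
print.mm_run <- function(x, ...) {
  cat(sprintf("Multimorbidity run: %d included patients, %d strata, xi = %g\n",
              sum(x$profiles$included), length(x$transaction_sets),
              x$min_support))
  cat(sprintf("%d multimorbidity patterns (size >= %d) across strata\n",
              nrow(x$patterns), x$min_size))
  if (nrow(x$comparison$patterns))
    print(table(cell = paste(x$comparison$patterns$age_band,
                             x$comparison$patterns$obesity_class),
                class = x$comparison$patterns$class_label))
  invisible(x)
}
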