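#' Classify multimorbidity patterns by cross-race sharing
#'
#' Within each (age band, obesity class) cell, every pattern frequent in at
#' least one race stratum is classified by the set of races in which it is
#' frequent: `shared_all` when frequent in every configured race,
#' `distinct` when frequent in exactly one, `shared_some` otherwise. The
#' three classes partition the cell's pattern union. For every configured
#' race -- frequent or not -- the pattern's support, prevalence and exact
#' binomial confidence interval are computed from that race's transactions
#' (the "gray sector" analogue: a race below threshold still has a
#' measured prevalence).
#'
#' @param patterns pattern data.frame with stratum columns, typically
#'   `filter_multimorbidity(mine_strata(...))`.
#' @param transaction_sets the named list from [build_transactions()] the
#'   patterns were mined from.
#' @param race_list configured race categories (classification is defined
#'   relative to this list).
#' @param min_support the support threshold the patterns were mined at.
#' @param level confidence level for the Clopper-Pearson intervals.
#' @return object of class `pattern_comparison`: a list with
#'   `$patterns` (one row per cell x pattern: `class_label`,
#'   `races_frequent` semicolon-joined, `n_races_frequent`,
#'   `max_prevalence`) and `$per_race` (one row per cell x pattern x race:
#'   `support_count`, `n`, `prevalence`, `ci_lower`, `ci_upper`,
#'   `frequent`).
#' @export
classify_patterns <- function(patterns, transaction_sets,
                              race_list = default_race_list(),
                              min_support = 0.05, level = 0.95) {
  if (!length(race_list)) stop("race_list must be non-empty", call. = FALSE)
  race_list <- sort(unique(race_list))
  strata <- lapply(transaction_sets, `[[`, "stratum")
  cells <- unique(data.frame(
    age_band = vapply(strata, `[[`, "", "age_band"),
    obesity_class = vapply(strata, `[[`, "", "obesity_class"),
    stringsAsFactors = FALSE))
  cells <- cells[order(cells$age_band, cells$obesity_class), , drop = FALSE]

  pat_rows <- list(); pr_rows <- list()
  for (ci in seq_len(nrow(cells))) {
    band <- cells$age_band[ci]; ob <- cells$obesity_class[ci]
    in_cell <- patterns$age_band == band & patterns$obesity_class == ob
    keys <- sort(unique(patterns$items[in_cell]))
    if (!length(keys)) next
    ts_by_race <- stats::setNames(vector("list", length(race_list)), race_list)
    for (ts in transaction_sets) {
      s <- ts$stratum
      if (s$age_band == band && s$obesity_class == ob &&
          s$race %in% race_list) ts_by_race[[s$race]] <- ts
    }
    for (k in keys) {
      items <- key_items(k)
      freq_in <- character(0)
      for (race in race_list) {
        ts <- ts_by_race[[race]]
        if (is.null(ts)) {
          sup <- 0L; n <- 0L; frq <- FALSE
        } else {
          sup <- count_support(items, ts$transactions)
          n <- ts$n_patients
          minc <- max(1L, as.integer(ceiling(min_support * n - 1e-9)))
          frq <- sup >= minc
        }
        ci_b <- if (n > 0) clopper_pearson(sup, n, level) else
          data.frame(point = NA_real_, lower = NA_real_, upper = NA_real_)
        pr_rows[[length(pr_rows) + 1L]] <- data.frame(
          age_band = band, obesity_class = ob, items = k, race = race,
          support_count = sup, n = n,
          prevalence = if (n > 0) sup / n else NA_real_,
          ci_lower = ci_b$lower, ci_upper = ci_b$upper,
          frequent = frq, stringsAsFactors = FALSE)
        if (frq) freq_in <- c(freq_in, race)
      }
      label <- if (setequal(freq_in, race_list)) "shared_all"
        else if (length(freq_in) == 1L) "distinct"
        else "shared_some"
      prev <- vapply(utils::tail(pr_rows, length(race_list)),
                     function(r) r$prevalence, numeric(1))
      pat_rows[[length(pat_rows) + 1L]] <- data.frame(
        age_band = band, obesity_class = ob, items = k,
        size = length(items), class_label = label,
        races_frequent = paste(freq_in, collapse = ";"),
        n_races_frequent = length(freq_in),
        max_prevalence = max(prev, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  empty_pat <- data.frame(age_band = character(0), obesity_class = character(0),
                          items = character(0), size = integer(0),
                          class_label = character(0),
                          races_frequent = character(0),
                          n_races_frequent = integer(0),
                          max_prevalence = numeric(0), stringsAsFactors = FALSE)
  empty_pr <- data.frame(age_band = character(0), obesity_class = character(0),
                         items = character(0), race = character(0),
                         support_count = integer(0), n = integer(0),
                         prevalence = numeric(0), ci_lower = numeric(0),
                         ci_upper = numeric(0), frequent = logical(0),
                         stringsAsFactors = FALSE)
  structure(list(
    patterns = if (length(pat_rows)) do.call(rbind, pat_rows) else empty_pat,
    per_race = if (length(pr_rows)) do.call(rbind, pr_rows) else empty_pr,
    race_list = race_list, min_support = min_support, level = level),
    class = "pattern_comparison")
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat(sprintf("Pattern comparison: %d patterns across %d cell(s), %d races\n",
              nrow(x$patterns),
              nrow(unique(x$patterns[c("age_band", "obesity_class")])),
              length(x$race_list)))
  print(table(x$patterns$class_label))
  invisible(x)
}

count_support <- function(items, transactions) {
  sum(vapply(transactions, function(t) all(items %in% t), logical(1)))
}

#' Per-race pattern counts (overall and distinct)
#'
#' Summary-table analogue: for each cell and race, the number of
#' multimorbidity patterns frequent in that race (`overall_count`) and the
#' number frequent in that race alone (`distinct_count`).
#'
#' @param comparison a [classify_patterns()] result.
#' @return data.frame with `age_band`, `obesity_class`, `race`,
#'   `overall_count`, `distinct_count`.
#' @export
count_summary <- function(comparison) {
  stopifnot(inherits(comparison, "pattern_comparison"))
  pr <- comparison$per_race
  pat <- comparison$patterns
  cells <- unique(pat[c("age_band", "obesity_class")])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    band <- cells$age_band[ci]; ob <- cells$obesity_class[ci]
    for (race in comparison$race_list) {
      sel <- pr$age_band == band & pr$obesity_class == ob & pr$race == race
      overall <- sum(pr$frequent[sel])
      dsel <- pat$age_band == band & pat$obesity_class == ob &
        pat$class_label == "distinct" & pat$races_frequent == race
      rows[[length(rows) + 1L]] <- data.frame(
        age_band = band, obesity_class = ob, race = race,
        overall_count = overall, distinct_count = sum(dsel),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(age_band = character(0), obesity_class = character(0),
               race = character(0), overall_count = integer(0),
               distinct_count = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Display-threshold filter for reporting
#'
#' Figures can become unreadable when a cell holds dozens of patterns, so
#' reports may keep only patterns whose maximum per-race prevalence meets a
#' display threshold. Purely presentational: classification is computed
#' before, and unaffected by, this filter.
#'
#' @param comparison a [classify_patterns()] result.
#' @param min_display_prevalence keep patterns with
#'   `max_prevalence >= min_display_prevalence` (default 0 = keep all).
#' @return a filtered `pattern_comparison`.
#' @export
report_filter <- function(comparison, min_display_prevalence = 0) {
  stopifnot(inherits(comparison, "pattern_comparison"))
  keep <- comparison$patterns$max_prevalence >= min_display_prevalence
  kept <- comparison$patterns[keep, , drop = FALSE]
  key <- paste(kept$age_band, kept$obesity_class, kept$items)
  pr <- comparison$per_race
  pr_keep <- paste(pr$age_band, pr$obesity_class, pr$items) %in% key
  out <- comparison
  out$patterns <- kept
  out$per_race <- pr[pr_keep, , drop = FALSE]
  rownames(out$patterns) <- rownames(out$per_race) <- NULL
  out
}
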