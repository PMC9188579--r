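#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact (tail-inversion) interval for a binomial proportion: the lower
#' bound is the largest p with `P(Bin(n, p) >= x) <= alpha/2` (0 when
#' x = 0) and the upper bound the smallest p with
#' `P(Bin(n, p) <= x) <= alpha/2` (1 when x = n), computed through the
#' equivalent Beta-quantile closed form. Coverage is conservative
#' (>= `level`) by construction.
#'
#' @param x number of successes (vectorized), `0 <= x <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return data.frame with `x`, `n`, `point`, `lower`, `upper`, `level`.
#' @examples
#' clopper_pearson(3, 5)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(n) == 1L) n <- rep(n, length(x))
  stopifnot(length(x) == length(n))
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  data.frame(x = x, n = n, point = x / n, lower = lower, upper = upper,
             level = level)
}

#' G-test (likelihood-ratio test) of independence
#'
#' `G = 2 * sum(O * ln(O / E))` over the cells of a contingency table,
#' with `0 * ln(0) = 0` and expected counts `E_ij = row_i * col_j / N`,
#' referred to the chi-square distribution on `(r - 1)(c - 1)` degrees of
#' freedom. Used here to compare a pattern's prevalence (present/absent
#' counts) across race groups. No correction is applied by default;
#' `williams = TRUE` divides G by the Williams correction factor.
#'
#' @param observed numeric matrix of non-negative counts (at least 2 x 2);
#'   no row or column margin may be zero.
#' @param williams apply the Williams small-sample correction.
#' @return object of class `htest` with `statistic` (G), `parameter`
#'   (df) and `p.value`.
#' @examples
#' g_test(rbind(c(10, 20), c(20, 10)))
#' @export
g_test <- function(observed, williams = FALSE) {
  o <- as.matrix(observed)
  if (nrow(o) < 2L || ncol(o) < 2L)
    stop("observed must be at least 2 x 2", call. = FALSE)
  if (any(is.na(o)) || any(o < 0))
    stop("observed must be non-negative counts", call. = FALSE)
  rs <- rowSums(o); cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  n <- sum(o)
  e <- outer(rs, cs) / n
  terms <- ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * sum(terms)
  if (williams) {
    q <- 1 + ((n * sum(1 / rs) - 1) * (n * sum(1 / cs) - 1)) /
      (6 * n * (nrow(o) - 1) * (ncol(o) - 1))
    g <- g / q
  }
  df <- (nrow(o) - 1) * (ncol(o) - 1)
  structure(list(
    statistic = c(G = g), parameter = c(df = df),
    p.value = stats::pchisq(g, df, lower.tail = FALSE),
    method = paste0("G-test of independence",
                    if (williams) " (Williams-corrected)"),
    data.name = deparse(substitute(observed))),
    class = "htest")
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Pools all observations, assigns mid-ranks, and computes
#' `H = 12 / (N (N + 1)) * sum(n_i * rbar_i^2) - 3 (N + 1)`, divided by the
#' tie-correction factor `C = 1 - sum(t^3 - t) / (N^3 - N)` (t = size of
#' each tie group); p-value from the chi-square distribution on `k - 1`
#' degrees of freedom. Used as the sensitivity analysis comparing median
#' BMI across race groups within each age/obesity cell.
#'
#' @param groups list of numeric vectors, one per group (k >= 2, each
#'   non-empty, not all values identical).
#' @return object of class `htest` with `statistic` (H), `parameter`
#'   (df) and `p.value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 numeric vectors", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (any(is.na(x))) stop("NA values not allowed", call. = FALSE)
  n <- length(x)
  if (length(unique(x)) == 1L)
    stop("all values identical: statistic undefined (C = 0)", call. = FALSE)
  r <- rank(x)                               # mid-ranks for ties
  g <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * rbar^2) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  df <- length(groups) - 1L
  structure(list(
    statistic = c(H = h), parameter = c(df = df),
    p.value = stats::pchisq(h, df, lower.tail = FALSE),
    method = "Kruskal-Wallis rank test (tie-corrected)",
    data.name = deparse(substitute(groups))),
    class = "htest")
}

#' Median BMI per stratum
#'
#' Median of the per-patient mean BMI within each occupied stratum
#' (even-length groups use the mean of the two middle values).
#'
#' @param profiles output of [assign_stratum()] (included patients used).
#' @param digits rounding for the reported median (default 1).
#' @return data.frame with `race`, `age_band`, `obesity_class`,
#'   `n_patients`, `median_bmi`.
#' @export
median_bmi_summary <- function(profiles, digits = 1) {
  inc <- profiles[profiles$included, , drop = FALSE]
  if (nrow(inc) == 0L) {
    warning("no included patients", call. = FALSE)
    return(data.frame(race = character(0), age_band = character(0),
                      obesity_class = character(0), n_patients = integer(0),
                      median_bmi = numeric(0)))
  }
  key <- interaction(inc$race, inc$age_band, inc$obesity_class,
                     sep = "|", drop = TRUE)
  med <- tapply(inc$mean_bmi, key, stats::median)
  parts <- do.call(rbind, strsplit(names(med), "|", fixed = TRUE))
  out <- data.frame(race = parts[, 1], age_band = parts[, 2],
                    obesity_class = parts[, 3],
                    n_patients = as.integer(table(key)[names(med)]),
                    median_bmi = round(as.numeric(med), digits),
                    stringsAsFactors = FALSE)
  out <- out[order(out$age_band, out$obesity_class, out$race), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pattern g-tests of prevalence across races
#'
#' For every classified pattern, builds the races x (present, absent)
#' contingency table from the full per-race counts (races below the
#' support threshold included) and runs [g_test()]. Races with zero
#' patients in the cell are dropped from the table.
#'
#' @param comparison a [classify_patterns()] result.
#' @param williams passed to [g_test()].
#' @param p_adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @return data.frame with one row per cell x pattern: `statistic`, `df`,
#'   `p_value` (and `p_adjusted` when requested), `n_races`.
#' @export
pattern_g_tests <- function(comparison, williams = FALSE, p_adjust = "none") {
  stopifnot(inherits(comparison, "pattern_comparison"))
  pat <- comparison$patterns
  pr <- comparison$per_race
  rows <- list()
  for (i in seq_len(nrow(pat))) {
    sel <- pr$age_band == pat$age_band[i] &
      pr$obesity_class == pat$obesity_class[i] & pr$items == pat$items[i] &
      pr$n > 0
    tab <- cbind(present = pr$support_count[sel],
                 absent = pr$n[sel] - pr$support_count[sel])
    res <- tryCatch(g_test(tab, williams = williams), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      age_band = pat$age_band[i], obesity_class = pat$obesity_class[i],
      items = pat$items[i],
      statistic = if (is.null(res)) NA_real_ else unname(res$statistic),
      df = if (is.null(res)) NA_integer_ else unname(res$parameter),
      p_value = if (is.null(res)) NA_real_ else res$p.value,
      n_races = sum(sel), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(age_band = character(0), obesity_class = character(0),
               items = character(0), statistic = numeric(0), df = integer(0),
               p_value = numeric(0), n_races = integer(0),
               stringsAsFactors = FALSE)
  if (p_adjust != "none") out$p_adjusted <- stats::p.adjust(out$p_value,
                                                            method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis BMI sensitivity analysis per cell
#'
#' Compares per-patient mean BMI across races within each (age band,
#' obesity class) cell, guarding against one race's BMI distribution
#' skewing its prevalence estimates within a weight class.
#'
#' @param profiles output of [assign_stratum()].
#' @return data.frame with one row per cell: `statistic`, `df`, `p_value`.
#' @export
bmi_kruskal_tests <- function(profiles) {
  inc <- profiles[profiles$included, , drop = FALSE]
  cells <- unique(inc[c("age_band", "obesity_class")])
  cells <- cells[order(cells$age_band, cells$obesity_class), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- inc$age_band == cells$age_band[i] &
      inc$obesity_class == cells$obesity_class[i]
    groups <- split(inc$mean_bmi[sel], inc$race[sel])
    groups <- groups[lengths(groups) > 0]
    res <- tryCatch(kruskal_wallis(groups), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      age_band = cells$age_band[i], obesity_class = cells$obesity_class[i],
      statistic = if (is.null(res)) NA_real_ else unname(res$statistic),
      df = if (is.null(res)) NA_integer_ else unname(res$parameter),
      p_value = if (is.null(res)) NA_real_ else res$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
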