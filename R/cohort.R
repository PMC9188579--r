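#' Final race/ethnicity categories used in the analysis
#'
#' @return character vector of the six analysis categories.
#' @export
default_race_list <- function() {
  c("African American", "Asian/Pacific Islander", "Biracial",
    "Caucasian", "Hispanic", "Native American")
}

#' Default source-label to analysis-category race mapping
#'
#' Asian, Pacific Islander and Asian/Pacific Islander are merged into a
#' single Asian/Pacific Islander category (the source labels cannot be
#' separated reliably). Missing labels, "Other" and "Mid-Eastern Indian"
#' map to `"excluded"`; the six final categories pass through unchanged.
#'
#' @return named character vector: `names()` are source labels, values are
#'   final categories or `"excluded"`.
#' @export
default_race_mapping <- function() {
  m <- c("Asian" = "Asian/Pacific Islander",
         "Pacific Islander" = "Asian/Pacific Islander",
         "Asian/Pacific Islander" = "Asian/Pacific Islander",
         "Other" = "excluded",
         "Mid-Eastern Indian" = "excluded")
  ids <- default_race_list()
  ids <- ids[ids != "Asian/Pacific Islander"]
  c(m, stats::setNames(ids, ids))
}

#' Map raw race/ethnicity labels to analysis categories
#'
#' @param race_raw character vector of source labels (may be empty/`NA`).
#' @param mapping named character vector, see [default_race_mapping()].
#' @param warn warn about unrecognized labels (default `TRUE`).
#' @return character vector of final categories; `"excluded"` for missing
#'   or deliberately dropped labels; `NA` (with a warning) for labels the
#'   mapping does not know.
#' @examples
#' map_race(c("Pacific Islander", "", "Caucasian"))
#' @export
map_race <- function(race_raw, mapping = default_race_mapping(), warn = TRUE) {
  x <- trimws(as.character(race_raw))
  out <- rep(NA_character_, length(x))
  missing_lab <- is.na(x) | x == ""
  out[missing_lab] <- "excluded"
  known <- !missing_lab & x %in% names(mapping)
  out[known] <- unname(mapping[x[known]])
  unknown <- !missing_lab & !known
  if (warn && any(unknown)) {
    warning(sprintf("unrecognized race label(s): %s",
                    paste(unique(x[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Study window constructor
#'
#' The analysis aggregates each patient's diagnoses over a fixed window
#' (default two calendar years, 2016-2017).
#'
#' @param start,end window bounds (inclusive), coercible to `Date`.
#' @return length-2 `Date` vector.
#' @export
study_window <- function(start = "2016-01-01", end = "2017-12-31") {
  w <- as.Date(c(start, end))
  if (any(is.na(w)) || w[1] > w[2]) stop("invalid study window", call. = FALSE)
  w
}

# tolerant code-system labels: "ICD10", "icd-10-cm", "ICD10CM" -> "ICD10"
norm_code_system <- function(x) {
  s <- toupper(gsub("[^A-Z0-9]", "", as.character(x)))
  out <- rep(NA_character_, length(s))
  out[grepl("^ICD10", s)] <- "ICD10"
  out[grepl("^ICD9", s)] <- "ICD9"
  out
}

#' Apply the cohort inclusion criteria
#'
#' A patient is included iff all of: (1) age 45+; (2) at least one valid
#' BMI measurement (18.5-206, inclusive); (3) an assigned race/ethnicity
#' after mapping; (4) at least one in-window ICD-10-CM diagnosis record;
#' and (5) no in-window ICD-9-CM record. Exclusion is a result, not an
#' error: every failed criterion is recorded (no short-circuiting), so the
#' exclusion cascade is auditable.
#'
#' @param demographics data.frame with columns `patient_id`, `race`, `age`
#'   and `bmi`; multiple rows per patient carry repeated BMI measurements.
#' @param diagnoses data.frame with columns `patient_id`, `encounter_id`,
#'   `date`, `code`, `code_system`.
#' @param window study window from [study_window()].
#' @param race_mapping see [map_race()].
#' @param min_age minimum age in years (default 45).
#' @param bmi_range inclusive validity bounds for a BMI measurement.
#' @return data.frame of patient profiles: one row per patient with
#'   `race_raw`, `race`, `age_years`, `n_bmi`, `n_bmi_valid`, `mean_bmi`
#'   (over valid measurements only), per-criterion flags, `included` and a
#'   semicolon-joined `reasons` string for excluded patients.
#' @export
apply_inclusion <- function(demographics, diagnoses,
                            window = study_window(),
                            race_mapping = default_race_mapping(),
                            min_age = 45, bmi_range = c(18.5, 206)) {
  need <- c("patient_id", "race", "age", "bmi")
  if (!all(need %in% names(demographics)))
    stop("demographics must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  pid <- as.character(demographics$patient_id)
  ids <- unique(pid)
  idx <- match(ids, pid)                      # first row per patient
  race_raw <- as.character(demographics$race)[idx]
  age <- as.integer(demographics$age)[idx]

  bmi <- as.numeric(demographics$bmi)
  valid <- !is.na(bmi) & bmi >= bmi_range[1] & bmi <= bmi_range[2]
  f <- factor(pid, levels = ids)
  n_bmi <- as.integer(tapply(!is.na(bmi), f, sum, default = 0L))
  n_bmi_valid <- as.integer(tapply(valid, f, sum, default = 0L))
  sum_valid <- as.numeric(tapply(ifelse(valid, bmi, 0), f, sum, default = 0))
  mean_bmi <- ifelse(n_bmi_valid > 0, sum_valid / n_bmi_valid, NA_real_)

  race <- map_race(race_raw, race_mapping)

  dx_date <- as.Date(diagnoses$date)
  in_win <- !is.na(dx_date) & dx_date >= window[1] & dx_date <= window[2]
  sys <- norm_code_system(diagnoses$code_system)
  dpid <- factor(as.character(diagnoses$patient_id), levels = ids)
  n_icd10 <- as.integer(tapply(in_win & sys == "ICD10", dpid, sum, default = 0L))
  n_icd10[is.na(n_icd10)] <- 0L
  n_icd9 <- as.integer(tapply(in_win & sys == "ICD9", dpid, sum, default = 0L))
  n_icd9[is.na(n_icd9)] <- 0L

  ok_age <- !is.na(age) & age >= min_age
  ok_bmi <- n_bmi_valid >= 1L
  ok_race <- !is.na(race) & race != "excluded"
  ok_dx <- n_icd10 >= 1L
  ok_icd9 <- n_icd9 == 0L

  reasons <- mapply(function(a, b, r, d, i9) {
    paste(c(if (!a) "age_under_45", if (!b) "no_valid_bmi",
            if (!r) "race_missing", if (!d) "no_icd10_dx",
            if (!i9) "icd9_present"), collapse = ";")
  }, ok_age, ok_bmi, ok_race, ok_dx, ok_icd9, USE.NAMES = FALSE)

  data.frame(patient_id = ids, race_raw = race_raw, race = race,
             age_years = age, n_bmi = n_bmi, n_bmi_valid = n_bmi_valid,
             mean_bmi = mean_bmi,
             n_icd10_window = n_icd10, n_icd9_window = n_icd9,
             included = ok_age & ok_bmi & ok_race & ok_dx & ok_icd9,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Per-reason exclusion counts
#'
#' @param profiles output of [apply_inclusion()].
#' @return data.frame with `reason` and `n_patients`; a patient failing
#'   several criteria contributes to each reason.
#' @export
exclusion_summary <- function(profiles) {
  r <- unlist(strsplit(profiles$reasons[!profiles$included], ";", fixed = TRUE))
  all_reasons <- c("age_under_45", "no_valid_bmi", "race_missing",
                   "no_icd10_dx", "icd9_present")
  tab <- table(factor(r, levels = all_reasons))
  data.frame(reason = names(tab), n_patients = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Assign each included patient to a (race, age band, obesity class) stratum
#'
#' Age bands: middle_aged for 45-64, elderly for 65+. Obesity class: mean
#' of valid BMI measurements >= 30 is with_obesity ("30+" is inclusive),
#' otherwise without_obesity.
#'
#' @param profiles output of [apply_inclusion()].
#' @return `profiles` with `age_band` and `obesity_class` columns (`NA`
#'   for excluded patients).
#' @export
assign_stratum <- function(profiles) {
  inc <- profiles$included
  profiles$age_band <- ifelse(inc,
    ifelse(profiles$age_years >= 65, "elderly", "middle_aged"), NA_character_)
  profiles$obesity_class <- ifelse(inc,
    ifelse(profiles$mean_bmi >= 30, "with_obesity", "without_obesity"),
    NA_character_)
  profiles
}

#' Transaction set constructor
#'
#' A transaction set is a stratum's patient-to-diagnosis-category mapping:
#' one deduplicated, sorted set of eligible 3-character categories per
#' patient, plus the stratum denominator. Patients whose in-window records
#' contain no eligible category still count in `n_patients` (empty
#' transaction): eligibility filtering narrows outcomes, not the cohort.
#'
#' @param transactions named list, patient id -> character vector of items.
#' @param n_patients denominator; defaults to `length(transactions)`.
#' @param stratum optional list with `race`, `age_band`, `obesity_class`.
#' @return object of class `transaction_set`.
#' @export
transaction_set <- function(transactions, n_patients = length(transactions),
                            stratum = NULL) {
  stopifnot(is.list(transactions), n_patients >= length(transactions))
  transactions <- lapply(transactions, function(t) sort(unique(as.character(t))))
  structure(list(transactions = transactions,
                 n_patients = as.integer(n_patients),
                 stratum = stratum),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  s <- x$stratum
  if (!is.null(s))
    cat(sprintf("Stratum %s / %s / %s\n", s$race, s$age_band, s$obesity_class))
  cat(sprintf("%d patients, %d with >=1 eligible category, %d distinct categories\n",
              x$n_patients, sum(lengths(x$transactions) > 0),
              length(unique(unlist(x$transactions)))))
  invisible(x)
}

#' Build per-stratum transaction sets from profiles and diagnosis records
#'
#' Aggregates each included patient's in-window ICD-10-CM records to the
#' set of eligible normalized categories, then partitions patients by
#' stratum.
#'
#' @param profiles output of [assign_stratum()].
#' @param diagnoses long-format diagnosis table (see [apply_inclusion()]).
#' @param filter a [chapter_filter()].
#' @param window study window.
#' @param drop_empty drop patients with zero eligible categories from the
#'   denominator (default `FALSE`: they stay in `n_patients`).
#' @return named list of [transaction_set()] objects, keyed
#'   `"race|age_band|obesity_class"`, in deterministic key order.
#' @export
build_transactions <- function(profiles, diagnoses,
                               filter = chapter_filter(),
                               window = study_window(),
                               drop_empty = FALSE) {
  inc <- profiles[profiles$included, , drop = FALSE]
  if (nrow(inc) == 0L) {
    warning("no patients pass the inclusion criteria", call. = FALSE)
    return(list())
  }
  dx_date <- as.Date(diagnoses$date)
  keep <- as.character(diagnoses$patient_id) %in% inc$patient_id &
    !is.na(dx_date) & dx_date >= window[1] & dx_date <= window[2] &
    norm_code_system(diagnoses$code_system) == "ICD10"
  keep[is.na(keep)] <- FALSE
  dx <- diagnoses[keep, , drop = FALSE]
  norm <- normalize_icd10(dx$code)
  elig <- !is.na(norm$category) & is_eligible(norm$category, filter)
  items_by_patient <- split(norm$category[elig],
                            factor(as.character(dx$patient_id)[elig],
                                   levels = inc$patient_id))

  key <- paste(inc$race, inc$age_band, inc$obesity_class, sep = "|")
  out <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    ids <- inc$patient_id[sel]
    trans <- lapply(items_by_patient[ids], function(t) sort(unique(t)))
    names(trans) <- ids
    if (drop_empty) trans <- trans[lengths(trans) > 0]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    out[[k]] <- transaction_set(
      trans,
      n_patients = if (drop_empty) length(trans) else sum(sel),
      stratum = list(race = parts[1], age_band = parts[2],
                     obesity_class = parts[3]))
  }
  out
}

#' Cohort composition summary
#'
#' One row per occupied stratum with patient count and the share of the
#' age-band cohort it represents (demographic-table analogue).
#'
#' @param profiles output of [assign_stratum()].
#' @return data.frame with `race`, `age_band`, `obesity_class`,
#'   `n_patients`, `pct_of_age_band`.
#' @export
cohort_summary <- function(profiles) {
  inc <- profiles[profiles$included, , drop = FALSE]
  if (nrow(inc) == 0L)
    return(data.frame(race = character(0), age_band = character(0),
                      obesity_class = character(0), n_patients = integer(0),
                      pct_of_age_band = numeric(0)))
  tab <- as.data.frame(table(race = inc$race, age_band = inc$age_band,
                             obesity_class = inc$obesity_class),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n_patients"
  tab <- tab[tab$n_patients > 0, , drop = FALSE]
  band_n <- tapply(inc$patient_id, inc$age_band, length)
  tab$pct_of_age_band <- 100 * tab$n_patients / as.numeric(band_n[tab$age_band])
  tab <- tab[order(tab$age_band, tab$obesity_class, tab$race), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
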