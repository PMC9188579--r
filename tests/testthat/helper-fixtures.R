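# Five patient diagnosis lists used as the canonical small mining example
# (minimum support 60% -> frequent: {I10}, {E78}, {I10,E78}).
worked_example <- function() {
  list(c("I10", "G47", "E78"),
       c("I10", "E78"),
       c("G47"),
       c("I10", "R06"),
       c("I10", "R06", "E78"))
}

# random transaction list over a small item universe
random_transactions <- function(n, n_items = 8, p = 0.35) {
  items <- paste0(LETTERS[seq_len(n_items)], "01")
  lapply(seq_len(n), function(i) items[stats::runif(n_items) < p])
}

# minimal demographics/diagnosis pair: one included patient per row spec
make_demo <- function(patient_id, race = "Caucasian", age = 50, bmi = 25) {
  data.frame(patient_id = patient_id, race = race, age = age, bmi = bmi,
             stringsAsFactors = FALSE)
}

make_dx <- function(patient_id, code, date = "2016-06-01",
                    code_system = "ICD10") {
  data.frame(patient_id = patient_id,
             encounter_id = paste0(patient_id, "-E1"),
             date = date, code = code, code_system = code_system,
             stringsAsFactors = FALSE)
}

# small-but-unequal synthetic cohort used by the faster end-to-end tests
small_synth_config <- function(...) {
  synth_config(
    stratum_sizes = c("Caucasian" = 400, "African American" = 300,
                      "Asian/Pacific Islander" = 250,
                      "Native American" = 220, "Hispanic" = 200,
                      "Biracial" = 150),
    n_invalid = c(age_under_45 = 7L, no_valid_bmi = 6L, race_missing = 5L,
                  no_icd10_dx = 4L, icd9_present = 3L),
    ...)
}

# independent Clopper-Pearson oracle: bisection on the exact binomial tails
cp_bisect <- function(x, n, level = 0.95, tol = 1e-11) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else {
    lo <- 0; hi <- x / n
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      # P(Bin(n, mid) >= x) <= alpha/2 keeps mid a valid lower bound
      if (stats::pbinom(x - 1, n, mid, lower.tail = FALSE) <= alpha / 2)
        lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  upper <- if (x == n) 1 else {
    lo <- x / n; hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (stats::pbinom(x, n, mid) <= alpha / 2) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  c(lower = lower, upper = upper)
}
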