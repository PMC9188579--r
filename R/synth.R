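#' Planted disease cluster specification
#'
#' A cluster is a set of 2-4 eligible categories activated jointly with
#' probability `q` in each patient of its target strata; each member item
#' also occurs independently at its background prevalence, so the expected
#' joint prevalence has the closed form `q' = q + (1 - q) * prod(p_i)`.
#'
#' @param items character vector of 2-4 categories (must pass the default
#'   chapter filter).
#' @param q activation probability in (0, 1).
#' @param races races the cluster is planted in.
#' @param design_class intended classification (`"shared_all"`,
#'   `"shared_some"` or `"distinct"`), used by [ledger_check()].
#' @param age_bands,obesity_classes cells the cluster is planted in
#'   (default: all).
#' @return a list of class `mm_cluster`.
#' @export
mm_cluster <- function(items, q, races, design_class,
                       age_bands = c("middle_aged", "elderly"),
                       obesity_classes = c("without_obesity", "with_obesity")) {
  items <- sort(unique(as.character(items)))
  if (length(items) < 2L || length(items) > 4L)
    stop("cluster must have 2-4 items", call. = FALSE)
  if (!all(is_eligible(items)))
    stop("cluster items must pass the default chapter filter", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  if (!design_class %in% c("shared_all", "shared_some", "distinct"))
    stop("unknown design_class", call. = FALSE)
  structure(list(items = items, q = q, races = races,
                 age_bands = age_bands, obesity_classes = obesity_classes,
                 design_class = design_class),
            class = "mm_cluster")
}

#' Expected joint prevalence of a planted cluster
#'
#' @param cluster an [mm_cluster()].
#' @param background named background prevalence vector.
#' @return `q + (1 - q) * prod(p_i)` over the cluster's items.
#' @export
cluster_expected_prevalence <- function(cluster, background) {
  p <- background[cluster$items]
  p[is.na(p)] <- 0
  cluster$q + (1 - cluster$q) * prod(p)
}

default_background <- function() {
  c(# cluster-member items are kept rare in the background so planted
    # sharing labels are unambiguous
    E78 = 0.02, I10 = 0.02, E11 = 0.02, N18 = 0.02, F17 = 0.02, J44 = 0.02,
    # common chronic categories at plausible stand-alone prevalences
    G47 = 0.10, K21 = 0.10, M54 = 0.12, M25 = 0.08, I25 = 0.06, E03 = 0.05,
    F32 = 0.06, F41 = 0.07, J45 = 0.05, N39 = 0.04, K57 = 0.03, M19 = 0.06,
    I48 = 0.04, E87 = 0.03, D64 = 0.05, G62 = 0.02, I50 = 0.04)
}

default_clusters <- function() {
  all_races <- default_race_list()
  list(
    mm_cluster(c("E78", "I10"), q = 0.30, races = all_races,
               design_class = "shared_all"),
    mm_cluster(c("E11", "N18"), q = 0.25,
               races = c("African American", "Native American"),
               design_class = "shared_some"),
    mm_cluster(c("F17", "J44"), q = 0.20, races = "African American",
               design_class = "distinct"))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the qualitative shape of a large US EHR warehouse
#' cohort: six race/ethnicity groups with strongly unequal sizes
#' (Caucasian-dominant), two age bands, two obesity classes, BMI
#' distributions centred near the observed class medians (about 25.5
#' without obesity, 34 with), an average of seven encounters per patient
#' over a two-year window, and a small block of deliberately invalid
#' records exercising each exclusion criterion.
#'
#' @param stratum_sizes named integer vector: patients per (race, age
#'   band, obesity class) stratum for each race.
#' @param background named numeric vector of per-item background
#'   prevalences (shared across strata).
#' @param clusters list of [mm_cluster()] plantings.
#' @param bmi list with `without_obesity`/`with_obesity` location-scale
#'   pairs; draws are truncated to keep each patient's mean on the correct
#'   side of 30 and inside the 18.5-206 validity range.
#' @param encounter_mean mean encounters per patient (shifted Poisson).
#' @param n_bmi_range range of repeated BMI measurements per patient.
#' @param subcode_prob probability a diagnosis is emitted with a dotted
#'   sub-code suffix (exercises code normalization).
#' @param n_invalid named counts of planted patients violating exactly one
#'   inclusion criterion each.
#' @param window study window.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(
    stratum_sizes = c("Caucasian" = 4000, "African American" = 2500,
                      "Asian/Pacific Islander" = 1500,
                      "Native American" = 1200, "Hispanic" = 1000,
                      "Biracial" = 800),
    background = default_background(),
    clusters = default_clusters(),
    bmi = list(without_obesity = c(location = 25.5, scale = 2.5),
               with_obesity = c(location = 34, scale = 3)),
    encounter_mean = 7,
    n_bmi_range = c(1L, 3L),
    subcode_prob = 0.5,
    n_invalid = c(age_under_45 = 25L, no_valid_bmi = 25L, race_missing = 25L,
                  no_icd10_dx = 25L, icd9_present = 25L),
    window = study_window()) {
  if (any(background < 0 | background > 1))
    stop("background prevalences must be in [0, 1]", call. = FALSE)
  if (any(stratum_sizes < 1)) stop("stratum sizes must be >= 1", call. = FALSE)
  if (is.null(names(stratum_sizes)))
    stop("stratum_sizes must be named by race", call. = FALSE)
  for (cl in clusters) {
    stopifnot(inherits(cl, "mm_cluster"))
    if (!all(cl$races %in% names(stratum_sizes)))
      stop("cluster targets a race without a stratum size", call. = FALSE)
  }
  structure(list(stratum_sizes = stratum_sizes, background = background,
                 clusters = clusters, bmi = bmi,
                 encounter_mean = encounter_mean,
                 n_bmi_range = as.integer(n_bmi_range),
                 subcode_prob = subcode_prob,
                 n_invalid = n_invalid, window = window),
            class = "synth_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic EHR-style dataset with known planted structure
#'
#' Produces the demographics and diagnosis tables the cohort builder
#' reads, plus a ground-truth ledger recording stratum sizes, planted
#' cluster prevalences and per-reason invalid-record counts, so every
#' downstream stage can be verified against the generating process. Fully
#' reproducible: the same `config` and `seed` give identical tables.
#'
#' Every valid patient receives one ineligible Z00 (general examination)
#' record, so all of them satisfy the diagnosis-presence inclusion
#' criterion and each stratum's analysis denominator equals its configured
#' size exactly.
#'
#' @param config a [synth_config()].
#' @param seed integer RNG seed.
#' @return list with `demographics` (patient_id, race, age, bmi; repeated
#'   rows carry repeated BMI measurements), `diagnoses` (patient_id,
#'   encounter_id, date, code, code_system) and `ledger`.
#' @export
generate_ehr <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  window <- config$window
  ndays <- as.integer(window[2] - window[1]) + 1L
  bg <- config$background
  items <- names(bg)
  races <- names(config$stratum_sizes)
  grid <- expand.grid(race = races,
                      age_band = c("middle_aged", "elderly"),
                      obesity_class = c("without_obesity", "with_obesity"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$race, grid$age_band, grid$obesity_class), ]
  grid$n <- as.integer(config$stratum_sizes[grid$race])

  demo_list <- list(); dx_list <- list()
  pid_next <- 1L
  for (si in seq_len(nrow(grid))) {
    n <- grid$n[si]
    race <- grid$race[si]; band <- grid$age_band[si]; ob <- grid$obesity_class[si]
    pid <- sprintf("P%07d", pid_next:(pid_next + n - 1L)); pid_next <- pid_next + n
    age <- if (band == "middle_aged") sample(45:64, n, replace = TRUE) else
      sample(65:95, n, replace = TRUE)
    bp <- config$bmi[[ob]]
    bmi <- if (ob == "with_obesity")
      rtruncnorm(n, bp[["location"]], bp[["scale"]], 30, 206) else
      rtruncnorm(n, bp[["location"]], bp[["scale"]], 18.5, 29.9)
    race_raw <- if (race == "Asian/Pacific Islander")
      sample(c("Asian", "Pacific Islander", "Asian/Pacific Islander"), n,
             replace = TRUE) else rep(race, n)

    # item incidence: background Bernoulli, then planted clusters
    mat <- matrix(stats::runif(n * length(items)) < rep(bg, each = n),
                  nrow = n, dimnames = list(NULL, items))
    for (cl in config$clusters) {
      if (race %in% cl$races && band %in% cl$age_bands &&
          ob %in% cl$obesity_classes) {
        active <- stats::runif(n) < cl$q
        mat[active, cl$items] <- TRUE
      }
    }

    # demographics: 1-3 identical BMI measurements per patient
    n_meas <- sample(config$n_bmi_range[1]:config$n_bmi_range[2], n,
                     replace = TRUE)
    demo_list[[si]] <- data.frame(
      patient_id = rep(pid, n_meas), race = rep(race_raw, n_meas),
      age = rep(age, n_meas), bmi = round(rep(bmi, n_meas), 1),
      stringsAsFactors = FALSE)

    # encounters: shifted Poisson count, uniform in-window dates
    n_enc <- 1L + stats::rpois(n, max(0, config$encounter_mean - 1))
    enc_offset <- cumsum(c(0L, n_enc[-n]))
    enc_dates <- window[1] + sample.int(ndays, sum(n_enc), replace = TRUE) - 1L

    hit <- which(mat, arr.ind = TRUE)
    pat_i <- c(seq_len(n), hit[, 1])             # Z00 row for everyone
    code <- c(rep("Z00", n), items[hit[, 2]])
    sub <- stats::runif(length(code)) < config$subcode_prob
    code[sub] <- paste0(code[sub], ".",
                        sample(0:9, sum(sub), replace = TRUE))
    enc_k <- 1L + floor(stats::runif(length(pat_i)) * n_enc[pat_i])
    enc_global <- enc_offset[pat_i] + enc_k
    dx_list[[si]] <- data.frame(
      patient_id = pid[pat_i],
      encounter_id = paste0(pid[pat_i], "-E", enc_k),
      date = as.character(enc_dates[enc_global]),
      code = code, code_system = "ICD10", stringsAsFactors = FALSE)
  }

  # planted-invalid patients: each violates exactly one criterion
  inv <- invalid_block(config, window)
  demographics <- rbind(do.call(rbind, demo_list), inv$demographics)
  diagnoses <- rbind(do.call(rbind, dx_list), inv$diagnoses)
  rownames(demographics) <- rownames(diagnoses) <- NULL

  ledger <- list(
    seed = seed,
    strata = grid,
    n_valid = sum(grid$n),
    clusters = lapply(config$clusters, function(cl) {
      list(items = cl$items, q = cl$q,
           expected_prevalence = cluster_expected_prevalence(cl, bg),
           races = cl$races, age_bands = cl$age_bands,
           obesity_classes = cl$obesity_classes,
           design_class = cl$design_class)
    }),
    exclusions = as.list(config$n_invalid))
  list(demographics = demographics, diagnoses = diagnoses, ledger = ledger)
}

invalid_block <- function(config, window) {
  ninv <- config$n_invalid
  reasons <- names(ninv)
  demo <- list(); dx <- list()
  k <- 0L
  for (r in reasons) {
    n <- as.integer(ninv[[r]])
    if (n == 0L) next
    pid <- sprintf("X%05d", (k + 1L):(k + n)); k <- k + n
    age <- sample(45:80, n, replace = TRUE)
    race <- rep("Caucasian", n)
    bmi <- round(rtruncnorm(n, 26, 3, 18.5, 40), 1)
    if (r == "age_under_45") age <- sample(18:44, n, replace = TRUE)
    if (r == "no_valid_bmi") bmi <- sample(c(210, 230, 15, 10), n, replace = TRUE)
    if (r == "race_missing")
      race <- sample(c("", "Other", "Mid-Eastern Indian"), n, replace = TRUE)
    demo[[r]] <- data.frame(patient_id = pid, race = race, age = age,
                            bmi = bmi, stringsAsFactors = FALSE)
    if (r != "no_icd10_dx") {
      d <- as.character(window[1] +
                          sample.int(as.integer(window[2] - window[1]) + 1L,
                                     n, replace = TRUE) - 1L)
      dx[[r]] <- data.frame(patient_id = pid,
                            encounter_id = paste0(pid, "-E1"),
                            date = d, code = "I10.0", code_system = "ICD10",
                            stringsAsFactors = FALSE)
      if (r == "icd9_present") {
        dx[[paste0(r, "_9")]] <- data.frame(
          patient_id = pid, encounter_id = paste0(pid, "-E1"), date = d,
          code = "401.9", code_system = "ICD9", stringsAsFactors = FALSE)
      }
    }
  }
  list(demographics = do.call(rbind, demo) %||%
         data.frame(patient_id = character(0), race = character(0),
                    age = integer(0), bmi = numeric(0)),
       diagnoses = do.call(rbind, dx) %||%
         data.frame(patient_id = character(0), encounter_id = character(0),
                    date = character(0), code = character(0),
                    code_system = character(0)))
}

#' Verify a pipeline run against the generator's ground-truth ledger
#'
#' Checks that (a) per-reason exclusion counts equal the planted counts
#' exactly; (b) every stratum's analysis denominator equals its configured
#' size; (c) each planted cluster whose expected prevalence q' clears the
#' support threshold with margin (q' >= xi + 3 sqrt(q'(1-q')/n)) was mined
#' in each of its target strata; and (d) each cluster's intended sharing
#' class matches the classification output in each target cell.
#'
#' @param ledger the ledger from [generate_ehr()].
#' @param run an `mm_run` from [run_pipeline()] on the generated tables.
#' @return list with `pass` (logical) and `checks` (data.frame of every
#'   individual check with its outcome).
#' @export
ledger_check <- function(ledger, run) {
  checks <- list()
  add <- function(check, detail, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, detail = detail, pass = pass, stringsAsFactors = FALSE)

  excl <- run$exclusions
  for (r in names(ledger$exclusions)) {
    got <- excl$n_patients[excl$reason == r]
    got <- if (length(got)) got else 0L
    add("exclusion_count", r, identical(as.integer(got),
                                        as.integer(ledger$exclusions[[r]])))
  }
  for (i in seq_len(nrow(ledger$strata))) {
    s <- ledger$strata[i, ]
    key <- paste(s$race, s$age_band, s$obesity_class, sep = "|")
    ts <- run$transaction_sets[[key]]
    add("stratum_size", key,
        !is.null(ts) && ts$n_patients == s$n)
  }
  xi <- run$min_support
  for (cl in ledger$clusters) {
    qp <- cl$expected_prevalence
    key <- items_key(cl$items)
    for (race in cl$races) for (band in cl$age_bands)
      for (ob in cl$obesity_classes) {
        skey <- paste(race, band, ob, sep = "|")
        ts <- run$transaction_sets[[skey]]
        if (is.null(ts)) { add("cluster_mined", paste(key, skey), FALSE); next }
        margin_ok <- qp >= xi + 3 * sqrt(qp * (1 - qp) / ts$n_patients)
        if (!margin_ok) next                 # planting too close to call
        hit <- any(run$patterns$items == key & run$patterns$race == race &
                     run$patterns$age_band == band &
                     run$patterns$obesity_class == ob)
        add("cluster_mined", paste(key, skey), hit)
      }
    for (band in cl$age_bands) for (ob in cl$obesity_classes) {
      row <- run$comparison$patterns
      sel <- row$items == key & row$age_band == band & row$obesity_class == ob
      add("design_class", paste(key, band, ob, cl$design_class),
          sum(sel) == 1L && row$class_label[sel] == cl$design_class)
    }
  }
  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL
  list(pass = all(checks$pass), checks = checks)
}
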