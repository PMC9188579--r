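test_that("generation is deterministic given the seed", {
  cfg <- small_synth_config()
  a <- generate_ehr(cfg, seed = 12)
  b <- generate_ehr(cfg, seed = 12)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_identical(a$ledger, b$ledger)
  c <- generate_ehr(cfg, seed = 13)
  expect_false(identical(a$diagnoses, c$diagnoses))
})

test_that("stratum sizes in the demographics match the config exactly", {
  cfg <- small_synth_config()
  dat <- generate_ehr(cfg, seed = 4)
  prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
  inc <- prof[prof$included, ]
  tab <- table(inc$race, inc$age_band, inc$obesity_class)
  for (r in names(cfg$stratum_sizes)) {
    expect_equal(unname(tab[r, "middle_aged", "with_obesity"]),
                 unname(cfg$stratum_sizes[[r]]))
    expect_equal(unname(tab[r, "elderly", "without_obesity"]),
                 unname(cfg$stratum_sizes[[r]]))
  }
  # invalid plantings are all excluded, each for its planted reason
  excl <- exclusion_summary(prof)
  for (r in excl$reason)
    expect_equal(excl$n_patients[excl$reason == r],
                 as.integer(cfg$n_invalid[[r]]))
})

test_that("a forced cluster (q = 1, no noise) reaches prevalence 1", {
  cfg <- synth_config(
    stratum_sizes = c("Caucasian" = 50, "African American" = 50),
    background = c(E78 = 0, I10 = 0, M54 = 0),
    clusters = list(mm_cluster(c("E78", "I10"), q = 0.999,
                               races = c("Caucasian", "African American"),
                               design_class = "shared_all")),
    n_invalid = c(age_under_45 = 0L, no_valid_bmi = 0L, race_missing = 0L,
                  no_icd10_dx = 0L, icd9_present = 0L))
  # q must be < 1 by the invariant; emulate the forced case by overriding
  cfg$clusters[[1]]$q <- 1
  dat <- generate_ehr(cfg, seed = 9)
  prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
  ts <- build_transactions(prof, dat$diagnoses)
  for (s in ts) {
    pats <- mine_frequent_itemsets(s, min_support = 0.05)
    expect_equal(pats$prevalence[pats$items == "E78;I10"], 1)
  }
})

test_that("mined cluster prevalence concentrates on the closed-form q'", {
  q <- 0.3; p_bg <- 0.05
  cfg <- synth_config(
    stratum_sizes = c("Caucasian" = 2000),
    background = c(E78 = p_bg, I10 = p_bg),
    clusters = list(mm_cluster(c("E78", "I10"), q = q, races = "Caucasian",
                               design_class = "distinct")),
    n_invalid = c(age_under_45 = 0L, no_valid_bmi = 0L, race_missing = 0L,
                  no_icd10_dx = 0L, icd9_present = 0L))
  qp <- q + (1 - q) * p_bg^2
  expect_equal(cluster_expected_prevalence(cfg$clusters[[1]],
                                           cfg$background), qp)
  dat <- generate_ehr(cfg, seed = 15)
  prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
  ts <- build_transactions(prof, dat$diagnoses)
  se <- sqrt(qp * (1 - qp) / 2000)
  for (s in ts) {
    pats <- mine_frequent_itemsets(s, min_support = 0.05)
    got <- pats$prevalence[pats$items == "E78;I10"]
    expect_lt(abs(got - qp), 3 * se)
  }
})

test_that("mined prevalence is unbiased for q' across seeds", {
  q <- 0.25; p_bg <- 0.04
  cfg <- synth_config(
    stratum_sizes = c("Caucasian" = 400),
    background = c(E11 = p_bg, N18 = p_bg),
    clusters = list(mm_cluster(c("E11", "N18"), q = q, races = "Caucasian",
                               design_class = "distinct")),
    n_invalid = c(age_under_45 = 0L, no_valid_bmi = 0L, race_missing = 0L,
                  no_icd10_dx = 0L, icd9_present = 0L))
  qp <- q + (1 - q) * p_bg^2
  prev <- vapply(1:20, function(seed) {
    dat <- generate_ehr(cfg, seed = seed)
    prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
    ts <- build_transactions(prof, dat$diagnoses)
    mean(vapply(ts, function(s) {
      hits <- vapply(s$transactions,
                     function(t) all(c("E11", "N18") %in% t), logical(1))
      sum(hits) / s$n_patients
    }, numeric(1)))
  }, numeric(1))
  # Monte-Carlo tolerance: 3 standard errors of the mean over 20 x 4 strata
  se_mean <- sqrt(qp * (1 - qp) / (400 * 4)) / sqrt(20)
  expect_lt(abs(mean(prev) - qp), 3 * se_mean)
})

test_that("sparse noise alone yields no patterns at a high threshold", {
  cfg <- synth_config(
    stratum_sizes = c("Caucasian" = 300),
    background = c(E78 = 0.1, I10 = 0.1, M54 = 0.1, K21 = 0.1),
    clusters = list(),
    n_invalid = c(age_under_45 = 0L, no_valid_bmi = 0L, race_missing = 0L,
                  no_icd10_dx = 0L, icd9_present = 0L))
  dat <- generate_ehr(cfg, seed = 33)
  prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
  ts <- build_transactions(prof, dat$diagnoses)
  for (s in ts) {
    pats <- filter_multimorbidity(mine_frequent_itemsets(s, 0.5))
    expect_equal(nrow(pats), 0L)
  }
})

test_that("BMI draws respect obesity class and validity bounds", {
  dat <- generate_ehr(small_synth_config(), seed = 18)
  prof <- assign_stratum(apply_inclusion(dat$demographics, dat$diagnoses))
  inc <- prof[prof$included, ]
  expect_true(all(inc$mean_bmi[inc$obesity_class == "with_obesity"] >= 30))
  expect_true(all(inc$mean_bmi[inc$obesity_class == "without_obesity"] < 30))
  med <- median_bmi_summary(prof)
  expect_true(all(abs(med$median_bmi[med$obesity_class == "with_obesity"] -
                        34) < 3))
  expect_true(all(abs(med$median_bmi[med$obesity_class == "without_obesity"] -
                        25.5) < 3))
})

test_that("invalid configurations are refused before generation", {
  expect_error(synth_config(background = c(E11 = 1.5)), "prevalences")
  expect_error(synth_config(stratum_sizes = c(Caucasian = 0)), ">= 1")
  expect_error(mm_cluster("E11", 0.5, "Caucasian", "distinct"), "2-4 items")
  expect_error(mm_cluster(c("Z51", "Z52"), 0.5, "Caucasian", "distinct"),
               "chapter filter")
  expect_error(mm_cluster(c("E11", "I10"), 1.2, "Caucasian", "distinct"),
               "q must")
  expect_error(synth_config(clusters = list(
    mm_cluster(c("E11", "I10"), 0.5, "Atlantean", "distinct"))),
    "without a stratum size")
})

test_that("ledger_check verifies a faithful run and flags a broken one", {
  dat <- generate_ehr(small_synth_config(), seed = 6)
  run <- run_pipeline(dat$demographics, dat$diagnoses)
  chk <- ledger_check(dat$ledger, run)
  expect_true(chk$pass)
  expect_true(all(chk$checks$pass))
  # sabotage: claim a cluster was planted with a different sharing class
  bad <- dat$ledger
  bad$clusters[[1]]$design_class <- "distinct"
  chk2 <- ledger_check(bad, run)
  expect_false(chk2$pass)
  expect_true(any(!chk2$checks$pass[chk2$checks$check == "design_class"]))
})
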