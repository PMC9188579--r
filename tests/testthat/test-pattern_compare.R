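# build one (elderly, with_obesity) cell with three races and hand-chosen
# transactions so the sharing classes are forced by construction
cell_fixture <- function() {
  mk <- function(race, trans) {
    names(trans) <- paste0(substr(race, 1, 2), seq_along(trans))
    transaction_set(trans, stratum = list(race = race, age_band = "elderly",
                                          obesity_class = "with_obesity"))
  }
  both <- c("E11", "I10")
  ts <- list(
    mk("African American", c(rep(list(both), 8),
                             rep(list(c("F17", "J44")), 5),
                             rep(list(character(0)), 7))),   # n = 20
    mk("Caucasian", c(rep(list(both), 6),
                      rep(list("E11"), 5),
                      rep(list(character(0)), 9))),          # n = 20
    mk("Hispanic", c(rep(list(both), 5),
                     rep(list(character(0)), 15))))          # n = 20
  names(ts) <- vapply(ts, function(s)
    paste(s$stratum$race, s$stratum$age_band, s$stratum$obesity_class,
          sep = "|"), "")
  ts
}

races3 <- c("African American", "Caucasian", "Hispanic")

test_that("patterns partition into shared_all / shared_some / distinct", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = races3, min_support = 0.25)
  lab <- setNames(cmp$patterns$class_label, cmp$patterns$items)
  # E11;I10 frequent at 8/20, 6/20, 5/20 >= 0.25 in all three races
  expect_equal(lab[["E11;I10"]], "shared_all")
  # F17;J44 frequent only in African American
  expect_equal(lab[["F17;J44"]], "distinct")
  expect_equal(cmp$patterns$races_frequent[cmp$patterns$items == "F17;J44"],
               "African American")
  # classes partition the union of patterns
  expect_equal(sort(unique(pats$items)), sort(cmp$patterns$items))
  expect_false(any(duplicated(cmp$patterns$items)))
})

test_that("a pattern frequent in two of three races is shared_some", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = races3, min_support = 0.25)
  # tighten the threshold so Hispanic (5/20 = 0.25) drops below it
  cmp2 <- classify_patterns(pats, ts, race_list = races3, min_support = 0.27)
  row <- cmp2$patterns[cmp2$patterns$items == "E11;I10", ]
  expect_equal(row$class_label, "shared_some")
  expect_equal(row$races_frequent, "African American;Caucasian")
  expect_equal(cmp$patterns$class_label[cmp$patterns$items == "E11;I10"],
               "shared_all")
})

test_that("non-frequent races still get full counts and CIs (gray sectors)", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = races3, min_support = 0.25)
  pr <- cmp$per_race[cmp$per_race$items == "F17;J44", ]
  expect_equal(nrow(pr), 3L)                     # every configured race
  hisp <- pr[pr$race == "Hispanic", ]
  expect_false(hisp$frequent)
  expect_equal(hisp$support_count, 0L)
  expect_equal(hisp$n, 20L)
  expect_equal(hisp$ci_lower, 0)                 # x = 0 boundary
  expect_true(all(pr$ci_lower <= pr$prevalence | pr$support_count == 0))
  expect_true(all(pr$ci_upper >= pr$prevalence))
})

test_that("adding a race with no data demotes shared_all to shared_some", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = c(races3, "Biracial"),
                           min_support = 0.25)
  expect_false(any(cmp$patterns$class_label == "shared_all"))
  expect_equal(cmp$patterns$class_label[cmp$patterns$items == "E11;I10"],
               "shared_some")
})

test_that("count_summary reports overall and distinct per race", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = races3, min_support = 0.25)
  cs <- count_summary(cmp)
  g <- function(race, col) cs[cs$race == race, col]
  expect_equal(g("African American", "overall_count"), 2L)
  expect_equal(g("African American", "distinct_count"), 1L)
  expect_equal(g("Caucasian", "overall_count"), 1L)
  expect_equal(g("Caucasian", "distinct_count"), 0L)
  expect_true(all(cs$distinct_count <= cs$overall_count))
  # partition arithmetic: distinct counts sum to distinct-class patterns
  expect_equal(sum(cs$distinct_count),
               sum(cmp$patterns$class_label == "distinct"))
})

test_that("report_filter is presentation-only and matches a direct scan", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  cmp <- classify_patterns(pats, ts, race_list = races3, min_support = 0.25)
  expect_equal(report_filter(cmp, 0)$patterns, cmp$patterns)
  expect_equal(nrow(report_filter(cmp, 1.01)$patterns), 0L)
  thr <- 0.26
  kept <- report_filter(cmp, thr)
  # direct scan oracle over the per-race prevalences
  expected <- unique(cmp$per_race$items[
    ave(cmp$per_race$prevalence, cmp$per_race$items, FUN = max) >= thr])
  expect_setequal(kept$patterns$items, expected)
  # classification labels unchanged by filtering
  expect_equal(kept$patterns$class_label,
               cmp$patterns$class_label[cmp$patterns$items %in% expected])
})

test_that("an empty race list is refused", {
  ts <- cell_fixture()
  pats <- filter_multimorbidity(mine_strata(ts, min_support = 0.25))
  expect_error(classify_patterns(pats, ts, race_list = character(0)),
               "non-empty")
})
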