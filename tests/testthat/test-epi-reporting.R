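rules <- attr_ruleset()

test_that("prevalence scales, rounds and guards its denominator", {
  expect_equal(prevalence(213, 860, 100), 24.8)
  expect_equal(prevalence(203, 938385, 1e5), 21.6)
  expect_equal(prevalence(0, 50, 100), 0)
  expect_equal(prevalence(213, 477, 100, digits = 2), 44.65)
  # scale equivariance
  expect_equal(prevalence(7, 20, 1000, digits = NULL),
               10 * prevalence(7, 20, 100, digits = NULL))
  expect_error(prevalence(1, 0), "positive")
})

test_that("classification table counts, percentages and totals reconcile", {
  asg <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    cohort = "hattr",
    label = c(rep("reference", 4), rep("potential", 5), "out_of_cohort"),
    index_date = as.Date("2016-06-01"),
    age_at_index = 60, entry_year = c(2015, 2015, 2016, 2016, 2015, 2016,
                                      2016, 2017, 2017, NA),
    sex = "M", state = "SP")
  like <- tibble::tibble(patient_id = sprintf("P%02d", 5:9),
                         cohort = "hattr",
                         class = c("like", "like", "non", "non", "non"))
  ct <- classification_table(asg, like)
  tot <- ct[ct$year == "Total", ]
  expect_equal(sum(tot$n), 9)
  expect_equal(tot$n[tot$label == "reference"], 4)
  expect_equal(tot$n[tot$label == "like"], 2)
  expect_equal(tot$n[tot$label == "non"], 3)
  # percentages recompute from counts within rounding
  expect_true(all(abs(tot$pct - 100 * tot$n / sum(tot$n)) <= 0.01))
  # per-year columns sum to the cohort-year totals
  y2015 <- ct[ct$year == "2015", ]
  expect_equal(sum(y2015$n), 3)
  # single-label column is 100%
  y2017 <- ct[ct$year == "2017", ]
  expect_equal(y2017$pct, 100)
})

test_that("classification totals equal the cascade partition counts", {
  sim <- simulate_claims(noiseless_config(n_patients = 700, seed = 61))
  j <- oracle_journeys(sim)
  asg <- build_cohorts(j, rules)
  pot <- asg[asg$label == "potential", ]
  like <- tibble::tibble(patient_id = pot$patient_id, cohort = pot$cohort,
                         class = rep_len(c("like", "non"), nrow(pot)))
  ct <- classification_table(asg, like)
  for (cohort in unique(asg$cohort)) {
    tot <- ct[ct$cohort == cohort & ct$year == "Total", ]
    expect_equal(sum(tot$n),
                 sum(asg$cohort == cohort &
                       asg$label %in% c("reference", "potential")))
  }
})

test_that("demographics summarise age and sex per group", {
  asg <- tibble::tibble(
    patient_id = c("A", "B", "C"), cohort = "hattr",
    label = "reference", final_label = "reference",
    index_date = as.Date("2016-01-01"),
    age_at_index = c(60, 66, 70), entry_year = 2016,
    sex = c("F", "M", "M"), state = c("SP", "SP", "MG"))
  d <- demographics_summary(asg)
  tot <- d$age[d$age$group == "Total", ]
  expect_equal(tot$median, 66)
  expect_equal(tot$mean, mean(c(60, 66, 70)))
  expect_equal(tot$q1, unname(quantile(c(60, 66, 70), 0.25)))
  ag <- d$age_groups[d$age_groups$group == "Total", ]
  expect_equal(sum(ag$pct), 100, tolerance = 0.1 / 100)
  expect_equal(as.character(ag$age_bin[ag$n == 2]), "60 to 69 years")
  sx <- d$sex[d$sex$group == "Total", ]
  expect_equal(sx$n[sx$sex == "M"], 2)
})

test_that("hospitalization rate scales with its denominator", {
  j <- make_journey("H1", icds = "I50.0",
                    dates = c("2016-03-01", "2016-08-01", "2017-01-01"))
  r <- annual_hospitalization_rate(j, 1e5, 2016, rules)
  expect_equal(r$rate_per_100k, 2)
  expect_equal(annual_hospitalization_rate(j, 2e5, 2016, rules)$rate_per_100k, 1)
  expect_equal(annual_hospitalization_rate(j, 1e5, 2019, rules)$rate_per_100k, 0)
  # outpatient and out-of-list claims do not count
  j2 <- j
  j2$setting <- "outpatient"
  expect_equal(annual_hospitalization_rate(j2, 1e5, 2016, rules)$rate_per_100k, 0)
  expect_error(annual_hospitalization_rate(j, 0, 2016, rules), "positive")
})

test_that("follow-up spans and PPPY behave at the boundaries", {
  j <- make_journey("F1", icds = c("E85.3", "J18.9", "J18.9"),
                    dates = c("2015-01-01", "2014-06-01", "2016-01-01"))
  fu <- follow_up(j, rules, "wtattr")
  # starts at first qualifying claim, ends at last claim of any kind
  expect_equal(fu$fup_start, as.Date("2015-01-01"))
  expect_equal(fu$fup_end, as.Date("2016-01-01"))
  expect_equal(fu$fup_years, 1.0, tolerance = 0.01)

  single <- make_journey("F2", icds = "E85.3", dates = "2016-01-01")
  expect_equal(follow_up(single, rules, "wtattr")$fup_years, 0)

  none <- make_journey("F3", icds = "J18.9", dates = "2016-01-01")
  expect_equal(nrow(follow_up(none, rules, "wtattr")), 0)

  expect_equal(pppy(4, 2), 2)
  expect_equal(pppy(0, 3.5), 0)
  expect_equal(pppy(3, 1.5), 2)
  expect_true(is.na(pppy(5, 0)))
})

test_that("resource utilization matches hand arithmetic on a 3-patient fixture", {
  taf <- "06.04.54.006-0"; echo <- "02.05.01.003-2"
  j <- dplyr::bind_rows(
    # A: 2 admissions (LOS 3+5), 1 outpatient visit, tafamidis once, 2y fup
    make_journey("A", icds = c("E85.3", "I50.0", "I50.0"),
                 dates = c("2015-01-01", "2016-01-01", "2017-01-01"),
                 procedures = c(NA, taf, echo),
                 setting = c("inpatient", "inpatient", "outpatient"),
                 dob = "1950-01-01"),
    # B: 1 admission, 1y fup
    make_journey("B", icds = c("I50.0", "I50.9"),
                 dates = c("2016-01-01", "2017-01-01"),
                 setting = c("inpatient", "outpatient"), dob = "1948-01-01"),
    # C: zero follow-up (single claim)
    make_journey("C", icds = "I50.0", dates = "2016-06-01",
                 dob = "1945-01-01"))
  j$length_of_stay[j$record_id == "A-01"] <- 3L
  j$length_of_stay[j$record_id == "A-02"] <- 5L
  j$length_of_stay[j$record_id == "B-01"] <- 4L
  j$length_of_stay[j$record_id == "C-01"] <- 7L
  asg <- tibble::tibble(patient_id = c("A", "B", "C"), cohort = "wtattr",
                        label = c("reference", "potential", "potential"),
                        final_label = c("reference", "like", "like"),
                        index_date = as.Date("2015-01-01"),
                        age_at_index = 65, entry_year = 2015, sex = "M",
                        state = "SP")
  hc <- hcru_summary(asg, j, rules)
  adm <- hc$metrics[hc$metrics$group == "Total" &
                      hc$metrics$metric == "n_admissions", ]
  expect_equal(adm$total, 4)            # 2 + 1 + 1
  expect_equal(adm$mean, 4 / 3)
  expect_equal(adm$median, 1)
  # PPPY: A = 2 adm / ~2 y; B = 1 / ~1 y; C excluded (zero fup).
  # Calendar spans are a shade over the Julian year, hence the tolerance.
  expect_equal(adm$median_pppy, 1, tolerance = 0.005)
  expect_equal(adm$n_zero_fup, 1)
  los <- hc$metrics[hc$metrics$group == "Total" &
                      hc$metrics$metric == "total_los", ]
  expect_equal(los$total, 3 + 5 + 4 + 7)
  fl <- hc$flags[hc$flags$group == "Total", ]
  expect_equal(fl$n_tafamidis, 1)
  expect_equal(fl$pct_tafamidis, round(100 / 3, 2))
  expect_equal(fl$n_heart_transplant, 0)
  expect_equal(fl$n_patients_with_admission, 3)
})

test_that("top procedures rank by unique patients with deterministic ties", {
  echo <- "02.05.01.003-2"; ecg <- "02.11.02.003-6"
  j <- dplyr::bind_rows(
    make_journey("A", icds = "I50.0", dates = sprintf("2016-0%d-01", 1:5),
                 procedures = c(echo, echo, echo, echo, echo)),
    make_journey("B", icds = "I50.0", dates = c("2016-01-01", "2016-02-01"),
                 procedures = c(echo, ecg)),
    make_journey("C", icds = "I50.0", dates = "2016-01-01",
                 procedures = ecg))
  asg <- tibble::tibble(patient_id = c("A", "B", "C"), cohort = "wtattr",
                        label = "potential", final_label = "like",
                        index_date = as.Date("2016-01-01"), age_at_index = 60,
                        entry_year = 2016, sex = "M", state = "SP")
  tp <- top_procedures(asg, j, n = 5)
  tot <- tp[tp$group == "Total", ]
  # echo: patients A and B (A's five claims count once); ecg: B and C
  expect_equal(tot$n_patients, c(2, 2))
  # tie broken by code order: 02051... before 02110...
  expect_equal(tot$procedure[1], gsub("[.-]", "", echo))
  expect_equal(tot$share, c(round(200 / 3, 2), round(200 / 3, 2)))
})
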