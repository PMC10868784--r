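rules <- attr_ruleset()

test_that("exclusion diagnoses remove whole journeys", {
  excl <- make_journey("E1", icds = c("C90.0", "I50.0"),
                       dates = c("2016-01-01", "2016-06-01"))
  kept <- make_journey("K1", icds = "I50.0",
                       dates = c("2016-01-01", "2016-06-01"))
  res <- apply_exclusions(dplyr::bind_rows(excl, kept), rules)
  expect_setequal(unique(res$excluded$patient_id), "E1")
  expect_setequal(unique(res$kept$patient_id), "K1")
  expect_equal(nrow(res$kept) + nrow(res$excluded), 4)

  # dot-insensitivity: C900 is the same code
  excl2 <- make_journey("E2", icds = "C900", dates = "2016-01-01")
  expect_equal(unique(apply_exclusions(excl2, rules)$excluded$patient_id), "E2")
})

test_that("quality filter rejects negative ages and >=50% missingness", {
  neg <- make_journey("N1", icds = "I50.0", dates = "2016-01-01",
                      dob = "2017-01-01")
  ok <- make_journey("OK", icds = "I50.0", dates = "2016-01-01")
  res <- quality_filter(dplyr::bind_rows(neg, ok))
  expect_setequal(unique(res$quality_rejected$patient_id), "N1")

  # 6 of 11 tracked fields missing (54.5%) -> rejected
  m6 <- make_claim("M6", "I50.0", "2016-01-01",
                   patient_key = NA, sex = NA, state = NA,
                   municipality = NA, zip = NA, procedure = NA,
                   length_of_stay = 2L)
  expect_equal(sum(is.na(m6[, c("patient_key", "dob", "sex", "state",
                                "municipality", "zip", "claim_date",
                                "setting", "icd10", "procedure",
                                "length_of_stay")])), 6)
  # 5 of 11 missing (45.5%) -> kept
  m5 <- make_claim("M5", "I50.0", "2016-01-01",
                   patient_key = NA, sex = NA, state = NA,
                   municipality = NA, zip = NA, procedure = "02.11.02.003-6",
                   length_of_stay = 2L)
  res2 <- quality_filter(dplyr::bind_rows(m6, m5))
  expect_setequal(unique(res2$quality_rejected$patient_id), "M6")
  expect_setequal(unique(res2$kept$patient_id), "M5")
})

test_that("index date is the earliest cohort-qualifying claim", {
  j <- make_journey("P", icds = c("E85.1", "E85.0"),
                    dates = c("2016-03-01", "2015-06-01"))
  expect_equal(compute_index_date(j, "hattr", rules), as.Date("2015-06-01"))

  single <- make_journey("P", icds = "E85.0", dates = "2018-07-04")
  expect_equal(compute_index_date(single, "hattr", rules),
               as.Date("2018-07-04"))

  # wt cohort: cardiac-related codes qualify, so the earlier I50.0 wins
  wt <- make_journey("P", icds = c("E85.3", "I50.0"),
                     dates = c("2018-01-01", "2016-01-01"))
  expect_equal(compute_index_date(wt, "wtattr", rules), as.Date("2016-01-01"))
  # but not for the hereditary cohort
  expect_true(is.na(compute_index_date(wt, "hattr", rules)))
})

test_that("age at index uses the Julian year and the study bins", {
  expect_equal(compute_age_at_index("1950-01-01", "2015-01-01"), 65.0,
               tolerance = 0.01 / 65)
  expect_equal(compute_age_at_index("2014-12-31", "2015-01-01"),
               1 / 365.25, tolerance = 1e-10)
  expect_error(compute_age_at_index("2015-01-01", "2015-01-01"),
               "inconsistent")
  expect_equal(as.character(age_group(66.8)), "60 to 69 years")
  expect_equal(as.character(age_group(c(18, 29.9, 80, 95))),
               c("18 to 29 years", "18 to 29 years", ">= 80 years",
                 ">= 80 years"))
})

test_that("reference and potential rules match their clause definitions", {
  # 66 y, hattr code + required cardiac code -> reference
  r1 <- make_journey("R1", icds = c("E85.0", "I50.0"),
                     dates = c("2016-01-01", "2016-06-01"), dob = "1950-01-01")
  expect_true(label_reference(r1, "hattr", rules))

  # 17 y at index: age gate fails
  r2 <- make_journey("R2", icds = c("E85.1", "I50.0"),
                     dates = c("2016-01-01", "2016-06-01"), dob = "1999-06-01")
  expect_false(label_reference(r2, "hattr", rules))

  # G56.0 is cardiac-related but not in the required sub-list
  r3 <- make_journey("R3", icds = c("E85.3", "G56.0"),
                     dates = c("2016-01-01", "2016-06-01"), dob = "1946-01-01")
  expect_false(label_reference(r3, "wtattr", rules))

  # wt route (a): cardiac-related + secondary + mandatory procedures
  echo <- "02.05.01.003-2"; scint <- "02.08.05.002-7"
  p1 <- make_journey("P1", icds = "I50.0",
                     dates = c("2016-01-01", "2016-02-01", "2016-03-01"),
                     procedures = c(NA, scint, echo), dob = "1960-01-01")
  expect_true(label_potential(p1, "wtattr", rules))

  # echo only: route (a) misses its mandatory procedure
  p2 <- make_journey("P2", icds = "I50.0",
                     dates = c("2016-01-01", "2016-02-01"),
                     procedures = c(NA, echo), dob = "1960-01-01")
  expect_false(label_potential(p2, "wtattr", rules))

  # hereditary route: amyloid code + one secondary procedure suffices at 40 y
  p3 <- make_journey("P3", icds = "E85.1",
                     dates = c("2016-01-01", "2016-02-01"),
                     procedures = c(NA, echo), dob = "1976-01-01")
  expect_true(label_potential(p3, "hattr", rules))
})

test_that("the cascade hand-traces on a six-branch fixture", {
  echo <- "02.05.01.003-2"; scint <- "02.08.05.002-7"
  fixture <- dplyr::bind_rows(
    make_journey("ref", icds = c("E85.0", "I50.0"),
                 dates = c("2016-01-01", "2016-06-01"), dob = "1950-01-01"),
    make_journey("pot", icds = "E85.1", dates = c("2016-01-01", "2016-02-01"),
                 procedures = c(NA, echo), dob = "1950-01-01"),
    make_journey("ooc", icds = "E85.2", dates = "2016-01-01",
                 dob = "1950-01-01"),
    make_journey("excl", icds = c("E85.0", "C90.0"),
                 dates = c("2016-01-01", "2016-02-01"), dob = "1950-01-01"),
    make_journey("qrej", icds = "E85.0", dates = "2016-01-01",
                 dob = "2017-01-01"),
    make_journey("nonq", icds = "J18.9", dates = "2016-01-01",
                 dob = "1950-01-01"))
  asg <- build_cohorts(fixture, rules)
  h <- asg[asg$cohort == "hattr", ]
  got <- setNames(h$label, h$patient_id)
  expect_equal(got[c("ref", "pot", "ooc", "excl", "qrej")],
               c(ref = "reference", pot = "potential", ooc = "out_of_cohort",
                 excl = "excluded", qrej = "quality_rejected"))
  expect_false("nonq" %in% h$patient_id)

  # index date present iff reference/potential; entry year matches
  expect_true(all(!is.na(h$index_date[h$label %in% c("reference", "potential")])))
  expect_true(all(is.na(h$index_date[!h$label %in% c("reference", "potential")])))
  expect_equal(h$entry_year[h$patient_id == "ref"], 2016)
})

test_that("cascade labels agree with the brute-force clause evaluator", {
  journeys <- random_rule_journeys(400, rules, seed = 97)
  claims <- dplyr::bind_rows(journeys)
  asg <- build_cohorts(claims, rules)
  for (cohort in c("hattr", "wtattr")) {
    sub <- asg[asg$cohort == cohort, ]
    got <- setNames(sub$label, sub$patient_id)
    for (j in journeys) {
      pid <- j$patient_id[1]
      want <- oracle_cascade(j, cohort, rules)
      if (is.na(want)) {
        expect_false(pid %in% names(got))
      } else {
        expect_equal(unname(got[pid]), want,
                     label = sprintf("%s/%s", pid, cohort))
      }
    }
    # single-journey operations agree with the cascade on kept journeys
    kept <- sub$patient_id[!sub$label %in% c("excluded", "quality_rejected")]
    for (j in journeys[vapply(journeys, function(x) x$patient_id[1] %in% kept,
                              logical(1))][1:50]) {
      ref <- label_reference(j, cohort, rules)
      pot <- !ref && label_potential(j, cohort, rules)
      lab <- got[j$patient_id[1]]
      expect_equal(unname(lab == "reference"), ref)
      expect_equal(unname(lab == "potential"), pot)
    }
  }
})

test_that("cascade partition and precedence invariants hold on synthetic data", {
  sim <- simulate_claims(noiseless_config(n_patients = 600, seed = 43))
  j <- oracle_journeys(sim)
  asg <- build_cohorts(j, rules)
  # one label per (patient, cohort)
  expect_equal(anyDuplicated(asg[, c("patient_id", "cohort")]), 0L)
  expect_true(all(asg$label %in% c("excluded", "quality_rejected", "reference",
                                   "potential", "out_of_cohort")))
  # determinism
  asg2 <- build_cohorts(j, rules)
  expect_identical(asg, asg2)

  # enlarging the exclusion list never increases the reference count
  wider <- attr_ruleset(exclusion_icds = c(rules$exclusion_icds, "I48.0"))
  asg3 <- build_cohorts(j, wider)
  expect_lte(sum(asg3$label == "reference"), sum(asg$label == "reference"))
})
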