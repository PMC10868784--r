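rules <- attr_ruleset()

test_that("feature encoding counts codes over the fixed vocabularies", {
  echo <- "02.05.01.003-2"
  j <- make_journey("F1",
                    icds = c("I50.0", "I50.0", "E85.1", "ZZZ9"),
                    dates = c("2015-01-01", "2016-01-01", "2016-06-01",
                              "2017-01-01"),
                    procedures = c(NA, echo, "09.99.99.999-9", NA),
                    dob = "1950-01-01")
  j$setting <- c("inpatient", "outpatient", "outpatient", "inpatient")
  j$length_of_stay <- c(4L, NA, NA, 2L)
  f <- build_features(j, rules)
  expect_equal(f$icd_I500, 2)
  expect_equal(f$icd_E851, 1)
  expect_equal(f[[paste0("proc_", gsub("[.-]", "", echo))]], 1)
  expect_equal(f$n_hospitalizations, 2)
  expect_equal(f$n_outpatient_visits, 2)
  expect_equal(f$total_length_of_stay, 6)
  expect_equal(f$age_at_index, as.numeric(as.Date("2015-01-01") -
                                            as.Date("1950-01-01")) / 365.25)
  # out-of-vocabulary codes contribute to no code feature
  code_cols <- grep("^(icd|proc)_", names(f), value = TRUE)
  expect_equal(sum(as.matrix(f[, code_cols])), 4)

  # a journey with no in-vocabulary codes has all-zero code features
  bg <- make_journey("F2", icds = "J18.9", dates = "2016-01-01")
  f2 <- build_features(bg, rules)
  expect_equal(sum(as.matrix(f2[, code_cols])), 0)
})

test_that("the stratified split is exact, disjoint and reproducible", {
  data <- tibble::tibble(patient_id = sprintf("P%03d", 1:100),
                         x = rnorm(100),
                         y = factor(rep(c("0", "1"), c(70, 30))))
  parts <- split_dataset(data, split_spec(seed = 5))
  expect_equal(vapply(parts, nrow, numeric(1)),
               c(train = 60, validation = 20, test = 20))
  ids <- unlist(lapply(parts, `[[`, "patient_id"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_setequal(ids, data$patient_id)
  # stratification: class shares preserved
  expect_equal(sum(parts$train$y == "1"), 18)
  expect_identical(split_dataset(data, split_spec(seed = 5)), parts)

  # degenerate labels and tiny inputs are errors
  expect_error(split_dataset(data[1:5, ], split_spec()), "at least 10")
  one <- data
  one$y <- factor("1", levels = c("0", "1"))
  expect_error(split_dataset(one, split_spec()), "single class")
  rare <- data
  rare$y <- factor(rep(c("0", "1"), c(99, 1)))
  expect_error(split_dataset(rare, split_spec(seed = 5)), "stratification")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(9)
  for (i in 1:500) {
    m <- as.list(sample(0:40, 4, replace = TRUE))
    names(m) <- c("tp", "fn", "tn", "fp")
    pm <- performance_metrics(m$tp, m$fn, m$tn, m$fp)
    total <- m$tp + m$fn + m$tn + m$fp
    if (total > 0) expect_equal(pm$accuracy, (m$tp + m$tn) / total)
    if (m$tp + m$fn > 0) expect_equal(pm$sensitivity, m$tp / (m$tp + m$fn))
    else expect_true(is.na(pm$sensitivity))
    if (m$tn + m$fp > 0) expect_equal(pm$specificity, m$tn / (m$tn + m$fp))
    else expect_true(is.na(pm$specificity))
  }
  # zero-denominator sensitivity is signalled as NA, never 0 or 1
  expect_true(is.na(performance_metrics(0, 0, 10, 5)$sensitivity))
})

test_that("a known confusion matrix reproduces its printed metrics", {
  pm <- performance_metrics(tp = 41, fn = 2, tn = 40, fp = 13)
  expect_equal(round(100 * pm$sensitivity, 2), 95.35)
  expect_equal(round(100 * pm$specificity, 2), 75.47)
  expect_equal(round(100 * pm$accuracy, 2), 84.38)
})

make_separable <- function(n, seed) {
  set.seed(seed)
  y <- rep(c("0", "1"), each = n / 2)
  tibble::tibble(
    patient_id = sprintf("S%03d", seq_len(n)),
    f1 = ifelse(y == "1", 5, -5) + rnorm(n, sd = 0.1),
    f2 = rnorm(n),
    y = factor(y))
}

test_that("model selection finds a separable signal and is deterministic", {
  data <- make_separable(120, seed = 21)
  parts <- split_dataset(data, split_spec(seed = 3))
  m1 <- select_model(parts$train, parts$validation, split_spec(seed = 3))
  expect_equal(m1$selection_report[[m1$family]]$validation_accuracy, 1)
  pm <- evaluate_model(m1, parts$test)
  expect_equal(pm$accuracy, 1)
  expect_equal(pm$sensitivity, 1)
  expect_equal(pm$specificity, 1)

  m2 <- select_model(parts$train, parts$validation, split_spec(seed = 3))
  expect_equal(m1$family, m2$family)

  # single-class training labels are a training error
  degenerate <- parts$train
  degenerate$y <- factor("1", levels = c("0", "1"))
  expect_error(select_model(degenerate, parts$validation, split_spec(seed = 3)),
               "single class")
  expect_error(evaluate_model(m1, parts$test[0, ]), "empty")
})

test_that("permuted labels drive validation accuracy to the majority rate", {
  set.seed(33)
  n <- 150
  data <- tibble::tibble(
    patient_id = sprintf("N%03d", seq_len(n)),
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
    y = factor(sample(rep(c("0", "1"), c(90, 60)))))
  parts <- split_dataset(data, split_spec(seed = 13))
  m <- select_model(parts$train, parts$validation, split_spec(seed = 13),
                    candidates = "logistic")
  maj <- 90 / 150
  n_val <- nrow(parts$validation)
  se <- sqrt(maj * (1 - maj) / n_val)
  acc <- m$selection_report$logistic$validation_accuracy
  expect_lt(abs(acc - maj), 3 * se)
})

test_that("classify_potential labels every patient and checks dimensions", {
  data <- make_separable(120, seed = 22)
  parts <- split_dataset(data, split_spec(seed = 4))
  m <- select_model(parts$train, parts$validation, split_spec(seed = 4))

  pool <- make_separable(40, seed = 23)
  labs <- classify_potential(m, pool[, c("patient_id", "f1", "f2")])
  expect_equal(nrow(labs), 40)
  expect_true(all(labs$class %in% c("like", "non")))
  # planted positives recovered in the separable case
  expect_equal(labs$class, ifelse(pool$y == "1", "like", "non"))

  # empty pool -> empty labelling
  empty <- classify_potential(m, pool[0, ])
  expect_equal(nrow(empty), 0)

  # missing feature columns are an input error
  expect_error(classify_potential(m, pool[, c("patient_id", "f1")]),
               "dimensionality")
})

test_that("like/non classification separates planted classes end to end", {
  cfg <- generator_config(n_patients = 1200, seed = 55,
                          emission = recovery_emission(),
                          noise = list(p_field_typo = 0, p_field_missing = 0,
                                       p_low_quality_record = 0))
  sim <- simulate_claims(cfg)
  j <- oracle_journeys(sim)
  asg <- build_cohorts(j, rules)
  res <- classify_cohort(j, asg, "wtattr", rules, split_spec(seed = 55),
                         seed = 55)
  expect_equal(res$report$status, "ok")
  rec <- like_recovery(res$like_labels, sim$truth, "wtattr")
  # planted wild-type cases called like far more often than other classes
  m <- dplyr::inner_join(res$like_labels,
                         dplyr::distinct(sim$truth[, c("patient_id",
                                                       "latent_class")]),
                         by = "patient_id")
  like_rate_planted <- mean(m$class[m$latent_class == "wtattr_cm"] == "like")
  like_rate_other <- mean(m$class[m$latent_class != "wtattr_cm"] == "like")
  expect_gt(like_rate_planted, like_rate_other + 0.5)
})
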