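#' Train/validation/test split specification
#'
#' The labeled patients are split 60/20/20 at the patient level, stratified
#' by label; hyperparameters are tuned by K-fold cross-validation inside the
#' training partition.
#'
#' @param train_fraction,validation_fraction,test_fraction Fractions summing
#'   to 1.
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed making the split reproducible.
#' @return An object of class `attr_split_spec`.
#' @export
split_spec <- function(train_fraction = 0.6, validation_fraction = 0.2,
                       test_fraction = 0.2, k_folds = 5, seed = 1L) {
  fr <- c(train_fraction, validation_fraction, test_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    abort_config("train/validation/test fractions", "must be >= 0 and sum to 1")
  }
  if (!is.numeric(k_folds) || k_folds < 2) {
    abort_config("k_folds", "must be an integer >= 2")
  }
  structure(list(train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "attr_split_spec")
}

#' Encode journeys as classifier feature vectors
#'
#' One row per patient: per-code claim counts over the study ICD-10
#' vocabulary and over the configured procedure vocabulary, age (at the
#' supplied index date when available, else at the first claim), state of
#' residence, hospitalization and outpatient visit counts, and total length
#' of stay. Codes outside the vocabularies are ignored.
#'
#' @param journeys Claims table with a `patient_id` column.
#' @param rules An [attr_ruleset()]; fixes the vocabularies and hence the
#'   feature dimensionality.
#' @param index_dates Optional tibble (`patient_id`, `index_date`) anchoring
#'   the age feature.
#' @param include_state Include state of residence as a categorical feature.
#' @return A tibble with `patient_id` and numeric/categorical feature
#'   columns.
#' @export
build_features <- function(journeys, rules, index_dates = NULL,
                           include_state = TRUE) {
  stopifnot(inherits(rules, "attr_ruleset"))
  vocab <- study_vocabularies(rules)
  pats <- sort(unique(journeys$patient_id))
  pat_f <- factor(journeys$patient_id, levels = pats)

  icd_levels <- norm_code(vocab$icd)
  icd_counts <- table(pat_f, factor(norm_code(journeys$icd10),
                                    levels = icd_levels))
  proc_levels <- norm_code(vocab$procedure)
  proc_counts <- table(pat_f, factor(norm_code(journeys$procedure),
                                     levels = proc_levels))

  base <- dplyr::summarise(
    dplyr::group_by(journeys, .data$patient_id),
    dob = first_valid(parse_dob(.data$dob)),
    first_claim = min(as.Date(.data$claim_date)),
    state = first_valid(.data$state),
    n_hospitalizations = sum(.data$setting == "inpatient"),
    n_outpatient_visits = sum(.data$setting == "outpatient"),
    total_length_of_stay = sum(.data$length_of_stay, na.rm = TRUE),
    .groups = "drop")
  base <- base[match(pats, base$patient_id), ]

  anchor <- base$first_claim
  if (!is.null(index_dates)) {
    m <- match(pats, index_dates$patient_id)
    idx <- as.Date(index_dates$index_date[m])
    anchor[!is.na(idx)] <- idx[!is.na(idx)]
  }
  age <- as.numeric(anchor - base$dob) / 365.25
  age[is.na(age) | age < 0] <- NA_real_

  feats <- tibble::tibble(patient_id = pats, age_at_index = age)
  icd_df <- as.data.frame.matrix(icd_counts)
  names(icd_df) <- paste0("icd_", icd_levels)
  proc_df <- as.data.frame.matrix(proc_counts)
  names(proc_df) <- paste0("proc_", proc_levels)
  feats <- dplyr::bind_cols(feats, tibble::as_tibble(icd_df),
                            tibble::as_tibble(proc_df))
  feats$n_hospitalizations <- base$n_hospitalizations
  feats$n_outpatient_visits <- base$n_outpatient_visits
  feats$total_length_of_stay <- base$total_length_of_stay
  if (include_state) feats$state <- base$state
  feats
}

# Largest-remainder stratified allocation of one class's indices.
allocate_strata <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  base
}

#' Stratified patient-level train/validation/test split
#'
#' @param data Tibble with a `y` label column (two classes) and one row per
#'   patient.
#' @param spec An [split_spec()].
#' @return A list with `train`, `validation`, `test` tibbles: disjoint,
#'   exhaustive, label-stratified, reproducible under the spec seed.
#' @export
split_dataset <- function(data, spec = split_spec()) {
  stopifnot(inherits(spec, "attr_split_spec"))
  if (nrow(data) < 10) stop("need at least 10 labeled patients", call. = FALSE)
  y <- as.factor(data$y)
  if (nlevels(droplevels(y)) < 2) {
    stop("labels are degenerate: a single class", call. = FALSE)
  }
  set.seed(spec$seed)
  fr <- c(spec$train_fraction, spec$validation_fraction, spec$test_fraction)
  part <- rep(NA_character_, nrow(data))
  for (cl in levels(droplevels(y))) {
    idx <- sample(which(y == cl))
    sizes <- allocate_strata(length(idx), fr)
    part[idx] <- rep(c("train", "validation", "test"), times = sizes)
  }
  out <- list(train = data[part == "train", , drop = FALSE],
              validation = data[part == "validation", , drop = FALSE],
              test = data[part == "test", , drop = FALSE])
  for (nm in names(out)) {
    if (nlevels(droplevels(as.factor(out[[nm]]$y))) < 2) {
      stop(sprintf("stratification error: partition '%s' lacks a class", nm),
           call. = FALSE)
    }
  }
  out
}

# --- model fitting internals -------------------------------------------------

feature_matrix <- function(df, state_levels = NULL) {
  df <- df[, setdiff(names(df), c("patient_id", "y")), drop = FALSE]
  if ("state" %in% names(df)) {
    lev <- state_levels %||% sort(unique(df$state))
    st <- factor(df$state, levels = lev)
    oh <- sapply(lev, function(l) as.numeric(!is.na(st) & st == l))
    if (is.null(dim(oh))) oh <- matrix(oh, nrow = nrow(df))
    colnames(oh) <- paste0("state_", lev)
    df$state <- NULL
    X <- cbind(as.matrix(df), oh)
  } else {
    X <- as.matrix(df)
  }
  X[is.na(X)] <- 0
  storage.mode(X) <- "double"
  X
}

default_grids <- function(p) {
  list(
    logistic = data.frame(lambda = c(0.001, 0.01, 0.1)),
    svm = data.frame(cost = c(0.5, 2, 8)),
    xgboost = expand.grid(max_depth = c(2L, 4L), nrounds = 60L, eta = 0.3),
    random_forest = data.frame(mtry = unique(pmax(1L,
      c(floor(sqrt(p)), floor(p / 3)))))
  )
}

fit_candidate <- function(family, X, y, params, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c("0", "1"))
  fit <- switch(family,
    logistic = glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                              lambda = params$lambda),
    svm = e1071::svm(X, yf, kernel = "radial", cost = params$cost,
                     probability = TRUE, scale = apply(X, 2, sd) > 0),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(yf) - 1),
      nrounds = params$nrounds, verbose = 0),
    random_forest = ranger::ranger(
      x = X, y = yf, probability = TRUE, num.trees = 300,
      mtry = min(params$mtry, ncol(X)), seed = seed, num.threads = 1),
    stop("unknown candidate family: ", family, call. = FALSE))
  list(family = family, fit = fit, params = params)
}

predict_prob <- function(cand, X) {
  switch(cand$family,
    logistic = as.numeric(predict(cand$fit, X, s = cand$params$lambda,
                                  type = "response")),
    svm = {
      pr <- attr(predict(cand$fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    xgboost = as.numeric(predict(cand$fit, xgboost::xgb.DMatrix(X))),
    random_forest = as.numeric(predict(cand$fit,
                                       data = X)$predictions[, "1"]))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Confusion-matrix performance metrics
#'
#' Accuracy `(tp+tn)/(tp+tn+fp+fn)`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`. A zero denominator yields `NA` (reported as not
#' applicable, never silently 0 or 1).
#'
#' @param tp,fn,tn,fp Confusion counts.
#' @return A list with the counts and the three metrics.
#' @export
performance_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = if (total == 0) NA_real_ else (tp + tn) / total,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

confusion_from <- function(pred, y) {
  performance_metrics(tp = sum(pred == 1 & y == 1),
                      fn = sum(pred == 0 & y == 1),
                      tn = sum(pred == 0 & y == 0),
                      fp = sum(pred == 1 & y == 0))
}

#' Tune, compare and select the supervised classifier
#'
#' Four candidate families — regularized logistic regression, a radial
#' support-vector classifier, gradient-boosted trees, and a random forest —
#' are each tuned by stratified K-fold cross-validation on the training
#' partition over a small fixed hyperparameter grid, then refitted on the
#' full training partition and scored on the validation partition. The
#' winner has the highest validation accuracy; ties break by higher
#' validation sensitivity, then by the fixed family order.
#'
#' @param train,validation Tibbles with a two-class `y` column and feature
#'   columns as from [build_features()].
#' @param spec An [split_spec()] (supplies `k_folds` and the seed).
#' @param candidates Character vector of families to try, in tie-break
#'   order.
#' @param threshold Probability cut-off used later by
#'   [classify_potential()].
#' @return An object of class `attr_model`: the fitted winner, the feature
#'   encoding, and a per-candidate selection report.
#' @export
select_model <- function(train, validation, spec = split_spec(),
                         candidates = c("logistic", "svm", "xgboost",
                                        "random_forest"),
                         threshold = 0.5) {
  y_tr <- as.character(train$y)
  if (length(unique(y_tr)) < 2) {
    stop("training labels are degenerate: a single class", call. = FALSE)
  }
  state_levels <- if ("state" %in% names(train))
    sort(unique(c(train$state, validation$state))) else NULL
  X_tr <- feature_matrix(train, state_levels)
  X_va <- feature_matrix(validation, state_levels)
  grids <- default_grids(ncol(X_tr))
  folds <- stratified_folds(y_tr, spec$k_folds, spec$seed)

  report <- list()
  best <- NULL
  for (fam in candidates) {
    grid <- grids[[fam]]
    cv_acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      accs <- numeric(spec$k_folds)
      for (k in seq_len(spec$k_folds)) {
        tr <- folds != k
        if (length(unique(y_tr[tr])) < 2) { accs[k] <- NA; next }
        cand <- fit_candidate(fam, X_tr[tr, , drop = FALSE], y_tr[tr],
                              grid[g, , drop = FALSE],
                              seed = spec$seed + 100 * k + g)
        pred <- as.integer(predict_prob(cand, X_tr[!tr, , drop = FALSE]) >= 0.5)
        accs[k] <- mean(pred == as.integer(y_tr[!tr] == "1"))
      }
      cv_acc[g] <- mean(accs, na.rm = TRUE)
    }
    g_best <- which.max(cv_acc)
    cand <- fit_candidate(fam, X_tr, y_tr, grid[g_best, , drop = FALSE],
                          seed = spec$seed + 17)
    prob_va <- predict_prob(cand, X_va)
    pred_va <- as.integer(prob_va >= 0.5)
    met <- confusion_from(pred_va, as.integer(validation$y == "1"))
    report[[fam]] <- list(best_params = as.list(grid[g_best, , drop = FALSE]),
                          cv_accuracy = cv_acc[g_best],
                          validation_accuracy = met$accuracy,
                          validation_sensitivity = met$sensitivity)
    if (is.null(best) ||
        met$accuracy > best$val_accuracy + 1e-12 ||
        (abs(met$accuracy - best$val_accuracy) <= 1e-12 &&
         isTRUE(met$sensitivity > best$val_sensitivity + 1e-12))) {
      best <- list(cand = cand, val_accuracy = met$accuracy,
                   val_sensitivity = met$sensitivity)
    }
  }

  structure(list(
    family = best$cand$family,
    candidate = best$cand,
    state_levels = state_levels,
    feature_cols = setdiff(names(train), c("patient_id", "y")),
    threshold = threshold,
    selection_report = report
  ), class = "attr_model")
}

#' @method print attr_model
#' @export
print.attr_model <- function(x, ...) {
  cat("<attr_model> winning family:", x$family, "\n")
  for (fam in names(x$selection_report)) {
    r <- x$selection_report[[fam]]
    cat(sprintf("  %-14s cv acc %.3f | val acc %.3f | val sens %.3f\n", fam,
                r$cv_accuracy, r$validation_accuracy,
                r$validation_sensitivity %||% NA))
  }
  invisible(x)
}

#' Evaluate a selected model on the held-out test partition
#'
#' @param model An [select_model()] result.
#' @param test Tibble with `y` and feature columns; untouched during
#'   selection.
#' @return [performance_metrics()] of the test confusion matrix.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(model, "attr_model"))
  if (!nrow(test)) stop("test partition is empty", call. = FALSE)
  X <- feature_matrix(test, model$state_levels)
  pred <- as.integer(predict_prob(model$candidate, X) >= model$threshold)
  confusion_from(pred, as.integer(test$y == "1"))
}

#' Classify the potential pool into like and non cases
#'
#' Applies the selected model to journeys labeled potential by the cascade:
#' predicted probability at or above the threshold labels the patient a
#' "like" (probable under-recognized) case, below it a "non" case.
#'
#' @param model An [select_model()] result.
#' @param pool Feature tibble ([build_features()]) of the potential
#'   patients, with `patient_id`.
#' @return A tibble (`patient_id`, `prob`, `class`), `class` in
#'   `{"like","non"}`; empty pool yields an empty tibble.
#' @export
classify_potential <- function(model, pool) {
  stopifnot(inherits(model, "attr_model"))
  if (!nrow(pool)) {
    return(tibble::tibble(patient_id = character(), prob = numeric(),
                          class = character()))
  }
  miss <- setdiff(model$feature_cols, names(pool))
  if (length(miss)) {
    stop(sprintf("feature dimensionality mismatch; pool lacks: %s",
                 paste(head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  X <- feature_matrix(pool[, c("patient_id", model$feature_cols)],
                      model$state_levels)
  prob <- predict_prob(model$candidate, X)
  tibble::tibble(patient_id = pool$patient_id, prob = prob,
                 class = ifelse(prob >= model$threshold, "like", "non"))
}

#' Assemble the labeled training frame for one cohort
#'
#' Positives are the cascade's reference patients. The negative class is
#' not defined by the case-finding rules, so it is taken as kept journeys
#' bearing cardiac-related codes that meet neither the reference nor the
#' potential criteria, subsampled to a configurable positive:negative
#' ratio.
#'
#' @param journeys Linked claims table.
#' @param assignments [build_cohorts()] output.
#' @param cohort `"hattr"` or `"wtattr"`.
#' @param rules An [attr_ruleset()].
#' @param neg_ratio Maximum negatives per positive.
#' @param seed Seed for negative subsampling.
#' @param include_state Passed to [build_features()].
#' @return A feature tibble with a `y` factor column (`"1"` reference,
#'   `"0"` negative).
#' @export
build_training_frame <- function(journeys, assignments, cohort, rules,
                                 neg_ratio = 3, seed = 1L,
                                 include_state = TRUE) {
  kept <- quality_filter(apply_exclusions(journeys, rules)$kept)$kept
  asg <- assignments[assignments$cohort == cohort, ]
  pos <- asg$patient_id[asg$label == "reference"]

  cardrel <- dplyr::summarise(
    dplyr::group_by(kept, .data$patient_id),
    has_cardrel = any(code_in(.data$icd10, rules$norm$cardiac_related_icds)),
    .groups = "drop")
  in_case <- asg$patient_id[asg$label %in% c("reference", "potential")]
  neg_pool <- setdiff(cardrel$patient_id[cardrel$has_cardrel], in_case)

  set.seed(seed)
  n_neg <- min(length(neg_pool), max(1L, round(neg_ratio * length(pos))))
  neg <- sort(sample(neg_pool, n_neg))

  sel <- kept[kept$patient_id %in% c(pos, neg), , drop = FALSE]
  idx <- asg[asg$label == "reference", c("patient_id", "index_date")]
  feats <- build_features(sel, rules, index_dates = idx,
                          include_state = include_state)
  feats$y <- factor(ifelse(feats$patient_id %in% pos, "1", "0"),
                    levels = c("0", "1"))
  feats
}

#' Recovery of planted like cases against the latent truth
#'
#' Compares predicted like/non labels on a cohort's potential pool with
#' the generator's latent classes: a potential patient is a planted like
#' case when the latent class is the cohort's own disease form
#' (`wtattr_cm` for the wild-type cohort, `hattr_cm` for the hereditary
#' cohort); every other latent class — including the other disease form —
#' is a true negative for this cohort's model. Sensitivity is the share
#' of planted cases labeled like; specificity the share of the rest
#' labeled non.
#'
#' @param like_labels [classify_potential()] output.
#' @param truth Patient-level truth (`patient_id`, `latent_class`).
#' @param cohort `"hattr"` or `"wtattr"`.
#' @return A list with `sensitivity`, `specificity`, and the pool
#'   composition counts.
#' @export
like_recovery <- function(like_labels, truth, cohort = "wtattr") {
  target <- switch(cohort, hattr = "hattr_cm", wtattr = "wtattr_cm",
                   stop("unknown cohort: ", cohort, call. = FALSE))
  m <- dplyr::inner_join(like_labels,
                         dplyr::distinct(truth[, c("patient_id", "latent_class")]),
                         by = "patient_id")
  planted <- m$latent_class == target
  list(
    sensitivity = if (!any(planted)) NA_real_ else
      mean(m$class[planted] == "like"),
    specificity = if (all(planted)) NA_real_ else
      mean(m$class[!planted] == "non"),
    n_planted = sum(planted), n_other = sum(!planted)
  )
}
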