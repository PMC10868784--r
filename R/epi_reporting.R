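#' Final per-patient classification labels
#'
#' Joins the cascade assignments with the model's like/non labels:
#' reference patients keep their label; potential patients become `like`
#' or `non`.
#'
#' @param assignments [build_cohorts()] output.
#' @param like_labels Tibble (`patient_id`, `cohort`, `class`) from
#'   [classify_potential()], one row per potential patient.
#' @return The assignments tibble with a `final_label` column
#'   (`reference`/`like`/`non` for cases, the cascade label otherwise).
#' @export
final_labels <- function(assignments, like_labels) {
  out <- assignments
  out$final_label <- out$label
  if (nrow(like_labels) && !"cohort" %in% names(like_labels)) {
    stop("like_labels must carry a `cohort` column", call. = FALSE)
  }
  if (nrow(like_labels)) {
    key <- paste(like_labels$patient_id, like_labels$cohort)
    m <- match(paste(out$patient_id, out$cohort), key)
    hit <- !is.na(m) & out$label == "potential"
    out$final_label[hit] <- like_labels$class[m[hit]]
  }
  out
}

#' Classification proportions by cohort and entry year
#'
#' Cross-tabulates reference / like / non counts per cohort and entry
#' year (plus a Total column), with percentages of each cohort-year total.
#'
#' @param assignments [build_cohorts()] output.
#' @param like_labels As in [final_labels()].
#' @return A tidy tibble: `cohort`, `year` (`"Total"` or the calendar
#'   year), `label`, `n`, `pct`.
#' @export
classification_table <- function(assignments, like_labels) {
  fl <- final_labels(assignments, like_labels)
  fl <- fl[fl$final_label %in% c("reference", "like", "non"), ]
  if (!nrow(fl)) {
    return(tibble::tibble(cohort = character(), year = character(),
                          label = character(), n = integer(),
                          pct = numeric()))
  }
  per_year <- dplyr::count(fl, cohort = .data$cohort,
                           year = as.character(.data$entry_year),
                           label = .data$final_label)
  total <- dplyr::count(fl, cohort = .data$cohort, label = .data$final_label)
  total$year <- "Total"
  tab <- dplyr::bind_rows(total[, c("cohort", "year", "label", "n")], per_year)
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$cohort, .data$year),
                       pct = round(100 * .data$n / sum(.data$n), 2))
  dplyr::arrange(dplyr::ungroup(tab), .data$cohort, .data$year,
                 match(.data$label, c("reference", "like", "non")))
}

#' Scaled prevalence or proportion
#'
#' `numerator / denominator * scale`, rounded to the requested number of
#' digits (matching the rounding used when a rate is printed, e.g. one
#' decimal for percentages, two for table proportions).
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param scale Reporting scale (100 for percent, 1e5 for rates per
#'   100,000).
#' @param digits Rounding digits; `NULL` for no rounding.
#' @return The scaled rate.
#' @export
prevalence <- function(numerator, denominator, scale = 100, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  r <- numerator / denominator * scale
  if (is.null(digits)) r else round(r, digits)
}

#' Demographic summary of final case groups
#'
#' Per cohort and final label (plus a Total group per cohort): age mean,
#' SD, median, min, max and IQR; counts and percentages per age group and
#' sex.
#'
#' @param assignments Output of [final_labels()] (or [build_cohorts()]
#'   output, in which case cascade labels are summarized).
#' @param labels Which final labels constitute the case groups.
#' @return A list of tibbles: `age`, `age_groups`, `sex`.
#' @export
demographics_summary <- function(assignments,
                                 labels = c("reference", "like")) {
  lab_col <- if ("final_label" %in% names(assignments)) "final_label" else "label"
  df <- assignments[assignments[[lab_col]] %in% labels, ]
  df$group <- df[[lab_col]]
  tot <- df
  tot$group <- "Total"
  df <- dplyr::bind_rows(tot, df)

  age <- dplyr::summarise(
    dplyr::group_by(df, .data$cohort, .data$group),
    n = dplyr::n(),
    mean = mean(.data$age_at_index, na.rm = TRUE),
    sd = sd(.data$age_at_index, na.rm = TRUE),
    median = median(.data$age_at_index, na.rm = TRUE),
    min = min(.data$age_at_index, na.rm = TRUE),
    max = max(.data$age_at_index, na.rm = TRUE),
    q1 = q_lin(.data$age_at_index, 0.25),
    q3 = q_lin(.data$age_at_index, 0.75),
    .groups = "drop")

  df$age_bin <- age_group(df$age_at_index)
  age_groups <- dplyr::count(df, .data$cohort, .data$group, .data$age_bin)
  age_groups <- dplyr::mutate(
    dplyr::group_by(age_groups, .data$cohort, .data$group),
    pct = round(100 * .data$n / sum(.data$n), 2))
  sex <- dplyr::count(df, .data$cohort, .data$group, .data$sex)
  sex <- dplyr::mutate(dplyr::group_by(sex, .data$cohort, .data$group),
                       pct = round(100 * .data$n / sum(.data$n), 2))
  list(age = age, age_groups = dplyr::ungroup(age_groups),
       sex = dplyr::ungroup(sex))
}

#' State-of-residence distribution of final case groups
#'
#' @inheritParams demographics_summary
#' @return A tibble: cohort, group, state, n, pct.
#' @export
state_distribution <- function(assignments,
                               labels = c("reference", "like")) {
  lab_col <- if ("final_label" %in% names(assignments)) "final_label" else "label"
  df <- assignments[assignments[[lab_col]] %in% labels, ]
  df$group <- df[[lab_col]]
  tot <- df
  tot$group <- "Total"
  df <- dplyr::bind_rows(tot, df)
  out <- dplyr::count(df, .data$cohort, .data$group, .data$state)
  out <- dplyr::mutate(dplyr::group_by(out, .data$cohort, .data$group),
                       pct = round(100 * .data$n / sum(.data$n), 2))
  dplyr::arrange(dplyr::ungroup(out), .data$cohort, .data$group,
                 dplyr::desc(.data$n))
}

#' Annual hospitalization rate per 100,000
#'
#' Counts inpatient claims bearing study ICD codes (amyloidosis or
#' cardiac-related) among the given patients in a calendar year, scaled to
#' the supplied population size. The population denominator is a
#' configuration input: the study data do not define it.
#'
#' @param journeys Claims of the labeled group (with `patient_id`).
#' @param population_size Positive denominator population.
#' @param year Calendar year(s).
#' @param rules An [attr_ruleset()].
#' @return A tibble (`year`, `n_hospitalizations`, `rate_per_100k`).
#' @export
annual_hospitalization_rate <- function(journeys, population_size, year,
                                        rules) {
  if (population_size <= 0) stop("population_size must be positive",
                                 call. = FALSE)
  study <- union(cohort_qualifying_codes(rules, "wtattr"),
                 cohort_amyloid_codes(rules, "hattr"))
  hosp <- journeys$setting == "inpatient" & code_in(journeys$icd10, study)
  yr <- as.integer(format(as.Date(journeys$claim_date), "%Y"))
  counts <- vapply(year, function(y) sum(hosp & yr == y), numeric(1))
  tibble::tibble(year = year, n_hospitalizations = counts,
                 rate_per_100k = counts / population_size * 1e5)
}

#' Follow-up span of each patient
#'
#' Follow-up starts at the first claim bearing a cohort-qualifying ICD and
#' ends at the last claim date available; single-claim journeys have zero
#' follow-up.
#'
#' @param journeys Claims table with `patient_id`.
#' @param rules An [attr_ruleset()].
#' @param cohort Cohort whose qualifying codes anchor the start.
#' @return A tibble (`patient_id`, `fup_start`, `fup_end`, `fup_years`);
#'   patients with no qualifying claim are omitted.
#' @export
follow_up <- function(journeys, rules, cohort = "wtattr") {
  qual_codes <- cohort_qualifying_codes(rules, cohort)
  df <- tibble::tibble(patient_id = journeys$patient_id,
                       claim_date = as.Date(journeys$claim_date),
                       qual = code_in(journeys$icd10, qual_codes))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$patient_id),
    fup_start = if (any(.data$qual)) min(.data$claim_date[.data$qual])
                else as.Date(NA),
    fup_end = max(.data$claim_date),
    .groups = "drop")
  out <- out[!is.na(out$fup_start), ]
  out$fup_years <- as.numeric(out$fup_end - out$fup_start) / 365.25
  out
}

#' Events per patient per year
#'
#' `n_events / fup_years`. Zero follow-up yields `NA`; such patients are
#' excluded from PPPY medians and reported as a separate count rather than
#' crashing or distorting the rate.
#'
#' @param n_events Event count(s).
#' @param fup_years Follow-up in years.
#' @return The PPPY rate(s).
#' @export
pppy <- function(n_events, fup_years) {
  ifelse(fup_years > 0, n_events / fup_years, NA_real_)
}

hcru_stat_block <- function(x, fup_years) {
  rate <- pppy(x, fup_years)
  list(total = sum(x), mean = mean(x), sd = sd(x),
       median = median(x), q1 = q_lin(x, 0.25), q3 = q_lin(x, 0.75),
       median_pppy = median(rate, na.rm = TRUE),
       q1_pppy = q_lin(rate, 0.25), q3_pppy = q_lin(rate, 0.75),
       n_zero_fup = sum(fup_years == 0))
}

#' Treatment patterns and healthcare resource utilization
#'
#' Per cohort and final label (plus Total): admissions, outpatient visits,
#' total length of stay, treatment claims and diagnostic procedure claims
#' — each as mean (SD), median (IQR) and median per-patient-per-year —
#' plus the therapeutic-itinerary flags (patients with at least one claim
#' for tafamidis, heart transplant, liver transplant). Claims are
#' restricted to those bearing the study ICD codes; treatment and
#' procedure claims are additionally restricted to the configured code
#' lists.
#'
#' @param assignments Output of [final_labels()].
#' @param journeys Claims table with `patient_id`.
#' @param rules An [attr_ruleset()].
#' @param labels Final labels forming the case groups.
#' @return A list with `metrics` (long tibble: cohort, group, metric,
#'   statistic columns) and `flags` (therapy flag counts/percentages).
#' @export
hcru_summary <- function(assignments, journeys, rules,
                         labels = c("reference", "like")) {
  stopifnot("final_label" %in% names(assignments))
  study <- union(cohort_qualifying_codes(rules, "wtattr"),
                 cohort_amyloid_codes(rules, "hattr"))
  taf <- norm_code("06.04.54.006-0")
  heart_tx <- norm_code("05.05.02.004-1")
  liver_tx <- norm_code(c("05.05.02.005-0", "05.05.02.006-8"))
  diag_proc <- union(rules$norm$mandatory_procedures,
                     rules$norm$secondary_procedures)
  treat_proc <- rules$norm$treatment_procedures

  metrics <- list()
  flags <- list()
  for (cohort in unique(assignments$cohort)) {
    asg <- assignments[assignments$cohort == cohort &
                         assignments$final_label %in% labels, ]
    groups <- c(list(Total = asg$patient_id),
                split(asg$patient_id, asg$final_label))
    fup <- follow_up(journeys[journeys$patient_id %in% asg$patient_id, ],
                     rules, cohort)
    for (grp in names(groups)) {
      pats <- groups[[grp]]
      if (!length(pats)) next
      cl <- journeys[journeys$patient_id %in% pats &
                       code_in(journeys$icd10, study), ]
      per_pat <- dplyr::summarise(
        dplyr::group_by(cl, .data$patient_id),
        n_admissions = sum(.data$setting == "inpatient"),
        n_outpatient = sum(.data$setting == "outpatient"),
        total_los = sum(.data$length_of_stay, na.rm = TRUE),
        n_treatment = sum(code_in(.data$procedure, treat_proc)),
        n_procedures = sum(code_in(.data$procedure, diag_proc)),
        has_tafamidis = any(code_in(.data$procedure, taf)),
        has_heart_tx = any(code_in(.data$procedure, heart_tx)),
        has_liver_tx = any(code_in(.data$procedure, liver_tx)),
        .groups = "drop")
      # patients with no study-code claims contribute zeros
      missing_pats <- setdiff(pats, per_pat$patient_id)
      if (length(missing_pats)) {
        zero <- tibble::tibble(
          patient_id = missing_pats, n_admissions = 0L, n_outpatient = 0L,
          total_los = 0, n_treatment = 0L, n_procedures = 0L,
          has_tafamidis = FALSE, has_heart_tx = FALSE, has_liver_tx = FALSE)
        per_pat <- dplyr::bind_rows(per_pat, zero)
      }
      fy <- fup$fup_years[match(per_pat$patient_id, fup$patient_id)]
      fy[is.na(fy)] <- 0

      for (metric in c("n_admissions", "n_outpatient", "total_los",
                       "n_treatment", "n_procedures")) {
        blk <- hcru_stat_block(per_pat[[metric]], fy)
        metrics[[length(metrics) + 1]] <- tibble::as_tibble(
          c(list(cohort = cohort, group = grp, metric = metric), blk))
      }
      n <- length(pats)
      flags[[length(flags) + 1]] <- tibble::tibble(
        cohort = cohort, group = grp, n = n,
        n_tafamidis = sum(per_pat$has_tafamidis),
        pct_tafamidis = round(100 * sum(per_pat$has_tafamidis) / n, 2),
        n_heart_transplant = sum(per_pat$has_heart_tx),
        pct_heart_transplant = round(100 * sum(per_pat$has_heart_tx) / n, 2),
        n_liver_transplant = sum(per_pat$has_liver_tx),
        pct_liver_transplant = round(100 * sum(per_pat$has_liver_tx) / n, 2),
        n_patients_with_admission = sum(per_pat$n_admissions > 0),
        n_patients_with_outpatient = sum(per_pat$n_outpatient > 0))
    }
  }
  list(metrics = dplyr::bind_rows(metrics), flags = dplyr::bind_rows(flags))
}

#' Most frequent procedures by unique patients
#'
#' Ranks procedures by the number of unique patients with at least one
#' claim (a patient with five echocardiogram claims counts once), per
#' cohort and final label; ties break by code order.
#'
#' @param assignments Output of [final_labels()].
#' @param journeys Claims table with `patient_id`.
#' @param n Number of top procedures to keep per group.
#' @param labels Final labels forming the case groups.
#' @return A tibble: cohort, group, procedure, n_patients, share.
#' @export
top_procedures <- function(assignments, journeys, n = 20,
                           labels = c("reference", "like")) {
  lab_col <- if ("final_label" %in% names(assignments)) "final_label" else "label"
  out <- list()
  for (cohort in unique(assignments$cohort)) {
    asg <- assignments[assignments$cohort == cohort &
                         assignments[[lab_col]] %in% labels, ]
    groups <- c(list(Total = asg$patient_id),
                split(asg$patient_id, asg[[lab_col]]))
    for (grp in names(groups)) {
      pats <- groups[[grp]]
      cl <- journeys[journeys$patient_id %in% pats &
                       !is.na(journeys$procedure), ]
      if (!nrow(cl)) next
      counts <- dplyr::summarise(
        dplyr::group_by(cl, procedure = norm_code(.data$procedure)),
        n_patients = dplyr::n_distinct(.data$patient_id), .groups = "drop")
      counts <- counts[order(-counts$n_patients, counts$procedure), ]
      counts <- head(counts, n)
      out[[length(out) + 1]] <- tibble::tibble(
        cohort = cohort, group = grp, rank = seq_len(nrow(counts)),
        procedure = counts$procedure, n_patients = counts$n_patients,
        share = round(100 * counts$n_patients / length(pats), 2))
    }
  }
  dplyr::bind_rows(out)
}

#' Plot annual hospitalization rates
#'
#' @param rates Tibble with `year`, `rate_per_100k` and optionally a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_annual_rates <- function(rates) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$year,
                                           y = .data$rate_per_100k))
  if ("group" %in% names(rates)) {
    p <- p + ggplot2::aes(colour = .data$group, group = .data$group)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Hospitalizations per 100,000") +
    ggplot2::theme_minimal()
}
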