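QUALITY_FIELDS <- c("patient_key", "dob", "sex", "state", "municipality",
                    "zip", "claim_date", "setting", "icd10", "procedure",
                    "length_of_stay")

parse_dob <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(suppressWarnings(
    ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x)),
           as.character(x), NA_character_)))
}

first_valid <- function(x) {
  v <- x[!is.na(x)]
  if (length(v)) v[1] else x[1]
}

#' Remove journeys bearing exclusion diagnoses
#'
#' A journey with at least one claim coded with an exclusion ICD (blood
#' cancers, end-stage renal disease, cerebral amyloid angiopathy, and
#' related amyloid-overlap conditions) is moved whole to the excluded
#' partition.
#'
#' @param journeys Linked claims table with a `patient_id` column.
#' @param rules An [attr_ruleset()].
#' @return A list with `kept` and `excluded` claims tables partitioning the
#'   input.
#' @export
apply_exclusions <- function(journeys, rules) {
  stopifnot(inherits(rules, "attr_ruleset"))
  hit <- code_in(journeys$icd10, rules$norm$exclusion_icds)
  excl_pat <- unique(journeys$patient_id[hit])
  sel <- journeys$patient_id %in% excl_pat
  list(kept = journeys[!sel, , drop = FALSE],
       excluded = journeys[sel, , drop = FALSE])
}

#' Reject journeys with inconsistent or mostly missing data
#'
#' A journey is rejected when any claim implies a non-positive age (date of
#' birth on or after the claim date) or when at least 50% of the tracked
#' claim fields are missing, averaged over the journey's claims. The
#' denominator is the 11 claim data fields (patient key, date of birth,
#' sex, state, municipality, ZIP, claim date, setting, ICD-10, procedure,
#' length of stay).
#'
#' @param journeys Linked claims table with a `patient_id` column.
#' @return A list with `kept` and `quality_rejected` claims tables.
#' @export
quality_filter <- function(journeys) {
  dob <- parse_dob(journeys$dob)
  cd <- as.Date(journeys$claim_date)
  neg_age <- !is.na(dob) & !is.na(cd) & dob >= cd

  miss <- rep(0, nrow(journeys))
  for (f in intersect(QUALITY_FIELDS, names(journeys))) {
    miss <- miss + is_missing_field(journeys[[f]])
  }
  miss_frac <- miss / length(QUALITY_FIELDS)

  per_pat <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(patient_id = journeys$patient_id,
                                   neg_age = neg_age, miss_frac = miss_frac),
                    .data$patient_id),
    reject = any(.data$neg_age) | mean(.data$miss_frac) >= 0.5,
    .groups = "drop")
  bad <- per_pat$patient_id[per_pat$reject]
  sel <- journeys$patient_id %in% bad
  list(kept = journeys[!sel, , drop = FALSE],
       quality_rejected = journeys[sel, , drop = FALSE])
}

#' Index date of a journey for a cohort
#'
#' The earliest claim date among claims bearing a cohort-qualifying ICD:
#' the hereditary amyloidosis codes for the hereditary cohort; the
#' wild-type amyloidosis codes or any cardiac-related code for the
#' wild-type cohort.
#'
#' @param journey Claims of a single patient.
#' @param cohort `"hattr"` or `"wtattr"`.
#' @param rules An [attr_ruleset()].
#' @return A `Date`, or `NA` when no claim qualifies (the patient is out of
#'   this cohort).
#' @export
compute_index_date <- function(journey, cohort, rules) {
  qual <- code_in(journey$icd10, cohort_qualifying_codes(rules, cohort))
  if (!any(qual)) return(as.Date(NA))
  min(as.Date(journey$claim_date)[qual])
}

#' Age in years at the index date
#'
#' `(index_date - dob) / 365.25`, using the Julian year.
#'
#' @param dob Date of birth (`Date` or ISO-8601 string).
#' @param index_date Index date.
#' @return Age in years.
#' @export
compute_age_at_index <- function(dob, index_date) {
  dob <- parse_dob(dob)
  index_date <- as.Date(index_date)
  if (any(!is.na(dob) & !is.na(index_date) & dob >= index_date)) {
    stop("date of birth on or after the index date (inconsistent record)",
         call. = FALSE)
  }
  as.numeric(index_date - dob) / 365.25
}

#' Age-group bin used by the demographic tables
#'
#' @param age Age in years.
#' @return A factor over the study bins ("18 to 29 years" ... ">= 80 years").
#' @export
age_group <- function(age) {
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, 80, Inf), right = FALSE,
      labels = c("18 to 29 years", "30 to 39 years", "40 to 49 years",
                 "50 to 59 years", "60 to 69 years", "70 to 79 years",
                 ">= 80 years"))
}

journey_rule_flags <- function(journey, rules) {
  list(
    has_hattr = any(code_in(journey$icd10, rules$norm$hattr_icds)),
    has_wt = any(code_in(journey$icd10, rules$norm$wtattr_icds)),
    has_cardreq = any(code_in(journey$icd10, rules$norm$cardiac_required_icds)),
    has_cardrel = any(code_in(journey$icd10, rules$norm$cardiac_related_icds)),
    has_mand = any(code_in(journey$procedure, rules$norm$mandatory_procedures)),
    has_sec = any(code_in(journey$procedure, rules$norm$secondary_procedures))
  )
}

journey_age_at_index <- function(journey, cohort, rules) {
  idx <- compute_index_date(journey, cohort, rules)
  if (is.na(idx)) return(NA_real_)
  dob <- parse_dob(first_valid(journey$dob))
  if (is.na(dob) || dob >= idx) return(NA_real_)
  compute_age_at_index(dob, idx)
}

#' Does a journey meet the reference-case rule?
#'
#' Reference cases are the confirmed-diagnosis training labels: age at the
#' index date at or above the cohort gate, at least one claim with the
#' cohort's amyloidosis ICD codes, and at least one claim with a code from
#' the required cardiac sub-list.
#'
#' @inheritParams compute_index_date
#' @return `TRUE` or `FALSE`.
#' @export
label_reference <- function(journey, cohort, rules) {
  fl <- journey_rule_flags(journey, rules)
  age <- journey_age_at_index(journey, cohort, rules)
  amyl <- if (cohort == "hattr") fl$has_hattr else fl$has_wt
  isTRUE(age >= cohort_min_age(rules, cohort)) && amyl && fl$has_cardreq
}

#' Does a journey meet the potential-case rule?
#'
#' Evaluated only for journeys that are not reference cases. For the
#' wild-type cohort a journey qualifies by route (a): a cardiac-related
#' claim plus at least one secondary and one mandatory procedure; or route
#' (b): a wild-type amyloidosis claim plus at least one mandatory or
#' secondary procedure. For the hereditary cohort: a hereditary
#' amyloidosis claim plus at least one mandatory or secondary procedure.
#' The cohort age gate applies as for reference cases.
#'
#' @inheritParams compute_index_date
#' @return `TRUE` or `FALSE`.
#' @export
label_potential <- function(journey, cohort, rules) {
  fl <- journey_rule_flags(journey, rules)
  age <- journey_age_at_index(journey, cohort, rules)
  if (!isTRUE(age >= cohort_min_age(rules, cohort))) return(FALSE)
  if (cohort == "wtattr") {
    (fl$has_cardrel && fl$has_sec && fl$has_mand) ||
      (fl$has_wt && (fl$has_mand || fl$has_sec))
  } else {
    fl$has_hattr && (fl$has_mand || fl$has_sec)
  }
}

#' Run the full labelling cascade over linked journeys
#'
#' Applies, in order: exclusion-diagnosis removal, the data-quality filter,
#' and then — per cohort, for every patient bearing a cohort-qualifying
#' code — index date and age computation, the reference rule, the
#' potential rule, and finally the out-of-cohort label for kept journeys
#' meeting neither. Exactly one label is emitted per (patient, cohort)
#' pair; the index date and entry year are present only for reference and
#' potential cases.
#'
#' @param journeys Linked claims table with a `patient_id` column.
#' @param rules An [attr_ruleset()].
#' @return A tibble of cohort assignments (`patient_id`, `cohort`, `label`,
#'   `index_date`, `age_at_index`, `entry_year`, `sex`, `state`) with a
#'   `"audit"` attribute recording the counts at every cascade step.
#' @export
build_cohorts <- function(journeys, rules) {
  stopifnot(inherits(rules, "attr_ruleset"))
  assert_columns(journeys, c("patient_id", "icd10", "claim_date", "dob"),
                 "journeys")

  ex <- apply_exclusions(journeys, rules)
  qf <- quality_filter(ex$kept)
  excluded_pat <- unique(ex$excluded$patient_id)
  qrej_pat <- unique(qf$quality_rejected$patient_id)

  flags <- dplyr::summarise(
    dplyr::group_by(journeys, .data$patient_id),
    has_hattr = any(code_in(.data$icd10, rules$norm$hattr_icds)),
    has_wt = any(code_in(.data$icd10, rules$norm$wtattr_icds)),
    has_cardreq = any(code_in(.data$icd10, rules$norm$cardiac_required_icds)),
    has_cardrel = any(code_in(.data$icd10, rules$norm$cardiac_related_icds)),
    has_mand = any(code_in(.data$procedure, rules$norm$mandatory_procedures)),
    has_sec = any(code_in(.data$procedure, rules$norm$secondary_procedures)),
    dob = first_valid(parse_dob(.data$dob)),
    sex = first_valid(.data$sex),
    state = first_valid(.data$state),
    idx_hattr = if (any(code_in(.data$icd10, rules$norm$hattr_icds)))
      min(as.Date(.data$claim_date)[code_in(.data$icd10, rules$norm$hattr_icds)])
    else as.Date(NA),
    idx_wtattr = if (any(code_in(.data$icd10,
                                 cohort_qualifying_codes(rules, "wtattr"))))
      min(as.Date(.data$claim_date)[code_in(.data$icd10,
                                            cohort_qualifying_codes(rules, "wtattr"))])
    else as.Date(NA),
    .groups = "drop")

  out <- list()
  audit <- list(n_patients = nrow(flags),
                n_excluded = length(excluded_pat),
                n_quality_rejected = length(qrej_pat))

  for (cohort in c("hattr", "wtattr")) {
    qualifies <- if (cohort == "hattr") flags$has_hattr else
      (flags$has_wt | flags$has_cardrel)
    fl <- flags[qualifies, , drop = FALSE]
    if (!nrow(fl)) next
    idx <- if (cohort == "hattr") fl$idx_hattr else fl$idx_wtattr
    age <- ifelse(!is.na(fl$dob) & !is.na(idx) & fl$dob < idx,
                  as.numeric(idx - fl$dob) / 365.25, NA_real_)
    gate <- cohort_min_age(rules, cohort)
    amyl <- if (cohort == "hattr") fl$has_hattr else fl$has_wt

    is_ref <- !is.na(age) & age >= gate & amyl & fl$has_cardreq
    is_pot <- !is_ref & !is.na(age) & age >= gate &
      (if (cohort == "wtattr")
        (fl$has_cardrel & fl$has_sec & fl$has_mand) |
         (fl$has_wt & (fl$has_mand | fl$has_sec))
       else fl$has_hattr & (fl$has_mand | fl$has_sec))

    label <- rep("out_of_cohort", nrow(fl))
    label[is_pot] <- "potential"
    label[is_ref] <- "reference"
    label[fl$patient_id %in% qrej_pat] <- "quality_rejected"
    label[fl$patient_id %in% excluded_pat] <- "excluded"

    keep_idx <- label %in% c("reference", "potential")
    assign <- tibble::tibble(
      patient_id = fl$patient_id,
      cohort = cohort,
      label = label,
      index_date = as.Date(ifelse(keep_idx, idx, NA), origin = "1970-01-01"),
      age_at_index = ifelse(keep_idx, age, NA_real_),
      entry_year = ifelse(keep_idx, as.integer(format(idx, "%Y")), NA_integer_),
      sex = fl$sex,
      state = fl$state
    )
    out[[cohort]] <- assign
    audit[[paste0(cohort, "_counts")]] <- as.list(table(label))
  }

  res <- dplyr::bind_rows(out)
  attr(res, "audit") <- audit
  res
}
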