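LATENT_CLASSES <- c("hattr_cm", "wtattr_cm", "other_cardiac", "background",
                    "excluded_condition")

# ICD codes used for patients whose claims are unrelated to the study lists.
BACKGROUND_ICDS <- c("J18.9", "K52.9", "M54.5", "A09", "Z00.0", "E11.9",
                     "J45.9", "S52.5")

BR_STATES <- c(SP = 0.30, MG = 0.12, BA = 0.08, PR = 0.07, RJ = 0.07,
               RS = 0.06, PE = 0.05, CE = 0.05, GO = 0.04, SC = 0.04,
               ES = 0.03, DF = 0.03, PA = 0.03, MA = 0.03, PB = 0.02,
               RN = 0.02, MS = 0.02, MT = 0.02, PI = 0.01, SE = 0.01)

#' Default class-conditional code emission distributions
#'
#' One categorical distribution over ICD-10 codes and one over procedure
#' codes (including a `"none"` atom) per latent class. Hereditary-disease
#' patients emit the hereditary amyloidosis codes plus cardiac codes;
#' wild-type patients emit the wild-type amyloidosis codes plus cardiac
#' codes; other-cardiac patients emit cardiac and background codes only;
#' background patients emit only non-study codes; excluded-condition
#' patients emit exclusion-list codes. Probabilities are normalized to
#' sum to one.
#'
#' @return A named list (one element per latent class) of lists with
#'   elements `icd` and `procedure`, each a named probability vector.
#' @export
default_emission <- function() {
  nrm <- function(x) x / sum(x)
  list(
    hattr_cm = list(
      icd = nrm(c("E85.0" = 0.12, "E85.1" = 0.15, "E85.2" = 0.08,
                  "I50.0" = 0.14, "I50.9" = 0.08, "I42.2" = 0.04,
                  "I44.2" = 0.04, "I48.0" = 0.03, "G56.0" = 0.05,
                  "N18.9" = 0.05, "J18.9" = 0.08, "M54.5" = 0.06,
                  "K52.9" = 0.04, "Z00.0" = 0.04)),
      procedure = nrm(c("none" = 0.25, "02.08.05.002-7" = 0.05,
                        "02.07.02.001-9" = 0.04, "02.01.01.014-3" = 0.01,
                        "02.11.02.003-6" = 0.22, "02.05.01.003-2" = 0.18,
                        "02.02.03.128-4" = 0.06, "02.02.03.120-9" = 0.05,
                        "04.03.02.012-3" = 0.02, "06.04.54.006-0" = 0.04,
                        "03.03.06.021-2" = 0.08))),
    wtattr_cm = list(
      icd = nrm(c("E85" = 0.10, "E85.3" = 0.08, "E85.4" = 0.06,
                  "E85.8" = 0.05, "E85.9" = 0.09, "I50.0" = 0.12,
                  "I50.9" = 0.07, "I35.0" = 0.03, "I44.2" = 0.03,
                  "I48.0" = 0.04, "N18.9" = 0.04, "G56.0" = 0.03,
                  "J18.9" = 0.10, "M54.5" = 0.08, "E11.9" = 0.08)),
      procedure = nrm(c("none" = 0.24, "02.08.05.002-7" = 0.05,
                        "02.08.05.003-5" = 0.02, "02.07.02.001-9" = 0.03,
                        "02.11.02.003-6" = 0.22, "02.05.01.003-2" = 0.17,
                        "02.02.03.128-4" = 0.06, "02.02.03.120-9" = 0.05,
                        "06.04.54.006-0" = 0.02, "05.05.02.004-1" = 0.04,
                        "03.03.06.021-2" = 0.10))),
    other_cardiac = list(
      icd = nrm(c("I50.0" = 0.28, "I50.9" = 0.15, "I11.0" = 0.06,
                  "I42.0" = 0.06, "I44.2" = 0.04, "I48.0" = 0.06,
                  "I51.7" = 0.04, "N18.9" = 0.06, "J18.9" = 0.10,
                  "E11.9" = 0.08, "M54.5" = 0.07)),
      procedure = nrm(c("none" = 0.30, "02.11.02.003-6" = 0.25,
                        "02.05.01.003-2" = 0.18, "02.02.03.120-9" = 0.06,
                        "02.02.03.128-4" = 0.04, "02.08.05.002-7" = 0.02,
                        "02.07.02.001-9" = 0.03, "05.05.02.004-1" = 0.01,
                        "03.03.06.021-2" = 0.11))),
    background = list(
      icd = nrm(c("J18.9" = 0.22, "K52.9" = 0.14, "M54.5" = 0.18,
                  "A09" = 0.12, "Z00.0" = 0.14, "E11.9" = 0.10,
                  "J45.9" = 0.06, "S52.5" = 0.04)),
      procedure = nrm(c("none" = 0.80, "02.11.02.003-6" = 0.12,
                        "02.05.01.003-2" = 0.08))),
    excluded_condition = list(
      icd = nrm(c("C90.0" = 0.25, "N18.6" = 0.15, "C83.3" = 0.08,
                  "I68.0" = 0.07, "I50.0" = 0.15, "I50.9" = 0.08,
                  "J18.9" = 0.12, "M54.5" = 0.10)),
      procedure = nrm(c("none" = 0.55, "02.11.02.003-6" = 0.20,
                        "02.05.01.003-2" = 0.15, "02.02.03.120-9" = 0.10)))
  )
}

#' Emission distributions for the like-case recovery experiment
#'
#' Returns [default_emission()] with the wild-type class's ICD distribution
#' rescaled so that a configurable share of a planted patient's claims
#' bears the disease-defining (wild-type amyloidosis) codes, the remainder
#' keeping the default cardiac/background proportions. The share is the
#' experiment's signal strength: planted like cases share the reference
#' class's emission profile, and recovery of the planted labels is only a
#' meaningful expectation when the signal is strong enough for the
#' classifier to see. The package documents 0.5 as that threshold; the
#' default here sits just above it.
#'
#' @param amyloid_share Expected fraction of a wild-type patient's claims
#'   bearing wild-type amyloidosis codes.
#' @return An emission list as [default_emission()].
#' @export
recovery_emission <- function(amyloid_share = 0.52) {
  stopifnot(amyloid_share > 0, amyloid_share < 1)
  em <- default_emission()
  icd <- em$wtattr_cm$icd
  wt_codes <- c("E85", "E85.3", "E85.4", "E85.8", "E85.9")
  is_wt <- names(icd) %in% wt_codes
  icd[is_wt] <- icd[is_wt] / sum(icd[is_wt]) * amyloid_share
  icd[!is_wt] <- icd[!is_wt] / sum(icd[!is_wt]) * (1 - amyloid_share)
  em$wtattr_cm$icd <- icd
  em
}

#' Configuration for the synthetic claims generator
#'
#' Defines the population size, the mixture over latent disease classes,
#' the class-conditional ICD/procedure emission distributions, the claims
#' volume model, the study window, and the identifier-noise model. Every
#' downstream stage is testable against the latent truth this generator
#' records.
#'
#' @param n_patients Number of patients to simulate.
#' @param class_mix Named probabilities over
#'   `c("hattr_cm","wtattr_cm","other_cardiac","background","excluded_condition")`;
#'   must sum to 1.
#' @param emission Per-class emission distributions, as [default_emission()].
#' @param claims_per_patient List with `min` (integer floor) and `lambda`
#'   (Poisson mean of additional claims); per-patient claim count is
#'   `min + Poisson(lambda)`.
#' @param study_window Length-2 `Date` vector `(start, end)`; claims are
#'   dated uniformly within it.
#' @param noise List with `p_field_typo`, `p_field_missing` (per linking
#'   field: date of birth, municipality, ZIP) and `p_low_quality_record`
#'   (record-level quality flag), all in `[0, 1]`.
#' @param age_ranges Named list of `c(min, max)` age (years) at window
#'   start per latent class; defaults keep hereditary patients adult and
#'   wild-type patients at least 50.
#' @param p_inpatient Probability that a claim is an inpatient record.
#' @param mean_length_of_stay Mean additional days of stay beyond 1 for
#'   inpatient claims.
#' @param exclusion_icds Codes counted as exclusion conditions; every
#'   `excluded_condition` patient is guaranteed at least one such claim.
#' @param vocabulary List with `icd` and `procedure` code vectors; emission
#'   distributions may only reference these codes. Defaults to the union of
#'   the codes named by `emission`.
#' @param seed Integer seed; identical configurations reproduce identical
#'   tables byte for byte.
#' @return An object of class `attr_generator_config`.
#' @export
generator_config <- function(
    n_patients = 2000,
    class_mix = c(hattr_cm = 0.03, wtattr_cm = 0.08, other_cardiac = 0.40,
                  background = 0.46, excluded_condition = 0.03),
    emission = default_emission(),
    claims_per_patient = list(min = 1, lambda = 5),
    study_window = as.Date(c("2015-01-01", "2021-12-30")),
    noise = list(p_field_typo = 0.02, p_field_missing = 0.02,
                 p_low_quality_record = 0.05),
    age_ranges = list(hattr_cm = c(25, 85), wtattr_cm = c(52, 92),
                      other_cardiac = c(30, 90), background = c(18, 90),
                      excluded_condition = c(30, 90)),
    p_inpatient = 0.4,
    mean_length_of_stay = 5,
    exclusion_icds = c("C90.0", "N18.6", "C83.3", "I68.0"),
    vocabulary = NULL,
    seed = 20150101) {

  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort_config("n_patients", "must be a positive count")
  }
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% LATENT_CLASSES)) {
    abort_config("class_mix",
                 sprintf("must be named with classes among {%s}",
                         paste(LATENT_CLASSES, collapse = ", ")))
  }
  if (any(class_mix < 0 | class_mix > 1)) {
    abort_config("class_mix", "probabilities must lie in [0, 1]")
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    abort_config("class_mix", "must sum to 1 (within 1e-9)")
  }
  if (!inherits(study_window, "Date") || length(study_window) != 2 ||
      !(study_window[1] < study_window[2])) {
    abort_config("study_window", "must be two dates with start < end")
  }
  for (nm in c("p_field_typo", "p_field_missing", "p_low_quality_record")) {
    p <- noise[[nm]]
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1) {
      abort_config(paste0("noise$", nm), "must be a probability in [0, 1]")
    }
  }
  if (!is.numeric(p_inpatient) || p_inpatient < 0 || p_inpatient > 1) {
    abort_config("p_inpatient", "must be a probability in [0, 1]")
  }

  classes <- names(class_mix)[class_mix > 0]
  for (cl in classes) {
    em <- emission[[cl]]
    if (is.null(em) || is.null(em$icd) || is.null(em$procedure)) {
      abort_config(paste0("emission$", cl),
                   "must provide `icd` and `procedure` distributions")
    }
    for (part in c("icd", "procedure")) {
      p <- em[[part]]
      if (any(p < 0 | p > 1)) {
        abort_config(paste0("emission$", cl, "$", part),
                     "probabilities must lie in [0, 1]")
      }
      if (abs(sum(p) - 1) > 1e-9) {
        abort_config(paste0("emission$", cl, "$", part),
                     "must sum to 1 (within 1e-9)")
      }
    }
  }

  if (is.null(vocabulary)) {
    vocabulary <- list(
      icd = unique(unlist(lapply(emission, function(e) names(e$icd)))),
      procedure = setdiff(
        unique(unlist(lapply(emission, function(e) names(e$procedure)))),
        "none")
    )
  }
  for (cl in classes) {
    bad_icd <- setdiff(names(emission[[cl]]$icd), vocabulary$icd)
    if (length(bad_icd)) {
      abort_config(paste0("emission$", cl, "$icd"),
                   sprintf("references codes outside the vocabulary: %s",
                           paste(bad_icd, collapse = ", ")))
    }
    bad_proc <- setdiff(names(emission[[cl]]$procedure),
                        c("none", vocabulary$procedure))
    if (length(bad_proc)) {
      abort_config(paste0("emission$", cl, "$procedure"),
                   sprintf("references codes outside the vocabulary: %s",
                           paste(bad_proc, collapse = ", ")))
    }
  }
  for (cl in classes) {
    if (is.null(age_ranges[[cl]]) || length(age_ranges[[cl]]) != 2 ||
        age_ranges[[cl]][1] > age_ranges[[cl]][2] || age_ranges[[cl]][1] < 0) {
      abort_config(paste0("age_ranges$", cl), "must be c(min, max) with 0 <= min <= max")
    }
  }

  structure(list(
    n_patients = as.integer(n_patients), class_mix = class_mix,
    emission = emission, claims_per_patient = claims_per_patient,
    study_window = study_window, noise = noise, age_ranges = age_ranges,
    p_inpatient = p_inpatient, mean_length_of_stay = mean_length_of_stay,
    exclusion_icds = exclusion_icds, vocabulary = vocabulary,
    seed = as.integer(seed)
  ), class = "attr_generator_config")
}

#' Draw the latent patient population
#'
#' Samples each patient's latent disease class from the configured mixture,
#' then demographics: sex, state of residence, a municipality code nested in
#' the state, an 8-digit ZIP, and a date of birth placing the patient's age
#' at window start uniformly within the class age range (hereditary patients
#' adult, wild-type patients at least 50 with a configurable margin).
#'
#' @param config An [generator_config()].
#' @return A list with `patients` (one row per patient: identifiers,
#'   demographics, latent class) and `truth` (initially the patient-to-class
#'   map; claim record ids are appended by [generate_claims()]).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "attr_generator_config"))
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_patients
  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  state <- sample(names(BR_STATES), n, replace = TRUE, prob = BR_STATES)
  ages <- unname(vapply(cls, function(cl) {
    r <- config$age_ranges[[cl]]
    runif(1, r[1], r[2])
  }, numeric(1)))
  dob <- config$study_window[1] - round(ages * 365.25)
  patients <- tibble::tibble(
    patient_id = sprintf("T%05d", seq_len(n)),
    latent_class = cls,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.42, 0.58)),
    state = state,
    municipality = sprintf("%s%04d", substr(state, 1, 2),
                           sample.int(300L, n, replace = TRUE)),
    zip = sprintf("%08d", sample.int(99999999L, n, replace = TRUE)),
    dob = dob,
    patient_key = sprintf("K%010d", sample.int(.Machine$integer.max - 1L, n))
  )
  list(patients = patients,
       truth = tibble::tibble(patient_id = patients$patient_id,
                              latent_class = patients$latent_class))
}

#' Emit inpatient and outpatient claims for a generated population
#'
#' Draws a per-patient claim count (`min + Poisson(lambda)`), dates each
#' claim uniformly within the study window, assigns the care setting, and
#' samples ICD-10 and procedure codes from the patient's class-conditional
#' emission distributions. Excluded-condition patients are guaranteed at
#' least one claim bearing an exclusion-list code. The encrypted patient
#' key is carried only on outpatient records, mirroring systems where only
#' the outpatient database has a stable pseudonymous identifier.
#'
#' @param population Result of [generate_population()].
#' @param config The same [generator_config()].
#' @return A list with `inpatient`, `outpatient` claim tables (common
#'   schema; `length_of_stay` absent for outpatient rows) and `truth`
#'   (record-level: record id, patient id, latent class).
#' @export
generate_claims <- function(population, config) {
  stopifnot(inherits(config, "attr_generator_config"))
  set.seed(derive_seed(config$seed, 2))
  pat <- population$patients
  cpp <- config$claims_per_patient
  n_claims <- (cpp$min %||% 1L) + rpois(nrow(pat), cpp$lambda)
  n_claims <- pmax(n_claims, 1L)
  idx <- rep(seq_len(nrow(pat)), n_claims)
  total <- length(idx)
  window_days <- as.integer(config$study_window[2] - config$study_window[1])

  claims <- tibble::tibble(
    record_id = sprintf("R%07d", seq_len(total)),
    patient_id = pat$patient_id[idx],
    latent_class = pat$latent_class[idx],
    dob = format(pat$dob[idx], "%Y-%m-%d"),
    sex = pat$sex[idx],
    state = pat$state[idx],
    municipality = pat$municipality[idx],
    zip = pat$zip[idx],
    claim_date = config$study_window[1] +
      sample.int(window_days + 1L, total, replace = TRUE) - 1L,
    setting = ifelse(runif(total) < config$p_inpatient,
                     "inpatient", "outpatient")
  )
  claims$icd10 <- NA_character_
  claims$procedure <- NA_character_
  for (cl in unique(claims$latent_class)) {
    sel <- claims$latent_class == cl
    em <- config$emission[[cl]]
    claims$icd10[sel] <- sample(names(em$icd), sum(sel), replace = TRUE,
                                prob = em$icd)
    proc <- sample(names(em$procedure), sum(sel), replace = TRUE,
                   prob = em$procedure)
    claims$procedure[sel] <- ifelse(proc == "none", NA_character_, proc)
  }

  # Construction guarantee: every excluded-condition patient bears at least
  # one exclusion-list code.
  excl_norm <- norm_code(config$exclusion_icds)
  excl_pat <- pat$patient_id[pat$latent_class == "excluded_condition"]
  if (length(excl_pat)) {
    has_excl <- tapply(code_in(claims$icd10, excl_norm), claims$patient_id, any)
    fix <- excl_pat[!has_excl[excl_pat]]
    for (pid in fix) {
      first <- which(claims$patient_id == pid)[1]
      claims$icd10[first] <- config$exclusion_icds[1]
    }
  }

  claims$length_of_stay <- ifelse(
    claims$setting == "inpatient",
    1L + rpois(total, config$mean_length_of_stay), NA_integer_)
  claims$patient_key <- ifelse(
    claims$setting == "outpatient",
    pat$patient_key[idx], NA_character_)
  claims$low_quality <- FALSE

  truth <- tibble::tibble(record_id = claims$record_id,
                          patient_id = claims$patient_id,
                          latent_class = claims$latent_class)
  cols <- c("record_id", "patient_key", "dob", "sex", "state", "municipality",
            "zip", "claim_date", "setting", "icd10", "procedure",
            "length_of_stay", "low_quality")
  list(
    inpatient = claims[claims$setting == "inpatient", cols],
    outpatient = claims[claims$setting == "outpatient", cols],
    truth = truth
  )
}

substitute_digit <- function(x, pos, repl) {
  substr(x, pos, pos) <- repl
  x
}

corrupt_field <- function(x, p_typo, p_missing) {
  n <- length(x)
  u <- runif(n)
  typo_pos <- ceiling(runif(n) * nchar(ifelse(is.na(x), "0", x)))
  typo_char <- as.character(sample(0:9, n, replace = TRUE))
  out <- as.character(x)
  make_typo <- !is.na(out) & u >= p_missing & u < p_missing + p_typo
  for (i in which(make_typo)) {
    cur <- substr(out[i], typo_pos[i], typo_pos[i])
    repl <- typo_char[i]
    if (repl == cur) repl <- as.character((as.integer(cur) + 1) %% 10)
    if (!grepl("[0-9]", cur)) next  # only digits are perturbed
    out[i] <- substitute_digit(out[i], typo_pos[i], repl)
  }
  out[!is.na(out) & u < p_missing] <- NA_character_
  out
}

#' Plant identifier noise in generated claims tables
#'
#' Each linking field (date of birth, municipality, ZIP) is independently
#' either blanked (`p_field_missing`) or given a single-digit substitution
#' typo (`p_field_typo`); records are flagged low quality at rate
#' `p_low_quality_record`, emulating the roughly 5% of claims discarded for
#' poor data quality before linkage. The latent truth table is unchanged.
#'
#' @param tables A list with `inpatient` and `outpatient` claim tables.
#' @param config The [generator_config()] providing `noise` and the seed.
#' @return The list with both tables corrupted.
#' @export
corrupt_identifiers <- function(tables, config) {
  stopifnot(inherits(config, "attr_generator_config"))
  nz <- config$noise
  set.seed(derive_seed(config$seed, 3))
  out <- tables
  for (tab in c("inpatient", "outpatient")) {
    df <- out[[tab]]
    if (!nrow(df)) next
    for (f in c("dob", "municipality", "zip")) {
      df[[f]] <- corrupt_field(df[[f]], nz$p_field_typo, nz$p_field_missing)
    }
    df$low_quality <- runif(nrow(df)) < nz$p_low_quality_record
    out[[tab]] <- df
  }
  out
}

#' Simulate a complete synthetic claims study
#'
#' Convenience wrapper: draws the population, emits claims, and plants
#' identifier noise. Deterministic under a fixed configuration.
#'
#' @param config An [generator_config()].
#' @return A list with `inpatient`, `outpatient`, `truth`, `patients`, and
#'   the `config` used.
#' @export
simulate_claims <- function(config = generator_config()) {
  pop <- generate_population(config)
  tabs <- generate_claims(pop, config)
  noisy <- corrupt_identifiers(tabs[c("inpatient", "outpatient")], config)
  list(inpatient = noisy$inpatient, outpatient = noisy$outpatient,
       truth = tabs$truth, patients = pop$patients, config = config)
}

#' Write simulated claims tables as CSV
#'
#' Writes `inpatient.csv`, `outpatient.csv` and `truth.csv` (UTF-8, header
#' row, ISO-8601 dates) into `dir`.
#'
#' @param sim Result of [simulate_claims()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_claims_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(inpatient = file.path(dir, "inpatient.csv"),
             outpatient = file.path(dir, "outpatient.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(sim$inpatient, paths["inpatient"])
  readr::write_csv(sim$outpatient, paths["outpatient"])
  readr::write_csv(sim$truth, paths["truth"])
  invisible(paths)
}

#' Truth-linked patient journeys
#'
#' Binds the inpatient and outpatient tables and assigns each claim its
#' true patient via the latent truth table — i.e., a perfect-linkage
#' oracle. Useful for exercising the cohort and classifier stages
#' independently of linkage quality.
#'
#' @param sim Result of [simulate_claims()].
#' @return A claims table with a `patient_id` column, date-sorted within
#'   patient.
#' @export
oracle_journeys <- function(sim) {
  claims <- dplyr::bind_rows(sim$inpatient, sim$outpatient)
  claims <- dplyr::inner_join(claims,
                              sim$truth[, c("record_id", "patient_id")],
                              by = "record_id")
  dplyr::arrange(claims, .data$patient_id, .data$claim_date, .data$record_id)
}
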