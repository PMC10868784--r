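#' Diagnosis and procedure rule set driving the case-finding cascade
#'
#' Bundles the ICD-10 code lists, SIGTAP procedure code lists and age gates
#' used to label patient journeys as reference, potential, or out-of-cohort
#' ATTR-CM cases. The defaults are the expert-validated study lists:
#' hereditary-amyloidosis codes (E85.0-E85.2), wild-type/systemic amyloidosis
#' codes (E85 and E85.3-E85.9), the cardiac code list split into the
#' "required" sub-list that anchors the reference definition and the full
#' cardiac-related list (heart failure, cardiomyopathies, conduction disease,
#' carpal tunnel syndrome, chronic kidney disease), and the exclusion codes
#' for blood cancers, end-stage renal disease and cerebral amyloid
#' angiopathy.
#'
#' Procedure tiers: `mandatory_procedures` are the amyloidosis-specific
#' confirmatory investigations (heart biopsy, bone scintigraphy, cardiac MRI);
#' `secondary_procedures` are supportive cardiology workup and associated
#' surgery (ECG, echocardiography, natriuretic peptides, troponin,
#' carpal-tunnel release, tenosynovectomy, pacemaker/valve implants);
#' `treatment_procedures` are the therapeutic-itinerary codes (tafamidis,
#' heart/liver transplant, heart-failure treatment codes) used by the
#' resource-utilization reports.
#'
#' Code matching is insensitive to dots and dashes (`I500` matches `I50.0`);
#' the bare stem `E85` matches only claims coded exactly `E85`.
#'
#' @param hattr_icds ICD-10 codes defining hereditary ATTR amyloidosis.
#' @param wtattr_icds ICD-10 codes defining wild-type/other amyloidosis.
#' @param cardiac_required_icds Cardiac codes required (alongside an
#'   amyloidosis code) for a reference label.
#' @param cardiac_related_icds Full cardiac-related code list; superset of
#'   `cardiac_required_icds`, also drives wild-type cohort entry.
#' @param exclusion_icds Codes whose presence excludes a patient.
#' @param mandatory_procedures,secondary_procedures,treatment_procedures
#'   SIGTAP procedure code sets (see Details).
#' @param min_age_hattr,min_age_wtattr Minimum age in years at the index
#'   date for the hereditary and wild-type cohorts.
#' @return An object of class `attr_ruleset`.
#' @examples
#' rules <- attr_ruleset()
#' rules$min_age_wtattr
#' @export
attr_ruleset <- function(
    hattr_icds = c("E85.0", "E85.1", "E85.2"),
    wtattr_icds = c("E85", "E85.3", "E85.4", "E85.8", "E85.9"),
    cardiac_required_icds = c("I50.0", "I50.1", "I50.9", "I11.0", "I42.0",
                              "I42.1", "I42.2", "I35.0", "I44.1", "I44.2",
                              "I42.5"),
    cardiac_related_icds = c("I50.0", "I50.1", "I50.9", "I51.7", "I11.0",
                             "I35.0", "I42.0", "I42.1", "I42.2", "I42.5",
                             "I44.0", "I44.1", "I44.2", "I44.7", "I47.2",
                             "I48.0", "Q25.3", "G56.0", "N18.0", "N18.8",
                             "N18.9"),
    exclusion_icds = c("C83.0", "C83.3", "C85.1", "C90.0", "C90.1", "C88.8",
                       "C90.2", "C90.3", "C88.0", "D47.2", "D89.1", "E88.0",
                       "N18.6", "I68.0"),
    mandatory_procedures = c("02.01.01.014-3",  # heart biopsy
                             "02.08.05.002-7",  # bone scintigraphy (full body)
                             "02.08.05.001-9",  # scintigraphy joints/extremities/bone
                             "02.08.05.003-5",  # bone scintigraphy +/- blood flow
                             "02.07.02.001-9"), # heart/aorta MRI
    secondary_procedures = c("02.11.02.003-6",  # electrocardiogram
                             "02.05.01.003-2",  # transthoracic echo
                             "02.05.01.002-4",  # transesophageal echo
                             "02.02.03.128-4",  # BNP / NT-proBNP
                             "02.02.03.120-9",  # troponin
                             "04.03.02.012-3",  # carpal tunnel release
                             "04.08.02.030-0",  # tenosynovectomy, upper limb
                             "04.06.01.061-7", "04.06.01.062-5", "04.06.01.063-3",
                             "04.06.01.064-1", "04.06.01.065-0", "04.06.01.066-8",
                             "04.06.01.067-6",  # pacemaker implants
                             "04.06.01.069-2"), # valve prosthesis implant
    treatment_procedures = c("06.04.54.006-0",  # tafamidis 20 mg
                             "05.05.02.004-1",  # heart transplant
                             "05.05.02.005-0",  # liver transplant (deceased donor)
                             "05.05.02.006-8",  # liver transplant (living donor)
                             "03.03.06.003-4",  # hypertrophic heart disease treatment
                             "03.03.06.023-9",  # myocardiopathy treatment
                             "03.03.06.002-6",  # arrhythmia treatment
                             "03.03.06.021-2"), # heart failure treatment
    min_age_hattr = 18,
    min_age_wtattr = 50) {

  sets <- list(hattr_icds = hattr_icds, wtattr_icds = wtattr_icds,
               cardiac_required_icds = cardiac_required_icds,
               cardiac_related_icds = cardiac_related_icds,
               exclusion_icds = exclusion_icds,
               mandatory_procedures = mandatory_procedures,
               secondary_procedures = secondary_procedures)
  for (nm in names(sets)) {
    if (!length(sets[[nm]])) abort_config(nm, "must be a non-empty code set")
  }
  if (length(intersect(norm_code(mandatory_procedures),
                       norm_code(secondary_procedures)))) {
    abort_config("mandatory_procedures",
                 "must not overlap secondary_procedures")
  }
  if (!is.numeric(min_age_hattr) || min_age_hattr <= 0) {
    abort_config("min_age_hattr", "must be a positive number of years")
  }
  if (!is.numeric(min_age_wtattr) || min_age_wtattr <= 0) {
    abort_config("min_age_wtattr", "must be a positive number of years")
  }

  structure(list(
    hattr_icds = hattr_icds,
    wtattr_icds = wtattr_icds,
    cardiac_required_icds = cardiac_required_icds,
    cardiac_related_icds = cardiac_related_icds,
    exclusion_icds = exclusion_icds,
    mandatory_procedures = mandatory_procedures,
    secondary_procedures = secondary_procedures,
    treatment_procedures = treatment_procedures,
    min_age_hattr = min_age_hattr,
    min_age_wtattr = min_age_wtattr,
    norm = lapply(c(sets, list(treatment_procedures = treatment_procedures)),
                  norm_code)
  ), class = "attr_ruleset")
}

#' @method print attr_ruleset
#' @export
print.attr_ruleset <- function(x, ...) {
  cat("<attr_ruleset>\n")
  cat("  hereditary amyloidosis ICDs:", paste(x$hattr_icds, collapse = ", "), "\n")
  cat("  wild-type amyloidosis ICDs: ", paste(x$wtattr_icds, collapse = ", "), "\n")
  cat("  cardiac required:", length(x$cardiac_required_icds), "codes;",
      "cardiac related:", length(x$cardiac_related_icds), "codes\n")
  cat("  exclusions:", length(x$exclusion_icds), "codes\n")
  cat("  procedures: ", length(x$mandatory_procedures), "mandatory /",
      length(x$secondary_procedures), "secondary /",
      length(x$treatment_procedures), "treatment\n")
  cat("  age gates: hereditary >=", x$min_age_hattr,
      "y; wild-type >=", x$min_age_wtattr, "y\n")
  invisible(x)
}

# Qualifying ICD set for cohort entry / index-date computation.
cohort_qualifying_codes <- function(rules, cohort) {
  switch(cohort,
         hattr = rules$norm$hattr_icds,
         wtattr = union(rules$norm$wtattr_icds, rules$norm$cardiac_related_icds),
         stop("unknown cohort: ", cohort, call. = FALSE))
}

# Amyloidosis ICD set of a cohort (the disease-defining codes).
cohort_amyloid_codes <- function(rules, cohort) {
  switch(cohort,
         hattr = rules$norm$hattr_icds,
         wtattr = rules$norm$wtattr_icds,
         stop("unknown cohort: ", cohort, call. = FALSE))
}

cohort_min_age <- function(rules, cohort) {
  switch(cohort, hattr = rules$min_age_hattr, wtattr = rules$min_age_wtattr,
         stop("unknown cohort: ", cohort, call. = FALSE))
}

#' Study code vocabularies implied by a rule set
#'
#' The ICD vocabulary is the union of the amyloidosis and cardiac-related
#' lists; the procedure vocabulary is the union of the mandatory, secondary
#' and treatment tiers. These fix the feature dimensionality of the
#' classifier.
#'
#' @param rules An [attr_ruleset()].
#' @return A list with elements `icd` and `procedure` (display-form codes).
#' @export
study_vocabularies <- function(rules) {
  stopifnot(inherits(rules, "attr_ruleset"))
  list(
    icd = unique(c(rules$hattr_icds, rules$wtattr_icds,
                   rules$cardiac_related_icds)),
    procedure = unique(c(rules$mandatory_procedures,
                         rules$secondary_procedures,
                         rules$treatment_procedures))
  )
}
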