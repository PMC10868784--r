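# Independent brute-force evaluator of the labelling cascade: per-claim
# loops over every rule clause, written without the package's matching or
# grouping helpers so it can disagree with them.

oracle_strip <- function(code) gsub("[.– -]", "", toupper(code))

oracle_has_icd <- function(journey, codes) {
  codes <- vapply(codes, oracle_strip, character(1))
  hit <- FALSE
  for (i in seq_len(nrow(journey))) {
    code <- journey$icd10[i]
    if (!is.na(code) && oracle_strip(code) %in% codes) hit <- TRUE
  }
  hit
}

oracle_has_proc <- function(journey, codes) {
  codes <- vapply(codes, oracle_strip, character(1))
  hit <- FALSE
  for (i in seq_len(nrow(journey))) {
    code <- journey$procedure[i]
    if (!is.na(code) && oracle_strip(code) %in% codes) hit <- TRUE
  }
  hit
}

oracle_index_date <- function(journey, qual_codes) {
  qual_codes <- vapply(qual_codes, oracle_strip, character(1))
  best <- as.Date(NA)
  for (i in seq_len(nrow(journey))) {
    code <- journey$icd10[i]
    if (is.na(code) || !(oracle_strip(code) %in% qual_codes)) next
    d <- as.Date(journey$claim_date[i])
    if (is.na(best) || d < best) best <- d
  }
  best
}

# Full cascade for one clean journey; NA when the patient bears no
# cohort-qualifying code (no assignment row expected).
oracle_cascade <- function(journey, cohort, rules) {
  qual <- if (cohort == "hattr") rules$hattr_icds else
    c(rules$wtattr_icds, rules$cardiac_related_icds)
  if (!oracle_has_icd(journey, qual)) return(NA_character_)
  if (oracle_has_icd(journey, rules$exclusion_icds)) return("excluded")

  idx <- oracle_index_date(journey, qual)
  dob <- as.Date(journey$dob[1])
  age <- if (!is.na(idx) && dob < idx) as.numeric(idx - dob) / 365.25 else NA
  gate <- if (cohort == "hattr") rules$min_age_hattr else rules$min_age_wtattr
  age_ok <- !is.na(age) && age >= gate

  amyl <- if (cohort == "hattr") oracle_has_icd(journey, rules$hattr_icds) else
    oracle_has_icd(journey, rules$wtattr_icds)
  if (age_ok && amyl && oracle_has_icd(journey, rules$cardiac_required_icds)) {
    return("reference")
  }
  mand <- oracle_has_proc(journey, rules$mandatory_procedures)
  sec <- oracle_has_proc(journey, rules$secondary_procedures)
  pot <- if (cohort == "wtattr") {
    (oracle_has_icd(journey, rules$cardiac_related_icds) && sec && mand) ||
      (oracle_has_icd(journey, rules$wtattr_icds) && (mand || sec))
  } else {
    oracle_has_icd(journey, rules$hattr_icds) && (mand || sec)
  }
  if (age_ok && pot) return("potential")
  "out_of_cohort"
}

# Random clean journeys of <= 5 claims over the 30-code study vocabulary
# (amyloidosis + cardiac-related + one exclusion code), procedures drawn
# from each tier and an out-of-vocabulary code.
random_rule_journeys <- function(n, rules, seed) {
  set.seed(seed)
  vocab30 <- c(rules$hattr_icds, rules$wtattr_icds,
               rules$cardiac_related_icds, "C90.0")
  procs <- c(NA_character_, rules$mandatory_procedures[1],
             rules$mandatory_procedures[2], rules$secondary_procedures[1],
             rules$secondary_procedures[2], "09.99.99.999-9")
  lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1)
    age <- runif(1, 10, 90)
    dob <- format(as.Date("2015-01-01") - round(age * 365.25), "%Y-%m-%d")
    make_journey(sprintf("J%04d", i),
                 icds = sample(vocab30, k, replace = TRUE),
                 dates = as.Date("2015-01-01") + sample(0:2550, k, replace = TRUE),
                 dob = dob,
                 procedures = sample(procs, k, replace = TRUE))
  })
}
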