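`%||%` <- function(x, y) if (is.null(x)) y else x

.rec_counter <- new.env()
.rec_counter$i <- 0L
next_record_id <- function() {
  .rec_counter$i <- .rec_counter$i + 1L
  sprintf("F%07d", .rec_counter$i)
}

# Hand-buildable claim rows for rule/cascade fixtures. All identifier fields
# populated so the quality filter is exercised only where a test plants gaps.
make_claim <- function(patient_id, icd10, claim_date, dob = "1950-06-15",
                       procedure = NA_character_, setting = "inpatient",
                       sex = "M", state = "SP", municipality = "SP0001",
                       zip = "01000000", patient_key = NA_character_,
                       length_of_stay = if (setting == "inpatient") 3L else NA_integer_,
                       record_id = NULL) {
  tibble::tibble(
    record_id = record_id %||% next_record_id(),
    patient_id = patient_id, patient_key = patient_key, dob = dob, sex = sex,
    state = state, municipality = municipality, zip = zip,
    claim_date = as.Date(claim_date), setting = setting, icd10 = icd10,
    procedure = procedure, length_of_stay = length_of_stay,
    low_quality = FALSE)
}

make_journey <- function(patient_id, icds, dates, dob = "1950-06-15",
                         procedures = NA_character_, setting = "inpatient",
                         ...) {
  n <- max(length(icds), length(dates))
  icds <- rep_len(icds, n)
  dates <- rep_len(dates, n)
  procedures <- rep_len(procedures, n)
  setting <- rep_len(setting, n)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_claim(patient_id, icds[i], dates[i], dob = dob,
               procedure = procedures[i], setting = setting[i],
               record_id = sprintf("%s-%02d", patient_id, i), ...)
  }))
}

noiseless_config <- function(n_patients = 500, seed = 7, ...) {
  generator_config(n_patients = n_patients,
                   noise = list(p_field_typo = 0, p_field_missing = 0,
                                p_low_quality_record = 0),
                   seed = seed, ...)
}
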