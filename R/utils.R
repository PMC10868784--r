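#' @importFrom rlang %||% .data
#' @importFrom stats median quantile rbinom rpois runif sd setNames predict
#' @importFrom utils combn head
NULL

# Normalize an ICD-10 or SIGTAP code for matching: drop dots, dashes
# (including en-dashes as printed in some code lists) and spaces, uppercase.
# DATASUS files omit dots, so I500 and I50.0 must compare equal.
norm_code <- function(x) {
  toupper(gsub("[.–‐ -]", "", as.character(x)))
}

# Exact match on normalized codes. A bare stem such as E85 matches only
# claims coded exactly E85, never its subcodes.
code_in <- function(codes, code_set_norm) {
  !is.na(codes) & norm_code(codes) %in% code_set_norm
}

# Derive a per-stage seed from a global seed; kept below 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 7919 * stage) %% 2147483647)
}

is_missing_field <- function(x) {
  is.na(x) | (is.character(x) & trimws(as.character(x)) == "")
}

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# Quantiles use the linear-interpolation convention (type 7) throughout the
# reporting layer so medians/IQRs are reproducible across implementations.
q_lin <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))

assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
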