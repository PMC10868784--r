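CLAIM_COLUMNS <- c("record_id", "patient_key", "dob", "sex", "state",
                   "municipality", "zip", "claim_date", "setting", "icd10",
                   "procedure", "length_of_stay")

LINKING_FIELDS <- c("dob", "sex", "state", "municipality", "zip")

#' Define one blocking pass of the record linkage
#'
#' A pass compares only record pairs agreeing exactly on the `blocking_keys`;
#' within a block, a candidate pair's score is the fraction of
#' `comparison_keys` on which the two records agree (a missing value counts
#' as disagreement), and pairs scoring at least `min_agreement` are merged.
#'
#' @param name Label for the pass, used in the linkage report.
#' @param blocking_keys Non-empty subset of
#'   `c("dob","sex","state","municipality","zip")`.
#' @param comparison_keys Fields compared within a block; defaults to the
#'   linking fields not used for blocking.
#' @param min_agreement Required agreement fraction in `[0, 1]`. With no
#'   comparison keys every blocked pair is accepted.
#' @return An object of class `attr_linkage_pass`.
#' @export
linkage_pass <- function(name, blocking_keys, comparison_keys = NULL,
                         min_agreement = 1) {
  if (!length(blocking_keys)) {
    abort_config("blocking_keys", "must be non-empty")
  }
  bad <- setdiff(blocking_keys, LINKING_FIELDS)
  if (length(bad)) {
    abort_config("blocking_keys",
                 sprintf("contains unknown fields: %s", paste(bad, collapse = ", ")))
  }
  if (is.null(comparison_keys)) {
    comparison_keys <- setdiff(LINKING_FIELDS, blocking_keys)
  }
  if (!is.numeric(min_agreement) || min_agreement < 0 || min_agreement > 1) {
    abort_config("min_agreement", "must lie in [0, 1]")
  }
  structure(list(name = name, blocking_keys = blocking_keys,
                 comparison_keys = comparison_keys,
                 min_agreement = min_agreement),
            class = "attr_linkage_pass")
}

#' Default linkage passes
#'
#' Three ordered passes over the quasi-identifiers: (1) exact agreement on
#' date of birth, sex, municipality and ZIP; (2) blocking on date of birth,
#' sex and municipality with 0.75 agreement required over the remaining
#' fields; (3) likewise blocking on date of birth, sex and ZIP.
#'
#' @return A list of [linkage_pass()] objects.
#' @export
default_linkage_passes <- function() {
  list(
    linkage_pass("exact_dob_sex_mun_zip",
                 c("dob", "sex", "municipality", "zip")),
    linkage_pass("dob_sex_mun", c("dob", "sex", "municipality"),
                 min_agreement = 0.75),
    linkage_pass("dob_sex_zip", c("dob", "sex", "zip"),
                 min_agreement = 0.75)
  )
}

#' Clean claims before linkage
#'
#' Normalizes field case/whitespace and rejects records unusable for
#' linkage: unparseable or absent date of birth or claim date, date of
#' birth not before the claim date, or the planted low-quality flag. Kept
#' and rejected tables partition the input.
#'
#' @param table A claims table with the standard columns.
#' @return A list with `kept` and `rejected` (the latter carries a
#'   `reject_reason` column).
#' @export
clean_records <- function(table) {
  assert_columns(table, setdiff(CLAIM_COLUMNS, "length_of_stay"),
                 "claims table")
  df <- table
  for (f in c("sex", "state", "icd10")) {
    df[[f]] <- toupper(trimws(df[[f]]))
  }
  for (f in c("municipality", "zip", "procedure", "dob")) {
    df[[f]] <- trimws(df[[f]])
  }
  dob_parsed <- as.Date(suppressWarnings(
    ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", df$dob), df$dob, NA_character_)))
  claim_date <- as.Date(df$claim_date)

  reason <- rep(NA_character_, nrow(df))
  reason[isTRUE_vec(df$low_quality)] <- "low_quality_flag"
  reason[is.na(claim_date)] <- "missing_claim_date"
  reason[is.na(dob_parsed)] <- "unparseable_dob"
  reason[!is.na(dob_parsed) & !is.na(claim_date) &
           dob_parsed >= claim_date] <- "dob_not_before_claim"

  keep <- is.na(reason)
  kept <- df[keep, , drop = FALSE]
  kept$dob <- format(dob_parsed[keep], "%Y-%m-%d")
  rejected <- df[!keep, , drop = FALSE]
  rejected$reject_reason <- reason[!keep]
  list(kept = kept, rejected = rejected)
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' Multi-pass record linkage into patient journeys
#'
#' Reconstructs longitudinal patient records across the inpatient and
#' outpatient tables. Outpatient records sharing an encrypted patient key
#' are pre-clustered; the configured blocking passes are then applied in
#' order, each merging record clusters whose agreement score reaches the
#' pass threshold (transitive closure within a pass). Records matched in an
#' earlier pass do not participate in later passes. Every cleaned record
#' ends in exactly one journey or in the unlinked table.
#'
#' @param inpatient,outpatient Cleaned claims tables ([clean_records()]).
#' @param passes List of [linkage_pass()] objects, applied in order.
#' @param max_block Safety cap on block size; larger blocks are skipped
#'   with a warning (quasi-identifier blocks should be small).
#' @return A list with `journeys` (claims with an assigned `patient_id`,
#'   date-sorted within patient), `unlinked` (records ineligible for every
#'   pass and never matched), and `report` (per-pass merge counts).
#' @export
link_records <- function(inpatient, outpatient, passes = default_linkage_passes(),
                         max_block = 500) {
  if (!length(passes)) abort_config("passes", "must contain at least one pass")
  stopifnot(all(vapply(passes, inherits, logical(1), "attr_linkage_pass")))

  claims <- dplyr::bind_rows(inpatient, outpatient)
  n <- nrow(claims)
  if (!n) {
    return(list(journeys = claims, unlinked = claims,
                report = list(n_records = 0L, passes = list())))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  # Pre-cluster outpatient records by encrypted patient key.
  key_ok <- !is.na(claims$patient_key) & claims$setting == "outpatient"
  if (any(key_ok)) {
    for (grp in split(which(key_ok), claims$patient_key[key_ok])) {
      if (length(grp) > 1) for (k in grp[-1]) union_(grp[1], k)
    }
  }

  matched <- rep(FALSE, n)
  ever_eligible <- rep(FALSE, n)
  pass_report <- list()

  for (p in passes) {
    eligible <- !matched
    for (bk in p$blocking_keys) {
      eligible <- eligible & !is_missing_field(claims[[bk]])
    }
    ever_eligible <- ever_eligible | eligible
    idx <- which(eligible)
    n_merged <- 0L
    if (length(idx) > 1) {
      block_id <- do.call(paste, c(lapply(p$blocking_keys,
                                          function(k) claims[[k]][idx]),
                                   sep = "\r"))
      for (grp in split(idx, block_id)) {
        if (length(grp) < 2) next
        if (length(grp) > max_block) {
          warning(sprintf("pass '%s': skipping block of %d records",
                          p$name, length(grp)))
          next
        }
        prs <- combn(grp, 2)
        if (length(p$comparison_keys)) {
          score <- rep(0, ncol(prs))
          for (ck in p$comparison_keys) {
            v <- claims[[ck]]
            agree <- !is.na(v[prs[1, ]]) & !is.na(v[prs[2, ]]) &
              v[prs[1, ]] == v[prs[2, ]]
            score <- score + agree
          }
          score <- score / length(p$comparison_keys)
        } else {
          score <- rep(1, ncol(prs))
        }
        acc <- which(score >= p$min_agreement)
        # Deterministic merge order: highest score first, then record order.
        acc <- acc[order(-score[acc], prs[1, acc], prs[2, acc])]
        for (a in acc) {
          union_(prs[1, a], prs[2, a])
          n_merged <- n_merged + 1L
          matched[prs[1, a]] <- TRUE
          matched[prs[2, a]] <- TRUE
        }
      }
    }
    pass_report[[p$name]] <- list(eligible_records = length(idx),
                                  accepted_pairs = n_merged)
  }

  root <- vapply(seq_len(n), find, integer(1))
  cluster_sizes <- table(root)
  in_cluster <- cluster_sizes[as.character(root)] > 1

  unlinked_sel <- !in_cluster & !ever_eligible
  journey_sel <- !unlinked_sel

  # Stable patient ids: order clusters by their smallest record_id.
  roots_j <- unique(root[journey_sel])
  first_rec <- vapply(roots_j, function(r) min(claims$record_id[root == r]),
                      character(1))
  roots_j <- roots_j[order(first_rec)]
  pid_map <- setNames(sprintf("L%06d", seq_along(roots_j)),
                      as.character(roots_j))

  journeys <- claims[journey_sel, , drop = FALSE]
  journeys$patient_id <- unname(pid_map[as.character(root[journey_sel])])
  journeys <- dplyr::arrange(journeys, .data$patient_id, .data$claim_date,
                             .data$record_id)
  unlinked <- claims[unlinked_sel, , drop = FALSE]

  list(journeys = journeys, unlinked = unlinked,
       report = list(n_records = n,
                     n_journeys = length(roots_j),
                     n_unlinked = sum(unlinked_sel),
                     passes = pass_report))
}

#' Pairwise precision and recall of a linkage against the latent truth
#'
#' Treats linkage as clustering: over all record pairs, a true positive is
#' a pair co-assigned by both the linkage and the truth table. Precision is
#' the fraction of predicted co-assignments that are true; recall the
#' fraction of true co-assignments (over every record the supplied truth
#' covers) that the linkage predicted — a truth pair whose records never
#' reached a journey counts as missed.
#'
#' @param journeys Linked claims table (with `patient_id`), as returned in
#'   `link_records()$journeys`.
#' @param truth Truth table with `record_id` and `patient_id`, covering at
#'   least every journey record.
#' @return A list with `precision` and `recall` (both 1 when neither side
#'   has any co-assigned pair).
#' @export
linkage_quality <- function(journeys, truth) {
  missing_ids <- setdiff(journeys$record_id, truth$record_id)
  if (length(missing_ids)) {
    stop(sprintf("%d record ids absent from the truth table", length(missing_ids)),
         call. = FALSE)
  }
  pred <- journeys[, c("record_id", "patient_id")]
  names(pred)[2] <- "pred_id"
  tt <- truth[, c("record_id", "patient_id")]
  names(tt)[2] <- "true_id"
  m <- dplyr::inner_join(pred, tt, by = "record_id")

  pairs2 <- function(k) sum(choose(k, 2))
  cell <- dplyr::count(m, .data$pred_id, .data$true_id)
  tp <- pairs2(cell$n)
  pred_pairs <- pairs2(dplyr::count(m, .data$pred_id)$n)
  true_pairs <- pairs2(dplyr::count(tt, .data$true_id)$n)
  list(
    precision = if (pred_pairs == 0) 1 else tp / pred_pairs,
    recall = if (true_pairs == 0) 1 else tp / true_pairs
  )
}
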