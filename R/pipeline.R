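#' Assemble and validate a full pipeline configuration
#'
#' Bundles the generator, linkage, rule-set, split, classification and
#' reporting settings into one validated object. A single global seed
#' deterministically derives the per-stage seeds, so stages rerun alone
#' reproduce the full run's results.
#'
#' @param generator Named list of [generator_config()] arguments.
#' @param linkage_passes List of [linkage_pass()] objects (or lists of
#'   their arguments); defaults to [default_linkage_passes()].
#' @param rules Named list of [attr_ruleset()] arguments.
#' @param split Named list of [split_spec()] arguments.
#' @param classify List with `neg_ratio`, `threshold`, `include_state`,
#'   `min_reference` (minimum reference cases to attempt classification).
#' @param reporting List with `population_size` (hospitalization-rate
#'   denominator; defaults to the synthetic population size) and `top_n`.
#' @param global_seed Integer master seed.
#' @return An object of class `attr_pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), linkage_passes = NULL,
                            rules = list(), split = list(),
                            classify = list(), reporting = list(),
                            global_seed = 1L) {
  if (is.null(generator$seed)) generator$seed <- derive_seed(global_seed, 1)
  gen_cfg <- do.call(generator_config, generator)

  if (is.null(linkage_passes)) {
    passes <- default_linkage_passes()
  } else {
    passes <- lapply(linkage_passes, function(p) {
      if (inherits(p, "attr_linkage_pass")) p else do.call(linkage_pass, p)
    })
  }
  rule_set <- do.call(attr_ruleset, rules)
  if (is.null(split$seed)) split$seed <- derive_seed(global_seed, 2)
  split_cfg <- do.call(split_spec, split)

  classify <- utils::modifyList(
    list(neg_ratio = 3, threshold = 0.5, include_state = TRUE,
         min_reference = 10L, seed = derive_seed(global_seed, 3)),
    classify)
  reporting <- utils::modifyList(
    list(population_size = gen_cfg$n_patients, top_n = 20L), reporting)
  if (reporting$population_size <= 0) {
    abort_config("reporting$population_size", "must be positive")
  }

  structure(list(generator = gen_cfg, linkage_passes = passes,
                 rules = rule_set, split = split_cfg, classify = classify,
                 reporting = reporting,
                 global_seed = as.integer(global_seed)),
            class = "attr_pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, and checks every field;
#' violations are reported together, each with its field path. Recognized
#' top-level blocks: `generator`, `linkage_passes`, `rules`, `split`,
#' `classify`, `reporting`, `global_seed`; a missing block falls back to
#' the package defaults (the expert-validated code lists for `rules`).
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return A validated `attr_pipeline_config`.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else {
    path
  }
  raw <- raw %||% list()
  gen <- raw$generator %||% list()
  if (!is.null(gen$class_mix)) gen$class_mix <- unlist(gen$class_mix)
  if (!is.null(gen$study_window)) gen$study_window <- as.Date(unlist(gen$study_window))
  if (!is.null(gen$claims_per_patient)) {
    gen$claims_per_patient <- as.list(gen$claims_per_patient)
  }
  tryCatch(
    pipeline_config(
      generator = gen,
      linkage_passes = raw$linkage_passes,
      rules = lapply(raw$rules %||% list(), unlist),
      split = raw$split %||% list(),
      classify = raw$classify %||% list(),
      reporting = raw$reporting %||% list(),
      global_seed = raw$global_seed %||% 1L),
    error = function(e) stop("configuration rejected: ", conditionMessage(e),
                             call. = FALSE))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
}

#' Run the full case-finding pipeline
#'
#' Executes simulate, clean + link, cohort cascade, classification and
#' reporting in order, writing every artifact and a run manifest into
#' `outdir`. Reruns with an identical configuration produce byte-identical
#' tables and reports.
#'
#' @param config An `attr_pipeline_config` ([pipeline_config()] or
#'   [validate_config()]).
#' @param outdir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The run manifest (invisibly written to `manifest.json`):
#'   config hash, seeds, per-stage row counts, timings, package version.
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "attr_pipeline_config"))
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite) {
    stop("output directory is not empty (use overwrite = TRUE): ", outdir,
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("attrclaims")),
                   global_seed = config$global_seed,
                   stages = list(), timings = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # configuration snapshot + hash
  cfg_path <- file.path(outdir, "config_snapshot.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  sim <- stage("simulate", {
    s <- simulate_claims(config$generator)
    write_claims_tables(s, outdir)
    s
  })
  manifest$stages$simulate <- list(
    n_patients = nrow(sim$patients),
    n_inpatient = nrow(sim$inpatient),
    n_outpatient = nrow(sim$outpatient))

  linked <- stage("link", {
    cin <- clean_records(sim$inpatient)
    cout <- clean_records(sim$outpatient)
    lk <- link_records(cin$kept, cout$kept, config$linkage_passes)
    readr::write_csv(lk$journeys, file.path(outdir, "journeys.csv"))
    readr::write_csv(dplyr::bind_rows(cin$rejected, cout$rejected),
                     file.path(outdir, "rejected_records.csv"))
    write_json_report(c(lk$report,
                        list(n_rejected = nrow(cin$rejected) + nrow(cout$rejected))),
                      file.path(outdir, "linkage_report.json"))
    c(lk, list(n_rejected = nrow(cin$rejected) + nrow(cout$rejected),
               n_input = nrow(sim$inpatient) + nrow(sim$outpatient)))
  })
  manifest$stages$link <- list(
    n_input = linked$n_input, n_rejected = linked$n_rejected,
    n_linked = nrow(linked$journeys), n_unlinked = nrow(linked$unlinked),
    n_journeys = linked$report$n_journeys)

  assignments <- stage("cohort", {
    asg <- build_cohorts(linked$journeys, config$rules)
    readr::write_csv(asg, file.path(outdir, "assignments.csv"))
    write_json_report(attr(asg, "audit"),
                      file.path(outdir, "cascade_audit.json"))
    asg
  })
  manifest$stages$cohort <- lapply(
    split(assignments$label, assignments$cohort),
    function(x) as.list(table(x)))

  cls <- stage("classify", {
    out <- list(like_labels = tibble::tibble(patient_id = character(),
                                             cohort = character(),
                                             prob = numeric(),
                                             class = character()),
                reports = list())
    for (cohort in unique(assignments$cohort)) {
      res <- classify_cohort(linked$journeys, assignments, cohort,
                             config$rules, config$split,
                             neg_ratio = config$classify$neg_ratio,
                             threshold = config$classify$threshold,
                             include_state = config$classify$include_state,
                             min_reference = config$classify$min_reference,
                             seed = config$classify$seed)
      out$reports[[cohort]] <- res$report
      if (!is.null(res$like_labels) && nrow(res$like_labels)) {
        res$like_labels$cohort <- cohort
        out$like_labels <- dplyr::bind_rows(out$like_labels, res$like_labels)
      }
    }
    readr::write_csv(out$like_labels, file.path(outdir, "like_labels.csv"))
    write_json_report(out$reports, file.path(outdir, "classifier_report.json"))
    out
  })
  manifest$stages$classify <- lapply(cls$reports, function(r) {
    list(status = r$status, winner = r$winner %||% NA,
         test_accuracy = r$test_metrics$accuracy %||% NA)
  })

  stage("report", {
    fl <- final_labels(assignments, cls$like_labels)
    readr::write_csv(fl, file.path(outdir, "final_assignments.csv"))
    ct <- classification_table(assignments, cls$like_labels)
    readr::write_csv(ct, file.path(outdir, "classification_table.csv"))
    demo <- demographics_summary(fl)
    readr::write_csv(demo$age, file.path(outdir, "demographics_age.csv"))
    readr::write_csv(demo$age_groups,
                     file.path(outdir, "demographics_age_groups.csv"))
    readr::write_csv(demo$sex, file.path(outdir, "demographics_sex.csv"))
    readr::write_csv(state_distribution(fl),
                     file.path(outdir, "state_distribution.csv"))

    years <- as.integer(format(config$generator$study_window[1], "%Y")):
      as.integer(format(config$generator$study_window[2], "%Y"))
    rates <- list()
    for (cohort in unique(fl$cohort)) {
      for (grp in c("reference", "like")) {
        pats <- fl$patient_id[fl$cohort == cohort & fl$final_label == grp]
        if (!length(pats)) next
        r <- annual_hospitalization_rate(
          linked$journeys[linked$journeys$patient_id %in% pats, ],
          config$reporting$population_size, years, config$rules)
        r$cohort <- cohort
        r$group <- grp
        rates[[length(rates) + 1]] <- r
      }
    }
    rates <- dplyr::bind_rows(rates)
    readr::write_csv(rates, file.path(outdir, "hospitalization_rates.csv"))

    hc <- hcru_summary(fl, linked$journeys, config$rules)
    readr::write_csv(hc$metrics, file.path(outdir, "hcru_metrics.csv"))
    readr::write_csv(hc$flags, file.path(outdir, "hcru_flags.csv"))
    readr::write_csv(top_procedures(fl, linked$journeys,
                                    config$reporting$top_n),
                     file.path(outdir, "top_procedures.csv"))

    headline <- headline_numbers(fl, assignments)
    write_json_report(headline, file.path(outdir, "headline.json"))
    NULL
  })

  write_json_report(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}

# Totals the reporting layer leads with.
headline_numbers <- function(final_assignments, assignments) {
  out <- list()
  for (cohort in unique(final_assignments$cohort)) {
    fl <- final_assignments[final_assignments$cohort == cohort, ]
    n_ref <- sum(fl$final_label == "reference")
    n_like <- sum(fl$final_label == "like")
    n_non <- sum(fl$final_label == "non")
    n_pool <- sum(fl$label %in% c("reference", "potential", "out_of_cohort"))
    out[[cohort]] <- list(
      cohort_pool = n_pool, reference = n_ref, like = n_like, non = n_non,
      total_cases = n_ref + n_like,
      prevalence_among_pool_pct =
        if (n_pool > 0) prevalence(n_ref, n_pool, 100, digits = 2) else NA)
  }
  out
}

serialize_config <- function(config) {
  gen <- config$generator
  list(
    global_seed = config$global_seed,
    generator = list(
      n_patients = gen$n_patients,
      class_mix = as.list(gen$class_mix),
      claims_per_patient = gen$claims_per_patient,
      study_window = format(gen$study_window),
      noise = gen$noise, p_inpatient = gen$p_inpatient, seed = gen$seed),
    linkage_passes = lapply(config$linkage_passes, function(p) {
      list(name = p$name, blocking_keys = p$blocking_keys,
           comparison_keys = p$comparison_keys,
           min_agreement = p$min_agreement)
    }),
    rules = config$rules[c("hattr_icds", "wtattr_icds",
                           "cardiac_required_icds", "cardiac_related_icds",
                           "exclusion_icds", "mandatory_procedures",
                           "secondary_procedures", "min_age_hattr",
                           "min_age_wtattr")],
    split = unclass(config$split),
    classify = config$classify,
    reporting = config$reporting)
}

#' Train, select, evaluate and apply the classifier for one cohort
#'
#' Composes the classifier stage: training-frame assembly, stratified
#' 60/20/20 split, model selection with K-fold cross-validation,
#' evaluation on the held-out test partition, and classification of the
#' potential pool. Cohorts with too few reference cases to train on are
#' skipped with a status note.
#'
#' @param journeys Linked claims table.
#' @param assignments [build_cohorts()] output.
#' @param cohort `"hattr"` or `"wtattr"`.
#' @param rules An [attr_ruleset()].
#' @param spec An [split_spec()].
#' @param neg_ratio,threshold,include_state,seed Classifier settings (see
#'   [build_training_frame()] and [classify_potential()]).
#' @param min_reference Minimum reference cases needed to train.
#' @return A list: `model`, `report` (selection report, test metrics,
#'   status), `like_labels` (classification of the potential pool).
#' @export
classify_cohort <- function(journeys, assignments, cohort, rules,
                            spec = split_spec(), neg_ratio = 3,
                            threshold = 0.5, include_state = TRUE,
                            min_reference = 10L, seed = 1L) {
  asg <- assignments[assignments$cohort == cohort, ]
  n_ref <- sum(asg$label == "reference")
  if (n_ref < min_reference) {
    return(list(model = NULL,
                report = list(status = "skipped_too_few_reference",
                              n_reference = n_ref),
                like_labels = NULL))
  }
  frame <- build_training_frame(journeys, assignments, cohort, rules,
                                neg_ratio = neg_ratio, seed = seed,
                                include_state = include_state)
  parts <- split_dataset(frame, spec)
  model <- select_model(parts$train, parts$validation, spec,
                        threshold = threshold)
  test_metrics <- evaluate_model(model, parts$test)

  pot <- asg[asg$label == "potential", c("patient_id", "index_date")]
  pool_claims <- journeys[journeys$patient_id %in% pot$patient_id, ]
  pool <- build_features(pool_claims, rules, index_dates = pot,
                         include_state = include_state)
  like_labels <- classify_potential(model, pool)
  if (nrow(like_labels)) like_labels$cohort <- cohort

  list(model = model,
       report = list(status = "ok", winner = model$family,
                     n_reference = n_ref,
                     n_negatives = sum(frame$y == "0"),
                     n_potential = nrow(pot),
                     selection = model$selection_report,
                     test_metrics = test_metrics),
       like_labels = like_labels)
}

#' A small demonstration pipeline configuration
#'
#' Synthetic study at a desk-scale size with the default latent class mix,
#' emission distributions, noise model and linkage passes.
#'
#' @param n_patients Population size.
#' @param global_seed Master seed.
#' @return An `attr_pipeline_config`.
#' @export
demo_pipeline_config <- function(n_patients = 5000, global_seed = 20210101) {
  pipeline_config(generator = list(n_patients = n_patients),
                  global_seed = global_seed)
}
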