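# End-to-end orchestration: synthesize or read a cohort, assign sites,
# classify metastasis, adjudicate, and compute the agreement and balance
# statistics, with per-stage row-count logging and full determinism under a
# fixed seed.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate via [simulate_cohort()]) or
#'   `"files"` (read via [read_cohort()]).
#' @param sim A [sim_config()] (synthetic mode; carries the seed).
#' @param input_dir Cohort bundle directory (files mode).
#' @param window_start,window_end Diagnosis window; defaults to the
#'   simulation window in synthetic mode.
#' @param grouper,codes,med_map,rules Knowledge bases; packaged defaults.
#' @param methods Metastasis classifiers to run (at least `icd` and `nlp`
#'   are required for adjudication).
#' @param balance_group,balance_variables Optional covariate-balance
#'   grouping column and variables (looked up in the truth table in
#'   synthetic mode).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       sim = NULL, input_dir = NULL,
                       window_start = NULL, window_end = NULL,
                       grouper = read_grouper(),
                       codes = default_met_codes(),
                       med_map = read_met_meds(),
                       rules = default_assertion_rules(),
                       methods = met_method_names(),
                       balance_group = "prom_completed",
                       balance_variables = c("portal_use", "site_b",
                                             "adjudication")) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && !inherits(sim, "sim_config")) {
    abort("Synthetic mode requires a sim_config (which carries the seed)",
          class = "oncophen_config_error")
  }
  if (mode == "files") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      abort("Files mode requires an existing input_dir",
            class = "oncophen_config_error")
    }
  }
  if (!length(methods)) {
    abort("No classifiers enabled", class = "oncophen_config_error")
  }
  if (!all(c("icd", "nlp") %in% methods)) {
    abort("The icd and nlp classifiers are required for adjudication",
          class = "oncophen_config_error")
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 window_start = window_start, window_end = window_end,
                 grouper = grouper, codes = codes, med_map = med_map,
                 rules = rules, methods = methods,
                 balance_group = balance_group,
                 balance_variables = balance_variables),
            class = "run_config")
}

#' Run the full phenotyping pipeline
#'
#' Stages: acquire cohort, check eligibility, filter diagnoses, assign sites
#' (three methods), classify metastasis (six classifiers), adjudicate,
#' compute per-site method counts, detection fractions, site and
#' metastasis agreement, combination counts, and (when a grouping variable
#' is available) the covariate balance table. Row counts are logged per
#' stage; output is deterministic given the configuration and its seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: report tables are rendered there via
#'   [write_report_tables()].
#' @param quiet Suppress stage logging.
#' @return A results list of class `oncophen_results`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }

  cohort <- if (config$mode == "synthetic") {
    simulate_cohort(config$sim)
  } else {
    read_cohort(config$input_dir)
  }
  ws <- as.Date(config$window_start %||% cohort$window_start %||%
                  min(cohort$diagnoses$date))
  we <- as.Date(config$window_end %||% cohort$window_end %||%
                  max(cohort$diagnoses$date))
  say("cohort: %d diagnosis rows, %d notes, window %s..%s",
      nrow(cohort$diagnoses), nrow(cohort$notes), ws, we)

  eligible <- eligible_patients(cohort, config$grouper)
  all_ids <- sort(unique(cohort$diagnoses$patient_id))
  say("eligibility: %d of %d patients eligible (%d excluded)",
      length(eligible), length(all_ids), length(all_ids) - length(eligible))
  if (!length(eligible)) {
    abort("Stage eligibility: no eligible patients",
          class = "oncophen_error")
  }

  dx <- filter_diagnoses(cohort$diagnoses, ws, we)
  say("diagnosis filter: %d -> %d rows", nrow(cohort$diagnoses), nrow(dx))

  sites <- assign_sites(cohort, config$grouper, ws, we, patients = eligible)
  say("site assignment: %d patients", nrow(sites))

  met_calls <- classify_metastasis(cohort, sites, ws, we,
                                   codes = config$codes,
                                   med_map = config$med_map,
                                   rules = config$rules,
                                   patients = eligible)
  say("metastasis calls: %d patients, %d adjudicated metastatic",
      nrow(met_calls), sum(met_calls$adjudication == "metastatic"))

  counts <- site_method_counts(sites)
  nonzero <- counts[counts$n_a > 0, ]
  attr(nonzero, "n_total") <- attr(counts, "n_total")
  det <- detection_fraction(nonzero)
  site_agr <- site_agreement(nonzero)
  met_agr <- met_agreement(met_calls)
  combos <- combination_counts(met_calls)
  say("agreement: %d site rows, %d classifier pairs",
      nrow(site_agr), nrow(met_agr))

  balance <- NULL
  if (!is.null(config$balance_group) && !is.null(cohort$truth)) {
    bal_data <- cohort$truth %>%
      left_join(select(sites, "patient_id", "site_b"), by = "patient_id") %>%
      left_join(select(met_calls, "patient_id", "adjudication"),
                by = "patient_id") %>%
      filter(.data$patient_id %in% eligible)
    vars <- intersect(config$balance_variables, names(bal_data))
    if (config$balance_group %in% names(bal_data) && length(vars)) {
      balance <- balance_table(bal_data, config$balance_group, vars)
      say("balance: %d variables, max SMD %.3f", nrow(balance),
          max(balance$smd))
    }
  }

  results <- structure(list(
    cohort = cohort, eligible = eligible, sites = sites,
    site_counts = counts, detection = det, site_agreement = site_agr,
    met_calls = met_calls, met_agreement = met_agr,
    combination_counts = combos, balance = balance,
    manifest = list(mode = config$mode,
                    seed = if (!is.null(config$sim)) config$sim$seed,
                    n_patients = nrow(met_calls),
                    window = c(as.character(ws), as.character(we)),
                    package_version = as.character(
                      utils::packageVersion("oncophen"))),
    log = log
  ), class = "oncophen_results")

  if (!is.null(out_dir)) {
    write_report_tables(results, out_dir)
    jsonlite::write_json(results$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("report tables written to %s", out_dir)
  }
  results
}

#' @export
print.oncophen_results <- function(x, ...) {
  cat("<oncophen_results>\n")
  cat(sprintf("  %d patients; %d adjudicated metastatic, %d uncertain\n",
              nrow(x$met_calls),
              sum(x$met_calls$adjudication == "metastatic"),
              sum(x$met_calls$adjudication == "uncertain")))
  icd_nlp <- x$met_agreement %>%
    filter(.data$method1 == "icd", .data$method2 == "nlp")
  if (nrow(icd_nlp)) {
    cat(sprintf("  icd-nlp kappa %.2f (n = %d)\n",
                round_half_up(icd_nlp$kappa, 2), icd_nlp$n_used))
  }
  invisible(x)
}
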