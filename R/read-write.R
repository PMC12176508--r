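# Readers and writers for the flat-file EHR interchange formats.
# One file per entity: diagnoses.csv, notes.jsonl, registry.csv, plans.csv,
# meds.csv, encounters.csv. All dates are ISO-8601 calendar dates.

dx_sources <- c("encounter", "hospital", "problem_list")
dx_statuses <- c("active", "deleted")

cohort_entities <- function() {
  c("diagnoses", "notes", "registry", "plans", "meds", "encounters")
}

empty_entity <- function(entity) {
  switch(entity,
    diagnoses = tibble(patient_id = character(), code = character(),
                       source = character(), status = character(),
                       date = as.Date(character())),
    notes = tibble(patient_id = character(), date = as.Date(character()),
                   text = character()),
    registry = tibble(patient_id = character(),
                      distant_at_diagnosis = logical()),
    plans = tibble(patient_id = character(), goal = character()),
    meds = tibble(patient_id = character(), drug = character(),
                  date = as.Date(character())),
    encounters = tibble(patient_id = character(), department = character(),
                        visit_type = character(), description = character(),
                        date = as.Date(character()))
  )
}

validate_diagnoses <- function(dx, file = NULL) {
  dx$patient_id <- as.character(dx$patient_id)
  if (any(is.na(dx$code) | dx$code == "")) {
    row <- which(is.na(dx$code) | dx$code == "")[1]
    abort(sprintf("Empty diagnosis code%s (row %d, field 'code')",
                  if (is.null(file)) "" else paste0(" in ", file), row),
          class = "oncophen_parse_error")
  }
  dx$source <- norm_enum(dx$source, dx_sources, "source", file)
  dx$status <- norm_enum(dx$status, dx_statuses, "status", file)
  bad <- dx$status == "deleted" & dx$source != "problem_list"
  if (any(bad)) {
    row <- which(bad)[1]
    abort(sprintf(
      "Deleted status outside the problem list%s (row %d, field 'status'): only problem-list entries can be marked deleted",
      if (is.null(file)) "" else paste0(" in ", file), row),
      class = "oncophen_parse_error")
  }
  dx$date <- as_date_strict(dx$date, "date", file)
  as_tibble(dx[c("patient_id", "code", "source", "status", "date")])
}

#' Read an EHR cohort bundle from flat files
#'
#' Reads the six entity files of a cohort extract into typed tibbles. CSV for
#' tabular entities; JSON-lines for notes (one note object per line, fields
#' `patient_id`, `date`, `text`). Enum fields are case-normalized before
#' validation; any schema violation errors with the file, row, and field.
#' A `truth.csv` beside the entity files (written by [simulate_cohort()]) is
#' read back when present.
#'
#' @param dir Directory holding the entity files, or a named list of paths
#'   (names among `diagnoses`, `notes`, `registry`, `plans`, `meds`,
#'   `encounters`, `truth`).
#' @return A list of tibbles of class `ehr_cohort`.
#' @export
read_cohort <- function(dir) {
  paths <- if (is.list(dir)) {
    dir
  } else {
    p <- list(
      diagnoses = file.path(dir, "diagnoses.csv"),
      notes = file.path(dir, "notes.jsonl"),
      registry = file.path(dir, "registry.csv"),
      plans = file.path(dir, "plans.csv"),
      meds = file.path(dir, "meds.csv"),
      encounters = file.path(dir, "encounters.csv"),
      truth = file.path(dir, "truth.csv")
    )
    p[file.exists(unlist(p)) | names(p) == "diagnoses"]
  }
  if (is.null(paths$diagnoses) || !file.exists(paths$diagnoses)) {
    abort("Cohort bundle must include a diagnoses file",
          class = "oncophen_parse_error")
  }
  read_csv_chr <- function(path) {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  out <- list()
  out$diagnoses <- validate_diagnoses(read_csv_chr(paths$diagnoses),
                                      paths$diagnoses)
  out$notes <- if (!is.null(paths$notes)) {
    lines <- readLines(paths$notes, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) empty_entity("notes") else {
      recs <- purrr::map(lines, jsonlite::fromJSON)
      tibble(
        patient_id = purrr::map_chr(recs, ~ as.character(.x$patient_id)),
        date = as_date_strict(purrr::map_chr(recs, ~ as.character(.x$date)),
                              "date", paths$notes),
        text = purrr::map_chr(recs, ~ as.character(.x$text %||% ""))
      )
    }
  } else empty_entity("notes")
  out$registry <- if (!is.null(paths$registry)) {
    r <- read_csv_chr(paths$registry)
    tibble(patient_id = as.character(r$patient_id),
           distant_at_diagnosis =
             norm_str(r$distant_at_diagnosis) %in% c("true", "1", "yes"))
  } else empty_entity("registry")
  out$plans <- if (!is.null(paths$plans)) {
    p <- read_csv_chr(paths$plans)
    g <- as.character(p$goal)
    g[!is.na(g) & g == ""] <- NA_character_
    tibble(patient_id = as.character(p$patient_id), goal = g)
  } else empty_entity("plans")
  out$meds <- if (!is.null(paths$meds)) {
    m <- read_csv_chr(paths$meds)
    tibble(patient_id = as.character(m$patient_id),
           drug = as.character(m$drug),
           date = as_date_strict(m$date, "date", paths$meds))
  } else empty_entity("meds")
  out$encounters <- if (!is.null(paths$encounters)) {
    e <- read_csv_chr(paths$encounters)
    tibble(patient_id = as.character(e$patient_id),
           department = as.character(e$department),
           visit_type = as.character(e$visit_type),
           description = as.character(e$description),
           date = as_date_strict(e$date, "date", paths$encounters))
  } else empty_entity("encounters")
  if (!is.null(paths$truth) && file.exists(paths$truth)) {
    tr <- readr::read_csv(paths$truth, col_types = readr::cols(
      patient_id = "c", sites = "c", metastatic = "l",
      prom_completed = "l", portal_use = "l", .default = "c"
    ), progress = FALSE)
    out$truth <- as_tibble(tr)
  }
  structure(out, class = "ehr_cohort")
}

#' Write an EHR cohort bundle to flat files
#'
#' Inverse of [read_cohort()]: one CSV per tabular entity, JSON-lines for
#' notes, dates rendered ISO-8601. Reading the written bundle back yields
#' identical records.
#'
#' @param cohort An `ehr_cohort` list (e.g. from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")), na = "")
  }
  wcsv(cohort$diagnoses, "diagnoses")
  wcsv(cohort$registry, "registry")
  wcsv(cohort$plans, "plans")
  wcsv(cohort$meds, "meds")
  wcsv(cohort$encounters, "encounters")
  con <- file(file.path(dir, "notes.jsonl"), "w")
  on.exit(close(con))
  if (nrow(cohort$notes)) {
    lines <- purrr::pmap_chr(cohort$notes, function(patient_id, date, text) {
      jsonlite::toJSON(list(patient_id = patient_id,
                            date = format(date, "%Y-%m-%d"),
                            text = text), auto_unbox = TRUE)
    })
    writeLines(lines, con)
  }
  if (!is.null(cohort$truth)) wcsv(cohort$truth, "truth")
  invisible(dir)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>\n")
  for (e in intersect(c(cohort_entities(), "truth"), names(x))) {
    cat(sprintf("  %-10s %6d rows\n", e, nrow(x[[e]])))
  }
  invisible(x)
}

#' Render the pipeline's report tables
#'
#' Writes machine-readable CSVs and aligned plain-text renderings of the
#' three result tables: per-site method counts with agreement, per-method
#' metastasis calls with the pairwise kappa matrix, and the covariate balance
#' table. Percentages are displayed to one decimal and kappa/SMD to two, both
#' half-up; rounding happens only here, never upstream.
#'
#' @param results A results bundle from [run_pipeline()] (needs components
#'   `site_agreement`, `met_calls`, `met_agreement`; `balance` optional).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  need <- c("site_agreement", "met_calls", "met_agreement")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort(paste0("Cannot render report tables; missing upstream result(s): ",
                 paste(miss, collapse = ", ")), class = "oncophen_error")
  }
  if (!nrow(results$met_calls)) {
    abort("Cannot render report tables for an empty cohort",
          class = "oncophen_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sa <- tidy(results$site_agreement)
  sa_disp <- sa %>%
    mutate(dplyr::across(dplyr::starts_with("kappa"),
                         ~ sprintf("%.2f", round_half_up(.x, 2))))
  readr::write_csv(sa_disp, file.path(dir, "site_agreement.csv"))

  n_pat <- nrow(results$met_calls)
  met_long <- results$met_calls %>%
    tidyr::pivot_longer(dplyr::all_of(met_method_names()),
                        names_to = "method", values_to = "call") %>%
    count(.data$method, .data$call) %>%
    mutate(pct = fmt_pct(.data$n, n_pat))
  readr::write_csv(met_long, file.path(dir, "met_calls_summary.csv"))

  ma <- tidy(results$met_agreement) %>%
    mutate(kappa = sprintf("%.2f", round_half_up(.data$kappa, 2)))
  readr::write_csv(ma, file.path(dir, "met_agreement.csv"))

  if (!is.null(results$balance)) {
    bt <- tidy(results$balance) %>%
      mutate(smd = sprintf("%.2f", round_half_up(.data$smd, 2)))
    readr::write_csv(bt, file.path(dir, "balance.csv"))
  }

  txt <- c(
    "Site-method agreement (kappa, two decimals half-up)",
    utils::capture.output(print(as.data.frame(sa_disp), row.names = FALSE)),
    "",
    sprintf("Metastasis calls by method (N = %d)", n_pat),
    utils::capture.output(print(as.data.frame(met_long), row.names = FALSE))
  )
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
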