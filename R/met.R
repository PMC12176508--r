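# The six tri-state metastasis classifiers and the adjudication rule over
# the two whole-cohort classifiers (diagnosis codes and the text engine).
# Each classifier returns yes / no / missing per patient; "missing" means
# the classifier's source data is absent for that patient and is never
# imputed.

call_levels <- c("yes", "no", "missing")

#' Metastasis call from diagnosis codes
#'
#' Yes iff at least one filtered event carries a distant-metastasis code
#' (see [default_met_codes()]); regional lymph-node codes never qualify.
#' Every cohort patient has diagnosis data, so this classifier never returns
#' missing.
#'
#' @param events Diagnosis tibble already passed through
#'   [filter_diagnoses()] (same window and deleted-entry rules as site
#'   assignment).
#' @param patients Patient ids to call.
#' @param codes A `met_code_set`.
#' @return Tibble `patient_id`, `icd`.
#' @export
call_icd <- function(events, patients, codes = default_met_codes()) {
  hit <- unique(events$patient_id[is_met_code(events$code, codes)])
  tibble(patient_id = patients,
         icd = ifelse(patients %in% hit, "yes", "no"))
}

#' Metastasis call from tumor-registry stage at diagnosis
#'
#' Registry intake captures distant spread at diagnosis only; patients not
#' in the registry are missing, and a registry "no" stays no even if the
#' disease later progresses (the registry is not updated longitudinally).
#'
#' @param registry Tibble `patient_id`, `distant_at_diagnosis`.
#' @param patients Patient ids to call.
#' @return Tibble `patient_id`, `registry`.
#' @export
call_registry <- function(registry, patients) {
  m <- match(patients, registry$patient_id)
  call <- ifelse(is.na(m), "missing",
                 ifelse(registry$distant_at_diagnosis[m], "yes", "no"))
  tibble(patient_id = patients, registry = call)
}

#' Metastasis call from treatment-plan goals
#'
#' Yes iff any plan's goal is "Palliative" or "Control" (case-insensitive);
#' goals present but none qualifying is no; no plan, or plans without any
#' stated goal, is missing (a goal can be absent even when a plan exists).
#'
#' @param plans Tibble `patient_id`, `goal` (goal may be `NA`).
#' @param patients Patient ids to call.
#' @return Tibble `patient_id`, `treatment_plan`.
#' @export
call_treatment_plan <- function(plans, patients) {
  g <- plans %>% filter(!is.na(.data$goal)) %>%
    mutate(qual = norm_str(.data$goal) %in% c("palliative", "control")) %>%
    group_by(.data$patient_id) %>%
    summarise(any_qual = any(.data$qual), .groups = "drop")
  m <- match(patients, g$patient_id)
  call <- ifelse(is.na(m), "missing", ifelse(g$any_qual[m], "yes", "no"))
  tibble(patient_id = patients, treatment_plan = call)
}

#' Metastasis call from incurable-indication medications
#'
#' Yes iff an ordered drug indicates incurable disease of a site the
#' patient actually carries (any-category site assignment intersected with
#' the sites the medication map covers). Patients without medication data
#' are missing.
#'
#' @param meds Tibble `patient_id`, `drug`, `date`.
#' @param sites_a Tibble `patient_id`, `sites_a` (list column, Method A
#'   sites), e.g. from [assign_sites()].
#' @param patients Patient ids to call.
#' @param med_map A `met_med_map` from [read_met_meds()].
#' @return Tibble `patient_id`, `medications`.
#' @export
call_medications <- function(meds, sites_a, patients,
                             med_map = read_met_meds()) {
  valid <- attr(med_map, "valid_sites")
  site_of <- setNames(med_map$site, med_map$drug)
  pt_sites <- setNames(sites_a$sites_a, sites_a$patient_id)
  m <- meds %>%
    mutate(drug_site = unname(site_of[norm_str(.data$drug)])) %>%
    group_by(.data$patient_id) %>%
    summarise(hits = list(unique(.data$drug_site[!is.na(.data$drug_site)])),
              .groups = "drop")
  has_data <- unique(meds$patient_id)
  hit_sites <- setNames(m$hits, m$patient_id)
  call <- purrr::map_chr(patients, function(p) {
    if (!p %in% has_data) return("missing")
    hs <- hit_sites[[p]] %||% character()
    ps <- intersect(pt_sites[[p]] %||% character(), valid)
    if (length(intersect(hs, ps))) "yes" else "no"
  })
  tibble(patient_id = patients, medications = call)
}

#' Metastasis call from phase I trial encounters
#'
#' Yes iff the patient has an encounter in the phase-I-trials clinic whose
#' description contains the phrase "Trial" (case-sensitive by default, per
#' how such visit descriptions are capitalized); absence of such an
#' encounter is uninformative, so the classifier returns missing, never no.
#'
#' @param encounters Encounter tibble.
#' @param patients Patient ids to call.
#' @param ignore_case Match "trial" case-insensitively.
#' @return Tibble `patient_id`, `phase1_trial`.
#' @export
call_phase1 <- function(encounters, patients, ignore_case = FALSE) {
  dep <- norm_str(encounters$department)
  in_clinic <- stringr::str_detect(dep, "phase (1|i)\\b") & !is.na(dep)
  desc <- encounters$description
  has_trial <- if (ignore_case) {
    stringr::str_detect(tolower(desc), stringr::fixed("trial"))
  } else {
    stringr::str_detect(desc, stringr::fixed("Trial"))
  }
  hit <- unique(encounters$patient_id[in_clinic & has_trial &
                                        !is.na(has_trial)])
  tibble(patient_id = patients,
         phase1_trial = ifelse(patients %in% hit, "yes", "missing"))
}

#' Adjudicate metastatic status from the two primary classifiers
#'
#' Conservative rule: metastatic only when the diagnosis-code and text
#' classifiers both say yes; not metastatic when both say no; uncertain when
#' they disagree. Both inputs must be yes/no — these two classifiers cover
#' the whole cohort and never return missing.
#'
#' @param icd,nlp Character vectors of `"yes"`/`"no"` calls.
#' @return Character vector: `"metastatic"`, `"not_metastatic"`,
#'   `"uncertain"`.
#' @export
adjudicate <- function(icd, nlp) {
  if (length(icd) != length(nlp)) {
    abort("icd and nlp call vectors must have equal length",
          class = "oncophen_error")
  }
  if (any(!icd %in% c("yes", "no")) || any(!nlp %in% c("yes", "no"))) {
    abort("Adjudication requires yes/no calls from both primary classifiers",
          class = "oncophen_error")
  }
  ifelse(icd == "yes" & nlp == "yes", "metastatic",
         ifelse(icd == "no" & nlp == "no", "not_metastatic", "uncertain"))
}

#' Run all six metastasis classifiers and adjudicate
#'
#' @param cohort An `ehr_cohort`.
#' @param sites Site assignments from [assign_sites()] (Method A feeds the
#'   medication classifier).
#' @param window_start,window_end Diagnosis window for the code classifier.
#' @param codes,med_map,rules Classifier knowledge bases.
#' @param patients Patient ids (default: all with diagnoses).
#' @param possible_as_yes Passed to [summarize_patient()].
#' @return Tibble: `patient_id`, six call columns, `adjudication`.
#' @export
classify_metastasis <- function(cohort, sites,
                                window_start = min(cohort$diagnoses$date),
                                window_end = max(cohort$diagnoses$date),
                                codes = default_met_codes(),
                                med_map = read_met_meds(),
                                rules = default_assertion_rules(),
                                patients = NULL,
                                possible_as_yes = FALSE) {
  patients <- patients %||% sort(unique(cohort$diagnoses$patient_id))
  dx <- filter_diagnoses(cohort$diagnoses, window_start, window_end)
  mentions <- nlp_mentions(cohort$notes, rules)
  nlp <- summarize_patient(mentions, patients, possible_as_yes)
  out <- call_icd(dx, patients, codes) %>%
    left_join(nlp, by = "patient_id") %>%
    left_join(call_registry(cohort$registry, patients), by = "patient_id") %>%
    left_join(call_treatment_plan(cohort$plans, patients),
              by = "patient_id") %>%
    left_join(call_medications(cohort$meds, sites, patients, med_map),
              by = "patient_id") %>%
    left_join(call_phase1(cohort$encounters, patients), by = "patient_id")
  out$adjudication <- adjudicate(out$icd, out$nlp)
  out
}

#' Patients classifiable as metastatic by k of the five methods
#'
#' Histogram over the number of "yes" calls per patient across the five
#' classifiers with usable agreement data (the phase-I-trial classifier is
#' excluded); missing counts as not-yes. The histogram always sums to the
#' cohort size.
#'
#' @param calls Output of [classify_metastasis()].
#' @return Tibble `k` (0-5), `n`.
#' @export
combination_counts <- function(calls) {
  methods <- c("icd", "nlp", "registry", "treatment_plan", "medications")
  yes_k <- rowSums(as.matrix(calls[methods]) == "yes")
  counts <- vapply(0:5, function(i) sum(yes_k == i), integer(1))
  tibble(k = 0:5, n = counts)
}
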