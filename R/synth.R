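# Synthetic EHR cohort generator. Every entity the readers consume is
# emitted together with a ground-truth table (true sites, true metastatic
# state, realized per-classifier calls), so each downstream stage can be
# tested against known labels. Classifier calls are drawn conditionally on
# the true metastatic state at configured operating points
# (sensitivity/specificity/missingness); the emitted records are then
# constructed to realize exactly those calls.

default_operating_points <- function() {
  list(
    icd = c(sens = 0.90, spec = 0.90, miss = 0.000),
    nlp = c(sens = 0.90, spec = 0.90, miss = 0.000),
    registry = c(sens = 0.60, spec = 0.97, miss = 0.522),
    treatment_plan = c(sens = 0.75, spec = 0.80, miss = 0.690),
    medications = c(sens = 0.25, spec = 0.98, miss = 0.038),
    phase1_trial = c(sens = 0.05, spec = 0.999, miss = 0.000)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a large medical-oncology cohort: a site
#' mixture proportional to published any-category per-site counts, one true
#' site for about two-thirds of patients (two for a quarter, three for the
#' rest), and per-classifier operating points reflecting each data source's
#' coverage (the registry covers about half the cohort, treatment-plan goals
#' about a third, medication data nearly everyone; the phase-I-trial signal
#' is rare and can never produce an explicit "no").
#'
#' @param n_patients Number of patients.
#' @param site_mixture Named probability vector over the 12 valid sites.
#' @param p_multi_site Probability vector for 1, 2, and 3 true sites.
#' @param p_metastatic True metastatic prevalence.
#' @param operating_points Named list per classifier with `sens`, `spec`,
#'   `miss` in `[0, 1]`.
#' @param icd_nlp_correlation Gaussian-copula correlation between the latent
#'   draws of the diagnosis-code and text classifiers (default 0:
#'   conditional independence given truth).
#' @param dx_rate_primary,dx_rate_secondary Mean extra diagnosis events per
#'   patient for the most-coded site and for additional sites (each site
#'   always gets at least one event).
#' @param note_modifier_weights Named weights over the mention modifier of a
#'   non-metastatic-call patient's note: `none`, `negated`, `possible`,
#'   `historical`, `family`.
#' @param p_prom,p_portal_prom,p_portal_noprom Probability of completing a
#'   symptom survey, and of portal use conditional on completion status.
#' @param window_start,window_end The diagnosis/encounter date window.
#' @param make_notes Generate note text (disable for large structural
#'   simulations where only calls are needed).
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       site_mixture = NULL,
                       p_multi_site = c(0.66, 0.25, 0.09),
                       p_metastatic = 0.40,
                       operating_points = default_operating_points(),
                       icd_nlp_correlation = 0,
                       dx_rate_primary = 6,
                       dx_rate_secondary = 2,
                       note_modifier_weights = c(none = 0.30, negated = 0.35,
                                                 possible = 0.10,
                                                 historical = 0.15,
                                                 family = 0.10),
                       p_prom = 0.79,
                       p_portal_prom = 0.834,
                       p_portal_noprom = 0.493,
                       window_start = as.Date("2019-03-01"),
                       window_end = as.Date("2023-02-28"),
                       make_notes = TRUE,
                       seed) {
  if (missing(seed)) abort("sim_config() requires a seed",
                           class = "oncophen_config_error")
  if (is.null(site_mixture)) {
    ref <- reference_site_counts()
    site_mixture <- setNames(ref$n_a / sum(ref$n_a), ref$site)
  }
  chk_prob_vec <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must be a probability vector summing to 1", what),
            class = "oncophen_config_error")
    }
  }
  chk_prob_vec(site_mixture, "site_mixture")
  chk_prob_vec(p_multi_site, "p_multi_site")
  if (!setequal(names(site_mixture), site_categories())) {
    abort("site_mixture must be named by the 12 valid sites",
          class = "oncophen_config_error")
  }
  if (p_metastatic < 0 || p_metastatic > 1) {
    abort("p_metastatic must be in [0, 1]", class = "oncophen_config_error")
  }
  for (m in met_method_names()) {
    op <- operating_points[[m]]
    if (is.null(op) || !all(c("sens", "spec", "miss") %in% names(op)) ||
        any(op < 0) || any(op > 1)) {
      abort(sprintf(
        "operating_points$%s must supply sens, spec, miss in [0, 1]", m),
        class = "oncophen_config_error")
    }
  }
  if (abs(icd_nlp_correlation) > 1) {
    abort("icd_nlp_correlation must be in [-1, 1]",
          class = "oncophen_config_error")
  }
  nw <- note_modifier_weights / sum(note_modifier_weights)
  structure(list(
    n_patients = as.integer(n_patients),
    site_mixture = site_mixture[site_categories()],
    p_multi_site = p_multi_site,
    p_metastatic = p_metastatic,
    operating_points = operating_points,
    icd_nlp_correlation = icd_nlp_correlation,
    dx_rate_primary = dx_rate_primary,
    dx_rate_secondary = dx_rate_secondary,
    note_modifier_weights = nw,
    p_prom = p_prom, p_portal_prom = p_portal_prom,
    p_portal_noprom = p_portal_noprom,
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    make_notes = isTRUE(make_notes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw k-th site distinct from the earlier ones (renormalized mixture,
# realized by vectorized rejection).
draw_distinct_site <- function(prev, mixture) {
  sites <- names(mixture)
  n <- nrow(prev)
  out <- sample(sites, n, replace = TRUE, prob = mixture)
  repeat {
    clash <- purrr::map_lgl(seq_len(n), function(i) out[i] %in% prev[i, ])
    if (!any(clash)) break
    out[clash] <- sample(sites, sum(clash), replace = TRUE, prob = mixture)
  }
  out
}

# Tri-state call given truth at one operating point; u overrides the uniform
# used for the yes/no draw (copula hook).
draw_call <- function(met, op, u = NULL) {
  n <- length(met)
  u <- u %||% runif(n)
  p_yes <- ifelse(met, op[["sens"]], 1 - op[["spec"]])
  call <- ifelse(u < p_yes, "yes", "no")
  call[runif(n) < op[["miss"]]] <- "missing"
  call
}

note_templates <- function() {
  list(
    positive = c(
      "Imaging shows widely metastatic disease involving the liver.",
      "Biopsy confirms metastasis to bone.",
      "Patient with stage iv disease, on systemic therapy for metastatic cancer."),
    negated = c(
      "No evidence of metastatic disease on current imaging.",
      "Staging scans negative for metastasis.",
      "Restaging without metastases."),
    possible = c(
      "Lung nodule possibly representing metastasis; follow-up advised.",
      "Findings suspicious for metastatic disease, biopsy pending."),
    historical = c(
      "History of bone metastasis in 2015, now resolved.",
      "Prior metastatic disease, in remission."),
    family = c(
      "Mother had metastatic breast cancer.",
      "Family history of metastasis in a brother."),
    none = c(
      "Routine follow-up visit. Labs stable. Metabolic panel normal.",
      "Seen for supportive care; symptoms well controlled.")
  )
}

#' Generate one templated note text
#'
#' Returns note text carrying a metastasis term under the requested modifier
#' (`positive`, `negated`, `possible`, `historical`, `family`) or a
#' mention-free note (`none`). A `positive` modifier is only consistent with
#' a metastatic truth.
#'
#' @param truth `"yes"` or `"no"` — the patient-level call the note should
#'   support.
#' @param modifier Mention modifier.
#' @return A single note text string.
#' @export
make_note <- function(truth = c("yes", "no"),
                      modifier = c("positive", "negated", "possible",
                                   "historical", "family", "none")) {
  truth <- match.arg(truth)
  modifier <- match.arg(modifier)
  if (truth == "no" && modifier == "positive") {
    abort("A positive current patient mention contradicts a 'no' truth",
          class = "oncophen_error")
  }
  tpl <- note_templates()[[modifier]]
  tpl[sample.int(length(tpl), 1)]
}

#' Simulate a synthetic EHR cohort with ground truth
#'
#' Draws true sites and metastatic state per patient, draws each
#' classifier's tri-state call conditionally on truth at its operating
#' point, and then emits diagnosis events, notes, registry rows, treatment
#' plans, medication orders, and encounters that realize exactly those calls
#' (e.g. a "yes" diagnosis-code call materializes distant-site codes inside
#' the window; a deleted problem-list met code or a regional node code never
#' does). Every patient is constructed eligible. A medication "yes" drawn
#' for a patient whose sites carry no indicator drug is downgraded to "no"
#' and the truth table records the realized call.
#'
#' @param config A [sim_config()].
#' @return An `ehr_cohort` list including a `truth` tibble.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  days <- seq(config$window_start, config$window_end, by = "day")
  rdate <- function(k) sample(days, k, replace = TRUE)

  # --- truth: sites -------------------------------------------------------
  n_sites <- sample(1:3, n, replace = TRUE, prob = config$p_multi_site)
  site1 <- sample(names(config$site_mixture), n, replace = TRUE,
                  prob = config$site_mixture)
  site_mat <- matrix(NA_character_, n, 3)
  site_mat[, 1] <- site1
  i2 <- n_sites >= 2
  if (any(i2)) {
    site_mat[i2, 2] <- draw_distinct_site(site_mat[i2, 1, drop = FALSE],
                                          config$site_mixture)
  }
  i3 <- n_sites == 3
  if (any(i3)) {
    site_mat[i3, 3] <- draw_distinct_site(site_mat[i3, 1:2, drop = FALSE],
                                          config$site_mixture)
  }
  sites_list <- purrr::map(seq_len(n), ~ site_mat[.x, seq_len(n_sites[.x])])

  # --- truth: metastatic state and per-classifier calls -------------------
  met <- runif(n) < config$p_metastatic
  ops <- config$operating_points
  rho <- config$icd_nlp_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  calls <- list(
    icd = draw_call(met, ops$icd, u = pnorm(z1)),
    nlp = draw_call(met, ops$nlp, u = pnorm(z2)),
    registry = draw_call(met, ops$registry),
    treatment_plan = draw_call(met, ops$treatment_plan),
    medications = draw_call(met, ops$medications),
    phase1_trial = draw_call(met, ops$phase1_trial)
  )
  calls$phase1_trial[calls$phase1_trial == "no"] <- "missing"

  med_map <- read_met_meds()
  valid_med_sites <- attr(med_map, "valid_sites")
  realizable <- purrr::map_lgl(sites_list,
                               ~ length(intersect(.x, valid_med_sites)) > 0)
  calls$medications[calls$medications == "yes" & !realizable] <- "no"

  # --- diagnoses ----------------------------------------------------------
  grouper <- read_grouper()
  site_codes <- split(grouper$code[grouper$site != "excluded"],
                      grouper$site[grouper$site != "excluded"])
  ps <- tibble(
    patient_id = rep(ids, n_sites),
    site = unlist(sites_list),
    rank = unlist(purrr::map(n_sites, seq_len))
  )
  ps$n_ev <- 1L + rpois(nrow(ps), ifelse(ps$rank == 1L,
                                         config$dx_rate_primary,
                                         config$dx_rate_secondary))
  ev <- ps[rep(seq_len(nrow(ps)), ps$n_ev), c("patient_id", "site")]
  ev$code <- NA_character_
  for (s in unique(ev$site)) {
    idx <- which(ev$site == s)
    ev$code[idx] <- sample(site_codes[[s]], length(idx), replace = TRUE)
  }
  ev <- ev %>% select(-"site")
  ev$source <- sample(c("encounter", "hospital", "problem_list"),
                      nrow(ev), replace = TRUE, prob = c(0.7, 0.1, 0.2))
  ev$status <- "active"
  ev$date <- rdate(nrow(ev))

  met_code_pool <- c("C78.00", "C78.7", "C79.31", "C79.51", "C80.0")
  icd_yes <- ids[calls$icd == "yes"]
  met_rows <- if (length(icd_yes)) {
    k <- 1L + rpois(length(icd_yes), 2)
    tibble(patient_id = rep(icd_yes, k),
           code = sample(met_code_pool, sum(k), replace = TRUE),
           source = "encounter", status = "active", date = rdate(sum(k)))
  } else NULL
  # distractors that must NOT trigger the code classifier: regional nodes
  # inside the window, and deleted problem-list met codes
  icd_no <- ids[calls$icd == "no"]
  reg_rows <- if (length(icd_no)) {
    pick <- runif(length(icd_no)) < 0.15
    if (any(pick)) tibble(patient_id = icd_no[pick], code = "C77.0",
                          source = "encounter", status = "active",
                          date = rdate(sum(pick))) else NULL
  } else NULL
  del_rows <- if (length(icd_no)) {
    pick <- runif(length(icd_no)) < 0.05
    if (any(pick)) tibble(patient_id = icd_no[pick], code = "C79.51",
                          source = "problem_list", status = "deleted",
                          date = rdate(sum(pick))) else NULL
  } else NULL
  # out-of-window noise (dropped by the window filter)
  oow <- runif(n) < 0.05
  oow_rows <- if (any(oow)) {
    tibble(patient_id = ids[oow],
           code = purrr::map_chr(sites_list[oow],
                                 ~ sample(site_codes[[.x[1]]], 1)),
           source = "encounter", status = "active",
           date = config$window_start - sample(30:400, sum(oow),
                                               replace = TRUE))
  } else NULL
  diagnoses <- bind_rows(ev, met_rows, reg_rows, del_rows, oow_rows) %>%
    arrange(.data$patient_id, .data$date)

  # --- encounters (all patients eligible; phase-I visits where called) ----
  encounters <- tibble(
    patient_id = ids,
    department = "Medical Oncology",
    visit_type = sample(c("Initial", "Follow-up"), n, replace = TRUE,
                        prob = c(0.3, 0.7)),
    description = "Medical oncology evaluation",
    date = rdate(n)
  )
  p1 <- ids[calls$phase1_trial == "yes"]
  if (length(p1)) {
    encounters <- bind_rows(encounters, tibble(
      patient_id = p1, department = "Phase 1 Trials Clinic",
      visit_type = "Follow-up", description = "Phase I Trial Visit",
      date = rdate(length(p1))
    ))
  }

  # --- registry, plans, medications ---------------------------------------
  reg_idx <- calls$registry != "missing"
  registry <- tibble(patient_id = ids[reg_idx],
                     distant_at_diagnosis = calls$registry[reg_idx] == "yes")

  plan_missing <- calls$treatment_plan == "missing"
  goalless <- plan_missing & runif(n) < 0.45   # plan exists, goal absent
  plans <- bind_rows(
    tibble(patient_id = ids[goalless], goal = NA_character_),
    tibble(patient_id = ids[calls$treatment_plan == "yes"],
           goal = sample(c("Palliative", "Control"),
                         sum(calls$treatment_plan == "yes"), replace = TRUE)),
    tibble(patient_id = ids[calls$treatment_plan == "no"],
           goal = "Curative")
  )

  med_yes <- ids[calls$medications == "yes"]
  med_yes_drug <- purrr::map_chr(which(calls$medications == "yes"),
    function(i) {
      s <- intersect(sites_list[[i]], valid_med_sites)[1]
      sample(med_map$drug[med_map$site == s], 1)
    })
  med_no <- ids[calls$medications == "no"]
  meds <- bind_rows(
    if (length(med_yes)) tibble(patient_id = med_yes, drug = med_yes_drug,
                                date = rdate(length(med_yes))),
    if (length(med_no)) tibble(patient_id = med_no, drug = "metformin",
                               date = rdate(length(med_no)))
  )
  if (is.null(meds)) meds <- empty_entity("meds")

  # --- notes ---------------------------------------------------------------
  if (config$make_notes) {
    tpl <- note_templates()
    pick_tpl <- function(mods) {
      purrr::map_chr(mods, function(m) {
        v <- tpl[[m]]
        v[sample.int(length(v), 1)]
      })
    }
    nlp_yes <- calls$nlp == "yes"
    neg_mods <- sample(names(config$note_modifier_weights), n, replace = TRUE,
                       prob = config$note_modifier_weights)
    mod1 <- ifelse(nlp_yes, "positive", neg_mods)
    notes <- tibble(patient_id = ids, date = rdate(n), text = pick_tpl(mod1),
                    modifier = mod1)
    # metastatic-call patients often also carry negated/historical text
    extra <- nlp_yes & runif(n) < 0.5
    if (any(extra)) {
      mod2 <- sample(c("negated", "historical", "family", "none"),
                     sum(extra), replace = TRUE)
      notes <- bind_rows(notes, tibble(patient_id = ids[extra],
                                       date = rdate(sum(extra)),
                                       text = pick_tpl(mod2),
                                       modifier = mod2))
    }
    note_modifiers <- notes[c("patient_id", "modifier")]
    notes <- notes %>% arrange(.data$patient_id, .data$date) %>%
      select(-"modifier")
  } else {
    notes <- empty_entity("notes")
    note_modifiers <- tibble(patient_id = character(), modifier = character())
  }

  prom <- runif(n) < config$p_prom
  portal <- runif(n) < ifelse(prom, config$p_portal_prom,
                              config$p_portal_noprom)

  truth <- tibble(
    patient_id = ids,
    sites = purrr::map_chr(sites_list, paste, collapse = ";"),
    n_sites = n_sites,
    metastatic = met,
    icd = calls$icd, nlp = calls$nlp, registry = calls$registry,
    treatment_plan = calls$treatment_plan, medications = calls$medications,
    phase1_trial = calls$phase1_trial,
    prom_completed = prom, portal_use = portal
  )

  structure(list(diagnoses = as_tibble(diagnoses), notes = notes,
                 registry = registry, plans = as_tibble(plans),
                 meds = as_tibble(meds), encounters = as_tibble(encounters),
                 truth = truth, note_modifiers = note_modifiers,
                 window_start = config$window_start,
                 window_end = config$window_end),
            class = "ehr_cohort")
}
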