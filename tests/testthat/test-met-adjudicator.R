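test_that("the code classifier honors the code set, deletion, and window rules", {
  ev <- make_dx(
    c("P1", "P2", "P2", "P3", "P4"),
    c("C79.51", "C79.51", "C50.9", "C77.0", "C50.9"),
    source = c("encounter", "problem_list", "encounter", "encounter",
               "encounter"),
    status = c("active", "deleted", "active", "active", "active"))
  dx <- filter_diagnoses(ev, "2020-01-01", "2020-12-31")
  calls <- call_icd(dx, c("P1", "P2", "P3", "P4"))
  # P1: distant code -> yes; P2: met code only as deleted problem-list -> no;
  # P3: regional lymph node only -> no; P4: site code only -> no
  expect_identical(calls$icd, c("yes", "no", "no", "no"))

  # regional exclusion is configurable
  loose <- default_met_codes(regional_prefixes = character())
  expect_identical(call_icd(dx, "P3", loose)$icd, "yes")

  # monotone: adding a qualifying event never flips yes -> no
  more <- dplyr::bind_rows(dx, make_dx("P4", "C78.00"))
  expect_identical(call_icd(more, c("P1", "P4"))$icd, c("yes", "yes"))
})

test_that("registry calls reflect stage at diagnosis only", {
  reg <- tibble::tibble(patient_id = c("P1", "P2"),
                        distant_at_diagnosis = c(TRUE, FALSE))
  calls <- call_registry(reg, c("P1", "P2", "P3"))
  expect_identical(calls$registry, c("yes", "no", "missing"))
})

test_that("treatment-plan goals classify palliative/control as metastatic", {
  plans <- tibble::tibble(
    patient_id = c("P1", "P2", "P2", "P3", "P4"),
    goal = c("Curative", "Curative", "palliative", NA, "CONTROL"))
  calls <- call_treatment_plan(plans, paste0("P", 1:5))
  expect_identical(calls$treatment_plan,
                   c("no", "yes", "missing", "yes", "missing"))
  # P3 has a plan but no stated goal -> missing; P5 has no plan -> missing
})

test_that("medication calls require an indicator drug for a site the patient has", {
  med_map <- read_met_meds()
  meds <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    drug = c("Palbociclib", "palbociclib", "metformin"),
    date = as.Date("2021-01-01"))
  sites_a <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    sites_a = list("breast", "lung", "breast", "breast"))
  calls <- call_medications(meds, sites_a, paste0("P", 1:4), med_map)
  # P1 breast drug + breast dx -> yes; P2 breast drug but lung dx -> no;
  # P3 unmapped drug -> no; P4 no medication data -> missing
  expect_identical(calls$medications, c("yes", "no", "no", "missing"))
})

test_that("phase-1 calls need 'Trial' in a phase-1 clinic and never say no", {
  enc <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    department = c("Phase 1 Trials Clinic", "Medical Oncology",
                   "Phase 1 Trials Clinic", "Phase 1 Trials Clinic"),
    visit_type = "Follow-up",
    description = c("Phase I Trial Visit", "Trial Visit", "Consult",
                    "trial visit"),
    date = as.Date("2021-05-01"))
  calls <- call_phase1(enc, paste0("P", 1:5))
  expect_identical(calls$phase1_trial,
                   c("yes", "missing", "missing", "missing", "missing"))
  expect_false(any(calls$phase1_trial == "no"))
  # case-insensitive switch picks up the lowercase description
  expect_identical(call_phase1(enc, "P4", ignore_case = TRUE)$phase1_trial,
                   "yes")
})

test_that("adjudication maps agreement to status and rejects missing input", {
  expect_identical(adjudicate("yes", "yes"), "metastatic")
  expect_identical(adjudicate("no", "no"), "not_metastatic")
  expect_identical(adjudicate("no", "yes"), "uncertain")
  expect_identical(adjudicate("yes", "no"), "uncertain")
  expect_error(adjudicate("missing", "yes"), class = "oncophen_error")
  expect_error(adjudicate(c("yes", "no"), "yes"), class = "oncophen_error")
})

test_that("adjudication statuses partition the cohort", {
  cohort <- tiny_cohort(n = 250, seed = 61)
  sites <- assign_sites(cohort, window_start = cohort$window_start,
                        window_end = cohort$window_end)
  calls <- classify_metastasis(cohort, sites, cohort$window_start,
                               cohort$window_end)
  expect_identical(nrow(calls), 250L)
  tab <- table(factor(calls$adjudication,
                      c("metastatic", "not_metastatic", "uncertain")))
  expect_identical(sum(tab), 250L)
  expect_false(any(is.na(calls$adjudication)))
})

test_that("combination counts equal a brute-force per-patient tally and sum to N", {
  cohort <- tiny_cohort(n = 250, seed = 61)
  sites <- assign_sites(cohort, window_start = cohort$window_start,
                        window_end = cohort$window_end)
  calls <- classify_metastasis(cohort, sites, cohort$window_start,
                               cohort$window_end)
  combos <- combination_counts(calls)
  expect_identical(sum(combos$n), nrow(calls))
  methods <- c("icd", "nlp", "registry", "treatment_plan", "medications")
  brute <- vapply(seq_len(nrow(calls)), function(i) {
    sum(vapply(methods, function(m) calls[[m]][i] == "yes", logical(1)))
  }, numeric(1))
  expect_identical(combos$n, vapply(0:5, function(k) sum(brute == k),
                                    integer(1)))
  # a patient with yes on exactly icd+nlp lands in k = 2
  one <- tibble::tibble(icd = "yes", nlp = "yes", registry = "missing",
                        treatment_plan = "no", medications = "missing")
  expect_identical(combination_counts(one)$n[3], 1L)
  all_missing <- tibble::tibble(icd = "no", nlp = "no", registry = "missing",
                                treatment_plan = "missing",
                                medications = "missing")
  expect_identical(combination_counts(all_missing)$n[1], 1L)
})

test_that("classifier outputs recover the generator's realized truth calls", {
  cohort <- tiny_cohort(n = 300, seed = 77)
  sites <- assign_sites(cohort, window_start = cohort$window_start,
                        window_end = cohort$window_end)
  calls <- classify_metastasis(cohort, sites, cohort$window_start,
                               cohort$window_end)
  truth <- cohort$truth[match(calls$patient_id, cohort$truth$patient_id), ]
  for (m in met_method_names()) {
    expect_identical(calls[[m]], truth[[m]], info = m)
  }
})
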