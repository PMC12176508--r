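grouper <- read_grouper()

test_that("diagnosis filtering drops deleted entries and respects closed window", {
  ev <- make_dx(
    c("P1", "P1", "P2", "P3", "P4"),
    c("C50.9", "C79.51", "C18.9", "C18.9", "C34.90"),
    source = c("encounter", "problem_list", "encounter", "encounter",
               "encounter"),
    status = c("active", "deleted", "active", "active", "active"),
    date = as.Date(c("2020-06-01", "2020-06-01", "2020-01-01",
                     "2020-12-31", "2021-01-01"))
  )
  got <- filter_diagnoses(ev, "2020-01-01", "2020-12-31")
  expect_setequal(got$patient_id, c("P1", "P2", "P3"))
  expect_false(any(got$status == "deleted"))
  # both endpoints inclusive
  expect_true("2020-01-01" %in% as.character(got$date))
  expect_true("2020-12-31" %in% as.character(got$date))
  expect_error(filter_diagnoses(ev, "2021-01-01", "2020-01-01"),
               "Inverted", class = "oncophen_error")
})

test_that("window filtering agrees with a brute-force predicate on random events", {
  withr::local_seed(14)
  ev <- make_dx(
    paste0("P", sample(1:20, 100, TRUE)),
    sample(c("C50.9", "C18.9", "C79.1"), 100, TRUE),
    source = sample(c("encounter", "problem_list"), 100, TRUE),
    date = as.Date("2020-01-01") + sample(-200:600, 100, TRUE)
  )
  ev$status <- ifelse(ev$source == "problem_list" & runif(100) < 0.3,
                      "deleted", "active")
  ws <- as.Date("2020-01-01"); we <- as.Date("2020-12-31")
  got <- filter_diagnoses(ev, ws, we)
  keep <- vapply(seq_len(100), function(i) {
    ev$status[i] != "deleted" && ev$date[i] >= ws && ev$date[i] <= we
  }, logical(1))
  expect_equal(as.data.frame(got), as.data.frame(ev[keep, ]))
})

test_that("site tallies go through the grouper and drop excluded categories", {
  ev <- make_dx("P1", c("C50.9", "C50.1", "C50.4", "C18.9"))
  v <- count_sites(ev, grouper)
  expect_equal(v$n_dx[v$site == "breast"], 3L)
  expect_equal(v$n_dx[v$site == "gastrointestinal"], 1L)

  # benign, metastatic, lymph-node, and unknown codes all resolve to excluded
  ex <- make_dx("P2", c("D36.9", "C79.51", "C77.9", "ZZZ99"))
  expect_identical(nrow(count_sites(ex, grouper)), 0L)

  # oracle: independent tally over mapped sites
  withr::local_seed(3)
  codes <- sample(c("C50.9", "C18.9", "C34.90", "C61", "D36.9", "C79.1"),
                  200, TRUE)
  ev2 <- make_dx(paste0("P", sample(1:10, 200, TRUE)), codes)
  got <- count_sites(ev2, grouper)
  map <- c(C50.9 = "breast", C18.9 = "gastrointestinal", C34.90 = "lung",
           C61 = "genitourinary")
  oracle <- as.data.frame(table(ev2$patient_id, map[ev2$code]))
  oracle <- oracle[oracle$Freq > 0, ]
  key <- paste(got$patient_id, got$site)
  okey <- paste(oracle$Var1, oracle$Var2)
  expect_setequal(key, okey)
  expect_equal(got$n_dx[match(okey, key)], oracle$Freq)
})

test_that("the three assignment methods implement their selection rules", {
  v <- counts_of(breast = 3, gastrointestinal = 1)
  expect_setequal(method_a(v), c("breast", "gastrointestinal"))
  expect_identical(method_b(v), "breast")        # 3/4 strict majority
  expect_setequal(method_c(v), c("breast", "gastrointestinal"))

  even <- counts_of(breast = 2, gastrointestinal = 2)
  expect_identical(method_b(even), "multiple")   # 2/4 is not a majority

  empty <- counts_of()
  expect_identical(method_a(empty), character(0))
  expect_identical(method_b(empty), "nonspecific")
  expect_identical(method_c(empty), character(0))

  top3 <- counts_of(lung = 5, breast = 2, sarcoma = 1)
  expect_setequal(method_c(top3), c("lung", "breast"))
  expect_identical(method_b(top3), "lung")       # 5/8 strict majority

  # tie for second slot: earlier first-diagnosis date wins
  tie <- tibble::tibble(
    patient_id = "P1", site = c("lung", "sarcoma", "breast"),
    n_dx = c(3L, 1L, 1L),
    first_date = as.Date(c("2020-01-01", "2020-03-01", "2020-02-01"))
  )
  expect_setequal(method_c(tie), c("lung", "breast"))
})

test_that("counting distinct codes instead of events is available as a switch", {
  ev <- make_dx("P1", c("C50.9", "C50.9", "C50.9", "C50.1", "C18.9"))
  by_events <- count_sites(ev, grouper, unit = "events")
  by_codes <- count_sites(ev, grouper, unit = "codes")
  expect_equal(by_events$n_dx[by_events$site == "breast"], 4L)
  expect_equal(by_codes$n_dx[by_codes$site == "breast"], 2L)
})

test_that("assignments nest and the single-category method partitions the cohort", {
  cohort <- tiny_cohort(n = 400, seed = 17)
  sites <- assign_sites(cohort, grouper,
                        cohort$window_start, cohort$window_end)
  valid <- sites$site_b %in% site_categories()
  for (i in which(valid)) {
    expect_true(sites$site_b[i] %in% sites$sites_c[[i]])
  }
  for (i in seq_len(nrow(sites))) {
    expect_true(all(sites$sites_c[[i]] %in% sites$sites_a[[i]]))
    expect_lte(length(sites$sites_c[[i]]), 2L)
  }
  # exactly one single-category label per patient; labels partition N
  expect_identical(sum(table(sites$site_b)), nrow(sites))
  # per-site positives nest: A >= C >= B
  counts <- site_method_counts(sites)
  expect_true(all(counts$n_a >= counts$n_c & counts$n_c >= counts$n_b))
  # empty tally <=> nonspecific
  empties <- lengths(sites$sites_a) == 0
  expect_identical(sites$site_b == "nonspecific", empties)
})

test_that("tallying after filtering is idempotent under repeated filtering", {
  cohort <- tiny_cohort(n = 80, seed = 23)
  ws <- cohort$window_start; we <- cohort$window_end
  once <- count_sites(filter_diagnoses(cohort$diagnoses, ws, we), grouper)
  twice <- count_sites(
    filter_diagnoses(filter_diagnoses(cohort$diagnoses, ws, we), ws, we),
    grouper)
  expect_identical(once, twice)
})

test_that("eligibility requires the conjunction of grouper dx and oncology visit", {
  enc <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    department = c("Surgery", "Medical Oncology", "Medical Oncology",
                   "Medical Oncology"),
    visit_type = c("Initial", "Procedure", "Follow-up", "Initial"),
    description = "visit", date = as.Date("2020-06-01"))
  dx <- make_dx(c("P1", "P2", "P3"), "C50.9")
  cohort <- structure(list(diagnoses = dx, encounters = enc,
                           notes = tibble::tibble(), registry = tibble::tibble(),
                           plans = tibble::tibble(), meds = tibble::tibble()),
                      class = "ehr_cohort")
  expect_identical(eligible_patients(cohort, grouper), "P3")
  # P1: wrong department; P2: wrong visit type; P4: no diagnosis

  synth <- tiny_cohort(n = 60, seed = 2)
  expect_setequal(eligible_patients(synth, grouper), synth$truth$patient_id)
})

test_that("detection fractions summarize the published counts correctly", {
  det <- detection_fraction(reference_site_counts())
  g <- glance(det)
  expect_equal(g$median_pct_c, 92)
  expect_equal(g$median_pct_b, 65)
  expect_equal(c(g$min_pct_c, g$max_pct_c), c(77, 98))
  expect_equal(g$max_pct_b, 89)

  same <- tibble::tibble(site = c("a", "b", "c"), n_a = c(10L, 20L, 30L),
                         n_b = c(10L, 20L, 30L), n_c = c(10L, 20L, 30L))
  expect_equal(glance(detection_fraction(same))$median_pct_c, 100)

  zero <- tibble::tibble(site = c("a", "b"), n_a = c(0L, 10L),
                         n_b = c(0L, 5L), n_c = c(0L, 9L))
  expect_warning(d0 <- detection_fraction(zero), "no Method A positives")
  expect_identical(nrow(d0), 1L)
})
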