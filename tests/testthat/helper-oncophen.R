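# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use a different computational route than the package
# (expanded rating vectors and direct formulas rather than cell arithmetic).

make_dx <- function(patient_id, code, source = "encounter",
                    status = "active", date = as.Date("2020-06-01")) {
  tibble::tibble(patient_id = patient_id, code = code, source = source,
                 status = status, date = as.Date(date))
}

counts_of <- function(...) {
  # quick site-count fixture: counts_of(breast = 3, gastrointestinal = 1)
  x <- c(...)
  if (!length(x)) {
    return(tibble::tibble(patient_id = character(), site = character(),
                          n_dx = integer(),
                          first_date = as.Date(character())))
  }
  tibble::tibble(patient_id = "P1", site = names(x), n_dx = as.integer(x),
                 first_date = as.Date("2020-01-01") + seq_along(x))
}

# Cohen's kappa recomputed from expanded per-subject rating vectors via the
# raw agreement definition (independent of the cell-count formula).
oracle_cohen <- function(a, b, c, d) {
  r1 <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  r2 <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  po <- mean(r1 == r2)
  pe <- mean(r1) * mean(r2) + (1 - mean(r1)) * (1 - mean(r2))
  (po - pe) / (1 - pe)
}

# Fleiss' kappa from the full n x 2 category-count matrix.
oracle_fleiss <- function(yes_votes, m) {
  nij <- cbind(yes_votes, m - yes_votes)
  pj <- colSums(nij) / (nrow(nij) * m)
  Pi <- (rowSums(nij^2) - m) / (m * (m - 1))
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# The per-site counts and agreement values as printed in the source
# cohort's site-method comparison table (12 sites, N = 50,559).
printed_site_table <- function() {
  tibble::tribble(
    ~site, ~k_ab, ~k_ac, ~k_bc, ~k_abc,
    "breast",           0.93, 0.99, 0.94, 0.95,
    "endocrine",        0.55, 0.93, 0.61, 0.72,
    "gastrointestinal", 0.88, 0.98, 0.90, 0.92,
    "genitourinary",    0.76, 0.96, 0.80, 0.85,
    "gynecologic",      0.88, 0.98, 0.90, 0.92,
    "head_and_neck",    0.83, 0.95, 0.88, 0.89,
    "hematologic",      0.73, 0.95, 0.78, 0.83,
    "lung",             0.82, 0.96, 0.86, 0.88,
    "melanoma",         0.75, 0.92, 0.82, 0.84,
    "nervous_system",   0.69, 0.92, 0.77, 0.80,
    "sarcoma",          0.77, 0.95, 0.82, 0.85,
    "skin_other",       0.20, 0.85, 0.26, 0.50
  )
}

tiny_cohort <- function(n = 120, seed = 7, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed, ...))
}
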