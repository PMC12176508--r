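# Cancer-site assignment from coded diagnoses: cohort eligibility, diagnosis
# filtering, the grouper tally, and the three competing assignment methods.
#
# Method A keeps every coded site category (most sensitive); Method B keeps
# the single category holding a strict majority of a patient's qualifying
# diagnosis events, falling back to "multiple"/"nonspecific" (most specific);
# Method C keeps the two most frequent categories. By construction the
# positives nest per site: B-positives form a subset of C-positives, which
# form a subset of A-positives.

#' Patients eligible for the analysis cohort
#'
#' A patient qualifies with (1) at least one diagnosis mapping to a valid
#' grouper category or to a recognised excluded cancer category (i.e. any
#' all-cancers-grouper code), (2) at least one medical-oncology encounter,
#' and (3) an encounter visit type of initial or follow-up evaluation.
#'
#' @param cohort An `ehr_cohort`.
#' @param grouper A grouper from [read_grouper()].
#' @return Character vector of eligible patient ids.
#' @export
eligible_patients <- function(cohort, grouper = read_grouper()) {
  dx <- cohort$diagnoses
  # any code known to the grouper table (valid site or excluded cancer
  # category) counts as a grouper diagnosis; truly unknown codes do not
  code <- toupper(gsub("[ .]", "", dx$code))
  key <- gsub("[.]", "", grouper$code)
  known <- code %in% key | substr(code, 1, 3) %in% key
  has_dx <- unique(dx$patient_id[known])

  enc <- cohort$encounters
  dep <- norm_str(enc$department)
  vt <- gsub("[ -]", "_", norm_str(enc$visit_type))
  ok <- dep == "medical oncology" & vt %in% c("initial", "follow_up")
  has_enc <- unique(enc$patient_id[ok & !is.na(ok)])
  sort(intersect(has_dx, has_enc))
}

#' Filter diagnosis events to the analysis window
#'
#' Retains events dated inside the closed window and drops problem-list
#' entries marked deleted (entered in error).
#'
#' @param events Diagnosis tibble (`patient_id`, `code`, `source`, `status`,
#'   `date`).
#' @param window_start,window_end Window bounds, inclusive on both ends.
#' @return Filtered diagnosis tibble.
#' @export
filter_diagnoses <- function(events, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start > window_end) {
    abort("Inverted window: window_start is after window_end",
          class = "oncophen_error")
  }
  events %>%
    filter(.data$status != "deleted",
           in_window(.data$date, window_start, window_end))
}

#' Tally qualifying diagnosis events per patient and site
#'
#' Maps each event code through the grouper; events resolving to excluded
#' categories (metastatic, benign, unspecified, lymph-node, ...) or to
#' unknown codes are discarded. The counting unit is diagnosis events, not
#' distinct codes (a configurable alternative counts each distinct code
#' once).
#'
#' @param events Filtered diagnosis tibble (see [filter_diagnoses()]).
#' @param grouper A grouper from [read_grouper()].
#' @param unit `"events"` (default) or `"codes"` (count distinct codes).
#' @return Tibble `patient_id`, `site`, `n_dx`, `first_date` — one row per
#'   patient-site with at least one qualifying event.
#' @export
count_sites <- function(events, grouper = read_grouper(),
                        unit = c("events", "codes")) {
  unit <- match.arg(unit)
  if (!nrow(events)) {
    return(tibble(patient_id = character(), site = character(),
                  n_dx = integer(), first_date = as.Date(character())))
  }
  ev <- events %>% mutate(site = grouper_site(.data$code, grouper)) %>%
    filter(.data$site != "excluded")
  if (!nrow(ev)) {
    return(tibble(patient_id = character(), site = character(),
                  n_dx = integer(), first_date = as.Date(character())))
  }
  if (unit == "codes") {
    ev <- ev %>%
      group_by(.data$patient_id, .data$site, .data$code) %>%
      summarise(date = min(.data$date), .groups = "drop")
  }
  ev %>%
    group_by(.data$patient_id, .data$site) %>%
    summarise(n_dx = dplyr::n(), first_date = min(.data$date),
              .groups = "drop")
}

# Split a site-count tibble into per-patient frames, preserving patients.
split_counts <- function(counts, patients = NULL) {
  ids <- patients %||% sort(unique(counts$patient_id))
  sp <- split(counts, factor(counts$patient_id, levels = ids))
  sp
}

#' Site assignment, Method A: all coded categories
#'
#' @param counts One patient's rows of the [count_sites()] tally.
#' @return Character vector of sites (possibly empty).
#' @export
method_a <- function(counts) sort(unique(counts$site))

#' Site assignment, Method B: single strict-majority category
#'
#' One category per patient: with a single coded category, that category;
#' with several, the one holding strictly more than half of the qualifying
#' events; `"multiple"` when no category holds a strict majority;
#' `"nonspecific"` when no valid category was coded at all.
#'
#' @inheritParams method_a
#' @return One site label (may be a sentinel).
#' @export
method_b <- function(counts) {
  if (!nrow(counts)) return("nonspecific")
  if (nrow(counts) == 1L) return(counts$site)
  tot <- sum(counts$n_dx)
  top <- counts$site[counts$n_dx * 2L > tot]
  if (length(top) == 1L) top else "multiple"
}

#' Site assignment, Method C: the two most frequent categories
#'
#' Up to two categories per patient. With three or more coded categories the
#' two highest event counts win; ties for the second slot break by higher
#' count, then earlier first-diagnosis date, then site name.
#'
#' @inheritParams method_a
#' @return Character vector of at most two sites.
#' @export
method_c <- function(counts) {
  if (nrow(counts) <= 2L) return(sort(counts$site))
  ord <- order(-counts$n_dx, counts$first_date, counts$site)
  sort(counts$site[ord[1:2]])
}

#' Assign cancer sites to every patient by Methods A, B, and C
#'
#' Runs the full site algorithm: filter the diagnosis window, tally sites
#' through the grouper, and apply the three methods per patient. Patients in
#' `patients` with no qualifying events get an empty A/C set and a
#' nonspecific B label.
#'
#' @param cohort An `ehr_cohort` (its `diagnoses` are used).
#' @param grouper Grouper map.
#' @param window_start,window_end Diagnosis window (inclusive).
#' @param patients Patient ids to assign (default: every patient with a
#'   diagnosis row).
#' @param unit Counting unit, see [count_sites()].
#' @return Tibble `patient_id`, `sites_a` (list), `site_b` (chr), `sites_c`
#'   (list).
#' @export
assign_sites <- function(cohort, grouper = read_grouper(),
                         window_start = min(cohort$diagnoses$date),
                         window_end = max(cohort$diagnoses$date),
                         patients = NULL, unit = "events") {
  dx <- filter_diagnoses(cohort$diagnoses, window_start, window_end)
  counts <- count_sites(dx, grouper, unit = unit)
  ids <- patients %||% sort(unique(cohort$diagnoses$patient_id))
  per <- split_counts(counts, ids)
  tibble(
    patient_id = ids,
    sites_a = purrr::map(per, method_a),
    sites_c = purrr::map(per, method_c),
    site_b = purrr::map_chr(per, method_b)
  )[, c("patient_id", "sites_a", "site_b", "sites_c")]
}

#' Per-site detection fractions of the restrictive methods
#'
#' For each site, the fraction of any-category (Method A) positives that the
#' single-majority method (B) and the two-category method (C) retain, with
#' the median and range across sites. Medians are taken over the unrounded
#' fractions; display percentages are rounded to whole numbers.
#'
#' @param per_site_counts Tibble with `site`, `n_a`, `n_b`, `n_c` (e.g.
#'   [reference_site_counts()] or [site_method_counts()]).
#' @return Object of class `detection_fraction`: per-site tibble with
#'   `frac_b`, `frac_c`; summaries via [glance()].
#' @export
detection_fraction <- function(per_site_counts) {
  x <- per_site_counts
  if (any(x$n_b > x$n_a | x$n_c > x$n_a)) {
    abort("Per-site counts violate nesting: n_b and n_c cannot exceed n_a",
          class = "oncophen_error")
  }
  drop <- x$n_a == 0
  if (any(drop)) {
    warn(sprintf("Skipping site(s) with no Method A positives: %s",
                 paste(x$site[drop], collapse = ", ")))
    x <- x[!drop, ]
  }
  out <- x %>% mutate(frac_b = .data$n_b / .data$n_a,
                      frac_c = .data$n_c / .data$n_a)
  class(out) <- c("detection_fraction", class(out))
  out
}

#' @method tidy detection_fraction
#' @export
tidy.detection_fraction <- function(x, ...) {
  as_tibble(x) %>%
    mutate(pct_b = round_half_up(100 * .data$frac_b, 0),
           pct_c = round_half_up(100 * .data$frac_c, 0))
}

#' @method glance detection_fraction
#' @export
glance.detection_fraction <- function(x, ...) {
  tibble(
    median_pct_b = round_half_up(100 * median(x$frac_b), 0),
    min_pct_b = round_half_up(100 * min(x$frac_b), 0),
    max_pct_b = round_half_up(100 * max(x$frac_b), 0),
    median_pct_c = round_half_up(100 * median(x$frac_c), 0),
    min_pct_c = round_half_up(100 * min(x$frac_c), 0),
    max_pct_c = round_half_up(100 * max(x$frac_c), 0),
    n_sites = nrow(x)
  )
}

#' @method autoplot detection_fraction
#' @export
autoplot.detection_fraction <- function(object, ...) {
  long <- tidy(object) %>%
    select("site", "frac_b", "frac_c") %>%
    tidyr::pivot_longer(c("frac_b", "frac_c"), names_to = "method",
                        values_to = "fraction") %>%
    mutate(method = dplyr::recode(.data$method, frac_b = "single category (B)",
                                  frac_c = "two categories (C)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction,
                                     y = stats::reorder(.data$site,
                                                        .data$fraction),
                                     colour = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "fraction of any-category positives detected",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-site method-positive counts from site assignments
#'
#' Collapses per-patient assignments into the per-site marginals (`n_a`,
#' `n_b`, `n_c`) that feed [detection_fraction()] and [site_agreement()].
#'
#' @param assignments Output of [assign_sites()].
#' @return Tibble `site`, `n_a`, `n_b`, `n_c` over the 12 valid sites, with
#'   attribute `n_total`.
#' @export
site_method_counts <- function(assignments) {
  sites <- site_categories()
  n_a <- purrr::map_int(sites, function(s)
    sum(purrr::map_lgl(assignments$sites_a, ~ s %in% .x)))
  n_c <- purrr::map_int(sites, function(s)
    sum(purrr::map_lgl(assignments$sites_c, ~ s %in% .x)))
  n_b <- purrr::map_int(sites, function(s) sum(assignments$site_b == s))
  out <- tibble(site = sites, n_a = n_a, n_b = n_b, n_c = n_c)
  attr(out, "n_total") <- nrow(assignments)
  out
}
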