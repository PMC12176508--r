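# Controlled vocabularies: cancer-site categories, classifier names, and the
# packaged code/drug mapping tables.

#' Valid cancer-site categories
#'
#' The twelve specific site categories a diagnosis grouper can target.
#' The sentinel labels `"multiple"` and `"nonspecific"` are legal only as
#' outputs of the single-category site method (see [method_b()]), never as
#' grouper targets.
#'
#' @return Character vector of the 12 valid site labels.
#' @export
site_categories <- function() {
  c("breast", "endocrine", "gastrointestinal", "genitourinary",
    "gynecologic", "head_and_neck", "hematologic", "lung",
    "melanoma", "nervous_system", "sarcoma", "skin_other")
}

#' @rdname site_categories
#' @export
site_sentinels <- function() c("multiple", "nonspecific")

# Grouper categories excluded from site assignment (label -> no site).
excluded_grouper_labels <- function() {
  c("Other solid tumor with distant metastatic",
    "Neoplasm of uncertain or unspecific behavior",
    "Metastatic",
    "Other solid tumor",
    "Benign neoplasm",
    "Unspecified",
    "Lymph node disease")
}

met_method_names <- function() {
  c("icd", "nlp", "registry", "treatment_plan", "medications", "phase1_trial")
}

# ---------------------------------------------------------------------------
# Diagnosis grouper

#' Load a diagnosis grouper mapping
#'
#' A grouper maps ICD-10-CM codes to a raw category label and each label to a
#' valid site category or to `"excluded"`. The packaged default
#' (`inst/extdata/grouper.tsv`) is a curated synthetic stand-in for an
#' EHR-vendor "all cancers" grouper (such tables are institution-specific and
#' not published); replace it with your own TSV of the same shape
#' (`code`, `label`, `site`). Codes absent from the table fall back to a
#' three-character family match, then to excluded.
#'
#' @param path Path to a grouper TSV; default is the packaged table.
#' @return A tibble of class `oncophen_grouper` with columns `code`, `label`,
#'   `site`.
#' @export
read_grouper <- function(path = system.file("extdata", "grouper.tsv",
                                            package = "oncophen")) {
  g <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("code", "label", "site")
  if (!all(need %in% names(g))) {
    abort(sprintf("Grouper file %s must have columns: %s",
                  path, paste(need, collapse = ", ")),
          class = "oncophen_parse_error")
  }
  ok <- c(site_categories(), "excluded")
  bad <- setdiff(unique(g$site), ok)
  if (length(bad)) {
    abort(sprintf("Grouper site label(s) not recognised: %s",
                  paste(bad, collapse = ", ")),
          class = "oncophen_parse_error")
  }
  g$code <- toupper(gsub(" ", "", g$code))
  structure(as_tibble(g[need]), class = c("oncophen_grouper", class(g)))
}

# Vectorized code -> site lookup. Exact code first, then the 3-character
# family, else excluded (unknown codes never invent a site).
grouper_site <- function(code, grouper) {
  code <- toupper(gsub("[ .]", "", code))
  key <- gsub("[.]", "", grouper$code)
  site <- grouper$site[match(code, key)]
  fam <- grouper$site[match(substr(code, 1, 3), key)]
  site[is.na(site)] <- fam[is.na(site)]
  site[is.na(site)] <- "excluded"
  site
}

# ---------------------------------------------------------------------------
# Metastasis code set

#' Default metastasis ICD-10 code set
#'
#' Secondary/distant-site malignancy families (C77-C79 plus disseminated
#' C80.0), with regional lymph-node codes excluded: distant spread, not
#' regional nodal involvement, is what qualifies as metastatic. The regional
#' exclusion defaults to C77.0-C77.3 and is configurable.
#'
#' @param include_prefixes Code prefixes counted as metastatic.
#' @param regional_prefixes Code prefixes treated as regional lymph-node
#'   involvement and excluded.
#' @return A list of class `met_code_set`.
#' @export
default_met_codes <- function(include_prefixes = c("C77", "C78", "C79", "C800"),
                              regional_prefixes = c("C770", "C771", "C772",
                                                    "C773")) {
  stopifnot(length(include_prefixes) > 0)
  structure(list(include = toupper(gsub("[.]", "", include_prefixes)),
                 regional = toupper(gsub("[.]", "", regional_prefixes))),
            class = "met_code_set")
}

#' Test whether ICD-10 codes indicate metastatic disease
#'
#' @param code Character vector of ICD-10-CM codes.
#' @param codeset A [default_met_codes()] object.
#' @return Logical vector.
#' @export
is_met_code <- function(code, codeset = default_met_codes()) {
  code <- toupper(gsub("[ .]", "", code))
  hit <- Reduce(`|`, lapply(codeset$include, function(p) startsWith(code, p)))
  reg <- if (length(codeset$regional)) {
    Reduce(`|`, lapply(codeset$regional, function(p) startsWith(code, p)))
  } else rep(FALSE, length(code))
  hit & !reg
}

# ---------------------------------------------------------------------------
# Incurable-indication medication map

#' Load the metastasis-indicating medication map
#'
#' Maps drugs to the cancer site whose incurable (metastatic) disease they
#' indicate. The medication classifier applies only to the sites present in
#' this map; for other sites the medication evidence is uninformative. The
#' packaged table is a synthetic curated stand-in; supply your own TSV with
#' columns `drug`, `site` to replace it.
#'
#' @param path Path to a TSV; default is the packaged table.
#' @return A tibble of class `met_med_map` with attribute `valid_sites`.
#' @export
read_met_meds <- function(path = system.file("extdata", "met_meds.tsv",
                                             package = "oncophen")) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("drug", "site") %in% names(m))) {
    abort("Medication map must have columns drug, site",
          class = "oncophen_parse_error")
  }
  bad <- setdiff(unique(m$site), site_categories())
  if (length(bad)) {
    abort(sprintf("Medication map site(s) not recognised: %s",
                  paste(bad, collapse = ", ")),
          class = "oncophen_parse_error")
  }
  m$drug <- norm_str(m$drug)
  out <- as_tibble(m[c("drug", "site")])
  attr(out, "valid_sites") <- sort(unique(out$site))
  class(out) <- c("met_med_map", class(out))
  out
}

# ---------------------------------------------------------------------------
# Published reference counts used as validation inputs

#' Per-site method-positive counts from a published 50,559-patient cohort
#'
#' Patient counts per cancer site under the three site-assignment methods
#' (all categories; single majority category; two most frequent categories)
#' reported for a large medical-oncology cohort. Because the methods are
#' nested by construction (every majority-method positive is a two-category
#' positive, and every two-category positive an any-category positive), these
#' marginals determine all pairwise 2x2 tables — see
#' [reconstruct_nested_tables()]. Used to validate the agreement statistics.
#'
#' @return Tibble with columns `site`, `n_a`, `n_b`, `n_c` and attribute
#'   `n_total` (cohort size 50,559).
#' @export
reference_site_counts <- function() {
  out <- tibble(
    site = site_categories(),
    n_a = c(11898L, 3474L, 15248L, 7007L, 3919L, 2954L,
            5848L, 6669L, 2331L, 3669L, 3380L, 6905L),
    n_b = c(10611L, 1386L, 12774L, 4556L, 3113L, 2144L,
            3524L, 4835L, 1426L, 2003L, 2175L, 860L),
    n_c = c(11684L, 3031L, 14735L, 6491L, 3744L, 2710L,
            5348L, 6209L, 2010L, 3152L, 3060L, 5334L)
  )
  attr(out, "n_total") <- 50559L
  out
}

#' Metastasis-classifier marginals from the same published cohort
#'
#' Both-positive and per-method positive counts for the two whole-cohort
#' metastasis classifiers (diagnosis codes and the text engine), from which
#' the full 2x2 agreement table is reconstructed.
#'
#' @return Named list: `both_yes`, `icd_yes`, `nlp_yes`, `n`.
#' @export
reference_met_counts <- function() {
  list(both_yes = 16554L, icd_yes = 22461L, nlp_yes = 22336L, n = 50559L)
}
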