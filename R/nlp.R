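# Rule-based metastasis mention engine: lexicon matching on token boundaries,
# then ConText-style assertion classification (certainty, temporality,
# experiencer) with fixed-window, sentence-bounded cue scoping, then an
# existential patient-level summary.
#
# Output is a pure function of (text, rules): no state, no ordering effects.

#' Default assertion rules for the metastasis text engine
#'
#' The metastasis lexicon, the cue lists for each assertion attribute, and
#' the scope window. Cues on the stated side of a mention, within
#' `scope_window` tokens and not across a sentence boundary or a scope
#' terminator ("but", "however"), set the attribute; the defaults are
#' positive / current / patient. All lists are user-editable and can be
#' stored in / loaded from YAML ([read_assertion_rules()]).
#'
#' @param scope_window Cue scope in tokens (default 6).
#' @return A list of class `assertion_rules`.
#' @export
default_assertion_rules <- function(scope_window = 6) {
  structure(list(
    lexicon = c("metastatic disease", "metastatic", "metastasis",
                "metastases", "mets", "stage iv", "stage 4"),
    pre_negation = c("no evidence of", "no", "without", "denies",
                     "negative for", "free of", "rules out", "ruled out",
                     "absence of"),
    post_negation = c("was ruled out", "is unlikely", "not identified",
                      "not seen"),
    pre_uncertainty = c("possible", "possibly", "probable", "suspicious for",
                        "concerning for", "cannot exclude", "may represent",
                        "questionable"),
    post_uncertainty = c("cannot be excluded", "is possible"),
    pre_historical = c("history of", "prior", "previous", "resolved",
                       "past medical history of", "h/o"),
    post_historical = c("in remission", "now resolved", "years ago"),
    pre_experiencer = c("mother", "father", "sister", "brother", "aunt",
                        "uncle", "grandmother", "grandfather",
                        "family history of", "mother's", "father's"),
    post_experiencer = character(),
    terminators = c("but", "however", "although", "aside"),
    scope_window = as.integer(scope_window)
  ), class = "assertion_rules")
}

validate_rules <- function(rules) {
  if (!length(rules$lexicon)) {
    abort("Assertion rules need a non-empty lexicon",
          class = "oncophen_error")
  }
  if (is.null(rules$scope_window) || rules$scope_window < 1) {
    abort("Assertion rules need scope_window >= 1", class = "oncophen_error")
  }
  invisible(rules)
}

#' Read / write assertion rules as YAML
#'
#' @param path YAML file path.
#' @return For `read_assertion_rules()`, an `assertion_rules` object.
#' @export
read_assertion_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_assertion_rules()
  for (nm in intersect(names(raw), names(base))) base[[nm]] <- raw[[nm]]
  base$scope_window <- as.integer(base$scope_window)
  base$lexicon <- as.character(base$lexicon)
  validate_rules(base)
  base
}

#' @rdname read_assertion_rules
#' @param rules An `assertion_rules` object.
#' @export
write_assertion_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

# Tokenize text into word tokens with 0-based half-open character spans and
# sentence ids (sentences split on . ! ? ;).
tokenize <- function(text) {
  m <- gregexpr("[A-Za-z0-9']+", text)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), start = integer(), end = integer(),
                  sentence = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tok <- tolower(substring(text, start + 1L, start + len))
  # sentence index: count boundary characters before each token
  bnd <- gregexpr("[.!?;]", text)[[1]]
  bnd <- if (bnd[1] == -1) integer() else as.integer(bnd) - 1L
  sent <- vapply(start, function(s) sum(bnd < s), integer(1))
  tibble(token = tok, start = start, end = start + len, sentence = sent + 1L)
}

#' Detect metastasis mentions in a note
#'
#' Case-insensitive lexicon matching on token boundaries; multi-word terms
#' are supported and overlapping matches resolve longest-first (so
#' "metastatic disease" wins over "metastatic"). Substrings inside other
#' words never match ("metabolic" does not contain a mention).
#'
#' @param text A single note text.
#' @param rules Assertion rules.
#' @return Tibble with 0-based half-open character `start`/`end`, the
#'   matched `term`, token positions, and unset assertion columns.
#' @export
detect_mentions <- function(text, rules = default_assertion_rules()) {
  validate_rules(rules)
  empty <- tibble(start = integer(), end = integer(), term = character(),
                  tok_first = integer(), tok_last = integer(),
                  certainty = character(), temporality = character(),
                  experiencer = character())
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  toks <- tokenize(text)
  if (!nrow(toks)) return(empty)
  terms <- stringr::str_split(tolower(rules$lexicon), stringr::fixed(" "))
  ord <- order(-lengths(terms))
  taken <- rep(FALSE, nrow(toks))
  hits <- list()
  for (ti in ord) {
    tt <- terms[[ti]]
    L <- length(tt)
    if (L > nrow(toks)) next
    for (i in seq_len(nrow(toks) - L + 1L)) {
      if (any(taken[i:(i + L - 1L)])) next
      if (all(toks$token[i:(i + L - 1L)] == tt) &&
          toks$sentence[i] == toks$sentence[i + L - 1L]) {
        taken[i:(i + L - 1L)] <- TRUE
        hits[[length(hits) + 1L]] <- tibble(
          start = toks$start[i], end = toks$end[i + L - 1L],
          term = rules$lexicon[ti], tok_first = i, tok_last = i + L - 1L
        )
      }
    }
  }
  if (!length(hits)) return(empty)
  bind_rows(hits) %>%
    arrange(.data$start) %>%
    mutate(certainty = NA_character_, temporality = NA_character_,
           experiencer = NA_character_)
}

# Does any cue phrase occur in the token window? Cues are token sequences;
# the window is cut at sentence boundaries and scope terminators.
cue_in_window <- function(toks, idx_range, cues) {
  if (!length(idx_range) || !length(cues)) return(FALSE)
  win <- toks$token[idx_range]
  for (cue in stringr::str_split(tolower(cues), stringr::fixed(" "))) {
    L <- length(cue)
    if (L > length(win)) next
    for (i in seq_len(length(win) - L + 1L)) {
      if (all(win[i:(i + L - 1L)] == cue)) return(TRUE)
    }
  }
  FALSE
}

scope_indices <- function(toks, anchor, rules, side) {
  sent <- toks$sentence[anchor]
  if (side == "pre") {
    idx <- seq(max(1L, anchor - rules$scope_window), anchor - 1L)
  } else {
    idx <- seq(anchor + 1L, min(nrow(toks), anchor + rules$scope_window))
  }
  idx <- idx[idx >= 1L & idx <= nrow(toks) & idx != anchor]
  idx <- idx[toks$sentence[idx] == sent]
  # a terminator cuts the scope between cue and mention
  term <- idx[toks$token[idx] %in% tolower(rules$terminators)]
  if (length(term)) {
    if (side == "pre") idx <- idx[idx > max(term)] else idx <- idx[idx < min(term)]
  }
  idx
}

#' Set assertion status on detected mentions
#'
#' Classifies each mention's certainty (positive / negative / possible),
#' temporality (current / historical), and experiencer (patient / other).
#' A cue inside the scope window on its stated side of the mention sets the
#' attribute; negation takes precedence over uncertainty; defaults are
#' positive, current, patient.
#'
#' @param mentions Output of [detect_mentions()] on the same `text`.
#' @param text The note text.
#' @param rules Assertion rules.
#' @return The mentions tibble with assertion columns filled.
#' @export
assert_status <- function(mentions, text, rules = default_assertion_rules()) {
  validate_rules(rules)
  if (!nrow(mentions)) return(mentions)
  toks <- tokenize(text)
  for (k in seq_len(nrow(mentions))) {
    pre <- scope_indices(toks, mentions$tok_first[k], rules, "pre")
    post <- scope_indices(toks, mentions$tok_last[k], rules, "post")
    neg <- cue_in_window(toks, pre, rules$pre_negation) ||
      cue_in_window(toks, post, rules$post_negation)
    unc <- cue_in_window(toks, pre, rules$pre_uncertainty) ||
      cue_in_window(toks, post, rules$post_uncertainty)
    hist <- cue_in_window(toks, pre, rules$pre_historical) ||
      cue_in_window(toks, post, rules$post_historical)
    exp_ <- cue_in_window(toks, pre, rules$pre_experiencer) ||
      cue_in_window(toks, post, rules$post_experiencer)
    mentions$certainty[k] <- if (neg) "negative" else if (unc) "possible" else "positive"
    mentions$temporality[k] <- if (hist) "historical" else "current"
    mentions$experiencer[k] <- if (exp_) "other" else "patient"
  }
  mentions
}

#' Extract asserted metastasis mentions from a notes table
#'
#' @param notes Tibble with `patient_id`, `date`, `text`.
#' @param rules Assertion rules.
#' @return Tibble of mentions with `patient_id` and `note` (row index).
#' @export
nlp_mentions <- function(notes, rules = default_assertion_rules()) {
  if (!nrow(notes)) {
    return(mutate(detect_mentions("", rules), patient_id = character(0),
                  note = integer(0)))
  }
  purrr::imap(notes$text, function(tx, i) {
    m <- detect_mentions(tx, rules)
    if (!nrow(m)) return(NULL)
    assert_status(m, tx, rules) %>%
      mutate(patient_id = notes$patient_id[i], note = i)
  }) %>% bind_rows()
}

#' Patient-level metastasis call from text mentions
#'
#' The existential summary: a patient is called metastatic iff at least one
#' mention is positive, current, and about the patient. Patients without
#' notes (or without mentions) are called non-metastatic — the text engine,
#' like the diagnosis-code classifier, runs on the whole cohort and never
#' returns missing. Optionally, "possible" certainty can count as positive.
#'
#' @param mentions Output of [nlp_mentions()].
#' @param patients Patient ids to call (required so note-less patients get a
#'   call).
#' @param possible_as_yes Count possible/current/patient mentions as yes
#'   (default `FALSE`).
#' @return Tibble `patient_id`, `nlp` (`"yes"`/`"no"`).
#' @export
summarize_patient <- function(mentions, patients,
                              possible_as_yes = FALSE) {
  ok_cert <- if (possible_as_yes) c("positive", "possible") else "positive"
  pos <- mentions %>%
    filter(.data$certainty %in% ok_cert,
           .data$temporality == "current",
           .data$experiencer == "patient") %>%
    pull("patient_id") %>% unique()
  tibble(patient_id = patients,
         nlp = ifelse(patients %in% pos, "yes", "no"))
}
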