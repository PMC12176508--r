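# Chance-corrected agreement (Cohen's and Fleiss' kappa), standardized mean
# differences for covariate balance, and the nested-marginal reconstruction
# that turns published per-method positive counts into full contingency
# tables.
#
# Internal values are kept at full precision; two-decimal display happens in
# the report renderers.

#' A 2x2 agreement table
#'
#' @param a Both-positive count.
#' @param b Rater-1-only count.
#' @param c Rater-2-only count.
#' @param d Both-negative count.
#' @return Object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || sum(cells) <= 0) {
    abort("two_by_two needs non-negative cells with a positive total",
          class = "oncophen_error")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (a + d) / n` and expected agreement
#' `p_e = [(a+b)(a+c) + (c+d)(b+d)] / n^2`. Note kappa is agreement beyond
#' chance, not raw agreement: 0.50 means 50% of the non-chance agreement is
#' attained. Degenerate tables with `p_e = 1` (all mass on one margin
#' pattern) leave kappa undefined and raise an error of class
#' `oncophen_undefined_kappa` rather than returning a number.
#'
#' @param t A [two_by_two()] (or a 2x2 matrix, rater 1 in rows, positive
#'   first).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(t) {
  if (is.matrix(t)) t <- two_by_two(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  p_o <- (t$a + t$d) / n
  p_e <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (1 - p_e < 1e-12) {
    abort("Cohen's kappa undefined: expected agreement is 1",
          class = "oncophen_undefined_kappa")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa for m binary raters
#'
#' Standard Fleiss computation for a fixed rater count: per-subject
#' agreement `P_i = [sum_j n_ij (n_ij - 1)] / [m (m - 1)]` averaged over
#' subjects, against chance agreement `P_e = sum_j p_j^2` from the pooled
#' category proportions.
#'
#' @param yes_votes Integer vector: per-subject count of "yes" ratings, or a
#'   named histogram over vote counts `0..m` (names are the vote counts).
#' @param m Number of raters (>= 2).
#' @return Fleiss' kappa; errors with class `oncophen_undefined_kappa` when
#'   `P_e = 1`.
#' @export
fleiss_kappa <- function(yes_votes, m) {
  stopifnot(m >= 2)
  if (!is.null(names(yes_votes))) {
    votes <- as.integer(names(yes_votes))
    ns <- as.numeric(yes_votes)
  } else {
    if (any(yes_votes < 0 | yes_votes > m)) {
      abort("Vote counts must lie in 0..m", class = "oncophen_error")
    }
    votes <- 0:m
    ns <- vapply(votes, function(v) sum(yes_votes == v), numeric(1))
  }
  if (any(votes < 0 | votes > m)) {
    abort("Vote counts must lie in 0..m", class = "oncophen_error")
  }
  n_sub <- sum(ns)
  if (n_sub <= 0) abort("No subjects", class = "oncophen_error")
  p_yes <- sum(ns * votes) / (n_sub * m)
  p_e <- p_yes^2 + (1 - p_yes)^2
  p_i <- (votes * (votes - 1) + (m - votes) * (m - votes - 1)) / (m * (m - 1))
  p_bar <- sum(ns * p_i) / n_sub
  if (1 - p_e < 1e-12) {
    abort("Fleiss' kappa undefined: expected agreement is 1",
          class = "oncophen_undefined_kappa")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Reconstruct agreement tables from nested per-site marginals
#'
#' The three site-assignment methods nest by construction: every
#' single-majority (B) positive is a two-category (C) positive, and every C
#' positive an any-category (A) positive. Under that nesting the three
#' per-site positive counts and the cohort size determine every pairwise
#' 2x2 table and the three-rater vote histogram exactly — which is what
#' makes published per-method counts testable without patient-level data.
#'
#' @param site Site label (used in error messages).
#' @param n_a,n_c,n_b Positive counts under Methods A, C, B.
#' @param n Cohort size.
#' @return List with `ab`, `ac`, `bc` ([two_by_two()] tables; first-named
#'   method is rater 1) and `votes` (named histogram of yes-votes 3..0).
#' @export
reconstruct_nested_tables <- function(site, n_a, n_c, n_b, n) {
  if (!(n_b <= n_c && n_c <= n_a && n_a <= n)) {
    abort(sprintf("Counts for site '%s' violate nesting n_b <= n_c <= n_a <= n",
                  site), class = "oncophen_error")
  }
  list(
    ab = two_by_two(n_b, n_a - n_b, 0, n - n_a),
    ac = two_by_two(n_c, n_a - n_c, 0, n - n_a),
    bc = two_by_two(n_b, 0, n_c - n_b, n - n_c),
    votes = setNames(c(n_b, n_c - n_b, n_a - n_c, n - n_a),
                     c("3", "2", "1", "0"))
  )
}

#' Per-site agreement among the three site methods
#'
#' Applies [reconstruct_nested_tables()] to each site's marginals and
#' computes the three pairwise Cohen kappas plus the three-method Fleiss
#' kappa from the vote histogram.
#'
#' @param per_site_counts Tibble `site`, `n_a`, `n_b`, `n_c` (e.g.
#'   [reference_site_counts()] or [site_method_counts()]).
#' @param n Cohort size; defaults to the table's `n_total` attribute.
#' @return Tibble of class `site_agreement`: `site`, `n_a`, `n_b`, `n_c`,
#'   `kappa_ab`, `kappa_ac`, `kappa_bc`, `kappa_abc`.
#' @export
site_agreement <- function(per_site_counts,
                           n = attr(per_site_counts, "n_total")) {
  if (is.null(n)) abort("Supply the cohort size n", class = "oncophen_error")
  rows <- purrr::pmap(per_site_counts[c("site", "n_a", "n_b", "n_c")],
    function(site, n_a, n_b, n_c) {
      r <- reconstruct_nested_tables(site, n_a, n_c, n_b, n)
      tibble(site = site, n_a = n_a, n_b = n_b, n_c = n_c,
             kappa_ab = cohen_kappa(r$ab), kappa_ac = cohen_kappa(r$ac),
             kappa_bc = cohen_kappa(r$bc),
             kappa_abc = fleiss_kappa(r$votes, m = 3))
    })
  out <- bind_rows(rows)
  attr(out, "n_total") <- n
  class(out) <- c("site_agreement", class(out))
  out
}

#' @method tidy site_agreement
#' @export
tidy.site_agreement <- function(x, ...) as_tibble(x)

#' @method glance site_agreement
#' @export
glance.site_agreement <- function(x, ...) {
  tibble(n_sites = nrow(x), n_total = attr(x, "n_total"),
         median_kappa_ab = median(x$kappa_ab),
         median_kappa_ac = median(x$kappa_ac),
         median_kappa_bc = median(x$kappa_bc),
         min_kappa = min(x$kappa_ab, x$kappa_ac, x$kappa_bc))
}

#' @method autoplot site_agreement
#' @export
autoplot.site_agreement <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("site", dplyr::starts_with("kappa")) %>%
    tidyr::pivot_longer(-"site", names_to = "pair", values_to = "kappa") %>%
    mutate(pair = toupper(sub("kappa_", "", .data$pair)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kappa,
                                     y = stats::reorder(.data$site,
                                                        .data$kappa),
                                     colour = .data$pair)) +
    ggplot2::geom_vline(xintercept = c(0.41, 0.61), linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "kappa", y = NULL, colour = "methods") +
    ggplot2::theme_minimal()
}

#' Cohen's kappa between tri-state call vectors, excluding missing
#'
#' Pairwise-complete agreement: patients are kept only when both classifiers
#' produced a yes/no call; missing is never imputed. Reports the kappa and
#' the number of patients used.
#'
#' @param calls1,calls2 Equal-length vectors over `"yes"`, `"no"`,
#'   `"missing"`.
#' @return One-row tibble `kappa`, `n_used`.
#' @export
pairwise_kappa_with_missing <- function(calls1, calls2) {
  if (length(calls1) != length(calls2)) {
    abort("Call vectors must have equal length", class = "oncophen_error")
  }
  keep <- calls1 %in% c("yes", "no") & calls2 %in% c("yes", "no")
  if (!any(keep)) {
    abort("Kappa undefined: no pairwise-complete patients",
          class = "oncophen_undefined_kappa")
  }
  x <- calls1[keep]; y <- calls2[keep]
  t <- two_by_two(sum(x == "yes" & y == "yes"),
                  sum(x == "yes" & y == "no"),
                  sum(x == "no" & y == "yes"),
                  sum(x == "no" & y == "no"))
  tibble(kappa = cohen_kappa(t), n_used = sum(keep))
}

#' Pairwise kappa matrix across metastasis classifiers
#'
#' Computes [pairwise_kappa_with_missing()] for every classifier pair. The
#' phase-I-trial classifier is excluded by default: it never produces an
#' explicit "no", so agreement with it is not meaningful.
#'
#' @param calls Output of [classify_metastasis()].
#' @param methods Classifier columns to compare.
#' @return Tibble of class `met_agreement`: `method1`, `method2`, `kappa`,
#'   `n_used` (lower triangle).
#' @export
met_agreement <- function(calls,
                          methods = c("icd", "nlp", "registry",
                                      "treatment_plan", "medications")) {
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  out <- purrr::map(pairs, function(p) {
    res <- tryCatch(
      pairwise_kappa_with_missing(calls[[p[1]]], calls[[p[2]]]),
      oncophen_undefined_kappa = function(e) tibble(kappa = NA_real_,
                                                    n_used = 0L)
    )
    mutate(res, method1 = p[1], method2 = p[2], .before = 1)
  }) %>% bind_rows()
  class(out) <- c("met_agreement", class(out))
  out
}

#' @method tidy met_agreement
#' @export
tidy.met_agreement <- function(x, ...) as_tibble(x)

#' @method glance met_agreement
#' @export
glance.met_agreement <- function(x, ...) {
  best <- x[which.max(x$kappa), ]
  tibble(n_pairs = nrow(x), max_kappa = best$kappa,
         max_pair = paste(best$method1, best$method2, sep = "-"),
         median_kappa = median(x$kappa, na.rm = TRUE))
}

#' @method autoplot met_agreement
#' @export
autoplot.met_agreement <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$method1, y = .data$method2,
                               fill = .data$kappa)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", round_half_up(.data$kappa, 2)))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "kappa") +
    ggplot2::theme_minimal()
}

# ---------------------------------------------------------------------------
# Standardized mean differences

#' Standardized mean difference for a binary variable
#'
#' Pooled-SD form for two proportions:
#' `|p1 - p2| / sqrt([p1 (1 - p1) + p2 (1 - p2)] / 2)`. Equal proportions
#' give 0 even when the pooled variance vanishes; unequal proportions with
#' zero pooled variance (both degenerate at opposite ends) return `Inf`.
#'
#' @param p1,p2 Group proportions in `[0, 1]`.
#' @return SMD (non-negative).
#' @export
smd_binary <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (p1 == p2) return(0)
  s <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (s == 0) return(Inf)
  abs(p1 - p2) / s
}

#' Standardized mean difference for a multi-category variable
#'
#' Mahalanobis generalization over the category proportions: with
#' `D = p1 - p2` truncated to the first k-1 categories and pooled
#' multinomial covariance
#' `S_ij = [p1_i (d_ij - p1_j) + p2_i (d_ij - p2_j)] / 2`, the SMD is
#' `sqrt(D' S^-1 D)`. The pseudo-inverse handles singular `S`, which also
#' makes the result invariant to which category is dropped. The k = 2 case
#' reduces to [smd_binary()].
#'
#' @param p1,p2 Probability vectors over the same k >= 2 categories.
#' @return SMD (non-negative).
#' @export
smd_multicategory <- function(p1, p2) {
  if (length(p1) != length(p2) || length(p1) < 2) {
    abort("p1 and p2 must be probability vectors of equal length >= 2",
          class = "oncophen_error")
  }
  if (abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6) {
    abort("Category proportions must each sum to 1",
          class = "oncophen_error")
  }
  k <- length(p1)
  idx <- seq_len(k - 1)
  D <- (p1 - p2)[idx]
  S <- matrix(0, k - 1, k - 1)
  for (i in idx) for (j in idx) {
    dij <- as.numeric(i == j)
    S[i, j] <- (p1[i] * (dij - p1[j]) + p2[i] * (dij - p2[j])) / 2
  }
  val <- drop(t(D) %*% MASS::ginv(S) %*% D)
  sqrt(max(val, 0))
}

#' Covariate balance table between two groups
#'
#' One SMD per variable: binary/logical variables via [smd_binary()],
#' categorical variables via [smd_multicategory()] over their observed
#' category distributions. Imbalance flags at the conventional thresholds:
#' SMD >= 0.20 small, >= 0.50 moderate.
#'
#' @param data Tibble with one row per patient.
#' @param group Name of a logical (or two-level) grouping column.
#' @param variables Character vector of columns to balance-check.
#' @param thresholds Two named or positional thresholds, small then
#'   moderate.
#' @return Tibble of class `balance_table`: `variable`, `type`, `smd`,
#'   `flag`.
#' @export
balance_table <- function(data, group, variables,
                          thresholds = c(small = 0.20, moderate = 0.50)) {
  g <- data[[group]]
  if (is.null(g)) abort("Grouping column not found", class = "oncophen_error")
  if (!is.logical(g)) g <- g == sort(unique(g))[1]
  if (any(is.na(g))) abort("Group flag must be defined for every patient",
                           class = "oncophen_error")
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    if (is.logical(x)) {
      smd <- smd_binary(mean(x[g]), mean(x[!g]))
      type <- "binary"
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2) {
        warn(sprintf("Variable '%s' has a single category; SMD set to 0", v))
        smd <- 0
        type <- "degenerate"
      } else {
        p1 <- as.numeric(table(factor(x[g], levels = lev))) / sum(g)
        p2 <- as.numeric(table(factor(x[!g], levels = lev))) / sum(!g)
        smd <- smd_multicategory(p1, p2)
        type <- "categorical"
      }
    }
    tibble(variable = v, type = type, smd = smd)
  })
  out <- bind_rows(rows) %>%
    mutate(flag = dplyr::case_when(
      .data$smd >= thresholds[[2]] ~ "moderate",
      .data$smd >= thresholds[[1]] ~ "small",
      TRUE ~ "balanced"
    ))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("balance_table", class(out))
  out
}

#' @method tidy balance_table
#' @export
tidy.balance_table <- function(x, ...) as_tibble(x)

#' @method glance balance_table
#' @export
glance.balance_table <- function(x, ...) {
  tibble(n_variables = nrow(x), max_smd = max(x$smd),
         n_small = sum(x$flag == "small"),
         n_moderate = sum(x$flag == "moderate"))
}

#' @method autoplot balance_table
#' @export
autoplot.balance_table <- function(object, ...) {
  th <- attr(object, "thresholds")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$smd,
                               y = stats::reorder(.data$variable,
                                                  .data$smd))) +
    ggplot2::geom_vline(xintercept = th, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized mean difference", y = NULL) +
    ggplot2::theme_minimal()
}
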