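# Shared helpers: display rounding and enum normalization.
# Rounding is applied only at render time; internal values keep full precision.

#' Round half-up to a fixed number of decimals
#'
#' Display rounding for report tables: 0.535 renders as 0.54, never 0.53.
#' Base `round()` rounds half-to-even, which does not match how clinical
#' tables are conventionally printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.535, 2)
#' round_half_up(44.424, 1)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Format a proportion as a display percentage string (one decimal, half-up).
fmt_pct <- function(num, den) {
  sprintf("%.1f", round_half_up(100 * num / den, 1))
}

# Lower-case, trim, and collapse internal whitespace; NA passes through.
norm_str <- function(x) {
  out <- stringr::str_squish(tolower(as.character(x)))
  out[is.na(x)] <- NA_character_
  out
}

# Map a raw string onto an enum after case normalization, erroring with
# file/row/field context when it does not belong.
norm_enum <- function(x, levels, field, file = NULL) {
  y <- norm_str(x)
  y <- gsub("[ -]", "_", y)
  bad <- !is.na(y) & !(y %in% levels)
  if (any(bad)) {
    row <- which(bad)[1]
    abort(sprintf(
      "Unknown value '%s' for field '%s'%s (row %d); expected one of: %s",
      x[row], field, if (is.null(file)) "" else paste0(" in ", file),
      row, paste(levels, collapse = ", ")
    ), class = "oncophen_parse_error")
  }
  y
}

# Inclusive date-window predicate used by every calendar filter.
in_window <- function(date, window_start, window_end) {
  date >= window_start & date <= window_end
}

as_date_strict <- function(x, field, file = NULL) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(d)
  if (any(bad)) {
    row <- which(bad)[1]
    abort(sprintf(
      "Unparseable ISO-8601 date '%s' for field '%s'%s (row %d)",
      x[row], field, if (is.null(file)) "" else paste0(" in ", file), row
    ), class = "oncophen_parse_error")
  }
  d
}
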