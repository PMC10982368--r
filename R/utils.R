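#' faersignal: disproportionality signal detection for FAERS reports
#'
#' Pipeline components for spontaneous-report pharmacovigilance: FAERS ASCII
#' ingestion, FDA-rule deduplication, cohort curation, PT/SOC mapping,
#' ROR and BCPNN-IC screening, descriptive characterization, time-to-onset
#' analysis, subgroup re-screening, and a synthetic data generator with
#' planted signals.
#'
#' @keywords internal
"_PACKAGE"

# Canonical MedDRA-style preferred-term casing: trimmed, internal whitespace
# collapsed, first letter upper-cased, remainder lower-cased. FAERS PT casing
# is inconsistent across quarters and counts must not split on case variants.

#' Normalize a preferred-term string
#'
#' Trims surrounding whitespace, collapses internal whitespace runs to a
#' single space, and applies sentence case (first character upper, rest
#' lower). All PT counting in the package happens on this canonical form.
#'
#' @param x character vector of verbatim preferred terms.
#' @return character vector of the same length; `NA` stays `NA`, and strings
#'   that are empty after trimming become `NA`.
#' @examples
#' normalize_pt(c("DRY MOUTH", "  Blood  pressure increased "))
#' @export
normalize_pt <- function(x) {
  x <- as.character(x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  out <- ifelse(
    is.na(x) | x == "",
    NA_character_,
    paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
  )
  out
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables in pharmacovigilance
#' papers are conventionally rounded half-up, so proportions such as
#' 60.065 print as 60.07 rather than 60.06.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round far below the target precision to strip float representation
  # error before the half-up decision
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

# Word-bounded, case-insensitive pattern matching. A pattern matches when it
# occurs in the text delimited by non-alphanumeric characters (or the string
# edges), so "MIRABEGRON" matches "MIRABEGRON 50 MG TABLET" but not
# "MIRTAZAPINE". Patterns are treated as literal strings.
word_match <- function(text, patterns) {
  if (length(patterns) == 0L) stop("patterns must be non-empty")
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", patterns)
  rx <- paste0(
    "(^|[^[:alnum:]])(", paste(esc, collapse = "|"), ")([^[:alnum:]]|$)"
  )
  out <- grepl(rx, text, ignore.case = TRUE)
  out[is.na(text)] <- FALSE
  out
}

# internal: stop unless all named columns are present (case-insensitive names
# are resolved upstream)
check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# internal: empty-string-safe numeric parse
as_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
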