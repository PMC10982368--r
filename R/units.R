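# Age and weight arrive in mixed units; analyses band them in years and kg.

#' Convert FAERS age values to years
#'
#' Unit codes: `YR` years, `DEC` decades, `MON` months, `WK` weeks, `DY`
#' days, `HR` hours. An unknown/blank unit with a value in the 18--120 range
#' is taken to be years (the overwhelmingly common data-entry omission);
#' anything else with an unknown unit, and any negative value, is returned as
#' `NA` (unknown).
#'
#' @param value numeric vector of age values.
#' @param unit character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years (`NA` = unknown).
#' @examples
#' normalize_age(c(65, 780, 7), c("YR", "MON", "DEC"))
#' @export
normalize_age <- function(value, unit) {
  value <- as_num(as.character(value))
  unit <- toupper(trimws(as.character(unit)))
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  factor_for <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1429,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_for[unit])
  out <- value * f
  # blank/unknown unit: plausible adult ages pass through as years
  unk <- (is.na(f) | unit == "" | unit == "UNK") & !is.na(value)
  out[unk] <- ifelse(value[unk] >= 18 & value[unk] <= 120, value[unk], NA)
  neg <- !is.na(value) & value < 0
  if (any(neg)) {
    warning(sprintf("%d negative age value(s) set to unknown", sum(neg)))
    out[neg] <- NA
  }
  out
}

#' Convert FAERS weight values to kilograms
#'
#' Unit codes: `KG` kilograms, `LBS` pounds (x 0.453592), `GMS` grams
#' (/ 1000). Non-positive values and unknown units are returned as `NA`.
#'
#' @param value numeric vector of weight values.
#' @param unit character vector of unit codes (recycled if length 1).
#' @return numeric vector of weights in kg (`NA` = unknown).
#' @examples
#' normalize_weight(c(70, 220), c("KG", "LBS"))
#' @export
normalize_weight <- function(value, unit) {
  value <- as_num(as.character(value))
  unit <- toupper(trimws(as.character(unit)))
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  factor_for <- c(KG = 1, LBS = 0.453592, GMS = 1 / 1000)
  f <- unname(factor_for[unit])
  out <- value * f
  bad <- !is.na(value) & value <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive weight value(s) set to unknown", sum(bad)))
  }
  out[bad | is.na(f)] <- NA
  out
}
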