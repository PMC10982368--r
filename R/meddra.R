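# PT -> SOC resolution. MedDRA is licensed and cannot ship with the package:
# real analyses must supply a two-column mapping extracted from a licensed
# MedDRA release. A toy ontology covering the vocabulary used by the
# synthetic generator and the shipped examples lives in inst/extdata.

#' Load a preferred-term to system-organ-class mapping
#'
#' Two delimited columns, PT then SOC, with a header line. PTs are
#' case-normalized exactly as event terms are (see [normalize_pt()]), so
#' case variants collapse. Identical duplicate rows are deduplicated;
#' conflicting duplicates (one PT, two SOCs) are a hard error because each PT
#' must resolve to exactly one primary SOC.
#'
#' @param path mapping file.
#' @param delim field delimiter, default tab.
#' @param version_tag free-text tag recorded on the map.
#' @return object of class `pt_soc_map`: a named character vector
#'   (PT -> SOC) with a `version_tag` attribute.
#' @export
load_pt_soc_map <- function(path, delim = "\t", version_tag = basename(path)) {
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("mapping file must have two columns (PT, SOC)")
  pt <- normalize_pt(df[[1L]])
  soc <- trimws(df[[2L]])
  keep <- !duplicated(paste(pt, soc, sep = "\r"))
  pt <- pt[keep]; soc <- soc[keep]
  dup <- pt[duplicated(pt)]
  if (length(dup) > 0L) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  structure(stats::setNames(soc, pt), class = "pt_soc_map",
            version_tag = version_tag)
}

#' Resolve preferred terms to their primary SOC
#'
#' Total and deterministic: unmapped terms resolve to `"UNMAPPED"`. Unmapped
#' PTs still take part in PT-level screening but are excluded from SOC-level
#' aggregation.
#'
#' @param pt character vector of preferred terms (any casing).
#' @param map a `pt_soc_map` from [load_pt_soc_map()].
#' @return character vector of SOC names.
#' @export
resolve_soc <- function(pt, map) {
  out <- unname(map[normalize_pt(pt)])
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' Bundled toy PT->SOC ontology
#'
#' A small ontology (~70 PTs across 14 SOCs, urology/cardiology-flavoured)
#' used by the synthetic generator, the examples and the tests. It is *not*
#' MedDRA; supply a real mapping for real FAERS data.
#'
#' @return a `pt_soc_map`.
#' @export
toy_pt_soc_map <- function() {
  load_pt_soc_map(system.file("extdata", "toy_pt_soc.tsv",
                              package = "faersignal"),
                  version_tag = "toy-ontology")
}

#' Default excluded system organ classes
#'
#' Event classes generally unrelated to drug action that are removed before
#' disproportionality screening: injury/poisoning/procedural complications,
#' product issues, surgical and medical procedures, and social circumstances.
#'
#' @return character vector of four SOC names.
#' @export
faers_excluded_socs <- function() {
  c("Injury, poisoning and procedural complications",
    "Product issues",
    "Surgical and medical procedures",
    "Social circumstances")
}

#' Remove events belonging to excluded SOCs
#'
#' @param events data.frame with at least a `soc` column.
#' @param excluded character vector of SOC names to drop.
#' @return the filtered data.frame, with an `"n_removed"` attribute.
#' @export
exclude_socs <- function(events, excluded = faers_excluded_socs()) {
  drop <- events$soc %in% excluded
  out <- events[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Expected-reaction annotation list
#'
#' The default annotation of preferred terms regarded as expected from the
#' product label (23 terms for mirabegron). Joined onto screen output as the
#' `expected` flag.
#'
#' @return character vector of normalized PTs.
#' @export
expected_pts <- function() {
  normalize_pt(readLines(system.file("extdata", "expected_pts.txt",
                                     package = "faersignal"), warn = FALSE))
}

#' Load a country to continent mapping
#'
#' Two delimited columns (country code or name, continent). Lookups are
#' case-insensitive; unknown countries resolve to `"Unknown"`.
#'
#' @param path mapping file; default is the bundled table covering the
#'   country codes emitted by the synthetic generator plus common FAERS ones.
#' @param delim field delimiter.
#' @return object of class `country_continent_map` (named character vector).
#' @export
load_country_continent_map <- function(path = NULL, delim = "\t") {
  if (is.null(path)) {
    path <- system.file("extdata", "country_continent.tsv",
                        package = "faersignal")
  }
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  structure(stats::setNames(trimws(df[[2L]]), toupper(trimws(df[[1L]]))),
            class = "country_continent_map")
}

#' Resolve countries to continents
#'
#' @param country character vector of country codes or names.
#' @param map a `country_continent_map`.
#' @return character vector of continents, `"Unknown"` when unmatched.
#' @export
resolve_continent <- function(country, map = load_country_continent_map()) {
  out <- unname(map[toupper(trimws(as.character(country)))])
  out[is.na(out)] <- "Unknown"
  out
}
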