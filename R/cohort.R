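# Case-level curation: FDA deduplication rule, target-drug name matching,
# assembly of a relational case set, and cohort selection (primary-suspect
# restriction + healthcare-professional reporter restriction).

#' Default target-drug name patterns
#'
#' Generic and brand names of mirabegron used for retrieval; matching is
#' case-insensitive and word-bounded (see [match_target()]).
#'
#' @return character vector of patterns.
#' @export
mirabegron_patterns <- function() {
  c("MIRABEGRON", "BETMIGA", "BETANIS", "MYRBETRIQ")
}

#' Deduplicate DEMO records to one report version per case
#'
#' FDA-recommended rule: among records sharing a `CASEID`, retain the one
#' with the largest `FDA_DT`; among ties on `FDA_DT`, retain the largest
#' `PRIMARYID`. Both comparisons are on parsed numeric magnitude, never
#' lexicographic (identifiers may carry leading zeros). Records with a
#' missing `CASEID` are kept as their own singleton cases, with a warning.
#' The result is invariant to input order and idempotent.
#'
#' @param demo data.frame with columns `PRIMARYID`, `CASEID`, `FDA_DT`.
#' @return the retained rows of `demo` (one per distinct case), with
#'   attribute `"n_removed"` giving the number of duplicate versions dropped.
#' @export
dedup_cases <- function(demo) {
  check_cols(demo, c("PRIMARYID", "CASEID", "FDA_DT"), "DEMO")
  n <- nrow(demo)
  if (n == 0L) {
    attr(demo, "n_removed") <- 0L
    return(demo)
  }
  caseid <- trimws(demo$CASEID)
  missing_case <- is.na(caseid) | caseid == ""
  if (any(missing_case)) {
    warning(sprintf("%d record(s) without CASEID kept as singleton cases",
                    sum(missing_case)))
    caseid[missing_case] <- paste0("\x01singleton\x01", seq_len(n)[missing_case])
  }
  fda <- as_num(demo$FDA_DT)
  fda[is.na(fda)] <- -Inf
  prim <- as_num(demo$PRIMARYID)
  prim[is.na(prim)] <- -Inf
  ord <- order(caseid, fda, prim, method = "radix")
  keep_sorted <- !duplicated(caseid[ord], fromLast = TRUE)
  keep <- sort(ord[keep_sorted])
  out <- demo[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  out
}

#' Match target-drug rows in a DRUG table
#'
#' A row matches when any pattern occurs as a word-bounded, case-insensitive
#' substring of `DRUGNAME` or `PROD_AI` (verbatim FAERS names carry dose and
#' form suffixes, so exact equality would miss most rows while an unanchored
#' substring would over-match).
#'
#' @param drug data.frame with `DRUGNAME` and optionally `PROD_AI`.
#' @param patterns character vector of name patterns.
#' @return logical vector, one element per row of `drug`.
#' @export
match_target <- function(drug, patterns = mirabegron_patterns()) {
  hit <- word_match(drug$DRUGNAME, patterns)
  if ("PROD_AI" %in% names(drug)) {
    hit <- hit | word_match(drug$PROD_AI, patterns)
  }
  hit
}

#' Assemble a deduplicated case set from quarter bundles
#'
#' Concatenates one or more quarters, applies [dedup_cases()], restricts all
#' child tables to the retained report versions, parses demographics (ages to
#' years, weights to kg, dates with precision tags), normalizes reaction PTs
#' and drops within-report duplicate PTs, and flags target-drug rows.
#'
#' @param bundles a `faers_quarter` or list of them.
#' @param patterns target-drug name patterns.
#' @return object of class `faers_cases`: list of data.frames `demo` (one row
#'   per case; includes `is_target` = target drug in any role and `target_ps`
#'   = target drug with role PS), `drugs`, `reactions` (distinct case/PT),
#'   `therapies`, `outcomes` (distinct case/code), `indications`, and a
#'   `counts` list used for the attrition manifest.
#' @export
build_cases <- function(bundles, patterns = mirabegron_patterns()) {
  if (inherits(bundles, "faers_quarter")) bundles <- list(bundles)
  cat_tab <- function(tb) {
    do.call(rbind, lapply(bundles, function(b) {
      df <- b[[tb]]
      if (nrow(df) > 0L) df$quarter <- b$label
      df
    }))
  }
  demo_raw <- cat_tab("demo")
  if (is.null(demo_raw) || nrow(demo_raw) == 0L) stop("no DEMO records")

  counts <- list(
    demo_rows = nrow(demo_raw),
    malformed = Reduce(`+`, lapply(bundles, function(b) sum(b$counts$malformed))),
    orphans = Reduce(`+`, lapply(bundles, function(b) sum(b$counts$orphans)))
  )

  demo <- dedup_cases(demo_raw)
  counts$duplicates_removed <- attr(demo, "n_removed")
  counts$cases <- nrow(demo)

  keep_ids <- demo$PRIMARYID
  drugs <- cat_tab("drug")
  drugs <- drugs[drugs$PRIMARYID %in% keep_ids, , drop = FALSE]
  drugs$is_target <- match_target(drugs, patterns)

  reac <- cat_tab("reac")
  reac <- reac[reac$PRIMARYID %in% keep_ids, , drop = FALSE]
  reac$pt <- normalize_pt(reac$PT)
  reac <- reac[!is.na(reac$pt), c("PRIMARYID", "pt"), drop = FALSE]
  reac <- reac[!duplicated(paste(reac$PRIMARYID, reac$pt, sep = "\r")), ,
               drop = FALSE]

  ther <- cat_tab("ther")
  ther <- ther[ther$PRIMARYID %in% keep_ids, , drop = FALSE]
  if (nrow(ther) > 0L) {
    st <- faers_parse_date(ther$START_DT)
    en <- faers_parse_date(ther$END_DT)
    ther$start_date <- st$date
    ther$start_precision <- st$precision
    ther$end_date <- en$date
    ther$end_precision <- en$precision
  }

  outc <- cat_tab("outc")
  outc <- outc[outc$PRIMARYID %in% keep_ids, , drop = FALSE]
  if (nrow(outc) > 0L) {
    outc$OUTC_COD <- toupper(trimws(outc$OUTC_COD))
    outc <- outc[!duplicated(paste(outc$PRIMARYID, outc$OUTC_COD, sep = "\r")), ,
                 drop = FALSE]
  }

  indi <- cat_tab("indi")
  indi <- indi[indi$PRIMARYID %in% keep_ids, , drop = FALSE]
  if (nrow(indi) > 0L) indi$indi_pt <- normalize_pt(indi$INDI_PT)

  ev <- faers_parse_date(demo$EVENT_DT)
  demo$event_date <- ev$date
  demo$event_precision <- ev$precision
  fd <- faers_parse_date(demo$FDA_DT)
  demo$fda_date <- fd$date
  demo$sex <- toupper(trimws(demo$SEX))
  demo$sex[!(demo$sex %in% c("F", "M"))] <- "UNK"
  demo$age_years <- suppressWarnings(normalize_age(demo$AGE, demo$AGE_COD))
  demo$weight_kg <- suppressWarnings(normalize_weight(demo$WT, demo$WT_COD))
  demo$occp_cod <- toupper(trimws(demo$OCCP_COD))
  demo$occp_cod[is.na(demo$occp_cod) | demo$occp_cod == ""] <- "UNK"
  country <- toupper(trimws(demo$REPORTER_COUNTRY))
  occr <- toupper(trimws(demo$OCCR_COUNTRY))
  use_occr <- (is.na(country) | country == "") & !is.na(occr) & occr != ""
  country[use_occr] <- occr[use_occr]
  country[is.na(country) | country == ""] <- "UNK"
  demo$country <- country
  counts$country_from_occurrence <- sum(use_occr)

  tgt <- drugs[drugs$is_target, c("PRIMARYID", "ROLE_COD"), drop = FALSE]
  demo$is_target <- demo$PRIMARYID %in% tgt$PRIMARYID
  demo$target_ps <- demo$PRIMARYID %in%
    tgt$PRIMARYID[toupper(tgt$ROLE_COD) == "PS"]
  counts$target_any_role <- sum(demo$is_target)
  counts$target_ps <- sum(demo$target_ps)

  structure(list(demo = demo, drugs = drugs, reactions = reac,
                 therapies = ther, outcomes = outc, indications = indi,
                 counts = counts),
            class = "faers_cases")
}

#' Select target and comparator cohorts
#'
#' The target cohort contains deduplicated cases where a matched drug has
#' role `PS` and the reporter occupation is in `reporter_codes` (default the
#' healthcare professions MD, PH, OT). The comparator ("background") cohort
#' is every other deduplicated case under the same reporter filter, so both
#' arms of the 2x2 are curated identically; set `hcp_background = FALSE` to
#' compare against the unfiltered remainder instead. `strict_ps` additionally
#' requires that no non-target drug in the report carries role PS.
#'
#' @param cases a `faers_cases` from [build_cases()].
#' @param reporter_codes occupation codes defining eligible reporters.
#' @param strict_ps logical; require the target to be the *only* PS drug.
#' @param hcp_background logical; apply the reporter filter to the comparator.
#' @return object of class `faers_cohort`: list with `target` and
#'   `background` (rows of `demo`), the underlying `cases`, and `counts`.
#' @export
select_cohort <- function(cases, reporter_codes = c("MD", "PH", "OT"),
                          strict_ps = FALSE, hcp_background = TRUE) {
  demo <- cases$demo
  in_rep <- demo$occp_cod %in% reporter_codes
  is_tgt <- demo$target_ps
  if (strict_ps) {
    other_ps <- cases$drugs$PRIMARYID[
      toupper(cases$drugs$ROLE_COD) == "PS" & !cases$drugs$is_target]
    is_tgt <- is_tgt & !(demo$PRIMARYID %in% other_ps)
  }
  target <- demo[is_tgt & in_rep, , drop = FALSE]
  bg_pool <- if (hcp_background) demo[in_rep, , drop = FALSE] else demo
  background <- bg_pool[!(bg_pool$PRIMARYID %in% target$PRIMARYID), ,
                        drop = FALSE]
  if (nrow(target) == 0L) {
    stop(sprintf(paste0("empty target cohort (cases=%d, target any role=%d, ",
                        "target PS=%d, reporter-eligible=%d)"),
                 nrow(demo), sum(demo$is_target), sum(demo$target_ps),
                 sum(in_rep)), call. = FALSE)
  }
  counts <- c(cases$counts, list(
    reporter_eligible = sum(in_rep),
    reporter_excluded = nrow(demo) - sum(in_rep),
    cohort_target = nrow(target),
    cohort_background = nrow(background)
  ))
  structure(list(target = target, background = background, cases = cases,
                 reporter_codes = reporter_codes, strict_ps = strict_ps,
                 hcp_background = hcp_background, counts = counts),
            class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("FAERS cohort: %d target, %d background report(s) (%d cases)\n",
              nrow(x$target), nrow(x$background), nrow(x$cases$demo)))
  invisible(x)
}
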