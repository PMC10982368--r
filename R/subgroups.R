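# Subgroup re-screening: restrict both cohort arms to a report stratum
# (weight band, continent, or concomitant-drug co-reporting) and re-run the
# identical disproportionality machinery within the stratum.

#' Declare a report stratum
#'
#' @param kind `"weight_band"` (parameter one of `<50`, `50-100`, `>100`,
#'   `Unknown`), `"continent"` (e.g. `"Asia"`), `"concomitant_drug"` (a drug
#'   name pattern, word-bounded match), or `"all"` (the trivial stratum; the
#'   subgroup screen then equals the global screen).
#' @param parameter the band label / continent name / drug pattern.
#' @return object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(kind = c("weight_band", "continent",
                                   "concomitant_drug", "all"),
                          parameter = NULL) {
  kind <- match.arg(kind)
  if (kind == "weight_band" &&
      !parameter %in% c("<50", "50-100", ">100", "Unknown")) {
    stop("invalid weight band: ", parameter)
  }
  if (kind == "continent" &&
      !parameter %in% c("North America", "Europe", "Asia", "South America",
                        "Oceania", "Africa", "Unknown")) {
    stop("invalid continent: ", parameter)
  }
  if (kind == "concomitant_drug" &&
      (is.null(parameter) || !nzchar(parameter))) {
    stop("concomitant_drug requires a non-empty drug pattern")
  }
  structure(list(kind = kind, parameter = parameter),
            class = "subgroup_spec")
}

# internal: report ids co-listing a drug matching `pattern` in a non-target
# role row. `roles` limits the co-drug's role codes (NULL = any role).
co_drug_ids <- function(cases, pattern, roles = NULL) {
  drugs <- cases$drugs
  hit <- word_match(drugs$DRUGNAME, pattern) |
    word_match(drugs$PROD_AI, pattern)
  hit <- hit & !drugs$is_target
  if (!is.null(roles)) hit <- hit & toupper(drugs$ROLE_COD) %in% roles
  unique(drugs$PRIMARYID[hit])
}

#' Restrict a cohort to a stratum
#'
#' Both target and background arms are restricted to reports satisfying the
#' spec, giving a within-stratum 2x2. For `concomitant_drug` the stratum is
#' reports that also list a drug matching the parameter pattern in a role
#' other than the (target) PS match; `co_roles` can limit which roles count
#' (e.g. `c("C")` for strictly concomitant, the default `NULL` accepts any
#' role including SS).
#'
#' @param cohort a `faers_cohort`.
#' @param spec a `subgroup_spec`.
#' @param continent_map a `country_continent_map` (continent strata only).
#' @param co_roles optional role codes for the concomitant drug.
#' @return a `faers_cohort` restricted to the stratum; an empty target
#'   stratum produces a warning, not an error.
#' @export
stratify <- function(cohort, spec, continent_map = load_country_continent_map(),
                     co_roles = NULL) {
  keep_ids <- switch(
    spec$kind,
    all = c(cohort$target$PRIMARYID, cohort$background$PRIMARYID),
    weight_band = {
      demo <- cohort$cases$demo
      demo$PRIMARYID[assign_weight_group(demo$weight_kg) == spec$parameter]
    },
    continent = {
      demo <- cohort$cases$demo
      demo$PRIMARYID[resolve_continent(demo$country, continent_map) ==
                       spec$parameter]
    },
    concomitant_drug = co_drug_ids(cohort$cases, spec$parameter, co_roles)
  )
  out <- cohort
  out$target <- cohort$target[cohort$target$PRIMARYID %in% keep_ids, ,
                              drop = FALSE]
  out$background <- cohort$background[
    cohort$background$PRIMARYID %in% keep_ids, , drop = FALSE]
  out$subgroup <- spec
  if (nrow(out$target) == 0L) {
    warning(sprintf("empty target stratum for %s = %s", spec$kind,
                    spec$parameter %||% ""))
  }
  out
}

#' Most common co-reported drugs in the target cohort
#'
#' Counts distinct target reports listing each (upper-cased, whitespace
#' collapsed) non-target drug name; ties are broken alphabetically.
#'
#' @param cohort a `faers_cohort`.
#' @param k number of drugs to return.
#' @return data.frame with `drug` and `n_reports`, ranked.
#' @export
top_concomitants <- function(cohort, k = 10L) {
  drugs <- cohort$cases$drugs
  co <- drugs[drugs$PRIMARYID %in% cohort$target$PRIMARYID & !drugs$is_target, ,
              drop = FALSE]
  name <- gsub("[[:space:]]+", " ", toupper(trimws(co$DRUGNAME)))
  keep <- !is.na(name) & nzchar(name)
  pair <- unique(paste(co$PRIMARYID[keep], name[keep], sep = "\r"))
  nm <- sub("^[^\r]*\r", "", pair)
  tab <- table(nm)
  ord <- order(-as.integer(tab), names(tab))
  head(data.frame(drug = names(tab)[ord], n_reports = as.integer(tab)[ord],
                  stringsAsFactors = FALSE), k)
}

#' Disproportionality screen within a stratum
#'
#' Runs [screen_signals()] on the stratified cohort; output rows carry a
#' `subgroup` label. With the trivial spec (`kind = "all"`) the result is
#' identical to the global screen.
#'
#' @param cohort a `faers_cohort`.
#' @param spec a `subgroup_spec`.
#' @param continent_map a `country_continent_map`.
#' @param co_roles optional concomitant-drug role restriction.
#' @param ... passed to [screen_signals()].
#' @return a `faers_signals` data.frame with a `subgroup` column, ordered by
#'   descending ROR ("signal intensity") within level.
#' @export
screen_subgroup <- function(cohort, spec,
                            continent_map = load_country_continent_map(),
                            co_roles = NULL, ...) {
  sub <- stratify(cohort, spec, continent_map, co_roles)
  if (nrow(sub$target) == 0L) {
    res <- screen_signals(cohort, ...)[0L, , drop = FALSE]
  } else {
    res <- screen_signals(sub, ...)
  }
  res$subgroup <- paste0(spec$kind, ":", spec$parameter %||% "all")
  res
}
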