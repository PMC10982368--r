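# Clinical-characteristics summary of the target cohort: sex, age and weight
# bands, reporter occupation, country and continent, indications, serious
# outcomes, daily dose and medication duration.

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`.
#' @return `100 * numerator / denominator` rounded half-up to 2 decimals;
#'   `NA` when the denominator is 0.
#' @examples
#' percent(1743, 2902)
#' @export
percent <- function(numerator, denominator) {
  out <- round_half_up(100 * numerator / denominator, 2)
  out[rep_len(denominator <= 0, length(out))] <- NA_real_
  out
}

#' Assign age group
#'
#' Bands: `<=17`, `18-64`, `65-85`, `>=86`, `Unknown`; boundaries inclusive
#' as labelled. Fractional ages floor to completed years before banding
#' (bands are integer-labelled).
#'
#' @param age_years numeric vector (NA = unknown).
#' @return character vector of band labels.
#' @export
assign_age_group <- function(age_years) {
  yrs <- floor(age_years)
  out <- rep("Unknown", length(age_years))
  out[!is.na(yrs) & yrs <= 17] <- "<=17"
  out[!is.na(yrs) & yrs >= 18 & yrs <= 64] <- "18-64"
  out[!is.na(yrs) & yrs >= 65 & yrs <= 85] <- "65-85"
  out[!is.na(yrs) & yrs >= 86] <- ">=86"
  out
}

#' Assign weight group
#'
#' Bands: `<50`, `50-100`, `>100` (kg), `Unknown`; the middle band includes
#' both endpoints, the outer bands are strict.
#'
#' @param weight_kg numeric vector (NA = unknown).
#' @return character vector of band labels.
#' @export
assign_weight_group <- function(weight_kg) {
  out <- rep("Unknown", length(weight_kg))
  ok <- !is.na(weight_kg)
  out[ok & weight_kg < 50] <- "<50"
  out[ok & weight_kg >= 50 & weight_kg <= 100] <- "50-100"
  out[ok & weight_kg > 100] <- ">100"
  out
}

#' Daily dose in milligrams
#'
#' Defined only when the dose unit is milligrams and the frequency maps to a
#' known per-day multiplier (QD 1, BID 2, TID 3, QID 4, QOD 0.5); anything
#' else is unknown.
#'
#' @param dose_amt numeric dose amount.
#' @param dose_unit unit text (must be `MG` after trimming/upcasing).
#' @param dose_freq frequency code.
#' @return numeric mg/day (`NA` = unknown).
#' @export
dose_per_day <- function(dose_amt, dose_unit, dose_freq) {
  amt <- as_num(as.character(dose_amt))
  unit <- toupper(trimws(as.character(dose_unit)))
  freq <- toupper(trimws(as.character(dose_freq)))
  mult <- c(QD = 1, BID = 2, TID = 3, QID = 4, QOD = 0.5)[freq]
  out <- amt * unname(mult)
  out[unit != "MG" | is.na(unit)] <- NA_real_
  out
}

# printed dose bins; doses outside the listed values fall into "Other"
assign_dose_group <- function(mg_day) {
  out <- rep("Unknown", length(mg_day))
  ok <- !is.na(mg_day)
  out[ok] <- "Other"
  out[ok & mg_day == 12.5] <- "12.5"
  out[ok & mg_day == 25] <- "25"
  out[ok & mg_day > 25 & mg_day < 50] <- "25-50"
  out[ok & mg_day == 50] <- "50"
  out[ok & mg_day == 75] <- "75"
  out[ok & mg_day == 100] <- "100"
  out[ok & mg_day == 150] <- "150"
  out
}

#' Therapy duration in days
#'
#' Calendar-day difference `end - start` (same-day therapy = 0 days),
#' requiring day precision on both dates; `end < start` yields unknown with
#' a warning count.
#'
#' @param start_date,end_date `Date` vectors.
#' @param start_precision,end_precision precision tags from
#'   [faers_parse_date()].
#' @return integer days (`NA` = unknown).
#' @export
duration_days <- function(start_date, end_date,
                          start_precision = "day", end_precision = "day") {
  ok <- start_precision == "day" & end_precision == "day" &
    !is.na(start_date) & !is.na(end_date)
  out <- rep(NA_integer_, length(start_date))
  d <- as.integer(end_date - start_date)
  neg <- ok & d < 0
  if (any(neg)) {
    warning(sprintf("%d therapy interval(s) with end before start set to unknown",
                    sum(neg)))
  }
  out[ok & !neg] <- d[ok & !neg]
  out
}

#' Assign medication-duration group
#'
#' Bins in days: `0-30`, `31-60`, `61-90`, `91-180`, `181-360`, `>360`,
#' `Unknown`. (Published tables sometimes label the open bin `>361`; day 361
#' belongs to the open bin here so that every duration is binnable.)
#'
#' @param days integer vector (NA = unknown).
#' @return character vector of bin labels.
#' @export
assign_duration_group <- function(days) {
  cut_bins(days, c(30, 60, 90, 180, 360))
}

# shared binning for duration and time-to-onset: upper edges inclusive,
# values above the last edge in ">last"
cut_bins <- function(days, edges) {
  lower <- c(0, edges[-length(edges)] + 1)
  labels <- c(paste0(lower, "-", edges), paste0(">", edges[length(edges)]))
  out <- rep("Unknown", length(days))
  ok <- !is.na(days) & days >= 0
  idx <- findInterval(days[ok], c(edges + 1L)) + 1L
  out[ok] <- labels[idx]
  out
}

#' Summarize clinical characteristics of the target cohort
#'
#' Emits the standard report-characteristics panels with counts and percents
#' against the cohort size: sex, age group, weight group, reporter
#' occupation, reporting country (ranked), continent, indication (ranked,
#' for the matched target drug), serious outcomes, daily dose group of the
#' target PS drug, and medication duration group. Exhaustive panels (sex,
#' age, weight, continent, dose, duration) always include every band, zeros
#' included, and their counts sum to the cohort size; the outcome panel is
#' per-code (a case can carry several codes) and the indication/country
#' panels list observed values only.
#'
#' @param cohort a `faers_cohort`.
#' @param continent_map a `country_continent_map`.
#' @return data.frame (class `faers_characteristics`) with columns `panel`,
#'   `label`, `n`, `pct`.
#' @export
summarize_characteristics <- function(cohort,
                                      continent_map = load_country_continent_map()) {
  tgt <- cohort$target
  n <- nrow(tgt)
  panel <- function(name, values, levels = NULL, rank = FALSE) {
    if (is.null(levels)) {
      tab <- table(values)
      if (rank) tab <- tab[order(-as.integer(tab), names(tab))]
    } else {
      tab <- table(factor(values, levels = levels))
    }
    data.frame(panel = name, label = names(tab), n = as.integer(tab),
               pct = percent(as.integer(tab), n), stringsAsFactors = FALSE)
  }

  ids <- tgt$PRIMARYID
  drugs <- cohort$cases$drugs
  tdrug <- drugs[drugs$PRIMARYID %in% ids & drugs$is_target &
                   toupper(drugs$ROLE_COD) == "PS", , drop = FALSE]

  # indications of the matched PS drug, one per report
  indi <- cohort$cases$indications
  ti <- indi[indi$PRIMARYID %in% ids, , drop = FALSE]
  if (nrow(ti) > 0L && nrow(tdrug) > 0L) {
    key <- paste(tdrug$PRIMARYID, tdrug$DRUG_SEQ, sep = "\r")
    ti <- ti[paste(ti$PRIMARYID, ti$INDI_DRUG_SEQ, sep = "\r") %in% key, ,
             drop = FALSE]
    ti <- ti[!is.na(ti$indi_pt), , drop = FALSE]
    ti <- ti[!duplicated(paste(ti$PRIMARYID, ti$indi_pt, sep = "\r")), ,
             drop = FALSE]
  }

  outc <- cohort$cases$outcomes
  to <- outc[outc$PRIMARYID %in% ids, , drop = FALSE]

  # mg/day of the target PS drug; first defined value per report
  mg <- dose_per_day(tdrug$DOSE_AMT, tdrug$DOSE_UNIT, tdrug$DOSE_FREQ)
  per_case_mg <- tapply(mg, tdrug$PRIMARYID, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 0L) v[1L] else NA_real_
  })
  mg_case <- unname(per_case_mg[ids])

  # medication duration of the target PS drug: earliest-start valid therapy row
  ther <- cohort$cases$therapies
  dur_case <- rep(NA_integer_, n)
  if (nrow(ther) > 0L && nrow(tdrug) > 0L) {
    key <- paste(tdrug$PRIMARYID, tdrug$DRUG_SEQ, sep = "\r")
    tt <- ther[paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ, sep = "\r") %in% key, ,
               drop = FALSE]
    if (nrow(tt) > 0L) {
      tt$dur <- suppressWarnings(duration_days(tt$start_date, tt$end_date,
                                               tt$start_precision,
                                               tt$end_precision))
      tt <- tt[!is.na(tt$dur), , drop = FALSE]
      if (nrow(tt) > 0L) {
        tt <- tt[order(tt$PRIMARYID, tt$start_date), , drop = FALSE]
        first <- tt[!duplicated(tt$PRIMARYID), , drop = FALSE]
        dur_case[match(first$PRIMARYID, ids)] <- first$dur
      }
    }
  }

  out <- rbind(
    data.frame(panel = "reports", label = "Number of reports", n = n,
               pct = NA_real_, stringsAsFactors = FALSE),
    panel("sex", c(F = "Female", M = "Male", UNK = "Unknown")[tgt$sex],
          levels = c("Female", "Male", "Unknown")),
    panel("age", assign_age_group(tgt$age_years),
          levels = c("<=17", "18-64", "65-85", ">=86", "Unknown")),
    panel("weight", assign_weight_group(tgt$weight_kg),
          levels = c("<50", "50-100", ">100", "Unknown")),
    panel("reporter", tgt$occp_cod, rank = TRUE),
    panel("country", tgt$country, rank = TRUE),
    panel("continent", resolve_continent(tgt$country, continent_map),
          levels = c("North America", "Europe", "Asia", "South America",
                     "Oceania", "Africa", "Unknown")),
    if (nrow(ti) > 0L) panel("indication", ti$indi_pt, rank = TRUE),
    panel("outcome", factor(to$OUTC_COD,
                            levels = c("DE", "LT", "HO", "DS", "CA", "RI", "OT")),
          levels = c("DE", "LT", "HO", "DS", "CA", "RI", "OT")),
    panel("dose_mg_day", assign_dose_group(mg_case),
          levels = c("12.5", "25", "25-50", "50", "75", "100", "150",
                     "Other", "Unknown")),
    panel("duration_days", assign_duration_group(dur_case),
          levels = c("0-30", "31-60", "61-90", "91-180", "181-360", ">360",
                     "Unknown"))
  )
  rownames(out) <- NULL
  class(out) <- c("faers_characteristics", "data.frame")
  out
}
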