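# Time-to-onset: days from the start of therapy with the matched
# primary-suspect drug to the adverse-event onset date.

#' Per-case time-to-onset
#'
#' For each target-cohort report: the start date is the earliest
#' day-precision therapy start among rows linked (via the drug sequence
#' index) to a matched PS drug; the event date is the report's onset date at
#' day precision. `tto = event - start` in days. Cases with a missing or
#' partial date are unknown (`reason` `"missing"`); negative intervals are
#' excluded and counted (`reason` `"negative"`).
#'
#' @param cohort a `faers_cohort`.
#' @return data.frame with `PRIMARYID`, `CASEID`, `tto_days`, `reason`
#'   (`"ok"`, `"missing"`, `"negative"`); attribute `"n_negative"`.
#' @export
compute_tto <- function(cohort) {
  tgt <- cohort$target
  drugs <- cohort$cases$drugs
  ther <- cohort$cases$therapies
  tdrug <- drugs[drugs$PRIMARYID %in% tgt$PRIMARYID & drugs$is_target &
                   toupper(drugs$ROLE_COD) == "PS", , drop = FALSE]
  start <- rep(as.Date(NA), nrow(tgt))
  if (nrow(ther) > 0L && nrow(tdrug) > 0L) {
    key <- paste(tdrug$PRIMARYID, tdrug$DRUG_SEQ, sep = "\r")
    tt <- ther[paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ, sep = "\r") %in% key &
                 ther$start_precision == "day", , drop = FALSE]
    if (nrow(tt) > 0L) {
      first <- tapply(tt$start_date, tt$PRIMARYID, min)
      idx <- match(names(first), tgt$PRIMARYID)
      start[idx] <- as.Date(unname(first), origin = "1970-01-01")
    }
  }
  event <- tgt$event_date
  event[tgt$event_precision != "day"] <- NA
  tto <- as.integer(event - start)
  reason <- ifelse(is.na(tto), "missing",
                   ifelse(tto < 0, "negative", "ok"))
  tto[reason != "ok"] <- NA_integer_
  out <- data.frame(PRIMARYID = tgt$PRIMARYID, CASEID = tgt$CASEID,
                    tto_days = tto, reason = reason, stringsAsFactors = FALSE)
  attr(out, "n_negative") <- sum(reason == "negative")
  out
}

#' Time-to-onset bins
#'
#' @param days integer vector of onset times.
#' @return character vector with labels `0-30`, `31-60`, `61-90`, `91-180`,
#'   `181-360`, `>360` (`Unknown` for `NA`); bin edges inclusive.
#' @export
assign_tto_bin <- function(days) {
  cut_bins(days, c(30, 60, 90, 180, 360))
}

#' Summarize time-to-onset
#'
#' Median and interquartile range use the linear-interpolation quantile
#' convention (type 7, the common default in scientific software); binned
#' counts and percents are reported against the evaluable count.
#'
#' @param tto a data.frame from [compute_tto()] or a numeric vector of onset
#'   days.
#' @return list of class `tto_summary`: `n_valid`, `n_missing`, `n_negative`,
#'   `median_days`, `iqr_low`, `iqr_high`, and a `bins` data.frame
#'   (`bin`, `n`, `pct`).
#' @export
summarize_tto <- function(tto) {
  if (is.data.frame(tto)) {
    days <- tto$tto_days[tto$reason == "ok"]
    n_missing <- sum(tto$reason == "missing")
    n_negative <- sum(tto$reason == "negative")
  } else {
    days <- tto[!is.na(tto)]
    n_missing <- sum(is.na(tto))
    n_negative <- 0L
  }
  n <- length(days)
  bins_lv <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")
  tab <- table(factor(assign_tto_bin(days), levels = bins_lv))
  structure(list(
    n_valid = n,
    n_missing = n_missing,
    n_negative = n_negative,
    median_days = if (n > 0) stats::median(days) else NA_real_,
    iqr_low = if (n > 0) stats::quantile(days, 0.25, names = FALSE) else NA_real_,
    iqr_high = if (n > 0) stats::quantile(days, 0.75, names = FALSE) else NA_real_,
    bins = data.frame(bin = bins_lv, n = as.integer(tab),
                      pct = percent(as.integer(tab), n),
                      stringsAsFactors = FALSE)
  ), class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("Time-to-onset: %d evaluable report(s); median %s days (IQR %s-%s)\n",
              x$n_valid, format(x$median_days), format(x$iqr_low),
              format(x$iqr_high)))
  print(x$bins, row.names = FALSE)
  invisible(x)
}
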