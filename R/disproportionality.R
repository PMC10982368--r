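# Disproportionality statistics on the report-level 2x2 table
#
#               event   no event
#   target        a        b        (a + b = target cohort size)
#   comparator    c        d        (c + d = comparator cohort size)
#
# ROR = ad/(bc) with a Wald CI on the log scale; the BCPNN information
# component IC = log2 of the observed vs expected co-reporting probability
# under independence, with Bayesian shrinkage. Counting is report-level: a
# report contributes at most once per distinct event term.

#' Build 2x2 contingency tables for a set of events
#'
#' @param target_events data.frame with columns `id` (report identifier) and
#'   `term` (event term), distinct pairs; reports in the target cohort.
#' @param background_events same, for the comparator cohort.
#' @param n_target,n_background cohort sizes (a+b and c+d).
#' @param terms terms to tabulate; default every term with `a >= 1`.
#' @return data.frame with columns `term`, `a`, `b`, `c`, `d`.
#' @export
contingency_tables <- function(target_events, background_events,
                               n_target, n_background, terms = NULL) {
  tgt <- unique(paste(target_events$id, target_events$term, sep = "\r"))
  bg <- unique(paste(background_events$id, background_events$term, sep = "\r"))
  t_term <- sub("^[^\r]*\r", "", tgt)
  b_term <- sub("^[^\r]*\r", "", bg)
  if (is.null(terms)) terms <- sort(unique(t_term))
  a <- as.integer(table(factor(t_term, levels = terms)))
  cc <- as.integer(table(factor(b_term, levels = terms)))
  stopifnot(all(a <= n_target), all(cc <= n_background))
  data.frame(term = terms, a = a, b = n_target - a, c = cc,
             d = n_background - cc, stringsAsFactors = FALSE)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = ad/(bc); the CI is exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' When any cell is zero the Haldane-Anscombe correction (add 0.5 to every
#' cell) is applied first and flagged in `corrected`. Tables with an empty
#' margin (a+b = 0 or a+c = 0) are tagged `defined = FALSE` and return `NA`
#' rather than a silent `NaN`.
#'
#' @param a,b,c,d vectors of 2x2 cell counts.
#' @param alpha two-sided error rate for the CI (default 0.05 gives 95%).
#' @return data.frame with `ror`, `ci_low`, `ci_high`, `corrected`, `defined`.
#' @export
compute_ror <- function(a, b, c, d, alpha = 0.05) {
  defined <- (a + b) > 0 & (a + c) > 0
  corrected <- (a == 0 | b == 0 | c == 0 | d == 0) & defined
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  z <- stats::qnorm(1 - alpha / 2)
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ci_low <- exp(log(ror) - z * se)
  ci_high <- exp(log(ror) + z * se)
  ror[!defined] <- NA_real_
  ci_low[!defined] <- NA_real_
  ci_high[!defined] <- NA_real_
  data.frame(ror = ror, ci_low = ci_low, ci_high = ci_high,
             corrected = corrected, defined = defined)
}

#' BCPNN prior pseudo-counts
#'
#' Standard constants of the BCPNN formulation: cell prior `gamma11 = 1`,
#' margin priors `alpha1 = beta1 = 1` with totals `alpha = beta = 2`, and the
#' cell prior total `gamma` tied to the margins so that the prior expectation
#' of the IC is 0.
#'
#' @param gamma11,alpha1,beta1,alpha,beta positive prior pseudo-counts.
#' @return list of priors.
#' @export
ic_priors <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                      alpha = 2, beta = 2) {
  stopifnot(gamma11 > 0, alpha1 > 0, beta1 > 0, alpha > alpha1, beta > beta1)
  list(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
       alpha = alpha, beta = beta)
}

#' BCPNN information component with credibility bound
#'
#' `ic_raw` is the maximum-likelihood information component
#' `log2(a N / ((a+b)(a+c)))`. The Bayesian model places independent Beta
#' posteriors on the joint reporting probability `p11` and the two margins
#' `p1.`, `p.1` (priors from [ic_priors()]); `IC = log2(p11 / (p1. p.1))`
#' and `IC025 = E(IC) - 2 sqrt(V(IC))`.
#'
#' Variance models:
#' \describe{
#'   \item{`bate1998`}{posterior mean and variance of `IC` in closed form via
#'     the exact log-Beta moments (digamma/trigamma); default.}
#'   \item{`bate1998_delta`}{the classic first-order series approximation of
#'     the same moments, kept for reference; it can sit ~0.4 bits above the
#'     posterior percentile for very small `a`.}
#'   \item{`montecarlo`}{samples the posterior directly and takes the 2.5th
#'     percentile; the validation oracle for the closed forms. Uses the
#'     current RNG stream.}
#' }
#'
#' @param a,b,c,d vectors of 2x2 cell counts.
#' @param priors list from [ic_priors()].
#' @param variance_model one of `"bate1998"`, `"bate1998_delta"`,
#'   `"montecarlo"`.
#' @param n_draws Monte-Carlo draws per table (montecarlo model only).
#' @return data.frame with `ic_raw`, `ic_expected`, `ic_variance`, `ic025`,
#'   `defined`, `variance_model`.
#' @export
compute_ic <- function(a, b, c, d, priors = ic_priors(),
                       variance_model = c("bate1998", "bate1998_delta",
                                          "montecarlo"),
                       n_draws = 200000L) {
  variance_model <- match.arg(variance_model)
  g11 <- priors$gamma11; a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta
  N <- a + b + c + d
  n1 <- a + b   # target margin
  n2 <- a + c   # event margin
  defined <- n1 > 0 & n2 > 0
  ic_raw <- ifelse(defined, log2(a * N / (n1 * n2)), NA_real_)
  # prior total for the cell, tied to the (posterior) margins so the prior
  # IC expectation is null
  g <- g11 * (N + al) * (N + be) / ((n1 + a1) * (n2 + b1))
  ln2 <- log(2)
  if (variance_model == "bate1998") {
    e_ic <- (digamma(a + g11) - digamma(N + g) -
               digamma(n1 + a1) + digamma(N + al) -
               digamma(n2 + b1) + digamma(N + be)) / ln2
    v_ic <- (trigamma(a + g11) - trigamma(N + g) +
               trigamma(n1 + a1) - trigamma(N + al) +
               trigamma(n2 + b1) - trigamma(N + be)) / ln2^2
  } else if (variance_model == "bate1998_delta") {
    e_ic <- log2((a + g11) * (N + al) * (N + be) /
                   ((N + g) * (n1 + a1) * (n2 + b1)))
    v_ic <- ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
               (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
               (N - n2 + be - b1) / ((n2 + b1) * (1 + N + be))) / ln2^2
  } else {
    e_ic <- v_ic <- ic025_mc <- rep(NA_real_, length(N))
    for (i in seq_along(N)) {
      if (!defined[i]) next
      draws <- log2(stats::rbeta(n_draws, a[i] + g11, N[i] - a[i] + g[i] - g11)) -
        log2(stats::rbeta(n_draws, n1[i] + a1, N[i] - n1[i] + al - a1)) -
        log2(stats::rbeta(n_draws, n2[i] + b1, N[i] - n2[i] + be - b1))
      e_ic[i] <- mean(draws)
      v_ic[i] <- stats::var(draws)
      ic025_mc[i] <- stats::quantile(draws, 0.025, names = FALSE)
    }
  }
  ic025 <- if (variance_model == "montecarlo") ic025_mc else
    e_ic - 2 * sqrt(v_ic)
  e_ic[!defined] <- NA_real_
  v_ic[!defined] <- NA_real_
  ic025[!defined] <- NA_real_
  data.frame(ic_raw = ic_raw, ic_expected = e_ic, ic_variance = v_ic,
             ic025 = ic025, defined = defined,
             variance_model = variance_model)
}

#' Dual signal criteria
#'
#' @param n event count in the target cohort (cell `a`).
#' @param ror_ci_low lower bound of the 95% ROR confidence interval.
#' @param ic025 lower bound of the IC credibility interval.
#' @param thresholds list from [signal_thresholds()].
#' @return data.frame with logicals `ror_positive` (`ci_low > 1` and
#'   `n >= 3`), `ic_positive` (`ic025 > 0`) and `of_interest` (both).
#' @export
apply_signal_criteria <- function(n, ror_ci_low, ic025,
                                  thresholds = signal_thresholds()) {
  ror_positive <- !is.na(ror_ci_low) & ror_ci_low > thresholds$ror_ci_low &
    n >= thresholds$min_n
  ic_positive <- !is.na(ic025) & ic025 > thresholds$ic025
  data.frame(ror_positive = ror_positive, ic_positive = ic_positive,
             of_interest = ror_positive & ic_positive)
}

#' Signal thresholds
#'
#' Defaults: ROR positive when the 95% CI lower limit exceeds 1 with at
#' least 3 target reports; IC positive when IC025 exceeds 0; a term is of
#' interest when both hold.
#'
#' @param min_n minimum target-cohort event count.
#' @param ror_ci_low threshold for the ROR CI lower bound.
#' @param ic025 threshold for IC025.
#' @return list of thresholds.
#' @export
signal_thresholds <- function(min_n = 3, ror_ci_low = 1, ic025 = 0) {
  list(min_n = min_n, ror_ci_low = ror_ci_low, ic025 = ic025)
}

# internal: distinct (report, term) events of a cohort arm at PT or SOC level
cohort_events <- function(cohort, which = c("target", "background"),
                          level = c("pt", "soc"), map = NULL,
                          excluded = faers_excluded_socs()) {
  which <- match.arg(which)
  level <- match.arg(level)
  ids <- cohort[[which]]$PRIMARYID
  reac <- cohort$cases$reactions
  ev <- reac[reac$PRIMARYID %in% ids, , drop = FALSE]
  if (!is.null(map)) {
    ev$soc <- resolve_soc(ev$pt, map)
    ev <- exclude_socs(ev, excluded)
  } else {
    ev$soc <- NA_character_
  }
  if (level == "soc") {
    ev <- ev[ev$soc != "UNMAPPED" & !is.na(ev$soc), , drop = FALSE]
    data.frame(id = ev$PRIMARYID, term = ev$soc, stringsAsFactors = FALSE)
  } else {
    data.frame(id = ev$PRIMARYID, term = ev$pt, soc = ev$soc,
               stringsAsFactors = FALSE)
  }
}

#' Disproportionality screen at PT and/or SOC level
#'
#' Builds report-level 2x2 tables for every event term observed at least once
#' in the target cohort, computes ROR with 95% CI and the BCPNN IC with
#' IC025, and applies the dual signal criteria. Events in excluded SOCs are
#' removed from both cohorts beforehand; unmapped PTs are screened at PT
#' level only. Without a PT->SOC map, only the PT level is produced (with a
#' warning).
#'
#' @param cohort a `faers_cohort`.
#' @param map a `pt_soc_map`, or `NULL` for PT-level-only screening.
#' @param level `"pt"`, `"soc"` or `"both"`.
#' @param thresholds list from [signal_thresholds()].
#' @param priors list from [ic_priors()].
#' @param variance_model passed to [compute_ic()].
#' @param excluded SOC names removed before screening.
#' @param expected character vector of PTs annotated as expected (labelled
#'   reactions); `NULL` to skip the annotation.
#' @param alpha two-sided error rate of the ROR CI.
#' @return data.frame (class `faers_signals`) with one row per (level, term):
#'   counts `a`--`d`, `n` (= a), ROR with CI, IC statistics, the criteria
#'   flags, `of_interest`, and `expected`. Rows are ordered by level, SOC,
#'   then descending ROR, ties broken by descending `a` then term.
#' @export
screen_signals <- function(cohort, map = NULL, level = c("both", "pt", "soc"),
                           thresholds = signal_thresholds(),
                           priors = ic_priors(),
                           variance_model = "bate1998",
                           excluded = faers_excluded_socs(),
                           expected = expected_pts(), alpha = 0.05) {
  level <- match.arg(level)
  if (is.null(map) && level %in% c("both", "soc")) {
    warning("no PT->SOC map supplied: SOC-level screen skipped")
    level <- "pt"
  }
  n_t <- nrow(cohort$target)
  n_b <- nrow(cohort$background)
  one_level <- function(lv) {
    te <- cohort_events(cohort, "target", lv, map, excluded)
    be <- cohort_events(cohort, "background", lv, map, excluded)
    tab <- contingency_tables(te, be, n_t, n_b)
    if (nrow(tab) == 0L) return(NULL)
    ror <- compute_ror(tab$a, tab$b, tab$c, tab$d, alpha = alpha)
    ic <- compute_ic(tab$a, tab$b, tab$c, tab$d, priors = priors,
                     variance_model = variance_model)
    crit <- apply_signal_criteria(tab$a, ror$ci_low, ic$ic025, thresholds)
    soc <- if (lv == "soc") tab$term else if (!is.null(map))
      resolve_soc(tab$term, map) else NA_character_
    out <- data.frame(level = toupper(lv), soc = soc, term = tab$term,
                      n = tab$a, tab[c("a", "b", "c", "d")],
                      ror[c("ror", "ci_low", "ci_high", "corrected")],
                      ic[c("ic_raw", "ic_expected", "ic_variance", "ic025")],
                      crit, stringsAsFactors = FALSE)
    out$expected <- if (lv == "pt" && !is.null(expected))
      out$term %in% normalize_pt(expected) else NA
    # deterministic ranking: SOC, then ROR desc, then a desc, then term
    ord <- order(out$soc, -ifelse(is.na(out$ror), -Inf, out$ror), -out$a,
                 out$term, method = "radix")
    out[ord, , drop = FALSE]
  }
  res <- switch(level,
                pt = one_level("pt"),
                soc = one_level("soc"),
                both = rbind(one_level("soc"), one_level("pt")))
  rownames(res) <- NULL
  class(res) <- c("faers_signals", "data.frame")
  res
}

#' Format a signal table the way safety papers print it
#'
#' @param signals a `faers_signals` data.frame.
#' @param digits decimal places for ROR and IC columns.
#' @return data.frame with `SOC`, `PT`/term, `N`, `ROR (95% CI)`,
#'   `IC (IC025)`, `Expected` columns.
#' @export
format_signal_table <- function(signals, digits = 2) {
  r <- function(x) format(round_half_up(x, digits), nsmall = digits, trim = TRUE)
  data.frame(
    Level = signals$level,
    SOC = signals$soc,
    Term = signals$term,
    N = signals$n,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", r(signals$ror), r(signals$ci_low),
                             r(signals$ci_high)),
    `IC (IC025)` = sprintf("%s (%s)", r(signals$ic_expected),
                           r(signals$ic025)),
    Expected = ifelse(is.na(signals$expected), "",
                      ifelse(signals$expected, "Yes", "No")),
    of_interest = signals$of_interest,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
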