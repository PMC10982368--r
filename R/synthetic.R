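# Synthetic FAERS-like data with known ground truth: planted drug-event
# relative risks, duplicate report versions, missingness, mixed units and a
# skewed time-to-onset distribution. Every pipeline stage is testable on this
# generator without downloading anything.

#' Background event vocabulary of the synthetic generator
#'
#' A toy vocabulary (~50 PTs) drawn from the bundled ontology, each with a
#' background per-report reporting probability. Includes a handful of PTs in
#' the four excluded SOCs and one deliberately unmapped PT so the exclusion
#' and UNMAPPED paths are exercised.
#'
#' @return data.frame with `pt` and `p_background`.
#' @export
synthetic_pt_vocabulary <- function() {
  v <- c(
    "Nausea" = 0.040, "Headache" = 0.035, "Fatigue" = 0.030,
    "Dizziness" = 0.030, "Fall" = 0.020, "Rash" = 0.020,
    "Diarrhoea" = 0.020, "Dyspnoea" = 0.020, "Hypertension" = 0.015,
    "Insomnia" = 0.012, "Constipation" = 0.012, "Malaise" = 0.012,
    "Back pain" = 0.010, "Urinary retention" = 0.010, "Dry mouth" = 0.010,
    "Blood pressure increased" = 0.010, "Product quality issue" = 0.010,
    "Atrial fibrillation" = 0.008, "Palpitations" = 0.008,
    "Tachycardia" = 0.008, "Vision blurred" = 0.006,
    "Hyperglycaemia" = 0.006, "Decreased appetite" = 0.006,
    "Pruritus" = 0.006, "Haematuria" = 0.004, "Dysuria" = 0.004,
    "Urinary incontinence" = 0.004, "Nasopharyngitis" = 0.004,
    "Nocturia" = 0.003, "Pollakiuria" = 0.003, "Arrhythmia" = 0.003,
    "Angina pectoris" = 0.003, "Dry eye" = 0.003,
    "Erectile dysfunction" = 0.003, "Hypersensitivity" = 0.003,
    "Rhinitis" = 0.003, "Acute myocardial infarction" = 0.003,
    "Overdose" = 0.003, "Feeling jittery" = 0.003,
    "Micturition urgency" = 0.002, "Dementia" = 0.002,
    "Transient ischaemic attack" = 0.002, "Glaucoma" = 0.002,
    "Peptic ulcer" = 0.002, "Lip swelling" = 0.002,
    "Swollen tongue" = 0.002, "Angioedema" = 0.002, "Delirium" = 0.002,
    "Hip arthroplasty" = 0.002, "Dry throat" = 0.001, "Thirst" = 0.001,
    "Petechiae" = 0.001, "Homelessness" = 0.001
  )
  data.frame(pt = names(v), p_background = unname(v),
             stringsAsFactors = FALSE)
}

#' Synthetic-data generator configuration
#'
#' Defaults define the generator's study conditions: a 2,000-report target
#' cohort (healthcare-professional reports with the target drug as primary
#' suspect) against a 20,000-report background, three planted signals
#' (relative risks 5, 3 and 2 on PTs with background probabilities 0.01), a
#' 15% duplicate-version rate, field missingness typical of FAERS
#' demographics, and a lognormal time-to-onset with median 25 days and
#' IQR roughly 7--75 days.
#'
#' @param seed RNG seed (all generator randomness flows from it).
#' @param n_target number of target-cohort reports (HCP reporter, target
#'   drug as PS).
#' @param n_target_nonhcp extra target-drug PS reports from non-HCP
#'   reporters (excluded by the cohort filter).
#' @param n_target_nonps extra reports listing the target drug in a non-PS
#'   role only.
#' @param n_background reports without the target drug.
#' @param pt_vocabulary data.frame `pt`, `p_background`.
#' @param planted_signals data.frame `pt`, `rr` (relative risk > 0) applied
#'   to target-drug PS reports; empty frame = global null.
#' @param duplicate_rate fraction of cases emitted as two report versions.
#' @param missing named list of missingness fractions (`event_dt`,
#'   `ther_start`, `ther_start_partial`, `ther_end`, `age`, `weight`, `dose`).
#' @param negative_tto_rate fraction of reports with event before therapy
#'   start (planted data errors).
#' @param tto_meanlog,tto_sdlog lognormal onset-time model, days.
#' @param window character length-2, first/last FDA receipt date.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_target = 2000L,
                             n_target_nonhcp = 500L,
                             n_target_nonps = 300L,
                             n_background = 20000L,
                             pt_vocabulary = synthetic_pt_vocabulary(),
                             planted_signals = data.frame(
                               pt = c("Urinary retention",
                                      "Blood pressure increased",
                                      "Dry mouth"),
                               rr = c(5, 3, 2),
                               stringsAsFactors = FALSE),
                             duplicate_rate = 0.15,
                             missing = list(event_dt = 0.35,
                                            ther_start = 0.30,
                                            ther_start_partial = 0.10,
                                            ther_end = 0.45,
                                            age = 0.40,
                                            weight = 0.80,
                                            dose = 0.55),
                             negative_tto_rate = 0.02,
                             tto_meanlog = log(25),
                             tto_sdlog = 1.63,
                             window = c("2022-01-01", "2023-09-30")) {
  stopifnot(nrow(pt_vocabulary) > 0,
            all(pt_vocabulary$p_background >= 0),
            all(pt_vocabulary$p_background <= 1),
            is.null(planted_signals) || all(planted_signals$rr > 0),
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(unlist(missing) >= 0), all(unlist(missing) <= 1))
  if (is.null(planted_signals)) {
    planted_signals <- data.frame(pt = character(0), rr = numeric(0))
  }
  pt_vocabulary$pt <- normalize_pt(pt_vocabulary$pt)
  planted_signals$pt <- normalize_pt(planted_signals$pt)
  unknown <- setdiff(planted_signals$pt, pt_vocabulary$pt)
  if (length(unknown) > 0L) {
    stop("planted PT(s) not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  structure(list(seed = seed, n_target = n_target,
                 n_target_nonhcp = n_target_nonhcp,
                 n_target_nonps = n_target_nonps,
                 n_background = n_background,
                 pt_vocabulary = pt_vocabulary,
                 planted_signals = planted_signals,
                 duplicate_rate = duplicate_rate, missing = missing,
                 negative_tto_rate = negative_tto_rate,
                 tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
                 window = as.Date(window)),
            class = "synthetic_config")
}

# fixed categorical models of the generator (not user dials): reporter
# occupations, countries, target-drug spellings, co-drug pool, outcomes,
# indications
.synth_models <- list(
  sex = c(F = 0.60, M = 0.35, UNK = 0.05),
  occp_hcp = c(MD = 0.51, OT = 0.35, PH = 0.14),
  occp_nonhcp = c(CN = 0.80, LW = 0.10, RN = 0.05, UNK = 0.05),
  occp_all = c(MD = 0.25, OT = 0.17, PH = 0.12, CN = 0.33, LW = 0.04,
               RN = 0.05, UNK = 0.04),
  country = c(US = 0.45, JP = 0.15, GB = 0.11, ES = 0.04, FR = 0.04,
              DE = 0.04, CA = 0.04, CN = 0.03, KR = 0.02, IT = 0.02,
              NL = 0.02, BR = 0.02, AU = 0.01, ZA = 0.01),
  target_names = c("MIRABEGRON", "MYRBETRIQ", "BETMIGA", "BETANIS",
                   "MIRABEGRON 50 MG TABLET", "Myrbetriq (mirabegron)"),
  target_name_p = c(0.40, 0.25, 0.12, 0.08, 0.10, 0.05),
  co_drugs = c(ASPIRIN = 0.080, ATORVASTATIN = 0.060, SOLIFENACIN = 0.055,
               TAMSULOSIN = 0.040, METFORMIN = 0.035, AMLODIPINE = 0.030,
               OMEPRAZOLE = 0.025, FUROSEMIDE = 0.020),
  bg_drugs = c("LISINOPRIL", "METFORMIN", "ATORVASTATIN", "IBUPROFEN",
               "WARFARIN", "MIRTAZAPINE", "SERTRALINE", "INSULIN GLARGINE",
               "PREDNISONE", "LEVOTHYROXINE", "ADALIMUMAB", "RIVAROXABAN"),
  outcomes = c(OT = 0.45, HO = 0.17, DS = 0.025, LT = 0.022, DE = 0.019,
               CA = 0.001),
  indi_target = c("Hypertonic bladder" = 0.40, "Incontinence" = 0.18,
                  "Pollakiuria" = 0.05, "Micturition urgency" = 0.03,
                  "Nocturia" = 0.015, "Neurogenic bladder" = 0.01,
                  "Benign prostatic hyperplasia" = 0.01,
                  "Product used for unknown indication" = 0.305),
  indi_bg = c("Hypertension" = 0.25, "Diabetes mellitus" = 0.20,
              "Depression" = 0.15, "Pain" = 0.15,
              "Product used for unknown indication" = 0.25)
)

#' Generate synthetic FAERS quarterly data with ground truth
#'
#' Deterministic given `config$seed`. Target-drug PS reports draw each
#' vocabulary PT with probability `min(1, RR * p_background)` (RR = 1 unless
#' planted); all other reports use the background probabilities. A fraction
#' of cases is emitted as two report versions sharing a `CASEID` with
#' increasing `FDA_DT`/`PRIMARYID` (a fifth of those tie on `FDA_DT` so the
#' PRIMARYID tie-break is exercised). Therapy and event dates follow the
#' lognormal onset model.
#'
#' @param config a `synthetic_config`.
#' @param dir if non-NULL, the quarter files, the ground-truth sidecar and
#'   copies of the toy PT->SOC and country->continent maps are written there.
#' @return list of class `faers_synth`: `bundles` (named list of
#'   `faers_quarter`), `truth` (one row per case: group, demographics, true
#'   onset days, version lineage, one `has_<pt>` flag per planted PT),
#'   `config`, and `paths` (when written).
#' @export
generate_faers <- function(config = synthetic_config(), dir = NULL) {
  set.seed(config$seed)
  m <- .synth_models
  n_coh <- config$n_target
  n_nh <- config$n_target_nonhcp
  n_np <- config$n_target_nonps
  n_bg <- config$n_background
  n <- n_coh + n_nh + n_np + n_bg
  group <- rep(c("cohort", "target_nonhcp", "target_nonps", "background"),
               times = c(n_coh, n_nh, n_np, n_bg))
  causal <- group %in% c("cohort", "target_nonhcp")  # PS exposure to target
  has_target <- group != "background"

  caseid <- as.character(90000000L + seq_len(n))

  # demographics ---------------------------------------------------------
  sex <- sample(names(m$sex), n, replace = TRUE, prob = m$sex)
  age_true <- pmin(pmax(stats::rnorm(n, 70, 14), 5), 100)
  kid <- sample.int(n, max(1L, round(0.01 * n)))
  age_true[kid] <- stats::runif(length(kid), 5, 17)
  wt_true <- pmin(pmax(stats::rnorm(n, 75, 18), 35), 160)
  country <- sample(names(m$country), n, replace = TRUE, prob = m$country)
  occp <- character(n)
  occp[group == "cohort"] <- sample(names(m$occp_hcp), n_coh, replace = TRUE,
                                    prob = m$occp_hcp)
  occp[group == "target_nonhcp"] <- sample(names(m$occp_nonhcp), n_nh,
                                           replace = TRUE, prob = m$occp_nonhcp)
  rest <- group %in% c("target_nonps", "background")
  occp[rest] <- sample(names(m$occp_all), sum(rest), replace = TRUE,
                       prob = m$occp_all)

  # mixed units
  age_unit <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                     prob = c(0.90, 0.04, 0.06))
  age_val <- ifelse(age_unit == "YR", round(age_true, 1),
                    ifelse(age_unit == "DEC", floor(age_true / 10),
                           round(age_true * 12)))
  wt_unit <- sample(c("KG", "LBS", "GMS"), n, replace = TRUE,
                    prob = c(0.70, 0.25, 0.05))
  wt_val <- ifelse(wt_unit == "KG", round(wt_true, 1),
                   ifelse(wt_unit == "LBS", round(wt_true / 0.453592, 1),
                          round(wt_true * 1000)))
  age_missing <- stats::runif(n) < config$missing$age
  wt_missing <- stats::runif(n) < config$missing$weight

  # dates ----------------------------------------------------------------
  days_pool <- seq(config$window[1], config$window[2], by = "day")
  fda_date <- sample(days_pool, n, replace = TRUE)
  event_date <- fda_date - sample(7:120, n, replace = TRUE)
  tto_true <- pmax(0, round(stats::rlnorm(n, config$tto_meanlog,
                                          config$tto_sdlog)))
  neg <- stats::runif(n) < config$negative_tto_rate
  start_date <- event_date - tto_true
  start_date[neg] <- event_date[neg] + sample(1:30, sum(neg), replace = TRUE)
  tto_true[neg] <- NA_integer_
  end_date <- start_date + pmax(1, round(stats::rlnorm(n, log(60), 1)))

  event_missing <- stats::runif(n) < config$missing$event_dt
  start_missing <- stats::runif(n) < config$missing$ther_start
  start_partial <- !start_missing &
    stats::runif(n) < config$missing$ther_start_partial
  end_missing <- stats::runif(n) < config$missing$ther_end

  # reactions: Bernoulli per vocabulary PT, report-level -------------------
  vocab <- config$pt_vocabulary
  rr <- stats::setNames(rep(1, nrow(vocab)), vocab$pt)
  if (nrow(config$planted_signals) > 0L) {
    rr[config$planted_signals$pt] <- config$planted_signals$rr
  }
  p_t <- vocab$p_background * unname(rr[vocab$pt])
  if (any(p_t > 1)) {
    warning("planted RR * p_background exceeds 1 for some PT(s); clamped")
    p_t <- pmin(1, p_t)
  }
  reac_i <- vector("list", nrow(vocab))
  for (j in seq_len(nrow(vocab))) {
    pj <- ifelse(causal, p_t[j], vocab$p_background[j])
    reac_i[[j]] <- which(stats::runif(n) < pj)
  }
  reac <- data.frame(
    case = unlist(reac_i, use.names = FALSE),
    pt = rep(vocab$pt, lengths(reac_i)),
    stringsAsFactors = FALSE
  )
  # every report carries at least one reaction; reports with no vocabulary
  # draw get a filler PT outside the screened vocabulary so that planted
  # relative risks are not diluted
  none <- setdiff(seq_len(n), unique(reac$case))
  if (length(none) > 0L) {
    reac <- rbind(reac, data.frame(case = none, pt = "Drug ineffective",
                                   stringsAsFactors = FALSE))
  }
  reac <- reac[order(reac$case, reac$pt), , drop = FALSE]

  # drugs -----------------------------------------------------------------
  # primary suspect row first (drug_seq 1); target drug row for non-PS
  # carriers and co-drugs follow
  ps_name <- character(n)
  ps_name[causal] <- sample(m$target_names, sum(causal), replace = TRUE,
                            prob = m$target_name_p)
  ps_name[!causal] <- sample(m$bg_drugs, sum(!causal), replace = TRUE)
  ps_ai <- ifelse(causal & stats::runif(n) < 0.7, "MIRABEGRON", "")
  dose_amt <- sample(c(25, 50, 12.5, 100, 150), n, replace = TRUE,
                     prob = c(0.33, 0.56, 0.04, 0.05, 0.02))
  dose_freq <- sample(c("QD", "BID"), n, replace = TRUE, prob = c(0.85, 0.15))
  dose_missing <- stats::runif(n) < config$missing$dose | !causal

  drug_rows <- list(data.frame(
    case = seq_len(n), role = "PS", name = ps_name, ai = ps_ai,
    amt = ifelse(dose_missing, "", as.character(dose_amt)),
    unit = ifelse(dose_missing, "", "MG"),
    freq = ifelse(dose_missing, "", dose_freq),
    stringsAsFactors = FALSE))
  np <- which(group == "target_nonps")
  if (length(np) > 0L) {
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      case = np,
      role = sample(c("C", "SS", "I"), length(np), replace = TRUE,
                    prob = c(0.6, 0.3, 0.1)),
      name = sample(m$target_names, length(np), replace = TRUE,
                    prob = m$target_name_p),
      ai = "", amt = "", unit = "", freq = "", stringsAsFactors = FALSE)
  }
  for (k in seq_along(m$co_drugs)) {
    hit <- which(stats::runif(n) < m$co_drugs[k])
    if (length(hit) == 0L) next
    drug_rows[[length(drug_rows) + 1L]] <- data.frame(
      case = hit,
      role = sample(c("C", "SS", "I"), length(hit), replace = TRUE,
                    prob = c(0.80, 0.15, 0.05)),
      name = names(m$co_drugs)[k], ai = "", amt = "", unit = "", freq = "",
      stringsAsFactors = FALSE)
  }
  drug <- do.call(rbind, drug_rows)
  drug <- drug[order(drug$case, drug$role != "PS", drug$name), , drop = FALSE]
  drug$drug_seq <- stats::ave(seq_len(nrow(drug)), drug$case,
                              FUN = seq_along)

  # outcomes --------------------------------------------------------------
  outc_rows <- lapply(names(m$outcomes), function(cd) {
    hit <- which(stats::runif(n) < m$outcomes[cd])
    if (length(hit) == 0L) return(NULL)
    data.frame(case = hit, cod = cd, stringsAsFactors = FALSE)
  })
  outc <- do.call(rbind, outc_rows)

  # indications of the PS drug --------------------------------------------
  indi_pt <- character(n)
  indi_pt[has_target] <- sample(names(m$indi_target), sum(has_target),
                                replace = TRUE, prob = m$indi_target)
  indi_pt[!has_target] <- sample(names(m$indi_bg), sum(!has_target),
                                 replace = TRUE, prob = m$indi_bg)

  # duplicate versions -----------------------------------------------------
  n_dup <- round(config$duplicate_rate * n)
  dup_case <- if (n_dup > 0L) sort(sample.int(n, n_dup)) else integer(0)
  tie <- stats::runif(n_dup) < 0.2
  dup_fda <- fda_date[dup_case] - sample(30:300, n_dup, replace = TRUE)
  dup_fda <- pmax(dup_fda, config$window[1])
  dup_fda[tie] <- fda_date[dup_case][tie]

  primaryid <- paste0(caseid, "2")       # retained version
  dup_primaryid <- paste0(caseid[dup_case], "1")

  fmt <- function(d, missing = NULL, partial = NULL) {
    out <- format(d, "%Y%m%d")
    if (!is.null(partial)) out[partial] <- format(d[partial], "%Y%m")
    if (!is.null(missing)) out[missing] <- ""
    out[is.na(out)] <- ""
    out
  }

  demo <- data.frame(
    PRIMARYID = primaryid, CASEID = caseid,
    FDA_DT = fmt(fda_date),
    EVENT_DT = fmt(event_date, missing = event_missing),
    SEX = ifelse(sex == "UNK", "", sex),
    AGE = ifelse(age_missing, "", as.character(age_val)),
    AGE_COD = ifelse(age_missing, "", age_unit),
    WT = ifelse(wt_missing, "", as.character(wt_val)),
    WT_COD = ifelse(wt_missing, "", wt_unit),
    REPORTER_COUNTRY = country,
    OCCR_COUNTRY = country,
    OCCP_COD = ifelse(occp == "UNK", "", occp),
    stringsAsFactors = FALSE
  )
  if (n_dup > 0L) {
    dup_demo <- demo[dup_case, , drop = FALSE]
    dup_demo$PRIMARYID <- dup_primaryid
    dup_demo$FDA_DT <- fmt(dup_fda)
    demo <- rbind(demo, dup_demo)
  }

  expand <- function(df) {
    # child table for retained versions plus copies for duplicate versions
    df$PRIMARYID <- primaryid[df$case]
    if (n_dup > 0L) {
      dup <- df[df$case %in% dup_case, , drop = FALSE]
      dup$PRIMARYID <- paste0(caseid[dup$case], "1")
      df <- rbind(df, dup)
    }
    df
  }

  drug_out <- expand(drug)
  drug_tab <- data.frame(
    PRIMARYID = drug_out$PRIMARYID, DRUG_SEQ = as.character(drug_out$drug_seq),
    ROLE_COD = drug_out$role, DRUGNAME = drug_out$name,
    PROD_AI = drug_out$ai, DOSE_AMT = drug_out$amt,
    DOSE_UNIT = drug_out$unit, DOSE_FREQ = drug_out$freq,
    stringsAsFactors = FALSE)

  reac_out <- expand(reac)
  reac_tab <- data.frame(PRIMARYID = reac_out$PRIMARYID, PT = reac_out$pt,
                         stringsAsFactors = FALSE)

  ther <- data.frame(
    case = seq_len(n), dsg = "1",
    START_DT = fmt(start_date, missing = start_missing,
                   partial = start_partial),
    END_DT = fmt(end_date, missing = end_missing),
    stringsAsFactors = FALSE)
  ther_out <- expand(ther)
  ther_tab <- data.frame(PRIMARYID = ther_out$PRIMARYID,
                         DSG_DRUG_SEQ = ther_out$dsg,
                         START_DT = ther_out$START_DT,
                         END_DT = ther_out$END_DT, stringsAsFactors = FALSE)

  outc_out <- expand(outc)
  outc_tab <- data.frame(PRIMARYID = outc_out$PRIMARYID,
                         OUTC_COD = outc_out$cod, stringsAsFactors = FALSE)

  indi <- data.frame(case = seq_len(n), dsg = "1", pt = indi_pt,
                     stringsAsFactors = FALSE)
  indi_out <- expand(indi)
  indi_tab <- data.frame(PRIMARYID = indi_out$PRIMARYID,
                         INDI_DRUG_SEQ = indi_out$dsg,
                         INDI_PT = indi_out$pt, stringsAsFactors = FALSE)

  # split into quarter bundles by FDA receipt date -------------------------
  demo$quarterlab <- quarter_label(faers_parse_date(demo$FDA_DT)$date)
  q_of <- stats::setNames(demo$quarterlab, demo$PRIMARYID)
  labels <- sort(unique(demo$quarterlab))
  bundles <- lapply(labels, function(lb) {
    pick <- function(df) {
      out <- df[unname(q_of[df$PRIMARYID]) == lb, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    d <- pick(demo)
    d$quarterlab <- NULL
    structure(list(demo = d, drug = pick(drug_tab), reac = pick(reac_tab),
                   ther = pick(ther_tab), outc = pick(outc_tab),
                   indi = pick(indi_tab), label = lb,
                   counts = list(malformed = integer(0),
                                 orphans = integer(0))),
              class = "faers_quarter")
  })
  names(bundles) <- labels

  # ground truth ------------------------------------------------------------
  tto_observable <- !event_missing & !start_missing & !start_partial & !neg
  truth <- data.frame(
    caseid = caseid, primaryid = primaryid, group = group,
    in_cohort = group == "cohort" & occp %in% c("MD", "PH", "OT"),
    sex = sex, age_years = age_true, weight_kg = wt_true,
    country = country, occp = occp,
    tto_days = tto_true, tto_observable = tto_observable,
    n_versions = 1L + as.integer(seq_len(n) %in% dup_case),
    stringsAsFactors = FALSE
  )
  for (pt in config$planted_signals$pt) {
    truth[[paste0("has_", gsub("[^[:alnum:]]+", "_", tolower(pt)))]] <-
      seq_len(n) %in% reac$case[reac$pt == pt]
  }

  out <- list(bundles = bundles, truth = truth, config = config,
              paths = NULL)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- unlist(lapply(bundles, write_faers_quarter, dir = dir))
    truth_path <- file.path(dir, "ground_truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    maps <- c("toy_pt_soc.tsv", "country_continent.tsv")
    for (mf in maps) {
      file.copy(system.file("extdata", mf, package = "faersignal"),
                file.path(dir, mf), overwrite = TRUE)
    }
    out$paths <- c(paths, truth = truth_path,
                   stats::setNames(file.path(dir, maps), maps))
  }
  class(out) <- "faers_synth"
  out
}

#' Determinism check of the generator
#'
#' Generates twice with the same configuration into temporary directories and
#' compares the emitted files byte for byte.
#'
#' @param config a `synthetic_config`.
#' @return list with `pass` (logical) and `detail` (first differing file and
#'   record, or `NULL`).
#' @export
regenerate_check <- function(config = synthetic_config()) {
  d1 <- tempfile("synth1_"); d2 <- tempfile("synth2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generate_faers(config, dir = d1)
  generate_faers(config, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  if (!identical(f1, f2)) {
    diff <- union(setdiff(f1, f2), setdiff(f2, f1))
    return(list(pass = FALSE,
                detail = paste("file sets differ:",
                               paste(diff, collapse = ", "))))
  }
  for (f in f1) {
    a <- readLines(file.path(d1, f), warn = FALSE)
    b <- readLines(file.path(d2, f), warn = FALSE)
    if (!identical(a, b)) {
      len <- min(length(a), length(b))
      i <- which(a[seq_len(len)] != b[seq_len(len)])[1L]
      if (is.na(i)) i <- len + 1L
      return(list(pass = FALSE,
                  detail = sprintf("%s differs at record %d", f, i)))
    }
  }
  list(pass = TRUE, detail = NULL)
}
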