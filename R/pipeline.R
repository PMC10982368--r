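# Pipeline orchestration: chain ingestion, deduplication, cohort selection,
# screening, descriptives, time-to-onset and subgroups; emit delimited result
# tables and a machine-readable run manifest with the attrition counts.

#' Run the full screening pipeline
#'
#' Accepts quarter bundles already in memory (e.g. from [generate_faers()])
#' or a directory of FAERS ASCII files. Each stage's outputs are returned and,
#' when `out_dir` is given, written as tab-delimited tables together with a
#' JSON manifest (configuration echo, input hashes when reading from disk,
#' and row counts at every filter step). Re-running with identical inputs and
#' configuration reproduces identical tables.
#'
#' @param bundles a `faers_quarter`, a list of them, or `NULL` when
#'   `input_dir` is given.
#' @param input_dir directory of FAERS ASCII tables (used when `bundles` is
#'   `NULL`).
#' @param pt_soc_map a `pt_soc_map`, or `NULL` to skip SOC-level screening.
#' @param continent_map a `country_continent_map`.
#' @param patterns target-drug name patterns.
#' @param reporter_codes,strict_ps,hcp_background cohort options, see
#'   [select_cohort()].
#' @param thresholds,priors,variance_model screening options.
#' @param excluded SOCs removed before screening.
#' @param subgroup_specs list of `subgroup_spec`; the default covers the
#'   weight bands, the three largest continents and the top 3 concomitant
#'   drugs observed in the target cohort.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of class `faers_pipeline` with elements `cohort`, `signals`,
#'   `characteristics`, `tto`, `tto_summary`, `concomitants`, `subgroups`
#'   (named list of `faers_signals`), and `manifest`.
#' @export
run_pipeline <- function(bundles = NULL, input_dir = NULL,
                         pt_soc_map = NULL,
                         continent_map = load_country_continent_map(),
                         patterns = mirabegron_patterns(),
                         reporter_codes = c("MD", "PH", "OT"),
                         strict_ps = FALSE, hcp_background = TRUE,
                         thresholds = signal_thresholds(),
                         priors = ic_priors(), variance_model = "bate1998",
                         excluded = faers_excluded_socs(),
                         subgroup_specs = NULL, out_dir = NULL) {
  input_hashes <- NULL
  if (is.null(bundles)) {
    if (is.null(input_dir)) stop("supply bundles or input_dir")
    bundles <- read_faers_data(input_dir)
    files <- faers_quarter_files(input_dir)$path
    input_hashes <- as.list(tools::md5sum(files))
  }
  if (inherits(bundles, "faers_quarter")) bundles <- list(bundles)

  cases <- build_cases(bundles, patterns = patterns)
  cohort <- select_cohort(cases, reporter_codes = reporter_codes,
                          strict_ps = strict_ps,
                          hcp_background = hcp_background)

  signals <- screen_signals(cohort, map = pt_soc_map,
                            thresholds = thresholds, priors = priors,
                            variance_model = variance_model,
                            excluded = excluded)
  characteristics <- summarize_characteristics(cohort, continent_map)
  tto <- compute_tto(cohort)
  tto_summary <- summarize_tto(tto)
  concomitants <- top_concomitants(cohort, k = 10L)

  if (is.null(subgroup_specs)) {
    subgroup_specs <- c(
      lapply(c("<50", "50-100", ">100"), function(b)
        subgroup_spec("weight_band", b)),
      lapply(c("North America", "Europe", "Asia"), function(ct)
        subgroup_spec("continent", ct)),
      lapply(utils::head(concomitants$drug, 3L), function(dr)
        subgroup_spec("concomitant_drug", dr))
    )
  }
  subgroups <- lapply(subgroup_specs, function(sp) {
    suppressWarnings(
      screen_subgroup(cohort, sp, continent_map = continent_map,
                      map = pt_soc_map, thresholds = thresholds,
                      priors = priors, variance_model = variance_model,
                      excluded = excluded)
    )
  })
  names(subgroups) <- vapply(subgroup_specs, function(sp)
    paste0(sp$kind, ":", sp$parameter %||% "all"), character(1))

  counts <- cohort$counts
  counts$tto_evaluable <- tto_summary$n_valid
  counts$tto_negative <- tto_summary$n_negative
  counts$pts_screened <- sum(signals$level == "PT")
  counts$pts_of_interest <- sum(signals$of_interest[signals$level == "PT"])
  counts$socs_screened <- sum(signals$level == "SOC")
  counts$socs_of_interest <- sum(signals$of_interest[signals$level == "SOC"])

  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    quarters = vapply(bundles, function(b) b$label %||% NA_character_,
                      character(1)),
    input_hashes = input_hashes,
    config = list(patterns = patterns, reporter_codes = reporter_codes,
                  strict_ps = strict_ps, hcp_background = hcp_background,
                  thresholds = thresholds, priors = priors,
                  variance_model = variance_model, excluded_socs = excluded),
    counts = counts
  )

  result <- structure(list(cohort = cohort, signals = signals,
                           characteristics = characteristics, tto = tto,
                           tto_summary = tto_summary,
                           concomitants = concomitants,
                           subgroups = subgroups, manifest = manifest),
                      class = "faers_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' Write pipeline outputs as delimited tables plus a JSON manifest
#'
#' @param result a `faers_pipeline`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(
    wt(format_signal_table(result$signals[result$signals$level == "SOC", ]),
       "signals_soc"),
    wt(format_signal_table(result$signals[result$signals$level == "PT", ]),
       "signals_pt"),
    wt(result$characteristics, "characteristics"),
    wt(result$tto_summary$bins, "tto_bins"),
    wt(data.frame(statistic = c("n_valid", "median_days", "iqr_low",
                                "iqr_high"),
                  value = c(result$tto_summary$n_valid,
                            result$tto_summary$median_days,
                            result$tto_summary$iqr_low,
                            result$tto_summary$iqr_high)), "tto_summary"),
    wt(result$concomitants, "concomitants")
  )
  for (nm in names(result$subgroups)) {
    safe <- gsub("[^[:alnum:]]+", "_", tolower(nm))
    paths <- c(paths, wt(format_signal_table(result$subgroups[[nm]]),
                         paste0("subgroup_", safe)))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(paths, manifest_path))
}

#' @export
print.faers_pipeline <- function(x, ...) {
  cat("FAERS screening pipeline run\n")
  print(x$cohort)
  cat(sprintf("PT signals of interest: %d of %d screened\n",
              x$manifest$counts$pts_of_interest,
              x$manifest$counts$pts_screened))
  cat(sprintf("Time-to-onset: median %s days (n = %d)\n",
              format(x$tto_summary$median_days), x$tto_summary$n_valid))
  invisible(x)
}
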