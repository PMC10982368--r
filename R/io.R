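# Ingestion of FAERS quarterly ASCII extracts. Each quarter ships seven
# dollar-delimited tables with one header line; this reader is tolerant:
# column order is irrelevant, names are matched case-insensitively, known
# column aliases from older quarters are folded in, and rows with the wrong
# field count are counted as malformed rather than silently dropped.

# expected column sets (2012Q4+ schema plus the early-2012 aliases needed)
.faers_schema <- list(
  demo = list(
    required = c("PRIMARYID", "CASEID", "FDA_DT"),
    optional = c("EVENT_DT", "SEX", "AGE", "AGE_COD", "WT", "WT_COD",
                 "REPORTER_COUNTRY", "OCCR_COUNTRY", "OCCP_COD"),
    aliases = c(GNDR_COD = "SEX", CASE = "CASEID", ISR = "PRIMARYID")
  ),
  drug = list(
    required = c("PRIMARYID", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
    optional = c("PROD_AI", "DOSE_AMT", "DOSE_UNIT", "DOSE_FREQ"),
    aliases = c(ISR = "PRIMARYID")
  ),
  reac = list(
    required = c("PRIMARYID", "PT"),
    optional = character(0),
    aliases = c(ISR = "PRIMARYID")
  ),
  ther = list(
    required = c("PRIMARYID", "DSG_DRUG_SEQ"),
    optional = c("START_DT", "END_DT"),
    aliases = c(ISR = "PRIMARYID", DRUG_SEQ = "DSG_DRUG_SEQ")
  ),
  outc = list(
    required = c("PRIMARYID", "OUTC_COD"),
    optional = character(0),
    aliases = c(ISR = "PRIMARYID", OUTC_CD = "OUTC_COD")
  ),
  indi = list(
    required = c("PRIMARYID", "INDI_DRUG_SEQ", "INDI_PT"),
    optional = character(0),
    aliases = c(ISR = "PRIMARYID")
  ),
  rpsr = list(
    required = c("PRIMARYID", "RPSR_COD"),
    optional = character(0),
    aliases = c(ISR = "PRIMARYID")
  )
)

#' Read one dollar-delimited FAERS table
#'
#' @param path file path.
#' @param delim field delimiter (FAERS uses `"$"`).
#' @return data.frame of character columns with upper-cased names. Rows whose
#'   field count does not match the header are excluded and counted in the
#'   `"n_malformed"` attribute; `"n_data_lines"` records the raw data-line
#'   count so that rows in = rows parsed + rows malformed.
#' @export
read_faers_table <- function(path, delim = "$") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- toupper(trimws(strsplit(lines[1L], delim, fixed = TRUE)[[1L]]))
  ncol <- length(header)
  body <- lines[-1L]
  n_data <- length(body)
  if (n_data == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = ncol,
                               dimnames = list(NULL, header)),
                        stringsAsFactors = FALSE)
    attr(df, "n_malformed") <- 0L
    attr(df, "n_data_lines") <- 0L
    return(df)
  }
  # sentinel keeps trailing empty fields countable after strsplit
  sp <- strsplit(paste0(body, delim, "\x01"), delim, fixed = TRUE)
  lens <- lengths(sp)
  good <- lens == ncol + 1L
  n_malformed <- sum(!good)
  if (n_malformed > 0L) {
    warning(sprintf("%s: %d malformed row(s) excluded (field count != %d)",
                    basename(path), n_malformed, ncol))
  }
  m <- matrix(unlist(sp[good], use.names = FALSE),
              ncol = ncol + 1L, byrow = TRUE)
  df <- as.data.frame(m[, seq_len(ncol), drop = FALSE],
                      stringsAsFactors = FALSE)
  names(df) <- header
  df[] <- lapply(df, trimws)
  attr(df, "n_malformed") <- n_malformed
  attr(df, "n_data_lines") <- n_data
  df
}

# internal: apply aliases, check required columns, add missing optional ones
conform_table <- function(df, table) {
  sch <- .faers_schema[[table]]
  nm <- toupper(names(df))
  hit <- nm %in% names(sch$aliases) & !(unname(sch$aliases[nm]) %in% nm)
  nm[hit] <- unname(sch$aliases[nm[hit]])
  names(df) <- nm
  miss <- setdiff(sch$required, nm)
  if (length(miss) > 0L) {
    stop(sprintf("%s table is missing required column(s): %s",
                 toupper(table), paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(sch$optional, nm)) df[[col]] <- NA_character_
  df[, c(sch$required, sch$optional), drop = FALSE]
}

#' Locate FAERS table files in a directory
#'
#' Matches files named like `DEMO<tag>.txt` / `demo_2023Q1.TXT` etc.
#'
#' @param dir directory to search.
#' @return data.frame with columns `table`, `label`, `path`.
#' @export
faers_quarter_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|TXT)$", full.names = TRUE)
  base <- toupper(basename(files))
  rx <- "^(DEMO|DRUG|REAC|THER|OUTC|INDI|RPSR)[_-]?([0-9]{2,4}Q[1-4])?.*\\.TXT$"
  keep <- grepl(rx, base)
  data.frame(
    table = tolower(sub(rx, "\\1", base[keep])),
    label = sub(rx, "\\2", base[keep]),
    path = files[keep],
    stringsAsFactors = FALSE
  )
}

#' Read one FAERS quarter into a bundle
#'
#' `paths` is either a directory containing `DEMO*.txt`, `DRUG*.txt`, ... or
#' a named character vector/list with (case-insensitive) names among
#' `demo, drug, reac, ther, outc, indi, rpsr`. DEMO, DRUG and REAC are
#' mandatory; missing optional tables yield empty collections with a warning.
#' Child-table rows whose `PRIMARYID` does not appear in DEMO are counted as
#' orphans and excluded.
#'
#' @param paths directory or named paths (see details).
#' @param label quarter tag, e.g. `"2023Q1"`; inferred from file names when
#'   reading a directory that holds a single quarter.
#' @param delim field delimiter, default `"$"`.
#' @return object of class `faers_quarter`: a list with data.frames `demo`,
#'   `drug`, `reac`, `ther`, `outc`, `indi`, the `label`, and a `counts`
#'   list (malformed and orphan rows per table).
#' @export
read_faers_quarter <- function(paths, label = NULL, delim = "$") {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    found <- faers_quarter_files(paths)
    if (!is.null(label)) found <- found[found$label %in% c(label, ""), ]
    paths <- stats::setNames(as.list(found$path), found$table)
    if (is.null(label)) {
      labs <- unique(found$label[nzchar(found$label)])
      if (length(labs) == 1L) label <- labs
    }
  }
  names(paths) <- tolower(names(paths))
  for (tb in c("demo", "drug", "reac")) {
    if (is.null(paths[[tb]])) {
      stop("mandatory table missing: ", toupper(tb), call. = FALSE)
    }
  }
  counts <- list(malformed = integer(0), orphans = integer(0),
                 data_lines = integer(0))
  out <- list()
  for (tb in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    if (is.null(paths[[tb]])) {
      warning("optional table missing: ", toupper(tb),
              " (empty collection used)")
      sch <- .faers_schema[[tb]]
      cols <- c(sch$required, sch$optional)
      df <- as.data.frame(matrix(character(0), ncol = length(cols),
                                 dimnames = list(NULL, cols)),
                          stringsAsFactors = FALSE)
      counts$malformed[tb] <- 0L
      counts$data_lines[tb] <- 0L
    } else {
      df <- read_faers_table(paths[[tb]], delim = delim)
      counts$malformed[tb] <- attr(df, "n_malformed")
      counts$data_lines[tb] <- attr(df, "n_data_lines")
      df <- conform_table(df, tb)
    }
    out[[tb]] <- df
  }
  demo_ids <- out$demo$PRIMARYID
  for (tb in c("drug", "reac", "ther", "outc", "indi")) {
    orphan <- !(out[[tb]]$PRIMARYID %in% demo_ids)
    counts$orphans[tb] <- sum(orphan)
    if (any(orphan)) {
      warning(sprintf("%s: %d orphan row(s) with PRIMARYID absent from DEMO excluded",
                      toupper(tb), sum(orphan)))
      out[[tb]] <- out[[tb]][!orphan, , drop = FALSE]
    }
  }
  structure(c(out, list(label = label %||% NA_character_, counts = counts)),
            class = "faers_quarter")
}

#' Write a quarter bundle back to the FAERS ASCII dialect
#'
#' Emits `DEMO_<label>.txt`, `DRUG_<label>.txt`, ... in `dir`, one header
#' line, `NA` as the empty string. Used for fixtures and by the synthetic
#' generator; `read_faers_quarter()` round-trips its output.
#'
#' @param bundle a `faers_quarter`.
#' @param dir output directory (created if needed).
#' @param delim field delimiter.
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers_quarter <- function(bundle, dir, delim = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- if (is.na(bundle$label)) "" else paste0("_", bundle$label)
  paths <- character(0)
  for (tb in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    df <- bundle[[tb]]
    path <- file.path(dir, paste0(toupper(tb), lab, ".txt"))
    out <- df
    out[] <- lapply(out, function(col) ifelse(is.na(col), "", as.character(col)))
    lines <- c(paste(names(out), collapse = delim),
               if (nrow(out) > 0L) do.call(paste, c(out, sep = delim)))
    writeLines(lines, path)
    paths[tb] <- path
  }
  invisible(paths)
}

#' Read every quarter found in a directory
#'
#' @param dir directory holding `<TABLE>_<label>.txt` files for one or more
#'   quarters.
#' @param delim field delimiter.
#' @return named list of `faers_quarter` bundles, one per quarter label.
#' @export
read_faers_data <- function(dir, delim = "$") {
  found <- faers_quarter_files(dir)
  if (nrow(found) == 0L) stop("no FAERS table files found in ", dir)
  labs <- unique(found$label)
  out <- lapply(labs, function(lb) {
    sub <- found[found$label == lb, ]
    read_faers_quarter(stats::setNames(as.list(sub$path), sub$table),
                       label = if (nzchar(lb)) lb else NULL, delim = delim)
  })
  stats::setNames(out, ifelse(nzchar(labs), labs, "quarter"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
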