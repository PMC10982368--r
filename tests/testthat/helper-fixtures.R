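# In-code fixtures: a tiny hand-enumerable quarter bundle and a small
# synthetic configuration used across the test files.

mini_demo <- function() {
  data.frame(
    PRIMARYID = c("1001", "1002", "2001", "3001", "4001", "5001"),
    CASEID = c("100", "100", "200", "300", "400", "500"),
    FDA_DT = c("20200101", "20200301", "20200215", "20200310", "20200401",
               "20200501"),
    EVENT_DT = c("20200101", "20200126", "202002", "20200301", "", "20200420"),
    SEX = c("F", "F", "M", "F", "", "M"),
    AGE = c("65", "65", "780", "7", "45", ""),
    AGE_COD = c("YR", "YR", "MON", "DEC", "YR", ""),
    WT = c("70", "70", "220", "", "45", "0"),
    WT_COD = c("KG", "KG", "LBS", "", "KG", "KG"),
    REPORTER_COUNTRY = c("US", "US", "JP", "GB", "US", "JP"),
    OCCR_COUNTRY = c("US", "US", "JP", "GB", "US", "JP"),
    OCCP_COD = c("MD", "MD", "PH", "OT", "CN", "MD"),
    stringsAsFactors = FALSE
  )
}

mini_drug <- function() {
  data.frame(
    PRIMARYID = c("1002", "1002", "2001", "3001", "4001", "5001"),
    DRUG_SEQ = c("1", "2", "1", "1", "1", "1"),
    ROLE_COD = c("PS", "C", "PS", "SS", "PS", "PS"),
    DRUGNAME = c("MYRBETRIQ", "ASPIRIN", "Mirabegron 50 MG Tablet",
                 "BETMIGA", "MIRABEGRON", "LISINOPRIL"),
    PROD_AI = c("MIRABEGRON", "", "", "", "MIRABEGRON", ""),
    DOSE_AMT = c("50", "", "25", "", "", ""),
    DOSE_UNIT = c("MG", "", "MG", "", "", ""),
    DOSE_FREQ = c("QD", "", "BID", "", "", ""),
    stringsAsFactors = FALSE
  )
}

mini_reac <- function() {
  data.frame(
    PRIMARYID = c("1002", "1002", "2001", "2001", "3001", "4001", "5001"),
    PT = c("Dry mouth ", "Urinary retention", "DRY MOUTH", "Fall",
           "Tachycardia", "Dry mouth", "Headache"),
    stringsAsFactors = FALSE
  )
}

mini_ther <- function() {
  data.frame(
    PRIMARYID = c("1002", "2001"),
    DSG_DRUG_SEQ = c("1", "1"),
    START_DT = c("20200101", "202001"),
    END_DT = c("20200131", ""),
    stringsAsFactors = FALSE
  )
}

mini_outc <- function() {
  data.frame(
    PRIMARYID = c("1002", "1002", "2001"),
    OUTC_COD = c("HO", "HO", "OT"),
    stringsAsFactors = FALSE
  )
}

mini_indi <- function() {
  data.frame(
    PRIMARYID = c("1002", "2001"),
    INDI_DRUG_SEQ = c("1", "1"),
    INDI_PT = c("Hypertonic bladder", "Incontinence"),
    stringsAsFactors = FALSE
  )
}

mini_bundle <- function() {
  structure(list(demo = mini_demo(), drug = mini_drug(), reac = mini_reac(),
                 ther = mini_ther(), outc = mini_outc(), indi = mini_indi(),
                 label = "2020Q1",
                 counts = list(malformed = integer(0), orphans = integer(0))),
            class = "faers_quarter")
}

# write the mini bundle as FAERS ASCII files and return the directory
mini_dir <- function() {
  d <- tempfile("faers_mini_")
  write_faers_quarter(mini_bundle(), d)
  d
}

# small, fast synthetic configuration for structural tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_target = 300L, n_target_nonhcp = 60L,
                   n_target_nonps = 40L, n_background = 2000L, ...)
}

# cohort events as a data.frame(id, term) for contingency construction
events_df <- function(ids, terms) {
  data.frame(id = as.character(ids), term = terms, stringsAsFactors = FALSE)
}
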