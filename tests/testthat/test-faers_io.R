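test_that("date parsing assigns precision by digit count and validity", {
  res <- faers_parse_date(c("20200131", "202001", "2020", "20201332",
                            "202013", "", "abc", NA))
  expect_equal(res$precision,
               c("day", "month", "year", "none", "none", "none", "none",
                 "none"))
  expect_equal(res$date[1], as.Date("2020-01-31"))
  expect_equal(res$date[2], as.Date("2020-01-01"))
  expect_equal(res$date[3], as.Date("2020-01-01"))
  expect_true(all(is.na(res$date[4:8])))
  # total function: no error on garbage
  expect_no_error(faers_parse_date(c("99", "2020-01-01", "    ")))
})

test_that("age normalization converts every unit to years", {
  expect_equal(normalize_age(65, "YR"), 65)
  expect_equal(normalize_age(780, "MON"), 65)
  expect_equal(normalize_age(7, "DEC"), 70)
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(52.1429, "WK"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  # unknown unit: plausible adult values pass as years, others unknown
  expect_equal(normalize_age(70, ""), 70)
  expect_true(is.na(normalize_age(5, "")))
  expect_warning(res <- normalize_age(-1, "YR"), "negative")
  expect_true(is.na(res))
})

test_that("weight normalization converts to kg and rejects non-positives", {
  expect_equal(normalize_weight(70, "KG"), 70)
  expect_equal(normalize_weight(220, "LBS"), 99.79, tolerance = 0.01 / 99)
  expect_equal(normalize_weight(70000, "GMS"), 70)
  expect_warning(res <- normalize_weight(0, "KG"), "non-positive")
  expect_true(is.na(res))
  expect_true(is.na(normalize_weight(70, "UNK")))
})

test_that("quarter reading counts rows and maps columns by name", {
  d <- mini_dir()
  b <- read_faers_quarter(d)
  expect_s3_class(b, "faers_quarter")
  expect_equal(nrow(b$demo), 6)
  expect_equal(b$drug$ROLE_COD[b$drug$PRIMARYID == "1002"][1], "PS")
  expect_equal(b$label, "2020Q1")
  # a 3-line file (header + 2 rows) parses to 2 records
  p <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt", "1$10$20200101", "2$20$20200102"), p)
  df <- read_faers_table(p)
  expect_equal(nrow(df), 2)
  expect_equal(names(df), c("PRIMARYID", "CASEID", "FDA_DT"))
})

test_that("column order independence and legacy aliases", {
  d <- tempfile()
  dir.create(d)
  writeLines(c("FDA_DT$GNDR_COD$PRIMARYID$CASEID",
               "20200101$F$11$1"), file.path(d, "DEMO_2020Q1.txt"))
  writeLines(c("DRUGNAME$PRIMARYID$ROLE_COD$DRUG_SEQ",
               "MYRBETRIQ$11$PS$1"), file.path(d, "DRUG_2020Q1.txt"))
  writeLines(c("PT$PRIMARYID", "Dry mouth$11"),
             file.path(d, "REAC_2020Q1.txt"))
  w <- capture_warnings(b <- read_faers_quarter(d))
  expect_true(any(grepl("optional table missing", w)))
  expect_equal(b$demo$SEX, "F")
  expect_equal(b$demo$PRIMARYID, "11")
  expect_equal(nrow(b$ther), 0)
})

test_that("malformed rows are counted, never silently dropped", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$pt", "1$Dry mouth", "brokenrow", "2$Headache$extra",
               "3$Nausea"), p)
  expect_warning(df <- read_faers_table(p), "malformed")
  expect_equal(nrow(df), 2)
  expect_equal(attr(df, "n_malformed"), 2)
  # conservation: rows in = rows parsed + rows malformed
  expect_equal(attr(df, "n_data_lines"), nrow(df) + attr(df, "n_malformed"))
  # trailing empty fields still count as fields
  p2 <- tempfile(fileext = ".txt")
  writeLines(c("a$b$c", "1$$"), p2)
  df2 <- read_faers_table(p2)
  expect_equal(attr(df2, "n_malformed"), 0)
  expect_equal(df2$B, "")
  expect_equal(df2$C, "")
})

test_that("missing mandatory table errors; orphan child rows are excluded", {
  d <- mini_dir()
  file.remove(file.path(d, "DEMO_2020Q1.txt"))
  expect_error(read_faers_quarter(d), "DEMO")

  d2 <- mini_dir()
  reac_path <- file.path(d2, "REAC_2020Q1.txt")
  cat("9999$Phantom event\n", file = reac_path, append = TRUE)
  expect_warning(b <- read_faers_quarter(d2), "orphan")
  expect_false("9999" %in% b$reac$PRIMARYID)
  expect_equal(unname(b$counts$orphans["reac"]), 1L)
})

test_that("write/read round-trips the data model field by field", {
  syn <- generate_faers(small_config(seed = 3))
  b <- syn$bundles[[1]]
  d <- tempfile("rt_")
  write_faers_quarter(b, d)
  b2 <- read_faers_quarter(d, label = b$label)
  for (tb in c("demo", "drug", "reac", "ther", "outc", "indi")) {
    orig <- b[[tb]]
    back <- b2[[tb]][, names(orig), drop = FALSE]
    rownames(orig) <- rownames(back) <- NULL
    expect_equal(back, orig, info = tb)
  }
})

test_that("PT text is case-normalized and trimmed before counting", {
  expect_equal(normalize_pt("Dry mouth "), "Dry mouth")
  expect_equal(normalize_pt("DRY  MOUTH"), "Dry mouth")
  expect_equal(normalize_pt("dry mouth"), "Dry mouth")
  expect_true(is.na(normalize_pt("   ")))
  cases <- build_cases(mini_bundle())
  # 1002 lists "Dry mouth " once; 2001 lists "DRY MOUTH": one row each,
  # identical canonical form
  pts <- cases$reactions$pt[cases$reactions$PRIMARYID %in% c("1002", "2001")]
  expect_equal(sum(pts == "Dry mouth"), 2)
})
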