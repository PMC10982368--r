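test_that("deduplication retains max FDA_DT, then max PRIMARYID", {
  demo <- data.frame(
    PRIMARYID = c("1001", "1002"), CASEID = c("100", "100"),
    FDA_DT = c("20200101", "20200301"), stringsAsFactors = FALSE)
  expect_equal(dedup_cases(demo)$PRIMARYID, "1002")

  demo2 <- data.frame(
    PRIMARYID = c("1003", "1002"), CASEID = c("100", "100"),
    FDA_DT = c("20200301", "20200301"), stringsAsFactors = FALSE)
  expect_equal(dedup_cases(demo2)$PRIMARYID, "1003")

  # magnitude comparison, not lexicographic: "10" beats "9"
  demo3 <- data.frame(
    PRIMARYID = c("9", "10"), CASEID = c("1", "1"),
    FDA_DT = c("20200101", "20200101"), stringsAsFactors = FALSE)
  expect_equal(dedup_cases(demo3)$PRIMARYID, "10")

  # all-distinct caseids: identity
  demo4 <- data.frame(PRIMARYID = c("1", "2", "3"),
                      CASEID = c("10", "20", "30"),
                      FDA_DT = rep("20200101", 3), stringsAsFactors = FALSE)
  expect_equal(dedup_cases(demo4)$PRIMARYID, demo4$PRIMARYID)
  expect_equal(attr(dedup_cases(demo4), "n_removed"), 0L)
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(42)
  demo <- data.frame(
    PRIMARYID = as.character(sample(1:500)),
    CASEID = as.character(sample(1:120, 500, replace = TRUE)),
    FDA_DT = format(as.Date("2020-01-01") + sample(0:900, 500, replace = TRUE),
                    "%Y%m%d"),
    stringsAsFactors = FALSE)
  once <- dedup_cases(demo)
  twice <- dedup_cases(once)
  expect_equal(attr(twice, "n_removed"), 0L)
  expect_equal(twice$PRIMARYID, once$PRIMARYID)
  for (i in 1:5) {
    perm <- demo[sample(nrow(demo)), , drop = FALSE]
    expect_setequal(dedup_cases(perm)$PRIMARYID, once$PRIMARYID)
  }
  expect_equal(length(unique(once$CASEID)), nrow(once))
})

test_that("records without CASEID survive as singleton cases", {
  demo <- data.frame(PRIMARYID = c("1", "2", "3"),
                     CASEID = c("", "", "10"),
                     FDA_DT = rep("20200101", 3), stringsAsFactors = FALSE)
  expect_warning(out <- dedup_cases(demo), "singleton")
  expect_equal(nrow(out), 3)
})

test_that("target matching is word-bounded and case-insensitive", {
  drug <- data.frame(
    DRUGNAME = c("MYRBETRIQ", "Mirabegron 50 MG Tablet", "MIRTAZAPINE",
                 "betmiga", "UNKNOWN DRUG", "XMIRABEGRONX"),
    PROD_AI = c("", "", "", "", "MIRABEGRON", ""),
    stringsAsFactors = FALSE)
  expect_equal(match_target(drug),
               c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("cohort selection applies the PS and reporter filters", {
  cases <- build_cases(mini_bundle())
  coh <- select_cohort(cases)
  # case 100 retained as 1002 (MD, PS MYRBETRIQ) -> target
  expect_true("1002" %in% coh$target$PRIMARYID)
  # 2001 PH + PS mirabegron -> target
  expect_true("2001" %in% coh$target$PRIMARYID)
  # 3001 target drug in role SS only -> background, not target
  expect_true("3001" %in% coh$background$PRIMARYID)
  # 4001 consumer-reported -> excluded from both strata
  expect_false("4001" %in% c(coh$target$PRIMARYID, coh$background$PRIMARYID))
  # 5001 other drug, MD -> background
  expect_true("5001" %in% coh$background$PRIMARYID)
  # disjoint, exhaustive partition of the reporter-filtered case set
  expect_length(intersect(coh$target$PRIMARYID, coh$background$PRIMARYID), 0)
  expect_equal(nrow(coh$target) + nrow(coh$background),
               coh$counts$reporter_eligible)
})

test_that("adding a reporter code can only grow both strata", {
  syn <- generate_faers(small_config(seed = 11))
  cases <- build_cases(syn$bundles)
  base <- select_cohort(cases, reporter_codes = c("MD", "PH", "OT"))
  wider <- select_cohort(cases, reporter_codes = c("MD", "PH", "OT", "RN"))
  expect_gte(nrow(wider$target), nrow(base$target))
  expect_gte(nrow(wider$background), nrow(base$background))
  expect_true(all(base$target$PRIMARYID %in% wider$target$PRIMARYID))
})

test_that("strict PS mode drops reports with another primary suspect", {
  b <- mini_bundle()
  # add a second PS drug to report 1002
  b$drug <- rbind(b$drug, data.frame(
    PRIMARYID = "1002", DRUG_SEQ = "3", ROLE_COD = "PS",
    DRUGNAME = "WARFARIN", PROD_AI = "", DOSE_AMT = "", DOSE_UNIT = "",
    DOSE_FREQ = "", stringsAsFactors = FALSE))
  cases <- build_cases(b)
  lax <- select_cohort(cases, strict_ps = FALSE)
  strict <- select_cohort(cases, strict_ps = TRUE)
  expect_true("1002" %in% lax$target$PRIMARYID)
  expect_false("1002" %in% strict$target$PRIMARYID)
})

test_that("empty target cohort is a hard error with diagnostics", {
  b <- mini_bundle()
  cases <- build_cases(b, patterns = c("NONEXISTENTDRUGNAME"))
  expect_error(select_cohort(cases), "empty target cohort")
})

test_that("SOC exclusion removes only the excluded classes", {
  ev <- data.frame(
    pt = c("Fall", "Dry mouth", "Homelessness"),
    soc = c("Injury, poisoning and procedural complications",
            "Gastrointestinal disorders", "Social circumstances"),
    stringsAsFactors = FALSE)
  out <- exclude_socs(ev)
  expect_equal(out$pt, "Dry mouth")
  expect_equal(attr(out, "n_removed"), 2L)
  # empty excluded set is the identity
  id <- exclude_socs(ev, character(0))
  expect_equal(id$pt, ev$pt)
})
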