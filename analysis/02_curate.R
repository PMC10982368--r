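#!/usr/bin/env Rscript
# Ingest the synthetic quarterly files, deduplicate to one report version per
# case, and select the target (HCP reporter, target drug as primary suspect)
# and comparator cohorts. Writes the attrition counts.

library(faersignal)

bundles <- read_faers_data("results/synthetic")
cases <- build_cases(bundles)
cohort <- select_cohort(cases)

ct <- cohort$counts
cat(sprintf("Raw report versions: %d\n", ct$demo_rows))
cat(sprintf("Deduplicated cases:  %d (%d duplicate versions removed)\n",
            ct$cases, ct$duplicates_removed))
cat(sprintf("Target drug any role: %d | as primary suspect: %d\n",
            ct$target_any_role, ct$target_ps))
cat(sprintf("HCP-reported cases:  %d\n", ct$reporter_eligible))
cat(sprintf("Target cohort: %d | comparator: %d\n",
            ct$cohort_target, ct$cohort_background))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(ct, "results/attrition.json", auto_unbox = TRUE,
                     pretty = TRUE)
cat("wrote results/attrition.json\n")
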