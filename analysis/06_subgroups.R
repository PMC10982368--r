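#!/usr/bin/env Rscript
# Subgroup re-screening: weight bands, continents and the top co-reported
# drugs, each screened with the identical disproportionality machinery
# restricted to the stratum.

library(faersignal)

bundles <- read_faers_data("results/synthetic")
cohort <- select_cohort(build_cases(bundles))
map <- load_pt_soc_map("results/synthetic/toy_pt_soc.tsv")

top <- top_concomitants(cohort, k = 3)
cat("Top co-reported drugs in the target cohort:\n")
print(top, row.names = FALSE)

specs <- c(
  lapply(c("<50", "50-100", ">100"), function(b) subgroup_spec("weight_band", b)),
  lapply(c("North America", "Europe", "Asia"), function(ct)
    subgroup_spec("continent", ct)),
  lapply(top$drug, function(d) subgroup_spec("concomitant_drug", d))
)

for (sp in specs) {
  res <- suppressWarnings(
    screen_subgroup(cohort, sp, map = map, level = "pt"))
  label <- paste0(sp$kind, ":", sp$parameter)
  hits <- res[res$of_interest, ]
  cat(sprintf("\n%s - %d target report(s), %d PT(s) of interest\n",
              label, if (nrow(res) > 0)
                res$a[1] + res$b[1] else 0, nrow(hits)))
  if (nrow(hits) > 0) {
    print(utils::head(format_signal_table(hits), 10), row.names = FALSE)
  }
  safe <- gsub("[^[:alnum:]]+", "_", tolower(label))
  write.table(format_signal_table(res),
              file.path("results", paste0("subgroup_", safe, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nwrote results/subgroup_*.tsv\n")
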