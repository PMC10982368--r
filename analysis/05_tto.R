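#!/usr/bin/env Rscript
# Time-to-onset of adverse events in the target cohort: median, IQR and
# binned distribution. The generator's onset model is lognormal with median
# 25 days, so the recovered median should sit near 25.

library(faersignal)

bundles <- read_faers_data("results/synthetic")
cohort <- select_cohort(build_cases(bundles))

tto <- compute_tto(cohort)
s <- summarize_tto(tto)
print(s)
cat(sprintf("\nexcluded: %d missing/partial, %d negative interval(s)\n",
            s$n_missing, s$n_negative))

write.table(s$bins, "results/tto_bins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/tto_bins.tsv\n")
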