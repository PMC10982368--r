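#!/usr/bin/env Rscript
# Clinical characteristics of the target cohort: sex, age and weight bands,
# reporter occupation, country/continent, indications, serious outcomes,
# daily dose and medication duration.

library(faersignal)

bundles <- read_faers_data("results/synthetic")
cohort <- select_cohort(build_cases(bundles))
chars <- summarize_characteristics(cohort)

write.table(chars, "results/characteristics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/characteristics.tsv\n\n")
print(chars[chars$panel %in% c("sex", "age", "continent"), ],
      row.names = FALSE)
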