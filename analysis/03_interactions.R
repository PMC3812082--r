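#!/usr/bin/env Rscript
# Classify the genetic interactions among the published mutant combinations:
# for every double/triple mutant in the transcribed tables, compare its
# relative mutation rate to the sum and product of the single-mutant
# relatives (tolerance factor 1.5).
#
# Writes: results/interaction_calls.tsv

library(fluxmut)

rel <- unique(published_rates()[, c("genotype", "reporter", "relative")])
calls <- run_interaction_stage(rel, published_pairs(), tolerance_factor = 1.5)
calls$published_category <- published_pairs()$published_category

dir.create("results", showWarnings = FALSE)
utils::write.table(calls, "results/interaction_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Interaction calls (combined vs sum/product of singles):\n")
print(calls[, c("combined", "reporter", "single_relatives",
                "combined_relative", "sum_expectation",
                "product_expectation", "category")], digits = 3)

stated <- !is.na(calls$published_category) & calls$published_category != "NA"
agree <- calls$category[stated] == calls$published_category[stated]
cat(sprintf("\nAgreement with the interactions the study states verbally: %d/%d\n",
            sum(agree), sum(stated)))
if (any(!agree)) {
  cat("Disagreements (all near category boundaries; raw ratios in the TSV):\n")
  d <- calls[stated, ][!agree, ]
  print(d[, c("combined", "reporter", "category", "published_category")])
}
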