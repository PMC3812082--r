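#!/usr/bin/env Rscript
# Estimate mutation rates for the simulated panel: Drake per-culture median
# (with order-statistic 95% CIs) for the CAN1 and his7-2 reporters, MSS
# maximum likelihood for the GCR assays; then relative rates against the
# simulated wild type, and the recovered GCR fold increase.
#
# Reads:  results/simulated_assays.tsv   (from 01_simulate_assays.R)
# Writes: results/rate_report.tsv

library(fluxmut)

report <- run_rate_stage("results/simulated_assays.tsv")
report <- add_relative_rates(report, "E134")
write_rate_report(report, "results/rate_report.tsv")

cat("Rate report (rates per cell per generation):\n")
print(report, digits = 3)

truth <- c("E134.CAN1" = 19e-8, "hst3 hst4.CAN1" = 480e-8,
           "E134.his7-2" = 0.6e-8, "hst3 hst4.his7-2" = 14e-8,
           "E134.GCR" = 3.5e-10, "hst3 hst4.GCR" = 5.5e-6)
key <- paste(report$genotype, report$reporter, sep = ".")
cat("\nRecovery against simulated truth:\n")
for (i in seq_len(nrow(report)))
  cat(sprintf("  %-18s estimated %8.3g  true %8.3g  ratio %4.2f\n",
              key[i], report$rate[i], truth[key[i]],
              report$rate[i] / truth[key[i]]))

gcr <- report[report$reporter == "GCR", ]
fold <- gcr$rate[gcr$genotype == "hst3 hst4"] / gcr$rate[gcr$genotype == "E134"]
cat(sprintf("\nGCR fold increase (mutant / wild type): %.0f (simulated truth 15,714)\n",
            fold))
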