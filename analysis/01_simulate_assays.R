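#!/usr/bin/env Rscript
# Simulate a fluctuation-assay panel emulating the study conditions: a
# wild-type strain (CAN1 forward rate ~19e-8, his7-2 reversion ~0.6e-8), the
# deacetylation-deficient double mutant (CAN1 ~480e-8, his7-2 ~14e-8), and a
# GCR assay pair (wild type ~3.5e-10; the mutant's 15,600-fold increase would
# saturate full-size cultures, so its cultures are grown to 1e6 cells, as one
# would dilute a strong mutator). 15 cultures per genotype, ~2e8 cells each
# unless noted.
#
# Writes: results/simulated_assays.tsv

library(fluxmut)

seed <- 20260919L
N_t <- 2e8

panel <- list(
  sample_ld_counts(15, rate = 19e-8,  N_t = N_t, genotype = "E134",
                   reporter = "CAN1",   seed = seed),
  # strong mutator: smaller cultures keep selective plates countable
  sample_ld_counts(15, rate = 480e-8, N_t = 2e7, genotype = "hst3 hst4",
                   reporter = "CAN1",   seed = seed + 1),
  sample_ld_counts(15, rate = 0.6e-8, N_t = N_t, genotype = "E134",
                   reporter = "his7-2", seed = seed + 2),
  sample_ld_counts(15, rate = 14e-8,  N_t = N_t, genotype = "hst3 hst4",
                   reporter = "his7-2", seed = seed + 3),
  sample_ld_counts(15, rate = 3.5e-10, N_t = 5e8, genotype = "E134",
                   reporter = "GCR",    seed = seed + 4),
  sample_ld_counts(15, rate = 5.5e-6, N_t = 1e6, genotype = "hst3 hst4",
                   reporter = "GCR",    seed = seed + 5)
)

dir.create("results", showWarnings = FALSE)
write_assay_table(panel, "results/simulated_assays.tsv")

cat("Simulated", length(panel), "assays ->", "results/simulated_assays.tsv\n")
for (a in panel)
  cat(sprintf("  %-10s %-7s median r = %g, max r = %g\n", a$genotype,
              a$reporter, median(a$cultures$r), max(a$cultures$r)))
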