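---
title: "Fluctuation-assay mutation rates and reporter-gene spectra with fluxmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-assay mutation rates and reporter-gene spectra with fluxmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmut)
```

## The problem

Spontaneous mutation rates in budding yeast are classically measured with
Luria-Delbruck fluctuation assays: many parallel cultures are started from
small inocula, grown to saturation, and plated on a selective medium that
only mutants survive (canavanine for *CAN1* forward mutations, histidine
dropout for *his7-2* frameshift reversions, canavanine plus 5-FOA for gross
chromosomal rearrangements that co-delete *CAN1* and *URA3*). Because a
mutation arising early in growth founds a large clone, mutant counts are
wildly overdispersed ("jackpots"); the count distribution, not the mean
frequency, identifies the per-cell, per-generation mutation rate.

`fluxmut` implements the full quantitative workflow around such assays:

1. rate estimation per genotype (Drake median and Ma-Sandri-Sarkar maximum
   likelihood, with 95% confidence intervals),
2. relative rates against an isogenic wild type and classification of
   genetic interactions between mutator alleles,
3. mutation calling and spectrum classification in reporter ORF sequences,
   per-class rate decomposition, and direct-repeat detection at deletion
   junctions,
4. synthetic-data generation for every input, so the whole pipeline is
   testable without raw colony counts or Sanger reads, which the study we
   reproduce did not deposit.

## The probability model

Let `m` be the expected number of mutation *events* per culture. Under the
Lea-Coulson formulation (deterministic exponential growth, Poisson mutation
arrivals proportional to cell divisions, clonal expansion of each mutant
lineage), the number `r` of mutant cells at saturation follows the
Luria-Delbruck distribution with pmf given by the Ma-Sandri-Sarkar (MSS)
recursion

```
p_0 = exp(-m),    p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1).
```

`mss_pmf()` evaluates the recursion exactly; `mss_mle()` maximizes
`sum_i log p_{r_i}(m)` over a 61-point log-spaced grid on `m` in
[1e-3, 1e3] refined by Brent search (ties broken toward smaller `m`), and
converts to a rate via `mu = m / median(N_t)`. The pmf is computed to the
largest observed count plus a 20-term guard and never renormalized: its
`~m/r^2` tail means any finite truncation sums to less than 1, and the
likelihood must use the raw recursion values.

The 95% CI is Stewart's normal approximation on `ln m`,
`sigma = 1.225 * m^-0.315 / sqrt(C)` for `C` cultures, back-transformed.
In 500 simulated assays at `m = 2`, `C = 15` (the suite's coverage check)
it covers the true `m` in roughly 94% of replicates.

When every culture has zero mutants there is no point estimate; the
reported value is the upper bound at which all-zero data retain 5%
probability, `m = -ln(0.05) / C`, flagged as a "<" bound.

### The Drake median estimator

For the point-mutation reporters the headline estimator is Drake's implicit
formula relating the mutant frequency `f = r / N` to the rate:

```
mu = f / ln(N * mu)
```

`drake_rate()` solves the equivalent monotone root problem
`mu ln(N mu) = f` by bisection to machine precision. For `r < e` the root
lies above `f` (the bracket is expanded by doubling); `r = 0` is below the
assay's detection limit and returns 0 with a flag.

The study reports "median values with 95% confidence intervals" without
saying whether Drake's formula is applied per culture or once to the median
frequency. `drake_median_rate()` applies it per culture and reports the
median with the exact binomial order-statistic CI (the `(k, n-k+1)` order
statistics with `k` the largest integer leaving at most 2.5% binomial tail
on each side; for fewer than 6 cultures no two-sided 95% interval exists
and the CI is flagged unavailable). This matches the wording and the
convention of the laboratory's earlier work; `per_culture = FALSE` exposes
the pooled variant. A zero median count means the genotype sits below
detection: the estimate becomes the upper bound implied by a single mutant
colony in a culture of median size.

The Drake median is deliberately simple and has a known upward bias at
small counts (it solves `m ln m = r_med` while the LD median satisfies
`r_med ≈ m (ln m + 1.24)`); in the simulated panel of
`analysis/02_estimate_rates.R` recoveries are within a factor of about two
at single-digit median counts and much closer for well-populated assays.
MSS MLE, used for the GCR assays, is the statistically efficient choice.

Partially plated cultures are handled by scaling observed counts to
whole-culture scale, `r / plated_fraction_selective`, before estimation.
No plating-efficiency (epsilon) correction beyond this scaling is applied.

## Relative rates and genetic interactions

A mutant's relative rate is its absolute rate divided by the isogenic
wild-type rate for the same reporter, reported at 2 significant figures
(half away from zero), with the unrounded quotient retained.

Interactions among mutator alleles compare a combined mutant's relative
rate `R_ab` with the sum `S` and product `P` of the singles: synergy means
`R_ab > S` (the two pathways guard the same lesions), a multiplicative
relationship is the stronger sub-type with `R_ab ≈ P`, additivity
(`R_ab ≈ S`) means independent lesion pools, epistasis (`R_ab` at the level
of the stronger single) means a shared pathway, and suppression means the
combined mutant falls below both singles. The study states no numeric
tolerance for "equal to"; `classify_interaction()` uses a configurable
factor-of-1.5 log-ratio tolerance and always carries the raw ratios so a
reader can re-threshold. Two rule details are our own design, forced by
consistency: the multiplicative test also requires `R_ab > S` (otherwise a
value equal to the sum of two small singles, e.g. singles 2 and 3 with a
double at 5, would be scored "multiplicative" merely because sum and
product nearly coincide), and suppression is tested before epistasis
(a combined rate below the weaker single always lies below the stronger
single times the tolerance, so the epistasis clause would otherwise shadow
it). Near category boundaries — e.g. a double at 1.2 times the sum — the
calls are genuinely sensitive to the tolerance; `analysis/03_interactions.R`
prints where our calls differ from the study's verbal labels, and all such
differences are synergistic/multiplicative or epistatic/near-additive
boundary cases.

Per-culture rate distributions are compared with the two-tailed
Mann-Whitney U test (`rank_sum_test()`, exact by enumeration up to a
combined n of 20 without ties, otherwise the tie- and continuity-corrected
normal approximation). The study's printed p-values are not reproduction
targets because the underlying per-culture data are unpublished.

### Reproducing the published tables

`reproduce_tables()` recomputes every relative-rate cell of the three
transcribed strain-panel tables from the printed absolute rates
(wild-type references: *CAN1* 19e-8, *his7-2* 0.6e-8 for the main strain
background) and compares with the printed relatives. The printed columns
follow a resolution-dependent convention, which we reverse-engineered from
the 112 cells: quotients of at least 10 are printed at 2 significant
figures, quotients between 0.75 and 10 as integers, smaller quotients at 1
significant figure, all half away from zero. Under this rule 99 of 112
cells reproduce exactly. The remaining 13 cannot be reproduced from the
printed absolute rates by any simple rounding — for instance 1600/19 is
printed as 84 in one row and 83 in an adjacent one, and 370/19 as 20 in
one table and 19 in another — indicating the published relatives were
computed from unrounded absolute rates that were not printed. These cells
are frozen in a packaged skip list (`published_rate_skips()`) with our
recomputed values and are reported as documented mismatches, not failures.

## Mutation spectra

Mutant reporter ORFs are compared with the reference by unit-cost global
alignment. Among co-optimal alignments (a deletion across a repeated motif
can be written as two separated gaps of equal total cost) we prefer the one
with the fewest gap runs by adding a vanishing gap-opening penalty, then
left-normalize every indel to its leftmost placement within homopolymer
runs and repeats — the standard variant-normalization convention; the
study does not state one. Coordinates are 1-based on the reporter coding
strand, deletions addressed by their first deleted base, insertions placed
before the reference base at their position. An edit-distance cap (default
50, raised where medium-size deletions are expected) guards against
mispaired input sequences.

Classification follows the study's decision rules:

* two or more events within a 10-bp window (transitively clustered) form a
  **complex mutation**, the signature of DNA polymerase zeta;
* lone substitutions and 1-bp indels map to their own classes;
* a lone deletion of 11-10,000 bp is a **medium-size deletion** (the
  observed range was 40-1,036 bp; 2-10 bp deletions fall into `other`,
  as does any isolate carrying several well-separated clusters);
* isolates whose DNA fails the reporter PCR but supports the control
  amplicon are **gene deletions** (GCRs) and are never sequenced;
* *his7-2* reversion requires a net +1 frameshift inside the 51-bp window
  containing the A7 run, with no compensating frameshift outside it.

`spectrum_rates()` multiplies class fractions by the genotype's total rate;
the decomposition conserves the total exactly, and PCR-scored deletions
enter both the denominator and the deletion class.

`find_junction_repeats()` scans a deletion's flanks for the longest direct
repeat consistent with the deletion: copies at offsets `i` and `i + L`
(`L` the deletion length, so removing one copy and the intervening DNA
reproduces the mutant), the left copy overlapping or abutting the 5'
junction, at most one mismatch by default ("nearly perfect" is undefined
in the study; we chose <= 1 mismatch, no indels, minimum length 4). Ties
prefer longer repeats, then fewer mismatches, then the 5'-most placement —
so a longer nearly-perfect hit outranks a shorter perfect one; query with
`max_mismatches = 0` to restrict to perfect repeats. The scan is verified
against an exhaustive search on references up to 300 bp.

## Synthetic data: what it emulates and what it does not

`sample_ld_counts()` draws counts by inverse-CDF over the exact MSS pmf.
The pmf is truncated at `r_max` (default 5000) and the residual tail mass
(about `m / r_max`) is lumped into the top bin; the heavy `~m/r^2` tail
makes any fixed small tail tolerance unattainable in principle, so the
truncation point, not a tail threshold, is the contract. Counts above the
truncation point are therefore recorded at the cap — irrelevant for
estimation at the study's culture sizes, but the reason the simulated
strong mutator in `analysis/01_simulate_assays.R` is grown in smaller
cultures, exactly as one would dilute a strong mutator at the bench.

`simulate_growth_process()` is an independent mechanistic cross-check that
shares no code with the recursion: the population grows deterministically
from `N0` to `N_t`, mutations arrive as a Poisson process over cumulative
divisions (`m = mu (N_t - N0)`), and a mutation striking at population size
`x` leaves `floor(N_t / x)` mutant cells. As `N0/N_t -> 0` this converges
to the Lea-Coulson distribution, and at `n = 10^4` cultures the two
samplers are statistically indistinguishable (chi-square homogeneity on
binned counts). We considered a synchronous binary-fission model instead,
but its count distribution provably differs from Lea-Coulson at order-one
probabilities (its `p_2 = e^-m (m/4 + m^2/8)` versus the Lea-Coulson
`e^-m (m/6 + m^2/8)`), so it cannot serve as a distributional oracle for
the MSS machinery; the continuous-time model is the faithful one.

`generate_mutant_sequences()` plants exactly one classified mutation per
isolate from configurable class weights: substitutions anywhere, 1-bp
indels biased into homopolymer runs (80% by default), complex clusters of
2-3 changes within 10 bp, medium deletions placed between naturally
occurring direct k-mer repeats of the reference where possible (so the
junction carries a detectable repeat), and GCR isolates emitted as PCR
table rows without sequences. Truth events are emitted left-normalized, so
round-trip comparisons are exact equality. Default weights (45%
substitutions, 18% 1-bp deletions, 12% 1-bp insertions, 8% complex, 7%
medium deletions, 10% gene deletions) are a generic mutator spectrum;
`analysis/04_spectrum.R` uses weights transcribed from the published
deacetylation-mutant spectrum instead (40% gene deletions, 33%
substitutions).

What the generator does not emulate: sequencing errors and heterogeneous
read quality (inputs are finished ORF sequences), multiple independent
mutations per isolate, selection among *can1* alleles (every planted event
is treated as scoreable), phenotypic lag and differential mutant fitness in
the growth model, and chromosome-scale GCR structure (deletions are scored
by PCR presence/absence only). Passing round-trip tests therefore
demonstrate the correctness of calling, normalization and classification
logic — not robustness to raw-read artifacts.

## Numerical choices and degenerate inputs

* `m = 0` and all-zero assays: handled as closed-form degenerate cases
  (certain zero counts; zero-class upper bound).
* MLE bracketing: first grid maximum wins, so likelihood ties break toward
  smaller `m`.
* Bisection and root brackets: 200 halvings (machine precision); Drake's
  upper bracket doubles from `f` until the objective changes sign.
* Rounding: "half away from zero" throughout (`signif_half_away()`),
  matching the printed tables; base R `signif()` rounds half to even and
  would disagree at ties such as 25.5.
* Printed-table comparisons use a 1e-9 relative guard so binary decimal
  representation (0.6 vs 6*0.1) cannot produce spurious mismatches.
* Problem sizes in the test suite: pmf checks to r = 50 against a
  brute-force oracle at 1e-12; MLE recovery at 5000 cultures for
  m in {0.5, 2, 8} (within 5%); CI coverage over 500 assays; sampler
  concordance at 10^4 cultures; sequence round trip over 1000 isolates on
  a 1.77-kb reporter; junction-repeat oracle equivalence over 100 random
  references. These sizes give stable statistics at fixed seeds while
  keeping the default run short.

## Known limitations

* The Drake median path reproduces the study's estimator, including its
  small-count bias; it is not a recommendation of that estimator over MSS
  MLE.
* Confidence intervals for the MLE rely on Stewart's approximation, which
  is calibrated for moderate `m` and culture counts; coverage was verified
  at the study's regime (C around 15), not at extremes.
* Interaction categories are threshold-based verbal labels, and boundary
  cases are sensitive to the tolerance factor; the raw sum/product ratios
  are always reported and should be preferred for quantitative statements.
* The 13 unreproducible relative-rate cells are a property of the published
  tables themselves; no rounding rule can recover relatives computed from
  unpublished unrounded values.
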