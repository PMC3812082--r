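# Relative rates against an isogenic wild type, rank-based two-sample
# comparison, and classification of genetic interactions between mutator
# alleles.

#' Round half away from zero to a number of significant figures
#'
#' Unlike [signif()], which rounds half to even, ties are rounded away from
#' zero; this is the convention used when reporting relative mutation rates.
#'
#' @param x Numeric vector.
#' @param digits Significant figures.
#' @return Rounded numeric vector.
#' @examples
#' signif_half_away(233.3, 2)  # 230
#' signif_half_away(25.5, 2)   # 26
#' @export
signif_half_away <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5) * 10^e
  out
}

# Rounding rule that reproduces the printed relative-rate columns of the
# published tables: quotients >= 10 at 2 significant figures, quotients in
# [0.75, 10) to the nearest integer, smaller quotients at 1 significant
# figure, all half away from zero.
printed_relative <- function(x) {
  two <- signif_half_away(x, 2)
  ifelse(two >= 10, two,
         ifelse(x >= 0.75, floor(x + 0.5), signif_half_away(x, 1)))
}

#' Relative mutation rate of a mutant versus its isogenic wild type
#'
#' @param mutant,wild_type `rate_estimate` objects (or bare rates) for the
#'   same reporter. When both carry a `reporter` attribute or come from rate
#'   report rows, a reporter mismatch is an error.
#' @param sig_figs Significant figures for the reported quotient (half away
#'   from zero). The unrounded quotient is kept in the `"unrounded"`
#'   attribute.
#' @return The rounded quotient `mutant / wild_type` with attribute
#'   `unrounded`.
#' @examples
#' relative_rate(480e-8, 19e-8)   # 25
#' relative_rate(140e-8, 0.6e-8)  # 230
#' @export
relative_rate <- function(mutant, wild_type, sig_figs = 2) {
  get_rate <- function(x) if (inherits(x, "rate_estimate")) x$rate else as.numeric(x)
  get_rep <- function(x) attr(x, "reporter", exact = TRUE)
  rm_ <- get_rep(mutant); rw <- get_rep(wild_type)
  if (!is.null(rm_) && !is.null(rw) && !identical(rm_, rw))
    stop("cannot compare rates measured with different reporters")
  mu <- get_rate(mutant); wt <- get_rate(wild_type)
  if (!is.finite(wt) || wt <= 0) stop("wild-type rate must be positive")
  raw <- mu / wt
  out <- signif_half_away(raw, sig_figs)
  attr(out, "unrounded") <- raw
  out
}

#' Classify the genetic interaction between mutator alleles
#'
#' Compares the relative mutation rate of a combined (double or triple)
#' mutant, `R_ab`, with the sum `S` and product `P` of the single-mutant
#' relative rates. The decision rule, applied in order with a multiplicative
#' log-ratio tolerance `T` (`tolerance_factor`):
#'
#' 1. **multiplicative** if `|ln(R_ab/P)| <= ln(T)` and `R_ab > S` -
#'    multiplicative is the stronger sub-type of a synergistic interaction,
#'    so it also requires exceeding the sum;
#' 2. **synergistic** if `R_ab > S * synergy_margin`;
#' 3. **additive** if `|ln(R_ab/S)| <= ln(T)`;
#' 4. **suppressive** if `R_ab < min(R_i) / T` (the combined mutant falls
#'    below every single);
#' 5. **epistatic** if `R_ab <= max(R_i) * T` (the combined mutant looks like
#'    the stronger single);
#' 6. otherwise **additive_synergistic_boundary**, with both ratios reported.
#'
#' @param single_relatives Relative rates of the single mutants (two or more
#'   positive values).
#' @param combined_relative Relative rate of the combined mutant.
#' @param tolerance_factor Multiplicative tolerance for "equal to" the sum or
#'   product (default 1.5); the published data state no numeric tolerance, so
#'   raw ratios are always carried in the call for re-thresholding.
#' @param synergy_margin Factor by which `R_ab` must exceed the sum to count
#'   as synergistic (default 1, the literal "greater than the sum").
#' @param baseline_correction If `TRUE` the additive expectation is
#'   `sum(R_i) - (k - 1)` so the wild-type baseline is counted once.
#' @param floor Smallest admissible single-mutant relative rate.
#' @return An object of class `interaction_call`: a list with the inputs,
#'   `sum_expectation`, `product_expectation`, `category`, `ratio_to_sum`,
#'   `ratio_to_product` and `tolerance_factor`.
#' @examples
#' classify_interaction(c(33, 2), 84)  # multiplicative (synergistic subtype)
#' classify_interaction(c(9, 7), 9)    # epistatic
#' classify_interaction(c(2, 3), 5)    # additive
#' @export
classify_interaction <- function(single_relatives, combined_relative,
                                 tolerance_factor = 1.5, synergy_margin = 1,
                                 baseline_correction = FALSE, floor = 0.1) {
  R <- as.numeric(single_relatives)
  if (length(R) < 2L) stop("need at least two single-mutant relative rates")
  if (any(!is.finite(R)) || any(R <= 0) ||
      !is.finite(combined_relative) || combined_relative <= 0)
    stop("relative rates must be positive")
  if (any(R < floor)) stop("single-mutant relative rate below the floor")
  if (tolerance_factor <= 1) stop("'tolerance_factor' must exceed 1")
  S <- sum(R) - if (baseline_correction) length(R) - 1 else 0
  P <- prod(R)
  Rab <- combined_relative
  lt <- log(tolerance_factor)
  category <-
    if (abs(log(Rab / P)) <= lt && Rab > S) "multiplicative"
    else if (Rab > S * synergy_margin) "synergistic"
    else if (abs(log(Rab / S)) <= lt) "additive"
    else if (Rab < min(R) / tolerance_factor) "suppressive"
    else if (Rab <= max(R) * tolerance_factor) "epistatic"
    else "additive_synergistic_boundary"
  structure(list(single_relatives = R, combined_relative = Rab,
                 sum_expectation = S, product_expectation = P,
                 category = category,
                 ratio_to_sum = Rab / S, ratio_to_product = Rab / P,
                 tolerance_factor = tolerance_factor,
                 synergy_margin = synergy_margin,
                 is_synergistic = category %in% c("multiplicative", "synergistic")),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("Interaction: singles [%s] combined %.3g -> %s\n",
              paste(signif(x$single_relatives, 3), collapse = ", "),
              x$combined_relative, x$category))
  cat(sprintf("  sum expectation %.3g (ratio %.2f), product expectation %.3g (ratio %.2f)\n",
              x$sum_expectation, x$ratio_to_sum,
              x$product_expectation, x$ratio_to_product))
  invisible(x)
}

#' Mann-Whitney U (Wilcoxon rank-sum) two-tailed test
#'
#' Two-sided rank-sum comparison of two samples, as used to compare
#' per-culture mutation rates between genotypes. The p-value is exact (by
#' enumeration) when the combined sample size is at most 20 and there are no
#' ties, and otherwise uses the normal approximation with tie and continuity
#' corrections.
#'
#' @param sample_a,sample_b Numeric vectors (nonempty).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' rank_sum_test(1:5, 6:10)  # 2 / choose(10, 5)
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be nonempty")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- (length(sample_a) + length(sample_b)) <= 20 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  min(p, 1)
}
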