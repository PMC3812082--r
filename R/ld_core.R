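# Luria-Delbruck probability model and the two rate estimators used for
# fluctuation assays: the Drake per-culture/median estimator and the
# Ma-Sandri-Sarkar (MSS) maximum-likelihood estimator.

#' Construct a fluctuation assay
#'
#' A fluctuation assay is a set of parallel cultures of one genotype, each
#' grown from a small inoculum to saturation and plated on selective medium.
#' For each culture the mutant colony count `r`, the final number of viable
#' cells `N_t`, and the fractions of the culture plated on selective and
#' total-count medium are recorded.
#'
#' @param genotype Genotype label (single string).
#' @param reporter Reporter locus; one of `"CAN1"`, `"his7-2"`, `"GCR"`.
#' @param r Integer vector of mutant colony counts, one per culture.
#' @param N_t Final viable cells per culture (recycled if scalar).
#' @param plated_fraction_selective Fraction of each culture plated on the
#'   selective medium, in (0, 1]. Observed counts are scaled to whole-culture
#'   scale as `r / plated_fraction_selective` before rate estimation.
#' @param plated_fraction_total Fraction used for total-count plating, in
#'   (0, 1]. Carried for bookkeeping; `N_t` is assumed already corrected.
#' @param culture_id Optional culture identifiers; defaults to `c1, c2, ...`.
#'
#' @return An object of class `fluctuation_assay`: a list with elements
#'   `genotype`, `reporter` and a data frame `cultures`.
#' @examples
#' fluctuation_assay("hst3 hst4", "CAN1", r = c(0, 3, 1, 12, 0, 2),
#'                   N_t = 2e8)
#' @export
fluctuation_assay <- function(genotype, reporter, r, N_t,
                              plated_fraction_selective = 1,
                              plated_fraction_total = 1,
                              culture_id = NULL) {
  stopifnot(is.character(genotype), length(genotype) == 1L,
            is.character(reporter), length(reporter) == 1L)
  if (length(r) < 1L) stop("a fluctuation assay needs at least one culture")
  if (any(!is.finite(r)) || any(r < 0) || any(r != round(r)))
    stop("mutant counts 'r' must be nonnegative integers")
  n <- length(r)
  N_t <- rep_len(N_t, n)
  plated_fraction_selective <- rep_len(plated_fraction_selective, n)
  plated_fraction_total <- rep_len(plated_fraction_total, n)
  if (any(!is.finite(N_t)) || any(N_t <= 0))
    stop("'N_t' must be positive and finite")
  if (any(plated_fraction_selective <= 0) || any(plated_fraction_selective > 1) ||
      any(plated_fraction_total <= 0) || any(plated_fraction_total > 1))
    stop("plating fractions must lie in (0, 1]")
  if (is.null(culture_id)) culture_id <- paste0("c", seq_len(n))
  if (anyDuplicated(culture_id)) stop("duplicate culture ids")
  structure(list(
    genotype = genotype,
    reporter = reporter,
    cultures = data.frame(
      culture_id = as.character(culture_id),
      r = as.numeric(r),
      N_t = N_t,
      plated_fraction_selective = plated_fraction_selective,
      plated_fraction_total = plated_fraction_total,
      stringsAsFactors = FALSE
    )
  ), class = "fluctuation_assay")
}

#' @export
print.fluctuation_assay <- function(x, ...) {
  cat(sprintf("Fluctuation assay: %s / %s (%d cultures)\n",
              x$genotype, x$reporter, nrow(x$cultures)))
  cat(sprintf("  mutant counts: %s\n",
              paste(x$cultures$r, collapse = " ")))
  invisible(x)
}

new_rate_estimate <- function(rate, ci_low, ci_high, method,
                              m = NA_real_, n_cultures = NA_integer_,
                              is_upper_bound = FALSE, below_detection = FALSE,
                              ci_available = TRUE) {
  stopifnot(rate >= 0)
  if (!is_upper_bound && ci_available &&
      is.finite(ci_low) && is.finite(ci_high) &&
      !(ci_low <= rate + 1e-12 && rate <= ci_high + 1e-12))
    stop("confidence interval does not bracket the rate")
  structure(list(rate = rate, ci_low = ci_low, ci_high = ci_high,
                 method = method, m = m, n_cultures = n_cultures,
                 is_upper_bound = is_upper_bound,
                 below_detection = below_detection,
                 ci_available = ci_available),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  bound <- if (x$is_upper_bound) "<" else ""
  ci <- if (x$ci_available) sprintf(" (95%% CI %.3g-%.3g)", x$ci_low, x$ci_high) else ""
  cat(sprintf("Mutation rate [%s]: %s%.3g per cell per generation%s\n",
              x$method, bound, x$rate, ci))
  if (is.finite(x$m)) cat(sprintf("  m = %.4g mutations per culture\n", x$m))
  invisible(x)
}

#' Ma-Sandri-Sarkar probability mass function
#'
#' Probabilities of observing `r = 0..r_max` mutant colonies in a culture in
#' which mutations arise at an expected number `m` per culture and mutant
#' lineages expand clonally during growth (the Lea-Coulson formulation of the
#' Luria-Delbruck distribution). Computed with the recursion
#' `p_0 = exp(-m)`, `p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1)`.
#'
#' @param m Expected number of mutation events per culture (nonnegative).
#' @param r_max Largest mutant count for which to return the probability.
#' @return Numeric vector of length `r_max + 1` with the probabilities of
#'   `r = 0, 1, ..., r_max` mutants. Entries are nonnegative with partial sum
#'   at most 1; the distribution has a heavy `~ m/r^2` tail, so the vector
#'   does not sum to 1 at any finite truncation.
#' @examples
#' mss_pmf(1, 5)
#' @export
mss_pmf <- function(m, r_max) {
  if (length(m) != 1L || !is.finite(m)) stop("'m' must be a single finite number")
  if (m < 0) stop("'m' must be nonnegative")
  if (length(r_max) != 1L || !is.finite(r_max) || r_max < 0 || r_max != round(r_max))
    stop("'r_max' must be a nonnegative integer")
  p <- numeric(r_max + 1)
  p[1] <- exp(-m)
  if (r_max >= 1 && m > 0) {
    # reciprocal weights 1/(r - i + 1) reused across r
    w <- 1 / seq(2, r_max + 1)
    for (r in seq_len(r_max)) {
      p[r + 1] <- (m / r) * sum(p[seq_len(r)] * w[r:1])
    }
  }
  p
}

# Log-likelihood of counts r (integer vector) at parameter m, pmf computed to
# max(r) plus a tail guard. Raw recursion values, never renormalized.
mss_loglik <- function(m, r, tail_guard = 20L) {
  p <- mss_pmf(m, max(r) + tail_guard)
  lp <- log(p[r + 1])
  if (any(!is.finite(lp))) return(-Inf)
  sum(lp)
}

#' Ma-Sandri-Sarkar maximum-likelihood rate estimate
#'
#' Maximizes the Luria-Delbruck likelihood of the observed per-culture mutant
#' counts over the expected number of mutations per culture `m`, using a
#' log-spaced bracketing grid followed by Brent refinement, and converts to a
#' rate per cell per generation as `m / median(N_t)`. The 95% confidence
#' interval is a normal interval on `ln m` with
#' `sigma_ln m = 1.225 * m^(-0.315) / sqrt(C)` (Stewart's approximation for C
#' parallel cultures), back-transformed and divided by `median(N_t)`.
#'
#' Counts from partially plated cultures are scaled to whole-culture scale as
#' `round(r / plated_fraction_selective)` before estimation.
#'
#' If every culture has zero mutants no point estimate exists; the function
#' returns an upper bound at the `m` for which the probability of observing
#' all zeros is 0.05, i.e. `m = -ln(0.05) / C`, flagged with
#' `is_upper_bound = TRUE`.
#'
#' @param assay A [fluctuation_assay()].
#' @param grid_range Range of the log-spaced bracketing grid for `m`.
#' @param grid_points Number of grid points (default 61).
#' @param tail_guard Extra pmf terms computed beyond the largest count.
#' @return A `rate_estimate` with `method = "mss_mle"`.
#' @references Ma, Sandri & Sarkar (1992) J Appl Prob 29:255-267;
#'   Stewart (1994) Genetics 137:1139-1146.
#' @examples
#' a <- sample_ld_counts(15, m = 2, N_t = 1e8, seed = 1)
#' mss_mle(a)
#' @export
mss_mle <- function(assay, grid_range = c(1e-3, 1e3), grid_points = 61L,
                    tail_guard = 20L) {
  stopifnot(inherits(assay, "fluctuation_assay"))
  cu <- assay$cultures
  if (nrow(cu) < 2L) stop("MSS MLE needs at least two cultures")
  r <- as.integer(round(cu$r / cu$plated_fraction_selective))
  C <- length(r)
  N_ref <- stats::median(cu$N_t)
  if (all(r == 0)) {
    m_bound <- -log(0.05) / C
    return(new_rate_estimate(rate = m_bound / N_ref,
                             ci_low = m_bound / N_ref,
                             ci_high = m_bound / N_ref,
                             method = "mss_mle", m = m_bound, n_cultures = C,
                             is_upper_bound = TRUE, ci_available = FALSE))
  }
  lg <- seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_points)
  ll <- vapply(lg, function(x) mss_loglik(exp(x), r, tail_guard), numeric(1))
  best <- which.max(ll)  # first maximum: ties break toward smaller m
  lo <- lg[max(1L, best - 1L)]
  hi <- lg[min(grid_points, best + 1L)]
  opt <- stats::optimize(function(x) mss_loglik(exp(x), r, tail_guard),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  m_hat <- exp(opt$maximum)
  sigma <- 1.225 * m_hat^(-0.315) / sqrt(C)
  ci_m <- exp(log(m_hat) + c(-1, 1) * stats::qnorm(0.975) * sigma)
  new_rate_estimate(rate = m_hat / N_ref,
                    ci_low = ci_m[1] / N_ref, ci_high = ci_m[2] / N_ref,
                    method = "mss_mle", m = m_hat, n_cultures = C)
}

#' Drake formula rate estimate for one culture
#'
#' Solves the implicit Drake relation `mu = f / ln(N * mu)` with mutant
#' frequency `f = r / N`, i.e. finds the root of the monotone function
#' `g(mu) = mu * ln(N * mu) - f` on `mu > 1/(e N)`. For `r = 0` the rate is
#' below the detection limit and 0 is returned, flagged in the
#' `below_detection` attribute.
#'
#' @param r Mutant count(s), scaled to whole-culture scale if the culture was
#'   partially plated. Need not be integer.
#' @param N Final number of cells (recycled against `r`).
#' @return Numeric vector of rates (mutations per cell per generation) with a
#'   logical attribute `below_detection` marking `r = 0` entries.
#' @examples
#' drake_rate(20, 2e8)
#' @export
drake_rate <- function(r, N) {
  if (any(!is.finite(r)) || any(!is.finite(N)))
    stop("'r' and 'N' must be finite")
  if (any(r < 0) || any(N <= 0))
    stop("'r' must be nonnegative and 'N' positive")
  n <- max(length(r), length(N))
  r <- rep_len(r, n); N <- rep_len(N, n)
  out <- numeric(n)
  below <- r == 0
  for (i in which(!below)) {
    f <- r[i] / N[i]
    g <- function(mu) mu * log(N[i] * mu) - f
    lo <- 1 / (exp(1) * N[i]) * (1 + 1e-9)
    hi <- f
    while (g(hi) < 0) hi <- hi * 2  # r < e places the root above f
    # bisection to full double precision (deterministic, ~1e-16 relative)
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (mid == lo || mid == hi) break
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    out[i] <- (lo + hi) / 2
  }
  attr(out, "below_detection") <- below
  out
}

#' Median with exact binomial order-statistic confidence interval
#'
#' The sample median together with the exact 95% confidence interval given by
#' the `(k, n-k+1)`-th order statistics, where `k` is the largest integer such
#' that the cumulative Binomial(n, 1/2) probability in each tail outside the
#' interval is at most `(1 - conf)/2`. For `n < 6` no two-sided 95% interval
#' exists and the interval is flagged unavailable.
#'
#' @param x Numeric vector (e.g. per-culture mutation rates).
#' @param conf Confidence level (default 0.95).
#' @return List with `median`, `ci_low`, `ci_high`, `ci_available`, and the
#'   order-statistic indices `k_low`, `k_high`.
#' @examples
#' median_rate_with_ci(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9))
#' @export
median_rate_with_ci <- function(x, conf = 0.95) {
  if (length(x) == 0L) stop("empty input")
  if (any(!is.finite(x))) stop("input must be finite")
  n <- length(x)
  s <- sort(x)
  med <- stats::median(s)
  alpha2 <- (1 - conf) / 2
  # largest k with P(X < k) = pbinom(k-1, n, 1/2) <= alpha/2
  k <- 0L
  while (k + 1L <= n && stats::pbinom(k, n, 0.5) <= alpha2) k <- k + 1L
  if (k < 1L) {
    return(list(median = med, ci_low = NA_real_, ci_high = NA_real_,
                ci_available = FALSE, k_low = NA_integer_, k_high = NA_integer_))
  }
  list(median = med, ci_low = s[k], ci_high = s[n - k + 1L],
       ci_available = TRUE, k_low = k, k_high = n - k + 1L)
}

#' Drake median rate estimate for a fluctuation assay
#'
#' Applies the Drake formula to every culture (counts scaled to whole-culture
#' scale by the selective plating fraction) and reports the median per-culture
#' rate with the exact order-statistic 95% confidence interval. With
#' `per_culture = FALSE` the Drake formula is instead applied once to the
#' median mutant frequency (a pooled variant some laboratories use).
#'
#' If the median mutant count is zero, the genotype's rate is below the
#' detection limit of the assay; the estimate is reported as an upper bound at
#' the rate implied by a single mutant colony (`r = 1`) in a culture of the
#' median size, with `is_upper_bound = TRUE`.
#'
#' @param assay A [fluctuation_assay()].
#' @param per_culture Apply Drake per culture then take the median (default),
#'   or once to the median frequency.
#' @param conf Confidence level for the order-statistic interval.
#' @return A `rate_estimate` with `method = "drake_median"`.
#' @examples
#' a <- sample_ld_counts(12, m = 1.5, N_t = 2e8, seed = 7)
#' drake_median_rate(a)
#' @export
drake_median_rate <- function(assay, per_culture = TRUE, conf = 0.95) {
  stopifnot(inherits(assay, "fluctuation_assay"))
  cu <- assay$cultures
  r_adj <- cu$r / cu$plated_fraction_selective
  C <- nrow(cu)
  N_ref <- stats::median(cu$N_t)
  if (stats::median(cu$r) == 0) {
    bound <- drake_rate(1, N_ref)[1]
    # upper order statistic of the per-culture rates still informs the CI top
    per <- as.numeric(drake_rate(r_adj, cu$N_t))
    mc <- median_rate_with_ci(per, conf)
    hi <- if (mc$ci_available && mc$ci_high > bound) mc$ci_high else bound
    return(new_rate_estimate(rate = bound, ci_low = bound, ci_high = hi,
                             method = "drake_median", n_cultures = C,
                             is_upper_bound = TRUE,
                             ci_available = mc$ci_available))
  }
  if (per_culture) {
    per <- as.numeric(drake_rate(r_adj, cu$N_t))
    mc <- median_rate_with_ci(per, conf)
    new_rate_estimate(rate = mc$median, ci_low = mc$ci_low,
                      ci_high = mc$ci_high, method = "drake_median",
                      n_cultures = C, ci_available = mc$ci_available)
  } else {
    f_med <- stats::median(r_adj / cu$N_t)
    mu <- as.numeric(drake_rate(f_med * N_ref, N_ref))
    new_rate_estimate(rate = mu, ci_low = NA_real_, ci_high = NA_real_,
                      method = "drake_median", n_cultures = C,
                      ci_available = FALSE)
  }
}
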