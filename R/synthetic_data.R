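# Synthetic inputs for the whole pipeline: Luria-Delbruck-distributed
# fluctuation-assay counts (exact pmf sampler plus an independent
# growth-process sampler) and mutant reporter-ORF sequences drawn from a
# configurable spectrum, with truth tables.

#' Sample fluctuation-assay mutant counts from the MSS pmf
#'
#' Draws per-culture mutant counts by inverse-CDF sampling over [mss_pmf()].
#' The pmf is truncated at `r_max`; because the Luria-Delbruck tail decays
#' only like `m/r^2`, the residual tail mass (about `m / r_max`) is lumped
#' into the top bin rather than discarded. Fully reproducible from `seed`.
#'
#' @param n_cultures Number of parallel cultures.
#' @param m Expected mutations per culture; alternatively give `rate`, in
#'   which case `m = rate * N_t`.
#' @param rate Mutation rate per cell per generation (used when `m` is NULL).
#' @param N_t Final viable cells per culture.
#' @param genotype,reporter Labels for the returned assay.
#' @param plated_fraction_selective Plating fraction recorded on the assay
#'   (counts are drawn at whole-culture scale and thinned binomially when the
#'   fraction is below 1).
#' @param r_max Truncation point of the pmf (default 5000).
#' @param seed Optional integer seed.
#' @return A [fluctuation_assay()].
#' @examples
#' sample_ld_counts(12, m = 2, N_t = 1e8, seed = 1)
#' @export
sample_ld_counts <- function(n_cultures, m = NULL, rate = NULL, N_t = 1e8,
                             genotype = "sim", reporter = "CAN1",
                             plated_fraction_selective = 1,
                             r_max = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(m)) {
    if (is.null(rate)) stop("give either 'm' or 'rate'")
    m <- rate * N_t
  }
  if (m < 0) stop("'m' must be nonnegative")
  if (m == 0) {
    r <- rep(0L, n_cultures)
  } else {
    p <- mss_pmf(m, r_max)
    p[length(p)] <- p[length(p)] + max(0, 1 - sum(p))  # lump the tail
    r <- sample(0:r_max, n_cultures, replace = TRUE, prob = p)
    if (plated_fraction_selective < 1)
      r <- stats::rbinom(n_cultures, r, plated_fraction_selective)
  }
  fluctuation_assay(genotype, reporter, r = r, N_t = N_t,
                    plated_fraction_selective = plated_fraction_selective)
}

#' Simulate a fluctuation assay from an explicit growth process
#'
#' Independent sampler used as a mechanistic cross-check of the pmf-based
#' sampler: a culture grows deterministically and exponentially from `N0` to
#' `N_t` cells; mutations arrive along the way as a Poisson process over
#' cumulative cell divisions (expected total `m = mu * (N_t - N0)`), and each
#' mutant lineage expands clonally for the remainder of growth, so a mutation
#' occurring when the population has size `x` leaves `floor(N_t / x)` mutant
#' cells at saturation. No code is shared with the pmf recursion; as
#' `N0/N_t -> 0` the distribution of counts converges to the Lea-Coulson
#' (MSS) distribution.
#'
#' @param n_cultures Number of cultures.
#' @param mu Mutation rate per cell division.
#' @param N0 Inoculum size (default 1000 cells).
#' @param N_t Final population size; `N_t / N0` should be a power of 2 within
#'   rounding (growth by `round(log2(N_t/N0))` doublings).
#' @param genotype,reporter Labels for the returned assay.
#' @param seed Optional integer seed.
#' @return A [fluctuation_assay()].
#' @examples
#' simulate_growth_process(10, mu = 2e-8, N0 = 1e3, N_t = 1e3 * 2^17, seed = 1)
#' @export
simulate_growth_process <- function(n_cultures, mu, N0 = 1000, N_t = N0 * 2^17,
                                    genotype = "sim", reporter = "CAN1",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mu < 0) stop("'mu' must be nonnegative")
  if (N_t <= N0) stop("'N_t' must exceed 'N0'")
  gens <- log2(N_t / N0)
  if (abs(gens - round(gens)) > 0.1)
    warning("N_t/N0 is not close to a power of 2; growth spans a fractional generation")
  m <- mu * (N_t - N0)
  r <- integer(n_cultures)
  if (mu > 0) {
    k <- stats::rpois(n_cultures, m)
    for (i in which(k > 0)) {
      x <- stats::runif(k[i], min = N0, max = N_t)  # population size at mutation
      r[i] <- sum(pmin(floor(N_t / x), N_t))
    }
  }
  fluctuation_assay(genotype, reporter, r = r, N_t = N_t)
}

#' Random reporter-like reference sequence
#'
#' Random DNA with, by default, a planted A7 homopolymer run (so frameshift
#' classes have a target, as in the *his7-2* reversion window) placed at
#' `run_position`.
#'
#' @param length Sequence length (at least 100).
#' @param run_base,run_length,run_position Planted homopolymer run; set
#'   `run_length = 0` to skip planting. `run_position = NULL` places it near
#'   the middle.
#' @param seed Optional integer seed.
#' @return A DNA string with attribute `run_position`.
#' @examples
#' nchar(simulate_reporter_reference(300, seed = 1))
#' @export
simulate_reporter_reference <- function(length = 1770, run_base = "A",
                                        run_length = 7, run_position = NULL,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length < 100) stop("reference length must be at least 100")
  x <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  if (run_length > 0) {
    if (is.null(run_position)) run_position <- floor(length / 2)
    stopifnot(run_position + run_length - 1 <= length, run_position >= 2)
    x[run_position:(run_position + run_length - 1)] <- run_base
    # break accidental run extension on both flanks
    other <- setdiff(c("A", "C", "G", "T"), run_base)
    x[run_position - 1] <- sample(other, 1)
    if (run_position + run_length <= length)
      x[run_position + run_length] <- sample(other, 1)
  }
  structure(paste(x, collapse = ""), run_position = run_position)
}

#' Apply a set of mutation events to a reference sequence
#'
#' Reconstructs the mutant sequence implied by an event table (the inverse of
#' [call_mutations()] up to left-normalization equivalence). Events must not
#' overlap.
#'
#' @param reference DNA string.
#' @param events Event data frame.
#' @return The mutant DNA string.
#' @export
apply_events <- function(reference, events) {
  check_dna(reference, "reference")
  if (!is.data.frame(events)) stop("'events' must be an event data frame")
  s <- reference
  attributes(s) <- NULL
  if (nrow(events) == 0L) return(s)
  ev <- events[order(-events$position), , drop = FALSE]  # right to left
  for (i in seq_len(nrow(ev))) {
    p <- ev$position[i]
    if (ev$kind[i] == "substitution") {
      substr(s, p, p) <- ev$alt[i]
    } else if (ev$kind[i] == "deletion") {
      s <- paste0(substr(s, 1, p - 1), substr(s, p + ev$length[i], nchar(s)))
    } else {  # insertion before position p
      s <- paste0(substr(s, 1, p - 1), ev$alt[i], substr(s, p, nchar(s)))
    }
  }
  s
}

# homopolymer runs of at least min_len in a character vector of bases
find_runs <- function(chars, min_len = 3L) {
  rl <- rle(chars)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$lengths >= min_len
  data.frame(start = starts[keep], length = rl$lengths[keep],
             base = rl$values[keep], stringsAsFactors = FALSE)
}

# pairs of identical k-mers whose separation lies in del_range; each pair
# supports a deletion between direct repeats (delete [start1, start2 - 1])
find_repeat_pairs <- function(chars, k, del_range) {
  n <- length(chars)
  if (n < 2 * k + del_range[1]) return(NULL)
  kmers <- vapply(seq_len(n - k + 1L),
                  function(i) paste(chars[i:(i + k - 1L)], collapse = ""),
                  character(1))
  idx <- split(seq_along(kmers), kmers)
  idx <- idx[lengths(idx) >= 2L]
  out <- list()
  for (positions in idx) {
    cmb <- utils::combn(positions, 2L)
    sep <- cmb[2, ] - cmb[1, ]
    ok <- sep >= del_range[1] & sep <= del_range[2]
    if (any(ok)) out[[length(out) + 1L]] <-
        data.frame(start1 = cmb[1, ok], start2 = cmb[2, ok])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

default_spectrum_weights <- function() {
  c(base_substitution = 0.45, ins_1bp = 0.12, del_1bp = 0.18,
    complex = 0.08, medium_deletion = 0.07, gcr_deletion = 0.10)
}

#' Generate mutant reporter sequences with a known spectrum
#'
#' Draws `n` independent mutant isolates from a configurable class spectrum
#' and builds each mutant sequence by planting exactly one classified
#' mutation in the reference: random base substitutions; 1-bp insertions and
#' deletions biased into homopolymer runs; complex mutations of 2-3 changes
#' within `complex_window` bp; medium-size deletions placed, when possible,
#' between naturally occurring direct repeats of the reference so the
#' junction carries a detectable repeat; and whole-gene (GCR) deletions,
#' which produce no sequence but a PCR-table row with a failed reporter
#' amplicon, mirroring the PCR-then-sequence workflow.
#'
#' All planted indels are left-normalized, so the emitted truth events are in
#' the same canonical form [call_mutations()] reports.
#'
#' @param reference DNA string (length at least 100).
#' @param n Number of mutant isolates.
#' @param spectrum_weights Named nonnegative weights over the classes
#'   `base_substitution`, `ins_1bp`, `del_1bp`, `complex`, `medium_deletion`,
#'   `gcr_deletion`; normalized to sum to 1.
#' @param seed Optional integer seed.
#' @param complex_window Span of a complex mutation (default 10 bp).
#' @param medium_del_range Length range for medium-size deletions; trimmed to
#'   what the reference can accommodate.
#' @param run_bias Probability that a 1-bp indel targets a homopolymer run
#'   when one exists (default 0.8).
#' @param repeat_len Direct-repeat k-mer length sought for medium deletions
#'   (default 8).
#' @return A list with `isolates` (data frame: `isolate`, `class`),
#'   `sequences` (named character vector; GCR isolates are absent),
#'   `truth` (named list of event data frames), and `pcr` (data frame:
#'   `isolate`, `can1_amplified`, `pol2_amplified`).
#' @examples
#' ref <- simulate_reporter_reference(400, seed = 2)
#' gen <- generate_mutant_sequences(ref, 5, seed = 3)
#' gen$isolates
#' @export
generate_mutant_sequences <- function(reference, n,
                                      spectrum_weights = default_spectrum_weights(),
                                      seed = NULL, complex_window = 10,
                                      medium_del_range = c(40, 1036),
                                      run_bias = 0.8, repeat_len = 8) {
  check_dna(reference, "reference")
  L <- nchar(reference)
  if (L < 100) stop("reference length must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  w <- spectrum_weights
  if (is.null(names(w)) || !all(names(w) %in% MUTATION_CLASSES))
    stop("spectrum weights must be named with mutation classes")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative, not all zero")
  w <- w / sum(w)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  runs <- find_runs(chars, 3L)
  del_range <- c(max(2, medium_del_range[1]), min(medium_del_range[2], L - 60))
  rep_pairs <- if (del_range[2] >= del_range[1])
    find_repeat_pairs(chars, repeat_len, del_range) else NULL
  bases <- c("A", "C", "G", "T")
  other_base <- function(b) sample(setdiff(bases, b), 1)

  make_events <- function(class) {
    switch(class,
      base_substitution = {
        p <- sample.int(L, 1)
        mutation_events("substitution", p, chars[p], other_base(chars[p]))
      },
      ins_1bp = {
        if (nrow(runs) && stats::runif(1) < run_bias) {
          ri <- sample.int(nrow(runs), 1)
          mutation_events("insertion", runs$start[ri], "", runs$base[ri])
        } else {
          p <- sample.int(L, 1)
          ev <- mutation_events("insertion", p, "", sample(bases, 1))
          left_normalize_event(ev, chars)
        }
      },
      del_1bp = {
        if (nrow(runs) && stats::runif(1) < run_bias) {
          ri <- sample.int(nrow(runs), 1)
          mutation_events("deletion", runs$start[ri], runs$base[ri], "")
        } else {
          p <- sample.int(L, 1)
          ev <- mutation_events("deletion", p, chars[p], "")
          left_normalize_event(ev, chars)
        }
      },
      complex = {
        k <- sample(2:3, 1, prob = c(0.8, 0.2))
        anchor <- sample.int(L - complex_window, 1)
        offs <- sort(sample(0:complex_window, k))
        pos <- anchor + offs
        if (stats::runif(1) < 0.5 || k > 2) {
          # clustered substitutions
          mutation_events(rep("substitution", k), pos,
                          chars[pos], vapply(chars[pos], other_base, character(1)))
        } else {
          # 1-bp insertion plus adjacent substitution (net +1 frameshift)
          p_ins <- pos[1]; p_sub <- max(pos[2], p_ins + 1L)
          ins_base <- setdiff(bases, chars[p_ins - 1L])[1]  # keep placement canonical
          rbind(mutation_events("insertion", p_ins, "", ins_base),
                mutation_events("substitution", p_sub, chars[p_sub],
                                other_base(chars[p_sub])))
        }
      },
      medium_deletion = {
        if (del_range[2] < del_range[1]) stop("reference too short for a medium deletion")
        if (!is.null(rep_pairs) && nrow(rep_pairs)) {
          i <- sample.int(nrow(rep_pairs), 1)
          p <- rep_pairs$start1[i]
          len <- rep_pairs$start2[i] - rep_pairs$start1[i]
        } else {
          len <- sample(seq(del_range[1], del_range[2]), 1)
          p <- sample.int(L - len - 20, 1) + 10L
        }
        ev <- mutation_events("deletion", p,
                              paste(chars[p:(p + len - 1L)], collapse = ""), "")
        left_normalize_event(ev, chars)
      },
      stop("cannot build events for class ", class)
    )
  }

  classes <- sample(names(w), n, replace = TRUE, prob = w)
  ids <- sprintf("iso%03d", seq_len(n))
  sequences <- character(0)
  truth <- list()
  pcr <- data.frame(isolate = ids,
                    can1_amplified = classes != "gcr_deletion",
                    pol2_amplified = TRUE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (classes[i] == "gcr_deletion") next
    ev <- NULL
    for (attempt in 1:100) {
      cand <- try(make_events(classes[i]), silent = TRUE)
      if (inherits(cand, "try-error")) next
      # reject placements whose recovered class would be ambiguous by design
      cl <- cluster_and_classify(cand, complex_window = complex_window,
                                 medium_del_range = c(11, 10000))$mclass
      target <- if (classes[i] == "medium_deletion" &&
                    nrow(cand) == 1 && cand$length[1] <= 10) "other" else classes[i]
      if (cl == target) { ev <- cand; break }
    }
    if (is.null(ev))
      stop("could not place an event of class ", classes[i], " after 100 attempts")
    truth[[ids[i]]] <- ev
    sequences[[ids[i]]] <- apply_events(reference, ev)
  }
  list(isolates = data.frame(isolate = ids, class = classes,
                             stringsAsFactors = FALSE),
       sequences = sequences, truth = truth, pcr = pcr)
}
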