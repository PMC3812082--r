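# Mutation calling from mutant reporter-ORF sequences, classification into
# spectrum classes, PCR-based whole-gene deletion scoring, per-class rate
# decomposition, and deletion-junction direct-repeat detection.

MUTATION_CLASSES <- c("base_substitution", "ins_1bp", "del_1bp", "complex",
                      "medium_deletion", "gcr_deletion", "other")

empty_events <- function() {
  data.frame(kind = character(), position = integer(),
             ref = character(), alt = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Construct a mutation event table
#'
#' Events are rows of a data frame with columns `kind` (one of
#' `"substitution"`, `"insertion"`, `"deletion"`), `position` (1-based, on the
#' reporter coding strand; for indels the leftmost affected base, with an
#' insertion placed immediately before the reference base at `position`),
#' `ref` and `alt` (nucleotide strings; the absent side of an indel is the
#' empty string), and `length`.
#'
#' @param kind Character vector of event kinds.
#' @param position Integer vector of 1-based positions.
#' @param ref,alt Reference / alternate allele strings.
#' @return A data frame of events, sorted by position.
#' @examples
#' mutation_events("substitution", 101, "G", "T")
#' @export
mutation_events <- function(kind = character(), position = integer(),
                            ref = character(), alt = character()) {
  kind <- as.character(kind)
  if (!all(kind %in% c("substitution", "insertion", "deletion")))
    stop("unknown event kind")
  if (length(kind) &&
      any(!grepl("^[ACGT]*$", ref) | !grepl("^[ACGT]*$", alt)))
    stop("alleles must be over {A,C,G,T}")
  len <- ifelse(kind == "insertion", nchar(alt),
         ifelse(kind == "deletion", nchar(ref), nchar(ref)))
  bad_sub <- kind == "substitution" & (nchar(ref) != 1L | nchar(alt) != 1L)
  if (any(bad_sub)) stop("substitutions must have single-base alleles")
  ev <- data.frame(kind = kind, position = as.integer(position),
                   ref = as.character(ref), alt = as.character(alt),
                   length = as.integer(len), stringsAsFactors = FALSE)
  ev[order(ev$position, ev$kind), , drop = FALSE]
}

check_dna <- function(x, what) {
  if (length(x) != 1L || !is.character(x) || nchar(x) == 0L)
    stop(sprintf("'%s' must be a single nonempty string", what))
  if (!grepl("^[ACGT]+$", x))
    stop(sprintf("'%s' contains characters outside {A,C,G,T} (ambiguity codes are not allowed)", what))
  x
}

# Left-normalize one indel event against the reference: shift the event left
# one base at a time while the base entering from the left equals the last
# base of the shifted block (standard leftmost placement in homopolymers and
# other repeats).
left_normalize_event <- function(ev, ref_chars) {
  if (ev$kind == "deletion") {
    p <- ev$position; L <- ev$length
    block <- ref_chars[p:(p + L - 1L)]
    while (p > 1L && ref_chars[p - 1L] == block[L]) {
      block <- c(ref_chars[p - 1L], block[-L])
      p <- p - 1L
    }
    ev$position <- p
    ev$ref <- paste(block, collapse = "")
  } else if (ev$kind == "insertion") {
    p <- ev$position
    ins <- strsplit(ev$alt, "", fixed = TRUE)[[1]]
    L <- length(ins)
    while (p > 1L && ref_chars[p - 1L] == ins[L]) {
      ins <- c(ins[L], ins[-L])
      p <- p - 1L
    }
    ev$position <- p
    ev$alt <- paste(ins, collapse = "")
  }
  ev
}

#' Call mutations between a reference and a mutant ORF sequence
#'
#' Performs a unit-cost (Levenshtein) global alignment of the two sequences,
#' converts the edit transcript into events, merges runs of adjacent
#' single-base insertions or deletions into one event, and left-normalizes
#' indels to their leftmost placement within homopolymer runs and other
#' repeats. Substitutions are kept as single-base events.
#'
#' Unit-cost alignments are often degenerate (a deletion spanning a repeated
#' motif can be represented as two separated gaps of the same total cost); a
#' vanishing gap-opening penalty is added so that among all minimum-edit
#' alignments the one with the fewest gap runs is chosen, which keeps each
#' planted indel a single contiguous event.
#'
#' @param reference,mutant DNA strings over `{A,C,G,T}`.
#' @param max_edit Guard against mispaired inputs: if the edit distance
#'   exceeds this cap an error of class `"fluxmut_suspicious_pair"` is
#'   raised. Raise the cap when medium-size deletions (tens to hundreds of
#'   bp) are expected.
#' @return A data frame of events (see [mutation_events()]); zero rows if the
#'   sequences are identical.
#' @examples
#' call_mutations("ACGTACGT", "ACGAACGT")
#' @export
call_mutations <- function(reference, mutant, max_edit = 50) {
  check_dna(reference, "reference")
  check_dna(mutant, "mutant")
  if (identical(as.character(reference), as.character(mutant)))
    return(empty_events())
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                    baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(mutant, reference, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = 0.01, gapExtension = 1)
  mg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "", fixed = TRUE)[[1]]
  rg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "", fixed = TRUE)[[1]]
  n_edit <- sum(mg != rg)
  if (n_edit > max_edit) {
    stop(structure(class = c("fluxmut_suspicious_pair", "error", "condition"),
                   list(message = sprintf(
                     "edit distance %d exceeds cap %d; sequences may be mispaired",
                     n_edit, max_edit), call = sys.call(-1))))
  }
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  kind <- character(); pos <- integer(); refa <- character(); alta <- character()
  ri <- 1L
  i <- 1L
  n_op <- length(rg)
  while (i <= n_op) {
    if (rg[i] != "-" && mg[i] != "-") {
      if (rg[i] != mg[i]) {
        kind <- c(kind, "substitution"); pos <- c(pos, ri)
        refa <- c(refa, rg[i]); alta <- c(alta, mg[i])
      }
      ri <- ri + 1L; i <- i + 1L
    } else if (rg[i] == "-") {          # gap in reference: insertion
      j <- i
      while (j <= n_op && rg[j] == "-") j <- j + 1L
      kind <- c(kind, "insertion"); pos <- c(pos, ri)
      refa <- c(refa, "")
      alta <- c(alta, paste(mg[i:(j - 1L)], collapse = ""))
      i <- j
    } else {                            # gap in mutant: deletion
      j <- i
      while (j <= n_op && mg[j] == "-") j <- j + 1L
      k <- j - i
      kind <- c(kind, "deletion"); pos <- c(pos, ri)
      refa <- c(refa, paste(rg[i:(j - 1L)], collapse = ""))
      alta <- c(alta, "")
      ri <- ri + k; i <- j
    }
  }
  ev <- mutation_events(kind, pos, refa, alta)
  if (nrow(ev)) {
    for (r in seq_len(nrow(ev))) {
      if (ev$kind[r] != "substitution")
        ev[r, ] <- left_normalize_event(ev[r, ], ref_chars)
    }
    ev <- ev[order(ev$position, ev$kind), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' Cluster events and classify the mutation they form
#'
#' Events whose positions differ by at most `complex_window` are merged
#' transitively into one candidate. A candidate of two or more events is a
#' complex mutation (the signature of DNA polymerase zeta); a lone
#' substitution, 1-bp insertion or 1-bp deletion falls in the corresponding
#' simple class; a lone deletion with length inside `medium_del_range` is a
#' medium-size deletion; everything else (including isolates carrying several
#' well-separated clusters) is `other`.
#'
#' @param events Event data frame (see [mutation_events()]), ideally sorted
#'   by position; unsorted input is reordered with a warning.
#' @param complex_window Maximum span (bp) between event positions for them
#'   to count as one clustered mutation (default 10).
#' @param medium_del_range Inclusive length range of a medium-size deletion
#'   (default 11-10000 bp; 2-10 bp deletions fall into `other`).
#' @return An object of class `classified_mutation`: list with `events`,
#'   `mclass` and `net_frameshift` (summed insertion minus deletion lengths).
#' @examples
#' ev <- mutation_events(c("substitution", "substitution"), c(100, 105),
#'                       c("G", "C"), c("T", "A"))
#' cluster_and_classify(ev)$mclass  # "complex"
#' @export
cluster_and_classify <- function(events, complex_window = 10,
                                 medium_del_range = c(11, 10000)) {
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("need at least one event to classify")
  if (is.unsorted(events$position)) {
    warning("events were not sorted by position; sorting internally")
    events <- events[order(events$position), , drop = FALSE]
  }
  net <- sum(events$length[events$kind == "insertion"]) -
    sum(events$length[events$kind == "deletion"])
  n <- nrow(events)
  n_clusters <- if (n == 1L) 1L else 1L + sum(diff(events$position) > complex_window)
  mclass <- if (n_clusters > 1L) {
    "other"
  } else if (n >= 2L) {
    "complex"
  } else {
    kind <- events$kind[1]; len <- events$length[1]
    if (kind == "substitution") "base_substitution"
    else if (kind == "insertion" && len == 1L) "ins_1bp"
    else if (kind == "deletion" && len == 1L) "del_1bp"
    else if (kind == "deletion" && len >= medium_del_range[1] &&
             len <= medium_del_range[2]) "medium_deletion"
    else "other"
  }
  structure(list(events = events, mclass = mclass, net_frameshift = net),
            class = "classified_mutation")
}

#' @export
print.classified_mutation <- function(x, ...) {
  cat(sprintf("Classified mutation: %s (%d event%s, net frameshift %+d)\n",
              x$mclass, nrow(x$events), if (nrow(x$events) == 1) "" else "s",
              x$net_frameshift))
  invisible(x)
}

#' Score whole-gene deletions from diagnostic PCR results
#'
#' Isolates whose genomic DNA fails to template the reporter (*CAN1*) PCR
#' fragment but still produces the control (*POL2*) fragment have lost the
#' reporter to a gross chromosomal rearrangement and are classified as
#' carrying a gene deletion without sequencing. Isolates producing both
#' fragments proceed to sequencing; a failed control amplicon marks the DNA
#' preparation as invalid.
#'
#' @param can1_amplified,pol2_amplified Logical vectors (recycled).
#' @return Character vector with entries `"gcr_deletion"`,
#'   `"sequence_required"` or `"invalid_dna"`.
#' @examples
#' classify_gcr_pcr(c(FALSE, TRUE, TRUE), c(TRUE, TRUE, FALSE))
#' @export
classify_gcr_pcr <- function(can1_amplified, pol2_amplified) {
  n <- max(length(can1_amplified), length(pol2_amplified))
  can1 <- rep_len(as.logical(can1_amplified), n)
  pol2 <- rep_len(as.logical(pol2_amplified), n)
  ifelse(!pol2, "invalid_dna",
         ifelse(!can1, "gcr_deletion", "sequence_required"))
}

#' Decompose a total mutation rate into per-class rates
#'
#' Each class rate is the fraction of analyzed isolates in that class times
#' the genotype's total mutation rate. Isolates scored as gene deletions by
#' PCR enter both the denominator and the `gcr_deletion` class, mirroring the
#' PCR-then-sequence workflow.
#'
#' @param total Total mutation rate: a `rate_estimate` or a bare number.
#' @param classified List of `classified_mutation` objects (or a character
#'   vector of class labels) for the sequenced isolates.
#' @param gcr_calls Character vector of PCR calls from [classify_gcr_pcr()];
#'   only `"gcr_deletion"` entries add isolates here (the
#'   `"sequence_required"` isolates are the ones in `classified`).
#' @return An object of class `spectrum_rates`: list with `total_rate`,
#'   `n_isolates`, `class_counts` and `class_rates` (both named over all
#'   classes). Class rates sum to the total rate exactly.
#' @examples
#' spectrum_rates(480e-8, rep("base_substitution", 60),
#'                gcr_calls = rep("gcr_deletion", 40))
#' @export
spectrum_rates <- function(total, classified, gcr_calls = character()) {
  rate <- if (inherits(total, "rate_estimate")) total$rate else as.numeric(total)
  classes <- if (is.character(classified)) classified
             else vapply(classified, function(x) x$mclass, character(1))
  if (length(classes) && !all(classes %in% MUTATION_CLASSES))
    stop("unknown mutation class label")
  n_gcr <- sum(gcr_calls == "gcr_deletion")
  n <- length(classes) + n_gcr
  if (n == 0L) stop("no isolates to decompose over")
  counts <- table(factor(classes, levels = MUTATION_CLASSES))
  counts <- as.numeric(counts)
  names(counts) <- MUTATION_CLASSES
  counts["gcr_deletion"] <- counts["gcr_deletion"] + n_gcr
  structure(list(total_rate = total,
                 n_isolates = n,
                 class_counts = counts,
                 class_rates = counts / n * rate),
            class = "spectrum_rates")
}

#' @export
print.spectrum_rates <- function(x, ...) {
  rate <- if (inherits(x$total_rate, "rate_estimate")) x$total_rate$rate else x$total_rate
  cat(sprintf("Spectrum over %d isolates, total rate %.3g:\n", x$n_isolates, rate))
  keep <- x$class_counts > 0
  for (cl in names(x$class_counts)[keep])
    cat(sprintf("  %-18s %4d isolates  rate %.3g\n",
                cl, x$class_counts[[cl]], x$class_rates[[cl]]))
  invisible(x)
}

#' Check whether events revert a +1-frameshift reporter
#'
#' The *his7-2* allele reverts to *HIS7* when a net +1 frameshift is acquired
#' inside a 51-bp window containing an A7 run. The check is true when the net
#' frameshift of events inside the window is exactly +1 and events outside
#' the window cause no frameshift.
#'
#' @param events Event data frame.
#' @param window_start 1-based start of the reversion window on the reporter.
#' @param window_length Window length in bp (default 51).
#' @return `TRUE` or `FALSE`.
#' @examples
#' ev <- mutation_events("insertion", 120, "", "A")
#' his7_reversion_check(ev, window_start = 100)
#' @export
his7_reversion_check <- function(events, window_start, window_length = 51) {
  if (!is.data.frame(events)) stop("'events' must be an event data frame")
  if (nrow(events) == 0L) return(FALSE)
  shift <- ifelse(events$kind == "insertion", events$length,
           ifelse(events$kind == "deletion", -events$length, 0L))
  inside <- events$position >= window_start &
    events$position <= window_start + window_length - 1L
  sum(shift[inside]) == 1L && sum(shift[!inside]) == 0L
}

#' Find a direct repeat at the junctions of a deletion
#'
#' Medium-size deletions often arise between direct repeats: the reference
#' carries two copies of a short sequence, one overlapping the 5' breakpoint
#' and one overlapping the 3' breakpoint, and the deletion removes one copy
#' together with the intervening DNA. The scan considers every window pair
#' `(i, i + L)` (`L` the deletion length) whose left copy overlaps or abuts
#' the 5' junction, allowing up to `max_mismatches` mismatches, and returns
#' the maximal-length hit (ties broken by fewer mismatches, then by the
#' 5'-most left copy), or `NULL` when the best hit is shorter than `min_len`.
#'
#' @param reference Reference DNA string.
#' @param deletion A single-row deletion event (data frame row or list with
#'   `kind`, `position`, `length`).
#' @param min_len Minimum repeat length to report (default 4).
#' @param max_mismatches Maximum mismatches tolerated between the two copies
#'   (default 1; a hit with 0 mismatches is a perfect repeat).
#' @param max_len Longest repeat length scanned (default 50).
#' @return An object of class `repeat_junction` (list with the deletion, the
#'   two copy sequences, their start coordinates, `repeat_length`,
#'   `mismatches` and `is_perfect`), or `NULL`.
#' @examples
#' ref <- paste0("AAATTTGG", "GCGCGTAC", "TTACGGACTT", "GCGCGTAC", "CCATG")
#' del <- mutation_events("deletion", 9, substr(ref, 9, 26), "")
#' find_junction_repeats(ref, del, min_len = 6)
#' @export
find_junction_repeats <- function(reference, deletion, min_len = 4,
                                  max_mismatches = 1, max_len = 50) {
  check_dna(reference, "reference")
  if (is.data.frame(deletion)) {
    if (nrow(deletion) != 1L) stop("'deletion' must be a single event")
    deletion <- as.list(deletion)
  }
  if (!identical(deletion$kind, "deletion")) stop("event is not a deletion")
  p <- as.integer(deletion$position)
  L <- as.integer(deletion$length)
  n <- nchar(reference)
  if (p < 1L || L < 1L || p + L - 1L > n)
    stop("deletion coordinates fall outside the reference")
  rc <- strsplit(reference, "", fixed = TRUE)[[1]]
  best <- NULL
  for (len in seq(min_len, max_len)) {
    # left copy must overlap/abut the junction between p-1 and p
    for (i in seq(max(1L, p - len), p)) {
      j <- i + L
      if (j + len - 1L > n) next
      mism <- sum(rc[i:(i + len - 1L)] != rc[j:(j + len - 1L)])
      if (mism > max_mismatches) next
      if (is.null(best) || len > best$repeat_length ||
          (len == best$repeat_length &&
           (mism < best$mismatches ||
            (mism == best$mismatches && i < best$left_start)))) {
        best <- list(repeat_length = len, mismatches = mism,
                     left_start = i, right_start = j)
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(
    deletion = deletion,
    repeat_seq_left = paste(rc[best$left_start:(best$left_start + best$repeat_length - 1L)],
                            collapse = ""),
    repeat_seq_right = paste(rc[best$right_start:(best$right_start + best$repeat_length - 1L)],
                             collapse = ""),
    left_start = best$left_start, right_start = best$right_start,
    repeat_length = best$repeat_length, mismatches = best$mismatches,
    is_perfect = best$mismatches == 0L
  ), class = "repeat_junction")
}

#' @export
print.repeat_junction <- function(x, ...) {
  cat(sprintf("Junction repeat: %d bp (%s), %d mismatch%s\n  5' copy %s at %d, 3' copy %s at %d\n",
              x$repeat_length, if (x$is_perfect) "perfect" else "nearly perfect",
              x$mismatches, if (x$mismatches == 1) "" else "es",
              x$repeat_seq_left, x$left_start, x$repeat_seq_right, x$right_start))
  invisible(x)
}
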