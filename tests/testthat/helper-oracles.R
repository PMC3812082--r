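# Independent oracle implementations used to compute expected values.
# These deliberately share no code with the package internals.

# Luria-Delbruck recursion evaluated with plain accumulation loops.
oracle_ld_pmf <- function(m, r_max) {
  p <- numeric(r_max + 1)
  p[1] <- exp(-m)
  if (r_max > 0) {
    for (r in 1:r_max) {
      acc <- 0
      for (i in 0:(r - 1)) acc <- acc + p[i + 1] / (r - i + 1)
      p[r + 1] <- m / r * acc
    }
  }
  p
}

# Drake's implicit relation solved with stats::uniroot.
oracle_drake <- function(r, N) {
  f <- r / N
  g <- function(mu) mu * log(N * mu) - f
  hi <- f
  while (g(hi) < 0) hi <- hi * 2
  stats::uniroot(g, c(1 / (exp(1) * N) * (1 + 1e-12), hi),
                 tol = f * 1e-15)$root
}

# Exact two-sided rank-sum p-value by enumeration of group assignments
# (midranks used, so tied data enumerate over tied rankings).
oracle_rank_sum_exact <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  rk <- rank(x)
  w_obs <- sum(rk[seq_len(na)])
  idx <- utils::combn(length(x), na)
  ws <- apply(idx, 2, function(i) sum(rk[i]))
  p <- 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9))
  min(p, 1)
}

# Exhaustive search for the longest direct repeat consistent with a deletion
# of length L starting at p: copies at i and i + L, the left copy overlapping
# or abutting the 5' junction, mismatches counted base by base.
oracle_junction_repeat <- function(reference, p, L, min_len = 4,
                                   max_mismatches = 1, max_len = 50) {
  rc <- strsplit(reference, "", fixed = TRUE)[[1]]
  n <- length(rc)
  best <- NULL
  for (len in max_len:min_len) {
    for (i in 1:n) {
      if (i > p || i + len < p) next      # must overlap/abut the 5' junction
      j <- i + L
      if (i + len - 1 > n || j + len - 1 > n) next
      mm <- sum(rc[i:(i + len - 1)] != rc[j:(j + len - 1)])
      if (mm > max_mismatches) next
      if (is.null(best) ||
          len > best$len ||
          (len == best$len && (mm < best$mm || (mm == best$mm && i < best$i))))
        best <- list(len = len, mm = mm, i = i)
    }
  }
  best
}

# Build a reference that carries an exact direct repeat of length `rep_len`
# flanking a deletable segment of length `del_len` (repeat copies at
# `at` and `at + del_len`).
make_repeat_reference <- function(total_len, at, del_len, rep_len,
                                  mismatch_at = NA) {
  stopifnot(at + del_len + rep_len - 1 <= total_len)
  x <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  rep_seq <- sample(c("A", "C", "G", "T"), rep_len, replace = TRUE)
  x[at:(at + rep_len - 1)] <- rep_seq
  x[(at + del_len):(at + del_len + rep_len - 1)] <- rep_seq
  if (!is.na(mismatch_at)) {
    pos <- at + del_len + mismatch_at - 1
    x[pos] <- sample(setdiff(c("A", "C", "G", "T"), x[pos]), 1)
  }
  paste(x, collapse = "")
}
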