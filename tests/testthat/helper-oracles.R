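# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (exhaustive enumeration, direct summation) and share no
# code with the implementation they check.

# Exhaustive best segmentation: maximises the sum of strictly positive window
# qualities over all sets of disjoint intervals. q is an n x n matrix of
# window qualities (1-based inclusive indices).
brute_best_partition <- function(q) {
  n <- nrow(q)
  memo <- rep(NA_real_, n + 1)
  memo[n + 1] <- 0
  best_from <- function(pos) {
    if (!is.na(memo[pos])) return(memo[pos])
    best <- best_from(pos + 1)                     # bin pos left free
    for (e in pos:n) {
      if (!is.na(q[pos, e]) && q[pos, e] > 0) {
        cand <- q[pos, e] + best_from(e + 1)
        if (cand > best) best <- cand
      }
    }
    memo[pos] <<- best
    best
  }
  best_from(1)
}

# Direct per-diagonal means of a masked symmetric matrix.
brute_diag_means <- function(m, mask = rep(FALSE, nrow(m))) {
  n <- nrow(m)
  sapply(0:(n - 1), function(s) {
    vals <- c()
    for (i in seq_len(n - s)) {
      j <- i + s
      if (!mask[i] && !mask[j]) vals <- c(vals, m[i, j])
    }
    if (length(vals)) mean(vals) else NA_real_
  })
}

# Direct mean over unordered pairs of the given 1-based bin indices.
brute_pair_mean <- function(m, bins) {
  vals <- c()
  for (a in seq_along(bins)) {
    for (b in seq_along(bins)) {
      if (a < b) vals <- c(vals, m[bins[a], bins[b]])
    }
  }
  mean(vals)
}

# Random symmetric non-negative matrix.
random_sym_matrix <- function(n, rate = 1) {
  m <- matrix(rexp(n * n, rate), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Boundary-recovery F1 between truth and called TAD tables (start_bin /
# end_bin columns), with a +-tol bin match window.
boundary_f1 <- function(truth, called, tol = 1) {
  tb <- sort(unique(c(truth$start_bin, truth$end_bin)))
  cb <- sort(unique(c(called$start_bin, called$end_bin)))
  if (!length(cb) || !length(tb)) return(0)
  prec <- mean(sapply(cb, function(b) any(abs(tb - b) <= tol)))
  rec <- mean(sapply(tb, function(b) any(abs(cb - b) <= tol)))
  2 * prec * rec / (prec + rec)
}

# Small planted-TAD contact map: two dense blocks on a noisy background.
two_block_map <- function() {
  m <- matrix(1, 10, 10)
  m[1:5, 1:5] <- 5
  m[6:10, 6:10] <- 5
  diag(m) <- 0
  contact_map(m, bin_size = 20000L, arm_id = "toy")
}
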