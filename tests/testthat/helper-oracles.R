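# Independent reference implementations used as oracles.  These are written
# as plain enumeration loops, deliberately sharing no code with the package.

# Brute-force convolution with edge replication (same contract as
# smooth_region, computed position by position).
oracle_convolve <- function(x, taps) {
  h <- (length(taps) - 1) / 2
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(taps)) acc <- acc + taps[k] * xp[i + k - 1]
    out[i] <- acc
  }
  out
}

# Exhaustive ascend/descend pairing reference: at every step the maximal
# positive derivative is found by a full scan, all admissible descending
# partners are enumerated by a full scan, and the interval splits; FIFO
# processing (the package recurses), results sorted at the end.
oracle_pair_peaks <- function(smoothed, min_len = 20, max_len = 500) {
  n <- length(smoothed)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  d <- smoothed[-1] - smoothed[-n]
  out_start <- integer(0); out_end <- integer(0)
  queue <- list(c(1L, length(d)))
  qi <- 1L
  while (qi <= length(queue)) {
    lo <- queue[[qi]][1]; hi <- queue[[qi]][2]; qi <- qi + 1L
    if (hi < lo) next
    a <- 0L; besta <- 0
    for (k in lo:hi) if (d[k] > besta) { besta <- d[k]; a <- k }
    if (a == 0L) next
    b <- 0L; bestb <- 0
    for (j in lo:hi) {
      len <- j - a + 1L
      if (j > a && d[j] < 0 && len >= min_len && len <= max_len &&
          d[j] < bestb) {
        bestb <- d[j]; b <- j
      }
    }
    if (b == 0L) {
      queue[[length(queue) + 1L]] <- c(lo, a - 1L)
      queue[[length(queue) + 1L]] <- c(a + 1L, hi)
    } else {
      out_start <- c(out_start, a - 1L); out_end <- c(out_end, b)
      queue[[length(queue) + 1L]] <- c(lo, a - 1L)
      queue[[length(queue) + 1L]] <- c(b + 1L, hi)
    }
  }
  o <- order(out_start)
  data.frame(start = out_start[o], end = out_end[o])
}

# Two-sided exact Poisson p by direct probability-mass enumeration
# (minimum-likelihood method: total mass of outcomes no more likely than
# the observation, with the customary floating-point tie guard).
oracle_poisson_p <- function(k, lambda) {
  if (lambda == 0) return(as.numeric(k == 0))
  kmax <- max(k, ceiling(lambda + 20 * sqrt(lambda) + 30))
  masses <- dpois(0:kmax, lambda)
  min(1, sum(masses[masses <= dpois(k, lambda) * (1 + 1e-07)]))
}

# Two-sided exact binomial p by direct mass enumeration (the conditional
# form of the two-sample Poisson rate test).
oracle_binom_p <- function(x, n, p) {
  masses <- dbinom(0:n, n, p)
  min(1, sum(masses[masses <= dbinom(x, n, p) * (1 + 1e-07)]))
}

# Recall/false-call bookkeeping against planted truth.
match_truth <- function(peaks, truth, tol = 10) {
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    any(peaks$chrom == truth$chrom[i] & peaks$strand == truth$strand[i] &
        abs(peaks$start - truth$start[i]) <= tol &
        abs(peaks$end - truth$end[i]) <= tol)
  }, TRUE)
  spurious <- vapply(seq_len(nrow(peaks)), function(j) {
    !any(truth$chrom == peaks$chrom[j] & truth$strand == peaks$strand[j] &
         truth$start < peaks$end[j] & truth$end > peaks$start[j])
  }, TRUE)
  list(recall = mean(recalled), false_calls = sum(spurious))
}
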