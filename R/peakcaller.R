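# SELEX peak calling: filtered mate pairs -> fragment coverage -> candidate
# regions -> Gaussian smoothing -> first derivative -> paired maximal
# ascending/descending positions.

#' Filter mate pairs on span and chromosome concordance
#'
#' Keeps pairs whose mates map to the same chromosome with a 5'-end distance
#' of `min_span` to `max_span` bases, bounds inclusive.
#'
#' @param pairs mate pairs from [read_bedpe()] or [simulate_selex()].
#' @param min_span,max_span inclusive distance bounds (nt).
#' @return list with `kept` (the surviving pairs) and `stats` (counts removed
#'   per reason).
#' @export
filter_mate_pairs <- function(pairs, min_span = 20, max_span = 500) {
  cross <- if ("cross_chromosome" %in% names(pairs)) pairs$cross_chromosome
           else logical(nrow(pairs))
  span <- abs(pairs$end5_b - pairs$end5_a)
  short <- !cross & span < min_span
  long <- !cross & span > max_span
  keep <- !cross & !short & !long
  list(
    kept = pairs[keep, , drop = FALSE],
    stats = list(
      input = nrow(pairs),
      kept = sum(keep),
      cross_chromosome = sum(cross),
      span_too_short = sum(short),
      span_too_long = sum(long)
    )
  )
}

#' Per-base fragment coverage from filtered mate pairs
#'
#' Each pair contributes +1 to every base between its 5' ends, both ends
#' included (`span + 1` bases), on the pair's strand track.
#'
#' @param pairs filtered mate pairs.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param unstranded pool both strands onto a single unstranded track.
#' @return a [coverage_track()] of kind `fragment_coverage`.
#' @export
fragment_coverage <- function(pairs, chrom_sizes, unstranded = FALSE) {
  validate_chrom_sizes(chrom_sizes)
  strands <- if (unstranded) "*" else c("+", "-")
  track <- coverage_track(chrom_sizes, strands = strands,
                          signal_kind = "fragment_coverage")
  if (nrow(pairs) == 0) return(track)
  lo <- pmin(pairs$end5_a, pairs$end5_b)
  hi <- pmax(pairs$end5_a, pairs$end5_b)
  if (any(lo < 0) || any(hi >= chrom_sizes[pairs$chrom])) {
    stop("mate-pair coordinate beyond chromosome length")
  }
  st <- if (unstranded) rep("*", nrow(pairs)) else
    ifelse(pairs$strand == "-", "-", "+")
  for (ch in unique(pairs$chrom)) {
    n <- as.integer(chrom_sizes[[ch]])
    for (s in strands) {
      i <- which(pairs$chrom == ch & st == s)
      if (!length(i)) next
      # difference-array accumulation over [lo, hi] inclusive
      add <- tabulate(lo[i] + 1L, nbins = n + 1L)
      rem <- tabulate(hi[i] + 2L, nbins = n + 1L)
      track$data[[ch]][[s]] <- cumsum(add - rem)[seq_len(n)]
    }
  }
  track
}

#' Maximal runs of coverage at or above a threshold
#'
#' @param track a fragment-coverage track.
#' @param min_cov per-base read-count threshold (the run rule is
#'   `coverage >= min_cov`).
#' @return interval data frame of candidate regions (chrom, start, end,
#'   strand).
#' @export
find_candidate_regions <- function(track, min_cov = 5) {
  out <- list()
  for (ch in names(track$chrom_sizes)) {
    for (s in track$strands) {
      v <- track$data[[ch]][[s]]
      r <- rle(v >= min_cov)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = starts[keep], end = ends[keep], strand = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  do.call(rbind, out)
}

#' Discrete Gaussian smoothing kernel
#'
#' `w` taps proportional to `exp(-(i - (w-1)/2)^2 / (2 sigma^2))`,
#' normalised to sum 1.
#'
#' @param w odd number of taps.
#' @param sigma spread in bases.
#' @return list with `w`, `sigma` and the normalised `taps`.
#' @export
make_kernel <- function(w = 5, sigma = 1.0) {
  stopifnot(w >= 1, w %% 2 == 1, sigma > 0)
  off <- seq_len(w) - 1 - (w - 1) / 2
  taps <- exp(-off^2 / (2 * sigma^2))
  structure(list(w = as.integer(w), sigma = sigma, taps = taps / sum(taps)),
            class = "gaussian_kernel")
}

# valid-part convolution: length(x) - w + 1 values
conv_valid <- function(x, taps) {
  w <- length(taps)
  if (length(x) < w) stop("signal shorter than kernel")
  out <- numeric(length(x) - w + 1)
  for (k in seq_len(w)) {
    out <- out + taps[k] * x[k:(k + length(out) - 1)]
  }
  out
}

#' Smooth a signal with a Gaussian kernel (edge replication)
#'
#' Returns a vector of the same length as the input; boundaries are handled
#' by replicating the edge values.  When a region has been extracted with
#' true flanking coverage, smooth the extended vector and trim instead.
#'
#' @param x raw signal vector.
#' @param kernel a [make_kernel()] kernel.
#' @return smoothed vector, same length as `x`.
#' @export
smooth_region <- function(x, kernel) {
  h <- (kernel$w - 1) / 2
  if (h == 0) return(as.numeric(x))
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  conv_valid(xp, kernel$taps)
}

#' First derivative of a smoothed signal
#'
#' `d[i] = s[i+1] - s[i]`; the sum telescopes to `s[last] - s[first]`.
#'
#' @param s smoothed signal.
#' @return difference vector of length `length(s) - 1`.
#' @export
derivative <- function(s) {
  diff(s)
}

# Core pairing on a derivative vector.  Returns a matrix of 1-based
# derivative indices (ascend a, descend b); the peak occupies local 0-based
# offsets [a-1, b), i.e. length b - a + 1.
#
# Rules: the globally maximal positive derivative anchors a peak; it is
# paired with the most negative derivative after it within the length
# window; ties break leftmost; an anchor with no admissible partner is
# discarded; the interval then splits and both sides are processed the same
# way.  Implemented with an explicit worklist (candidate regions can span a
# whole chromosome).
pair_peaks_core <- function(d, min_len, max_len) {
  res_a <- integer(0); res_b <- integer(0)
  if (!length(d)) return(cbind(a = res_a, b = res_b))
  work <- list(c(1L, length(d)))
  while (length(work)) {
    iv <- work[[length(work)]]
    work[[length(work)]] <- NULL
    lo <- iv[1]; hi <- iv[2]
    if (hi < lo) next
    seg <- d[lo:hi]
    a <- lo + which.max(seg) - 1L
    if (d[a] <= 0) next
    b_lo <- a + min_len - 1L
    b_hi <- min(hi, a + max_len - 1L)
    b <- NA_integer_
    if (b_lo <= b_hi) {
      cand <- b_lo:b_hi
      cand <- cand[d[cand] < 0]
      if (length(cand)) b <- cand[which.min(d[cand])]
    }
    if (is.na(b)) {
      work <- c(work, list(c(lo, a - 1L)), list(c(a + 1L, hi)))
    } else {
      res_a <- c(res_a, a); res_b <- c(res_b, b)
      work <- c(work, list(c(lo, a - 1L)), list(c(b + 1L, hi)))
    }
  }
  o <- order(res_a)
  cbind(a = res_a[o], b = res_b[o])
}

#' Pair maximal ascending and descending positions in a smoothed region
#'
#' Detects peaks on the first derivative of the smoothed signal: each peak
#' runs from a maximal ascending position (derivative > 0) to a maximal
#' descending position (derivative < 0), with a length of `min_len` to
#' `max_len` bases, bounds inclusive.
#'
#' @param smoothed smoothed signal of a candidate region.
#' @param min_len,max_len inclusive peak length bounds (nt).
#' @return data frame with 0-based region-local `start`, `end`, and the
#'   derivative values `max_ascend` / `max_descend` at the boundaries.
#' @export
pair_peaks <- function(smoothed, min_len = 20, max_len = 500) {
  if (length(smoothed) < 2) {
    return(data.frame(start = integer(), end = integer(),
                      max_ascend = numeric(), max_descend = numeric()))
  }
  d <- derivative(smoothed)
  ab <- pair_peaks_core(d, min_len, max_len)
  data.frame(start = ab[, "a"] - 1L, end = ab[, "b"],
             max_ascend = d[ab[, "a"]], max_descend = d[ab[, "b"]])
}

#' Call RAP peaks from SELEX mate pairs
#'
#' Full peak-calling pipeline: span/chromosome filtering, per-base fragment
#' coverage, candidate regions of coverage at least `min_region_coverage`,
#' Gaussian smoothing (with true flanking coverage at the region edges),
#' first-derivative peak pairing, and annotation of each peak with its raw
#' peak coverage and fragment support.
#'
#' @param pairs mate pairs (unfiltered).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param config a [rap_config()].
#' @param unstranded pool both strands before calling.
#' @return data frame of RAP peaks sorted by (chrom, start, strand), with
#'   attribute `stats` (filter and call counts).
#' @export
call_raps <- function(pairs, chrom_sizes, config = rap_config(),
                      unstranded = FALSE) {
  filt <- filter_mate_pairs(pairs, config$min_span, config$max_span)
  track <- fragment_coverage(filt$kept, chrom_sizes, unstranded = unstranded)
  regions <- find_candidate_regions(track, config$min_region_coverage)
  kern <- make_kernel(config$kernel_window, config$kernel_sigma)
  h <- (kern$w - 1) / 2

  kept <- filt$kept
  lo <- pmin(kept$end5_a, kept$end5_b)
  hi <- pmax(kept$end5_a, kept$end5_b)
  kst <- if (unstranded) rep("*", nrow(kept)) else
    ifelse(kept$strand == "-", "-", "+")

  out <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]; s <- regions$strand[i]
    rs <- regions$start[i]; re <- regions$end[i]
    n <- as.integer(chrom_sizes[[ch]])
    cov <- track$data[[ch]][[s]]
    if (h > 0) {
      idx <- (rs - h):(re - 1L + h)
      idx <- pmin(pmax(idx, 0L), n - 1L)     # edge replication at chromosome ends
      sm <- conv_valid(cov[idx + 1L], kern$taps)
    } else {
      sm <- cov[(rs + 1L):re]
    }
    pk <- pair_peaks(sm, config$min_peak_len, config$max_peak_len)
    if (!nrow(pk)) next
    gstart <- rs + pk$start
    gend <- rs + pk$end
    peak_cov <- vapply(seq_len(nrow(pk)), function(j) {
      max(cov[(gstart[j] + 1L):gend[j]])
    }, 0)
    fi <- which(kept$chrom == ch & kst == s)
    support <- if (length(fi)) {
      IRanges::countOverlaps(
        IRanges::IRanges(gstart + 1L, gend),
        IRanges::IRanges(lo[fi] + 1L, hi[fi] + 1L))
    } else rep(0L, nrow(pk))
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = gstart, end = gend, strand = s,
      max_ascend = pk$max_ascend, max_descend = pk$max_descend,
      peak_coverage = peak_cov, support_reads = as.integer(support),
      stringsAsFactors = FALSE)
  }
  peaks <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), max_ascend = numeric(),
               max_descend = numeric(), peak_coverage = numeric(),
               support_reads = integer(), stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$strand), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$name <- sprintf("RAP%04d", seq_len(nrow(peaks)))
  attr(peaks, "stats") <- c(filt$stats, list(
    candidate_regions = nrow(regions), peaks_called = nrow(peaks)))
  peaks
}

#' Genome-wide coverage threshold for a Poisson background
#'
#' The candidate-region threshold must sit above the background coverage
#' band.  Given a background mean per-base coverage, this returns the
#' smallest threshold at which the expected number of background bases
#' reaching it, over the whole searched space, is at most
#' `expected_false_bases` (a Bonferroni-style genome-wide bound).
#'
#' @param lambda background mean coverage per base (e.g. the median track
#'   value, robust to a small enriched fraction).
#' @param n_bases number of strand-bases searched.
#' @param expected_false_bases tolerated expected count of background bases
#'   at or above the threshold.
#' @return integer threshold.
#' @export
background_min_cov <- function(lambda, n_bases, expected_false_bases = 0.05) {
  stopifnot(lambda >= 0, n_bases > 0, expected_false_bases > 0)
  t <- stats::qpois(1 - expected_false_bases / n_bases, lambda)
  while (n_bases * stats::ppois(t - 1, lambda, lower.tail = FALSE) >
         expected_false_bases) {
    t <- t + 1L
  }
  as.integer(max(t, 1))
}
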