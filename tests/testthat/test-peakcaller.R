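test_that("mate-pair filter enforces inclusive span bounds per removal reason", {
  pairs <- data.frame(
    chrom = "chrI",
    end5_a = c(100L, 100L, 100L, 100L, 100L),
    end5_b = c(700L, 120L, 600L, 119L, 500L),
    strand = "+", name = sprintf("p%d", 1:5),
    cross_chromosome = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  res <- filter_mate_pairs(pairs, min_span = 20, max_span = 500)
  expect_equal(res$kept$name, c("p2", "p3"))     # spans 20 and 500: inclusive
  expect_equal(res$stats$span_too_long, 1L)      # span 600
  expect_equal(res$stats$span_too_short, 1L)     # span 19
  expect_equal(res$stats$cross_chromosome, 1L)
  # span exactly 500 is kept, 501 is not
  p2 <- data.frame(chrom = "chrI", end5_a = 0L, end5_b = c(500L, 501L),
                   strand = "+", name = c("a", "b"),
                   cross_chromosome = FALSE, stringsAsFactors = FALSE)
  r2 <- filter_mate_pairs(p2)
  expect_equal(r2$kept$name, "a")
  expect_equal(filter_mate_pairs(pairs[0, ])$stats$input, 0L)
})

test_that("fragment coverage fills both 5' ends inclusive and conserves mass", {
  sizes <- c(chrI = 100)
  one <- data.frame(chrom = "chrI", end5_a = 10L, end5_b = 30L, strand = "+",
                    name = "a", cross_chromosome = FALSE)
  tr <- fragment_coverage(one, sizes)
  v <- tr$data$chrI[["+"]]
  expect_equal(which(v == 1) - 1L, 10:30)
  expect_true(all(v[-(11:31)] == 0))

  two <- rbind(one, one)
  expect_equal(max(fragment_coverage(two, sizes)$data$chrI[["+"]]), 2)

  set.seed(5)
  n <- 1000
  sizes2 <- c(chrI = 5000, chrII = 4000)
  start <- sample(0:3000, n, TRUE)
  span <- sample(20:500, n, TRUE)
  rnd <- data.frame(chrom = sample(names(sizes2), n, TRUE),
                    end5_a = start, end5_b = start + span,
                    strand = sample(c("+", "-"), n, TRUE),
                    name = as.character(1:n), cross_chromosome = FALSE)
  trk <- fragment_coverage(rnd, sizes2)
  expect_equal(sum(track_values(trk)), sum(span + 1))

  out <- data.frame(chrom = "chrI", end5_a = 4990L, end5_b = 5005L,
                    strand = "+", name = "x", cross_chromosome = FALSE)
  expect_error(fragment_coverage(out, sizes2), "beyond chromosome")
})

test_that("candidate regions are maximal runs at or above the threshold", {
  tr <- make_track(c(0, 0, 6, 7, 5, 4, 9, 0))
  reg <- find_candidate_regions(tr, 5)
  expect_equal(reg$start, c(2L, 6L))
  expect_equal(reg$end, c(5L, 7L))

  expect_equal(nrow(find_candidate_regions(make_track(rep(0, 50)), 5)), 0L)

  whole <- find_candidate_regions(make_track(rep(5, 1000)), 5)
  expect_equal(whole$start, 0L)
  expect_equal(whole$end, 1000L)
})

test_that("Gaussian kernel matches the evaluated density and normalises", {
  k <- make_kernel(5, 1)
  ref <- exp(-(-2:2)^2 / 2); ref <- ref / sum(ref)
  expect_equal(k$taps, ref, tolerance = 1e-12)
  expect_equal(round(k$taps, 4), c(0.0545, 0.2442, 0.4026, 0.2442, 0.0545))
  for (w in c(1, 3, 7, 11)) {
    kk <- make_kernel(w, runif(1, 0.5, 3))
    expect_equal(sum(kk$taps), 1, tolerance = 1e-12)
    expect_equal(kk$taps, rev(kk$taps))
  }
  expect_equal(make_kernel(1)$taps, 1)
  expect_error(make_kernel(4), "w")
})

test_that("smoothing preserves constants, reproduces the impulse response, and matches brute force", {
  k <- make_kernel(5, 1)
  expect_equal(smooth_region(rep(5, 5), k), rep(5, 5))

  x <- numeric(41); x[21] <- 1
  expect_equal(smooth_region(x, k)[19:23], k$taps, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    y <- rpois(50, 8)
    kk <- make_kernel(sample(c(3, 5, 9), 1), runif(1, 0.5, 2))
    expect_equal(smooth_region(y, kk), oracle_convolve(y, kk$taps),
                 tolerance = 1e-12)
  }
  expect_equal(smooth_region(c(2, 9, 4), make_kernel(1)), c(2, 9, 4))
})

test_that("derivative is the forward difference and telescopes", {
  expect_equal(derivative(rep(3, 10)), rep(0, 9))
  expect_equal(derivative(0:9), rep(1, 9))
  set.seed(3)
  s <- cumsum(rnorm(100))
  d <- derivative(s)
  expect_length(d, 99)
  expect_equal(sum(d), s[100] - s[1], tolerance = 1e-12)
})

test_that("peak pairing finds the trapezoid and respects length bounds", {
  k <- make_kernel(5, 1)
  cov <- c(rep(0, 100), seq(0, 20, length.out = 6), rep(20, 40),
           seq(20, 0, length.out = 6), rep(0, 100))
  pk <- pair_peaks(smooth_region(cov, k))
  expect_equal(nrow(pk), 1L)
  expect_true(abs(pk$start - 102) <= 3)
  expect_true(abs((pk$end - pk$start) - 45) <= 5)
  expect_gt(pk$max_ascend, 0)
  expect_lt(pk$max_descend, 0)

  # flat plateau: no positive derivative, no peaks
  expect_equal(nrow(pair_peaks(smooth_region(rep(7, 200), k))), 0L)

  # rise and fall 600 nt apart exceed the maximal peak length
  far <- c(rep(0, 20), rep(20, 600), rep(0, 20))
  expect_equal(nrow(pair_peaks(smooth_region(far, k), 20, 500)), 0L)
  # but the same shape passes with a 100 nt plateau
  near <- c(rep(0, 20), rep(20, 100), rep(0, 20))
  expect_equal(nrow(pair_peaks(smooth_region(near, k), 20, 500)), 1L)
})

test_that("peak pairing equals the exhaustive reference on random signals", {
  boundaries <- function(pk) {
    rownames(pk) <- NULL
    pk[c("start", "end")]
  }
  set.seed(101)
  for (i in 1:30) {
    n <- sample(60:400, 1)
    sm <- smooth_region(sample(0:20, n, TRUE), make_kernel(5, 1))
    expect_equal(boundaries(pair_peaks(sm, 20, 500)),
                 oracle_pair_peaks(sm, 20, 500))
  }
  # shorter admissible lengths exercise the discard-and-split branch harder
  for (i in 1:20) {
    sm <- smooth_region(sample(0:6, 150, TRUE), make_kernel(3, 0.8))
    expect_equal(boundaries(pair_peaks(sm, 5, 60)),
                 oracle_pair_peaks(sm, 5, 60))
  }
})

test_that("call_raps is deterministic, sorted, and annotates support", {
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 100000),
                       seed = 31)
  truth <- plant_raps(g, n_raps = 6, fold = 20, host_min_len = 1800, seed = 32)
  pairs <- simulate_selex(g, truth, n_pairs = 30000, seed = 33)
  cfg <- rap_config(min_region_coverage = background_min_cov(
    stats::median(track_values(fragment_coverage(
      filter_mate_pairs(pairs)$kept, g$chrom_sizes))),
    2 * sum(g$chrom_sizes)))
  p1 <- call_raps(pairs, g$chrom_sizes, cfg)
  p2 <- call_raps(pairs, g$chrom_sizes, cfg)
  expect_identical(p1, p2)
  expect_false(is.unsorted(order(p1$chrom, p1$start)))
  expect_true(all(p1$support_reads > 0))
  expect_true(all(p1$end - p1$start >= cfg$min_peak_len))
  expect_true(all(p1$end - p1$start <= cfg$max_peak_len))
  expect_true(all(p1$max_ascend > 0 & p1$max_descend < 0))
  expect_true(all(p1$peak_coverage >= cfg$min_region_coverage))

  empty <- call_raps(pairs[0, ], g$chrom_sizes, cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("planted-RAP recall never decreases with enrichment fold", {
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 1, chrom_length = 200000),
                       seed = 51)
  recalls <- sapply(c(2, 5, 10, 20), function(fold) {
    truth <- plant_raps(g, n_raps = 10, fold = fold, host_min_len = 1800,
                        seed = 52)
    pairs <- simulate_selex(g, truth, n_pairs = 60000, seed = 53)
    lam <- stats::median(track_values(fragment_coverage(
      filter_mate_pairs(pairs)$kept, g$chrom_sizes)))
    cfg <- rap_config(min_region_coverage = background_min_cov(
      lam, 2 * sum(g$chrom_sizes)))
    peaks <- call_raps(pairs, g$chrom_sizes, cfg)
    match_truth(peaks, truth, tol = 10)$recall
  })
  expect_true(all(diff(recalls) >= 0))
  expect_gte(recalls[4], 0.9)
})

test_that("background threshold tracks the Poisson tail bound", {
  t <- background_min_cov(20, 2e6, 0.05)
  expect_lte(2e6 * ppois(t - 1, 20, lower.tail = FALSE), 0.05)
  expect_gt(2e6 * ppois(t - 2, 20, lower.tail = FALSE), 0.05)
  expect_gte(background_min_cov(0, 1000), 1L)
})
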