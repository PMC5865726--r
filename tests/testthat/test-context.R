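test_that("RAP context classification partitions sense/antisense/intergenic", {
  genes <- gene_features(tiny_features())
  raps <- rbind(
    rap_row("chrI", 1200, 1300, "+", "sense_in_plus_gene"),
    rap_row("chrI", 4200, 4300, "+", "antisense_over_minus_gene"),
    rap_row("chrI", 6000, 6100, "+", "desert"),
    rap_row("chrI", 2499, 2600, "-", "one_base_antisense"))
  cl <- classify_raps(raps, genes)
  expect_equal(cl$classes, c("sense", "antisense", "intergenic", "antisense"))
  expect_equal(sum(cl$fractions), 1, tolerance = 1e-12)

  expect_warning(classify_raps(rap_row("chrI", 1200, 1300, "*"), genes),
                 "unstranded")
})

test_that("genome class background reflects strand-position space", {
  full <- gene_row("chrI", 0, 1000, "+")
  bg <- genome_class_background(full, c(chrI = 1000))
  expect_equal(unname(bg), c(0.5, 0.5, 0), tolerance = 1e-12)

  empty <- full[0, ]
  expect_equal(genome_class_background(empty, c(chrI = 1000))[["intergenic"]], 1)

  set.seed(9)
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 50000),
                       seed = 9)
  bg2 <- genome_class_background(gene_features(g$features), g$chrom_sizes)
  expect_equal(sum(bg2), 1, tolerance = 1e-12)
  expect_true(all(bg2 >= 0))
})

test_that("feature-class overlap counting assigns by a single base and counts RAPs", {
  feats <- tiny_features()
  raps <- rbind(
    rap_row("chrI", 2800, 2901, "+", "touch_trna_one_base"),
    rap_row("chrI", 9000, 9100, "+", "nothing"),
    rap_row("chrI", 2910, 2960, "+", "in_trna_a"),
    rap_row("chrI", 2950, 2995, "+", "in_trna_b"))
  counts <- count_feature_overlaps(raps, feats, tiny_sizes)
  expect_equal(counts[["tRNA"]], 3L)
  expect_equal(counts[["snoRNA"]], 2L)
  expect_equal(counts[["ORF"]], 0L)
  # a RAP overlapping nothing contributes to no class
  expect_equal(sum(count_feature_overlaps(raps[2, ], feats, tiny_sizes)), 0L)
})

test_that("strand-aware telomeric counting mirrors the CA-strand asymmetry", {
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 50000),
                       seed = 15)
  tel <- g$features[g$features$feature_class == "telomeric_repeat", ]
  # plant RAPs on the silent CA-rich strand of each telomeric repeat
  ca <- data.frame(chrom = tel$chrom, start = tel$start + 50,
                   end = tel$start + 150, strand = tel$strand,
                   name = paste0("ca", seq_len(nrow(tel))),
                   stringsAsFactors = FALSE)
  gu <- ca; gu$strand <- ifelse(ca$strand == "+", "-", "+")
  n_ca <- count_feature_overlaps(ca, g$features, g$chrom_sizes,
                                 classes = "telomeric_repeat",
                                 same_strand = TRUE)
  n_gu <- count_feature_overlaps(gu, g$features, g$chrom_sizes,
                                 classes = "telomeric_repeat",
                                 same_strand = TRUE)
  expect_equal(unname(n_ca), nrow(tel))
  expect_equal(unname(n_gu), 0L)
})

test_that("randomized placement preserves lengths, seeds, and uniformity", {
  raps <- rap_row("chrI", c(100, 900, 5000), c(400, 1100, 5050), "+",
                  c("a", "b", "c"))
  sizes <- c(chrI = 10000, chrII = 4000)
  r1 <- randomize_rap_locations(raps, sizes, seed = 4)
  r2 <- randomize_rap_locations(raps, sizes, seed = 4)
  expect_identical(r1, r2)
  expect_equal(sort(r1$end - r1$start), sort(raps$end - raps$start))
  expect_true(all(r1$start >= 0 & r1$end <= sizes[r1$chrom]))

  # single RAP on a single chromosome: start uniform on [0, N - L]
  one <- rap_row("chrI", 0, 100, "+")
  sz <- c(chrI = 1000)
  starts <- withr::with_seed(21, vapply(1:10000, function(i) {
    randomize_rap_locations(one, sz)$start
  }, 0))
  expect_gte(min(starts), 0)
  expect_lte(max(starts), 900)
  h <- table(cut(starts, breaks = seq(-0.5, 900.5, length.out = 11)))
  expect_gt(chisq.test(h)$p.value, 1e-4)
})

test_that("enrichment test reports consistent ratios and is order-invariant", {
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 50000,
                                       n_trna = 40), seed = 33)
  truth <- plant_raps(g, n_raps = 12, fold = 20, host_min_len = 1500, seed = 34)
  raps <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
                     strand = truth$strand, name = truth$rap_id,
                     stringsAsFactors = FALSE)
  et <- enrichment_test(raps, g$features, g$chrom_sizes,
                        classes = c("ORF", "tRNA"), n_boot = 500, seed = 8)
  expect_equal(et$enrichment, et$observed / et$expected_mean)
  expect_equal(et$log2_enrichment, log2(et$enrichment))
  expect_true(all(et$p > 0 & et$p <= 1))
  expect_equal(et$observed[et$class == "ORF"], nrow(raps))   # all planted genic

  perm <- sample(nrow(raps))
  et2 <- enrichment_test(raps[perm, ], g$features, g$chrom_sizes,
                         classes = c("ORF", "tRNA"), n_boot = 500, seed = 8)
  expect_identical(et, et2)

  expect_error(enrichment_test(raps, g$features, g$chrom_sizes, n_boot = 0),
               "no randomizations")
})

test_that("null RAP placements give calibrated empirical p-values", {
  g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 50000,
                                       n_trna = 40, n_snorna = 25), seed = 61)
  pv <- withr::with_seed(62, replicate(25, {
    raps <- randomize_rap_locations(
      rap_row("chrI", 0, rep(250, 30), "+", sprintf("r%02d", 1:30)),
      g$chrom_sizes)
    et <- enrichment_test(raps, g$features, g$chrom_sizes,
                          classes = c("ORF", "tRNA"), n_boot = 400)
    et$p
  }))
  # two-sided empirical p under the null: exceedance near or below nominal
  expect_lt(mean(pv < 0.05), 0.18)
  expect_gt(mean(pv > 0.2), 0.5)
})
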