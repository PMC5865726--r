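test_that("decile profiles tile the trimmed body and follow the gene strand", {
  sizes <- c(chrI = 3000)
  gene <- gene_row("chrI", 200, 2800, "+", "G")      # trimmed body 2200-ish
  v <- numeric(3000); v[(400 + 1):2600] <- 3         # constant 3 on the body
  tr <- make_occ_track(sizes, plus = list(chrI = v))
  prof <- decile_profile(gene, tr)
  expect_equal(prof$densities, rep(3, 10))
  expect_equal(prof$body, c(400, 2600))

  # signal only in the first decile
  v2 <- numeric(3000); v2[(400 + 1):620] <- 5
  tr2 <- make_occ_track(sizes, plus = list(chrI = v2))
  d2 <- decile_profile(gene, tr2)$densities
  expect_true(d2[1] > 0 && all(d2[2:10] == 0))

  # minus-strand gene: decile 1 is the genomic right-most tenth
  gene_m <- gene_row("chrI", 200, 2800, "-", "Gm")
  v3 <- numeric(3000); v3[2381:2600] <- 4            # right-most tenth of the body
  tr3 <- make_occ_track(sizes, minus = list(chrI = v3))
  d3 <- decile_profile(gene_m, tr3)$densities
  expect_true(d3[1] > 0 && all(d3[2:10] == 0))

  # too-short gene is excluded
  short <- gene_row("chrI", 0, 550, "+", "S")
  expect_null(decile_profile(short, tr))
})

test_that("per-decile up/down ratios reproduce constructed steps", {
  sizes <- c(chrI = 3000)
  gene <- gene_row("chrI", 200, 2400, "+", "G")      # body [400, 2200), 1800 nt
  v <- numeric(3000)
  v[(400 + 1):1300] <- 2                             # deciles 1..5
  v[1301:2200] <- 1                                  # deciles 6..10
  tr <- make_occ_track(sizes, plus = list(chrI = v))
  dd <- decile_updown_distribution(gene, rap_row("chrI", 0, 10, "+")[0, ], tr)
  expect_equal(nrow(dd), 9)
  expect_equal(dd$log2_ratio[dd$decile == 5], 1)     # mean up 2, mean down 1

  # uniform gene: all ratios 0
  vu <- numeric(3000); vu[(400 + 1):2200] <- 3
  ddu <- decile_updown_distribution(gene, rap_row("chrI", 0, 10, "+")[0, ],
                                    make_occ_track(sizes, plus = list(chrI = vu)))
  expect_true(all(ddu$log2_ratio == 0))

  # harbouring flag: a RAP inside decile 3 marks exactly that segment
  rap <- rap_row("chrI", 400 + 2 * 180 + 10, 400 + 2 * 180 + 60, "+")
  ddh <- decile_updown_distribution(gene, rap,
                                    make_occ_track(sizes, plus = list(chrI = vu)))
  expect_equal(ddh$decile[ddh$harbors_rap], 3)
})

test_that("the up/down rate test matches the exact binomial oracle", {
  sizes <- c(chrI = 4000)
  gene <- gene_row("chrI", 200, 3800, "+", "G")      # body [400, 3600)
  rap <- rap_row("chrI", 1400, 1600, "+", "R", gene_id = "G")
  # construct exact counts: 200 upstream over 1000 nt, 100 downstream over 2000 nt
  v <- numeric(4000)
  v[(400 + 1):1400] <- 0.2                           # n_up = 200
  v[(1600 + 1):3600] <- 0.05                         # n_down = 100
  tr <- make_occ_track(sizes, plus = list(chrI = v))
  res <- rap_updown_test(rap, gene, tr)
  expect_equal(res$n_up, 200); expect_equal(res$n_down, 100)
  expect_equal(res$p, oracle_binom_p(200, 300, 1000 / 3000), tolerance = 1e-12)
  expect_equal(res$call, "decrease")
  expect_equal(res$log2_ratio, log2((200 / 1000) / (100 / 2000)))

  # equal densities on equal lengths: symmetric null
  v2 <- numeric(4000); v2[(400 + 1):2000] <- 0.1; v2[(2000 + 1):3600] <- 0.1
  rap2 <- rap_row("chrI", 1990, 2010, "+", "R2", gene_id = "G")
  res2 <- rap_updown_test(rap2, gene, make_occ_track(sizes, plus = list(chrI = v2)))
  expect_equal(res2$call, "nochange")
  expect_equal(res2$log2_ratio, 0)
  expect_gt(res2$p, 0.9)

  # empty track: p = 1, nochange
  res0 <- rap_updown_test(rap, gene, make_occ_track(sizes, plus = list(chrI = numeric(4000))))
  expect_equal(res0$p, 1)
  expect_equal(res0$call, "nochange")

  # the alpha threshold is a strict inequality
  res3 <- rap_updown_test(rap, gene, tr, alpha = res$p)
  expect_equal(res3$call, "nochange")
  expect_equal(res3$log2_ratio, 0)
  res4 <- rap_updown_test(rap, gene, tr, alpha = res$p * 1.0001)
  expect_equal(res4$call, "decrease")

  # ineligible placements are excluded
  outside <- rap_row("chrI", 100, 150, "+", "Ro", gene_id = "G")
  expect_null(rap_updown_test(outside, gene, tr))
  near_end <- rap_row("chrI", 3500, 3595, "+", "Rn", gene_id = "G")
  expect_null(rap_updown_test(near_end, gene, tr))
})

test_that("equal-length 200 vs 100 split is called at the expected magnitude", {
  sizes <- c(chrI = 3000)
  gene <- gene_row("chrI", 200, 2800, "+", "G")      # body [400, 2600)
  rap <- rap_row("chrI", 1450, 1550, "+", "R", gene_id = "G")
  v <- numeric(3000)
  v[(400 + 1):1450] <- 200 / 1050                    # n_up = 200 over L_up = 1050
  v[(1550 + 1):2600] <- 100 / 1050                   # n_down = 100, same length
  res <- rap_updown_test(rap, gene, make_occ_track(sizes, plus = list(chrI = v)))
  expect_equal(res$p, oracle_binom_p(200, 300, 0.5), tolerance = 1e-12)
  expect_lt(res$p, 1e-8)                             # ~9.4e-9
  expect_equal(res$call, "decrease")
})

test_that("minus-strand genes orient upstream with transcription", {
  sizes <- c(chrI = 4000)
  gene <- gene_row("chrI", 200, 3800, "-", "G")      # 5' end at genomic right
  rap <- rap_row("chrI", 1900, 2000, "-", "R", gene_id = "G")
  v <- numeric(4000)
  v[(2000 + 1):3600] <- 0.25                         # genomic right = upstream
  v[(400 + 1):1900] <- 0.05                          # genomic left = downstream
  tr <- make_occ_track(sizes, minus = list(chrI = v))
  res <- rap_updown_test(rap, gene, tr)
  expect_equal(res$n_up, 400)
  expect_equal(res$L_up, 1600)
  expect_equal(res$call, "decrease")
})

test_that("background placements preserve relative position and seed", {
  sizes <- c(chrI = 10000)
  host <- gene_row("chrI", 1000, 3400, "+", "H")     # body [1200, 3200), 2000 nt
  target <- gene_row("chrI", 5000, 6400, "+", "T")   # body [5200, 6200), 1000 nt
  genes <- rbind(host, target)
  rap <- rap_row("chrI", 2000, 2200, "+", "R", gene_id = "H")  # rel (0.4, 0.5)
  v <- numeric(10000); v[(1200 + 1):3200] <- 0.5; v[(5200 + 1):6200] <- 0.5
  tr <- make_occ_track(sizes, plus = list(chrI = v))
  bg <- randomized_background(rap, genes, tr, n_per_rap = 1, seed = 3)
  expect_equal(nrow(bg), 1)
  expect_equal(bg$gene_id, "T")
  expect_equal(bg$L_up, 400)                         # placed at body + [400, 500)
  expect_equal(bg$L_down, 500)

  b1 <- randomized_background(rap, genes, tr, n_per_rap = 1, seed = 3)
  expect_identical(bg, b1)
})

test_that("background comparison matches closed-form chi-squared arithmetic", {
  mk <- function(counts, jitter = 0) {
    data.frame(call = rep(c("increase", "decrease", "nochange"), counts),
               log2_ratio = c(runif(counts[1], 0.5, 1), -runif(counts[2], 0.5, 1),
                              rep(0, counts[3])) + jitter)
  }
  set.seed(2)
  obs <- mk(c(5, 50, 45))
  bg <- mk(c(100, 200, 700))
  cmp <- compare_to_background(obs, bg)
  expect_equal(unname(cmp$expected), c(10, 20, 70))
  expect_equal(cmp$chi2, 2.5 + 45 + 625 / 70, tolerance = 1e-12)
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$chi2_p, pchisq(2.5 + 45 + 625 / 70, 2, lower.tail = FALSE))

  ident <- mk(c(10, 10, 80))
  cmp2 <- compare_to_background(ident, ident)
  expect_equal(cmp2$ks_D, 0, tolerance = 1e-12)
  expect_equal(cmp2$ks_p, 1)

  # sparse expected counts pool the significant categories
  expect_warning(cmp3 <- compare_to_background(mk(c(2, 3, 15)), mk(c(1, 2, 997))),
                 "pooling")
  expect_equal(cmp3$df, 1L)
})
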