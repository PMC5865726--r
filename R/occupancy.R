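# RNA Pol II occupancy around RAPs: trimmed decile profiles, per-decile
# up/down log2-ratio distributions, RAP-centric exact conditional rate
# tests, randomized background, and categorical/distributional comparisons.

# trimmed gene body [start+trim, end-trim); NULL when too short
gene_body <- function(gene, trim) {
  bs <- gene$start + trim
  be <- gene$end - trim
  if (be - bs < trim) return(NULL)   # gene shorter than 2*trim + trim-sized body
  c(bs, be)
}

# gene-body signal 5'->3' on the gene's strand
body_signal <- function(gene, body, track) {
  v <- track_vector(track, gene$chrom, gene$strand)
  x <- v[(body[1] + 1L):body[2]]
  if (gene$strand == "-") rev(x) else x
}

#' Decile occupancy profile of a trimmed gene body
#'
#' Removes `trim` nt from each gene end, splits the rest into `n_deciles`
#' equal segments (boundaries by rounding cumulative tenths, ordered
#' 5' to 3' on the gene's strand) and returns the mean read-end density of
#' each segment.
#'
#' @param gene one-row gene data frame (chrom, start, end, strand,
#'   feature_id).
#' @param track a read-end [coverage_track()].
#' @param trim nt excluded at each gene end.
#' @param n_deciles number of segments.
#' @param min_body minimum trimmed body length; shorter genes are excluded.
#' @return list with gene_id, densities (length `n_deciles`), body
#'   (genomic interval), strand — or `NULL` with attribute-free exclusion
#'   when the gene is too short.
#' @export
decile_profile <- function(gene, track, trim = 200, n_deciles = 10,
                           min_body = 200) {
  body <- gene_body(gene, trim)
  if (is.null(body) || body[2] - body[1] < min_body) return(NULL)
  x <- body_signal(gene, body, track)
  n <- length(x)
  b <- round(seq_len(n_deciles) * n / n_deciles)
  b0 <- c(0, b[-n_deciles])
  dens <- (cumsum(x)[b] - c(0, cumsum(x)[b[-n_deciles]])) / (b - b0)
  list(gene_id = gene$feature_id, densities = as.numeric(dens),
       body = body, strand = gene$strand)
}

# genomic intervals of the deciles (in genomic, not 5'->3', order mapping)
decile_intervals <- function(body, strand, n_deciles = 10) {
  n <- body[2] - body[1]
  b <- round(seq_len(n_deciles) * n / n_deciles)
  s5 <- c(0, b[-n_deciles]); e5 <- b      # 5'-relative [s5, e5)
  if (strand == "-") {
    gs <- body[2] - e5; ge <- body[2] - s5
  } else {
    gs <- body[1] + s5; ge <- body[1] + e5
  }
  cbind(start = gs, end = ge)
}

#' Per-decile up/down log2-ratio distributions
#'
#' For each gene and each boundary d = 1..(n_deciles-1), the ratio of the
#' mean density over deciles 1..d (upstream, including the focal segment)
#' to the mean over deciles d+1..n (downstream) is computed and log2
#' transformed.  A segment harbors a RAP when a same-strand RAP overlaps it
#' by at least one base.  Positive log2 ratios mean more polymerase
#' upstream.
#'
#' @param genes gene annotation data frame.
#' @param raps RAP interval data frame.
#' @param track read-end [coverage_track()].
#' @param trim nt excluded at each gene end.
#' @param n_deciles number of segments.
#' @return data frame with gene_id, decile, log2_ratio, harbors_rap;
#'   attribute `excluded` counts genes dropped (too short or zero
#'   denominator).
#' @export
decile_updown_distribution <- function(genes, raps, track, trim = 200,
                                       n_deciles = 10) {
  rows <- list()
  excluded <- c(short = 0L, zero_denominator = 0L)
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    prof <- decile_profile(gene, track, trim, n_deciles)
    if (is.null(prof)) { excluded["short"] <- excluded["short"] + 1L; next }
    dens <- prof$densities
    iv <- decile_intervals(prof$body, gene$strand, n_deciles)
    ri <- which(raps$chrom == gene$chrom &
                (raps$strand == gene$strand | raps$strand == "*" |
                 gene$strand == "*"))
    harbors <- logical(n_deciles)
    if (length(ri)) {
      for (d in seq_len(n_deciles)) {
        harbors[d] <- any(raps$start[ri] < iv[d, "end"] &
                          raps$end[ri] > iv[d, "start"])
      }
    }
    up <- cumsum(dens) / seq_len(n_deciles)
    dn <- rev(cumsum(rev(dens))) / rev(seq_len(n_deciles))
    d <- seq_len(n_deciles - 1)
    down_mean <- dn[d + 1]
    if (any(down_mean == 0)) {
      excluded["zero_denominator"] <- excluded["zero_denominator"] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$feature_id, decile = d,
      log2_ratio = log2(up[d] / down_mean),
      harbors_rap = harbors[d], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), decile = integer(),
               log2_ratio = numeric(), harbors_rap = logical())
  attr(out, "excluded") <- excluded
  out
}

#' Exact conditional rate test of Pol II occupancy up- vs downstream of a RAP
#'
#' Sums the read-end signal between the trimmed gene start and the RAP
#' (upstream) and between the RAP and the trimmed gene end (downstream),
#' rounds to integer counts (half-to-even; tracks may carry fractional
#' multi-mapper weights) and applies the exact conditional binomial form of
#' the two-sample Poisson rate test with success probability
#' `L_up / (L_up + L_down)`.  When not significant at `alpha` (strict
#' inequality), the log2 density ratio is recorded as 0 and the call is
#' `nochange`; otherwise the call is `decrease` when downstream density is
#' significantly lower, `increase` when higher.
#'
#' @param rap one-row RAP data frame (chrom, start, end, strand, name).
#' @param gene one-row gene data frame hosting the RAP.
#' @param track read-end [coverage_track()].
#' @param trim nt excluded at each gene end.
#' @param alpha significance threshold (call requires `p < alpha`).
#' @param min_flank minimum up/downstream length (nt).
#' @return one-row data frame (rap_id, gene_id, n_up, L_up, n_down, L_down,
#'   p, log2_ratio, call) or `NULL` when the placement is ineligible.
#' @export
rap_updown_test <- function(rap, gene, track, trim = 200, alpha = 0.01,
                            min_flank = 20) {
  body <- gene_body(gene, trim)
  if (is.null(body)) return(NULL)
  if (rap$start < body[1] || rap$end > body[2]) return(NULL)
  v <- track_vector(track, gene$chrom, gene$strand)
  if (gene$strand == "-") {      # upstream = 5' side = genomic right
    up_iv <- c(rap$end, body[2]); dn_iv <- c(body[1], rap$start)
  } else {
    up_iv <- c(body[1], rap$start); dn_iv <- c(rap$end, body[2])
  }
  L_up <- up_iv[2] - up_iv[1]; L_dn <- dn_iv[2] - dn_iv[1]
  if (L_up < min_flank || L_dn < min_flank) return(NULL)
  n_up <- round(sum(v[(up_iv[1] + 1L):up_iv[2]]))
  n_dn <- round(sum(v[(dn_iv[1] + 1L):dn_iv[2]]))
  if (n_up + n_dn == 0) {
    p <- 1
  } else {
    p <- stats::poisson.test(c(n_up, n_dn), T = c(L_up, L_dn))$p.value
  }
  dens_up <- n_up / L_up; dens_dn <- n_dn / L_dn
  sig <- p < alpha
  call <- if (!sig) "nochange" else if (dens_dn < dens_up) "decrease" else "increase"
  data.frame(
    rap_id = rap$name %||% NA_character_,
    gene_id = gene$feature_id,
    n_up = n_up, L_up = L_up, n_down = n_dn, L_down = L_dn,
    p = p,
    log2_ratio = if (sig) log2(dens_up / dens_dn) else 0,
    call = call, stringsAsFactors = FALSE)
}

# relative 5'-anchored position of a rap inside its host's trimmed body
rap_relative_position <- function(rap, gene, trim) {
  body <- gene_body(gene, trim)
  if (is.null(body)) return(NULL)
  Lb <- body[2] - body[1]
  if (gene$strand == "-") {
    f1 <- (body[2] - rap$end) / Lb; f2 <- (body[2] - rap$start) / Lb
  } else {
    f1 <- (rap$start - body[1]) / Lb; f2 <- (rap$end - body[1]) / Lb
  }
  c(f1, f2)
}

# place a rap at 5'-relative (f1, f2) inside a target gene's trimmed body
place_relative <- function(f, gene, trim) {
  body <- gene_body(gene, trim)
  if (is.null(body)) return(NULL)
  Lb <- body[2] - body[1]
  s5 <- round(f[1] * Lb); e5 <- round(f[2] * Lb)
  if (e5 <= s5) e5 <- s5 + 1
  if (gene$strand == "-") {
    c(body[2] - e5, body[2] - s5)
  } else {
    c(body[1] + s5, body[1] + e5)
  }
}

#' Randomized occupancy background by moving RAPs across genes
#'
#' Each RAP is moved to `n_per_rap` other genes, preserving its position
#' relative to the host's trimmed gene-body boundaries (relative scaling),
#' and the up/down rate test is repeated for every placement.  Eligible
#' target genes have a long-enough trimmed body and nonzero total signal;
#' sampling is without replacement (with replacement when fewer targets
#' exist).  Placements leaving less than `min_flank` nt on either side are
#' redrawn up to 10 times, then skipped.
#'
#' @param raps RAP data frame with a `gene_id` column naming the host gene.
#' @param genes gene annotation data frame.
#' @param track read-end [coverage_track()].
#' @param n_per_rap placements per RAP.
#' @param trim,alpha,min_flank as in [rap_updown_test()].
#' @param seed optional RNG seed.
#' @return data frame of background up/down calls.
#' @export
randomized_background <- function(raps, genes, track, n_per_rap = 100,
                                  trim = 200, alpha = 0.01, min_flank = 20,
                                  seed = NULL) {
  eligible <- vapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, , drop = FALSE]
    body <- gene_body(gene, trim)
    if (is.null(body)) return(FALSE)
    sum(body_signal(gene, body, track)) > 0
  }, TRUE)
  gene_ids <- genes$feature_id
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(raps))) {
      rap <- raps[i, , drop = FALSE]
      host <- genes[match(rap$gene_id, gene_ids), , drop = FALSE]
      f <- rap_relative_position(rap, host, trim)
      if (is.null(f)) next
      pool <- which(eligible & gene_ids != rap$gene_id)
      if (!length(pool)) next
      targets <- pool[sample.int(length(pool), n_per_rap,
                                 replace = length(pool) < n_per_rap)]
      for (ti in targets) {
        gene <- genes[ti, , drop = FALSE]
        res <- NULL
        for (try in 1:10) {
          iv <- place_relative(f, gene, trim)
          if (!is.null(iv)) {
            moved <- rap
            moved$chrom <- gene$chrom; moved$strand <- gene$strand
            moved$start <- iv[1]; moved$end <- iv[2]
            res <- rap_updown_test(moved, gene, track, trim, alpha, min_flank)
          }
          if (!is.null(res)) break
          # a fixed relative placement cannot change; re-draw the target
          gene <- genes[pool[sample.int(length(pool), 1)], , drop = FALSE]
        }
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(rap_id = character(), gene_id = character(),
                 n_up = numeric(), L_up = numeric(), n_down = numeric(),
                 L_down = numeric(), p = numeric(), log2_ratio = numeric(),
                 call = character(), stringsAsFactors = FALSE)
  })
}

#' Compare observed up/down calls with a randomized background
#'
#' Chi-squared goodness of fit of the observed increase/decrease/nochange
#' counts against the background category proportions (df = 2; categories
#' are pooled to significant/nochange with df = 1 when an expected count
#' falls below 1), plus a two-sample Kolmogorov-Smirnov test on the
#' log2-ratio distributions (zeros from nochange calls included, matching
#' the ratio-set-to-0 rule).
#'
#' @param observed_calls,background_calls data frames from
#'   [rap_updown_test()] / [randomized_background()].
#' @return list with observed and expected counts, chi2, df, chi2_p, ks_D,
#'   ks_p.
#' @export
compare_to_background <- function(observed_calls, background_calls) {
  cats <- c("increase", "decrease", "nochange")
  obs <- vapply(cats, function(k) sum(observed_calls$call == k), 0)
  bg <- vapply(cats, function(k) sum(background_calls$call == k), 0)
  if (sum(bg) == 0) stop("empty background")
  props <- bg / sum(bg)
  expd <- props * sum(obs)
  df <- 2L
  if (any(expd < 1)) {
    warning("expected count < 1; pooling increase+decrease (df = 1)")
    obs <- c(significant = obs[["increase"]] + obs[["decrease"]],
             nochange = obs[["nochange"]])
    expd <- c(significant = expd[["increase"]] + expd[["decrease"]],
              nochange = expd[["nochange"]])
    df <- 1L
  }
  nonzero <- expd > 0
  chi2 <- sum((obs[nonzero] - expd[nonzero])^2 / expd[nonzero])
  ks <- suppressWarnings(
    stats::ks.test(observed_calls$log2_ratio, background_calls$log2_ratio,
                   exact = FALSE))
  list(observed = obs, expected = expd, chi2 = chi2, df = df,
       chi2_p = stats::pchisq(chi2, df, lower.tail = FALSE),
       ks_D = unname(ks$statistic), ks_p = ks$p.value)
}
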