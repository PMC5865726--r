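# Association between RAP presence and host-gene transcript abundance:
# TPM-ordered cumulative curve and per-segment exact Poisson tests.

#' Genes hosting at least one sense-oriented RAP
#'
#' @param raps RAP interval data frame.
#' @param genes stranded gene annotation with a `feature_id` column.
#' @return character vector of gene ids (each gene once, regardless of RAP
#'   multiplicity).
#' @export
sense_rap_genes <- function(raps, genes) {
  if (nrow(raps) == 0 || nrow(genes) == 0) return(character(0))
  hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ri <- which(raps$chrom == ch)
    if (!length(ri)) next
    h <- IRanges::findOverlaps(as_iranges0(genes[gi, , drop = FALSE]),
                               as_iranges0(raps[ri, , drop = FALSE]))
    gs <- genes$strand[gi][S4Vectors::queryHits(h)]
    rs <- raps$strand[ri][S4Vectors::subjectHits(h)]
    ok <- gs == rs | gs == "*" | rs == "*"
    hit[gi] <- hit[gi] | tabulate(S4Vectors::queryHits(h)[ok],
                                  nbins = length(gi)) > 0
  }
  sort(unique(genes$feature_id[hit]))
}

#' Cumulative RAP-gene count along the TPM ordering
#'
#' Genes are ranked by increasing TPM (ties broken by gene id for
#' determinism); the curve gives the cumulative count of RAP-hosting genes
#' up to each rank.  Under a uniform RAP assignment the normalised curve
#' follows the diagonal.
#'
#' @param expression data frame with gene_id, tpm.
#' @param rap_genes character vector of RAP-hosting gene ids.
#' @return data frame with rank, gene_id, tpm, is_rap_gene, cum_rap_genes.
#' @export
cumulative_curve <- function(expression, rap_genes) {
  o <- order(expression$tpm, expression$gene_id)
  df <- expression[o, c("gene_id", "tpm")]
  df$rank <- seq_len(nrow(df))
  df$is_rap_gene <- df$gene_id %in% rap_genes
  df$cum_rap_genes <- cumsum(df$is_rap_gene)
  rownames(df) <- NULL
  df[c("rank", "gene_id", "tpm", "is_rap_gene", "cum_rap_genes")]
}

#' TPM segments from inner boundaries
#'
#' Bounds `c(1, 30, 80)` give the right-closed segments (0,1], (1,30],
#' (30,80], (80,Inf).  Genes with TPM = 0 fall in the first segment.
#'
#' @param bounds increasing inner boundaries.
#' @return data frame with lower, upper, label.
#' @export
tpm_segments <- function(bounds = c(1, 30, 80)) {
  stopifnot(length(bounds) >= 1, !is.unsorted(bounds, strictly = TRUE),
            all(bounds > 0))
  lower <- c(-Inf, bounds)
  upper <- c(bounds, Inf)
  data.frame(lower = lower, upper = upper,
             label = sprintf("(%s,%s]", c(0, bounds),
                             c(bounds, "max")),
             stringsAsFactors = FALSE)
}

#' Exact Poisson segment tests of RAP density along the TPM axis
#'
#' Splits the gene universe into TPM segments and tests, per segment, the
#' observed count of RAP-hosting genes against the expectation under a
#' uniform assignment (`lambda = n_rap_genes * segment share of genes`),
#' with the two-sided exact Poisson test (minimum-likelihood method, as in
#' `stats::poisson.test`).
#'
#' @param expression data frame with gene_id, tpm (the gene universe).
#' @param rap_genes character vector of RAP-hosting gene ids.
#' @param bounds inner TPM segment boundaries.
#' @param alpha significance level used only to flag a direction.
#' @return data frame with segment label, n_genes, k (observed RAP genes),
#'   lambda (expected), p, direction.
#' @export
segment_poisson_test <- function(expression, rap_genes, bounds = c(1, 30, 80),
                                 alpha = 0.05) {
  seg <- tpm_segments(bounds)
  n_total <- nrow(expression)
  is_rap <- expression$gene_id %in% rap_genes
  k_total <- sum(is_rap)
  if (any(expression$tpm == 0)) {
    message(sum(expression$tpm == 0),
            " gene(s) with TPM = 0 assigned to the lowest segment")
  }
  res <- lapply(seq_len(nrow(seg)), function(i) {
    inseg <- expression$tpm > seg$lower[i] & expression$tpm <= seg$upper[i]
    n_genes <- sum(inseg)
    k <- sum(inseg & is_rap)
    lambda <- k_total * n_genes / max(n_total, 1)
    p <- if (n_genes == 0 || lambda == 0) {
      if (k == 0) 1 else 0
    } else {
      stats::poisson.test(k, T = 1, r = lambda)$p.value
    }
    data.frame(segment = seg$label[i], n_genes = n_genes, k = k,
               lambda = lambda, p = p,
               direction = if (p < alpha && k > lambda) "enriched"
                           else if (p < alpha && k < lambda) "depleted"
                           else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
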