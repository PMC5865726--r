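# Genomic context of RAP peaks: sense/antisense/intergenic classification
# against gene annotations, and feature-class enrichment against a
# length-preserving randomization null.

#' Select gene-like features from an annotation
#' @param features annotation data frame from [read_annotation()].
#' @param classes feature classes treated as genes.
#' @return the gene subset of `features`.
#' @export
gene_features <- function(features, classes = c("ORF", "gene")) {
  features[features$feature_class %in% classes, , drop = FALSE]
}

#' Classify RAPs as sense, antisense or intergenic
#'
#' A RAP overlapping (>= 1 base) a gene on its own strand is sense; one
#' overlapping only opposite-strand genes is antisense; one overlapping no
#' gene is intergenic.  Sense takes precedence when genes on both strands
#' are hit.  Unstranded RAPs that overlap a gene are classified sense with
#' a warning.
#'
#' @param raps RAP interval data frame.
#' @param genes stranded gene annotation (interval data frame).
#' @return list with `classes` (character vector, one entry per RAP) and
#'   `fractions` (named proportions over sense/antisense/intergenic).
#' @export
classify_raps <- function(raps, genes) {
  n <- nrow(raps)
  if (n == 0) {
    return(list(classes = character(0),
                fractions = c(sense = NA_real_, antisense = NA_real_,
                              intergenic = NA_real_)))
  }
  any_hit <- overlaps_any(raps, genes, same_strand = FALSE)
  sense_hit <- overlaps_any(raps, genes, same_strand = TRUE)
  if (any(raps$strand == "*" & any_hit)) {
    warning("unstranded RAP(s) overlapping genes classified as sense")
  }
  cls <- ifelse(!any_hit, "intergenic",
                ifelse(sense_hit, "sense", "antisense"))
  frac <- c(sense = mean(cls == "sense"),
            antisense = mean(cls == "antisense"),
            intergenic = mean(cls == "intergenic"))
  list(classes = cls, fractions = frac)
}

#' Genomic background fractions of the three context classes
#'
#' Fraction of the two-stranded position space that is sense-genic (covered
#' by a gene on the same strand), antisense-genic (covered only on the
#' opposite strand), or intergenic.
#'
#' @param genes stranded gene annotation.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return named fractions summing to 1.
#' @export
genome_class_background <- function(genes, chrom_sizes) {
  validate_chrom_sizes(chrom_sizes)
  total <- 2 * sum(chrom_sizes)
  sense <- 0; anti <- 0
  for (ch in names(chrom_sizes)) {
    n <- as.integer(chrom_sizes[[ch]])
    cov <- list()
    for (s in c("+", "-")) {
      g <- genes[genes$chrom == ch & (genes$strand == s | genes$strand == "*"), ,
                 drop = FALSE]
      v <- logical(n)
      if (nrow(g)) {
        red <- IRanges::reduce(as_iranges0(g))
        for (k in seq_along(red)) {
          v[IRanges::start(red)[k]:IRanges::end(red)[k]] <- TRUE
        }
      }
      cov[[s]] <- v
    }
    sense <- sense + sum(cov[["+"]]) + sum(cov[["-"]])
    anti <- anti + sum(cov[["-"]] & !cov[["+"]]) + sum(cov[["+"]] & !cov[["-"]])
  }
  c(sense = sense / total, antisense = anti / total,
    intergenic = 1 - (sense + anti) / total)
}

# Merged (reduced) per-class interval index in flattened genome coordinates.
# Chromosomes are laid end to end so that a single findInterval does the
# overlap query; placements never cross chromosome boundaries, so flattening
# is safe.
class_index <- function(features, chrom_sizes, classes,
                        same_strand = FALSE) {
  offs <- cumsum(c(0, as.numeric(chrom_sizes)))
  names(offs) <- c(names(chrom_sizes), ".end")
  build <- function(f) {
    if (!nrow(f)) return(list(starts = numeric(0), ends = numeric(0)))
    s <- offs[f$chrom] + f$start
    e <- offs[f$chrom] + f$end
    o <- order(s)
    s <- s[o]; e <- cummax(e[o])
    # merge touching/overlapping intervals
    new_run <- c(TRUE, s[-1] > e[-length(e)])
    grp <- cumsum(new_run)
    list(starts = as.numeric(tapply(s, grp, min)),
         ends = as.numeric(tapply(e, grp, max)))
  }
  idx <- lapply(classes, function(cl) {
    f <- features[features$feature_class == cl, , drop = FALSE]
    if (same_strand) {
      list(`+` = build(f[f$strand %in% c("+", "*"), , drop = FALSE]),
           `-` = build(f[f$strand %in% c("-", "*"), , drop = FALSE]))
    } else {
      list(`*` = build(f))
    }
  })
  names(idx) <- classes
  list(classes = idx, offsets = offs, same_strand = same_strand)
}

# Overlap indicator of global-coordinate intervals [s, e) against one merged
# interval list.
hits_index <- function(s, e, one) {
  if (!length(one$starts)) return(logical(length(s)))
  k <- findInterval(s, one$starts)
  left <- k >= 1 & ifelse(k >= 1, one$ends[pmax(k, 1)] > s, FALSE)
  nxt <- k + 1
  right <- nxt <= length(one$starts) &
    ifelse(nxt <= length(one$starts), one$starts[pmin(nxt, length(one$starts))] < e,
           FALSE)
  left | right
}

#' Count RAPs overlapping each feature class
#'
#' One base of overlap assigns a RAP to a class; a RAP may count toward
#' several classes, and counts RAPs (not bases or features).
#'
#' @param raps RAP interval data frame.
#' @param features annotation data frame.
#' @param classes classes to count; defaults to all classes present.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param same_strand require the RAP and feature strand to match.
#' @return named integer vector of observed counts.
#' @export
count_feature_overlaps <- function(raps, features, chrom_sizes,
                                   classes = NULL, same_strand = FALSE) {
  classes <- classes %||% sort(unique(features$feature_class))
  idx <- class_index(features, chrom_sizes, classes, same_strand)
  s <- idx$offsets[raps$chrom] + raps$start
  e <- idx$offsets[raps$chrom] + raps$end
  counts <- vapply(classes, function(cl) {
    ix <- idx$classes[[cl]]
    if (same_strand) {
      hp <- hits_index(s, e, ix[["+"]])
      hm <- hits_index(s, e, ix[["-"]])
      sum(ifelse(raps$strand == "+", hp,
                 ifelse(raps$strand == "-", hm, hp | hm)))
    } else {
      sum(hits_index(s, e, ix[["*"]]))
    }
  }, 0)
  stats::setNames(as.integer(counts), classes)
}

# n draws of a uniform placement for one RAP length: chromosome weighted by
# its count of admissible starts, start uniform on [0, N - L].
random_starts <- function(L, chrom_sizes, n) {
  adm <- pmax(as.numeric(chrom_sizes) - L + 1, 0)
  if (all(adm == 0)) stop("RAP longer than every chromosome")
  ci <- sample.int(length(adm), n, replace = TRUE, prob = adm)
  start <- floor(stats::runif(n) * adm[ci])
  list(chrom_i = ci, start = start)
}

#' Randomize RAP locations, preserving lengths
#'
#' Each RAP keeps its length and is placed uniformly over the two-stranded
#' genome (chromosomes weighted by admissible starts, strand fair coin),
#' never overhanging a chromosome end.
#'
#' @param raps RAP interval data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param seed optional seed for a reproducible placement.
#' @return data frame like `raps` with new chrom/start/end/strand.
#' @export
randomize_rap_locations <- function(raps, chrom_sizes, seed = NULL) {
  validate_chrom_sizes(chrom_sizes)
  with_seed(seed, {
    L <- raps$end - raps$start
    out <- raps
    for (i in seq_len(nrow(raps))) {
      p <- random_starts(L[i], chrom_sizes, 1L)
      out$chrom[i] <- names(chrom_sizes)[p$chrom_i]
      out$start[i] <- as.integer(p$start)
      out$end[i] <- as.integer(p$start + L[i])
    }
    out$strand <- sample(c("+", "-"), nrow(raps), replace = TRUE)
    out
  })
}

#' Feature-class enrichment against a randomization null
#'
#' Compares observed per-class RAP overlap counts with `n_boot` randomized
#' placements of the same RAP lengths.  The empirical p-value uses the +1
#' correction on each tail and reports the two-sided value
#' `min(1, 2 * smaller tail)`, with the smaller-tail side as direction.
#'
#' @param raps RAP interval data frame.
#' @param features annotation data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param classes classes to test; defaults to all present.
#' @param n_boot number of randomized experiments.
#' @param seed optional RNG seed.
#' @param same_strand strand-aware overlap counting (randomized strands are
#'   drawn fairly).
#' @param chunk internal batch size for the vectorised bootstrap.
#' @return data frame with class, observed, expected_mean, enrichment,
#'   log2_enrichment, p, direction, n_boot.
#' @export
enrichment_test <- function(raps, features, chrom_sizes, classes = NULL,
                            n_boot = 100000L, seed = NULL,
                            same_strand = FALSE, chunk = 20000L) {
  if (n_boot < 1) stop("no randomizations")
  classes <- classes %||% sort(unique(features$feature_class))
  idx <- class_index(features, chrom_sizes, classes, same_strand)
  observed <- count_feature_overlaps(raps, features, chrom_sizes, classes,
                                     same_strand)
  L <- raps$end - raps$start
  n_raps <- length(L)
  offs <- idx$offsets

  with_seed(seed, {
    ge <- matrix(0, nrow = 0, ncol = length(classes))  # boot counts
    done <- 0L
    sum_counts <- numeric(length(classes))
    n_ge <- numeric(length(classes)); n_le <- numeric(length(classes))
    while (done < n_boot) {
      b <- min(chunk, n_boot - done)
      counts <- matrix(0L, nrow = b, ncol = length(classes))
      # one placement matrix per RAP, vectorised over the b experiments;
      # canonical length order makes the result invariant to RAP row order
      for (i in order(L)) {
        p <- random_starts(L[i], chrom_sizes, b)
        s <- offs[p$chrom_i] + p$start
        e <- s + L[i]
        if (same_strand) {
          st <- sample(c("+", "-"), b, replace = TRUE)
        }
        for (j in seq_along(classes)) {
          ix <- idx$classes[[classes[j]]]
          h <- if (same_strand) {
            ifelse(st == "+", hits_index(s, e, ix[["+"]]),
                   hits_index(s, e, ix[["-"]]))
          } else {
            hits_index(s, e, ix[["*"]])
          }
          counts[, j] <- counts[, j] + h
        }
      }
      sum_counts <- sum_counts + colSums(counts)
      n_ge <- n_ge + colSums(counts >= rep(observed, each = b))
      n_le <- n_le + colSums(counts <= rep(observed, each = b))
      done <- done + b
    }
    expected <- sum_counts / n_boot
    p_up <- (1 + n_ge) / (n_boot + 1)
    p_dn <- (1 + n_le) / (n_boot + 1)
    p <- pmin(1, 2 * pmin(p_up, p_dn))
    enrich <- ifelse(expected > 0, observed / expected,
                     ifelse(observed > 0, Inf, NA_real_))
    data.frame(
      class = classes,
      observed = as.integer(observed),
      expected_mean = expected,
      enrichment = enrich,
      log2_enrichment = log2(enrich),
      p = p,
      direction = ifelse(p_up <= p_dn, "enriched", "depleted"),
      n_boot = as.integer(n_boot),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
}
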