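# Synthetic-data generators: a yeast-like annotated genome, genomic SELEX
# mate pairs with planted high-affinity regions, log-normal expression
# tables with segment-dependent RAP assignment, and strand-specific Pol II
# read-end tracks with planted downstream occupancy drops.  Every generator
# is a pure function of (spec, seed) and returns its planted truth.

#' Specification for a simulated genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (nt); recycled.
#' @param gene_meanlog,gene_sdlog log-normal gene-length parameters.
#' @param gene_len_range gene lengths are clipped to this range (nt).
#' @param p_plus probability a gene sits on the + strand.
#' @param min_gap minimum intergenic gap (nt).
#' @param telomere_len telomere tract per chromosome end (nt).
#' @param n_trna,n_snorna,n_ars,n_x_element auxiliary feature counts per
#'   genome, placed into intergenic gaps.
#' @return list of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(n_chromosomes = 3, chrom_length = 300000,
                            gene_meanlog = log(1600), gene_sdlog = 0.45,
                            gene_len_range = c(500, 4000), p_plus = 0.5,
                            min_gap = 80, telomere_len = 300,
                            n_trna = 30, n_snorna = 15, n_ars = 20,
                            n_x_element = 8) {
  spec <- list(n_chromosomes = n_chromosomes,
               chrom_length = rep_len(chrom_length, n_chromosomes),
               gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
               gene_len_range = gene_len_range, p_plus = p_plus,
               min_gap = min_gap, telomere_len = telomere_len,
               n_trna = n_trna, n_snorna = n_snorna, n_ars = n_ars,
               n_x_element = n_x_element)
  class(spec) <- "sim_genome_spec"
  spec
}

#' Telomeric repeat string on the CA-rich strand
#'
#' Concatenation of C(1-3)A units, i.e. the string matches `(C{1,3}A)+`
#' exactly and has exactly `n` characters.
#'
#' @param n string length (>= 2).
#' @param seed optional RNG seed.
#' @return a character scalar.
#' @export
telomere_repeat_string <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  with_seed(seed, {
    units <- character(0)
    rem <- n
    while (rem > 0) {
      kmax <- min(3, rem - 1)
      k <- sample.int(kmax, 1)
      if (rem - (k + 1) == 1) next   # never strand a lone final character
      units <- c(units, paste0(strrep("C", k), "A"))
      rem <- rem - (k + 1)
    }
    paste(units, collapse = "")
  })
}

# place n_feat features of the given length range into intergenic gaps
place_in_gaps <- function(gaps, n_feat, len_range, class, prefix, strand_p = 0.5) {
  out <- list()
  if (n_feat == 0 || nrow(gaps) == 0) return(out)
  widths <- gaps$end - gaps$start
  for (i in seq_len(n_feat)) {
    len <- sample(len_range[1]:len_range[2], 1)
    ok <- which(widths >= len)
    if (!length(ok)) break
    g <- ok[sample.int(length(ok), 1)]
    start <- gaps$start[g] + sample.int(widths[g] - len + 1, 1) - 1L
    out[[i]] <- data.frame(
      chrom = gaps$chrom[g], start = start, end = start + len,
      strand = if (stats::runif(1) < strand_p) "+" else "-",
      feature_class = class,
      feature_id = sprintf("%s%03d", prefix, i), stringsAsFactors = FALSE)
    # split the used gap, keeping both flanking pieces available
    right <- data.frame(chrom = gaps$chrom[g], start = start + len,
                        end = gaps$end[g], stringsAsFactors = FALSE)
    gaps$end[g] <- start
    gaps <- rbind(gaps, right)
    widths <- gaps$end - gaps$start
  }
  out
}

#' Simulate an annotated genome
#'
#' Chromosomes carry telomere tracts at both ends (with a stranded
#' telomeric-repeat feature on the CA-rich strand), non-overlapping genes
#' with log-normal lengths separated by intergenic gaps, and auxiliary
#' features (tRNA, snoRNA, ARS, X elements) placed into the gaps.
#'
#' @param spec a [sim_genome_spec()].
#' @param seed RNG seed; identical (spec, seed) give identical genomes.
#' @return list of class `sim_genome` with `chrom_sizes` and `features`.
#' @export
simulate_genome <- function(spec = sim_genome_spec(), seed = 1) {
  with_seed(seed, {
    sizes <- stats::setNames(as.numeric(spec$chrom_length),
                             sprintf("chr%s", as.roman(seq_len(spec$n_chromosomes))))
    feats <- list()
    gaps <- list()
    gi <- 0L
    for (ch in names(sizes)) {
      n <- sizes[[ch]]
      t <- spec$telomere_len
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = ch, start = c(0, n - t), end = c(t, n), strand = "*",
        feature_class = "telomere",
        feature_id = paste0(ch, c("_TEL_L", "_TEL_R")), stringsAsFactors = FALSE)
      # CA-rich (silent) strand: "-" at the left end, "+" at the right end
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = ch, start = c(0, n - t), end = c(t, n), strand = c("-", "+"),
        feature_class = "telomeric_repeat",
        feature_id = paste0(ch, c("_TR_L", "_TR_R")), stringsAsFactors = FALSE)
      pos <- t + spec$min_gap
      repeat {
        len <- round(stats::rlnorm(1, spec$gene_meanlog, spec$gene_sdlog))
        len <- min(max(len, spec$gene_len_range[1]), spec$gene_len_range[2])
        gap <- spec$min_gap + stats::rpois(1, spec$min_gap)
        if (pos + len + spec$min_gap + t > n) break
        gi <- gi + 1L
        feats[[length(feats) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = pos + len,
          strand = if (stats::runif(1) < spec$p_plus) "+" else "-",
          feature_class = "ORF",
          feature_id = sprintf("GENE%04d", gi), stringsAsFactors = FALSE)
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ch, start = pos + len, end = pos + len + gap,
          stringsAsFactors = FALSE)
        pos <- pos + len + gap
      }
    }
    gaps <- do.call(rbind, gaps)
    aux <- c(
      place_in_gaps(gaps, spec$n_trna, c(70, 120), "tRNA", "TRNA"),
      place_in_gaps(gaps, spec$n_snorna, c(90, 250), "snoRNA", "SNR"),
      place_in_gaps(gaps, spec$n_ars, c(100, 200), "ARS", "ARS"),
      place_in_gaps(gaps, spec$n_x_element, c(200, 475), "X_element", "XEL")
    )
    features <- do.call(rbind, c(feats, aux))
    rownames(features) <- NULL
    validate_intervals(features, sizes)
    structure(list(chrom_sizes = sizes, features = features, spec = spec),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$chrom_sizes), "chromosomes,",
      format(sum(x$chrom_sizes), big.mark = ","), "bases\n")
  print(table(x$features$feature_class))
  invisible(x)
}

#' Plant ground-truth RAPs inside host genes
#'
#' Hosts are drawn from genes of at least `host_min_len` nt; the RAP start
#' sits at a central relative position of the trimmed gene body (mirroring
#' candidate selection away from the very 5' and 3' gene ends), on the host
#' strand.
#'
#' @param genome a [simulate_genome()] result.
#' @param n_raps number of planted RAPs.
#' @param fold SELEX enrichment fold per RAP (recycled).
#' @param delta downstream occupancy drop fraction per RAP (recycled),
#'   0 <= delta < 1.
#' @param rap_len_range RAP length range (nt).
#' @param host_min_len minimum host gene length (nt).
#' @param rel_start_range relative start of the RAP within the trimmed
#'   body.
#' @param trim gene-end trim used to define the body (nt).
#' @param seed RNG seed.
#' @return data frame of class `sim_truth`: rap_id, chrom, start, end,
#'   strand, gene_id, fold, delta.
#' @export
plant_raps <- function(genome, n_raps = 30, fold = 20, delta = 0.4,
                       rap_len_range = c(80, 200), host_min_len = 2000,
                       rel_start_range = c(0.35, 0.55), trim = 200,
                       seed = 1) {
  stopifnot(all(delta >= 0), all(delta < 1), all(fold >= 1))
  genes <- gene_features(genome$features)
  hosts <- genes[genes$end - genes$start >= host_min_len, , drop = FALSE]
  if (nrow(hosts) < n_raps) stop("not enough eligible host genes")
  with_seed(seed, {
    hosts <- hosts[sample.int(nrow(hosts), n_raps), , drop = FALSE]
    fold <- rep_len(fold, n_raps)
    delta <- rep_len(delta, n_raps)
    rows <- lapply(seq_len(n_raps), function(i) {
      g <- hosts[i, , drop = FALSE]
      body <- gene_body(g, trim)
      Lb <- body[2] - body[1]
      len <- sample(rap_len_range[1]:rap_len_range[2], 1)
      f <- stats::runif(1, rel_start_range[1], rel_start_range[2])
      s5 <- round(f * Lb)
      s5 <- min(s5, Lb - len - 20)       # keep a downstream flank
      if (g$strand == "-") {
        start <- body[2] - s5 - len
      } else {
        start <- body[1] + s5
      }
      data.frame(rap_id = sprintf("TRAP%03d", i), chrom = g$chrom,
                 start = start, end = start + len, strand = g$strand,
                 gene_id = g$feature_id, fold = fold[i], delta = delta[i],
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
    class(truth) <- c("sim_truth", class(truth))
    truth
  })
}

#' Simulate genomic SELEX mate pairs
#'
#' Fragment initiation follows a per-strand-base weight of `background_rate`
#' over the genome and `background_rate * fold` inside a planted RAP on its
#' strand; `n_pairs` fragments are drawn from the normalised mixture (fixed
#' sequencing depth).  Background fragments start uniformly with lengths
#' uniform in `frag_len_range`; planted fragments straddle their RAP, with
#' jittered shoulders on both sides.  With `fold = 1` everywhere the output
#' is statistically uniform.
#'
#' @param genome a [simulate_genome()] result.
#' @param truth planted RAPs from [plant_raps()] (or NULL for pure
#'   background).
#' @param n_pairs total mate pairs.
#' @param background_rate background initiation weight per strand-base.
#' @param frag_len_range background fragment length range (nt).
#' @param jitter mean shoulder length of planted fragments beyond each RAP
#'   boundary (nt); shoulders are geometric (capped at `6 * jitter`), so
#'   fragment boundaries pile up sharply at the RAP boundaries, as expected
#'   for clonally enriched winner species.
#' @param seed RNG seed.
#' @return mate-pair data frame (chrom, end5_a, end5_b, strand, name,
#'   cross_chromosome), shuffled.
#' @export
simulate_selex <- function(genome, truth = NULL, n_pairs = 200000,
                           background_rate = 1, frag_len_range = c(30, 400),
                           jitter = 8, seed = 1) {
  sizes <- genome$chrom_sizes
  G2 <- 2 * sum(sizes)
  w_bg <- background_rate * G2
  n_truth <- if (is.null(truth)) 0L else nrow(truth)
  w_rap <- if (n_truth) {
    background_rate * (truth$fold - 1) * (truth$end - truth$start)
  } else numeric(0)
  with_seed(seed, {
    alloc <- as.vector(stats::rmultinom(1, n_pairs, c(w_bg, w_rap)))
    n_bg <- alloc[1]
    # background: uniform over the two-stranded genome
    ci <- sample.int(length(sizes), n_bg, replace = TRUE, prob = sizes)
    len <- sample(frag_len_range[1]:frag_len_range[2], n_bg, replace = TRUE)
    maxs <- as.numeric(sizes)[ci] - len
    start <- floor(stats::runif(n_bg) * (maxs + 1))
    bg <- data.frame(chrom = names(sizes)[ci],
                     end5_a = as.integer(start),
                     end5_b = as.integer(start + len - 1),
                     strand = sample(c("+", "-"), n_bg, replace = TRUE),
                     stringsAsFactors = FALSE)
    planted <- list()
    for (i in seq_len(n_truth)) {
      m <- alloc[i + 1]
      if (m == 0) next
      s <- truth$start[i]; e <- truth$end[i]
      u <- pmin(stats::rgeom(m, 1 / (1 + jitter)), 6L * jitter)  # left shoulder
      v <- pmin(stats::rgeom(m, 1 / (1 + jitter)), 6L * jitter)  # right shoulder
      fs <- pmax(s - u, 0)
      fe <- pmin(e + v, sizes[[truth$chrom[i]]])
      planted[[length(planted) + 1L]] <- data.frame(
        chrom = truth$chrom[i], end5_a = as.integer(fs),
        end5_b = as.integer(fe - 1L), strand = truth$strand[i],
        stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, c(list(bg), planted))
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs$name <- sprintf("frag%07d", seq_len(nrow(pairs)))
    pairs$cross_chromosome <- FALSE
    pairs
  })
}

#' Simulate a gene expression table with segment-dependent RAP assignment
#'
#' TPM values are log-normal.  RAP-hosting genes are drawn without
#' replacement with sampling weight `odds_low` for genes in the low-TPM
#' segment `(bounds[1], bounds[2]]` and 1 elsewhere; `odds_low = 1` makes
#' the assignment independent of expression (the null).
#'
#' @param genome a [simulate_genome()] result (supplies the gene universe);
#'   alternatively pass `n_genes` to use an abstract universe.
#' @param n_rap_genes number of RAP-hosting genes.
#' @param odds_low assignment odds multiplier in the low-TPM segment.
#' @param bounds inner TPM segment boundaries.
#' @param meanlog,sdlog log-normal TPM parameters.
#' @param n_genes gene count when no genome is given.
#' @param seed RNG seed.
#' @return list with `expression` (gene_id, tpm) and `rap_genes`.
#' @export
simulate_expression <- function(genome = NULL, n_rap_genes = 200,
                                odds_low = 3, bounds = c(1, 30, 80),
                                meanlog = 1.8, sdlog = 1.8,
                                n_genes = 2000, seed = 1) {
  ids <- if (!is.null(genome)) {
    gene_features(genome$features)$feature_id
  } else {
    sprintf("GENE%04d", seq_len(n_genes))
  }
  with_seed(seed, {
    tpm <- stats::rlnorm(length(ids), meanlog, sdlog)
    w <- ifelse(tpm > bounds[1] & tpm <= bounds[2], odds_low, 1)
    rap_genes <- ids[sample.int(length(ids), min(n_rap_genes, length(ids)),
                                prob = w)]
    list(expression = data.frame(gene_id = ids, tpm = tpm,
                                 stringsAsFactors = FALSE),
         rap_genes = sort(rap_genes))
  })
}

#' Simulate strand-specific RNA Pol II read-end tracks
#'
#' Per-base expected density inside a gene is `mean_density`, multiplied by
#' `fiveprime_boost` within the first `boost_len` nt (the 5'-proximal
#' polymerase peak), decayed exponentially toward the 3' end so that the
#' final base sits at `threeprime_decay` of the post-peak level, and
#' multiplied by `1 - delta` downstream of a planted RAP's 3' boundary.
#' Realised counts are Poisson per base; intergenic space carries no
#' signal.
#'
#' @param genome a [simulate_genome()] result.
#' @param truth planted RAPs from [plant_raps()] (uses their `delta`), or
#'   NULL.
#' @param mean_density baseline expected read ends per base.
#' @param fiveprime_boost multiplier over the first `boost_len` nt; 1
#'   disables the 5' peak.
#' @param boost_len length of the 5'-proximal peak (nt).
#' @param threeprime_decay expected density at the gene end relative to the
#'   post-peak level; 1 disables the decay.
#' @param seed RNG seed.
#' @return a read-end [coverage_track()].
#' @export
simulate_occupancy <- function(genome, truth = NULL, mean_density = 0.2,
                               fiveprime_boost = 3, boost_len = 200,
                               threeprime_decay = 0.6, seed = 1) {
  sizes <- genome$chrom_sizes
  genes <- gene_features(genome$features)
  track <- coverage_track(sizes, strands = c("+", "-"),
                          signal_kind = "read_end_counts")
  with_seed(seed, {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, , drop = FALSE]
      n <- g$end - g$start
      mu <- rep(mean_density, n)          # indexed 5' -> 3'
      bl <- min(boost_len, n)
      mu[seq_len(bl)] <- mu[seq_len(bl)] * fiveprime_boost
      if (threeprime_decay < 1 && n > boost_len) {
        x <- seq_len(n - boost_len)
        mu[boost_len + x] <- mu[boost_len + x] *
          threeprime_decay^(x / (n - boost_len))
      }
      if (!is.null(truth)) {
        ti <- which(truth$gene_id == g$feature_id)
        for (t in ti) {
          # 5'-relative offset of the RAP's 3' boundary
          off <- if (g$strand == "-") g$end - truth$start[t]
                 else truth$end[t] - g$start
          if (off < n) {
            mu[(off + 1):n] <- mu[(off + 1):n] * (1 - truth$delta[t])
          }
        }
      }
      counts <- stats::rpois(n, mu)
      if (g$strand == "-") counts <- rev(counts)
      v <- track$data[[g$chrom]][[g$strand]]
      v[(g$start + 1):g$end] <- v[(g$start + 1):g$end] + counts
      track$data[[g$chrom]][[g$strand]] <- v
    }
    track
  })
}
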