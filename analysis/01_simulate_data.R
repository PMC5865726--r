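#!/usr/bin/env Rscript
# Stage 1: generate every pipeline input with planted ground truth.
#
# Writes the standard-format files the later stages consume to
# scratch/simdata/ (large, regenerated at will) and the planted truth as
# JSON.  Conditions: a 1 Mb two-chromosome genome, 30 planted RAPs at
# 20-fold SELEX enrichment with a 40% downstream occupancy drop, 200,000
# sequenced mate pairs, log-normal expression with 3-fold RAP odds in the
# low-TPM segment.

library(rapscan)

out <- "scratch/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260101

message("simulating genome ...")
g <- simulate_genome(sim_genome_spec(n_chromosomes = 2, chrom_length = 500000),
                     seed = seed)
print(g)
write_chrom_sizes(g$chrom_sizes, file.path(out, "genome.chrom.sizes"))
write_annotation(g$features, file.path(out, "annotation.gff3"))

message("planting ground-truth RAPs ...")
truth <- plant_raps(g, n_raps = 30, fold = 20, delta = 0.4, seed = seed + 1)
write_truth(list(raps = as.data.frame(truth)), file.path(out, "truth.json"))

message("simulating SELEX mate pairs ...")
pairs <- simulate_selex(g, truth, n_pairs = 200000, seed = seed + 2)
write_bedpe(pairs, file.path(out, "selex.bedpe"))
message("  ", nrow(pairs), " mate pairs")

message("simulating expression table ...")
# transcriptome-wide abstract universe (the expression table is an
# independent input, like the published mRNA-seq TPMs the analysis sorts)
se <- simulate_expression(n_genes = 2000, n_rap_genes = 200, odds_low = 3,
                          seed = seed + 3)
write_expression(se$expression, file.path(out, "expression.tsv"))
writeLines(se$rap_genes, file.path(out, "expression_rap_genes.txt"))

message("simulating RNA Pol II occupancy tracks ...")
occ <- simulate_occupancy(g, truth, mean_density = 0.2, fiveprime_boost = 3,
                          threeprime_decay = 0.6, seed = seed + 4)
write_bedgraph(occ, file.path(out, "polii.plus.bedgraph"),
               file.path(out, "polii.minus.bedgraph"))
# a drop-free realisation of the same genome for null comparisons
occ0 <- simulate_occupancy(g, truth = NULL, mean_density = 0.2,
                           fiveprime_boost = 3, threeprime_decay = 0.6,
                           seed = seed + 5)
write_bedgraph(occ0, file.path(out, "polii_null.plus.bedgraph"),
               file.path(out, "polii_null.minus.bedgraph"))

message("done; inputs in ", out)
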