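---
title: "rapscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rapscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`rapscan` implements the computational side of a genomic-SELEX screen for
RNA-polymerase-binding aptamers (RAPs) in a yeast-like genome, together
with the downstream characterisation of the called peaks:

1. **Peak calling** from mapped SELEX mate pairs (`call_raps()`),
2. **Genomic context**: sense/antisense/intergenic classification and
   feature-class enrichment against a randomization null
   (`classify_raps()`, `enrichment_test()`),
3. **Expression association**: cumulative TPM-ordered curves and exact
   Poisson segment tests (`cumulative_curve()`, `segment_poisson_test()`),
4. **RNA Pol II occupancy**: per-decile up/down ratios and RAP-centric
   exact conditional rate tests against a randomized background
   (`decile_updown_distribution()`, `rap_updown_test()`,
   `randomized_background()`, `compare_to_background()`),
5. **Synthetic data**: generators for every input with planted ground
   truth (`simulate_genome()`, `plant_raps()`, `simulate_selex()`,
   `simulate_expression()`, `simulate_occupancy()`).

The pipeline starts from mapped coordinates: read trimming, mapping,
duplicate handling, motif discovery and GO enrichment are out of scope.
All internal coordinates are 0-based half-open (BED convention); GFF3 is
converted at the file boundary by `internal = (gff_start - 1, gff_end)`.

# The peak caller

The SELEX evidence unit is a mate pair: one sequenced fragment of the
selection pool, represented by the 5'-end coordinates of its two reads.
Pairs are kept when both mates map to the same chromosome with a 5'-end
distance of 20 to 500 bases, bounds inclusive ("no less than / no more
than" reads naturally as inclusive, and the same convention is applied to
peak lengths).

Per-base **fragment coverage** counts, for each pair, every base between
the two 5' ends (both included, so a pair of span $s$ contributes $s + 1$
bases).  Coverage is accumulated per strand; the pair's transcribed strand
is taken from the first mate's strand column, a declared convention for
the fixed-orientation library (`--unstranded` pooling is available via
`call_raps(unstranded = TRUE)`).

**Candidate regions** are maximal runs of coverage at or above
`min_region_coverage`.  The threshold applies to the raw per-base
coverage, *before* smoothing: smoothing may dip region edges below the
threshold without invalidating the region.  The default threshold is 5
reads, appropriate for a strongly enriched selection pool in which the
non-binding background is shallow.  When the background is deep — as in
the synthetic depth-matched experiments, where ~200,000 fragments over a
1 Mb genome put the uniform background near 20x per strand —
`background_min_cov()` supplies the threshold instead: the smallest
coverage $c$ such that the expected number of background bases reaching
$c$ under a Poisson($\hat\lambda$) model, over the whole searched strand
space, stays below a target (default 0.05; a Bonferroni-style genome-wide
bound).  $\hat\lambda$ is estimated by the median track value, which is
robust to the small enriched fraction.

Each candidate region is extracted with $(w-1)/2$ flanking bases of true
coverage on each side (edge-replicated at chromosome ends) and smoothed
with a **discrete Gaussian kernel**: `w` taps proportional to
$\exp(-i^2 / 2\sigma^2)$, normalised to sum 1.  The window is read as 5
taps; the spread is not derivable from first principles, so $\sigma = 1$
base is the default and both are configurable.  The **first derivative**
is the forward difference $d_i = s_{i+1} - s_i$; "ascending" means
$d > 0$.

**Pairing** selects peaks as (maximal ascending, maximal descending)
position pairs 20–500 bases apart:

* the globally maximal positive derivative anchors a peak;
* it is paired with the most negative derivative after it within the
  length window;
* ties break leftmost (determinism);
* an anchor with no admissible partner is discarded;
* the interval then splits at the accepted peak (or discarded anchor) and
  both sides are processed identically, so long regions can yield several
  peaks.

The superlative "maximal" motivates anchoring at global extremes before
recursing.  The test suite holds this procedure against an independent
exhaustive reference that enumerates candidate pairs by full scans, on
hundreds of random tracks.

Called peaks carry the boundary derivatives, the maximal raw coverage
inside the peak, and the number of supporting fragments.

# Genomic context

A RAP overlapping a gene by at least one base on its own strand is
**sense**; overlapping only opposite-strand genes, **antisense**;
otherwise **intergenic**.  Sense takes precedence when both strands are
hit (the precedence is declared; the three-way split is reported next to
the genome's own strand-space composition from
`genome_class_background()`).

**Feature-class enrichment** counts RAPs (not bases, not features): one
base of overlap assigns a RAP to a class, and a RAP may count toward
several classes.  The null distribution of each class count comes from
randomized placements that preserve every RAP length: each placement is
uniform over the two-stranded genome with chromosomes weighted by their
number of admissible starts, never overhanging a chromosome end, strand
by fair coin.  Randomized RAPs may overlap each other (placements are
independent), and placement is genome-wide rather than
within-chromosome — both declared choices.

The empirical p-value uses the +1 correction on each tail,
$p_\text{tail} = (1 + \#\{b : \text{count}_b \gtrless \text{obs}\}) /
(n_\text{boot} + 1)$, and the reported value is the two-sided
$\min(1,\, 2\,\min(p_\text{up}, p_\text{dn}))$ with the smaller-tail side
reported as the direction.  The doubling matters: the raw smaller tail
exceeds its nominal level about twice as often under a true null, whereas
the doubled version is calibrated — the test suite verifies the null
exceedance and the centring of the log2 enrichment over hundreds of
replicate null experiments.  Enrichment is `observed / mean(boot)`; a
zero-mean class with a nonzero observation reports infinite enrichment at
the smallest achievable p.

Two practical notes for calibration experiments.  First,
`log2(observed/expected)` of a count is biased downward by Jensen's
inequality at small expected counts (about $-1/(2\mu\ln 2)$), so
calibration checks use feature classes with expected overlap counts well
above ~20.  Second, a class that almost every RAP hits (ORFs in a
gene-dense genome) has a degenerate count distribution and carries no
Monte-Carlo information; such classes are reported but not useful for
null calibration.

# Expression association

Only genes hosting at least one *sense* RAP enter the analysis, each gene
once.  Genes are ranked by TPM (ties broken by gene id) and the cumulative
count of RAP-hosting genes is plotted against rank; under uniform
assignment the normalised curve follows the diagonal.

The TPM axis is split at 1, 30 and 80 into four right-closed segments
$(0,1], (1,30], (30,80], (80,\infty)$ — the boundary-membership convention
is declared since the interval notation leaves it open.  Genes with zero
TPM fall in the lowest segment and are flagged.  Per segment, the
observed RAP-gene count $k$ is tested against
$\lambda = K \cdot n_\text{seg}/n_\text{tot}$ with the two-sided exact
Poisson test (`stats::poisson.test`, minimum-likelihood method: the total
mass of outcomes no more likely than $k$).  The tests agree with a direct
probability-mass enumeration to $10^{-10}$ across the tested grid.

Because the total number of RAP genes is fixed, the vector of segment
counts is hypergeometric-like with variance below Poisson; the segment
tests are therefore conservative under the null (most visibly for
segments holding a large share of genes).  This matches the test's role
as a screen for gross deviations from uniformity.

# RNA Pol II occupancy

Occupancy tracks hold non-negative read-end counts per base and strand;
values may be fractional when multi-mapper signal was distributed
proportionally.  Genes are **trimmed** by 200 nt at each end — the 5'
trim avoids the initiation-proximal polymerase peak, the 3' trim mirrors
it for symmetry — and genes whose trimmed body is shorter than 200 nt are
excluded.

The trimmed body is split into **ten equal segments** (boundaries by
rounding cumulative tenths, ordered 5'→3' on the gene's strand).  For
each boundary $d \in \{1..9\}$ the ratio of the mean density over
segments $1..d$ to the mean over $d{+}1..10$ is log2-transformed; the
focal segment joins the upstream side so every boundary is used exactly
once.  A segment "harbors" a RAP when a same-strand RAP overlaps it by at
least one base.  Positive values mean more polymerase upstream; with a 5'
peak and a 3' decay the whole distribution sits above zero, and planted
downstream drops shift the harbouring segments further up.

Note that the nine ratios of one gene share that gene's counts and are
strongly dependent: distribution-level comparisons should use one segment
per gene (the acceptance suite does), or treat the pooled view as
descriptive.

The **RAP-centric test** sums the track between the trimmed gene start
and the RAP (upstream) and between the RAP and the trimmed gene end
(downstream), within the same trimmed body used everywhere else.  Sums
are rounded half-to-even to integer counts (tracks may carry fractional
weights; the rate test needs counts).  Significance comes from the exact
conditional binomial form of the two-sample Poisson rate test
(`stats::poisson.test` with two counts and the two region lengths as
exposure times).  The call is `decrease` when the downstream density is
significantly lower at $p < \alpha$ (strict inequality, $\alpha = 0.01$),
`increase` when higher, otherwise `nochange` — and a non-significant
log2 ratio is recorded as 0.  Flanks shorter than 20 nt exclude the
placement.

The **randomized background** moves each RAP to 100 other genes,
preserving its position *relative to the trimmed gene-body boundaries*
(relative scaling, which preserves the up/down length proportions the
conditional test conditions on).  Eligible targets have a long-enough
trimmed body and nonzero signal; sampling is without replacement when
possible; degenerate placements are redrawn up to 10 times, then skipped.
Category frequencies are compared by a chi-squared goodness-of-fit test
(df 2; when an expected count falls below 1 the increase/decrease
categories pool to df 1), and the log2-ratio distributions by a
two-sample Kolmogorov–Smirnov test in which the zeros from `nochange`
calls participate on both sides.

# The synthetic-data module

The generators are pure functions of (specification, seed): identical
inputs give identical files, and every planted quantity is returned (and
serialisable to JSON) so pipeline output can be joined to truth by id.

**Genome** (`simulate_genome()`): chromosomes with telomere tracts at
both ends (the silent CA-rich strand carries a stranded telomeric-repeat
feature; `telomere_repeat_string()` emits exact $(C_{1-3}A)_n$ strings),
non-overlapping genes with clipped log-normal lengths (500–4,000 nt,
median ~1.6 kb), fair-coin strands, Poisson-jittered intergenic gaps, and
auxiliary classes (tRNA, snoRNA, ARS, X elements) placed into the gaps.

**Ground truth** (`plant_raps()`): RAP hosts are genes of at least
2,000 nt with the RAP placed centrally in the trimmed body (relative
start 0.35–0.55).  This mirrors how reporter candidates are chosen — a
RAP in the middle of the host, away from the very 5' and 3' ends — and
gives the conditional rate test non-trivial counts on both sides.  Each
RAP carries a SELEX enrichment fold (default 20) and an occupancy drop
fraction $\delta$ (default 0.4, the scale of the reporter effect).

**SELEX pairs** (`simulate_selex()`): fragment initiation carries weight
`background_rate` per strand-base genome-wide and `background_rate x
fold` inside a planted RAP on its strand; `n_pairs` fragments are drawn
from the normalised mixture, fixing sequencing depth.  Background
fragments start uniformly with lengths uniform in 30–400 nt.  Planted
fragments cover their RAP entirely, with geometric shoulders (mean 8 nt,
capped) beyond each boundary: clonally enriched winner species pile their
ends at the selected element's boundaries, which is also what gives the
coverage profile a well-defined maximal-derivative position.  With
`fold = 1` everywhere the output is statistically uniform and the caller,
thresholded by `background_min_cov()`, returns (almost) nothing.

**Expression** (`simulate_expression()`): log-normal TPMs
(meanlog 1.8, sdlog 1.8, putting roughly 16% of genes below TPM 1 and
two thirds in the 1–30 segment); RAP-hosting genes drawn without
replacement with odds multiplied by `odds_low` (default 3) in $(1,30]$.

**Occupancy** (`simulate_occupancy()`): per-base expected density =
gene baseline (0.2 read ends/nt) x a 3-fold boost over the first 200 nt
x an exponential 3' decay reaching 60% of the post-peak level at the
gene end x $(1-\delta)$ downstream of a planted RAP's 3' boundary;
realised counts are Poisson per base.  Calibration experiments disable
boost and decay (`fiveprime_boost = 1, threeprime_decay = 1`) so the
drop-free track is an exact null for the rate test.

**What is not modelled**: sequence-level reads and mappability,
PCR duplicates, zero-inflation, library-size variation, replicate
structure, cross-hybridising repeats, and selection kinetics across SELEX
cycles.  Green tests therefore demonstrate that the algorithms recover
the effects they target under Poisson sampling at realistic depths — not
that real libraries are free of the artefacts the generators omit.

# Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_span` / `max_span` | 20 / 500 | nt | mate 5'-end distance bounds, inclusive |
| `min_region_coverage` | 5 | reads/base | candidate-region threshold (see `background_min_cov()`) |
| `kernel_window` | 5 | taps | Gaussian smoothing window |
| `kernel_sigma` | 1.0 | bases | Gaussian spread |
| `min_peak_len` / `max_peak_len` | 20 / 500 | nt | peak length bounds, inclusive |
| `n_boot` | 100,000 | — | randomized placements for enrichment |
| `trim` | 200 | nt | gene-end exclusion |
| `n_deciles` | 10 | — | gene-body segments |
| `alpha` | 0.01 | — | up/down call threshold (strict) |
| `n_background_genes` | 100 | — | placements per RAP |
| `min_flank` | 20 | nt | minimal up/downstream region |
| `tpm_bounds` | 1, 30, 80 | TPM | segment boundaries, right-closed |

# Problem sizes in the test suite

The shipped tests run the full pipeline at desk scale: a 1 Mb genome with
30 planted RAPs and 200,000 mate pairs for peak recovery; 200 replicate
null experiments at 2,000 randomizations each for enrichment calibration;
10,000 placements over ten independent track realisations for the rate
test's size; cohorts of 100 planted 40%-drop genes for effect recovery;
and 200 replicates of 2,000-gene expression tables for segment-test
power.  Enrichment defaults to 100,000 randomizations in production use;
the calibration experiments scale this to 2,000 per replicate to keep
many replicates affordable.

# Known limitations

* The mate-orientation convention for BEDPE input (strand of mate 1 =
  transcribed strand) is declared, not inferred; libraries with other
  conventions need their strand columns adjusted on the way in.
* Peak calling assumes a roughly uniform background within a track;
  strong chromosome-scale coverage trends would call for a locally
  estimated threshold.
* The enrichment randomizer does not exclude assembly gaps or low
  mappability regions (none exist in simulated genomes).
* `poisson.test`-based calls treat counts as independent Poisson; fixed
  totals make the segment tests conservative, and fractional
  multi-mapper weights are rounded to the nearest integer count.
* The decile ratio view pools dependent within-gene values and is
  descriptive; inferential comparisons should sample one segment per
  gene.
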