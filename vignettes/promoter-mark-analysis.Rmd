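---
title: "Promoter-centric histone-mark analysis: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-centric histone-mark analysis: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markscape)
```

markscape compares the enrichment of two promoter-associated histone
marks (the defaults are named `me3` and `ac`, for H3K4me3 and H3K4ac)
across cell lines, entirely at the level of fixed promoter windows. This
vignette explains the statistical model behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical decisions taken where more than one
reasonable convention exists.

## The enrichment model

Promoters are symmetric windows `[tss - flank, tss + flank)` (default
flank 1000 bp), 0-based half-open, clamped at chromosome boundaries.
Strand never changes the window — it is symmetric about the TSS — and is
only used later to orient profile bins 5′→3′. One TSS per gene is taken
from the annotation as given: when transcripts of a gene disagree about
the TSS, resolving them is the annotation provider's job, not this
package's.

Signal density is RPKM, `count · 1e9 / (total_aligned_reads · length)`,
computed identically for promoters (promoter length) and chromosomes
(chromosome length) so ratios live on one scale. Fold enrichment is

```
FE = RPKM_treatment / max(RPKM_input, floor),
```

where `floor` is the 5th percentile (linear interpolation on the sorted
values, the type-7 quantile) of all input RPKM values of that sample.
The floor exists because a near-zero input density would otherwise
manufacture arbitrarily large FE at poorly covered promoters; taking the
percentile per input sample keeps samples self-contained, with no
cross-sample leakage. If the percentile itself is zero the smallest
positive input value stands in, and an all-zero input vector is an
error — no positive floor exists. Two properties are worth knowing:

* flooring is monotone (raising an input value never lowers its floored
  value), and re-applying the *computed floor* is the identity;
* re-*estimating* an interpolated percentile on an already-floored
  vector lands slightly above the old floor, so composing the whole
  operation with itself is not exactly the identity. This is inherent
  to interpolated percentiles, not a defect; the pipeline floors once.

On the log scale, `log2_fe = log2(max(FE, 2^-10))`: a zero-treatment
promoter keeps its true linear zero but maps to −10 rather than −∞ so
differences of log FE are always finite.

A promoter is **marked** when `FE >= 4`. The cutoff is inclusive: the
boundary case belongs to the marked class, which gives a clean, testable
rule (`4.0` marked, `3.999...` not). The **analysis universe** is the
set of promoters marked for at least one mark in at least one cell line;
Venn partitions, rankings and downstream gene lists are all restricted
to it. Top-fraction strata use `ceiling(fraction * N)` and break FE ties
by ascending gene id, so a 10,964-promoter universe yields strata of
exactly 2741 (25 %) and 220 (2 %). Ranking is per mark; with
`cell_line = NULL` it uses each promoter's maximum FE across lines,
matching the "highest fold enrichment" reading, and a single line can be
requested instead.

## Differential marking and gene-set over-representation

For an ordered pair of cell lines (A, B), `delta = log2FE(B) −
log2FE(A)` per promoter and mark. A promoter is differential when
`|delta| >= log2(4)`, attributed to the gaining line (B if positive).
Categories then combine the two marks per gaining line: `ac_only`,
`me3_only`, `both` (both marks gained by the *same* line — opposite
gains stay separate), or `none`.

Over-representation of a gene set S in a query list Q uses the exact
binomial upper tail:

```
p = P(X >= |Q ∩ S|),  X ~ Binomial(|Q|, |S| / universe_size)
```

inclusive at the observed intersection, which is the standard
over-representation convention. The universe size is a property of the
gene-set collection — the number of unique genes across all sets (the
standard MSigDB-scale constant is 21 439) — and query genes outside the
collection's namespace are dropped (with a reported count) before
testing, so trials and successes refer to the same population.
Significance is controlled either by Bonferroni (`alpha / n_tests`,
family = sets × query lists) or by an explicit p-value threshold. The
pipeline default is the explicit threshold `4.9e-9`: it is the
Bonferroni-corrected threshold used for full-collection analyses, and it is *not*
derivable as 0.05/4914 (the family size behind it is unstated), so the
package exposes it as a configurable constant rather than guessing a
derivation. The implementation's tail is verified against a brute-force
log-space summation of the pmf to |Δ| < 1e-12.

## Profiles and clustering

Profile matrices hold per-bin FE across TSS ± 2 kb. Bin width defaults
to 100 bp (40 bins): fine enough to resolve a TSS peak whose scale is a
few hundred bp, small enough that profile matrices stay cheap. Input
bins are floored with the same 5th-percentile rule, computed over all
bins of the input sample. Minus-strand promoters have their bin order
reversed so every row reads 5′→3′ relative to its TSS.

The heatmap clustering is Lloyd's k-means with Euclidean distance on the
raw FE profiles — no row scaling, so "total FE" of a cluster center is
meaningful and the hottest cluster is genuinely the most enriched.
Defaults are k = 4 and at most 10 iterations (stopping earlier when
assignments stabilise). Initial centers are k distinct rows sampled
uniformly under the given seed — the simplest reading of "random
centers"; k-means++ would be a different algorithm. A cluster that
empties during iteration is re-seeded to the point farthest from its
current center. After fitting, clusters are relabelled in decreasing
order of the center's total FE (ties keep original label order); the
relabelling permutes labels only and never changes the partition. Genes
that defined the query set are split out before clustering and shown as
a separate block on top of the heatmap. Raw per-line FE triplets can be
clustered instead of profile bins by passing such a matrix — the
clustering functions are agnostic to the feature space — but binned
profiles are the default.

## Expression integration

Counts are normalized by median-of-ratios size factors: reference genes
are those with positive counts in every sample, each gene's geometric
mean across samples is the pseudo-reference, and a sample's factor is
the median of its ratios to that reference. This matches the standard
convention for "normalized counts". One subtlety: factors from an
in-sample geometric-mean reference are defined only up to a single
global constant, so rescaling one sample's raw counts by *c* multiplies
its factor by *c* relative to the others and shifts all normalized
counts by one common constant — every between-sample and
between-category ratio is exactly preserved, which is the invariance
that matters downstream.

Genes with fewer than 3 counts are removed before normalization. The
across-sample aggregation for that rule is the maximum by default (a
gene reaching 3 counts in any sample survives); mean and total are
available, since the convention is not fixed by the filter's usual
statement. Replicates are averaged on the normalized scale per cell
line, and the log2 is taken after averaging (log of mean, with a +1
display offset), so a category median in log space corresponds to the
median of per-gene mean expression. Category summaries report the
median normalized count per category and gaining line plus fold ratios
between categories; medians use the even-count mean-of-middle-two rule.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

* **Latent FE.** Per cell line and mark, a promoter is marked with
  probability `marked_fraction` (default 0.2). Unmarked promoters sit at
  latent FE exactly 1; marked promoters draw FE from a log-normal with
  log-mean `log(10)` and log-sd 0.6, truncated to ≥ 4. The truncation
  makes "marked" identifiable against the FE ≥ 4 classification rule;
  the location and spread put the median marked promoter near 10-fold,
  a realistic magnitude for strong promoter marks. Planted gene sets
  multiply latent FE by a configured fold in one target line and mark,
  creating differential signal with known membership.
* **Counts.** Negative binomial throughout, parameterized by mean and
  dispersion with `var = mu + dispersion · mu²` (default dispersion
  0.1), the standard overdispersed model for sequencing counts. Input
  means are proportional to promoter length at the configured depth;
  treatment means multiply the input mean by latent FE.
* **Library totals.** Per-sample totals are fixed at the nominal depth,
  and promoters carry only a `promoter_load` fraction of a library
  (default 0.1). This emulates promoters being a small slice of the
  genome: promoter-level enrichment then leaves the library total
  essentially unchanged, and the RPKM-ratio estimator is unbiased for
  the latent FE. (Tying totals to the sum of promoter counts instead
  would deflate every estimated FE by the mean enrichment of the
  library — a real phenomenon in heavily enriched libraries, but one
  that would make latent-truth recovery tests meaningless.)
* **Binned coverage.** Expected treatment signal in a bin is
  `input_level · (1 + (FE − 1) · g(bin))` with g a unit-height Gaussian
  centred on the TSS, sd 500 bp: enriched promoters show a TSS peak
  decaying to input level at ± 2 kb; FE = 1 promoters are flat.
* **Expression.** Gene means follow `expr_base ·
  expr_coupling^(log2 FE_ac)` in each line (defaults 100 and 2), so an
  acetylation-marked promoter at FE 10 is expected ~10-fold more
  expressed than an unmarked one — comfortably past the > 6-fold
  category contrast the analysis is designed to detect. Replicates
  share means.

Everything is seeded: each generator stage derives its own sub-seed from
the configuration seed, so stages are independently reproducible and a
fixed seed gives bit-identical output. ChIP libraries are generated as
already-combined samples (the pipeline's convention is to sum biological
replicates before RPKM in any case); the `replicates` parameter drives
the expression generator.

What the generator does **not** emulate: read-level artefacts (mapping,
duplicates, fragment-length effects), locus-to-locus covariance of
marks, copy-number structure, GC or mappability bias, correlated
marking between the two marks at one promoter, or non-promoter signal.
Passing tests on synthetic data therefore demonstrate that the
*computational procedure* recovers the structure it assumes — not that
real libraries satisfy those assumptions.

### A note on noise floors

With NB dispersion d, the log of a single-promoter FE estimate carries
an irreducible noise of about `sqrt(2d)` (~0.45 at d = 0.1) regardless
of sequencing depth, because both numerator and denominator keep their
dispersion-driven coefficient of variation `sqrt(d)` even at infinite
counts. Two consequences shape the validation suite: latent-truth
recovery of *linear* FE has a ~30 % median relative error floor at the
default dispersion (the suite therefore checks recovery on the log2
scale, where the default settings give ~13 % median relative error and
which is the scale every downstream decision uses); and
convergence-to-latent checks are run at dispersion 1e-4 and depth 1e8,
where the floor is genuinely small. Marked/unmarked *classification* is
much easier than FE estimation — the classes are separated by the
truncation gap — so sensitivity ~0.92 and specificity ~0.999 hold at
the default dispersion.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at 2,000
genes and depth 1e6 for recovery and planted-set checks (20 seeded
replicate runs for detection rates), 500 genes for null-configuration
checks, and 2,000 promoters at depth 1e7 for the Monte-Carlo comparison
of binned coverage against its closed-form expectation — at that size
the per-bin standard error (~0.8 %) sits well inside the 3 % acceptance
band, so the check is sharp rather than lucky. Stratum arithmetic is
checked on a synthetic universe of exactly 10,964 promoters.

## Known limitations

* FE is a ratio of floored densities; it is not a calibrated effect size
  and inherits the input library's biases.
* The binomial over-representation model treats genes as exchangeable
  draws; it ignores gene length, expression level and set overlap, and
  is anticonservative when the query shares structure with the sets
  beyond membership.
* The three-way Venn partition is specific to three-condition designs by
  construction.
* Differential marking is a per-promoter threshold rule, not a
  statistical test with an error rate: promoters near the cutoff flip
  with noise, which is why planted-signal recovery is assessed at the
  gene-set level.
* Real-data mode expects pre-computed promoter count tables; the package
  does not align reads or call peaks.
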