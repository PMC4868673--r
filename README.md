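# markscape

Promoter-centric comparison of histone-mark ChIP enrichment across cell
lines, built for studies that profile two related marks — e.g. H3K4
tri-methylation (H3K4me3) and H3K4 acetylation (H3K4ac) — in matched
conditions and ask where the marks diverge, which gene programs the
divergence touches, and whether it tracks gene expression.

## What it computes

Everything is anchored on fixed promoter windows (TSS ± 1 kb) and the
fold enrichment of ChIP signal density over input:

```
FE = RPKM_treatment / RPKM_input,   RPKM = count · 10⁹ / (total_reads · length_bp)
```

with the input density floored at its 5th percentile so ratios stay
bounded where the input is minimally covered. On top of that core
statistic the package provides:

- **Marked-promoter classification** (FE ≥ 4 over input) and the
  three-way Venn partition of marked promoters across cell lines, plus
  chromosome-level FE and per-chromosome median promoter FE.
- **Top-fraction ranking** of the marked universe by FE (top quartile,
  top 2 %, …) with deterministic tie-breaking.
- **Pairwise differential marking**: Δ = log₂FE(B) − log₂FE(A),
  differential when |Δ| ≥ log₂4, attributed to the gaining line and
  classified as `ac_only`, `me3_only` or `both`.
- **Gene-set over-representation** by an exact binomial upper tail —
  success probability = set size / universe size (21 439 for the full
  MSigDB-scale collection), trials = query size, successes = the
  intersection — with Bonferroni control or an explicit threshold
  (default 4.9 × 10⁻⁹).
- **TSS ± 2 kb FE profiles** in 100-bp bins, aggregate (meta-promoter)
  curves, and the heatmap clustering procedure: seeded Lloyd k-means
  (k = 4, ≤ 10 iterations) with clusters relabelled in decreasing order
  of total FE and query genes split out above the clustered block.
- **Expression integration**: median-of-ratios normalization, a
  low-expression filter (< 3 counts removed), and median normalized
  counts per differential-mark category with fold ratios between
  categories.
- A **negative-binomial synthetic-data generator** — gene models,
  ChIP/input promoter counts with latent FE (1 for unmarked, log-normal
  truncated ≥ 4 for marked), binned TSS coverage with a Gaussian peak
  scaled by FE, planted differential gene sets, and expression counts
  coupled to promoter acetylation — so the whole pipeline is testable
  end to end with known ground truth.

## Worked example

A synthetic study with three cell lines, a planted 100-gene set given an
8-fold acetylation gain in `lineB`, and expression coupled to promoter
acetylation:

```r
library(markscape)

cfg <- synthetic_config(
  n_genes = 1000, seed = 1,
  planted_sets = list(list(name = "EMT_UP", n_genes = 100,
                           cell_line = "lineB", mark = "ac", fold = 8)))
gm   <- simulate_gene_models(cfg)
prom <- derive_promoters(gm$genes, flank = 1000, chrom_sizes = gm$chrom_sizes)
chip <- simulate_chip_counts(cfg, prom)
enr  <- enrichment_table(chip$treatment, chip$input, prom)

mm <- classify_marked(enr, threshold = 4)
length(mm$universe)                      # promoters marked anywhere
#> [1] 743
venn_partition(mm, "ac", cfg$cell_lines)$counts
#>             lineA             lineB             lineC       lineA&lineB
#>               107               170               106                67
#>       lineA&lineC       lineB&lineC lineA&lineB&lineC
#>                11                37                 6
```

`lineB` carries the most acetylation-marked promoters — the planted gain.
Differential marking against `lineA` and the over-representation test
recover the planted set:

```r
d     <- differential_fe(enr, "lineA", "lineB", cutoff = 4)
cats  <- assign_mark_category(d)
query <- cats$gene_id[cats$cell_line == "lineB" &
                      cats$category %in% c("ac_only", "both")]
coll  <- simulate_gene_sets(cfg, gm$genes$gene_id)
res   <- apply_bonferroni(binomial_overrep(query, coll), threshold = 4.9e-9)
head(res[order(res$p_value), c("set", "set_size", "intersection",
                               "p_value", "significant")], 3)
#>           set set_size intersection      p_value significant
#> 1      EMT_UP      100           63 6.030802e-16        TRUE
#> 29 RANDOM_028      100           30 2.818050e-02       FALSE
#> 16 RANDOM_015      100           29 4.464334e-02       FALSE
```

63 of the 100 planted genes land in the acetylation-gain query
(p ≈ 6 × 10⁻¹⁶, far past the 4.9 × 10⁻⁹ threshold) while the 50 random
decoy sets stay flat. Expression follows the marks — promoters gaining
acetylation alone are ~10-fold more expressed than those gaining
tri-methylation alone:

```r
norm <- normalize_expression(filter_low_expression(
  simulate_expression(cfg, chip$latent)))
out  <- expression_by_category(norm$line_means, cats)
subset(out$summary, cell_line == "lineB")
#>   cell_line category   n    median
#> 4     lineB  ac_only 171 997.36007
#> 5     lineB me3_only 123  98.94887
#> 6     lineB     both  39 939.55234
```

The full pipeline (enrichment → Venn/ranking → differential →
over-representation → profiles/clusters → expression) runs from one
configuration object with `run_pipeline(pipeline_config(...), out_dir)`,
or from a YAML file via the `inst/cli/markscape` script
(`markscape simulate|run|overrep`).

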