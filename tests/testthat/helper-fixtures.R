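# Shared fixture builders for the test suite. All randomness is seeded
# through synthetic_config, so fixtures are reproducible.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 60, n_chroms = 2, chrom_size = 1e6,
                   depth = 2e5, seed = 1)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Full small study: gene models, promoters, chip counts, enrichment table.
tiny_study <- function(cfg = tiny_config()) {
  gm <- simulate_gene_models(cfg)
  promoters <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
  chip <- simulate_chip_counts(cfg, promoters)
  enr <- enrichment_table(chip$treatment, chip$input, promoters)
  list(cfg = cfg, genes = gm$genes, chrom_sizes = gm$chrom_sizes,
       promoters = promoters, chip = chip, enr = enr)
}

# Latent FE aligned to the rows of an enrichment table.
latent_for <- function(enr, latent) {
  key <- paste(enr$gene_id, enr$cell_line, enr$mark)
  lkey <- paste(latent$gene_id, latent$cell_line, latent$mark)
  latent$fe[match(key, lkey)]
}

# Hand-built long enrichment table from a named fe vector (one mark, one
# cell line unless given).
make_enrichment <- function(fe, mark = "ac", cell_line = "lineA",
                            chrom = "chr1") {
  data.frame(gene_id = names(fe), chrom = chrom, mark = mark,
             cell_line = cell_line, rpkm_t = fe, rpkm_i_floored = 1,
             fe = unname(fe), log2_fe = log2(pmax(unname(fe), 2^-10)),
             stringsAsFactors = FALSE)
}

# Brute-force binomial upper tail P(X >= k): log-space pmf summation via
# lchoose, independent of pbinom/dbinom.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a_comb <- sum(choose(rowSums(tab), 2))
  b_comb <- sum(choose(colSums(tab), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  max_index <- (a_comb + b_comb) / 2
  if (max_index == expected) return(1)
  (sum_comb - expected) / (max_index - expected)
}

# One planted-signal run: returns the flagged over-representation table.
planted_run <- function(seed, n_genes = 2000, fold = 8, set_size = 200) {
  cfg <- synthetic_config(
    seed = seed, n_genes = n_genes,
    planted_sets = list(list(name = "PLANTED", n_genes = set_size,
                             cell_line = "lineB", mark = "ac",
                             fold = fold)))
  gm <- simulate_gene_models(cfg)
  promoters <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
  chip <- simulate_chip_counts(cfg, promoters)
  enr <- enrichment_table(chip$treatment, chip$input, promoters)
  d <- differential_fe(enr, "lineA", "lineB")
  cats <- assign_mark_category(d)
  query <- cats$gene_id[cats$cell_line == "lineB" &
                          cats$category %in% c("ac_only", "both")]
  coll <- simulate_gene_sets(cfg, gm$genes$gene_id)
  res <- suppressMessages(binomial_overrep(query, coll))
  apply_bonferroni(res, threshold = 4.9e-9)
}
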