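test_that("gene models are spaced so promoters never overlap", {
  cfg <- synthetic_config(n_genes = 10, n_chroms = 1, chrom_size = 1e6)
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 10)
  expect_true(all(diff(gm$genes$tss) >= 4 * cfg$flank))
  prom <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
  expect_true(all(diff(prom$start) >= 2 * cfg$flank))
  expect_true(all(prom$end - prom$start == 2 * cfg$flank))
  # strands alternate
  expect_equal(gm$genes$strand[1:4], c("+", "-", "+", "-"))
})

test_that("gene model generation validates its configuration", {
  expect_error(simulate_gene_models(
    synthetic_config(n_genes = 0)), "n_genes")
  expect_error(simulate_gene_models(
    synthetic_config(n_genes = 1000, n_chroms = 1, chrom_size = 1e5)),
    "too small")
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- tiny_config(seed = 42,
                     planted_sets = list(list(name = "P", n_genes = 10,
                                              cell_line = "lineB",
                                              mark = "ac", fold = 4)))
  run <- function() {
    gm <- simulate_gene_models(cfg)
    prom <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
    chip <- simulate_chip_counts(cfg, prom)
    cov <- simulate_binned_coverage(cfg, prom, chip$latent)
    expr <- simulate_expression(cfg, chip$latent)
    sets <- simulate_gene_sets(cfg, gm$genes$gene_id)
    list(gm, chip, cov, expr, sets)
  }
  expect_identical(run(), run())
})

test_that("latent FE is 1 without marking and >= 4 when marked", {
  st <- tiny_study(tiny_config(marked_fraction = 0))
  expect_true(all(st$chip$latent$fe == 1))

  st2 <- tiny_study(tiny_config(n_genes = 200, marked_fraction = 0.5))
  lat <- st2$chip$latent
  expect_true(all(lat$fe == 1 | lat$fe >= 4))
  expect_gt(sum(lat$fe >= 4), 0)
})

test_that("a fold-1 planted set leaves the latent FE untouched", {
  base <- tiny_config(seed = 3)
  null_plant <- tiny_config(seed = 3, planted_sets = list(
    list(name = "P", n_genes = 10, cell_line = "lineB", mark = "ac",
         fold = 1)))
  gm <- simulate_gene_models(base)
  prom <- derive_promoters(gm$genes, base$flank, gm$chrom_sizes)
  a <- simulate_chip_counts(base, prom)$latent
  b <- simulate_chip_counts(null_plant, prom)$latent
  expect_equal(a$fe, b$fe)
})

test_that("planted folds multiply latent FE only in the target line/mark", {
  cfg <- tiny_config(seed = 3, marked_fraction = 0, planted_sets = list(
    list(name = "P", n_genes = 10, cell_line = "lineB", mark = "ac",
         fold = 8)))
  gm <- simulate_gene_models(cfg)
  prom <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
  lat <- simulate_chip_counts(cfg, prom)$latent
  planted <- attr(lat, "planted")$P
  expect_length(planted, 10)
  hit <- lat$gene_id %in% planted & lat$cell_line == "lineB" &
    lat$mark == "ac"
  expect_true(all(lat$fe[hit] == 8))
  expect_true(all(lat$fe[!hit] == 1))
})

test_that("empirical FE converges to latent FE as noise vanishes", {
  # law of large numbers: at high depth and near-zero dispersion the
  # RPKM-ratio estimator concentrates on the latent value
  cfg <- synthetic_config(seed = 1, n_genes = 500, depth = 1e8,
                          nb_dispersion = 1e-4)
  st <- tiny_study(cfg)
  lat_fe <- latent_for(st$enr, st$chip$latent)
  expect_gte(mean(abs(st$enr$fe - lat_fe) / lat_fe < 0.05), 0.95)
})

test_that("log2 FE of marked promoters is recovered within 15% at defaults", {
  st <- tiny_study(synthetic_config(seed = 1))
  lat_fe <- latent_for(st$enr, st$chip$latent)
  marked <- lat_fe >= 4
  rel_err <- abs(st$enr$log2_fe[marked] - log2(lat_fe[marked])) /
    log2(lat_fe[marked])
  expect_lt(median(rel_err), 0.15)
})

test_that("binned coverage matches its closed-form expectation", {
  cfg <- synthetic_config(seed = 1, n_genes = 2000, depth = 1e7)
  gm <- simulate_gene_models(cfg)
  prom <- derive_promoters(gm$genes, cfg$flank, gm$chrom_sizes)
  lat <- expand.grid(gene_id = prom$gene_id, cell_line = cfg$cell_lines,
                     mark = cfg$marks, stringsAsFactors = FALSE)
  lat$fe <- 8
  cov <- simulate_binned_coverage(cfg, prom, lat)
  g <- exp(-cov$bin_mids^2 / (2 * 500^2))
  input_level <- cfg$depth * cfg$promoter_load * cfg$bin_width /
    sum(prom$end - prom$start)
  expected <- input_level * (1 + (8 - 1) * g)
  observed <- colMeans(cov$treatment$lineA$me3)
  expect_lt(max(abs(observed - expected) / expected), 0.03)
  # the TSS-proximal bin dominates the edges for an enriched promoter
  expect_gt(expected[which.min(abs(cov$bin_mids))], expected[1])
  # FE = 1 promoters have a flat expected profile: input columns share a mean
  expect_lt(diff(range(colMeans(cov$input$lineA))) /
              mean(cov$input$lineA), 0.1)
})

test_that("expression means follow the acetylation coupling", {
  # closed form: FE_ac = 16 vs 1 at coupling 2 gives a 16-fold mean ratio
  cfg <- synthetic_config(seed = 1, n_genes = 2000, replicates = 10)
  ids <- sprintf("G%05d", 1:2000)
  lat <- expand.grid(gene_id = ids, cell_line = cfg$cell_lines,
                     mark = cfg$marks, stringsAsFactors = FALSE)
  lat$fe <- 1
  hi <- lat$mark == "ac" & lat$gene_id %in% ids[1:1000]
  lat$fe[hi] <- 16
  expr <- simulate_expression(cfg, lat)
  m <- rowMeans(expr$counts)
  ratio <- mean(m[1:1000]) / mean(m[1001:2000])
  expect_equal(ratio, 16, tolerance = 0.05)

  # coupling 1 decouples expression from the marks
  cfg0 <- synthetic_config(seed = 1, n_genes = 2000, replicates = 10,
                           expr_coupling = 1)
  m0 <- rowMeans(simulate_expression(cfg0, lat)$counts)
  expect_equal(mean(m0[1:1000]) / mean(m0[1001:2000]), 1, tolerance = 0.05)
  expect_equal(mean(m0), cfg0$expr_base, tolerance = 0.05)
})
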