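#' Build a pipeline configuration
#'
#' Assembles the thresholds and inputs of a full run. Exactly one of
#' \code{paths} (real data on disk) or \code{synthetic} (a
#' \code{\link{synthetic_config}}) must be supplied. Defaults mirror the
#' analysis conventions: promoters TSS +/- 1 kb, marked and differential
#' cutoffs at 4-fold, 5th-percentile input floor, profiles over TSS
#' +/- 2 kb in 100-bp bins, k = 4 clusters capped at 10 iterations, and an
#' explicit over-representation threshold of 4.9e-9 (the Bonferroni-
#' corrected value used with the full MSigDB-scale collection).
#'
#' @param synthetic A \code{synthetic_config}, or NULL.
#' @param paths Named list of input paths (\code{gene_models},
#'   \code{chrom_sizes}, \code{treatment} nested per line/mark,
#'   \code{input} per line, \code{gmt}, \code{expression}), or NULL.
#' @param marked_fe,differential_fe FE cutoffs (default 4).
#' @param percentile Input floor percentile (default 5).
#' @param flank Promoter half-width (default 1000).
#' @param k,max_iter k-means settings (defaults 4, 10).
#' @param alpha Family-wise error rate (default 0.05).
#' @param p_threshold Explicit over-representation p threshold (default
#'   4.9e-9); set NULL to use \code{alpha / n_tests}.
#' @param min_count Low-expression filter (default 3).
#' @param top_fractions Ranking strata to report (default 0.25 and 0.02).
#' @param seed Integer seed (default 1).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            marked_fe = 4, differential_fe = 4,
                            percentile = 5, flank = 1000,
                            k = 4, max_iter = 10, alpha = 0.05,
                            p_threshold = 4.9e-9, min_count = 3,
                            top_fractions = c(0.25, 0.02), seed = 1) {
  if (is.null(synthetic) == is.null(paths))
    stop("exactly one of 'synthetic' or 'paths' must be supplied")
  if (!is.null(paths)) {
    need <- c("gene_models", "chrom_sizes", "treatment", "input", "gmt",
              "expression")
    missing_keys <- setdiff(need, names(paths))
    if (length(missing_keys))
      stop("config error: missing path(s): ",
           paste(missing_keys, collapse = ", "))
    flat <- c(paths$gene_models, paths$chrom_sizes, paths$gmt,
              paths$expression, unlist(paths$treatment), unlist(paths$input))
    absent <- flat[!file.exists(flat)]
    if (length(absent))
      stop("config error: input file(s) not found: ",
           paste(absent, collapse = ", "))
  }
  stopifnot(marked_fe > 0, differential_fe > 0, percentile >= 0,
            flank > 0, k >= 1, max_iter >= 1, min_count >= 0,
            all(top_fractions > 0), all(top_fractions <= 1))
  structure(list(synthetic = synthetic, paths = paths,
                 marked_fe = marked_fe, differential_fe = differential_fe,
                 percentile = percentile, flank = flank, k = k,
                 max_iter = max_iter, alpha = alpha,
                 p_threshold = p_threshold, min_count = min_count,
                 top_fractions = top_fractions, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document holds the same keys as
#' \code{\link{pipeline_config}}; a \code{synthetic:} block is passed to
#' \code{\link{synthetic_config}}.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  syn <- if (!is.null(doc$synthetic))
    do.call(synthetic_config, doc$synthetic) else NULL
  doc$synthetic <- NULL
  args <- c(list(synthetic = syn), doc)
  do.call(pipeline_config, args)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits the same TSV/BED/GMT files the real-data pipeline consumes:
#' gene models and chromosome sizes, promoter BED, per-sample ChIP and
#' input count tables, a gene-set GMT, expression counts, and a manifest
#' (JSON) recording the configuration and seed.
#'
#' @param config A \code{synthetic_config}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the \code{paths} list suitable for
#'   \code{\link{pipeline_config}}.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- simulate_gene_models(config)
  promoters <- derive_promoters(gm$genes, config$flank, gm$chrom_sizes)
  chip <- simulate_chip_counts(config, promoters)
  expr <- simulate_expression(config, chip$latent)
  sets <- simulate_gene_sets(config, gm$genes$gene_id)

  p <- function(...) file.path(dir, paste0(...))
  utils::write.table(gm$genes, p("gene_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(gm$chrom_sizes), size = gm$chrom_sizes),
    p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_promoters_bed(promoters, p("promoters.bed"))
  paths <- list(gene_models = p("gene_models.tsv"),
                chrom_sizes = p("chrom_sizes.tsv"),
                gmt = p("gene_sets.gmt"),
                expression = p("expression.tsv"),
                treatment = list(), input = list())
  for (cl in config$cell_lines) {
    paths$input[[cl]] <- p("input_", cl, ".tsv")
    write_count_table(chip$input[[cl]], paths$input[[cl]])
    paths$treatment[[cl]] <- list()
    for (mk in config$marks) {
      paths$treatment[[cl]][[mk]] <- p("chip_", cl, "_", mk, ".tsv")
      write_count_table(chip$treatment[[cl]][[mk]],
                        paths$treatment[[cl]][[mk]])
    }
  }
  write_gmt(sets, paths$gmt)
  write_count_table(expr, paths$expression)
  manifest <- list(generator = "markscape synthetic_data",
                   seed = config$seed,
                   config = config[setdiff(names(config), "planted_sets")],
                   planted_sets = config$planted_sets,
                   package_version = as.character(
                     utils::packageVersion("markscape")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gm <- simulate_gene_models(syn)
    promoters <- derive_promoters(gm$genes, config$flank, gm$chrom_sizes)
    chip <- simulate_chip_counts(syn, promoters)
    coverage <- simulate_binned_coverage(syn, promoters, chip$latent)
    list(genes = gm$genes, chrom_sizes = gm$chrom_sizes,
         promoters = promoters,
         treatment = chip$treatment, input = chip$input,
         latent = chip$latent, coverage = coverage,
         collection = simulate_gene_sets(syn, gm$genes$gene_id),
         expression = simulate_expression(syn, chip$latent),
         cell_lines = syn$cell_lines, marks = syn$marks)
  } else {
    pt <- config$paths
    genes <- utils::read.table(pt$gene_models, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    cs <- utils::read.table(pt$chrom_sizes, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    chrom_sizes <- setNames(cs$size, cs$chrom)
    promoters <- derive_promoters(genes, config$flank, chrom_sizes)
    treatment <- lapply(pt$treatment, function(x) lapply(x, read_count_table))
    input <- lapply(pt$input, read_count_table)
    list(genes = genes, chrom_sizes = chrom_sizes, promoters = promoters,
         treatment = treatment, input = input, latent = NULL,
         coverage = NULL,
         collection = read_gmt(pt$gmt),
         expression = read_count_table(pt$expression),
         cell_lines = names(treatment),
         marks = names(treatment[[1]]))
  }
}

#' Run the full promoter-mark analysis pipeline
#'
#' Executes, in order: promoter derivation, RPKM / input floor / fold
#' enrichment, marked-promoter classification with three-way Venn
#' partition and top-fraction ranking, pairwise differential marking and
#' mark categories, binomial gene-set over-representation with the heat
#' matrix, TSS profile construction with aggregate curves and sorted
#' k-means clusters, and expression integration by mark category. All
#' tabular outputs are written to \code{out_dir} together with a manifest;
#' a rerun with the same configuration and seed reproduces them
#' byte-identically.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  tsv <- function(x, name) utils::write.table(
    x, p(name), sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage <- function(...) message("[markscape] ", ...)

  log_stage("loading inputs")
  inputs <- load_pipeline_inputs(config)
  write_promoters_bed(inputs$promoters, p("promoters.bed"))

  log_stage("fold enrichment at promoters")
  enr <- enrichment_table(inputs$treatment, inputs$input, inputs$promoters,
                          config$percentile)
  tsv(enr, "enrichment.tsv")
  chrom_medians <- median_promoter_fe_by_chrom(enr)
  tsv(chrom_medians, "chromosome_median_fe.tsv")

  log_stage("marked promoters, Venn partition, ranking")
  mm <- classify_marked(enr, config$marked_fe)
  venns <- list()
  if (length(inputs$cell_lines) == 3) {
    for (mk in inputs$marks) {
      v <- venn_partition(mm, mk, inputs$cell_lines)
      venns[[mk]] <- v
      tsv(data.frame(region = names(v$counts), count = v$counts,
                     percent = round(v$percent, 2)),
          paste0("venn_", mk, ".tsv"))
    }
  }
  strata <- list()
  for (mk in inputs$marks) {
    for (fr in config$top_fractions) {
      key <- paste0(mk, "_top", fr * 100)
      strata[[key]] <- rank_top_fraction(enr, mm, mk, fr)
      tsv(strata[[key]], paste0("stratum_", key, ".tsv"))
    }
  }

  log_stage("pairwise differential marking and categories")
  pairs <- utils::combn(inputs$cell_lines, 2, simplify = FALSE)
  diffs <- list()
  categories <- list()
  overrep <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    d <- differential_fe(enr, pr[1], pr[2], config$differential_fe)
    diffs[[key]] <- d
    tsv(d, paste0("differential_", key, ".tsv"))
    cat_tab <- assign_mark_category(d)
    categories[[key]] <- cat_tab
    tsv(cat_tab[cat_tab$category != "none", ],
        paste0("categories_", key, ".tsv"))
  }

  log_stage("gene-set over-representation")
  queries <- list()
  cat_tab <- categories[[1]]
  for (cl in unique(cat_tab$cell_line)) {
    for (ct in c("ac_only", "me3_only", "both")) {
      ids <- cat_tab$gene_id[cat_tab$cell_line == cl &
                               cat_tab$category == ct]
      if (length(ids)) queries[[paste(cl, ct, sep = ".")]] <- ids
    }
  }
  results_by_query <- list()
  for (qn in names(queries)) {
    res <- try(suppressMessages(
      binomial_overrep(queries[[qn]], inputs$collection)), silent = TRUE)
    if (inherits(res, "try-error")) next
    res <- apply_bonferroni(res, config$alpha,
                            n_tests = nrow(res) * length(queries),
                            threshold = config$p_threshold)
    results_by_query[[qn]] <- res
    tsv(res, paste0("overrep_", gsub("[^A-Za-z0-9_.]", "_", qn), ".tsv"))
  }
  heat <- if (length(results_by_query))
    build_heat_matrix(results_by_query) else NULL
  if (!is.null(heat) && nrow(heat))
    utils::write.table(data.frame(set = rownames(heat), heat,
                                  check.names = FALSE),
                       p("overrep_heat_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  log_stage("TSS profiles and clustering")
  profiles <- list()
  aggregates <- list()
  clusters <- NULL
  if (!is.null(inputs$coverage)) {
    cov <- inputs$coverage
    bin_width <- diff(cov$bin_mids[1:2])
    for (cl in inputs$cell_lines) {
      for (mk in inputs$marks) {
        pmx <- compute_profile_matrix(
          cov$treatment[[cl]][[mk]], cov$input[[cl]],
          treat_total = cov$totals, input_total = cov$totals,
          bin_width = bin_width, strand = inputs$promoters$strand,
          percentile = config$percentile)
        profiles[[paste(cl, mk, sep = ".")]] <- pmx
        aggregates[[paste(cl, mk, sep = ".")]] <-
          aggregate_tss_profile(pmx)
      }
    }
    agg_tab <- data.frame(bin_mid = cov$bin_mids,
                          do.call(cbind, aggregates), check.names = FALSE)
    tsv(agg_tab, "aggregate_profiles.tsv")
    pmx <- profiles[[1]]
    km <- sort_clusters(kmeans_profiles(pmx, config$k, config$max_iter,
                                        seed = config$seed))
    clusters <- km
    tsv(data.frame(gene_id = names(km$assignments),
                   cluster = unname(km$assignments)),
        "cluster_assignments.tsv")
  }

  log_stage("expression integration")
  expr_f <- filter_low_expression(inputs$expression, config$min_count)
  norm <- normalize_expression(expr_f)
  expr_summary <- suppressWarnings(
    expression_by_category(norm$line_means, categories[[1]]))
  tsv(expr_summary$summary, "expression_by_category.tsv")
  tsv(expr_summary$ratios, "expression_ratios.tsv")

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("marked_fe", "differential_fe", "percentile",
                          "flank", "k", "max_iter", "alpha", "p_threshold",
                          "min_count")],
    synthetic = !is.null(config$synthetic),
    n_promoters = nrow(inputs$promoters),
    universe_size = length(mm$universe),
    package_version = as.character(utils::packageVersion("markscape")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(inputs = inputs, enrichment = enr,
                 chrom_medians = chrom_medians, marked = mm, venns = venns,
                 strata = strata, differential = diffs,
                 categories = categories, overrep = results_by_query,
                 heat = heat, profiles = profiles, aggregates = aggregates,
                 clusters = clusters, expression = expr_summary,
                 normalized = norm))
}
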