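#' Configuration for the synthetic ChIP / expression generator
#'
#' Bundles every knob of the synthetic study: gene models, negative-binomial
#' promoter counts for two histone marks across cell lines plus input,
#' binned TSS coverage, planted differential gene sets, and expression
#' counts coupled to promoter acetylation. With a fixed \code{seed} all
#' generators are bit-reproducible.
#'
#' The negative binomial is parameterized by (mean, dispersion) with
#' variance \code{mu + dispersion * mu^2} (the standard overdispersed count
#' model for sequencing data). Marked promoters draw a latent fold
#' enrichment from a log-normal truncated to >= 4 so that "marked" is
#' identifiable against the downstream FE >= 4 classification cutoff;
#' unmarked promoters sit at latent FE = 1.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of chromosomes genes are spread over (default 4).
#' @param chrom_size Chromosome length in bp (default 1e7).
#' @param flank Promoter half-width in bp (default 1000).
#' @param profile_flank Half-width for binned TSS coverage (default 2000).
#' @param bin_width Coverage bin width in bp; must divide
#'   \code{2 * profile_flank} (default 100).
#' @param cell_lines Cell line names (default three lines).
#' @param marks Histone mark names (default \code{c("me3", "ac")}).
#' @param replicates Expression replicates per cell line (default 3).
#' @param depth Expected total aligned reads per sample (default 1e6).
#' @param promoter_load Fraction of a library's reads expected to fall in
#'   promoter windows at FE = 1 (default 0.1); emulates promoters being a
#'   small slice of the genome so ChIP enrichment at promoters does not
#'   materially inflate a library's total read count.
#' @param marked_fraction Probability a promoter is marked, per cell line
#'   and mark (default 0.2).
#' @param fe_marked_logmean,fe_marked_logsd Log-normal (natural-log)
#'   parameters of latent FE for marked promoters, truncated to >= 4
#'   (defaults \code{log(10)} and 0.6: median marked FE around 10-fold,
#'   typical of promoter marks such as H3K4me3).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param planted_sets List of planted differential gene sets; each element
#'   a list with \code{name}, \code{n_genes}, \code{cell_line}, \code{mark},
#'   \code{fold} (multiplier >= 1 applied to latent FE in the target
#'   line/mark).
#' @param expr_base Baseline expression mean (default 100).
#' @param expr_coupling Multiplicative expression effect per unit of
#'   log2 acetylation FE (default 2: a 16-fold-acetylated promoter is
#'   expected 16-fold more expressed than an unmarked one).
#' @param seed Integer seed (default 1).
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 2000, n_chroms = 4, chrom_size = 1e7,
                             flank = 1000, profile_flank = 2000,
                             bin_width = 100,
                             cell_lines = c("lineA", "lineB", "lineC"),
                             marks = c("me3", "ac"), replicates = 3,
                             depth = 1e6, promoter_load = 0.1,
                             marked_fraction = 0.2,
                             fe_marked_logmean = log(10),
                             fe_marked_logsd = 0.6,
                             nb_dispersion = 0.1,
                             planted_sets = list(),
                             expr_base = 100, expr_coupling = 2, seed = 1) {
  stopifnot(n_genes >= 0, n_chroms >= 1, depth > 0,
            marked_fraction >= 0, marked_fraction <= 1,
            promoter_load > 0, promoter_load <= 1,
            nb_dispersion > 0, expr_base > 0, expr_coupling > 0)
  if ((2 * profile_flank) %% bin_width != 0)
    stop("bin_width must divide the profile span (2 * profile_flank)")
  for (ps in planted_sets) {
    stopifnot(all(c("name", "n_genes", "cell_line", "mark", "fold")
                  %in% names(ps)))
    if (ps$fold < 1) stop("planted fold multiplier must be >= 1")
    if (!ps$cell_line %in% cell_lines || !ps$mark %in% marks)
      stop("planted set '", ps$name, "' targets an unknown cell line or mark")
  }
  structure(list(
    n_genes = n_genes, n_chroms = n_chroms, chrom_size = chrom_size,
    flank = flank, profile_flank = profile_flank, bin_width = bin_width,
    cell_lines = cell_lines, marks = marks, replicates = replicates,
    depth = depth, promoter_load = promoter_load,
    marked_fraction = marked_fraction,
    fe_marked_logmean = fe_marked_logmean, fe_marked_logsd = fe_marked_logsd,
    nb_dispersion = nb_dispersion, planted_sets = planted_sets,
    expr_base = expr_base, expr_coupling = expr_coupling,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Stage-specific sub-seed so each generator is independently reproducible.
stage_seed <- function(seed, stage) {
  offset <- c(models = 11L, fe = 23L, chip = 37L, coverage = 53L,
              expression = 71L, sets = 89L)[[stage]]
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

# rnbinom in (mean, dispersion) parameterization: var = mu + disp * mu^2.
rnbinom_md <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate gene models on evenly spaced, non-overlapping promoters
#'
#' Genes are laid out evenly within each chromosome with spacing of at
#' least \code{4 * flank}, so TSS +/- flank promoter windows can never
#' overlap (nor touch a window extended to twice the flank). Strands
#' alternate. The layout is fully deterministic.
#'
#' @param config A \code{synthetic_config}.
#' @return List with \code{genes} (gene-model data.frame) and
#'   \code{chrom_sizes} (named vector).
#' @export
simulate_gene_models <- function(config) {
  if (config$n_genes < 1) stop("config error: n_genes must be >= 1")
  n <- config$n_genes
  nc <- min(config$n_chroms, n)
  per_chrom <- rep(n %/% nc, nc)
  extra <- n %% nc
  if (extra) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
  spacing <- floor(config$chrom_size / (max(per_chrom) + 1))
  if (spacing < 4 * config$flank)
    stop("config error: chrom_size too small to space ", max(per_chrom),
         " genes at >= 4 * flank")
  chrom_names <- paste0("chr", seq_len(nc))
  chrom <- rep(chrom_names, per_chrom)
  idx_within <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  tss <- idx_within * spacing
  ids <- sprintf("G%05d", seq_len(n))
  genes <- data.frame(
    gene_id = ids, gene_name = ids, chrom = chrom,
    strand = rep_len(c("+", "-"), n), tss = tss,
    biotype = "protein_coding", stringsAsFactors = FALSE
  )
  list(genes = genes,
       chrom_sizes = setNames(rep(config$chrom_size, nc), chrom_names))
}

# Deterministic membership of planted sets (shared by the count generator
# and the gene-set builder). Sets are drawn sequentially without replacement
# so planted sets are disjoint.
planted_set_members <- function(config, gene_ids) {
  if (!length(config$planted_sets)) return(list())
  set.seed(stage_seed(config$seed, "sets"))
  pool <- gene_ids
  out <- list()
  for (ps in config$planted_sets) {
    if (ps$n_genes > length(pool))
      stop("not enough genes left to plant set '", ps$name, "'")
    members <- sample(pool, ps$n_genes)
    pool <- setdiff(pool, members)
    out[[ps$name]] <- members
  }
  out
}

# Latent per-promoter fold enrichment for every cell line x mark:
# 1 for unmarked, truncated log-normal (>= 4) for marked, then planted
# multipliers applied to the targeted line/mark.
simulate_latent_fe <- function(config, gene_ids) {
  set.seed(stage_seed(config$seed, "fe"))
  n <- length(gene_ids)
  grid <- expand.grid(cell_line = config$cell_lines, mark = config$marks,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    marked <- stats::runif(n) < config$marked_fraction
    fe <- rep(1, n)
    if (any(marked)) {
      p_lo <- stats::plnorm(4, config$fe_marked_logmean, config$fe_marked_logsd)
      u <- stats::runif(sum(marked), p_lo, 1)
      fe[marked] <- stats::qlnorm(u, config$fe_marked_logmean,
                                  config$fe_marked_logsd)
    }
    rows[[i]] <- data.frame(gene_id = gene_ids,
                            cell_line = grid$cell_line[i],
                            mark = grid$mark[i], fe = fe,
                            stringsAsFactors = FALSE)
  }
  latent <- do.call(rbind, rows)
  planted <- planted_set_members(config, gene_ids)
  for (ps in config$planted_sets) {
    hit <- latent$gene_id %in% planted[[ps$name]] &
      latent$cell_line == ps$cell_line & latent$mark == ps$mark
    latent$fe[hit] <- latent$fe[hit] * ps$fold
  }
  attr(latent, "planted") <- planted
  latent
}

#' Simulate ChIP and input promoter read counts
#'
#' For each cell line, an input library and one treatment library per mark
#' are simulated over the promoter set. Input counts are negative binomial
#' with mean proportional to promoter length at the configured sequencing
#' depth; treatment counts multiply that mean by the promoter's latent FE.
#' Per-sample totals are set to the nominal library depth: promoters carry
#' only a \code{promoter_load} fraction of a library, so promoter-level
#' enrichment leaves the library total essentially unchanged, and the
#' RPKM-ratio estimator downstream is unbiased for the latent FE.
#'
#' @param config A \code{synthetic_config}.
#' @param promoters Promoter data.frame from \code{\link{derive_promoters}}.
#' @return List with \code{treatment} (nested list
#'   \code{[[cell_line]][[mark]]} of \code{count_table}), \code{input}
#'   (list \code{[[cell_line]]} of \code{count_table}), and \code{latent}
#'   (long data.frame gene_id x cell_line x mark with latent \code{fe};
#'   planted-set membership in \code{attr(latent, "planted")}).
#' @export
simulate_chip_counts <- function(config, promoters) {
  latent <- simulate_latent_fe(config, promoters$gene_id)
  set.seed(stage_seed(config$seed, "chip"))
  lengths <- promoters$end - promoters$start
  mu_input <- config$depth * config$promoter_load * lengths / sum(lengths)
  n <- nrow(promoters)
  treatment <- list()
  input <- list()
  for (cl in config$cell_lines) {
    icounts <- rnbinom_md(n, mu_input, config$nb_dispersion)
    imat <- matrix(icounts, ncol = 1,
                   dimnames = list(promoters$gene_id, paste0(cl, "_input")))
    input[[cl]] <- count_table(imat,
                               totals = max(config$depth, sum(icounts)),
                               lengths = lengths)
    treatment[[cl]] <- list()
    for (mk in config$marks) {
      fe <- latent$fe[latent$cell_line == cl & latent$mark == mk]
      tcounts <- rnbinom_md(n, mu_input * fe, config$nb_dispersion)
      tmat <- matrix(tcounts, ncol = 1,
                     dimnames = list(promoters$gene_id,
                                     paste0(cl, "_", mk)))
      treatment[[cl]][[mk]] <- count_table(
        tmat, totals = max(config$depth, sum(tcounts)), lengths = lengths)
    }
  }
  list(treatment = treatment, input = input, latent = latent)
}

#' Simulate binned TSS coverage for profile analyses
#'
#' Bins span TSS +/- \code{profile_flank} at \code{bin_width} resolution.
#' The expected treatment signal in a bin is
#' \code{input_level * (1 + (FE - 1) * g(bin))} where \code{g} is a
#' unit-height Gaussian centred on the TSS bin with sd 500 bp: a marked
#' promoter shows a peak over the TSS decaying to input level at the window
#' edges, while an FE = 1 promoter is flat. Counts are negative binomial.
#' Bins are emitted in genomic (left-to-right) order; downstream profile
#' code reorients minus-strand promoters.
#'
#' @param config A \code{synthetic_config}.
#' @param promoters Promoter data.frame (used for ids and strand).
#' @param latent Latent FE table from \code{\link{simulate_chip_counts}}.
#' @return List with \code{treatment} (\code{[[cell_line]][[mark]]}
#'   promoter x bin count matrices), \code{input} (\code{[[cell_line]]}),
#'   \code{bin_mids} (bp relative to TSS, genomic order), and \code{totals}
#'   (nominal per-library depth).
#' @export
simulate_binned_coverage <- function(config, promoters, latent) {
  set.seed(stage_seed(config$seed, "coverage"))
  n_bins <- (2 * config$profile_flank) / config$bin_width
  bin_mids <- seq(-config$profile_flank + config$bin_width / 2,
                  config$profile_flank - config$bin_width / 2,
                  by = config$bin_width)
  g <- exp(-bin_mids^2 / (2 * 500^2))
  n <- nrow(promoters)
  # per-bp input rate matches the promoter count generator
  input_level <- config$depth * config$promoter_load * config$bin_width /
    sum(promoters$end - promoters$start)
  treatment <- list()
  input <- list()
  for (cl in config$cell_lines) {
    imat <- matrix(rnbinom_md(n * n_bins, input_level, config$nb_dispersion),
                   nrow = n, dimnames = list(promoters$gene_id, NULL))
    input[[cl]] <- imat
    treatment[[cl]] <- list()
    for (mk in config$marks) {
      fe <- latent$fe[latent$cell_line == cl & latent$mark == mk]
      mu <- input_level * (1 + outer(fe - 1, g))
      tmat <- matrix(rnbinom_md(length(mu), as.vector(mu),
                                config$nb_dispersion),
                     nrow = n, dimnames = list(promoters$gene_id, NULL))
      treatment[[cl]][[mk]] <- tmat
    }
  }
  list(treatment = treatment, input = input, bin_mids = bin_mids,
       totals = config$depth)
}

#' Simulate expression counts coupled to promoter acetylation
#'
#' Gene-level RNA-seq counts for every cell line and replicate. The
#' expected count is \code{expr_base * expr_coupling^(log2 FE_ac)} in that
#' cell line, so acetylated promoters drive proportionally higher
#' expression; replicates share the same mean. Counts are negative
#' binomial with the configured dispersion.
#'
#' @param config A \code{synthetic_config}.
#' @param latent Latent FE table from \code{\link{simulate_chip_counts}}.
#' @return A \code{count_table} (genes x cell_line:replicate samples);
#'   sample names are \code{<cell_line>_rep<i>}.
#' @export
simulate_expression <- function(config, latent) {
  set.seed(stage_seed(config$seed, "expression"))
  ac <- latent[latent$mark == "ac", ]
  gene_ids <- unique(ac$gene_id)
  n <- length(gene_ids)
  samples <- character(0)
  cols <- list()
  for (cl in config$cell_lines) {
    fe_ac <- ac$fe[ac$cell_line == cl][match(gene_ids,
                                             ac$gene_id[ac$cell_line == cl])]
    mu <- config$expr_base * config$expr_coupling^(log2(fe_ac))
    for (r in seq_len(config$replicates)) {
      cols[[length(cols) + 1L]] <- rnbinom_md(n, mu, config$nb_dispersion)
      samples <- c(samples, paste0(cl, "_rep", r))
    }
  }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(gene_ids, samples)
  count_table(mat, lengths = rep(1000, n))
}

#' Build a gene-set collection with planted and random sets
#'
#' The planted sets configured in \code{config} (with membership identical
#' to what \code{\link{simulate_chip_counts}} used) are combined with
#' random sets drawn uniformly from the gene universe, producing the GMT
#' collection the over-representation stage queries. The universe size is
#' the number of genes supplied.
#'
#' @param config A \code{synthetic_config}.
#' @param gene_ids Character vector: the gene universe.
#' @param n_random Number of random decoy sets (default 50).
#' @param random_size Size of each random set (default 100).
#' @return A \code{gene_set_collection}.
#' @export
simulate_gene_sets <- function(config, gene_ids, n_random = 50,
                               random_size = 100) {
  planted <- planted_set_members(config, gene_ids)
  set.seed(stage_seed(config$seed, "sets") + 1L)
  random_size <- min(random_size, length(gene_ids))
  sets <- planted
  for (i in seq_len(n_random)) {
    sets[[sprintf("RANDOM_%03d", i)]] <- sample(gene_ids, random_size)
  }
  structure(list(sets = sets,
                 descriptions = setNames(rep("synthetic", length(sets)),
                                         names(sets)),
                 universe_size = length(gene_ids)),
            class = "gene_set_collection")
}
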