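#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for count normalization: for each sample,
#' the median over reference genes of the ratio of its count to the gene's
#' geometric mean across samples. Reference genes are those with strictly
#' positive counts in every sample. Exact scale-equivariance holds: if one
#' sample's counts are exactly c times another's, their factors differ by
#' exactly c.
#'
#' @param counts Numeric matrix, genes x samples.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; cannot normalize")
  x <- counts[ref, , drop = FALSE]
  log_geomean <- rowMeans(log(x))
  f <- apply(x, 2, function(col) exp(stats::median(log(col) - log_geomean)))
  setNames(f, colnames(counts))
}

#' Remove genes with very low expression
#'
#' A gene is kept when its count aggregated across samples reaches
#' \code{min_count} (default 3: genes with fewer than 3 counts are
#' removed). The aggregation is the maximum across samples by default;
#' \code{"mean"} and \code{"total"} are available.
#'
#' @param counts Numeric matrix, genes x samples (or a \code{count_table}).
#' @param min_count Minimum count (default 3); retention is
#'   \code{aggregate >= min_count}.
#' @param aggregate One of \code{"max"}, \code{"mean"}, \code{"total"}.
#' @return The filtered matrix (or \code{count_table}).
#' @export
filter_low_expression <- function(counts, min_count = 3,
                                  aggregate = c("max", "mean", "total")) {
  stopifnot(min_count >= 0)
  aggregate <- match.arg(aggregate)
  is_ct <- inherits(counts, "count_table")
  mat <- if (is_ct) counts$counts else as.matrix(counts)
  stat <- switch(aggregate,
                 max = apply(mat, 1, max),
                 mean = rowMeans(mat),
                 total = rowSums(mat))
  keep <- stat >= min_count
  if (is_ct) {
    counts$counts <- mat[keep, , drop = FALSE]
    counts$lengths <- counts$lengths[keep]
    counts
  } else {
    mat[keep, , drop = FALSE]
  }
}

#' Normalize expression counts and average replicates per cell line
#'
#' Divides raw counts by median-of-ratios size factors, then averages the
#' normalized counts across each cell line's replicates (replicate sample
#' names must be \code{<cell_line>_rep<i>} or be mapped via
#' \code{sample_lines}). The log2 of the per-line mean (with a +1 offset
#' for display) is included for plotting.
#'
#' @param counts Numeric matrix genes x samples, or \code{count_table}.
#' @param sample_lines Optional character vector mapping each sample to its
#'   cell line; by default the part of the sample name before
#'   \code{"_rep"}.
#' @return List with \code{normalized} (genes x samples),
#'   \code{size_factors}, \code{line_means} (genes x cell lines),
#'   \code{log2_line_means}.
#' @export
normalize_expression <- function(counts, sample_lines = NULL) {
  mat <- if (inherits(counts, "count_table")) counts$counts else
    as.matrix(counts)
  sf <- size_factors(mat)
  normalized <- sweep(mat, 2, sf, "/")
  if (is.null(sample_lines))
    sample_lines <- sub("_rep[0-9]+$", "", colnames(mat))
  lines <- unique(sample_lines)
  line_means <- sapply(lines, function(cl)
    rowMeans(normalized[, sample_lines == cl, drop = FALSE]))
  list(normalized = normalized, size_factors = sf,
       line_means = line_means, log2_line_means = log2(line_means + 1))
}

#' Median expression by mark category
#'
#' For a pairwise cell-line comparison, summarizes normalized expression of
#' promoters in each mark category (\code{ac_only}, \code{me3_only},
#' \code{both}) by the median normalized count per gaining cell line, and
#' reports fold ratios between categories (the reference worked example is
#' 617.36 vs 100.43 for ac_only over me3_only, a > 6-fold difference).
#' An empty category yields an NA median with a warning.
#'
#' @param line_means Genes x cell-lines matrix of mean normalized counts
#'   (from \code{\link{normalize_expression}}).
#' @param categories data.frame from \code{\link{assign_mark_category}}.
#' @return List with \code{summary} (data.frame: cell_line, category, n,
#'   median), \code{ratios} (data.frame: cell_line, ac_only over me3_only
#'   etc.), and \code{genes} (per-gene table for scatter plots: gene_id,
#'   cell_line, category, log2 expression).
#' @export
expression_by_category <- function(line_means, categories) {
  cats <- c("ac_only", "me3_only", "both")
  lines <- unique(categories$cell_line)
  rows <- list()
  gene_rows <- list()
  for (cl in lines) {
    sub <- categories[categories$cell_line == cl &
                        categories$category %in% cats, ]
    for (ct in cats) {
      ids <- sub$gene_id[sub$category == ct]
      ids <- ids[ids %in% rownames(line_means)]
      med <- if (length(ids)) stats::median(line_means[ids, cl]) else {
        warning("no genes in category '", ct, "' for ", cl)
        NA_real_
      }
      rows[[paste(cl, ct)]] <- data.frame(
        cell_line = cl, category = ct, n = length(ids), median = med,
        stringsAsFactors = FALSE)
      if (length(ids))
        gene_rows[[paste(cl, ct)]] <- data.frame(
          gene_id = ids, cell_line = cl, category = ct,
          log2_expr = log2(line_means[ids, cl] + 1),
          stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  ratios <- do.call(rbind, lapply(lines, function(cl) {
    s <- summary[summary$cell_line == cl, ]
    med <- setNames(s$median, s$category)
    data.frame(cell_line = cl,
               ac_over_me3 = unname(med["ac_only"] / med["me3_only"]),
               both_over_me3 = unname(med["both"] / med["me3_only"]),
               stringsAsFactors = FALSE)
  }))
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), cell_line = character(0),
               category = character(0), log2_expr = numeric(0))
  rownames(genes) <- NULL
  list(summary = summary, ratios = ratios, genes = genes)
}
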