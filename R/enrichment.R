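#' Reads per kilobase per million (RPKM)
#'
#' \code{rpkm = count * 1e9 / (total_aligned_reads * length_bp)}. The same
#' density normalization is used for promoters (promoter length) and whole
#' chromosomes (chromosome length), so fold enrichment is a ratio of
#' densities on a common scale.
#'
#' @param ct A \code{count_table}.
#' @return Numeric matrix of RPKM values, features x samples.
#' @export
compute_rpkm <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  if (any(ct$totals <= 0)) stop("zero or negative sample total")
  sweep(ct$counts * 1e9 / ct$lengths, 2, ct$totals, "/")
}

#' Floor an input RPKM vector at a low percentile
#'
#' Input (control) densities near zero make fold-enrichment ratios blow up;
#' each input value is therefore raised to at least the given percentile of
#' all input RPKM values of that sample (default the 5th percentile,
#' linear interpolation on the sorted values). If the percentile is zero,
#' the smallest positive value stands in; an all-zero input vector is an
#' error because no positive floor exists.
#'
#' The operation is monotone, and re-applying the computed floor is the
#' identity (re-estimating an interpolated percentile on a floored vector
#' would land slightly above it, so the pipeline floors once per sample).
#'
#' @param rpkm_input Numeric vector of input RPKM values for one sample.
#' @param percentile Percentile in [0, 100] (default 5).
#' @return The floored vector, with the floor in \code{attr(,"floor")}.
#' @export
floor_input <- function(rpkm_input, percentile = 5) {
  if (!length(rpkm_input)) stop("empty input RPKM vector")
  p <- unname(stats::quantile(rpkm_input, percentile / 100, type = 7))
  if (p <= 0) {
    pos <- rpkm_input[rpkm_input > 0]
    if (!length(pos))
      stop("all-zero input RPKM vector: cannot form a positive floor")
    p <- min(pos)
  }
  out <- pmax(rpkm_input, p)
  attr(out, "floor") <- p
  out
}

# log2 with the package-wide epsilon: linear FE keeps true zeros, the log
# scale is floored at 2^-10.
LOG2_EPS <- 2^-10

#' Fold enrichment of treatment over floored input
#'
#' \code{fe = rpkm_treatment / rpkm_input_floored};
#' \code{log2_fe = log2(max(fe, 2^-10))} so zero-treatment promoters map to
#' -10 rather than -Inf while linear FE retains the true zero.
#'
#' @param rpkm_treatment,rpkm_input_floored Equal-length numeric vectors;
#'   the input must already be floored (strictly positive).
#' @return data.frame with \code{rpkm_t}, \code{rpkm_i_floored}, \code{fe},
#'   \code{log2_fe}.
#' @export
compute_fe <- function(rpkm_treatment, rpkm_input_floored) {
  if (length(rpkm_treatment) != length(rpkm_input_floored))
    stop("treatment and input vectors differ in length")
  if (any(rpkm_input_floored <= 0))
    stop("input must be floored (strictly positive) before computing FE")
  fe <- rpkm_treatment / rpkm_input_floored
  data.frame(rpkm_t = rpkm_treatment, rpkm_i_floored = rpkm_input_floored,
             fe = fe, log2_fe = log2(pmax(fe, LOG2_EPS)))
}

#' Promoter enrichment table across marks and cell lines
#'
#' Convenience wrapper running RPKM, the input floor and FE for every
#' (cell line, mark) pair of a simulated or loaded experiment, producing
#' the long per-promoter enrichment table the downstream stages consume.
#'
#' @param treatment Nested list \code{[[cell_line]][[mark]]} of
#'   \code{count_table} (one sample each).
#' @param input List \code{[[cell_line]]} of input \code{count_table}.
#' @param promoters Promoter data.frame (adds \code{chrom} to the output).
#' @param percentile Input floor percentile (default 5).
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{mark}, \code{cell_line}, \code{rpkm_t}, \code{rpkm_i_floored},
#'   \code{fe}, \code{log2_fe}.
#' @export
enrichment_table <- function(treatment, input, promoters, percentile = 5) {
  out <- list()
  for (cl in names(treatment)) {
    rpkm_i <- compute_rpkm(input[[cl]])[, 1]
    rpkm_i_floored <- floor_input(rpkm_i, percentile)
    for (mk in names(treatment[[cl]])) {
      ct <- treatment[[cl]][[mk]]
      rpkm_t <- compute_rpkm(ct)[, 1]
      fe <- compute_fe(rpkm_t, as.numeric(rpkm_i_floored))
      out[[paste(cl, mk)]] <- data.frame(
        gene_id = rownames(ct$counts),
        chrom = promoters$chrom[match(rownames(ct$counts),
                                      promoters$gene_id)],
        mark = mk, cell_line = cl, fe, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chromosome-level fold enrichment
#'
#' RPKM per chromosome (total aligned reads, chromosome length) for
#' treatment and input, and their ratio. No input floor is applied at
#' chromosome scale; a chromosome with zero input density is an error.
#'
#' @param treat_counts,input_counts Named numeric vectors of read counts
#'   per chromosome.
#' @param treat_total,input_total Total aligned reads of each library.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return data.frame with \code{chrom}, \code{rpkm_t}, \code{rpkm_i},
#'   \code{fe}, \code{log2_fe} (log2 FE is the display convention).
#' @export
chromosome_fe <- function(treat_counts, input_counts, treat_total,
                          input_total, chrom_lengths) {
  chroms <- names(chrom_lengths)
  stopifnot(!is.null(chroms), all(chroms %in% names(treat_counts)),
            all(chroms %in% names(input_counts)))
  rpkm_t <- treat_counts[chroms] * 1e9 / (treat_total * chrom_lengths)
  rpkm_i <- input_counts[chroms] * 1e9 / (input_total * chrom_lengths)
  if (any(rpkm_i == 0))
    stop("zero input RPKM on chromosome(s): ",
         paste(chroms[rpkm_i == 0], collapse = ", "))
  fe <- rpkm_t / rpkm_i
  data.frame(chrom = chroms, rpkm_t = unname(rpkm_t),
             rpkm_i = unname(rpkm_i), fe = unname(fe),
             log2_fe = unname(log2(pmax(fe, LOG2_EPS))),
             stringsAsFactors = FALSE)
}

#' Median promoter FE per chromosome
#'
#' Medians of per-promoter FE grouped by chromosome, for each mark and cell
#' line present in the enrichment table (the per-chromosome summary used to
#' compare marks across conditions). Chromosomes without promoters are
#' simply absent; requesting specific chromosomes that lack promoters
#' raises a warning.
#'
#' @param enrichment Long enrichment table (\code{\link{enrichment_table}}).
#' @param chroms Optional chromosome names to report on.
#' @return data.frame with \code{chrom}, \code{mark}, \code{cell_line},
#'   \code{median_fe}.
#' @export
median_promoter_fe_by_chrom <- function(enrichment, chroms = NULL) {
  if (!is.null(chroms)) {
    empty <- setdiff(chroms, unique(enrichment$chrom))
    if (length(empty))
      warning("no promoters on chromosome(s): ",
              paste(empty, collapse = ", "), "; omitted")
    enrichment <- enrichment[enrichment$chrom %in% chroms, ]
  }
  agg <- stats::aggregate(fe ~ chrom + mark + cell_line, data = enrichment,
                          FUN = stats::median)
  names(agg)[names(agg) == "fe"] <- "median_fe"
  agg[order(agg$cell_line, agg$mark, agg$chrom), , drop = FALSE]
}

#' Classify marked promoters
#'
#' A promoter is marked for a given mark and cell line when its fold
#' enrichment over input reaches the threshold (inclusive, default
#' 4-fold). Also computes the analysis universe: promoters marked for at
#' least one mark in at least one cell line.
#'
#' @param enrichment Long enrichment table.
#' @param threshold FE cutoff (default 4; \code{fe >= threshold} is marked).
#' @return Object of class \code{marked_matrix}: list with \code{marked}
#'   (logical matrix, promoters x "cell_line.mark" columns),
#'   \code{universe} (character vector of marked gene ids) and
#'   \code{threshold}.
#' @export
classify_marked <- function(enrichment, threshold = 4) {
  stopifnot(threshold > 0)
  key <- paste(enrichment$cell_line, enrichment$mark, sep = ".")
  genes <- unique(enrichment$gene_id)
  cols <- unique(key)
  marked <- matrix(FALSE, nrow = length(genes), ncol = length(cols),
                   dimnames = list(genes, cols))
  marked[cbind(match(enrichment$gene_id, genes), match(key, cols))] <-
    enrichment$fe >= threshold
  structure(list(marked = marked,
                 universe = genes[rowSums(marked) > 0],
                 threshold = threshold),
            class = "marked_matrix")
}

#' Three-way Venn partition of marked promoters
#'
#' For one mark across exactly three cell lines, counts the seven
#' membership regions of the Venn diagram of marked-promoter sets, plus
#' the union and each region's percentage of the union.
#'
#' @param mm A \code{marked_matrix} from \code{\link{classify_marked}}.
#' @param mark Mark name.
#' @param cell_lines Character vector of exactly three cell lines; their
#'   order fixes the region labels.
#' @return List with \code{counts} (named integer vector over the 7
#'   regions, names like \code{"A"}, \code{"A&B"}, \code{"A&B&C"} using the
#'   given cell-line names), \code{union} and \code{percent}.
#' @export
venn_partition <- function(mm, mark, cell_lines) {
  if (length(cell_lines) != 3)
    stop("venn_partition requires exactly three cell lines")
  cols <- paste(cell_lines, mark, sep = ".")
  if (!all(cols %in% colnames(mm$marked)))
    stop("marked matrix lacks columns: ",
         paste(setdiff(cols, colnames(mm$marked)), collapse = ", "))
  m <- mm$marked[, cols, drop = FALSE]
  in_any <- rowSums(m) > 0
  m <- m[in_any, , drop = FALSE]
  membership <- c("100", "010", "001", "110", "101", "011", "111")
  labels <- vapply(membership, function(b) {
    paste(cell_lines[strsplit(b, "")[[1]] == "1"], collapse = "&")
  }, character(1))
  pattern <- paste0(m[, 1] + 0, m[, 2] + 0, m[, 3] + 0)
  counts <- setNames(integer(7), labels)
  tab <- table(pattern)
  counts[labels[match(names(tab), membership)]] <- as.integer(tab)
  un <- nrow(m)
  list(counts = counts, union = un,
       percent = if (un > 0) 100 * counts / un else counts * 0)
}

#' Rank the top fraction of promoters by fold enrichment
#'
#' Restricted to the analysis universe (promoters marked somewhere), the
#' promoters are ranked by descending FE for the requested mark — in one
#' cell line, or on the per-promoter maximum across cell lines when
#' \code{cell_line} is NULL — and the top \code{ceiling(fraction * N)} are
#' returned. Ties are broken by ascending gene id so the stratum is
#' deterministic. On a universe of 10,964 marked promoters this
#' yields strata of 2741 (top quartile) and 220 (top 2\%).
#'
#' @param enrichment Long enrichment table.
#' @param mm \code{marked_matrix} defining the universe.
#' @param mark Mark to rank on.
#' @param fraction Fraction in (0, 1].
#' @param cell_line Cell line, or NULL for the max across lines.
#' @return data.frame of the stratum: \code{gene_id}, \code{fe}, in rank
#'   order.
#' @export
rank_top_fraction <- function(enrichment, mm, mark, fraction,
                              cell_line = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!length(mm$universe)) stop("empty analysis universe")
  sub <- enrichment[enrichment$mark == mark &
                      enrichment$gene_id %in% mm$universe, ]
  if (!is.null(cell_line)) sub <- sub[sub$cell_line == cell_line, ]
  fe_by_gene <- tapply(sub$fe, sub$gene_id, max)
  genes <- names(fe_by_gene)
  ord <- order(-fe_by_gene, genes)
  n_top <- ceiling(fraction * length(genes))
  data.frame(gene_id = genes[ord][seq_len(n_top)],
             fe = unname(fe_by_gene[ord][seq_len(n_top)]),
             stringsAsFactors = FALSE)
}
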