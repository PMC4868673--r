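#' Derive promoter windows around transcription start sites
#'
#' Builds one fixed-width promoter region per gene, centred on the gene's TSS
#' and extended by \code{flank} bp on each side. Coordinates are 0-based
#' half-open throughout the package; windows are clamped to chromosome
#' boundaries, so a promoter near an end may be narrower than \code{2 * flank}.
#'
#' Strand does not change the window (it is symmetric about the TSS); it is
#' carried through so downstream profile code can orient bins 5' to 3'.
#'
#' @param genes data.frame of gene models with columns \code{gene_id},
#'   \code{chrom}, \code{strand} (\code{"+"} or \code{"-"}), \code{tss}
#'   (0-based coordinate). Extra columns are ignored.
#' @param flank Half-width of the promoter window in bp (default 1000,
#'   giving the standard TSS +/- 1 kb promoter).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, one row per input gene in
#'   input order.
#' @export
derive_promoters <- function(genes, flank = 1000, chrom_sizes) {
  stopifnot(is.data.frame(genes), flank > 0)
  req <- c("gene_id", "chrom", "strand", "tss")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols))
    stop("gene models lack column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) absent from chrom_sizes: ", paste(unknown, collapse = ", "))
  sizes <- chrom_sizes[genes$chrom]
  bad <- genes$tss < 0 | genes$tss >= sizes
  if (any(bad))
    stop("TSS outside chromosome for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  data.frame(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(0, genes$tss - flank),
    end = pmin(unname(sizes), genes$tss + flank),
    strand = genes$strand,
    stringsAsFactors = FALSE
  )
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields are
#' set name, description, then member genes. Duplicate genes within a set
#' are dropped (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @param universe_size Optional override for the universe size. By default
#'   it is the number of unique genes across all sets (the convention used
#'   for the binomial over-representation test, where the standard
#'   collection-wide constant is 21439).
#' @return An object of class \code{gene_set_collection}: list with
#'   \code{sets} (named list of character vectors), \code{descriptions}
#'   and \code{universe_size}.
#' @export
read_gmt <- function(path, universe_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nm <- fields[[1]]
    if (nm %in% names(sets))
      stop("duplicate gene set name: ", nm)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes
    desc[[nm]] <- fields[[2]]
  }
  n_universe <- if (is.null(universe_size))
    length(unique(unlist(sets, use.names = FALSE))) else universe_size
  structure(list(sets = sets, descriptions = desc, universe_size = n_universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  nms <- names(collection$sets)
  desc <- collection$descriptions
  if (is.null(desc)) desc <- setNames(rep("na", length(nms)), nms)
  lines <- vapply(nms, function(nm) {
    paste(c(nm, desc[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write promoter regions as BED6
#'
#' Six columns (chrom, start, end, name, score, strand), 0-based half-open —
#' the BED convention, which matches the package's internal coordinates.
#' Score is written as 0.
#'
#' @param regions Promoter data.frame from \code{\link{derive_promoters}}.
#' @param path Output path.
#' @export
write_promoters_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = regions$gene_id,
    score = rep(0L, nrow(regions)),
    strand = regions$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 promoter file written by \code{write_promoters_bed}
#'
#' @param path BED6 path.
#' @return Promoter data.frame (gene_id, chrom, start, end, strand).
#' @export
read_promoters_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "numeric", "character"))
  data.frame(gene_id = bed[[4]], chrom = bed[[1]], start = bed[[2]],
             end = bed[[3]], strand = bed[[6]], stringsAsFactors = FALSE)
}

#' Construct a count table
#'
#' The package's container for per-feature read counts: an integer matrix
#' (features x samples) plus per-sample total aligned reads and per-feature
#' lengths in bp. Totals may exceed column sums (reads aligned outside the
#' counted features).
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param totals Per-sample total aligned reads; defaults to column sums.
#' @param lengths Per-feature length in bp.
#' @return Object of class \code{count_table}.
#' @export
count_table <- function(counts, totals = colSums(counts), lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature ids (rownames) and sample ids (colnames)")
  if (length(totals) != ncol(counts))
    stop("totals length must match number of samples")
  if (any(totals < colSums(counts)))
    stop("totals must be >= column sums of counts")
  if (length(lengths) != nrow(counts))
    stop("lengths must match number of features")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  structure(list(counts = counts,
                 totals = setNames(as.numeric(totals), colnames(counts)),
                 lengths = setNames(as.numeric(lengths), rownames(counts))),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  totals:", paste(format(x$totals, big.mark = ","), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a count table from TSV
#'
#' Layout: a header row (\code{feature_id}, \code{length}, then one column
#' per sample); optionally a first metadata line \code{#totals:<tab>v1<tab>v2...}
#' giving per-sample total aligned reads in column order. When the totals
#' line is absent, totals fall back to column sums and a warning is raised.
#'
#' @param path TSV path.
#' @return A \code{count_table}.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  totals <- NULL
  if (length(lines) && startsWith(lines[[1]], "#totals:")) {
    totals <- as.numeric(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][-1])
    lines <- lines[-1]
  }
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "length") %in% names(tab)))
    stop("count table needs 'feature_id' and 'length' columns")
  sample_cols <- setdiff(names(tab), c("feature_id", "length"))
  if (!length(sample_cols)) stop("count table has no sample columns")
  mat <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count cell in table")
  bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at row ", bad[1, 1],
         ", sample '", sample_cols[bad[1, 2]], "'")
  rownames(mat) <- tab$feature_id
  if (is.null(totals)) {
    warning("no '#totals:' line; using column sums as totals")
    totals <- colSums(mat)
  }
  count_table(mat, totals = totals, lengths = tab$length)
}

#' Write a count table to TSV (with a #totals: metadata line)
#'
#' @param ct A \code{count_table}.
#' @param path Output path.
#' @export
write_count_table <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#totals:", format(ct$totals, scientific = FALSE,
                                        trim = TRUE)), collapse = "\t"), con)
  tab <- data.frame(feature_id = rownames(ct$counts),
                    length = unname(ct$lengths),
                    ct$counts, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
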