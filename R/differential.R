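#' Pairwise differential fold enrichment between two cell lines
#'
#' For an ordered cell-line pair (A, B) and each mark, computes
#' \code{delta = log2_fe(B) - log2_fe(A)} per promoter. A promoter is
#' differentially marked when \code{|delta| >= log2(cutoff)} (default
#' 4-fold, i.e. |delta| >= 2); the gaining cell line is B for positive
#' delta and A for negative.
#'
#' @param enrichment Long enrichment table covering both cell lines.
#' @param line_a,line_b Cell-line names (ordered pair).
#' @param cutoff Linear FE cutoff (default 4).
#' @return Object of class \code{differential_table}: data.frame with
#'   \code{gene_id}, \code{mark}, \code{log2_fe_a}, \code{log2_fe_b},
#'   \code{delta}, \code{differential}, \code{gaining}; the pair and
#'   cutoff as attributes.
#' @export
differential_fe <- function(enrichment, line_a, line_b, cutoff = 4) {
  a <- enrichment[enrichment$cell_line == line_a, ]
  b <- enrichment[enrichment$cell_line == line_b, ]
  out <- list()
  for (mk in unique(enrichment$mark)) {
    am <- a[a$mark == mk, ]
    bm <- b[b$mark == mk, ]
    sym_diff <- length(setdiff(am$gene_id, bm$gene_id)) +
      length(setdiff(bm$gene_id, am$gene_id))
    if (sym_diff > 0)
      stop("promoter universes differ between cell lines for mark '", mk,
           "' (symmetric difference: ", sym_diff, " promoters)")
    bm <- bm[match(am$gene_id, bm$gene_id), ]
    delta <- bm$log2_fe - am$log2_fe
    differential <- abs(delta) >= log2(cutoff)
    out[[mk]] <- data.frame(
      gene_id = am$gene_id, mark = mk,
      log2_fe_a = am$log2_fe, log2_fe_b = bm$log2_fe, delta = delta,
      differential = differential,
      gaining = ifelse(!differential, NA_character_,
                       ifelse(delta > 0, line_b, line_a)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pair") <- c(line_a, line_b)
  attr(res, "cutoff") <- cutoff
  class(res) <- c("differential_table", "data.frame")
  res
}

#' Assign mark categories to differentially marked promoters
#'
#' For each gaining cell line of a pairwise comparison, classifies every
#' promoter as \code{ac_only} (acetylation differential toward that line,
#' tri-methylation not), \code{me3_only}, \code{both} (both marks
#' differential toward the same line), or \code{none}. Opposite gains
#' (e.g. ac toward B but me3 toward A) never merge into \code{both}: each
#' line's category reflects only the marks gained by that line.
#'
#' @param diff A \code{differential_table} covering marks "me3" and "ac".
#' @return data.frame with \code{gene_id}, \code{cell_line} (gaining line),
#'   \code{category}; one row per promoter per line of the pair.
#' @export
assign_mark_category <- function(diff) {
  pair <- attr(diff, "pair")
  stopifnot(all(c("me3", "ac") %in% unique(diff$mark)))
  ac <- diff[diff$mark == "ac", ]
  me3 <- diff[diff$mark == "me3", ]
  me3 <- me3[match(ac$gene_id, me3$gene_id), ]
  out <- lapply(pair, function(line) {
    ac_gain <- ac$differential & ac$gaining == line
    me3_gain <- me3$differential & me3$gaining == line
    ac_gain[is.na(ac_gain)] <- FALSE
    me3_gain[is.na(me3_gain)] <- FALSE
    category <- ifelse(ac_gain & me3_gain, "both",
                       ifelse(ac_gain, "ac_only",
                              ifelse(me3_gain, "me3_only", "none")))
    data.frame(gene_id = ac$gene_id, cell_line = line, category = category,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binomial over-representation of a gene set in a query list
#'
#' Tests whether a query gene list intersects a gene set more than expected
#' by chance, with the binomial model used for promoter-mark gene lists:
#' probability of success = set size / universe size, number of trials =
#' query size, number of successes = intersection size; the p-value is the
#' inclusive upper tail \code{P(X >= k)}. The query is deduplicated; with
#' \code{restrict_universe = TRUE} (default) query genes outside the
#' collection's namespace are dropped before testing.
#'
#' @param query Character vector of query genes.
#' @param collection A \code{gene_set_collection} (its
#'   \code{universe_size} supplies the denominator; the standard
#'   collection-wide constant is 21439).
#' @param sets Optional subset of set names to test (default all).
#' @param restrict_universe Drop query genes absent from the collection's
#'   gene namespace (default TRUE); the dropped count is reported via
#'   message when non-zero.
#' @return data.frame with one row per set: \code{set}, \code{set_size},
#'   \code{query_size}, \code{intersection}, \code{p_value},
#'   \code{neg_log10_p}.
#' @export
binomial_overrep <- function(query, collection, sets = NULL,
                             restrict_universe = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (collection$universe_size <= 0) stop("universe size must be positive")
  query <- unique(query)
  if (!length(query)) stop("empty query gene list")
  if (restrict_universe) {
    namespace <- unique(unlist(collection$sets, use.names = FALSE))
    dropped <- sum(!query %in% namespace)
    if (dropped > 0)
      message(dropped, " query gene(s) absent from the collection namespace; dropped")
    query <- query[query %in% namespace]
    if (!length(query))
      stop("no query gene lies in the collection's gene namespace")
  }
  nms <- if (is.null(sets)) names(collection$sets) else sets
  n <- length(query)
  rows <- lapply(nms, function(nm) {
    members <- collection$sets[[nm]]
    if (length(members) > collection$universe_size)
      stop("set '", nm, "' larger than the universe")
    k <- length(intersect(query, members))
    p_success <- length(members) / collection$universe_size
    p <- binom_upper_tail(k, n, p_success)
    data.frame(set = nm, set_size = length(members), query_size = n,
               intersection = k, p_value = p,
               neg_log10_p = -log10(max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Inclusive upper tail P(X >= k) for X ~ Binomial(n, p).
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Bonferroni flagging of over-representation results
#'
#' Marks results significant at \code{alpha / n_tests}, or at an explicit
#' p-value threshold when one is supplied (the pipeline's default
#' Bonferroni-corrected threshold is 4.9e-9).
#'
#' @param results data.frame from \code{\link{binomial_overrep}} (possibly
#'   several queries' results bound together).
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Family size; defaults to \code{nrow(results)}.
#' @param threshold Explicit p-value threshold overriding
#'   \code{alpha / n_tests} when non-NULL.
#' @return The results with added \code{significant} logical column and the
#'   applied threshold in \code{attr(,"threshold")}.
#' @export
apply_bonferroni <- function(results, alpha = 0.05, n_tests = NULL,
                             threshold = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.null(threshold)) {
    if (is.null(n_tests)) n_tests <- nrow(results)
    threshold <- alpha / n_tests
  }
  results$significant <- results$p_value <= threshold
  attr(results, "threshold") <- threshold
  results
}

#' Heat matrix of -log10 p-values across query lists
#'
#' Rows are gene sets significant in at least one query column, columns the
#' query lists; cells hold \code{-log10 p}. Rows are ordered by descending
#' maximum \code{-log10 p}. Intersection counts are attached for
#' annotation.
#'
#' @param results_by_query Named list of flagged result data.frames (one
#'   per query list), all over the same collection.
#' @return Numeric matrix (possibly 0-row) with \code{attr(,"intersections")}.
#' @export
build_heat_matrix <- function(results_by_query) {
  queries <- names(results_by_query)
  stopifnot(length(queries) >= 1)
  sig_sets <- unique(unlist(lapply(results_by_query, function(r)
    r$set[r$significant])))
  mat <- matrix(0, nrow = length(sig_sets), ncol = length(queries),
                dimnames = list(sig_sets, queries))
  ints <- mat
  for (q in queries) {
    r <- results_by_query[[q]]
    idx <- match(sig_sets, r$set)
    mat[, q] <- r$neg_log10_p[idx]
    ints[, q] <- r$intersection[idx]
  }
  if (nrow(mat) > 1) {
    ord <- order(-apply(mat, 1, max))
    mat <- mat[ord, , drop = FALSE]
    ints <- ints[ord, , drop = FALSE]
  }
  attr(mat, "intersections") <- ints
  mat
}
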