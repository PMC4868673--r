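#' Per-bin fold-enrichment profile matrix around the TSS
#'
#' Converts binned treatment and input counts (promoters x bins, genomic
#' order, spanning TSS +/- 2 kb by default) into per-bin FE: bin RPKM of
#' treatment over bin RPKM of input, the input floored at the 5th
#' percentile of all input bin RPKM values of the sample. Minus-strand
#' promoters have their bin order reversed so every row reads 5' to 3'
#' relative to the TSS.
#'
#' @param treat_bins,input_bins Count matrices, promoters x bins, same
#'   shape, genomic bin order.
#' @param treat_total,input_total Total aligned reads of each library.
#' @param bin_width Bin width in bp.
#' @param strand Per-promoter strand (\code{"+"}/\code{"-"}); NULL for all
#'   plus.
#' @param percentile Input floor percentile (default 5).
#' @return Numeric matrix of FE values (promoters x bins) with TSS-relative
#'   bin midpoints as \code{attr(,"bin_mids")}.
#' @export
compute_profile_matrix <- function(treat_bins, input_bins, treat_total,
                                   input_total, bin_width, strand = NULL,
                                   percentile = 5) {
  if (!identical(dim(treat_bins), dim(input_bins)))
    stop("treatment and input bin matrices differ in shape")
  rpkm_t <- treat_bins * 1e9 / (treat_total * bin_width)
  rpkm_i <- input_bins * 1e9 / (input_total * bin_width)
  floored <- floor_input(as.vector(rpkm_i), percentile)
  rpkm_i <- matrix(floored, nrow = nrow(rpkm_i),
                   dimnames = dimnames(input_bins))
  fe <- rpkm_t / rpkm_i
  if (!is.null(strand)) {
    rev_rows <- strand == "-"
    fe[rev_rows, ] <- fe[rev_rows, ncol(fe):1, drop = FALSE]
  }
  n_bins <- ncol(fe)
  span <- n_bins * bin_width
  attr(fe, "bin_mids") <- seq(-span / 2 + bin_width / 2,
                              span / 2 - bin_width / 2, by = bin_width)
  fe
}

#' Aggregate (mean) TSS profile over a promoter group
#'
#' @param profile FE profile matrix from
#'   \code{\link{compute_profile_matrix}}.
#' @param group Row indices or promoter ids; NULL for all promoters.
#' @return Numeric vector: mean FE per bin.
#' @export
aggregate_tss_profile <- function(profile, group = NULL) {
  if (is.null(group)) group <- seq_len(nrow(profile))
  if (is.character(group)) group <- match(group, rownames(profile))
  if (!length(group) || anyNA(group)) stop("empty or unknown promoter group")
  colMeans(profile[group, , drop = FALSE])
}

#' Seeded k-means clustering of FE profiles
#'
#' Lloyd's algorithm with Euclidean distance on the raw profile rows:
#' centers are initialized by sampling k distinct rows uniformly under the
#' given seed, iteration stops at convergence (no assignment changes) or
#' after \code{max_iter} passes (defaults k = 4, 10 iterations — the
#' heatmap procedure's settings). A cluster that empties is re-seeded to
#' the point currently farthest from its assigned center. The within-
#' cluster sum of squares is non-increasing across iterations.
#'
#' @param profile Numeric matrix, promoters x bins (or any feature space).
#' @param k Number of clusters (default 4).
#' @param max_iter Iteration cap (default 10).
#' @param seed Integer seed for initialization.
#' @return Object of class \code{cluster_model}: list with
#'   \code{assignments} (named integer vector), \code{centers} (k x bins),
#'   \code{iterations}, \code{wss} (per-iteration total within-cluster sum
#'   of squares), \code{converged}, \code{k}, \code{seed}.
#' @export
kmeans_profiles <- function(profile, k = 4, max_iter = 10, seed = 1) {
  n <- nrow(profile)
  if (n < k) stop("fewer promoters (", n, ") than clusters (", k, ")")
  set.seed(seed)
  centers <- profile[sample.int(n, k), , drop = FALSE]
  rownames(centers) <- NULL
  assign_old <- rep(0L, n)
  wss_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- point_center_dist2(profile, centers)
    assignments <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its center
    repeat {
      empty <- setdiff(seq_len(k), unique(assignments))
      if (!length(empty)) break
      cur <- d2[cbind(seq_len(n), assignments)]
      far <- which.max(cur)
      centers[empty[1], ] <- profile[far, ]
      d2 <- point_center_dist2(profile, centers)
      assignments <- max.col(-d2, ties.method = "first")
      assignments[far] <- empty[1]
    }
    iterations <- it
    wss_trace <- c(wss_trace, sum(d2[cbind(seq_len(n), assignments)]))
    if (identical(assignments, assign_old)) {
      converged <- TRUE
      break
    }
    assign_old <- assignments
    for (j in seq_len(k))
      centers[j, ] <- colMeans(profile[assignments == j, , drop = FALSE])
  }
  names(assignments) <- rownames(profile)
  structure(list(assignments = assignments, centers = centers,
                 iterations = iterations, wss = wss_trace,
                 converged = converged, k = k, seed = seed),
            class = "cluster_model")
}

# Squared Euclidean distances, points x centers.
point_center_dist2 <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' Relabel clusters in decreasing order of total FE
#'
#' Permutes cluster labels so the sum of each center's values (total FE) is
#' non-increasing in label order — cluster 1 is the hottest — relabelling
#' assignments consistently. Ties keep the original label order. The
#' partition itself is untouched.
#'
#' @param model A \code{cluster_model}.
#' @return The relabelled \code{cluster_model}.
#' @export
sort_clusters <- function(model) {
  totals <- rowSums(model$centers)
  ord <- order(-totals, seq_along(totals))
  relabel <- integer(model$k)
  relabel[ord] <- seq_len(model$k)
  model$centers <- model$centers[ord, , drop = FALSE]
  model$assignments[] <- relabel[model$assignments]
  model
}

#' Split a gene list into a query block and a clustering remainder
#'
#' Genes used to define a query gene set are excluded from clustering and
#' shown as a separate block at the top of the heatmap; this returns that
#' partition, preserving input order.
#'
#' @param gene_ids Character vector (heatmap row ids, in input order).
#' @param query_set Character vector of query genes.
#' @return List with \code{query} (members of query_set, input order) and
#'   \code{remainder}; warns when nothing is left to cluster.
#' @export
split_query_genes <- function(gene_ids, query_set) {
  in_query <- gene_ids %in% query_set
  if (all(in_query) && length(gene_ids))
    warning("query covers every gene; nothing left to cluster")
  list(query = gene_ids[in_query], remainder = gene_ids[!in_query])
}
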