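#' Plot aggregate TSS fold-enrichment profiles
#'
#' One curve per cell line / mark, mean FE against TSS-relative position.
#' Requires ggplot2.
#'
#' @param aggregates Named list of per-bin mean FE vectors (names like
#'   \code{"lineA.me3"}).
#' @param bin_mids TSS-relative bin midpoints (bp).
#' @return A ggplot object.
#' @export
plot_aggregate_profiles <- function(aggregates, bin_mids) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(names(aggregates), function(nm)
    data.frame(group = nm, position = bin_mids, fe = aggregates[[nm]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$fe,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean fold enrichment", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an over-representation heat matrix
#'
#' Tile heatmap of -log10 p-values (sets x query lists) from
#' \code{\link{build_heat_matrix}}. Requires ggplot2.
#'
#' @param heat Matrix from \code{\link{build_heat_matrix}}.
#' @return A ggplot object.
#' @export
plot_heat_matrix <- function(heat) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (!nrow(heat)) stop("heat matrix has no significant sets to plot")
  df <- expand.grid(set = rownames(heat), query = colnames(heat),
                    stringsAsFactors = FALSE)
  df$neg_log10_p <- as.vector(heat)
  df$set <- factor(df$set, levels = rev(rownames(heat)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query, y = .data$set,
                                   fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p") +
    ggplot2::theme_minimal()
}
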