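#' @importFrom ggplot2 ggplot aes geom_histogram geom_vline geom_point
#'   geom_segment geom_violin facet_wrap labs theme_minimal autoplot
#'   scale_size_area scale_colour_viridis_c
NULL

#' @export
ggplot2::autoplot

#' QC violin plots
#'
#' Detected genes, total UMIs and mitochondrial fraction per cell, split by
#' a grouping column (genotype by default).
#'
#' @param annotation Tibble from [compute_cell_qc()].
#' @param group_col Column to facet the violins by.
#' @return A ggplot.
#' @export
plot_qc <- function(annotation, group_col = "genotype") {
  long <- annotation |>
    select(all_of(c("barcode", group_col, "n_umi", "n_genes", "mito_fraction"))) |>
    tidyr::pivot_longer(c("n_umi", "n_genes", "mito_fraction"),
                        names_to = "metric")
  ggplot(long, aes(x = .data[[group_col]], y = .data$value,
                   fill = .data[[group_col]])) +
    geom_violin(scale = "width") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Per-cell QC metrics") +
    theme_minimal()
}

#' Dot plot of expression-group summaries
#'
#' Marker-panel style dot plot: dot size is the percent of cells expressing,
#' colour the mean normalized expression within expressers.
#'
#' @param summary_tbl Tibble from [expression_summary()].
#' @return A ggplot.
#' @export
plot_expression_summary <- function(summary_tbl) {
  ggplot(summary_tbl,
         aes(x = .data$group, y = .data$gene,
             size = .data$pct_expressing, colour = .data$mean_in_expressers)) +
    geom_point() +
    scale_size_area(max_size = 8, name = "% expressing") +
    scale_colour_viridis_c(name = "mean in\nexpressers") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Null distribution of a resampling enrichment test
#'
#' Histogram of the Monte-Carlo null overlap fractions with the observed
#' fraction (solid) and closed-form expectation (dashed).
#'
#' @param object A `conecod_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conecod_enrichment <- function(object, ...) {
  ggplot(tidy(object), aes(x = 100 * .data$null_fraction)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = 100 * object$observed_fraction,
               colour = "firebrick", linewidth = 1) +
    geom_vline(xintercept = 100 * object$expected_fraction_closed_form,
               linetype = "dashed") +
    labs(x = "null overlap (% of target set)", y = "iterations",
         title = sprintf("Observed %.1f%% vs null mean %.1f%%",
                         100 * object$observed_fraction,
                         100 * object$null_mean)) +
    theme_minimal()
}

#' Trajectory embedding coloured by pseudotime
#'
#' Cells in the leading two principal components of the ordering-gene space,
#' coloured by pseudotime (or branch), with the centroid MST overlaid.
#'
#' @param object A `conecod_trajectory` object.
#' @param colour `"pseudotime"` or `"branch"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conecod_trajectory <- function(object, colour = c("pseudotime", "branch"),
                                        ...) {
  colour <- match.arg(colour)
  df <- as_tibble(object$embedding[, 1:2])
  names(df) <- c("PC1", "PC2")
  df <- dplyr::bind_cols(df, object$cells)
  cen <- as_tibble(object$centroids[, 1:2])
  names(cen) <- c("PC1", "PC2")
  cen$id <- seq_len(nrow(cen))
  seg <- object$edges |>
    mutate(x = cen$PC1[as.integer(.data$from)],
           y = cen$PC2[as.integer(.data$from)],
           xend = cen$PC1[as.integer(.data$to)],
           yend = cen$PC2[as.integer(.data$to)])
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(aes(colour = .data[[colour]]), size = 0.6, alpha = 0.7) +
    geom_segment(data = seg, aes(x = .data$x, y = .data$y,
                                 xend = .data$xend, yend = .data$yend),
                 inherit.aes = FALSE, linewidth = 0.8) +
    geom_point(data = cen, aes(x = .data$PC1, y = .data$PC2),
               inherit.aes = FALSE, shape = 21, fill = "white", size = 3) +
    labs(title = "Centroid-MST trajectory") +
    theme_minimal()
  if (colour == "pseudotime") p <- p + scale_colour_viridis_c()
  p
}
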