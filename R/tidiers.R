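#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' One row per resampling iteration, with the null overlap fraction.
#'
#' @param x A `conecod_enrichment` object.
#' @param ... Unused.
#' @return Tibble: iteration, null_fraction.
#' @export
tidy.conecod_enrichment <- function(x, ...) {
  tibble(iteration = seq_along(x$null_fractions),
         null_fraction = x$null_fractions)
}

#' One-row summary of an enrichment result
#'
#' @param x A `conecod_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble with the observed and expected fractions, null
#'   moments and the three p-values.
#' @export
glance.conecod_enrichment <- function(x, ...) {
  tibble(observed_overlap = x$observed_overlap,
         observed_fraction = x$observed_fraction,
         expected_fraction = x$expected_fraction_closed_form,
         null_mean = x$null_mean, null_sd = x$null_sd,
         n_iterations = x$n_iterations,
         p_t = x$p_t, p_empirical = x$p_empirical,
         p_hypergeom = x$p_hypergeom)
}

#' Tidy a trajectory: one row per cell
#'
#' @param x A `conecod_trajectory` object.
#' @param ... Unused.
#' @return The per-cell tibble (barcode, pseudotime, centroid, state,
#'   branch).
#' @export
tidy.conecod_trajectory <- function(x, ...) x$cells

#' One-row summary of a trajectory
#'
#' @param x A `conecod_trajectory` object.
#' @param ... Unused.
#' @return One-row tibble: cells, centroids, states, branches, root,
#'   branch_node, max_pseudotime.
#' @export
glance.conecod_trajectory <- function(x, ...) {
  tibble(n_cells = nrow(x$cells),
         n_centroids = nrow(x$centroids),
         n_states = length(unique(x$cells$state)),
         n_branches = length(setdiff(unique(x$cells$branch), "trunk")),
         root = x$root, branch_node = x$branch_node,
         max_pseudotime = max(x$cells$pseudotime))
}

#' One-row summary of a pipeline run
#'
#' @param x A `conecod_run_report` object.
#' @param ... Unused.
#' @return One-row tibble with cell/gene counts per stage and headline
#'   results.
#' @export
glance.conecod_run_report <- function(x, ...) {
  tibble(
    cells_in = unname(x$stage_counts$input["cells"]),
    genes_in = unname(x$stage_counts$input["genes"]),
    cells_post_qc = unname(x$stage_counts$post_qc["cells"]),
    genes_post_qc = unname(x$stage_counts$post_qc["genes"]),
    n_populations = length(unique(x$cluster_annotation$population)),
    n_de_comparisons = length(x$de),
    n_de_significant = sum(vapply(x$de, function(d) sum(d$significant),
                                  integer(1))),
    enrichment_observed = if (!is.null(x$enrichment))
      x$enrichment$expressed$observed_fraction else NA_real_,
    enrichment_null_mean = if (!is.null(x$enrichment))
      x$enrichment$expressed$null_mean else NA_real_,
    wall_time_s = x$wall_time_s
  )
}
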