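#' Differential-expression configuration
#'
#' @param lfc_threshold Natural-log fold-change threshold for calling a gene
#'   significant (default 0.5, i.e. ~1.6-fold since e^0.5 = 1.649).
#' @param bonferroni_n Bonferroni divisor: `NULL` uses the number of genes
#'   expressed in at least two cells of the matrix at hand (the
#'   genes-expressed-at-timepoint convention), or give an explicit integer
#'   (e.g. 23645 for a day-100 run, 25622 for day 170).
#' @param min_cells_per_group Minimum cells per compared group.
#' @param de_universe_min_cells Genes must be detected in at least this many
#'   cells (across the compared cells) to enter the test universe.
#' @param min_pct Optional minimum percent-expressing (in either group)
#'   prefilter; 0 disables it.
#' @param lfc_method `"delogged_mean"` (default) or `"mean_log_diff"`.
#' @return A `conecod_de_config` list.
#' @export
de_config <- function(lfc_threshold = 0.5, bonferroni_n = NULL,
                      min_cells_per_group = 3, de_universe_min_cells = 10,
                      min_pct = 0,
                      lfc_method = c("delogged_mean", "mean_log_diff")) {
  assert_that(lfc_threshold >= 0, "lfc_threshold must be >= 0")
  if (!is.null(bonferroni_n))
    assert_that(bonferroni_n >= 1, "bonferroni_n must be >= 1")
  structure(list(lfc_threshold = lfc_threshold, bonferroni_n = bonferroni_n,
                 min_cells_per_group = min_cells_per_group,
                 de_universe_min_cells = de_universe_min_cells,
                 min_pct = min_pct, lfc_method = match.arg(lfc_method)),
            class = "conecod_de_config")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midrank tie handling throughout. The p-value is exact (from the null
#' rank-sum distribution) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (the Mann-Whitney U of `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop_conecod("both samples must be non-empty",
                 class = "conecod_validation_error")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (nx + ny <= 12 && !has_ties) {
    p <- if (u > nx * ny / 2) {
      stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE) * 2
    } else if (u < nx * ny / 2) {
      stats::pwilcox(u, nx, ny) * 2
    } else 1
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p.value = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = u, p.value = p)
}

#' Average natural-log fold change between two groups
#'
#' `ln(mean(exp(e) - 1) + 1)` per group on normalized values, differenced:
#' the log of pseudocounted mean de-logged expression, so that a value of
#' 0.5 corresponds to the ~1.6-fold boundary (e^0.5 = 1.6487). The
#' `"mean_log_diff"` method is the simple difference of mean log values.
#'
#' @param e1,e2 Normalized (log1p) expression values of the two groups.
#' @param method See [de_config()].
#' @return Natural-log fold change (positive when group 1 is higher).
#' @export
ln_fold_change <- function(e1, e2, method = c("delogged_mean", "mean_log_diff")) {
  method <- match.arg(method)
  assert_that(length(e1) > 0 && length(e2) > 0, "both groups must be non-empty")
  if (method == "delogged_mean") {
    log(mean(expm1(e1)) + 1) - log(mean(expm1(e2)) + 1)
  } else {
    mean(e1) - mean(e2)
  }
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum on normalized expression over all
#' cells of the two groups, the average natural-log fold change, and the
#' Bonferroni-corrected p-value. Significant genes satisfy
#' `p_bonferroni < 0.05` and `|ln_fc| > lfc_threshold`.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells_a,cells_b Disjoint barcode vectors or logical masks.
#' @param config A [de_config()].
#' @return Tibble sorted by p then |ln_fc|: gene, n_a, n_b, pct_a, pct_b,
#'   ln_fc, p, p_bonferroni, significant, direction. The Bonferroni divisor
#'   used is in attribute `bonferroni_n`.
#' @export
de_between_groups <- function(norm, cells_a, cells_b, config = de_config()) {
  cells_a <- resolve_cells(cells_a, norm, "cells_a")
  cells_b <- resolve_cells(cells_b, norm, "cells_b")
  if (length(intersect(cells_a, cells_b)) > 0)
    stop_conecod("cell groups overlap", class = "conecod_validation_error")
  assert_that(length(cells_a) >= config$min_cells_per_group &&
                length(cells_b) >= config$min_cells_per_group,
              "a group is below min_cells_per_group")
  sub <- norm[, c(cells_a, cells_b), drop = FALSE]
  universe <- rownames(sub)[Matrix::rowSums(sub > 0) >= config$de_universe_min_cells]
  bonf_n <- config$bonferroni_n %||%
    sum(Matrix::rowSums(norm > 0) >= 2)
  a <- as.matrix(sub[universe, cells_a, drop = FALSE])
  b <- as.matrix(sub[universe, cells_b, drop = FALSE])
  pct_a <- rowMeans(a > 0) * 100
  pct_b <- rowMeans(b > 0) * 100
  if (config$min_pct > 0) {
    keep <- pct_a >= config$min_pct | pct_b >= config$min_pct
    universe <- universe[keep]
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    pct_a <- pct_a[keep]; pct_b <- pct_b[keep]
  }
  res <- purrr::map_dfr(seq_along(universe), function(i) {
    w <- wilcoxon_rank_sum(a[i, ], b[i, ])
    tibble(gene = universe[i],
           ln_fc = ln_fold_change(a[i, ], b[i, ], config$lfc_method),
           p = w$p.value)
  })
  res |>
    mutate(n_a = length(cells_a), n_b = length(cells_b),
           pct_a = unname(pct_a), pct_b = unname(pct_b),
           p_bonferroni = pmin(1, .data$p * bonf_n),
           significant = .data$p_bonferroni < 0.05 &
             abs(.data$ln_fc) > config$lfc_threshold,
           direction = ifelse(.data$ln_fc > 0, "up", ifelse(.data$ln_fc < 0, "down", "none"))) |>
    arrange(.data$p, desc(abs(.data$ln_fc))) |>
    select("gene", "n_a", "n_b", "pct_a", "pct_b", "ln_fc", "p",
           "p_bonferroni", "significant", "direction") |>
    structure(bonferroni_n = bonf_n)
}

#' Three-way comparison of an intermediate population against two references
#'
#' Runs [de_between_groups()] of the query cells against each reference and
#' classifies every gene tested in both comparisons:
#' \describe{
#'   \item{refA-level}{not different from reference A, different from B}
#'   \item{refB-level}{not different from B, different from A}
#'   \item{intermediate}{different from both, with opposite fold signs
#'     (between the two references)}
#'   \item{above-both / below-both}{different from both with the same sign}
#' }
#' Genes different from neither reference get class `NA`.
#'
#' @param norm Normalized matrix.
#' @param cells_query,cells_ref_a,cells_ref_b Three disjoint non-empty cell
#'   groups (e.g. mutant rod-like cells vs WT rods and WT cones).
#' @param config A [de_config()].
#' @param ref_names Length-2 labels used in the class strings.
#' @return Tibble: gene, ln_fc_a, p_bonf_a, sig_a, ln_fc_b, p_bonf_b, sig_b,
#'   class.
#' @export
tri_compare <- function(norm, cells_query, cells_ref_a, cells_ref_b,
                        config = de_config(), ref_names = c("refA", "refB")) {
  cells_query <- resolve_cells(cells_query, norm, "cells_query")
  cells_ref_a <- resolve_cells(cells_ref_a, norm, "cells_ref_a")
  cells_ref_b <- resolve_cells(cells_ref_b, norm, "cells_ref_b")
  assert_that(length(cells_query) > 0, "query mask is empty")
  masks <- list(cells_query, cells_ref_a, cells_ref_b)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(masks[[i]], masks[[j]])) > 0)
      stop_conecod("cell masks overlap", class = "conecod_validation_error")
  de_a <- de_between_groups(norm, cells_query, cells_ref_a, config)
  de_b <- de_between_groups(norm, cells_query, cells_ref_b, config)
  joined <- dplyr::inner_join(
    de_a |> select("gene", ln_fc_a = "ln_fc", p_bonf_a = "p_bonferroni",
                   sig_a = "significant"),
    de_b |> select("gene", ln_fc_b = "ln_fc", p_bonf_b = "p_bonferroni",
                   sig_b = "significant"),
    by = "gene")
  classify <- function(sa, sb, fa, fb) {
    if (!sa && !sb) return(NA_character_)
    if (!sa && sb) return(paste0(ref_names[1], "-level"))
    if (sa && !sb) return(paste0(ref_names[2], "-level"))
    if (sign(fa) != sign(fb)) return("intermediate")
    if (fa > 0) "above-both" else "below-both"
  }
  joined |>
    mutate(class = purrr::pmap_chr(
      list(.data$sig_a, .data$sig_b, .data$ln_fc_a, .data$ln_fc_b), classify))
}
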