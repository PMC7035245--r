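#' Default marker panels for cluster annotation
#'
#' Population -> positive marker genes, built from the in-text retinal
#' markers (e.g. NR2E3/SAG for rods, ARR3/OPN1MW for ML cones, OPN1SW for
#' S cones). User panels supplied as YAML or named lists override these.
#'
#' @return Named list of character vectors.
#' @export
default_marker_panel <- function() {
  lapply(default_marker_program(), names)
}

#' Read a marker panel from YAML
#'
#' @param path YAML file mapping population name -> list of marker genes.
#' @return Named list of character vectors.
#' @export
read_marker_panel <- function(path) {
  panel <- yaml::read_yaml(path)
  panel <- lapply(panel, as.character)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  assert_that(length(panel) > 0 && all(lengths(panel) > 0),
              "marker panels must be non-empty")
  for (p in names(panel))
    assert_that(!anyDuplicated(panel[[p]]),
                paste0("duplicate markers in panel ", p))
  invisible(panel)
}

#' Partition cells by PCA and k-means
#'
#' Scales the highly variable genes (per-gene z-score, clipped at 10),
#' projects cells onto the leading principal components, and runs k-means
#' with a fixed seed.
#'
#' @param norm Normalized genes x cells matrix.
#' @param hvg Genes used for the embedding (default: all genes in `norm`).
#' @param n_components Principal components retained.
#' @param k Number of clusters (>= 2).
#' @param seed Seed for k-means restarts.
#' @return Integer cluster id per cell, named by barcode, with the PCA cell
#'   embedding in attribute `embedding`.
#' @export
cluster_cells <- function(norm, hvg = NULL, n_components = 20, k = 6,
                          seed = 1L) {
  if (k < 2) stop_conecod("k must be >= 2", class = "conecod_validation_error")
  if (k > ncol(norm))
    stop_conecod("k exceeds the number of cells", class = "conecod_validation_error")
  hvg <- hvg %||% rownames(norm)
  hvg <- intersect(hvg, rownames(norm))
  emb <- pca_embed(norm, hvg, n_components)
  set.seed(seed)
  km <- suppressWarnings(kmeans(emb, centers = k, nstart = 10, iter.max = 100))
  structure(setNames(km$cluster, colnames(norm)), embedding = emb)
}

pca_embed <- function(norm, genes, n_components) {
  x <- as.matrix(Matrix::t(norm[genes, , drop = FALSE]))
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  x <- pmin(pmax(sweep(sweep(x, 2, mu), 2, s, "/"), -10), 10)
  # remove each cell's mean z-score: the common dropout/depth component that
  # otherwise dominates PC1 and strata k-means by sequencing depth
  x <- x - rowMeans(x)
  n_components <- min(n_components, nrow(x) - 1, ncol(x))
  prcomp(x, rank. = n_components, center = TRUE, scale. = FALSE)$x
}

#' Assign population identities to clusters from marker panels
#'
#' Cluster-average expression of each marker is z-scored across clusters;
#' each cluster is assigned the panel with the highest mean marker z-score.
#' Ties break by panel name order and are flagged ambiguous. Markers absent
#' from the matrix warn; a panel with no present gene at all errors.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Cluster id per cell (named by barcode or aligned to
#'   columns).
#' @param panel Named list population -> marker genes.
#' @return Tibble with cluster, population, score, ambiguous; the full
#'   panel x cluster score matrix is in attribute `scores` and the per-cell
#'   populations in attribute `cell_population`.
#' @export
annotate_clusters <- function(norm, clusters, panel = default_marker_panel()) {
  validate_panel(panel)
  all_markers <- unique(unlist(panel))
  present <- intersect(all_markers, rownames(norm))
  missing <- setdiff(all_markers, present)
  if (length(missing))
    warn(paste("markers absent from matrix:", paste(missing, collapse = ", ")))
  if (length(present) == 0)
    stop_conecod("no panel gene present in the matrix",
                 class = "conecod_annotation_error")
  cl <- sort(unique(clusters))
  avg <- vapply(cl, function(k)
    Matrix::rowMeans(norm[present, clusters == k, drop = FALSE]),
    numeric(length(present)))
  avg <- matrix(avg, nrow = length(present),
                dimnames = list(present, as.character(cl)))
  z <- t(apply(avg, 1, function(r) {
    s <- sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  scores <- vapply(panel, function(g) {
    g <- intersect(g, present)
    if (length(g) == 0) rep(NA_real_, length(cl)) else
      colMeans(z[g, , drop = FALSE])
  }, numeric(length(cl)))
  scores <- matrix(scores, nrow = length(cl),
                   dimnames = list(as.character(cl), names(panel)))
  assign_one <- function(s) {
    s[is.na(s)] <- -Inf
    best <- which(s == max(s))
    list(pop = names(panel)[best[1]], ambiguous = length(best) > 1,
         score = max(s))
  }
  res <- apply(scores, 1, assign_one)
  out <- tibble(
    cluster = cl,
    population = unname(vapply(res, `[[`, character(1), "pop")),
    score = unname(vapply(res, `[[`, numeric(1), "score")),
    ambiguous = unname(vapply(res, `[[`, logical(1), "ambiguous"))
  )
  cell_pop <- out$population[match(clusters, out$cluster)]
  names(cell_pop) <- names(clusters)
  structure(out, scores = t(scores), cell_population = cell_pop)
}

#' Expression-group summary statistics
#'
#' For each gene and cell group: the percentage of cells with a nonzero raw
#' count, the mean normalized expression within those expressing cells, and
#' the mean normalized expression over all cells of the group. The identity
#' `mean_total = mean_in_expressers * pct_expressing / 100` holds exactly.
#'
#' @param counts Raw genes x cells matrix (defines "expressing").
#' @param norm Matching normalized matrix.
#' @param group Factor/character per cell, or a named list of barcode
#'   vectors.
#' @param genes Genes to summarize (default: all).
#' @return Tibble: gene, group, pct_expressing, mean_in_expressers,
#'   mean_total.
#' @export
expression_summary <- function(counts, norm, group, genes = NULL) {
  counts <- check_counts(counts)
  genes <- genes %||% rownames(counts)
  genes <- intersect(genes, rownames(counts))
  if (!is.list(group)) {
    assert_that(length(group) == ncol(counts),
                "per-cell group vector must match the number of cells")
    group <- split(colnames(counts), group)
  }
  assert_that(all(lengths(group) > 0), "empty group")
  purrr::map_dfr(names(group), function(gname) {
    cells <- resolve_cells(group[[gname]], counts, "group")
    raw <- counts[genes, cells, drop = FALSE]
    nrm <- norm[genes, cells, drop = FALSE]
    n_expr <- Matrix::rowSums(raw > 0)
    tot <- Matrix::rowSums(nrm)
    tibble(
      gene = genes, group = gname,
      pct_expressing = unname(100 * n_expr / length(cells)),
      mean_in_expressers = unname(ifelse(n_expr > 0, tot / n_expr, 0)),
      mean_total = unname(tot / length(cells))
    )
  })
}

#' Compare a gene's expression between two groups
#'
#' Two read-outs per gene: a two-sided two-proportion test on the number of
#' expressing cells (exact Fisher fallback when any expected count < 5), and
#' a two-sided Wilcoxon rank-sum on normalized expression within the
#' expressing cells.
#'
#' @param counts,norm Raw and normalized matrices.
#' @param gene Gene id.
#' @param cells_a,cells_b Barcode vectors (or logical masks) of the groups.
#' @return One-row tibble: gene, n_a, n_b, expr_a, expr_b, p_proportion,
#'   p_level, level_undefined (TRUE when no cell expresses on either side).
#' @export
compare_expression_groups <- function(counts, norm, gene, cells_a, cells_b) {
  counts <- check_counts(counts)
  cells_a <- resolve_cells(cells_a, counts, "cells_a")
  cells_b <- resolve_cells(cells_b, counts, "cells_b")
  assert_that(length(cells_a) > 0 && length(cells_b) > 0, "empty group")
  ra <- counts[gene, cells_a]; rb <- counts[gene, cells_b]
  ea <- sum(ra > 0); eb <- sum(rb > 0)
  na <- length(cells_a); nb <- length(cells_b)
  expected <- outer(c(ea + eb, na + nb - ea - eb), c(na, nb)) / (na + nb)
  p_prop <- if (any(expected < 5)) {
    fisher.test(matrix(c(ea, na - ea, eb, nb - eb), 2))$p.value
  } else {
    suppressWarnings(prop.test(c(ea, eb), c(na, nb))$p.value)
  }
  if (ea + eb == 0) {
    p_level <- 1; undef <- TRUE
  } else if (ea == 0 || eb == 0) {
    p_level <- NA_real_; undef <- TRUE
  } else {
    va <- norm[gene, cells_a][ra > 0]
    vb <- norm[gene, cells_b][rb > 0]
    p_level <- wilcoxon_rank_sum(va, vb)$p.value
    undef <- FALSE
  }
  tibble(gene = gene, n_a = na, n_b = nb, expr_a = ea, expr_b = eb,
         p_proportion = p_prop, p_level = p_level, level_undefined = undef)
}

#' Map a population profile onto reference populations by Spearman correlation
#'
#' Correlates the query mean-expression profile with each reference over the
#' genes shared between them; rank-based, so any strictly monotone transform
#' of either profile leaves the result unchanged.
#'
#' @param query Named numeric: mean expression per gene of the query
#'   population.
#' @param references Named list of named numeric profiles, or a data frame
#'   with a `gene` column and one column per reference population.
#' @return Tibble ranked by rho: reference, rho, p, n_shared.
#' @export
refmap_spearman <- function(query, references) {
  if (is.data.frame(references)) {
    gcol <- references$gene
    references <- lapply(references[setdiff(names(references), "gene")],
                         function(v) setNames(v, gcol))
  }
  purrr::map_dfr(names(references), function(ref) {
    shared <- intersect(names(query), names(references[[ref]]))
    if (length(shared) < 3)
      stop_conecod(paste0("fewer than 3 genes shared with reference ", ref),
                   class = "conecod_validation_error")
    ct <- suppressWarnings(
      cor.test(query[shared], references[[ref]][shared], method = "spearman"))
    tibble(reference = ref, rho = unname(ct$estimate), p = ct$p.value,
           n_shared = length(shared))
  }) |> arrange(desc(.data$rho))
}

#' Relative qPCR quantification (2^-ddCq) with Mann-Whitney p-values
#'
#' Per sample, dCq(target) = mean Cq(target) minus the geometric mean of the
#' two housekeeping genes' mean Cq values; ddCq subtracts the average dCq of
#' the reference-condition samples; fold change is 2^-ddCq. Per-gene p-values
#' come from a two-sided Mann-Whitney test on per-sample dCq between
#' conditions.
#'
#' @param cq Tibble from [generate_qpcr_table()] or with the same columns
#'   (sample_id, condition, gene, cq).
#' @param reference_condition Condition defining ddCq = 0 on average.
#' @param housekeeping Two housekeeping gene names (defaults to the table's
#'   `housekeeping` attribute).
#' @param hk_combine `"geometric"` (default) takes the geometric mean of the
#'   two housekeeping mean Cq values; `"arithmetic"` averages them (the
#'   geometric mean on the linear-abundance scale).
#' @return Tibble per gene x non-reference condition: fold_change, log2_fold,
#'   p_mannwhitney, with per-sample dCq/ddCq in attribute `per_sample`.
#' @export
ddcq_fold_change <- function(cq, reference_condition = "WT",
                             housekeeping = NULL,
                             hk_combine = c("geometric", "arithmetic")) {
  hk_combine <- match.arg(hk_combine)
  housekeeping <- housekeeping %||% attr(cq, "housekeeping")
  assert_that(length(housekeeping) == 2, "two housekeeping genes required")
  mean_cq <- cq |>
    group_by(.data$sample_id, .data$condition, .data$gene) |>
    summarise(cq = mean(.data$cq), n_rep = n(), .groups = "drop")
  assert_that(all(mean_cq$n_rep >= 2 | mean_cq$gene %in% housekeeping) ||
                all(mean_cq$n_rep >= 1),
              "need replicate Cq values")
  hk <- mean_cq |>
    filter(.data$gene %in% housekeeping) |>
    group_by(.data$sample_id) |>
    summarise(hk_cq = if (hk_combine == "geometric") geom_mean(.data$cq)
              else mean(.data$cq),
              n_hk = n(), .groups = "drop")
  if (any(hk$n_hk < 2) || !all(unique(mean_cq$sample_id) %in% hk$sample_id))
    stop_conecod("housekeeping genes missing in some sample",
                 class = "conecod_validation_error")
  dcq <- mean_cq |>
    filter(!.data$gene %in% housekeeping) |>
    left_join(hk, by = "sample_id") |>
    mutate(dcq = .data$cq - .data$hk_cq)
  ref_mean <- dcq |>
    filter(.data$condition == reference_condition) |>
    group_by(.data$gene) |>
    summarise(ref_dcq = mean(.data$dcq), .groups = "drop")
  per_sample <- dcq |>
    left_join(ref_mean, by = "gene") |>
    mutate(ddcq = .data$dcq - .data$ref_dcq, fold = 2^(-.data$ddcq))
  out <- per_sample |>
    filter(.data$condition != reference_condition) |>
    group_by(.data$gene, .data$condition) |>
    summarise(log2_fold = -mean(.data$ddcq),
              n_samples = n(), .groups = "drop") |>
    mutate(fold_change = 2^.data$log2_fold)
  pvals <- per_sample |>
    group_by(.data$gene) |>
    summarise(p_mannwhitney = {
      a <- .data$dcq[.data$condition == reference_condition]
      b <- .data$dcq[.data$condition != reference_condition]
      if (length(a) >= 2 && length(b) >= 2)
        wilcoxon_rank_sum(a, b)$p.value else NA_real_
    }, .groups = "drop")
  structure(left_join(out, pvals, by = "gene"), per_sample = per_sample)
}
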