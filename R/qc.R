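#' Quality-control configuration
#'
#' Thresholds of the cell/gene filters. Defaults follow the organoid
#' convention: cells with fewer than 200 detected genes are discarded, the
#' mitochondrial ceiling is 20% for day-170 runs and 15% for day-100 runs,
#' and genes must be detected in at least two cells.
#'
#' @param min_genes_per_cell Minimum detected genes per retained cell.
#' @param max_mito_fraction Maximum mitochondrial UMI fraction (0.20 for
#'   d170-like runs; use 0.15 for d100-like runs).
#' @param min_cells_per_gene Minimum cells a retained gene is detected in.
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes.
#' @return A `conecod_qc_config` list.
#' @export
qc_config <- function(min_genes_per_cell = 200, max_mito_fraction = 0.20,
                      min_cells_per_gene = 2, mito_prefix = "MT-") {
  assert_that(min_genes_per_cell >= 0 && min_cells_per_gene >= 0,
              "QC thresholds must be >= 0")
  assert_that(max_mito_fraction >= 0 && max_mito_fraction <= 1,
              "max_mito_fraction must be in [0, 1]")
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix),
            class = "conecod_qc_config")
}

#' Read a UMI count matrix
#'
#' Reads either a MatrixMarket triple (`matrix.mtx` + genes + barcodes TSVs)
#' or a dense TSV (gene ids in the first column, barcodes in the header).
#' Round-trips bit-exactly with [write_counts()].
#'
#' @param matrix_path Path to the `.mtx` file or dense TSV.
#' @param genes_path,barcodes_path Sidecar TSVs (first column used); required
#'   for MTX input.
#' @return Sparse genes x cells integer matrix with gene ids as rownames.
#' @export
read_counts <- function(matrix_path, genes_path = NULL, barcodes_path = NULL) {
  assert_that(file.exists(matrix_path), paste("file not found:", matrix_path))
  if (grepl("\\.mtx$", matrix_path)) {
    assert_that(!is.null(genes_path) && !is.null(barcodes_path),
                "MTX input needs genes_path and barcodes_path")
    m <- Matrix::readMM(matrix_path)
    genes <- read_id_column(genes_path)
    barcodes <- read_id_column(barcodes_path)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      stop_conecod(sprintf(
        "matrix is %d x %d but %d gene ids / %d barcodes supplied",
        nrow(m), ncol(m), length(genes), length(barcodes)),
        class = "conecod_format_error")
    dimnames(m) <- list(genes, barcodes)
  } else {
    tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  }
  if (anyDuplicated(rownames(m)))
    stop_conecod("duplicate gene ids in input", class = "conecod_format_error")
  if (anyDuplicated(colnames(m)))
    stop_conecod("duplicate barcodes in input", class = "conecod_format_error")
  check_counts(methods::as(m, "CsparseMatrix"))
}

read_id_column <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  if (length(lines) == 0) return(character())
  vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
}

#' Write a count matrix as MatrixMarket + TSV sidecars
#'
#' @param counts Sparse genes x cells matrix.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, dir) {
  counts <- check_counts(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(counts, paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}

#' Per-cell QC statistics
#'
#' Computes detected genes, total UMIs, and the mitochondrial UMI fraction
#' per cell; joins onto an annotation table when supplied.
#'
#' @param counts Sparse genes x cells matrix.
#' @param annotation Optional per-cell tibble with a `barcode` column.
#' @param mito_prefix Prefix identifying mitochondrial gene ids.
#' @return Tibble with barcode, n_umi, n_genes, mito_fraction (plus the
#'   annotation columns when given). Cells with zero UMIs get mito fraction 0.
#' @export
compute_cell_qc <- function(counts, annotation = NULL, mito_prefix = "MT-") {
  counts <- check_counts(counts)
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mt <- is_mito(rownames(counts), mito_prefix)
  mito_umi <- if (any(mt)) Matrix::colSums(counts[mt, , drop = FALSE]) else
    rep(0, ncol(counts))
  qc <- tibble(barcode = colnames(counts),
               n_umi = as.integer(n_umi),
               n_genes = as.integer(n_genes),
               mito_fraction = ifelse(n_umi > 0, mito_umi / n_umi, 0))
  if (is.null(annotation)) return(qc)
  assert_that("barcode" %in% names(annotation), "annotation needs a barcode column")
  # recompute rather than duplicate stale QC columns
  annotation <- annotation[setdiff(names(annotation),
                                   c("n_umi", "n_genes", "mito_fraction"))]
  left_join(annotation, qc, by = "barcode")
}

#' Filter cells on detected genes and mitochondrial content
#'
#' Retains cells with `n_genes >= min_genes_per_cell` and
#' `mito_fraction <= max_mito_fraction`; a cell with exactly the minimum gene
#' count survives ("less than" is the removal rule). Order is preserved.
#'
#' @param counts Sparse genes x cells matrix.
#' @param annotation Per-cell tibble aligned to `counts`; QC columns are
#'   computed if absent.
#' @param qc A [qc_config()].
#' @return List with filtered `counts` and `annotation`.
#' @export
filter_cells <- function(counts, annotation = NULL, qc = qc_config()) {
  counts <- check_counts(counts)
  ann <- compute_cell_qc(counts,
                         if (!is.null(annotation) &&
                             !all(c("n_genes", "mito_fraction") %in% names(annotation)))
                           annotation else NULL,
                         qc$mito_prefix)
  if (!is.null(annotation) &&
      all(c("n_genes", "mito_fraction") %in% names(annotation)))
    ann <- annotation
  ann <- ann[match(colnames(counts), ann$barcode), ]
  keep <- ann$n_genes >= qc$min_genes_per_cell &
    ann$mito_fraction <= qc$max_mito_fraction
  inform(sprintf("filter_cells: removed %d of %d cells (min_genes=%s, max_mito=%s)",
                 sum(!keep), length(keep), qc$min_genes_per_cell,
                 qc$max_mito_fraction))
  list(counts = counts[, keep, drop = FALSE],
       annotation = as_tibble(ann[keep, ]))
}

#' Filter genes on the number of cells detecting them
#'
#' @param counts Sparse genes x cells matrix.
#' @param min_cells_per_gene Minimum cells with a nonzero count.
#' @return Filtered matrix, gene order preserved.
#' @export
filter_genes <- function(counts, min_cells_per_gene = 2) {
  counts <- check_counts(counts)
  keep <- Matrix::rowSums(counts > 0) >= min_cells_per_gene
  inform(sprintf("filter_genes: removed %d of %d genes (min_cells=%d)",
                 sum(!keep), length(keep), min_cells_per_gene))
  counts[keep, , drop = FALSE]
}

#' Counts-per-10k log normalization
#'
#' `e(g, c) = ln(1 + s * x(g, c) / T(c))` with `T(c)` the cell's total UMI
#' count and scale `s = 10000`. Zeros map to zeros, so sparsity is preserved,
#' and the result is invariant to scaling all counts of a cell.
#'
#' @param counts Sparse genes x cells matrix with no all-zero cells (run
#'   [filter_cells()] first).
#' @param scale_factor Normalization scale `s`.
#' @return Sparse genes x cells matrix of normalized values, with a
#'   `scale_factor` attribute.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  counts <- check_counts(counts)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop_conecod("all-zero cells present; run filter_cells() first",
                 class = "conecod_validation_error")
  norm <- methods::as(counts %*% Matrix::Diagonal(x = scale_factor / tot),
                      "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Select highly variable genes by binned dispersion
#'
#' Within each group (genotype by default), genes are binned into
#' equal-frequency bins of mean normalized expression; the dispersion
#' (variance / mean) is z-scored within each bin and genes are ranked by the
#' z-score. The union of each group's top `n_top` is returned. Ties break by
#' gene id for determinism.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param annotation Optional per-cell tibble with `barcode` and the grouping
#'   column; with `NULL`, all cells form one group.
#' @param n_top Genes taken per group.
#' @param group_col Annotation column defining the groups.
#' @param n_bins Number of mean bins (reduced with a warning when there are
#'   fewer genes than bins).
#' @return Character vector: the union of per-group top genes, in score order.
#' @export
select_hvg <- function(norm, annotation = NULL, n_top = 2000,
                       group_col = "genotype", n_bins = 20) {
  assert_that(n_top >= 1, "n_top must be >= 1")
  groups <- if (is.null(annotation)) list(all = colnames(norm)) else
    split(annotation$barcode, annotation[[group_col]])
  picked <- character()
  for (g in names(groups)) {
    sub <- norm[, groups[[g]], drop = FALSE]
    mu <- Matrix::rowMeans(sub)
    ex2 <- Matrix::rowMeans(sub^2)
    v <- pmax(0, (ex2 - mu^2) * ncol(sub) / max(1, ncol(sub) - 1))
    disp <- ifelse(mu > 0, v / mu, 0)
    bins <- n_bins
    if (sum(mu > 0) < n_bins) {
      bins <- max(1, sum(mu > 0) %/% 2)
      warn(sprintf("fewer expressed genes than bins; using %d bins", bins))
    }
    ord_mu <- rank(mu, ties.method = "first")
    bin <- ceiling(ord_mu / length(mu) * bins)
    z <- stats::ave(disp, bin, FUN = function(d) {
      s <- sd(d)
      if (is.na(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
    })
    ord <- order(-z, rownames(norm))
    picked <- union(picked, rownames(norm)[head(ord, n_top)])
  }
  picked
}
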