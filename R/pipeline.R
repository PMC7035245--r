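#' Configure an end-to-end run
#'
#' Collects every stage's parameters. Input is either a synthetic
#' specification (`spec`) or paths to an MTX count matrix with sidecars
#' (`matrix_path`, `genes_path`, `barcodes_path`, optional `metadata_path`
#' TSV with a barcode column).
#'
#' @param spec A [synthetic_spec()], or `NULL` when reading a matrix.
#' @param matrix_path,genes_path,barcodes_path,metadata_path Input files
#'   (ignored when `spec` is given).
#' @param qc A [qc_config()].
#' @param panel Marker panel (named list or YAML path).
#' @param de A [de_config()].
#' @param ordering An [ordering_config()].
#' @param k_clusters k for the partitioning stage.
#' @param n_components Principal components for clustering.
#' @param n_hvg Highly variable genes per genotype.
#' @param gene_set Binding-site target gene set (character vector or file
#'   path); `NULL` uses the synthetic truth's designated set.
#' @param enrichment_iterations Resampling iterations.
#' @param run_trajectory Whether to run the pseudotime stage on WT
#'   photoreceptor cells.
#' @param out_dir Output directory (`NULL` = write nothing).
#' @param seed Global seed fanned out to per-stage seeds.
#' @return A `conecod_run_config` list.
#' @export
run_config <- function(spec = NULL, matrix_path = NULL, genes_path = NULL,
                       barcodes_path = NULL, metadata_path = NULL,
                       qc = qc_config(), panel = default_marker_panel(),
                       de = de_config(), ordering = ordering_config(),
                       k_clusters = 12, n_components = 20, n_hvg = 2000,
                       gene_set = NULL, enrichment_iterations = 1000,
                       run_trajectory = TRUE, out_dir = NULL, seed = 1L) {
  structure(list(spec = spec, matrix_path = matrix_path,
                 genes_path = genes_path, barcodes_path = barcodes_path,
                 metadata_path = metadata_path, qc = qc, panel = panel,
                 de = de, ordering = ordering, k_clusters = k_clusters,
                 n_components = n_components, n_hvg = n_hvg,
                 gene_set = gene_set,
                 enrichment_iterations = enrichment_iterations,
                 run_trajectory = run_trajectory, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "conecod_run_config")
}

#' Validate a run configuration
#'
#' Schema, path and threshold-range checks. Findings are returned, never
#' thrown; `level` distinguishes errors from warnings.
#'
#' @param config A [run_config()].
#' @return Tibble with columns level ("error"/"warning") and message; empty
#'   when fully valid.
#' @export
validate_run_config <- function(config) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1]] <<- tibble(level = level, message = msg)
  if (is.null(config$spec)) {
    for (p in c("matrix_path", "genes_path", "barcodes_path")) {
      if (is.null(config[[p]])) add("error", paste(p, "missing (no synthetic spec given)"))
      else if (!file.exists(config[[p]])) add("error", paste(p, "does not exist:", config[[p]]))
    }
  } else if (!inherits(config$spec, "conecod_spec")) {
    add("error", "spec is not a synthetic_spec()")
  }
  qc <- config$qc
  if (qc$max_mito_fraction > 1 || qc$max_mito_fraction < 0)
    add("error", "max_mito_fraction outside [0, 1]")
  if (qc$min_genes_per_cell < 0) add("error", "min_genes_per_cell negative")
  panel <- tryCatch({
    p <- if (is.character(config$panel)) read_marker_panel(config$panel) else config$panel
    validate_panel(p); p
  }, error = function(e) {
    add("error", paste("marker panel invalid:", conditionMessage(e))); NULL
  })
  if (!is.null(panel) && !is.null(config$spec)) {
    uni <- build_universe(config$spec)
    miss <- setdiff(unique(unlist(panel)), uni)
    if (length(miss))
      add("warning", paste("panel genes absent from the synthetic universe:",
                           paste(miss, collapse = ", ")))
  }
  if (is.character(config$gene_set) && length(config$gene_set) == 1 &&
      !file.exists(config$gene_set) && grepl("[/.]", config$gene_set))
    add("error", paste("gene_set file does not exist:", config$gene_set))
  if (config$k_clusters < 2) add("error", "k_clusters must be >= 2")
  if (length(findings) == 0)
    return(tibble(level = character(), message = character()))
  bind_rows(findings)
}

write_stage_tsv <- function(x, out_dir, name, config_hash) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(paste0("# conecod config ", config_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes, in order: data generation (or ingestion), per-cell QC, cell and
#' gene filtering, normalization, HVG selection, clustering, marker-panel
#' annotation, expression-group summaries of the opsin/rod markers,
#' per-population WT-vs-MUT differential expression, the three-way cod
#' classification (mutant cods vs WT rods and WT cones), binding-site
#' gene-set enrichment among expressed and differentially expressed genes,
#' and the WT photoreceptor trajectory. Every intermediate is written as a
#' tidy TSV under `out_dir` when given. Identical config + seed gives an
#' identical report (wall time aside).
#'
#' @param config A [run_config()].
#' @return A `conecod_run_report` list with per-stage counts, the headline
#'   tables, and an output-file manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  findings <- validate_run_config(config)
  if (any(findings$level == "error"))
    stop_conecod(paste0("invalid config:\n  ",
                        paste(findings$message[findings$level == "error"],
                              collapse = "\n  ")),
                 class = "conecod_validation_error")
  t0 <- Sys.time()
  seed <- config$seed
  config_hash <- substr(rlang::hash(config[setdiff(names(config), "out_dir")]), 1, 12)
  out <- config$out_dir
  manifest <- character()
  stage_counts <- list()
  log_stage <- function(stage, msg)
    inform(sprintf("[%s] %s", stage, msg))

  # --- input ---------------------------------------------------------------
  if (!is.null(config$spec)) {
    spec <- config$spec
    spec$seed <- derive_seed(seed, 1L)
    ds <- generate_organoid_dataset(spec)
    counts <- ds$counts; ann <- ds$annotation; truth <- ds$truth
    log_stage("simulate", sprintf("%d cells x %d genes", ncol(counts), nrow(counts)))
  } else {
    counts <- read_counts(config$matrix_path, config$genes_path,
                          config$barcodes_path)
    ann <- if (!is.null(config$metadata_path))
      readr::read_tsv(config$metadata_path, show_col_types = FALSE)
    else tibble(barcode = colnames(counts), genotype = "WT")
    truth <- NULL
    log_stage("ingest", sprintf("%d cells x %d genes", ncol(counts), nrow(counts)))
  }
  stage_counts$input <- c(cells = ncol(counts), genes = nrow(counts))

  # --- QC ------------------------------------------------------------------
  ann <- compute_cell_qc(counts, ann, config$qc$mito_prefix)
  fc <- filter_cells(counts, ann, config$qc)
  counts <- filter_genes(fc$counts, config$qc$min_cells_per_gene)
  ann <- fc$annotation
  stage_counts$post_qc <- c(cells = ncol(counts), genes = nrow(counts))
  manifest <- c(manifest, write_stage_tsv(ann, out, "cell_metadata", config_hash))

  # --- normalize + HVG -----------------------------------------------------
  norm <- normalize_counts(counts)
  hvg <- select_hvg(norm, ann, n_top = config$n_hvg)
  log_stage("hvg", sprintf("%d genes in the HVG union", length(hvg)))

  # --- cluster + annotate --------------------------------------------------
  clusters <- cluster_cells(norm, hvg, config$n_components,
                            k = min(config$k_clusters, ncol(norm)),
                            seed = derive_seed(seed, 2L))
  panel <- if (is.character(config$panel)) read_marker_panel(config$panel) else config$panel
  annot <- annotate_clusters(norm, clusters, panel)
  ann$cluster_id <- unname(clusters[ann$barcode])
  ann$population <- unname(attr(annot, "cell_population")[ann$barcode])
  log_stage("annotate", paste(annot$population, collapse = ", "))
  manifest <- c(manifest, write_stage_tsv(ann, out, "annotated_cells", config_hash))
  stage_counts$clustered <- c(cells = ncol(norm), clusters = nrow(annot))

  # --- expression summaries (Table-1 style) --------------------------------
  marker_genes <- intersect(c("OPN1SW", "OPN1MW", "NR2E3", "SAG", "ARR3",
                              "GNAT1", "RHO"), rownames(counts))
  grp <- paste(ann$genotype, ann$population, sep = ":")
  summary_tbl <- expression_summary(counts, norm, grp, marker_genes)
  manifest <- c(manifest, write_stage_tsv(summary_tbl, out, "expression_summary",
                                          config_hash))

  # --- per-population DE ---------------------------------------------------
  de_tables <- list()
  if (length(unique(ann$genotype)) == 2) {
    gts <- sort(unique(ann$genotype))
    for (pop in sort(unique(ann$population))) {
      in_pop <- ann$population == pop
      ca <- ann$barcode[in_pop & ann$genotype == gts[1]]
      cb <- ann$barcode[in_pop & ann$genotype == gts[2]]
      if (length(ca) >= config$de$min_cells_per_group &&
          length(cb) >= config$de$min_cells_per_group) {
        de_tables[[pop]] <- de_between_groups(norm, ca, cb, config$de)
        log_stage("de", sprintf("%s: %d significant (%s vs %s)", pop,
                                sum(de_tables[[pop]]$significant), gts[1], gts[2]))
      }
    }
    if (length(de_tables))
      manifest <- c(manifest, write_stage_tsv(
        bind_rows(de_tables, .id = "population"), out, "de_results", config_hash))
  }

  # --- cod three-way classification ----------------------------------------
  tri <- NULL
  # mutant cells in rod-like (cod or rod) clusters are the cod query, mirroring
  # the comparison of mutant rod-like cells against WT rods and WT cones
  cod_cells <- ann$barcode[ann$population %in% c("cod", "rod") &
                             ann$genotype == "MUT"]
  rod_cells <- ann$barcode[ann$population == "rod" & ann$genotype == "WT"]
  cone_cells <- ann$barcode[ann$population %in% c("ML_cone", "S_cone") &
                              ann$genotype == "WT"]
  if (length(cod_cells) >= config$de$min_cells_per_group &&
      length(rod_cells) >= config$de$min_cells_per_group &&
      length(cone_cells) >= config$de$min_cells_per_group) {
    tri <- tri_compare(norm, cod_cells, rod_cells, cone_cells, config$de,
                       ref_names = c("rod", "cone"))
    log_stage("tricompare", sprintf("%d genes classified",
                                    sum(!is.na(tri$class))))
    manifest <- c(manifest, write_stage_tsv(tri, out, "cod_classification",
                                            config_hash))
  }

  # --- binding-site enrichment ---------------------------------------------
  enr <- NULL
  gene_set <- config$gene_set
  if (is.character(gene_set) && length(gene_set) == 1 && file.exists(gene_set))
    gene_set <- read_gene_sets(gene_set)[[1]]
  if (is.null(gene_set) && !is.null(truth)) gene_set <- truth$binding_site_set
  if (!is.null(gene_set)) {
    full_universe <- if (!is.null(truth)) truth$universe else rownames(counts)
    expressed <- rownames(counts)[Matrix::rowSums(counts > 0) >=
                                    config$de$de_universe_min_cells]
    enr <- list(expressed = enrichment_test(
      full_universe, gene_set, expressed,
      n_iterations = config$enrichment_iterations,
      seed = derive_seed(seed, 3L)))
    if (!is.null(tri)) {
      de_genes <- tri$gene[!is.na(tri$class)]
      if (length(de_genes) >= 1)
        enr$de_genes <- enrichment_test(
          expressed, gene_set, intersect(de_genes, expressed),
          n_iterations = config$enrichment_iterations,
          seed = derive_seed(seed, 4L))
    }
    log_stage("enrich", sprintf("expressed-gene overlap %.1f%% (null %.1f%%)",
                                100 * enr$expressed$observed_fraction,
                                100 * enr$expressed$null_mean))
  }

  # --- WT photoreceptor trajectory -----------------------------------------
  traj <- NULL
  if (isTRUE(config$run_trajectory)) {
    phot <- ann$barcode[ann$genotype == "WT" &
                          ann$population %in% c("rod", "ML_cone", "S_cone",
                                                "developing", "cod",
                                                "photoreceptor")]
    if (length(phot) >= 50) {
      sub_counts <- counts[, phot, drop = FALSE]
      sub_norm <- norm[, phot, drop = FALSE]
      labels <- paste(ann$age_day[match(phot, ann$barcode)],
                      coarse_type_labels(sub_counts), sep = ":")
      ord <- tryCatch(
        select_ordering_genes(sub_counts, labels, config$ordering),
        error = function(e) NULL)
      if (!is.null(ord) && length(ord) >= 2) {
        traj <- build_trajectory(sub_norm, ord,
                                 seed = derive_seed(seed, 5L))
        log_stage("trajectory", sprintf("%d cells, branch node %s",
                                        nrow(traj$cells),
                                        as.character(traj$branch_node)))
        manifest <- c(manifest, write_stage_tsv(traj$cells, out,
                                                "trajectory_cells", config_hash))
        manifest <- c(manifest, write_stage_tsv(traj$edges, out,
                                                "trajectory_edges", config_hash))
      }
    }
  }

  report <- structure(list(
    stage_counts = stage_counts,
    config_hash = config_hash,
    seed = seed,
    annotation = ann,
    cluster_annotation = annot,
    expression_summary = summary_tbl,
    de = de_tables,
    tri_compare = tri,
    enrichment = enr,
    trajectory = traj,
    manifest = manifest[!vapply(manifest, is.null, logical(1))],
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    versions = c(conecod = as.character(utils::packageVersion("conecod")),
                 R = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "conecod_run_report")
  if (!is.null(out)) {
    rj <- report[setdiff(names(report), c("annotation", "trajectory", "de"))]
    rj$enrichment <- lapply(report$enrichment, function(e)
      e[setdiff(names(e), "null_fractions")])
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(rj, file.path(out, "run_report.json"),
                           auto_unbox = TRUE, digits = 10, force = TRUE)
  }
  report
}

#' @export
print.conecod_run_report <- function(x, ...) {
  cat("conecod run report (config ", x$config_hash, ")\n", sep = "")
  for (s in names(x$stage_counts))
    cat(sprintf("  %-10s %s\n", s,
                paste(names(x$stage_counts[[s]]), x$stage_counts[[s]],
                      sep = "=", collapse = ", ")))
  if (length(x$de))
    cat("  DE comparisons:",
        paste(sprintf("%s (%d sig)", names(x$de),
                      vapply(x$de, function(d) sum(d$significant), integer(1))),
              collapse = ", "), "\n")
  if (!is.null(x$tri_compare)) {
    tab <- table(x$tri_compare$class, useNA = "no")
    cat("  cod classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$enrichment))
    cat(sprintf("  enrichment (expressed): %.1f%% observed vs %.1f%% null\n",
                100 * x$enrichment$expressed$observed_fraction,
                100 * x$enrichment$expressed$null_mean))
  cat(sprintf("  wall time: %.1f s\n", x$wall_time_s))
  invisible(x)
}
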