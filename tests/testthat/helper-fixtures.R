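# Shared fixtures, all generated in code.

# Tiny hand-checkable count matrix: 3 genes x 2 cells.
tiny_counts <- function() {
  m <- Matrix::Matrix(matrix(c(1, 0, 5, 0, 2, 5), nrow = 3,
                             dimnames = list(c("MT-CO1", "NRL", "SAG"),
                                             c("c1", "c2"))),
                      sparse = TRUE)
  methods::as(m, "CsparseMatrix")
}

# Two equal populations (rod / ML cone), 8-fold markers.
two_pop_dataset <- function(n = 600, seed = 5) {
  generate_organoid_dataset(synthetic_spec(
    n_cells_per_genotype = n,
    population_fractions = list(WT = c(rod = 0.5, ML_cone = 0.5)),
    marker_program = default_marker_program()[c("rod", "ML_cone")],
    baseline_mean = 0.4, n_genes_total = 500, seed = seed))
}

# Six transcriptionally distinct populations for cluster naming.
six_pop_dataset <- function(n = 900, seed = 7) {
  fr <- c(rod = 0.2, ML_cone = 0.15, bipolar = 0.2, muller = 0.15,
          RGC = 0.15, amacrine = 0.15)
  generate_organoid_dataset(synthetic_spec(
    n_cells_per_genotype = n,
    population_fractions = list(WT = fr),
    marker_program = default_marker_program()[names(fr)],
    baseline_mean = 1, n_genes_total = 500, seed = seed))
}

# Mutant cods + S cones vs WT rods + ML cones, for the three-way comparison.
cod_dataset <- function(n = 400, seed = 13) {
  generate_organoid_dataset(synthetic_spec(
    n_cells_per_genotype = n,
    population_fractions = list(WT = c(rod = 0.6, ML_cone = 0.4),
                                MUT = c(cod = 0.7, S_cone = 0.3)),
    marker_program = default_marker_program()[c("rod", "ML_cone",
                                                "S_cone", "cod")],
    baseline_mean = 1, n_genes_total = 500, seed = seed))
}

# QC + normalization convenience for a generated dataset.
prep_norm <- function(ds, min_genes = 50) {
  fc <- suppressMessages(filter_cells(
    ds$counts, compute_cell_qc(ds$counts, ds$annotation),
    qc_config(min_genes_per_cell = min_genes)))
  counts <- suppressMessages(filter_genes(fc$counts, 2))
  list(counts = counts, norm = normalize_counts(counts),
       annotation = fc$annotation,
       truth = ds$truth$cells[match(colnames(counts),
                                    ds$truth$cells$barcode), ])
}

# Exhaustive two-sided Wilcoxon p by enumerating all rank assignments.
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  mu <- nx * (n - nx) / 2
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Brute-force hypergeometric upper tail P(X >= q).
enumerate_hyper_tail <- function(q, K, N, k) {
  xs <- max(0, q):min(K, k)
  sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}
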