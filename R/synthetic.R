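#' Default per-genotype population composition
#'
#' Stylized organoid composition: wild-type (WT) retina contains rods but no
#' rod/cone-intermediate "cod" cells; the NRL-null mutant (MUT) contains cods
#' but no rods. Short-wavelength (S) cones are over-represented in the mutant,
#' as expected when the rod fate is unavailable. Fractions per genotype sum
#' to 1.
#'
#' @return Named list with elements `WT` and `MUT`, each a named numeric
#'   vector of population fractions.
#' @export
default_population_fractions <- function() {
  list(
    WT = c(rod = 0.35, ML_cone = 0.12, S_cone = 0.04, developing = 0.18,
           bipolar = 0.08, amacrine = 0.06, horizontal = 0.04,
           muller = 0.08, RGC = 0.05),
    MUT = c(cod = 0.30, ML_cone = 0.12, S_cone = 0.09, developing = 0.18,
            bipolar = 0.08, amacrine = 0.06, horizontal = 0.04,
            muller = 0.08, RGC = 0.05)
  )
}

#' Default marker fold-elevation program
#'
#' Real retinal marker symbols with per-population fold elevations over the
#' baseline mean. The cod program encodes the intermediate signature: very
#' high OPN1SW, cone transduction genes well below cone level, rod genes well
#' below rod level.
#'
#' @return Named list: population name -> named numeric vector (gene -> fold,
#'   all >= 1).
#' @export
default_marker_program <- function() {
  rod_genes <- c("NR2E3", "SAG", "GNAT1", "RHO", "NRL", "PDE6G", "CNGA1",
                 "PDE6A", "ROM1", "GNGT1")
  cone_genes <- c("ARR3", "OPN1MW", "GNAT2", "PDE6H", "GNGT2", "GUCA1C",
                  "PDE6C", "CNGB3")
  list(
    rod = setNames(rep(8, length(rod_genes)), rod_genes),
    ML_cone = setNames(rep(8, length(cone_genes)), cone_genes),
    S_cone = c(OPN1SW = 12, CCDC136 = 8,
               setNames(rep(6, 4), c("ARR3", "GNAT2", "PDE6H", "GUCA1C"))),
    # cod: OPN1SW above both, cone genes near rod level, rod genes near cone
    # level; NRL itself absent (the mutant is NRL-null).
    cod = c(OPN1SW = 16,
            setNames(rep(3, 4), c("NR2E3", "SAG", "GNAT1", "RHO")),
            setNames(rep(2.5, 4), c("ARR3", "GNAT2", "PDE6H", "GNGT2"))),
    developing = c(CRX = 8, OTX2 = 8, RCVRN = 6, PRDM1 = 6, DCT = 4),
    bipolar = c(VSX1 = 8, VSX2 = 8, CABP5 = 8, GRM6 = 6, TRPM1 = 6),
    amacrine = c(TFAP2A = 8, TFAP2B = 8, GAD1 = 6, SLC32A1 = 6),
    horizontal = c(ONECUT1 = 8, ONECUT2 = 8, LHX1 = 6, CALB1 = 4),
    muller = c(RLBP1 = 8, SLC1A3 = 8, GLUL = 6, CLU = 6, APOE = 6),
    RGC = c(POU4F2 = 8, RBPMS = 8, NEFL = 6, GAP43 = 6, SNCG = 6)
  )
}

mito_gene_names <- function() {
  c("MT-CO1", "MT-CO2", "MT-CO3", "MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4",
    "MT-ND4L", "MT-ND5", "MT-ND6", "MT-ATP6", "MT-ATP8", "MT-CYB")
}

#' Specify a synthetic organoid scRNA-seq dataset
#'
#' Collects every parameter of the negative-binomial UMI simulator into a
#' validated specification. Counts for gene g in a cell of population p are
#' drawn NB with mean `baseline_mean * fold(p, g) * depth_factor(cell)` and
#' variance `mu + phi * mu^2`; a Beta-drawn fraction of each cell's expected
#' depth is reallocated to the mitochondrial (`MT-`) genes so that QC
#' thresholds are exercised realistically.
#'
#' @param n_cells_per_genotype Cells simulated per genotype (default 5000,
#'   matching the order of magnitude of one organoid age group).
#' @param population_fractions Named list genotype -> named fractions summing
#'   to 1. The mutant must contain `cod` and no `rod`; WT the reverse.
#' @param marker_program Named list population -> named numeric fold vector
#'   (all folds >= 1).
#' @param baseline_mean Mean UMI per non-marker gene per cell before depth
#'   scaling.
#' @param nb_dispersion NB dispersion phi (variance mu + phi mu^2); > 0 gives
#'   over-dispersed Drop-seq-like counts.
#' @param depth_lognormal_mu_sigma Length-2 numeric: meanlog and sdlog of the
#'   per-cell depth factor.
#' @param mito_beta_params Length-2 positive numeric: Beta shape parameters of
#'   the per-cell mitochondrial fraction.
#' @param n_genes_total Total gene universe size (markers + MT genes +
#'   ribosomal fillers + numbered fillers).
#' @param doublet_rate Optional fraction of cells replaced by summed random
#'   pairs (default 0; doublets are flagged in the ground truth).
#' @param seed Integer seed; fixes every emitted matrix bit-for-bit.
#' @return A `conecod_spec` list.
#' @export
synthetic_spec <- function(n_cells_per_genotype = 5000,
                           population_fractions = default_population_fractions(),
                           marker_program = default_marker_program(),
                           baseline_mean = 0.2,
                           nb_dispersion = 0.3,
                           depth_lognormal_mu_sigma = c(0, 0.35),
                           mito_beta_params = c(2, 18),
                           n_genes_total = 2000,
                           doublet_rate = 0,
                           seed = 1L) {
  assert_that(n_cells_per_genotype >= 0, "n_cells_per_genotype must be >= 0")
  assert_that(baseline_mean > 0, "baseline_mean must be positive")
  assert_that(nb_dispersion >= 0, "nb_dispersion must be >= 0")
  assert_that(all(mito_beta_params > 0), "mito_beta_params must be positive")
  assert_that(length(depth_lognormal_mu_sigma) == 2,
              "depth_lognormal_mu_sigma must have length 2")
  for (g in names(population_fractions)) {
    fr <- population_fractions[[g]]
    if (abs(sum(fr) - 1) > 1e-9)
      stop_conecod(paste0("population fractions for ", g, " sum to ", sum(fr),
                          ", not 1"), class = "conecod_validation_error")
    assert_that(all(fr >= 0), "population fractions must be non-negative")
  }
  if (!is.null(population_fractions$MUT)) {
    fr <- population_fractions$MUT
    assert_that("cod" %in% names(fr)[fr > 0] && !("rod" %in% names(fr)[fr > 0]),
                "mutant composition must contain 'cod' and exclude 'rod'")
  }
  if (!is.null(population_fractions$WT)) {
    fr <- population_fractions$WT
    assert_that("rod" %in% names(fr)[fr > 0] && !("cod" %in% names(fr)[fr > 0]),
                "WT composition must contain 'rod' and exclude 'cod'")
  }
  for (p in names(marker_program))
    assert_that(all(marker_program[[p]] >= 1),
                paste0("marker folds must be >= 1 (population ", p, ")"))
  pops_used <- unique(unlist(lapply(population_fractions,
                                    function(f) names(f)[f > 0])))
  missing_prog <- setdiff(pops_used, names(marker_program))
  if (length(missing_prog))
    rlang::warn(paste("populations without a marker program:",
                      paste(missing_prog, collapse = ", ")))
  marker_genes <- unique(unlist(lapply(marker_program, names)))
  assert_that(n_genes_total >= length(marker_genes) + length(mito_gene_names()),
              "n_genes_total smaller than the marker + MT gene count")
  structure(list(
    n_cells_per_genotype = as.integer(n_cells_per_genotype),
    population_fractions = population_fractions,
    marker_program = marker_program,
    baseline_mean = baseline_mean,
    nb_dispersion = nb_dispersion,
    depth_lognormal_mu_sigma = depth_lognormal_mu_sigma,
    mito_beta_params = mito_beta_params,
    n_genes_total = as.integer(n_genes_total),
    doublet_rate = doublet_rate,
    seed = as.integer(seed)
  ), class = "conecod_spec")
}

# Build the gene universe for a spec: markers, MT genes, ribosomal fillers,
# then numbered fillers up to n_genes_total.
build_universe <- function(spec) {
  markers <- unique(unlist(lapply(spec$marker_program, names)))
  mt <- mito_gene_names()
  n_rib <- min(20L, max(0L, spec$n_genes_total - length(markers) - length(mt)))
  rib <- c(sprintf("RPL%d", seq_len(ceiling(n_rib / 2))),
           sprintf("RPS%d", seq_len(floor(n_rib / 2))))
  n_fill <- spec$n_genes_total - length(markers) - length(mt) - length(rib)
  fill <- if (n_fill > 0) sprintf("GENE%04d", seq_len(n_fill)) else character()
  c(markers, mt, rib, fill)
}

# Exact integer composition of n cells over fractions (largest remainders).
allocate_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Draw a genes x cells NB count matrix given a per-gene base-mean matrix
# (genes x cells), with MT reallocation and depth scaling already applied.
draw_nb_matrix <- function(mu, phi) {
  n <- length(mu)
  x <- if (phi > 0) rnbinom(n, mu = as.vector(mu), size = 1 / phi)
       else stats::rpois(n, as.vector(mu))
  matrix(x, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Generate a synthetic organoid dataset with known ground truth
#'
#' Emulates Drop-seq-like UMI matrices for a WT and an NRL-null genotype with
#' distinct retinal populations, genotype-specific composition, per-cell
#' depth and mitochondrial-fraction covariates.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (sparse genes x cells), `annotation` (tibble:
#'   barcode, genotype, age_day, organoid_id), `truth` (list: `cells` tibble
#'   with true population labels, `universe`, `binding_site_set`).
#' @export
generate_organoid_dataset <- function(spec) {
  assert_that(inherits(spec, "conecod_spec"), "spec must come from synthetic_spec()")
  set.seed(spec$seed)
  universe <- build_universe(spec)
  mt_idx <- which(is_mito(universe))
  rib_idx <- which(is_ribosomal(universe))
  n_genes <- length(universe)

  genotypes <- names(spec$population_fractions)
  blocks <- list(); ann <- list(); truth_cells <- list()
  for (g in genotypes) {
    n <- spec$n_cells_per_genotype
    if (n == 0) next
    fr <- spec$population_fractions[[g]]
    fr <- fr[fr > 0]
    pop_n <- allocate_counts(n, fr)
    pops <- rep(names(fr), pop_n)
    barcodes <- sprintf("%s_%05d", g, seq_len(n))
    depth <- rlnorm(n, spec$depth_lognormal_mu_sigma[1],
                    spec$depth_lognormal_mu_sigma[2])
    mito_fr <- rbeta(n, spec$mito_beta_params[1], spec$mito_beta_params[2])

    # base mean per gene per population
    base <- matrix(spec$baseline_mean, nrow = n_genes, ncol = length(fr),
                   dimnames = list(universe, names(fr)))
    base[rib_idx, ] <- spec$baseline_mean * 3  # ribosomal genes run hot
    for (p in names(fr)) {
      prog <- spec$marker_program[[p]]
      prog <- prog[names(prog) %in% universe]
      if (length(prog)) base[names(prog), p] <- spec$baseline_mean * prog
    }
    base[mt_idx, ] <- 0

    mu <- base[, pops, drop = FALSE] *
      matrix(depth, nrow = n_genes, ncol = n, byrow = TRUE)
    # reallocate a mito_fr share of each cell's expected depth to MT genes
    non_mt_tot <- colSums(mu)
    mt_tot <- non_mt_tot * mito_fr / pmax(1 - mito_fr, 1e-6)
    mu[mt_idx, ] <- matrix(mt_tot / length(mt_idx), nrow = length(mt_idx),
                           ncol = n, byrow = TRUE)
    counts <- draw_nb_matrix(mu, spec$nb_dispersion)
    colnames(counts) <- barcodes
    blocks[[g]] <- counts
    ann[[g]] <- tibble(
      barcode = barcodes, genotype = g, age_day = 170L,
      organoid_id = sprintf("%s_org%d", g, ((seq_len(n) - 1L) %% 4L) + 1L)
    )
    truth_cells[[g]] <- tibble(barcode = barcodes, population = pops,
                               is_doublet = FALSE)
  }

  if (length(blocks) == 0) {
    counts <- Matrix::Matrix(0, nrow = n_genes, ncol = 0, sparse = TRUE,
                             dimnames = list(universe, character()))
    ann_tbl <- tibble(barcode = character(), genotype = character(),
                      age_day = integer(), organoid_id = character())
    truth_tbl <- tibble(barcode = character(), population = character(),
                        is_doublet = logical())
  } else {
    counts <- do.call(cbind, blocks)
    ann_tbl <- bind_rows(ann)
    truth_tbl <- bind_rows(truth_cells)
    if (spec$doublet_rate > 0) {
      n_dbl <- floor(spec$doublet_rate * ncol(counts))
      if (n_dbl > 0) {
        pick <- matrix(sample.int(ncol(counts), 2 * n_dbl), ncol = 2)
        counts[, pick[, 1]] <- counts[, pick[, 1]] + counts[, pick[, 2]]
        keep <- setdiff(seq_len(ncol(counts)), pick[, 2])
        dbl_bc <- colnames(counts)[pick[, 1]]
        counts <- counts[, keep, drop = FALSE]
        ann_tbl <- ann_tbl[keep, ]
        truth_tbl <- truth_tbl[keep, ]
        truth_tbl$is_doublet <- truth_tbl$barcode %in% dbl_bc
      }
    }
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  }

  # designate a binding-site target set: photoreceptor markers plus a random
  # fifth of the remaining (non-MT) universe
  phot <- unique(unlist(lapply(
    spec$marker_program[intersect(names(spec$marker_program),
                                  c("rod", "ML_cone", "S_cone", "cod"))],
    names)))
  rest <- setdiff(universe[-mt_idx], phot)
  bset <- sort(c(phot, sample(rest, round(0.2 * length(rest)))))

  list(counts = counts, annotation = ann_tbl,
       truth = list(cells = truth_tbl, universe = universe,
                    binding_site_set = bset))
}

#' Generate a bifurcating maturation trajectory with known pseudotime
#'
#' Cells are placed uniformly on a developmental axis t in `[0, 1]`; at
#' `branch_point` the axis splits into a rod and a cone branch.
#' Early-progenitor genes ramp down with t, shared maturation genes ramp up,
#' and branch-specific photoreceptor genes ramp up linearly after the split
#' on their branch only.
#'
#' @param spec A [synthetic_spec()]; `n_cells_per_genotype` gives the cell
#'   count, and the NB noise/depth parameters are reused.
#' @param branch_point Real strictly inside (0, 1).
#' @return List with `counts`, `annotation`, `truth` (the `cells` tibble
#'   carries true `pseudotime` and `branch` in trunk / rod_branch /
#'   cone_branch).
#' @export
generate_bifurcation <- function(spec, branch_point = 0.4) {
  assert_that(inherits(spec, "conecod_spec"), "spec must come from synthetic_spec()")
  if (!(branch_point > 0 && branch_point < 1))
    stop_conecod("branch_point must be strictly inside (0, 1)",
                 class = "conecod_validation_error")
  set.seed(derive_seed(spec$seed, 7L))
  n <- spec$n_cells_per_genotype
  rod_genes <- names(default_marker_program()$rod)
  cone_genes <- c(names(default_marker_program()$ML_cone), "OPN1SW")
  early_genes <- c("SOX2", "HES1", "HES5", "PAX6", "LHX2", "SFRP2",
                   sprintf("EARLY%02d", 1:24))
  shared_genes <- c("CRX", "OTX2", "RCVRN", "NEUROD1", "PRDM1",
                    sprintf("MATUR%02d", 1:25))
  core <- c(early_genes, shared_genes, rod_genes, cone_genes, mito_gene_names())
  n_fill <- max(0L, spec$n_genes_total - length(core))
  universe <- c(core, if (n_fill > 0) sprintf("GENE%04d", seq_len(n_fill)))

  t_true <- runif(n)
  branch <- ifelse(t_true <= branch_point, "trunk",
                   sample(c("rod_branch", "cone_branch"), n, replace = TRUE))
  barcodes <- sprintf("TRAJ_%05d", seq_len(n))
  depth <- rlnorm(n, spec$depth_lognormal_mu_sigma[1],
                  spec$depth_lognormal_mu_sigma[2])
  mito_fr <- rbeta(n, spec$mito_beta_params[1], spec$mito_beta_params[2])

  amp <- 7  # fold span of the linear ramps (1 -> 8), matching marker folds
  ramp_up <- 1 + amp * t_true
  ramp_down <- 1 + amp * (1 - t_true)
  post <- pmax(0, (t_true - branch_point) / (1 - branch_point))
  rod_ramp <- ifelse(branch == "rod_branch", 1 + amp * post, 1)
  cone_ramp <- ifelse(branch == "cone_branch", 1 + amp * post, 1)

  mu <- matrix(spec$baseline_mean, nrow = length(universe), ncol = n,
               dimnames = list(universe, barcodes))
  mu[early_genes, ] <- spec$baseline_mean * rep(ramp_down, each = length(early_genes))
  mu[shared_genes, ] <- spec$baseline_mean * rep(ramp_up, each = length(shared_genes))
  mu[rod_genes, ] <- spec$baseline_mean * rep(rod_ramp, each = length(rod_genes))
  mu[cone_genes, ] <- spec$baseline_mean * rep(cone_ramp, each = length(cone_genes))
  mt_idx <- which(is_mito(universe))
  mu[mt_idx, ] <- 0
  mu <- mu * rep(depth, each = length(universe))
  non_mt_tot <- colSums(mu)
  mu[mt_idx, ] <- matrix(non_mt_tot * mito_fr / pmax(1 - mito_fr, 1e-6) /
                           length(mt_idx),
                         nrow = length(mt_idx), ncol = n, byrow = TRUE)
  counts <- methods::as(Matrix::Matrix(draw_nb_matrix(mu, spec$nb_dispersion),
                                       sparse = TRUE), "CsparseMatrix")
  ann <- tibble(barcode = barcodes, genotype = "WT", age_day = 170L,
                organoid_id = sprintf("WT_org%d", ((seq_len(n) - 1L) %% 4L) + 1L))
  truth <- list(
    cells = tibble(barcode = barcodes, population = "photoreceptor",
                   pseudotime = t_true, branch = branch),
    universe = universe,
    binding_site_set = sort(c(rod_genes, cone_genes)),
    branch_point = branch_point,
    branch_genes = list(rod_branch = rod_genes, cone_branch = cone_genes,
                        shared = shared_genes, early = early_genes)
  )
  list(counts = counts, annotation = ann, truth = truth)
}

#' Generate a synthetic qPCR Cq table
#'
#' Cq values are `baseline(gene) - log2(fold in MUT) + Gaussian noise`;
#' housekeeping genes (true fold 1) are added if absent. With `noise_sd = 0`
#' the downstream 2^-ddCq recovers each injected fold exactly.
#'
#' @param true_fold_changes Named positive numeric: MUT/WT expression fold
#'   per target gene.
#' @param n_reps Technical replicates per gene per sample (>= 2).
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param n_samples Biological samples (differentiations) per condition.
#' @param housekeeping Two housekeeping gene names (true fold 1).
#' @param seed Integer seed.
#' @return Tibble with columns sample_id, condition, gene, replicate, cq,
#'   and a `housekeeping` attribute.
#' @export
generate_qpcr_table <- function(true_fold_changes, n_reps = 3, noise_sd = 0.1,
                                n_samples = 6, housekeeping = c("ACTB", "GAPDH"),
                                seed = 1L) {
  if (n_reps < 2)
    stop_conecod("n_reps must be >= 2", class = "conecod_validation_error")
  assert_that(all(true_fold_changes > 0), "fold changes must be positive")
  assert_that(length(housekeeping) == 2, "exactly two housekeeping genes required")
  set.seed(seed)
  for (hk in housekeeping)
    if (!hk %in% names(true_fold_changes)) true_fold_changes[hk] <- 1
  assert_that(all(abs(true_fold_changes[housekeeping] - 1) < 1e-12),
              "housekeeping genes must have true fold 1")
  genes <- names(true_fold_changes)
  baseline <- 20 + (seq_along(genes) * 0.37) %% 5
  names(baseline) <- genes
  grid <- tidyr::expand_grid(
    condition = c("WT", "MUT"),
    sample_idx = seq_len(n_samples),
    gene = genes,
    replicate = seq_len(n_reps)
  )
  grid |>
    mutate(
      sample_id = sprintf("%s_s%d", .data$condition, .data$sample_idx),
      cq = baseline[.data$gene] -
        ifelse(.data$condition == "MUT", log2(true_fold_changes[.data$gene]), 0) +
        rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    select("sample_id", "condition", "gene", "replicate", "cq") |>
    structure(housekeeping = housekeeping)
}
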