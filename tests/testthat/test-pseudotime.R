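test_that("NB likelihood-ratio p matches a grid-maximized likelihood oracle", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    grp <- factor(sample(c("A", "B"), n, replace = TRUE))
    if (nlevels(droplevels(grp)) < 2) next
    tot <- rpois(n, 500) + 100
    y <- rnbinom(n, mu = tot / mean(tot) * exp(rnorm(1)), size = 5)
    r <- nb_lrt(y, grp, tot)
    phi <- r$dispersion; s <- tot / mean(tot)
    ll <- function(b, idx) sum(dnbinom(y[idx], mu = s[idx] * exp(b),
                                       size = 1 / max(phi, 1e-8), log = TRUE))
    grid <- seq(-12, 12, by = 0.001)
    ll_alt <- sum(vapply(levels(grp), function(g)
      max(vapply(grid, ll, numeric(1), idx = grp == g)), numeric(1)))
    ll_null <- max(vapply(grid, ll, numeric(1), idx = rep(TRUE, n)))
    p_oracle <- pchisq(max(0, 2 * (ll_alt - ll_null)), 1, lower.tail = FALSE)
    expect_equal(r$p, p_oracle, tolerance = 1e-3)
  }
})

test_that("ordering-gene selection recovers spike-ins, is calibrated, and excludes patterns", {
  set.seed(31)
  n_cells <- 300
  grp <- rep(c("d100:rod", "d170:cone"), each = n_cells / 2)
  n_null <- 600
  mu0 <- 2
  base <- matrix(rnbinom(n_null * n_cells, mu = mu0, size = 3), n_null,
                 dimnames = list(sprintf("N%04d", 1:n_null), NULL))
  hot <- matrix(0, 50, n_cells, dimnames = list(sprintf("HOT%02d", 1:50), NULL))
  hot[, grp == "d100:rod"] <- rnbinom(sum(grp == "d100:rod") * 50, mu = mu0 * 4, size = 3)
  hot[, grp == "d170:cone"] <- rnbinom(sum(grp == "d170:cone") * 50, mu = mu0, size = 3)
  rib <- matrix(rnbinom(n_cells, mu = c(mu0 * 8, mu0)[1 + (grp == "d170:cone")],
                        size = 3), 1, dimnames = list("RPL3", NULL))
  m <- rbind(base, hot, rib)
  colnames(m) <- sprintf("c%04d", seq_len(n_cells))
  m <- Matrix::Matrix(m, sparse = TRUE)

  ranked <- select_ordering_genes(m, grp, ordering_config(n_ordering_genes = 100))
  expect_gte(sum(startsWith(ranked[1:100], "HOT")), 45)
  expect_false("RPL3" %in% ranked)
  full <- attr(ranked, "table")
  expect_false(any(grepl("^RP[LS]|^MT-", ranked)))

  # null calibration: no group effect anywhere
  set.seed(32)
  pvals <- unlist(lapply(1:4, function(i) {
    mm <- matrix(rnbinom(250 * 200, mu = 2, size = 3), 250,
                 dimnames = list(sprintf("g%03d", 1:250), sprintf("c%03d", 1:200)))
    mm <- Matrix::Matrix(mm, sparse = TRUE)
    r <- select_ordering_genes(mm, rep(c("a", "b"), each = 100),
                               ordering_config(n_ordering_genes = 2))
    attr(r, "table")$p
  }))
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("trajectory on a noiseless line recovers position perfectly", {
  n <- 120
  pos <- seq(0, 1, length.out = n)
  # two genes varying linearly along the line, no noise
  m <- rbind(A = 1 + 5 * pos, B = 6 - 5 * pos, NR2E3 = 1 + pos)
  colnames(m) <- sprintf("c%03d", 1:n)
  nm <- Matrix::Matrix(m, sparse = TRUE)
  tr <- build_trajectory(nm, rownames(nm), n_centroids = 6, seed = 1)
  sp <- cor(tr$cells$pseudotime, pos, method = "spearman")
  expect_equal(abs(sp), 1, tolerance = 0.01)
  # root pseudotime starts at zero and is maximal at a leaf
  expect_equal(min(tr$cells$pseudotime), 0, tolerance = 1e-9)
  expect_equal(unname(tr$centroid_pseudotime[as.character(tr$root)]), 0)
})

test_that("pseudotime is monotone along every root-to-leaf centroid path", {
  prep <- prep_norm(generate_bifurcation(
    synthetic_spec(n_cells_per_genotype = 600, baseline_mean = 1,
                   n_genes_total = 300, seed = 12), 0.4), min_genes = 30)
  ord <- suppressWarnings(select_ordering_genes(
    prep$counts, coarse_type_labels(prep$counts),
    ordering_config(n_ordering_genes = 120)))
  tr <- build_trajectory(prep$norm, ord, n_centroids = 10, seed = 2)
  d <- tr$centroid_pseudotime
  for (leaf in names(which(igraph::degree(tr$mst) == 1))) {
    path <- igraph::as_ids(igraph::shortest_paths(
      tr$mst, from = as.character(tr$root), to = leaf)$vpath[[1]])
    expect_true(all(diff(d[path]) > 0))
  }
  # states partition the cells
  expect_false(any(is.na(tr$cells$state)))
  expect_equal(nrow(tr$cells), ncol(prep$norm))
})

test_that("forcing the root to a terminal leaf reverses pseudotime", {
  prep <- prep_norm(generate_bifurcation(
    synthetic_spec(n_cells_per_genotype = 800, baseline_mean = 1,
                   n_genes_total = 300, seed = 3), 0.4), min_genes = 30)
  ord <- suppressWarnings(select_ordering_genes(
    prep$counts, coarse_type_labels(prep$counts),
    ordering_config(n_ordering_genes = 120)))
  tr <- build_trajectory(prep$norm, ord, n_centroids = 10, seed = 2)
  sp_fwd <- cor(tr$cells$pseudotime, prep$truth$pseudotime,
                method = "spearman")
  expect_gt(sp_fwd, 0.6)
  # re-root at the farthest leaf: ordering flips for cells on that lineage
  far_leaf <- as.integer(names(which.max(
    tr$centroid_pseudotime[names(which(igraph::degree(tr$mst) == 1))])))
  tr_rev <- build_trajectory(prep$norm, ord, n_centroids = 10,
                             root = far_leaf, seed = 2)
  on_lineage <- tr_rev$cells$branch == "trunk" |
    prep$truth$branch != "trunk"
  sp_rev <- cor(tr_rev$cells$pseudotime, prep$truth$pseudotime,
                method = "spearman")
  expect_lt(sp_rev, 0)
})

test_that("branch-node DE recovers branch spike-ins and handles edge cases", {
  prep <- prep_norm(generate_bifurcation(
    synthetic_spec(n_cells_per_genotype = 1000, baseline_mean = 1,
                   n_genes_total = 300, seed = 6), 0.35), min_genes = 30)
  ord <- suppressWarnings(select_ordering_genes(
    prep$counts, coarse_type_labels(prep$counts),
    ordering_config(n_ordering_genes = 120)))
  tr <- build_trajectory(prep$norm, ord, n_centroids = 12, seed = 2)
  branches <- setdiff(unique(tr$cells$branch), "trunk")
  expect_length(branches, 2)
  de <- branch_de(prep$counts, tr, branches[1], branches[2], top_n = 40)
  expect_true(all(de$q >= de$p))
  heat <- attr(de, "heatmap_genes")
  expect_length(heat, 40)
  expect_false(any(grepl("^RP[LS]", heat)))
  # branch-specific programs dominate the top set
  prog <- c(names(default_marker_program()$rod),
            names(default_marker_program()$ML_cone), "OPN1SW")
  expect_gte(sum(heat %in% prog), 10)
  # direction: rod genes higher on the rod-majority branch
  rodish <- de[de$gene == "NR2E3", ]
  expect_true(abs(log(rodish$mean_a + 0.01) - log(rodish$mean_b + 0.01)) > 0.5)

  de0 <- branch_de(prep$counts, tr, branches[1], branches[2], top_n = 0)
  expect_length(attr(de0, "heatmap_genes"), 0)
  expect_gt(nrow(de0), 0)
  expect_error(branch_de(prep$counts, tr, "no_such_branch", branches[2]),
               class = "conecod_validation_error")
})
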