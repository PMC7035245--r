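test_that("clustering recovers two well-separated populations", {
  prep <- prep_norm(two_pop_dataset())
  expect_error(cluster_cells(prep$norm, k = 1), class = "conecod_validation_error")
  expect_error(cluster_cells(prep$norm, k = ncol(prep$norm) + 1),
               class = "conecod_validation_error")
  cl <- cluster_cells(prep$norm, select_hvg(prep$norm, n_top = 100), k = 2,
                      seed = 1)
  agree <- max(mean((cl == 1) == (prep$truth$population == "rod")),
               mean((cl == 2) == (prep$truth$population == "rod")))
  expect_gte(agree, 0.95)
})

test_that("marker annotation names clusters and resolves ties deterministically", {
  prep <- prep_norm(two_pop_dataset())
  cl <- cluster_cells(prep$norm, select_hvg(prep$norm, n_top = 100), k = 2,
                      seed = 1)
  ann <- annotate_clusters(prep$norm, cl,
                           default_marker_panel()[c("rod", "ML_cone")])
  expect_setequal(ann$population, c("rod", "ML_cone"))
  pred <- attr(ann, "cell_population")[colnames(prep$norm)]
  expect_gte(mean(pred == prep$truth$population), 0.95)

  # uniform expression: every panel ties at z = 0; first panel name wins
  flat <- Matrix::Matrix(matrix(1, 4, 20,
                                dimnames = list(c("NR2E3", "SAG", "ARR3", "OPN1MW"),
                                                sprintf("c%02d", 1:20))),
                         sparse = TRUE)
  tie <- annotate_clusters(flat, rep(1:2, each = 10),
                           list(a_rod = c("NR2E3", "SAG"),
                                b_cone = c("ARR3", "OPN1MW")))
  expect_equal(tie$population, c("a_rod", "a_rod"))
  expect_true(all(tie$ambiguous))

  suppressWarnings(
    expect_error(annotate_clusters(flat, rep(1, 20), list(x = "ABSENT")),
                 class = "conecod_annotation_error"))
})

test_that("six-population fixture is named correctly at the cluster level", {
  ds <- six_pop_dataset()
  prep <- prep_norm(ds)
  cl <- cluster_cells(prep$norm, select_hvg(prep$norm, n_top = 300),
                      n_components = 10, k = 9, seed = 1)
  pops <- c("rod", "ML_cone", "bipolar", "muller", "RGC", "amacrine")
  ann <- annotate_clusters(prep$norm, cl, default_marker_panel()[pops])
  maj <- vapply(ann$cluster, function(k)
    names(which.max(table(prep$truth$population[cl == k]))), character(1))
  expect_gte(mean(ann$population == maj), 0.95)
})

test_that("annotation is invariant to cell order", {
  prep <- prep_norm(two_pop_dataset(n = 150))
  cl <- cluster_cells(prep$norm, k = 2, seed = 1)
  ann1 <- annotate_clusters(prep$norm, cl,
                            default_marker_panel()[c("rod", "ML_cone")])
  perm <- sample(ncol(prep$norm))
  ann2 <- annotate_clusters(prep$norm[, perm], cl[perm],
                            default_marker_panel()[c("rod", "ML_cone")])
  expect_equal(ann1$population, ann2$population)
})

test_that("expression-group statistics match hand arithmetic and their identity", {
  # 10 cells, gene nonzero in 3 with normalized values 1, 2, 3
  raw <- matrix(0, 2, 10, dimnames = list(c("G", "H"), sprintf("c%02d", 1:10)))
  raw["G", 1:3] <- 1; raw["H", ] <- 1
  norm <- raw; norm["G", 1:3] <- c(1, 2, 3)
  raw <- Matrix::Matrix(raw, sparse = TRUE)
  norm <- Matrix::Matrix(norm, sparse = TRUE)
  s <- expression_summary(raw, norm, rep("grp", 10), genes = c("G", "H"))
  g <- s[s$gene == "G", ]
  expect_equal(g$pct_expressing, 30)
  expect_equal(g$mean_in_expressers, 2)
  expect_equal(g$mean_total, 0.6)
  # absent gene
  raw2 <- raw; raw2["G", ] <- 0
  norm2 <- norm; norm2["G", ] <- 0
  s2 <- expression_summary(raw2, norm2, rep("grp", 10), genes = "G")
  expect_equal(unlist(s2[, 3:5], use.names = FALSE), c(0, 0, 0))
  expect_error(expression_summary(raw, norm, list(empty = character())),
               "empty")

  # identity on random fixtures
  set.seed(6)
  for (i in 1:5) {
    m <- Matrix::Matrix(matrix(rpois(600, 1), 20,
                               dimnames = list(sprintf("g%02d", 1:20),
                                               sprintf("c%02d", 1:30))),
                        sparse = TRUE)
    keep <- Matrix::colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    nm <- normalize_counts(m)
    grp <- rep(c("a", "b"), length.out = ncol(m))
    tab <- expression_summary(m, nm, grp)
    expect_true(all(abs(tab$mean_total -
                          tab$mean_in_expressers * tab$pct_expressing / 100)
                    < 1e-9))
    expect_true(all(tab$mean_total <= tab$mean_in_expressers + 1e-12))
  }
})

test_that("group comparison: identical groups, extreme proportions, calibration", {
  set.seed(4)
  base <- matrix(rpois(400, 2) + 1, 1, dimnames = list("G", sprintf("c%03d", 1:400)))
  m <- Matrix::Matrix(base, sparse = TRUE)
  nm <- normalize_counts(m)
  a <- colnames(m)[1:200]; b <- colnames(m)[201:400]
  # two identical groups (shared cells split evenly by construction)
  r <- compare_expression_groups(m, nm, "G", a, b)
  expect_gt(r$p_proportion, 0.2)
  expect_gt(r$p_level, 0.01)

  # 100 of 200 vs 0 of 200 expressers
  x <- matrix(0, 1, 400, dimnames = list("G", sprintf("c%03d", 1:400)))
  x[1, 1:100] <- 3
  x2 <- rbind(x, FILL = 1); rownames(x2) <- c("G", "FILL")
  mx <- Matrix::Matrix(x2, sparse = TRUE)
  nx <- normalize_counts(mx)
  r2 <- compare_expression_groups(mx, nx, "G", colnames(mx)[1:200],
                                  colnames(mx)[201:400])
  expect_lt(r2$p_proportion, 1e-6)
  expect_true(r2$level_undefined)

  # type-I calibration of the level test under a shared distribution
  set.seed(12)
  reject <- vapply(1:1000, function(i) {
    v <- rpois(60, 3) + 1
    mm <- matrix(v, 1, dimnames = list("G", sprintf("c%02d", 1:60)))
    mm <- Matrix::Matrix(rbind(mm, FILL = 1), sparse = TRUE)
    rownames(mm) <- c("G", "FILL")
    nmx <- normalize_counts(mm)
    cc <- compare_expression_groups(mm, nmx, "G", colnames(mm)[1:30],
                                    colnames(mm)[31:60])
    cc$p_level < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("reference mapping is rank-invariant and ranks constructed profiles", {
  q <- c(A = 1, B = 3, C = 2, D = 7, E = 5)
  refs <- list(same = q, transformed = q^3 + 1,
               scrambled = c(A = 7, B = 1, C = 5, D = 2, E = 3))
  r <- refmap_spearman(q, refs)
  expect_equal(r$rho[r$reference == "same"], 1)
  expect_equal(r$rho[r$reference == "transformed"], 1)
  expect_equal(r$reference[1:2] %in% c("same", "transformed"), c(TRUE, TRUE))
  expect_lt(r$rho[r$reference == "scrambled"], 0.5)
  expect_error(refmap_spearman(q[1:2], refs["same"]),
               class = "conecod_validation_error")

  # constructed fetal-like vs foveal-like references: argmax matches design
  set.seed(8)
  cone <- setNames(rexp(60), sprintf("G%02d", 1:60))
  fetal <- rank(cone) + rnorm(60, 0, 2)        # strong rank agreement
  foveal <- sample(rank(cone)) + rnorm(60)     # none
  names(fetal) <- names(foveal) <- names(cone)
  r2 <- refmap_spearman(cone, list(fetal_like = fetal, foveal_like = foveal))
  expect_equal(r2$reference[1], "fetal_like")
})

test_that("ddCq requires housekeeping genes and respects direction and significance", {
  cq <- generate_qpcr_table(c(NR2E3 = 0.2, SAG = 0.25, OPN1SW = 4),
                            n_reps = 3, noise_sd = 0.15, n_samples = 6,
                            seed = 9)
  res <- ddcq_fold_change(cq)
  expect_lt(res$log2_fold[res$gene == "NR2E3"], 0)
  expect_lt(res$log2_fold[res$gene == "SAG"], 0)
  expect_gt(res$log2_fold[res$gene == "OPN1SW"], 0)
  expect_true(all(res$p_mannwhitney < 0.005))

  bad <- cq[cq$gene != "ACTB" | cq$sample_id != "WT_s1", ]
  attr(bad, "housekeeping") <- attr(cq, "housekeeping")
  expect_error(ddcq_fold_change(bad), class = "conecod_validation_error")

  # arithmetic housekeeping combination agrees when both housekeepers are equal
  res2 <- ddcq_fold_change(cq, hk_combine = "arithmetic")
  expect_equal(res$log2_fold, res2$log2_fold, tolerance = 0.2)
})
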