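test_that("rank-sum test matches hand-derived exact values", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p.value, 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3),
               class = "conecod_validation_error")
})

test_that("exact p equals brute-force enumeration for every size up to n = 12", {
  set.seed(17)
  for (nx in 1:6) for (ny in nx:(12 - nx)) {
    for (rep in 1:3) {
      vals <- sample(seq_len(100), nx + ny)  # distinct -> no ties
      x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
      expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                   enumerate_wilcoxon_p(x, y),
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("large-sample approximation tracks the exact p outside the extreme tail", {
  # exhaustive over all possible U for n_x = n_y = 7 (total n = 14 takes the
  # normal-approximation path) where the exact p >= 0.05; in the far tail the
  # approximation is conservative, not within 5%
  nx <- 7; ny <- 7; mu <- nx * ny / 2
  # deterministic no-tie sample with a prescribed U: x_i sits above c_i of
  # the y values, sum(c) = u
  make_u_sample <- function(u) {
    cc <- integer(nx); rem <- u
    for (i in nx:1) { cc[i] <- min(ny, rem); rem <- rem - cc[i] }
    list(x = cc * 10 + seq_len(nx), y = (1:ny) * 10)
  }
  for (u in 0:(nx * ny)) {
    p_exact <- if (u > mu) min(1, 2 * pwilcox(u - 1, nx, ny, lower.tail = FALSE))
               else if (u < mu) min(1, 2 * pwilcox(u, nx, ny)) else 1
    if (p_exact < 0.05) next
    s <- make_u_sample(u)
    w <- wilcoxon_rank_sum(s$x, s$y)
    expect_equal(w$statistic, u)
    expect_lt(abs(w$p.value - p_exact) / p_exact, 0.05)
  }
})

test_that("tie-corrected approximation agrees with the reference implementation", {
  set.seed(23)
  for (i in 1:25) {
    x <- rpois(20, 2); y <- rpois(25, 2.5)
    ours <- wilcoxon_rank_sum(x, y)$p.value
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("natural-log fold change hits the 1.6-fold boundary and is antisymmetric", {
  e1 <- log1p(c(4.437, 4.437)); e2 <- log1p(c(2.297, 2.297))
  expect_equal(ln_fold_change(e1, e2), 0.5003, tolerance = 1e-3)
  expect_equal(exp(0.5), 1.6487, tolerance = 1e-4)
  expect_equal(ln_fold_change(e1, e1), 0)
  set.seed(2)
  a <- rexp(30); b <- rexp(40)
  expect_equal(ln_fold_change(a, b), -ln_fold_change(b, a))
  expect_equal(ln_fold_change(a, b, method = "mean_log_diff"),
               mean(a) - mean(b))
})

test_that("DE between groups is calibrated on null data and recovers spike-ins", {
  # null: both groups from one distribution, 20 seeds
  n_sig <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    m <- Matrix::Matrix(matrix(rnbinom(200 * 120, mu = 2, size = 2), 200,
                               dimnames = list(sprintf("g%03d", 1:200),
                                               sprintf("c%03d", 1:120))),
                        sparse = TRUE)
    keep <- Matrix::colSums(m) > 0
    nm <- normalize_counts(m[, keep, drop = FALSE])
    cells <- colnames(nm)
    half <- length(cells) %/% 2
    de <- de_between_groups(nm, cells[1:half], cells[(half + 1):length(cells)],
                            de_config(de_universe_min_cells = 5))
    n_sig <- n_sig + sum(de$significant)
  }
  expect_lte(n_sig, 2)

  # spike-in: rod program silenced in MUT
  prep <- prep_norm(cod_dataset())
  wt_rod <- prep$truth$barcode[prep$truth$population == "rod"]
  mut_cod <- prep$truth$barcode[prep$truth$population == "cod"]
  de <- de_between_groups(prep$norm, wt_rod, mut_cod, de_config())
  cod_prog <- names(default_marker_program()$cod)
  rod_only <- setdiff(names(default_marker_program()$rod), cod_prog)
  hits <- de[de$gene %in% rod_only, ]
  expect_true(all(hits$significant))
  expect_true(all(hits$direction == "up"))   # higher in WT rods

  # infinite threshold empties the significant set
  de_inf <- de_between_groups(prep$norm, wt_rod, mut_cod,
                              de_config(lfc_threshold = Inf))
  expect_equal(sum(de_inf$significant), 0)
  expect_error(de_between_groups(prep$norm, wt_rod, c(wt_rod[1], mut_cod)),
               class = "conecod_validation_error")
})

test_that("DE output is invariant to cell and gene order and Bonferroni is monotone", {
  prep <- prep_norm(two_pop_dataset(n = 120))
  rods <- prep$truth$barcode[prep$truth$population == "rod"]
  cones <- prep$truth$barcode[prep$truth$population == "ML_cone"]
  de1 <- de_between_groups(prep$norm, rods, cones, de_config())
  perm <- sample(ncol(prep$norm))
  gperm <- sample(nrow(prep$norm))
  de2 <- de_between_groups(prep$norm[gperm, perm], sample(rods), sample(cones),
                           de_config())
  expect_equal(de1[order(de1$gene), ], de2[order(de2$gene), ],
               ignore_attr = TRUE)

  de_small <- de_between_groups(prep$norm, rods, cones,
                                de_config(bonferroni_n = 10))
  de_big <- de_between_groups(prep$norm, rods, cones,
                              de_config(bonferroni_n = 1e5))
  expect_true(all(de_big$gene[de_big$significant] %in%
                    de_small$gene[de_small$significant]))
})

test_that("three-way comparison recovers the constructed cod signature", {
  prep <- prep_norm(cod_dataset())
  tp <- prep$truth$population
  cod <- prep$truth$barcode[tp == "cod"]
  rod <- prep$truth$barcode[tp == "rod"]
  cone <- prep$truth$barcode[tp == "ML_cone"]
  expect_error(tri_compare(prep$norm, character(), rod, cone), "empty")
  expect_error(tri_compare(prep$norm, cod, rod, c(cone, rod[1])),
               class = "conecod_validation_error")

  tri <- tri_compare(prep$norm, cod, rod, cone, de_config(),
                     ref_names = c("rod", "cone"))
  cls <- function(g) tri$class[tri$gene == g]
  # S opsin above both references
  expect_equal(cls("OPN1SW"), "above-both")
  # cone genes outside the cod program sit at rod level
  cod_prog <- names(default_marker_program()$cod)
  cone_only <- setdiff(names(default_marker_program()$ML_cone), cod_prog)
  expect_true(all(vapply(cone_only, cls, character(1)) == "rod-level"))
  # rod genes outside the cod program sit at cone level
  rod_only <- setdiff(names(default_marker_program()$rod), cod_prog)
  expect_true(all(vapply(rod_only, cls, character(1)) == "cone-level"))
  # genes boosted to intermediate folds in cods land between the references
  both <- intersect(cod_prog, c(names(default_marker_program()$rod),
                                names(default_marker_program()$ML_cone)))
  expect_true(mean(vapply(both, cls, character(1)) == "intermediate") >= 0.75)

  # a gene matching refA exactly and far from refB classifies as refA-level
  expect_true(any(tri$class %in% c("rod-level", "cone-level")))
})
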