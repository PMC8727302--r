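# Expression binning, binned-control module scores, first-PC continuum
# score.

test_that("bins partition genes near-equally by rank of mean expression", {
  # 100 genes with distinct means, 4 bins -> 25/25/25/25; the gene with the
  # 30th-smallest mean lands in bin 2 (rank arithmetic)
  set.seed(1)
  v <- matrix(rnorm(5 * 100), nrow = 5)
  colnames(v) <- sprintf("g%03d", 1:100)
  norm <- as_norm(v)
  bins <- bin_genes_by_expression(norm, n_bins = 4)
  expect_equal(as.integer(table(bins)), rep(25L, 4))
  g30 <- colnames(v)[order(colMeans(v))][30]
  expect_equal(unname(bins[g30]), 2L)

  # 24 genes, distinct means, 24 bins -> one per bin, ordered by mean
  v2 <- matrix(seq_len(24 * 2) / 10, nrow = 2, byrow = TRUE)
  colnames(v2) <- sprintf("h%02d", 1:24)
  b2 <- bin_genes_by_expression(as_norm(v2), n_bins = 24)
  expect_equal(as.integer(table(b2)), rep(1L, 24))
  expect_equal(unname(b2[order(colMeans(v2))]), 1:24)
})

test_that("tied average expression merges bins with a warning", {
  v <- matrix(1, nrow = 3, ncol = 10,
              dimnames = list(NULL, sprintf("g%d", 1:10)))
  expect_warning(bins <- bin_genes_by_expression(as_norm(v), n_bins = 4),
                 "bins merge")
  expect_equal(attr(bins, "n_bins_effective"), 1L)
  expect_true(all(bins == bins[1]))
})

test_that("module score is exactly 0 when all gene columns are equal", {
  v <- matrix(rep(c(1, 3, 0.5, 2), 6), nrow = 4,
              dimnames = list(NULL, sprintf("g%d", 1:6)))
  norm <- as_norm(v)
  mod <- gene_module("m", "up", c("g2", "g5"))
  suppressWarnings(sc <- module_score(norm, mod, n_bins = 1, seed = 1))
  expect_equal(unname(sc), rep(0, 4), ignore_attr = TRUE)
})

test_that("1-bin toy equals the brute-force mean-difference oracle", {
  v <- matrix(c(1.0, 0.2, 3.0, 0.0, 1.5,
                0.4, 2.0, 0.0, 1.0, 2.5,
                2.0, 1.0, 1.0, 0.5, 0.0), nrow = 3, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"),
                              c("g1", "g2", "g3", "g4", "g5")))
  norm <- as_norm(v)
  mod <- gene_module("m", "up", c("g1", "g4"))
  # n_ctrl >= all non-module genes -> controls are exactly {g2, g3, g5}
  sc <- module_score(norm, mod, n_bins = 1, n_ctrl = 100, seed = 1)
  oracle <- rowMeans(v[, c("g1", "g4")]) - rowMeans(v[, c("g2", "g3", "g5")])
  expect_equal(sc, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scores are equivariant under cell permutation and invariant to per-cell constants", {
  coh <- generate_cohort(small_config(seed = 15))
  norm <- normalize_counts(qc_filter(coh$counts))
  mod <- coh$modules$resistance
  sc <- module_score(norm, mod, seed = 42)

  perm <- sample(nrow(norm$values))
  norm_p <- norm
  norm_p$values <- norm$values[perm, , drop = FALSE]
  norm_p$cells <- norm$cells[perm, , drop = FALSE]
  sc_p <- module_score(norm_p, mod, seed = 42)
  expect_equal(sc_p[names(sc)], sc, ignore_attr = TRUE)

  # adding a cell-specific constant to every gene cancels in the
  # gene-minus-control differencing
  shift <- norm
  offs <- runif(nrow(norm$values), -2, 2)
  shift$values <- norm$values + offs
  sc_s <- module_score(shift, mod, seed = 42)
  expect_equal(sc_s, sc, tolerance = 1e-10)
})

test_that("control draws are seed-deterministic and seed changes add mean-zero noise", {
  coh <- generate_cohort(small_config(seed = 16))
  norm <- normalize_counts(qc_filter(coh$counts))
  mod <- coh$modules$sensitivity
  a <- module_score(norm, mod, seed = 7)
  b <- module_score(norm, mod, seed = 7)
  expect_identical(a, b)
  other <- module_score(norm, mod, seed = 8)
  d <- other - a
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-3)
})

test_that("missing module genes error with names", {
  norm <- as_norm(matrix(1:12, 3, 4,
                         dimnames = list(NULL, c("a", "b", "c", "d"))))
  expect_error(module_score(norm, gene_module("m", "up", c("zz", "yy"))),
               "zz")
})

test_that("leading PC matches a dense eigendecomposition up to sign", {
  set.seed(4)
  v <- matrix(rnorm(30 * 20), nrow = 30,
              dimnames = list(sprintf("c%d", 1:30), sprintf("g%d", 1:20)))
  sc <- scale_genes(as_norm(v))
  p <- pc_score(sc, colnames(v))
  x <- sweep(sc$values, 2, colMeans(sc$values))
  ev <- eigen(crossprod(x) / (nrow(x) - 1))$vectors[, 1]
  oracle <- as.vector(x %*% ev)
  if (cor(oracle, p) < 0) oracle <- -oracle
  expect_equal(unname(p), oracle, tolerance = 1e-8)
})

test_that("PC score recovers a planted 1-factor model and is oriented by the reference", {
  set.seed(5)
  n <- 200; g <- 40
  latent <- rnorm(n)
  load <- runif(g, 0.5, 1.5)
  v <- outer(latent, load) + matrix(rnorm(n * g, sd = 0.1), n, g)
  colnames(v) <- sprintf("g%d", 1:g)
  rownames(v) <- sprintf("c%d", 1:n)
  sc <- scale_genes(as_norm(v))
  p <- pc_score(sc, colnames(v), orient_by = latent)
  expect_gt(cor(p, latent), 0.99)  # oriented positively by construction

  # 2 cells: centered 1-D projection is symmetric about 0
  two <- scale_genes(as_norm(v[1:2, ]))
  p2 <- pc_score(two, colnames(v))
  expect_equal(unname(p2[1]), -unname(p2[2]), tolerance = 1e-10)

  const <- as_norm(matrix(1, 3, 4, dimnames = list(NULL, c("a", "b", "c", "d"))))
  expect_error(pc_score(scale_genes(const), c("a", "b")), "rank-0")
})

test_that("sensitivity and resistance scores anticorrelate when a program is planted, not otherwise", {
  coh <- generate_cohort(sim_config(n_patients = 8, cells_per_patient = 250,
                                    n_genes = 800, n_sens_genes = 100,
                                    n_res_genes = 50,
                                    contaminant_fraction = 0, seed = 27))
  norm <- normalize_counts(remove_blacklist_genes(qc_filter(coh$counts)))
  tab <- score_cells(norm, coh$modules, seed = 1)
  expect_lt(cor(tab$sensitivity_score, tab$resistance_score), -0.3)
  expect_gt(cor(tab$pc_score,
                tab$sensitivity_score - tab$resistance_score,
                method = "spearman"), 0.8)

  null_coh <- generate_cohort(sim_config(n_patients = 8,
                                         cells_per_patient = 250,
                                         n_genes = 800, n_sens_genes = 100,
                                         n_res_genes = 50, program_effect = 0,
                                         depth_mean_resistant = 4000,
                                         patient_effect_sd = 0,
                                         contaminant_fraction = 0, seed = 28))
  nnorm <- normalize_counts(remove_blacklist_genes(qc_filter(null_coh$counts)))
  ntab <- score_cells(nnorm, null_coh$modules, seed = 1)
  expect_lt(abs(cor(ntab$sensitivity_score, ntab$resistance_score)), 0.1)
})
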