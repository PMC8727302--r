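# Wilcoxon DE, gene-score correlation, pseudobulk pooling and bulk scoring.

test_that("Wilcoxon p equals stats::wilcox.test exact p on tie-free small groups", {
  set.seed(42)
  for (i in 1:30) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- rnorm(nx)
    y <- rnorm(ny)
    expect_equal(relapsescore:::wilcox_rank_sum_p(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon p equals brute-force enumeration, including under ties", {
  enum_p <- function(x, y) {
    r <- rank(c(x, y))
    n <- length(r); nx <- length(x)
    mu <- nx * (n + 1) / 2
    w <- sum(r[seq_len(nx)])
    ws <- combn(n, nx, function(ix) sum(r[ix]))
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  }
  set.seed(43)
  for (i in 1:20) {
    x <- sample(0:3, sample(3:7, 1), replace = TRUE)  # heavy ties
    y <- sample(0:3, sample(3:7, 1), replace = TRUE)
    expect_equal(relapsescore:::wilcox_rank_sum_p(x, y), enum_p(x, y),
                 tolerance = 1e-12)
  }
  # spec's 5-vs-5 separated toy: most extreme split of C(10,5)
  expect_equal(relapsescore:::wilcox_rank_sum_p(1:5, 6:10),
               2 / choose(10, 5), tolerance = 1e-12)
})

test_that("large-sample approximation keeps type-I error at the nominal level", {
  set.seed(44)
  n_genes <- 200
  v <- matrix(abs(rnorm(200 * n_genes)), nrow = 200)
  colnames(v) <- sprintf("g%d", seq_len(n_genes))
  grp <- rep(c("a", "b"), each = 100)
  de <- differential_expression(as_norm(v), grp, min_pct = 0)
  frac <- mean(de$p_value < 0.05)
  # binomial 99% bounds around 0.05 at n = 200
  bound <- 2.58 * sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac - 0.05), bound + 1e-9)
})

test_that("identical groups give zero lnFC and no significant genes", {
  set.seed(45)
  v <- matrix(abs(rnorm(40 * 30)), nrow = 40)
  colnames(v) <- sprintf("g%d", 1:30)
  vv <- rbind(v, v)  # the same cells duplicated into both groups
  grp <- rep(c("a", "b"), each = 40)
  de <- differential_expression(as_norm(vv), grp, min_pct = 0)
  expect_equal(de$ln_fold_change, rep(0, nrow(de)))
  expect_false(any(de$significant))
})

test_that("DE respects the detection prefilter and Bonferroni denominator", {
  set.seed(46)
  v <- cbind(matrix(abs(rnorm(60 * 5)), nrow = 60),
             rare = c(rep(0, 58), 1, 1))
  colnames(v)[1:5] <- sprintf("g%d", 1:5)
  grp <- rep(c("a", "b"), each = 30)
  de <- differential_expression(as_norm(v), grp, min_pct = 0.1)
  expect_false("rare" %in% de$gene)  # expressed in < 10% of both groups
  expect_equal(attr(de, "n_tested"), 5L)
  expect_equal(de$p_bonferroni, pmin(1, de$p_value * 5))
  expect_error(differential_expression(as_norm(v), rep("a", 60)),
               "two groups")
})

test_that("gene-score Spearman matches the rank-then-Pearson oracle", {
  set.seed(47)
  v <- matrix(rnorm(5 * 4), nrow = 5,
              dimnames = list(sprintf("c%d", 1:5), sprintf("g%d", 1:4)))
  v[, 4] <- 2  # constant gene
  sens <- rnorm(5)
  res <- rnorm(5)
  tab <- data.frame(cell = rownames(v), sensitivity_score = sens,
                    resistance_score = res)
  out <- correlate_genes_with_scores(as_norm(v), tab)
  for (j in 1:3) {
    expect_equal(out$rho_sensitivity[j], cor(rank(v[, j]), rank(sens)),
                 tolerance = 1e-12)
    expect_equal(out$rho_resistance[j], cor(rank(v[, j]), rank(res)),
                 tolerance = 1e-12)
  }
  expect_true(out$constant[4])
  expect_true(is.na(out$rho_sensitivity[4]))

  # a gene identical to the score correlates perfectly
  v2 <- cbind(v[, 1:3], exact = sens)
  out2 <- correlate_genes_with_scores(as_norm(v2), tab)
  expect_equal(out2$rho_sensitivity[out2$gene == "exact"], 1)
})

test_that("complete pooling adds transcripts and preserves total mass", {
  m <- matrix(c(1, 2, 0,
                0, 1, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  x <- cell_counts(m, cells = data.frame(cell = c("c1", "c2"),
                                         patient = "S1"))
  pb <- pool_bulk(x, mode = "complete")
  expect_equal(unname(pb$profiles["S1", ]), c(1, 3, 3))
  expect_equal(sum(pb$profiles), sum(m))
})

test_that("equal-mode pooling gives every cell exactly d transcripts", {
  coh <- generate_cohort(sim_config(n_patients = 2, cells_per_patient = 30,
                                    n_genes = 200, n_sens_genes = 20,
                                    n_res_genes = 10, seed = 51))
  x <- coh$counts
  totals <- rowSums(as.matrix(x$counts))
  d <- min(totals)
  # per-cell check: downsample one cell at a time via a 1-cell pool
  for (i in sample(nrow(x$counts), 5)) {
    one <- x[i, ]
    pb1 <- pool_bulk(one, sample_map = setNames("s", one$cells$cell),
                     mode = "equal", d = d, seed = i)
    expect_equal(sum(pb1$profiles), d)
    expect_true(all(pb1$profiles <= as.matrix(one$counts)))
  }
  # equal mode at each cell's own total equals complete pooling
  pb_eq <- pool_bulk(x, mode = "equal", d = min(totals), seed = 1)
  expect_equal(unname(rowSums(pb_eq$profiles)),
               unname(d * pb_eq$cells_used[rownames(pb_eq$profiles)]),
               ignore_attr = TRUE)
  expect_error(pool_bulk(x, mode = "equal", d = 0), "positive")
  expect_error(pool_bulk(x, mode = "equal", d = max(totals) + 1),
               "no cell reaches")
})

test_that("equal-mode downsampling matches the hypergeometric expectation", {
  m <- matrix(c(10, 0,
                0, 1000), nrow = 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  x <- cell_counts(m, cells = data.frame(cell = c("c1", "c2"),
                                         patient = "S"))
  pools <- vapply(1:200, function(s) {
    pool_bulk(x, mode = "equal", d = 10, seed = s)$profiles[1, ]
  }, numeric(2))
  avg <- rowMeans(pools)
  # each cell contributes exactly 10, so expected pooled profile is (10, 10)
  expect_equal(unname(avg), c(10, 10), tolerance = 1e-9)
  # complete pooling leaves gene 1 at 10/1010 of the mass instead of 1/2
  pb_full <- pool_bulk(x, mode = "complete")
  expect_equal(unname(pb_full$profiles[1, ] / sum(pb_full$profiles)),
               c(10 / 1010, 1000 / 1010))
})

test_that("resistant cells' transcript share is restored by equal pooling", {
  cfg <- sim_config(n_patients = 2, cells_per_patient = 200, n_genes = 300,
                    n_sens_genes = 40, n_res_genes = 20,
                    resistance_beta_params = rbind(c(20, 2), c(2, 20)),
                    depth_mean_sensitive = 3000, depth_mean_resistant = 1000,
                    contaminant_fraction = 0, seed = 55)
  coh <- generate_cohort(cfg)
  res_cells <- coh$truth$cell[coh$truth$latent_resistance > 0.5]
  cell_share <- length(res_cells) / nrow(coh$truth)
  m <- as.matrix(coh$counts$counts)
  mass_share <- sum(m[res_cells, ]) / sum(m)
  expect_lt(mass_share, cell_share)  # complete pooling under-represents

  pb <- pool_bulk(coh$counts, sample_map = setNames(rep("s", nrow(m)),
                                                    rownames(m)),
                  mode = "equal", d = "auto", seed = 56)
  expect_equal(pb$cells_dropped, 0L)
  # after downsampling every cell weighs d, so the share equals cell share
  down_share <- length(res_cells) / unname(pb$cells_used["s"])
  expect_equal(down_share, cell_share, tolerance = 1e-12)
})

test_that("bulk module scores separate pure-sensitive from pure-resistant pools", {
  cfg <- sim_config(n_patients = 2, cells_per_patient = 150, n_genes = 400,
                    n_sens_genes = 60, n_res_genes = 30,
                    resistance_beta_params = rbind(c(1, 30), c(30, 1)),
                    contaminant_fraction = 0, patient_effect_sd = 0,
                    seed = 57)
  coh <- generate_cohort(cfg)  # P01 nearly pure sensitive, P02 resistant
  pb <- pool_bulk(coh$counts, mode = "complete")
  sc <- bulk_module_score(pb, coh$modules, seed = 5)
  expect_gt(sc$sensitivity_score[sc$sample == "P01"],
            sc$sensitivity_score[sc$sample == "P02"])
  expect_gt(sc$resistance_score[sc$sample == "P02"],
            sc$resistance_score[sc$sample == "P01"])

  # identical profiles score identically
  two <- rbind(a = pb$profiles[1, ], b = pb$profiles[1, ])
  sc2 <- bulk_module_score(two, coh$modules, seed = 5)
  expect_equal(sc2$sensitivity_score[1], sc2$sensitivity_score[2])
  expect_error(bulk_module_score(pb$profiles[1, , drop = FALSE],
                                 coh$modules), "reference panel")
})
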