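# brute-force pair-counting oracle for U and CLES
pair_count_oracle <- function(low, high) {
  gt <- sum(outer(low, high, ">"))
  eq <- sum(outer(low, high, "=="))
  u <- gt + 0.5 * eq
  list(u = u, cles = u / (length(low) * length(high)))
}

test_that("Mann-Whitney U and CLES match exhaustive pair counting", {
  got <- mann_whitney_one_sided(c(2, 3), c(1, 2))
  expect_equal(got$cles, 3.5 / 4)
  expect_equal(got$u_statistic, pair_count_oracle(c(2, 3), c(1, 2))$u)
  sep <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$cles, 1.0)
  same <- mann_whitney_one_sided(1:5, 1:5)
  expect_equal(same$cles, 0.5)
  expect_gte(same$p_raw, 0.5)
  set.seed(33)
  for (i in 1:50) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    low <- sample(1:6, n1, replace = TRUE)    # heavy ties
    high <- sample(1:6, n2, replace = TRUE)
    oracle <- pair_count_oracle(low, high)
    got <- mann_whitney_one_sided(low, high)
    expect_equal(got$u_statistic, oracle$u)
    expect_equal(got$cles, oracle$cles)
  }
  expect_error(mann_whitney_one_sided(numeric(), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p agrees with wilcox.test without ties", {
  set.seed(12)
  for (i in 1:20) {
    low <- rnorm(sample(3:8, 1))
    high <- rnorm(sample(3:8, 1))
    got <- mann_whitney_one_sided(low, high)
    ref <- wilcox.test(low, high, alternative = "greater", exact = TRUE)
    expect_equal(got$method, "exact")
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_raw, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation p tracks wilcox.test under ties", {
  set.seed(13)
  low <- sample(1:20, 30, replace = TRUE)
  high <- sample(3:22, 25, replace = TRUE)
  got <- mann_whitney_one_sided(low, high)
  ref <- wilcox.test(low, high, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(got$method, "normal")
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("swapping the groups maps CLES to 1 - CLES exactly", {
  set.seed(14)
  for (i in 1:20) {
    a <- sample(1:10, sample(2:9, 1), replace = TRUE)
    b <- sample(1:10, sample(2:9, 1), replace = TRUE)
    expect_equal(mann_whitney_one_sided(a, b)$cles,
                 1 - mann_whitney_one_sided(b, a)$cles)
  }
})

test_that("Bonferroni multiplies and caps within the family", {
  expect_equal(bonferroni(0.004, 11), 0.044)
  expect_equal(bonferroni(0.2, 11), 1)
  expect_equal(bonferroni(0, 11), 0)
  expect_equal(bonferroni(c(0.01, 0.5), 3), c(0.03, 1))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni(0.5, 0), ">= 1")
})

test_that("permutation test splits at the mean and counts strictly above", {
  d <- c(0.1, 0.2, 0.3, 0.8, 0.9)   # mean 0.46: low = first 3
  x <- c(10, 11, 12, 1, 2)
  res <- permutation_test(x, d, n_perm = 500, seed = 1)
  expect_equal(res$n_low, 3L)
  expect_equal(res$n_high, 2L)
  expect_equal(res$observed_diff, mean(c(10, 11, 12)) - mean(c(1, 2)))
  expect_equal(res$p, sum(res$permuted_diffs > res$observed_diff) / 500)
  # exact reproducibility under a seed
  res2 <- permutation_test(x, d, n_perm = 500, seed = 1)
  expect_identical(res$permuted_diffs, res2$permuted_diffs)
  # constant expression: degenerate, p = 0 under the strict rule
  expect_message(res0 <- permutation_test(rep(5, 5), d, n_perm = 100,
                                          seed = 2), "constant")
  expect_equal(res0$observed_diff, 0)
  expect_true(all(res0$permuted_diffs == 0))
  expect_equal(res0$p, 0)
  # one-sided grouping failure
  expect_error(permutation_test(x, rep(0.5, 5), n_perm = 10), "cutoff")
})

test_that("permutation p is invariant to monotone transforms preserving groups", {
  set.seed(3)
  d <- runif(30)
  x <- rnorm(30)
  r1 <- permutation_test(x, d, n_perm = 300, seed = 7)
  d2 <- d^3  # monotone, but may move the mean cutoff; compare groupings
  r2 <- permutation_test(x, d2, n_perm = 300, seed = 7)
  if (identical(d > mean(d), d2 > mean(d2))) {
    expect_identical(r1$p, r2$p)
  }
  # a transform guaranteed to preserve grouping: affine
  r3 <- permutation_test(x, 2 * d + 1, n_perm = 300, seed = 7)
  expect_identical(r1$p, r3$p)
  expect_identical(r1$observed_diff, r3$observed_diff)
})

test_that("Spearman rho matches rank-then-Pearson and handles direction", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(10, 9, 9, 7, 6, 5)   # one tie, decreasing
  got <- spearman_one_sided(x, y)
  oracle <- cor(rank(x), rank(y))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(spearman_one_sided(x, -x)$rho, -1)
  expect_equal(spearman_one_sided(x, -x)$p_raw, 0)
  inc <- spearman_one_sided(x, x^3)
  expect_equal(inc$rho, 1)
  expect_gte(inc$p_raw, 0.5)
  expect_message(flat <- spearman_one_sided(x, rep(1, 6)), "zero rank")
  expect_true(is.na(flat$rho))
  expect_error(spearman_one_sided(1:2, 1:2), ">= 3")
})

test_that("one-sided Spearman p agrees with cor.test's t approximation", {
  set.seed(5)
  x <- runif(40)
  y <- -x + rnorm(40, sd = 0.5)
  got <- spearman_one_sided(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   alternative = "less", exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("rho is invariant to strictly monotone transforms", {
  set.seed(6)
  x <- runif(25)
  y <- rnorm(25)
  base <- spearman_one_sided(x, y)$rho
  expect_equal(spearman_one_sided(exp(x), y)$rho, base)
  expect_equal(spearman_one_sided(x, y^3 + 2 * y)$rho, base)
})

test_that("the association suite agrees across analyses on a strong signal", {
  cfg <- small_config(seed = 101L, beta_discordance = -200, noise_sd = 20,
                      n_aa = 60L, n_ea = 80L)
  co <- simulate_cohort(cfg)
  adj <- adjust_expression(co$expression[[1]], co$samples)
  # restrict to the 11-gene analysis set
  keep <- mtdna_gene_set(rownames(adj$residuals))
  adj$residuals <- adj$residuals[keep, ]
  res <- run_association_suite(adj, co$truth$discordance,
                               n_perm = 300, seed = 9)
  expect_equal(nrow(res$comparison), 11L)
  agree <- sum(res$comparison$cles > 0.5 & res$permutation$observed_diff > 0 &
                 res$correlation$rho < 0)
  expect_gte(agree, 10L)
  expect_equal(res$comparison$p_bonferroni,
               pmin(1, res$comparison$p_raw * 11))
  # orphan samples are named
  bad <- co$truth$discordance[-1, ]
  expect_error(run_association_suite(adj, bad, n_perm = 10),
               co$truth$discordance$sample_id[1])
})

test_that("a one-gene, one-tissue input yields one row per table", {
  set.seed(10)
  d <- data.frame(sample_id = sprintf("s%d", 1:20),
                  population = rep(c("EA", "AA"), each = 10),
                  discordance = c(runif(10, 0, 0.2), runif(10, 0.5, 1)))
  res_mat <- matrix(rnorm(20), 1, dimnames = list("ND1", d$sample_id))
  adj <- structure(list(tissue = "t", residuals = res_mat, n_used = 20L,
                        dropped_samples = character(),
                        skipped_genes = character(),
                        covariates_used = "age"),
                   class = "adjusted_expression")
  res <- run_association_suite(adj, d, n_perm = 50, seed = 2)
  expect_equal(nrow(res$comparison), 1L)
  expect_equal(nrow(res$permutation), 1L)
  expect_equal(nrow(res$correlation), 1L)
  expect_equal(res$summary$family_size, 1L)
})
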