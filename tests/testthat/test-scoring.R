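test_that("polygenic scores follow the training-standardised formula", {
  ## single SNP, a = 0.5, mean 1, sd 0.5, s = 2 -> score 1.0
  g <- genotype_matrix(matrix(2L, 1, 1),
                       data.frame(chrom = "1", pos = 1000L, id = "v1",
                                  a1 = "A", a2 = "B"),
                       data.frame(id = "s1"))
  eff <- data.frame(id = "v1", a1 = "A", effect = 0.5, mean = 1, sd = 0.5)
  expect_equal(unname(polygenic_score(g, eff)), 1.0)
  ## genotypes at the training mean score zero; zero effects score zero
  g2 <- toy_genotypes(20, 30, seed = 51)
  sz <- standardize(g2)
  eff2 <- data.frame(id = sz$stats$id, a1 = sz$stats$a1,
                     effect = runif(30), mean = sz$stats$mean,
                     sd = sz$stats$sd)
  g_mean <- g2
  ## a missing call contributes exactly zero (mean imputation)
  g_mean$geno[1, ] <- NA
  expect_equal(unname(polygenic_score(g_mean, eff2)[1]), 0)
  eff0 <- eff2; eff0$effect <- 0
  expect_equal(unname(polygenic_score(g2, eff0)), rep(0, 20))
})

test_that("scoring is invariant to variant order and allele flips", {
  set.seed(52)
  g <- toy_genotypes(40, 25, seed = 53)
  sz <- standardize(g)
  eff <- data.frame(id = sz$stats$id, a1 = sz$stats$a1,
                    effect = rnorm(25), mean = sz$stats$mean,
                    sd = sz$stats$sd, stringsAsFactors = FALSE)
  base <- polygenic_score(g, eff)
  ## permuted scoring rows
  expect_equal(polygenic_score(g, eff[sample(25), ]), base)
  ## flip target alleles for a subset: s -> 2 - s with swapped labels
  g_f <- g
  flip <- c(3, 7, 11)
  g_f$geno[, flip] <- 2L - g_f$geno[, flip]
  g_f$variants$a1[flip] <- "B"; g_f$variants$a2[flip] <- "A"
  expect_equal(polygenic_score(g_f, eff), base)
  ## unmatched variants: warn below the tolerance, error above
  eff_extra <- rbind(eff, data.frame(id = "nope", a1 = "A", effect = 1,
                                     mean = 1, sd = 1))
  expect_warning(sc <- polygenic_score(g, eff_extra, max_unmatched = 0.1),
                 "skipped")
  expect_equal(sc, base)
  expect_error(polygenic_score(g, eff_extra, max_unmatched = 0.01),
               "missing from target")
})

test_that("covariate adjustment is exact least squares", {
  set.seed(54)
  n <- 50
  age <- rnorm(n, 50, 5)
  ## y exactly linear in age: residuals all zero
  expect_equal(adjust_phenotype(2 + 0.3 * age, cbind(age = age)),
               rep(0, n), tolerance = 1e-10)
  ## covariate orthogonal to y: residuals are y - mean(y)
  y <- rnorm(n)
  x_orth <- resid(lm(rnorm(n) ~ y))
  adj <- adjust_phenotype(y, cbind(x = x_orth))
  expect_equal(adj, resid(lm(y ~ x_orth)), ignore_attr = TRUE)
  ## 4-point closed form against the normal equations
  y4 <- c(1, 3, 2, 5); x4 <- c(0, 1, 2, 3)
  xm <- cbind(1, x4)
  beta <- solve(t(xm) %*% xm, t(xm) %*% y4)
  expect_equal(adjust_phenotype(y4, cbind(x4)), drop(y4 - xm %*% beta),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## collinear covariates are refused
  expect_error(adjust_phenotype(y, cbind(a = age, b = 2 * age)),
               "collinear")
})

test_that("accuracy reports Fisher-z confidence intervals", {
  set.seed(55)
  y <- rnorm(200)
  a <- accuracy(y, y)
  expect_equal(a$r, 1)
  ## r = 0.5, n = 103: CI (0.339, 0.632) from SE = 0.1 on the z scale
  z <- atanh(0.5)
  lo <- tanh(z - 1.96 / sqrt(100)); hi <- tanh(z + 1.96 / sqrt(100))
  expect_equal(lo, 0.339, tolerance = 0.002)
  expect_equal(hi, 0.632, tolerance = 0.002)
  ## the implementation reproduces the same arithmetic
  x <- rnorm(103); yy <- 0.5 * scale(x) + rnorm(103)
  acc <- accuracy(x, drop(yy))
  r <- cor(x, drop(yy))
  expect_equal(acc$ci,
               tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(100)),
               tolerance = 1e-10)
  expect_error(accuracy(rep(1, 10), rnorm(10)), "constant")
  expect_error(accuracy(rnorm(3), rnorm(3)), "at least 4")
})

test_that("true genetic values predict at sqrt(h2) accuracy", {
  co <- quick_cohort(5000, 1000, h2 = 0.5, n_causal = 500, seed = 56)
  y_adj <- adjust_phenotype(co$phenotypes$y,
                            as.matrix(co$phenotypes[, c("sex", "age")]))
  r <- accuracy(co$truth$genetic_values[, 1], y_adj)$r
  expect_equal(r, sqrt(0.5), tolerance = 0.03)
})

test_that("k-fold cross-validation partitions cleanly and has no leakage", {
  set.seed(57)
  co <- quick_cohort(300, 200, h2 = 0, n_causal = 100, seed = 58)
  cv <- kfold_cv(co$genotypes, co$phenotypes$y,
                 covariates = as.matrix(co$phenotypes[, c("sex", "age")]),
                 k = 5)
  ## folds are disjoint and cover every sample
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(length(cv$fold_assignment), 300)
  expect_equal(nrow(cv$folds), 5)
  ## null trait: mean fold accuracy consistent with zero
  expect_lt(abs(cv$mean_r), 2 * cv$sd_r / sqrt(5) + 0.05)
  expect_error(kfold_cv(co$genotypes, co$phenotypes$y, k = 1), "at least 2")
})

test_that("subsampling series behaves like a learning curve", {
  set.seed(59)
  co <- quick_cohort(700, 300, h2 = 0.6, n_causal = 150, seed = 60)
  x <- as.matrix(co$phenotypes[, c("sex", "age")])
  holdout <- 1:150
  ser <- subsample_series(co$genotypes, co$phenotypes$y, x,
                          sizes = c(150, 300, 500), holdout = holdout,
                          n_reps = 2)
  expect_equal(nrow(ser), 6)
  ## two replicates at the same size differ (stochastic subsets)
  expect_false(isTRUE(all.equal(ser$r[1], ser$r[2])))
  ## accuracy trends upward on average
  expect_gt(cor(ser$n, ser$r, method = "spearman"), 0)
  expect_error(subsample_series(co$genotypes, co$phenotypes$y, x,
                                sizes = c(100, 200)), "3 distinct")
  expect_error(subsample_series(co$genotypes, co$phenotypes$y, x,
                                sizes = c(100, 200, 10000),
                                holdout = holdout), "exceeds")
})
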