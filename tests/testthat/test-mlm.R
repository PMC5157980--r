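test_that("single-component REML matches a grid-search oracle", {
  set.seed(31)
  co <- quick_cohort(200, 300, h2 = 0.5, n_causal = 300, seed = 32)
  sz <- standardize(co$genotypes)
  k <- compute_grm(sz$z)
  y <- co$phenotypes$y
  x <- as.matrix(co$phenotypes[, c("sex", "age")])
  fit <- reml_fit(y, k, x = x)
  oracle <- grid_reml(y, k, cbind(1, x))
  expect_equal(fit$components$sigma2_g, unname(oracle["sigma_g"]),
               tolerance = 1e-4)
  expect_equal(fit$sigma2_e, unname(oracle["sigma_e"]), tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("null heritability is not overestimated", {
  set.seed(33)
  co <- quick_cohort(600, 800, h2 = 0, n_causal = 400, seed = 34)
  sz <- standardize(co$genotypes)
  fit <- reml_fit(co$phenotypes$y, compute_grm(sz$z),
                  x = as.matrix(co$phenotypes[, c("sex", "age")]))
  expect_lt(fit$h2, 2 * fit$h2_se + 1e-6)
})

test_that("REML is invariant to covariate pre-adjustment", {
  set.seed(35)
  co <- quick_cohort(800, 400, h2 = 0.5, n_causal = 400, seed = 36)
  sz <- standardize(co$genotypes)
  k <- compute_grm(sz$z)
  x <- as.matrix(co$phenotypes[, c("sex", "age")])
  joint <- reml_fit(co$phenotypes$y, k, x = x)
  pre <- reml_fit(adjust_phenotype(co$phenotypes$y, x), k)
  expect_lt(abs(joint$h2 - pre$h2), 1e-3)
})

test_that("SNP-BLUP equals the ridge solution and GBLUP predictions", {
  set.seed(37)
  n <- 50; m <- 100
  co <- quick_cohort(n, m, h2 = 0.5, n_causal = m, seed = 38)
  sz <- standardize(co$genotypes)
  y <- co$phenotypes$y
  k <- compute_grm(sz$z)
  fit <- reml_fit(y, k)
  eff <- snp_blup(sz$z, y, fit, stats = sz$stats)
  ## primal ridge: (Z'Z + lambda I)^-1 Z'(y - Xb)
  lambda <- fit$sigma2_e / (fit$components$sigma2_g / m)
  r <- y - fit$beta[1]
  ridge <- solve(crossprod(sz$z) + diag(lambda, m), crossprod(sz$z, r))
  expect_lt(max(abs(eff$effect - ridge)), 1e-8)
  ## dual identity: Z a equals sigma2_g K V^-1 r
  v <- fit$components$sigma2_g * k + diag(fit$sigma2_e, n)
  gblup <- fit$components$sigma2_g * k %*% solve(v, r)
  expect_lt(max(abs(sz$z %*% eff$effect - gblup)), 1e-8)
  ## effects carry the scoring-file columns
  expect_true(all(c("id", "a1", "effect", "mean", "sd") %in% names(eff)))
  ## duplicated variant columns receive identical effects
  z2 <- cbind(sz$z, dup = sz$z[, 1])
  colnames(z2) <- c(colnames(sz$z), "dup")
  fit2 <- reml_fit(y, compute_grm(z2))
  eff2 <- snp_blup(z2, y, fit2)
  expect_equal(eff2$effect[1], eff2$effect[m + 1], tolerance = 1e-10)
})

test_that("vanishing genetic variance shrinks all effects to zero", {
  set.seed(39)
  co <- quick_cohort(80, 60, h2 = 0.3, seed = 40)
  sz <- standardize(co$genotypes)
  y <- co$phenotypes$y
  fit <- reml_fit(y, compute_grm(sz$z))
  fit$components$sigma2_g <- 1e-12
  eff <- snp_blup(sz$z, y, fit)
  expect_lt(max(abs(eff$effect)), 1e-10)
})

test_that("effect-size grouping isolates the outlier tail", {
  ## all effects equal: empty tail, flagged
  expect_warning(g0 <- effect_outlier_groups(data.frame(beta = rep(1, 10))),
                 "zero spread")
  expect_true(all(g0 == "main"))
  ## 99 null effects and one of 10: only that one is in the tail
  b <- c(rep(0, 99), 10)
  g1 <- effect_outlier_groups(data.frame(beta = b))
  expect_equal(which(g1 == "tail"), 100L)
  ## Gaussian effects: tail mass matches the 3-SD normal tail
  set.seed(41)
  g2 <- effect_outlier_groups(data.frame(beta = rnorm(1e5)))
  expect_equal(mean(g2 == "tail"), 2 * pnorm(-3), tolerance = 0.25)
})

test_that("MAF groups follow the strict published boundaries", {
  expect_warning(
    g <- maf_groups(c(0.30, 0.05, 0.0005, 0.02, 0.005, 0.01, 0.001)),
    "unassigned")
  expect_equal(g, c("common", NA, NA, "lowfreq", "rare", NA, NA))
  expect_error(maf_groups(c(0.2, 0.7)), "0.5")
})

test_that("two equal-variance components are not spuriously separated", {
  set.seed(43)
  co <- quick_cohort(500, 600, h2 = 0.5, n_causal = 600, seed = 44)
  sz <- standardize(co$genotypes)
  half <- seq_len(300)
  zs <- list(a = sz$z[, half], b = sz$z[, -half])
  fit <- reml_fit(co$phenotypes$y, lapply(zs, compute_grm),
                  m_variants = vapply(zs, ncol, 0L))
  d <- abs(diff(fit$components$sigma2_g))
  se_d <- sqrt(sum(fit$components$se^2))
  expect_lt(d, 2 * se_d)
  expect_equal(fit$components$sigma2_u,
               fit$components$sigma2_g / 300, tolerance = 1e-12)
})

test_that("multivariate REML recovers degenerate and null correlations", {
  set.seed(45)
  co <- quick_cohort(500, 400, h2 = 0.5, n_causal = 400, seed = 46)
  sz <- standardize(co$genotypes)
  k <- compute_grm(sz$z)
  y <- co$phenotypes$y
  ## duplicated trait (tiny jitter): genetic correlation ~ 1
  ym <- cbind(t1 = y, t2 = y + rnorm(length(y), 0, 0.02))
  fit <- reml_fit_multivariate(ym, k)
  expect_gte(fit$r_g[1, 2], 0.99)
  ## independent traits: r_g within 2 SE of zero
  set.seed(47)
  cfg <- cohort_config(
    n_samples = c(ref = 800), n_variants = 600, n_chromosomes = 2,
    ld_block_size = 1, within_block_r = 0, fst = numeric(0),
    maf_distribution = list(type = "uniform", min = 0.1, max = 0.5),
    traits = list(trait_architecture(0.5, 600, name = "a"),
                  trait_architecture(0.5, 600, name = "b")),
    seed = 48)
  co2 <- simulate_cohort(cfg)
  sz2 <- standardize(co2$genotypes)
  fit2 <- reml_fit_multivariate(
    as.matrix(co2$phenotypes[, c("a", "b")]), compute_grm(sz2$z),
    x = as.matrix(co2$phenotypes[, c("sex", "age")]))
  expect_lt(abs(fit2$r_g[1, 2]), 2 * fit2$r_g_se[1, 2] + 0.05)
  ## single trait defers to the univariate fitter
  expect_error(reml_fit_multivariate(matrix(y, ncol = 1), k),
               "reml_fit")
})

test_that("multivariate BLUP predictions match the univariate limit", {
  ## with a diagonal genetic covariance and equal traits, per-trait
  ## effects from the multivariate back-solve equal univariate BLUPs
  set.seed(49)
  co <- quick_cohort(150, 200, h2 = 0.5, seed = 50)
  sz <- standardize(co$genotypes)
  k <- compute_grm(sz$z)
  y <- co$phenotypes$y
  fit1 <- reml_fit(y, k)
  eff1 <- snp_blup(sz$z, y, fit1)
  mvfit <- structure(list(
    sigma_g = diag(rep(fit1$components$sigma2_g, 2)),
    sigma_e = diag(rep(fit1$sigma2_e, 2))), class = "variance_components_mv")
  a_mv <- snp_blup_multivariate(sz$z, cbind(y, y), mvfit)
  expect_equal(a_mv[, 1], eff1$effect, tolerance = 1e-6,
               ignore_attr = TRUE)
})
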