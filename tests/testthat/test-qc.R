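test_that("HWE exact test matches hand-enumerated configurations", {
  ## monomorphic site has a single configuration
  expect_equal(hwe_exact_test(0, 0, 25)$p, 1)
  ## (1 hom-minor, 0 het, 9 hom-major): weights 10 vs 180, p = 10/190
  expect_equal(hwe_exact_test(1, 0, 9)$p, 10 / 190, tolerance = 1e-12)
  ## (0, 2, 8): the observed configuration is the most probable
  expect_equal(hwe_exact_test(0, 2, 8)$p, 1, tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 0, 5), "nonnegative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("HWE exact test agrees with the enumeration oracle", {
  ## sweep of configurations at moderate totals (full sweep to 50 in
  ## the acceptance suite)
  for (n in c(5, 12, 25)) {
    for (nm in 0:n) {           # minor-allele count parity base
      for (h in seq(nm %% 2, min(nm, 2 * n - nm), by = 2)) {
        hom1 <- (nm - h) / 2
        hom2 <- n - hom1 - h
        if (hom2 < 0) next
        expect_equal(hwe_exact_test(hom1, h, hom2)$p,
                     hwe_oracle(hom1, h, hom2), tolerance = 1e-12)
      }
    }
  }
})

test_that("platform Fisher test is exact and survives the far tail", {
  ## equal missingness proportions: symmetric table, p = 1
  expect_equal(platform_missingness_test(5, 95, 5, 95)$p, 1)
  ## [[1,9],[0,10]]: hypergeometric over a unit margin, p = 1
  expect_equal(platform_missingness_test(1, 9, 0, 10)$p, 1,
               tolerance = 1e-12)
  ## agreement with fisher.test away from the tail
  for (tab in list(c(3, 17, 9, 11), c(10, 40, 25, 25), c(0, 30, 8, 22))) {
    ours <- platform_missingness_test(tab[1], tab[2], tab[3], tab[4])$p
    ref <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  ## 50% vs 0% missing at 5,000 per platform: finite log-space p far
  ## below the 1e-100 exclusion threshold
  ft <- platform_missingness_test(2500, 2500, 0, 5000)
  expect_true(is.finite(ft$log10_p))
  expect_lt(ft$log10_p, -100)
  expect_error(platform_missingness_test(0, 0, 0, 0), "empty")
})

test_that("variant QC applies the published thresholds in order", {
  set.seed(21)
  g <- toy_genotypes(200, 60, p = 0.3)
  ## variant 1: 3% missing -> removed at the missingness stage
  g$geno[1:6, 1] <- NA
  ## variant 2: MAF exactly 0.05 -> removed (strict MAF > 0.05 kept)
  g$geno[, 2] <- 0L
  g$geno[1:20, 2] <- 1L
  ## variant 3: gross HWE violation (all het)
  g$geno[, 3] <- 1L
  res <- variant_qc(g, qc_defaults())
  kept <- res$genotypes$variants$id
  expect_false("v0001" %in% kept)
  expect_false("v0002" %in% kept)
  expect_false("v0003" %in% kept)
  st <- res$report$stages
  expect_equal(st$retained, st$input - st$removed)
  expect_equal(st$filter[2], "variant_missingness")
  ## a clean simulated matrix is fully retained
  clean <- quick_cohort(300, 40, seed = 3, maf_min = 0.2)$genotypes
  res2 <- variant_qc(clean, qc_defaults())
  expect_equal(ncol(res2$genotypes$geno), 40)
  ## idempotence
  res3 <- variant_qc(res$genotypes, qc_defaults())
  expect_equal(res3$genotypes$variants$id, res$genotypes$variants$id)
  expect_error(variant_qc(g, list(maf = 2)), "outside")
})

test_that("platform-differential missingness is caught by the Fisher filter", {
  set.seed(22)
  co <- quick_cohort(3000, 50, seed = 5, maf_min = 0.2,
                     platform_missing_rates = c(0.001, 0.001),
                     biased_variant_fraction = 0.1,
                     biased_missing_rate = 0.5)
  biased <- attr(co$genotypes, "biased_variants")
  expect_gt(length(biased), 0)
  ## with the published settings the overall-missingness stage removes
  ## them first; relax it so the Fisher stage itself is exercised
  res <- variant_qc(co$genotypes, list(variant_missingness = 0.9))
  expect_false(any(biased %in% res$genotypes$variants$id))
  fisher_stage <- res$report$stages$removed[
    res$report$stages$filter == "platform_missingness"]
  expect_gte(fisher_stage, length(biased))
  ## under the published thresholds they are gone as well (earlier stage)
  res2 <- variant_qc(co$genotypes, qc_defaults())
  expect_false(any(biased %in% res2$genotypes$variants$id))
})

test_that("sample QC removes high-missingness and sex-discordant samples", {
  set.seed(23)
  cfg <- cohort_config(n_samples = c(ref = 300), n_variants = 400,
                       n_chromosomes = 2, ld_block_size = 1,
                       fst = numeric(0),
                       maf_distribution = list(type = "uniform",
                                               min = 0.2, max = 0.5),
                       traits = list(trait_architecture(0.5, 100)),
                       n_x_variants = 120, seed = 31)
  co <- simulate_cohort(cfg)
  g <- co$genotypes
  ## clean cohort: essentially nobody removed (the 3-SD heterozygosity
  ## rule can clip the odd tail sample by construction)
  res0 <- sample_qc(g, qc_defaults())
  expect_gte(length(res0$samples), 295)
  ## 6% autosomal missingness -> removed
  auto <- which(g$variants$chrom != "X")
  g$geno[1, sample(auto, round(0.06 * length(auto)))] <- NA
  ## a true male (X coded homozygous) reported as female -> removed
  male <- which(g$samples$sex == 1L)[1]
  g$samples$sex[male] <- 2L
  res <- sample_qc(g, qc_defaults())
  expect_false(g$samples$id[1] %in% res$samples)
  expect_false(g$samples$id[male] %in% res$samples)
  ## sex check without an X block is a contract violation
  g_auto <- subset_genotypes(g, variants = auto)
  expect_error(sample_qc(g_auto, qc_defaults(), sex_check = TRUE), "X")
})

test_that("phenotype outliers are clipped strictly outside 3 SD per sex", {
  set.seed(24)
  ph <- data.frame(id = sprintf("s%03d", 1:200),
                   sex = rep(1:2, each = 100),
                   y = rnorm(200), stringsAsFactors = FALSE)
  mu <- mean(ph$y[ph$sex == 1]); sg <- sd(ph$y[ph$sex == 1])
  ## exactly mean + 3 SD is retained (strictly "outside")
  ph$y[1] <- mu + 3 * sg
  ph$y[2] <- mu + 4 * sg
  out <- phenotype_outlier_filter(ph, "y")
  expect_false(is.na(out$y[1]))
  expect_true(is.na(out$y[2]))
  ## degenerate stratum: all equal -> nothing removed
  ph2 <- data.frame(id = c("a", "b", "c", "d"), sex = c(1, 1, 2, 2),
                    y = c(5, 5, 3, 3))
  expect_equal(phenotype_outlier_filter(ph2, "y")$y, ph2$y)
  ph3 <- data.frame(id = "a", sex = 1, y = 2)
  expect_error(phenotype_outlier_filter(ph3, "y"), "fewer than 2")
})

test_that("ancestry filter retains within-z samples and drops small groups", {
  set.seed(25)
  proj <- matrix(rnorm(300 * 20), 300, 20)
  groups <- rep(c("a", "b"), c(200, 100))
  ## all identical projections -> everyone retained
  same <- matrix(1, 300, 20)
  r0 <- ancestry_filter(same, groups, k = 20, z = 3, min_group_size = 10)
  expect_true(all(r0$retained))
  ## one sample displaced 5 SD on PC1 -> excluded as an outlier
  proj2 <- proj
  proj2[1, 1] <- mean(proj[groups == "a", 1]) +
    5 * sd(proj[groups == "a", 1])
  r1 <- ancestry_filter(proj2, groups, k = 20, z = 3, min_group_size = 10)
  expect_false(r1$retained[1])
  expect_true(r1$outlier[1])
  ## a group under the minimum size is dropped entirely
  r2 <- ancestry_filter(proj, groups, k = 20, z = 3, min_group_size = 101)
  expect_true(all(!r2$retained[groups == "b"]))
  expect_true("b" %in% r2$dropped_groups)
  expect_error(ancestry_filter(proj[, 1:5], groups, k = 20), "exceeds")
})

test_that("relatedness split isolates related samples greedily", {
  ## no pair above threshold: related group empty
  k <- diag(4); rownames(k) <- colnames(k) <- letters[1:4]
  s <- relatedness_split(k)
  expect_equal(sort(s$unrelated), letters[1:4])
  expect_length(s$related, 0)
  ## a single sib pair: exactly one moved to the related group
  k2 <- diag(4); k2[1, 2] <- k2[2, 1] <- 0.5
  rownames(k2) <- colnames(k2) <- letters[1:4]
  s2 <- relatedness_split(k2)
  expect_length(s2$related, 1)
  expect_length(s2$unrelated, 3)
  expect_true(s2$related %in% c("a", "b"))
  ## 3-clique: two removed, one retained
  k3 <- diag(5)
  k3[1:3, 1:3] <- 0.3; diag(k3) <- 1
  rownames(k3) <- colnames(k3) <- letters[1:5]
  s3 <- relatedness_split(k3)
  expect_length(s3$unrelated, 3)
  expect_length(s3$related, 2)
  expect_error(relatedness_split(matrix(0, 2, 3)), "square")
})

test_that("relatedness split postcondition holds on random kinship matrices", {
  set.seed(26)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    k <- matrix(0, n, n)
    npairs <- sample(0:10, 1)
    for (j in seq_len(npairs)) {
      ab <- sample(n, 2)
      k[ab[1], ab[2]] <- k[ab[2], ab[1]] <- runif(1, 0, 0.6)
    }
    diag(k) <- 1
    rownames(k) <- colnames(k) <- sprintf("s%02d", 1:n)
    s <- relatedness_split(k)
    ret <- match(s$unrelated, rownames(k))
    off <- k[ret, ret, drop = FALSE]
    diag(off) <- 0
    expect_lte(max(off), 0.0625)
    ## every related sample has a link into the retained set
    for (r in s$related) {
      expect_gt(max(k[match(r, rownames(k)), ret]), 0.0625)
    }
  }
})
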