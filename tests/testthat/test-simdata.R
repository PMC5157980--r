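test_that("Balding-Nichols frequencies have the right moments", {
  base <- cohort_config(n_samples = c(a = 10, b = 10), n_variants = 10000,
                        n_chromosomes = 1, ld_block_size = 1,
                        maf_distribution = list(type = "uniform",
                                                min = 0.3, max = 0.3),
                        fst = 0.1,
                        traits = list(trait_architecture(0.5, 10)))
  ## fst = 0: every population equals the ancestral frequency
  cfg0 <- base; cfg0$fst <- 0
  set.seed(1)
  f0 <- draw_allele_frequencies(cfg0)
  expect_equal(f0$pop[, 1], f0$pop[, 2])
  expect_equal(f0$pop[, 1], f0$ancestral)
  ## fst = 0.1, p = 0.3: Var(p_pop) = fst * p * (1 - p) = 0.021
  set.seed(2)
  f1 <- draw_allele_frequencies(base)
  expect_equal(var(f1$pop[, 2]), 0.1 * 0.3 * 0.7, tolerance = 0.1)
  expect_true(all(f1$pop > 0 & f1$pop < 1))
  ## fst = 1 is rejected at construction
  expect_error(cohort_config(n_samples = c(a = 5, b = 5), fst = 1), "fst")
})

test_that("unlinked genotypes have binomial moments and no cross-SNP LD", {
  set.seed(3)
  cfg <- cohort_config(n_samples = c(ref = 10000), n_variants = 12,
                       n_chromosomes = 1, ld_block_size = 1,
                       within_block_r = 0,
                       maf_distribution = list(type = "uniform",
                                               min = 0.5, max = 0.5),
                       fst = numeric(0),
                       traits = list(trait_architecture(0.5, 5)),
                       seed = 4)
  freqs <- draw_allele_frequencies(cfg)
  g <- draw_genotypes(freqs, cfg)
  expect_true(all(g$geno %in% 0:2))
  expect_equal(mean(colMeans(g$geno)), 1.0, tolerance = 0.02)
  expect_equal(mean(apply(g$geno, 2, var)), 0.5, tolerance = 0.03)
  cc <- cor(g$geno)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  ## positions on a regular 1-kb grid, 1-based
  expect_equal(g$variants$pos, seq_len(12) * 1000L)
})

test_that("degenerate LD (within_block_r = 1) duplicates adjacent SNPs", {
  set.seed(5)
  cfg <- cohort_config(n_samples = c(ref = 200), n_variants = 20,
                       n_chromosomes = 2, ld_block_size = 5,
                       within_block_r = 1, fst = numeric(0),
                       traits = list(trait_architecture(0.5, 5)),
                       seed = 6)
  g <- draw_genotypes(draw_allele_frequencies(cfg), cfg)
  blocks <- snpblup:::variant_blocks(cfg)$block
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    for (j in cols[-1]) {
      expect_identical(g$geno[, j], g$geno[, cols[1]])
    }
  }
})

test_that("LD blocks reach the target adjacent correlation approximately", {
  set.seed(7)
  cfg <- cohort_config(n_samples = c(ref = 3000), n_variants = 100,
                       n_chromosomes = 1, ld_block_size = 10,
                       within_block_r = 0.9, fst = numeric(0),
                       maf_distribution = list(type = "uniform",
                                               min = 0.2, max = 0.5),
                       traits = list(trait_architecture(0.5, 5)),
                       seed = 8)
  g <- draw_genotypes(draw_allele_frequencies(cfg), cfg)
  blocks <- snpblup:::variant_blocks(cfg)$block
  adj <- vapply(which(diff(blocks) == 0L), function(j) {
    cor(g$geno[, j], g$geno[, j + 1L])
  }, 0)
  ## thresholding attenuates the latent correlation; adjacent genotype
  ## LD must still be strong and far above the cross-block level
  expect_gt(mean(adj), 0.6)
  crossb <- vapply(which(diff(blocks) != 0L), function(j) {
    cor(g$geno[, j], g$geno[, j + 1L])
  }, 0)
  expect_lt(max(abs(crossb)), 0.15)
})

test_that("sib spiking follows Mendelian expectations", {
  set.seed(9)
  pool <- toy_genotypes(50, 3000, p = 0.4, seed = 10)
  ## no pairs: unchanged, no family labels
  expect_identical(spike_relatives(pool, 0), pool)
  out <- spike_relatives(pool, 5)
  expect_equal(nrow(out$geno), 60)
  fam <- out$samples$family
  expect_equal(sum(!is.na(fam)), 10)
  expect_equal(length(unique(na.omit(fam))), 5)
  ## reusing the same parents makes all offspring mutually related
  pids <- matrix(rep(pool$samples$id[1:2], 2), 2, byrow = TRUE)
  out2 <- spike_relatives(pool, 2, parent_ids = pids)
  ## standardise on the whole pool, then relate the 4 offspring
  sz <- standardize(out2)
  sibs <- which(!is.na(out2$samples$family))
  k <- compute_grm(sz$z[sibs, , drop = FALSE])
  offd <- k[upper.tri(k)]
  expect_true(all(offd > 0.0625))
  expect_error(spike_relatives(subset_genotypes(pool, samples = 1), 1),
               "2 candidate parents")
})

test_that("true effects follow the configured architecture", {
  mk_cfg <- function(traits, rg = NULL) {
    cohort_config(n_samples = c(ref = 10), n_variants = 20000,
                  n_chromosomes = 1, ld_block_size = 1, fst = numeric(0),
                  traits = traits, genetic_correlation = rg, seed = 1)
  }
  mafs <- runif(20000, 0.05, 0.5)
  ## independent traits: empirical cross-trait effect correlation ~ 0
  set.seed(11)
  cfg <- mk_cfg(list(trait_architecture(0.5, 10000, name = "a"),
                     trait_architecture(0.5, 10000, name = "b")))
  eff <- draw_snp_effects(cfg, mafs)
  causal <- attr(eff, "causal")
  expect_equal(length(causal), 10000)
  expect_true(all(eff[-causal, ] == 0))
  expect_lt(abs(cor(eff[causal, 1], eff[causal, 2])), 0.05)
  ## configured genetic correlation 0.5 recovered within sampling error
  set.seed(12)
  cfg2 <- mk_cfg(list(trait_architecture(0.5, 10000, name = "a"),
                      trait_architecture(0.5, 10000, name = "b")),
                 rg = matrix(c(1, 0.5, 0.5, 1), 2))
  eff2 <- draw_snp_effects(cfg2, mafs)
  cc <- attr(eff2, "causal")
  expect_equal(cor(eff2[cc, 1], eff2[cc, 2]), 0.5, tolerance = 0.04)
  ## two-component with zero tail fraction reduces to a single Gaussian
  set.seed(13)
  cfg3 <- mk_cfg(list(trait_architecture(0.5, 10000,
                                         effect_model = "two_component",
                                         tail_fraction = 0, name = "a")))
  eff3 <- draw_snp_effects(cfg3, mafs)
  set.seed(13)
  cfg4 <- mk_cfg(list(trait_architecture(0.5, 10000, name = "a")))
  eff4 <- draw_snp_effects(cfg4, mafs)
  ks <- suppressWarnings(
    ks.test(eff3[attr(eff3, "causal"), 1], eff4[attr(eff4, "causal"), 1]))
  expect_gt(ks$p.value, 0.01)
  ## non-PSD correlation rejected
  expect_error(mk_cfg(list(trait_architecture(0.5, 10, name = "a"),
                           trait_architecture(0.5, 10, name = "b")),
                      rg = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("phenotype assembly hits the target heritability", {
  ## h2 = 1: phenotype minus fixed effects equals the genetic value
  set.seed(14)
  co1 <- quick_cohort(300, 500, h2 = 1, n_causal = 200, seed = 15)
  fx <- co1$phenotypes$sex * co1$config$sex_effect +
    co1$phenotypes$age * co1$config$age_effect
  expect_equal(co1$phenotypes$y - fx, co1$truth$genetic_values[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(co1$truth$realized_h2[["y"]], 1)
  ## h2 = 0: phenotype independent of the (zeroed) genetic value
  co0 <- quick_cohort(400, 500, h2 = 0, n_causal = 200, seed = 16)
  expect_true(all(co0$truth$genetic_values == 0))
  ## h2 = 0.5 at n = 5,000: realized h2 and the regression R2 on the
  ## true genetic values both land within 0.03
  co5 <- quick_cohort(5000, 2000, h2 = 0.5, n_causal = 1000, seed = 17)
  expect_equal(co5$truth$realized_h2[["y"]], 0.5, tolerance = 0.03)
  fx5 <- co5$phenotypes$sex * co5$config$sex_effect +
    co5$phenotypes$age * co5$config$age_effect
  r2 <- cor(co5$phenotypes$y - fx5, co5$truth$genetic_values[, 1])^2
  expect_equal(r2, 0.5, tolerance = 0.03)
  ## genetic value identity: g = Z a with the stored effects
  sz <- standardize(co5$genotypes)
  g_rebuilt <- drop(sz$z %*% co5$truth$effects[, 1])
  expect_equal(g_rebuilt, co5$truth$genetic_values[, 1],
               tolerance = 1e-8, ignore_attr = TRUE)
  ## h2 = 1 with no causal variants is impossible
  expect_error(quick_cohort(50, 100, h2 = 1, n_causal = 0, seed = 18),
               "polymorphic causal")
})

test_that("multi-trait genetic values respect the configured correlation", {
  set.seed(19)
  cfg <- cohort_config(
    n_samples = c(ref = 2000), n_variants = 10000, n_chromosomes = 2,
    ld_block_size = 1, within_block_r = 0, fst = numeric(0),
    maf_distribution = list(type = "uniform", min = 0.1, max = 0.5),
    traits = list(trait_architecture(0.5, 10000, name = "a"),
                  trait_architecture(0.5, 10000, name = "b")),
    genetic_correlation = matrix(c(1, 0.6, 0.6, 1), 2),
    seed = 20)
  co <- simulate_cohort(cfg)
  rg_emp <- cor(co$truth$genetic_values[, 1], co$truth$genetic_values[, 2])
  expect_equal(rg_emp, 0.6, tolerance = 0.05)
})

test_that("platform missingness hits its configured rates", {
  ## zero rates: nothing missing
  co <- quick_cohort(100, 100, seed = 21)
  expect_false(anyNA(co$genotypes$geno))
  ## 1% baseline on ~1e6 entries: within 0.001
  co2 <- quick_cohort(2000, 500, seed = 22,
                      platform_missing_rates = c(0.01, 0.01))
  expect_lt(abs(mean(is.na(co2$genotypes$geno)) - 0.01), 0.001)
  expect_true(all(co2$genotypes$samples$platform %in% 1:2))
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- cohort_config(n_samples = c(a = 80, b = 40), n_variants = 300,
                       n_chromosomes = 3, ld_block_size = 5,
                       within_block_r = 0.7, fst = 0.05, n_sib_pairs = 6,
                       platform_missing_rates = c(0.01, 0.02),
                       biased_variant_fraction = 0.02,
                       traits = list(trait_architecture(0.4, 100)),
                       n_x_variants = 30, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$geno, c2$genotypes$geno)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth$effects, c2$truth$effects)
})
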