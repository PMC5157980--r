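# shared fixtures, built in code

## quick unstructured genotype matrix (binomial draws, no LD)
toy_genotypes <- function(n, m, p = 0.4, seed = NULL, missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rbinom(n * m, 2L, p), n, m)
  if (missing_rate > 0) {
    g[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  }
  genotype_matrix(
    g,
    data.frame(chrom = as.character(rep(1:2, length.out = m)),
               pos = rep(seq_len(ceiling(m / 2)) * 1000L, each = 2L)[1:m],
               id = sprintf("v%04d", seq_len(m)),
               a1 = "A", a2 = "B", stringsAsFactors = FALSE),
    data.frame(id = sprintf("s%04d", seq_len(n)),
               sex = rep(1:2, length.out = n),
               age = 50L, stringsAsFactors = FALSE))
}

## single-trait cohort with independent SNPs (ld_block_size = 1)
quick_cohort <- function(n, m, h2 = 0.5, n_causal = m, seed = 1,
                         maf_min = 0.1, maf_max = 0.5, ...) {
  cfg <- cohort_config(
    n_samples = c(ref = n), n_variants = m, n_chromosomes = 2,
    ld_block_size = 1, within_block_r = 0, fst = numeric(0),
    maf_distribution = list(type = "uniform", min = maf_min, max = maf_max),
    traits = list(trait_architecture(h2, n_causal, name = "y")),
    seed = seed, ...)
  simulate_cohort(cfg)
}
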