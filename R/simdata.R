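#' Trait architecture for the cohort simulator
#'
#' Describes one additive trait: its target SNP-heritability, the number
#' of causal variants, and the distribution of causal effect sizes on
#' the standardised-genotype scale.
#'
#' @param h2 target SNP-heritability in `[0, 1]`.
#' @param n_causal number of causal variants (autosomal).
#' @param effect_model one of `"single_gaussian"` (i.i.d. normal
#'   effects), `"two_component"` (a small fraction of causal SNPs drawn
#'   from an inflated-variance tail), or `"maf_stratified"` (per-SNP
#'   effect variance depends on the MAF bin).
#' @param tail_fraction,tail_var_ratio for `"two_component"`: fraction of
#'   causal SNPs in the large-effect tail and the ratio of tail to main
#'   effect variance.
#' @param maf_bin_breaks,maf_bin_var for `"maf_stratified"`: MAF bin
#'   boundaries (breaks on `[0, 0.5]`) and the relative effect variance
#'   per bin (`length(maf_bin_breaks) - 1` values).
#' @param name optional trait name.
#'
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(h2, n_causal,
                               effect_model = c("single_gaussian",
                                                "two_component",
                                                "maf_stratified"),
                               tail_fraction = 0.01, tail_var_ratio = 100,
                               maf_bin_breaks = c(0, 0.01, 0.05, 0.5),
                               maf_bin_var = c(1, 1, 1),
                               name = NULL) {
  effect_model <- match.arg(effect_model)
  stopifnot_scalar01(h2, "h2")
  if (n_causal < 0) stop("n_causal must be nonnegative", call. = FALSE)
  stopifnot_scalar01(tail_fraction, "tail_fraction")
  if (length(maf_bin_var) != length(maf_bin_breaks) - 1L) {
    stop("maf_bin_var must have one value per MAF bin", call. = FALSE)
  }
  structure(list(h2 = h2, n_causal = as.integer(n_causal),
                 effect_model = effect_model,
                 tail_fraction = tail_fraction,
                 tail_var_ratio = tail_var_ratio,
                 maf_bin_breaks = maf_bin_breaks,
                 maf_bin_var = maf_bin_var,
                 name = name),
            class = "trait_architecture")
}

#' Configuration for a synthetic genotype-phenotype cohort
#'
#' Bundles every parameter of the generative model: population sizes and
#' differentiation, LD-block structure, MAF spectrum, relatives,
#' platform missingness, and trait architectures. One seed fixes all
#' draws end to end.
#'
#' @param n_samples named integer vector of unrelated sample counts per
#'   population; the first population is the reference (ancestral
#'   frequencies).
#' @param n_variants number of autosomal variants.
#' @param n_chromosomes autosomes to spread variants over.
#' @param ld_block_size SNPs per LD block (blocks never span chromosomes).
#' @param within_block_r target correlation between adjacent SNPs inside
#'   a block, on the latent-haplotype scale of the Gaussian copula.
#' @param maf_distribution list; either
#'   `list(type = "uniform", min =, max =)` or
#'   `list(type = "beta", shape1 =, shape2 =)`, always truncated to
#'   `[0.001, 0.5]`.
#' @param fst Balding-Nichols differentiation parameter per
#'   non-reference population (recycled), each in `[0, 1)`.
#' @param n_sib_pairs number of full-sib pairs to append (parents drawn
#'   from the reference population).
#' @param platform_missing_rates baseline genotype missingness of the
#'   two genotyping platforms, each in `[0, 1)`.
#' @param biased_variant_fraction fraction of variants given elevated
#'   missingness on platform 2 only.
#' @param biased_missing_rate the elevated rate for those variants.
#' @param traits list of [trait_architecture()] objects (at least one).
#' @param genetic_correlation,environmental_correlation `T x T`
#'   correlation matrices across traits (unit diagonal, positive
#'   semi-definite).
#' @param sex_effect,age_effect fixed-effect sizes per trait (recycled);
#'   sex is coded 1 = male, 2 = female, age is drawn uniformly on
#'   `age_range`.
#' @param age_range integer bounds for the age draw.
#' @param n_x_variants number of X-like variants (males coded
#'   homozygous) appended on chromosome `"X"`; 0 disables the sex-check
#'   exercise.
#' @param seed integer seed fixing the whole cohort.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = c(pop1 = 1000),
                          n_variants = 5000,
                          n_chromosomes = 10,
                          ld_block_size = 10,
                          within_block_r = 0.8,
                          maf_distribution = list(type = "uniform",
                                                  min = 0.05, max = 0.5),
                          fst = 0.1,
                          n_sib_pairs = 0,
                          platform_missing_rates = c(0, 0),
                          biased_variant_fraction = 0,
                          biased_missing_rate = 0.5,
                          traits = list(trait_architecture(0.5, 1000)),
                          genetic_correlation = NULL,
                          environmental_correlation = NULL,
                          sex_effect = 0.5,
                          age_effect = 0.02,
                          age_range = c(40L, 70L),
                          n_x_variants = 0,
                          seed = 1L) {
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("pop", seq_along(n_samples))
  }
  if (any(n_samples < 0)) stop("n_samples must be nonnegative", call. = FALSE)
  if (n_variants < 1) stop("need at least one variant", call. = FALSE)
  if (ld_block_size < 1) stop("ld_block_size must be >= 1", call. = FALSE)
  stopifnot_scalar01(within_block_r, "within_block_r")
  for (f in fst) stopifnot_scalar01(f, "fst", open_upper = TRUE)
  for (r in platform_missing_rates) {
    stopifnot_scalar01(r, "platform_missing_rates", open_upper = TRUE)
  }
  stopifnot_scalar01(biased_variant_fraction, "biased_variant_fraction")
  stopifnot_scalar01(biased_missing_rate, "biased_missing_rate",
                     open_upper = TRUE)
  if (!length(traits)) stop("at least one trait is required", call. = FALSE)
  if (!all(vapply(traits, inherits, TRUE, "trait_architecture"))) {
    stop("traits must be trait_architecture objects", call. = FALSE)
  }
  tn <- length(traits)
  check_corr <- function(m, what) {
    if (is.null(m)) m <- diag(tn)
    m <- as.matrix(m)
    if (!isTRUE(all.equal(m, t(m))) || any(abs(diag(m) - 1) > 1e-8)) {
      stop(what, " must be symmetric with unit diagonal", call. = FALSE)
    }
    if (!is_psd(m)) stop(what, " must be positive semi-definite",
                         call. = FALSE)
    m
  }
  genetic_correlation <- check_corr(genetic_correlation,
                                    "genetic_correlation")
  environmental_correlation <- check_corr(environmental_correlation,
                                          "environmental_correlation")
  npop <- length(n_samples)
  fst <- rep_len(fst, max(npop - 1L, 1L))
  nm <- vapply(traits, function(t) t$name %||% NA_character_, "")
  if (anyNA(nm)) nm[is.na(nm)] <- paste0("trait", which(is.na(nm)))
  for (i in seq_along(traits)) traits[[i]]$name <- nm[i]
  structure(list(n_samples = n_samples, n_variants = as.integer(n_variants),
                 n_chromosomes = as.integer(n_chromosomes),
                 ld_block_size = as.integer(ld_block_size),
                 within_block_r = within_block_r,
                 maf_distribution = maf_distribution, fst = fst,
                 n_sib_pairs = as.integer(n_sib_pairs),
                 platform_missing_rates = platform_missing_rates,
                 biased_variant_fraction = biased_variant_fraction,
                 biased_missing_rate = biased_missing_rate,
                 traits = traits,
                 genetic_correlation = genetic_correlation,
                 environmental_correlation = environmental_correlation,
                 sex_effect = rep_len(sex_effect, tn),
                 age_effect = rep_len(age_effect, tn),
                 age_range = as.integer(age_range),
                 n_x_variants = as.integer(n_x_variants),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## block index per variant (blocks never span chromosome boundaries)
variant_blocks <- function(config) {
  M <- config$n_variants
  chrom <- rep(seq_len(config$n_chromosomes), length.out = M)
  chrom <- sort(chrom)
  blk <- integer(M)
  nb <- 0L
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    b <- (seq_along(idx) - 1L) %/% config$ld_block_size
    blk[idx] <- nb + b + 1L
    nb <- nb + max(b) + 1L
  }
  list(chrom = chrom, block = blk)
}

#' Draw ancestral and per-population allele frequencies
#'
#' Ancestral frequencies follow the configured MAF distribution;
#' non-reference populations draw SNP-wise from the Balding-Nichols beta
#' law `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency
#' `p`, so that `Var(p_pop) = F p (1-p)`. Frequencies are constant
#' within an LD block (one draw per block), which keeps the
#' Gaussian-copula haplotype model exact in its degenerate
#' `within_block_r = 1` limit; with `ld_block_size = 1` this reduces to
#' independent per-SNP draws.
#'
#' @param config a [cohort_config()].
#' @return A list with `ancestral` (length-`M` vector) and `pop`
#'   (`M x n_populations` matrix, reference population first).
#' @export
draw_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  bl <- variant_blocks(config)
  nb <- max(bl$block)
  md <- config$maf_distribution
  anc_b <- switch(md$type,
    uniform = runif(nb, md$min, md$max),
    beta = rbeta(nb, md$shape1, md$shape2),
    stop("unknown maf_distribution type: ", md$type, call. = FALSE))
  anc_b <- pmin(pmax(anc_b, 0.001), 0.5)
  npop <- length(config$n_samples)
  popf_b <- matrix(anc_b, nb, npop)
  if (npop > 1L) {
    for (k in 2:npop) {
      f <- config$fst[k - 1L]
      if (f > 0) {
        a <- anc_b * (1 - f) / f
        b <- (1 - anc_b) * (1 - f) / f
        popf_b[, k] <- pmin(pmax(rbeta(nb, a, b), 1e-6), 1 - 1e-6)
      }
    }
  }
  colnames(popf_b) <- names(config$n_samples)
  list(ancestral = anc_b[bl$block],
       pop = popf_b[bl$block, , drop = FALSE])
}

## one set of haplotypes across all variants: latent AR(1) Gaussian per
## LD block (correlation resets at block starts), thresholded per SNP.
## returns n x M 0/1 allele matrix for frequencies p (length M)
draw_haplotypes <- function(n, p, block, rho) {
  m <- length(p)
  z <- matrix(rnorm(n * m), n, m)
  if (m > 1L && rho > 0) {
    cont <- which(c(FALSE, diff(block) == 0L))  # columns continuing a block
    sq <- sqrt(1 - rho^2)
    for (j in cont) {
      z[, j] <- rho * z[, j - 1L] + sq * z[, j]
    }
  }
  ## allele = 1 iff latent below the p-quantile; identical thresholds
  ## (hence identical alleles at rho = 1) when frequencies are shared
  ## within the block
  (z < rep(qnorm(p), each = n)) + 0L
}

#' Draw unrelated genotypes under the LD-block copula model
#'
#' Each sample is the sum of two independent haplotypes; within an LD
#' block haplotype alleles come from thresholding a latent AR(1)
#' Gaussian with lag-one correlation `within_block_r`, across blocks
#' haplotypes are independent. Variant positions sit on a regular
#' 1-kb grid (1-based) per chromosome. If `n_x_variants > 0` an X-like
#' chromosome is appended on which males carry two copies of a single
#' haplotype (hemizygosity coded as homozygosity).
#'
#' @param freqs result of [draw_allele_frequencies()].
#' @param config a [cohort_config()].
#' @return A [genotype_matrix()] with `population`, `sex`, `age`,
#'   `family` columns in the sample table.
#' @export
draw_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(freqs$pop <= 0 | freqs$pop >= 1)) {
    stop("allele frequencies must lie strictly in (0,1)", call. = FALSE)
  }
  bl <- variant_blocks(config)
  M <- config$n_variants
  rho <- config$within_block_r
  ntot <- sum(config$n_samples)
  geno <- matrix(0L, ntot, M)
  pop_lab <- rep(names(config$n_samples), config$n_samples)
  row0 <- 0L
  for (k in seq_along(config$n_samples)) {
    nk <- config$n_samples[k]
    if (nk == 0L) next
    rows <- row0 + seq_len(nk)
    p <- freqs$pop[, k]
    geno[rows, ] <- draw_haplotypes(nk, p, bl$block, rho) +
      draw_haplotypes(nk, p, bl$block, rho)
    row0 <- row0 + nk
  }
  pos <- unlist(lapply(split(seq_len(M), bl$chrom),
                       function(ix) seq_along(ix) * 1000L), use.names = FALSE)
  variants <- data.frame(chrom = as.character(bl$chrom), pos = pos,
                         id = sprintf("snp%06d", seq_len(M)),
                         a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  sex <- rbinom(ntot, 1, 0.5) + 1L  # 1 = male, 2 = female
  age <- sample(seq(config$age_range[1], config$age_range[2]), ntot,
                replace = TRUE)
  samples <- data.frame(id = sprintf("ind%06d", seq_len(ntot)),
                        sex = sex, age = age, population = pop_lab,
                        family = NA_character_, stringsAsFactors = FALSE)
  ## X-like block: males hemizygous, coded as homozygotes
  if (config$n_x_variants > 0L) {
    mx <- config$n_x_variants
    px <- pmin(pmax(runif(mx, 0.05, 0.5), 0.001), 0.5)
    hx1 <- (matrix(runif(ntot * mx), ntot, mx) <
            rep(px, each = ntot)) + 0L
    hx2 <- (matrix(runif(ntot * mx), ntot, mx) <
            rep(px, each = ntot)) + 0L
    gx <- hx1 + hx2
    male <- sex == 1L
    gx[male, ] <- 2L * hx1[male, , drop = FALSE]
    geno <- cbind(geno, gx)
    variants <- rbind(variants,
                      data.frame(chrom = "X", pos = seq_len(mx) * 1000L,
                                 id = sprintf("snpX%05d", seq_len(mx)),
                                 a1 = "A", a2 = "B",
                                 stringsAsFactors = FALSE))
  }
  genotype_matrix(geno, variants, samples)
}

#' Append full-sib pairs by Mendelian gamete sampling
#'
#' Each pair's two parents are drawn (without replacement within a pair)
#' from the given parent pool; every sib genotype is assembled SNP by
#' SNP from one transmitted allele per parent, so sib pairs have
#' expected genomic relationship 0.5 and sibs relate to their parents
#' at 0.5 as well. X-like variants of male sibs are re-coded homozygous.
#'
#' @param pool a [genotype_matrix()] of candidate parents (no missing
#'   calls).
#' @param n_sib_pairs number of pairs; 0 returns the pool unchanged.
#' @param parent_ids optional matrix (`n_sib_pairs x 2`) of pool sample
#'   ids to use as parents; by default pairs are sampled from the pool.
#' @return A [genotype_matrix()] of the pool plus `2 * n_sib_pairs` sib
#'   rows; sibs carry a shared `family` label naming their parents.
#' @export
spike_relatives <- function(pool, n_sib_pairs, parent_ids = NULL) {
  stopifnot(inherits(pool, "genotype_matrix"))
  if (n_sib_pairs == 0L) return(pool)
  n_pool <- nrow(pool$geno)
  if (n_pool < 2L) stop("need at least 2 candidate parents", call. = FALSE)
  if (is.null(parent_ids)) {
    parent_ids <- t(replicate(n_sib_pairs, sample(pool$samples$id, 2L)))
    parent_ids <- matrix(parent_ids, ncol = 2L)
  }
  M <- ncol(pool$geno)
  x_cols <- which(pool$variants$chrom == "X")
  gamete <- function(g) {
    ## transmitted allele count from genotype 0/1/2
    tr <- integer(length(g))
    het <- g == 1L
    tr[g == 2L] <- 1L
    tr[het] <- rbinom(sum(het), 1L, 0.5)
    tr
  }
  sib_geno <- matrix(0L, 2L * n_sib_pairs, M)
  fam <- character(2L * n_sib_pairs)
  for (k in seq_len(n_sib_pairs)) {
    pa <- pool$geno[match(parent_ids[k, 1L], pool$samples$id), ]
    ma <- pool$geno[match(parent_ids[k, 2L], pool$samples$id), ]
    if (anyNA(pa) || anyNA(ma)) {
      stop("parent genotypes must be complete", call. = FALSE)
    }
    for (s in 1:2) {
      sib_geno[2L * (k - 1L) + s, ] <- gamete(pa) + gamete(ma)
    }
    fam[2L * (k - 1L) + 1:2] <- paste0("fam_", parent_ids[k, 1L], "_",
                                       parent_ids[k, 2L])
  }
  nsib <- 2L * n_sib_pairs
  sex <- rbinom(nsib, 1, 0.5) + 1L
  if (length(x_cols)) {
    male <- which(sex == 1L)
    for (i in male) {
      g <- sib_geno[i, x_cols]
      het <- which(g == 1L)
      g[het] <- 2L * rbinom(length(het), 1L, 0.5)
      sib_geno[i, x_cols] <- g
    }
  }
  ages <- pool$samples$age %||% rep(50L, n_pool)
  pool_samples <- pool$samples
  if (is.null(pool_samples$family)) pool_samples$family <- NA_character_
  if (is.null(pool_samples$population)) {
    pool_samples$population <- "pool"
  }
  p1 <- parent_ids[rep(seq_len(n_sib_pairs), each = 2L), 1L]
  sib_samples <- data.frame(
    id = sprintf("sib%06d", seq_len(nsib)),
    sex = sex,
    age = sample(ages, nsib, replace = TRUE),
    population = pool_samples$population[match(p1, pool_samples$id)],
    family = fam, stringsAsFactors = FALSE)
  keep <- intersect(names(pool_samples), names(sib_samples))
  genotype_matrix(rbind(pool$geno, sib_geno),
                  pool$variants,
                  rbind(pool_samples[, keep, drop = FALSE],
                        sib_samples[, keep, drop = FALSE]))
}

#' Draw true SNP effects on the standardised-genotype scale
#'
#' Causal variants are a random subset of the autosomal variants;
#' non-causal variants get exactly zero effect. Under
#' `"two_component"` a configured fraction of causal SNPs is drawn with
#' inflated variance; under `"maf_stratified"` the per-SNP variance
#' depends on its MAF bin. With several traits the per-SNP effect
#' vectors are drawn jointly from the configured genetic correlation
#' (the causal set is shared across traits).
#'
#' @param config a [cohort_config()].
#' @param mafs per-variant MAFs (length = number of autosomal variants).
#' @param causal optional indices of causal variants (defaults to a
#'   random draw of the first architecture's `n_causal`).
#' @return A matrix (`length(mafs) x T`) of effects; attribute
#'   `"causal"` holds the causal indices.
#' @export
draw_snp_effects <- function(config, mafs, causal = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  tn <- length(config$traits)
  M <- length(mafs)
  n_causal <- config$traits[[1]]$n_causal
  if (n_causal > M) stop("n_causal exceeds available variants", call. = FALSE)
  if (is.null(causal)) causal <- sort(sample.int(M, n_causal))
  eff <- matrix(0, M, tn)
  colnames(eff) <- vapply(config$traits, `[[`, "", "name")
  if (!length(causal)) return(structure(eff, causal = integer(0)))
  ## per-SNP relative variance from the (first) architecture's model;
  ## each trait's own model modulates its column
  base <- rmvn(length(causal), config$genetic_correlation)
  for (t in seq_len(tn)) {
    ar <- config$traits[[t]]
    v <- rep(1, length(causal))
    if (ar$effect_model == "two_component" && ar$tail_fraction > 0) {
      ntail <- round(ar$tail_fraction * length(causal))
      if (ntail > 0) {
        tail_ix <- seq_len(ntail)  # deterministic subset of the causal draw
        v[tail_ix] <- ar$tail_var_ratio
      }
    } else if (ar$effect_model == "maf_stratified") {
      bin <- cut(mafs[causal], breaks = ar$maf_bin_breaks,
                 include.lowest = TRUE, labels = FALSE)
      bin[is.na(bin)] <- 1L
      v <- ar$maf_bin_var[bin]
    }
    eff[causal, t] <- base[, t] * sqrt(v)
  }
  structure(eff, causal = causal)
}

#' Assemble phenotypes from genotypes and true effects
#'
#' Builds `y = mu + sex * beta_sex + age * beta_age + g + e` per trait,
#' where `g` is the standardised-genotype weighted sum of true effects,
#' rescaled so that `Var(g) = h2` and `Var(g) + Var(e) = 1`;
#' environmental draws follow the configured environmental correlation
#' across traits. Only autosomal variants contribute to `g`.
#'
#' @param geno a [genotype_matrix()] (complete calls).
#' @param effects effect matrix from [draw_snp_effects()].
#' @param config a [cohort_config()].
#' @return A list: `phenotypes` (data frame `id, sex, age, <traits>`)
#'   and `truth` (class `truth_set`: rescaled `effects`,
#'   `genetic_values`, `realized_h2`, `population`, `family`).
#' @export
assemble_phenotypes <- function(geno, effects, config) {
  stopifnot(inherits(geno, "genotype_matrix"))
  auto <- which(geno$variants$chrom != "X")
  if (nrow(effects) != length(auto)) {
    stop("effects must cover the autosomal variants", call. = FALSE)
  }
  tn <- length(config$traits)
  n <- nrow(geno$geno)
  G <- geno$geno[, auto, drop = FALSE]
  mu <- colMeans(G)
  s <- sqrt(colMeans(G^2) - mu^2)
  h2 <- vapply(config$traits, `[[`, 0, "h2")
  eff_scaled <- effects
  gmat <- matrix(0, n, tn)
  for (t in seq_len(tn)) {
    a <- effects[, t]
    nz <- which(a != 0 & s > 0)
    if (length(nz)) {
      Z <- sweep(sweep(G[, nz, drop = FALSE], 2L, mu[nz]), 2L, s[nz], "/")
      g_raw <- drop(Z %*% a[nz])
      vg <- var(g_raw) * (n - 1) / n
    } else {
      g_raw <- numeric(n)
      vg <- 0
    }
    if (h2[t] > 0 && vg == 0) {
      stop("h2 > 0 requires at least one polymorphic causal variant",
           call. = FALSE)
    }
    sc <- if (vg > 0) sqrt(h2[t] / vg) else 0
    eff_scaled[, t] <- a * sc
    gmat[, t] <- g_raw * sc
  }
  e <- rmvn(n, config$environmental_correlation)
  e <- sweep(e, 2L, sqrt(pmax(1 - h2, 0)), "*")
  sex <- geno$samples$sex
  age <- geno$samples$age
  y <- gmat + e +
    outer(as.numeric(sex), config$sex_effect) +
    outer(as.numeric(age), config$age_effect)
  colnames(y) <- vapply(config$traits, `[[`, "", "name")
  ve <- apply(e, 2L, var)
  vgr <- apply(gmat, 2L, var)
  realized <- ifelse(vgr + ve > 0, vgr / (vgr + ve), 0)
  phen <- data.frame(id = geno$samples$id, sex = sex, age = age,
                     y, stringsAsFactors = FALSE, check.names = FALSE)
  truth <- structure(list(effects = eff_scaled, genetic_values = gmat,
                          realized_h2 = setNames(realized, colnames(y)),
                          population = geno$samples$population,
                          family = geno$samples$family),
                     class = "truth_set")
  list(phenotypes = phen, truth = truth)
}

#' Impose platform-structured missingness
#'
#' Samples are split between two genotyping platforms; every call is
#' dropped independently at its platform's baseline rate, and a
#' configured fraction of variants additionally gets the elevated
#' `biased_missing_rate` on platform 2 only — the pattern the
#' platform-bias Fisher filter is designed to catch.
#'
#' @param geno a [genotype_matrix()].
#' @param config a [cohort_config()].
#' @return The genotype matrix with `NA` entries, a `platform` column
#'   (1/2) in the sample table, and attribute `"biased_variants"`
#'   listing the variant ids given platform-differential missingness.
#' @export
apply_missingness <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$geno); M <- ncol(geno$geno)
  platform <- rbinom(n, 1, 0.5) + 1L
  rates <- config$platform_missing_rates
  g <- geno$geno
  nbias <- round(config$biased_variant_fraction * M)
  biased <- if (nbias > 0) sort(sample.int(M, nbias)) else integer(0)
  for (pf in 1:2) {
    rows <- which(platform == pf)
    if (!length(rows)) next
    if (rates[pf] == 0 && (pf == 1L || !length(biased))) next
    drop <- matrix(runif(length(rows) * M) < rates[pf], length(rows), M)
    if (pf == 2L && length(biased)) {
      ## elevated rate replaces the baseline on the biased variants
      drop[, biased] <- runif(length(rows) * length(biased)) <
        config$biased_missing_rate
    }
    g[rows, ][drop] <- NA_integer_
  }
  geno$geno <- g
  geno$samples$platform <- platform
  attr(geno, "biased_variants") <- geno$variants$id[biased]
  geno
}

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generative pipeline under the config's seed: allele
#' frequencies, LD-blocked genotypes per population, sib pairs,
#' true effects, phenotypes with covariates, and platform missingness.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort`: list with `genotypes`
#'   (a [genotype_matrix()]), `phenotypes` (data frame), `truth`
#'   (`truth_set`), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  freqs <- draw_allele_frequencies(config)
  geno <- draw_genotypes(freqs, config)
  if (config$n_sib_pairs > 0L) {
    ref <- which(geno$samples$population == names(config$n_samples)[1])
    pool_ids <- geno$samples$id[ref]
    pairs <- matrix(sample(pool_ids, 2L * config$n_sib_pairs), ncol = 2L)
    geno <- spike_relatives(geno, config$n_sib_pairs, parent_ids = pairs)
  }
  auto <- which(geno$variants$chrom != "X")
  mafs <- variant_maf(subset_genotypes(geno, variants = auto))
  effects <- draw_snp_effects(config, mafs)
  ph <- assemble_phenotypes(geno, effects, config)
  geno <- apply_missingness(geno, config)
  structure(list(genotypes = geno, phenotypes = ph$phenotypes,
                 truth = ph$truth, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d variants, %d trait(s)\n",
              nrow(x$genotypes$geno), ncol(x$genotypes$geno),
              length(x$config$traits)))
  cat(sprintf("  realized h2: %s\n",
              paste(sprintf("%s=%.3f", names(x$truth$realized_h2),
                            x$truth$realized_h2), collapse = ", ")))
  invisible(x)
}
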