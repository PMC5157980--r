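#' Pipeline configuration
#'
#' Bundles every stage's parameters with the published defaults:
#' variant missingness 2%, platform Fisher p 1e-100, MAF 0.05 (strict),
#' HWE p 1e-50, sample missingness 5%, relatedness 0.0625, 20 PCs at
#' 3 SD, per-sex phenotype outliers at 3 SD, 10 CV folds, the p-value
#' grid 5e-8 ... 1, and an extrapolation target of 500,000 training
#' samples.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort
#'   (or `NULL` when running on data read from disk).
#' @param qc list of QC thresholds overriding [qc_defaults()].
#' @param cv_folds cross-validation folds.
#' @param p_thresholds C+T p-value grid.
#' @param extrapolate_n training-size target for the accuracy
#'   projection.
#' @param subsample_fractions training-set fractions for the
#'   subsampling series.
#' @param holdout_fraction fraction of the unrelated reference group
#'   held out as the within-ancestry validation set.
#' @param seed master seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, qc = list(), cv_folds = 10,
                            p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3,
                                             0.01, 0.05, 0.1, 0.5, 1),
                            extrapolate_n = 5e5,
                            subsample_fractions = c(0.4, 0.55, 0.7,
                                                    0.85, 1),
                            holdout_fraction = 0.2,
                            seed = 1L) {
  thr <- modifyList(qc_defaults(), qc)
  structure(list(cohort = cohort, qc = thr, cv_folds = cv_folds,
                 p_thresholds = p_thresholds,
                 extrapolate_n = extrapolate_n,
                 subsample_fractions = subsample_fractions,
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' Round-trips every scalar parameter, the QC thresholds and the cohort
#' description (trait architectures included). The format follows the
#' file extension: `.yaml`/`.yml` (requires the `yaml` package),
#' anything else JSON.
#'
#' @param config a [pipeline_config()].
#' @param path config file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$cohort)) {
    ch <- unclass(x$cohort)
    ch$n_samples <- as.list(ch$n_samples)   # keep population names
    ch$traits <- lapply(ch$traits, unclass)
    ch$genetic_correlation <- as.vector(ch$genetic_correlation)
    ch$environmental_correlation <- as.vector(ch$environmental_correlation)
    x$cohort <- ch
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  num <- function(v) as.numeric(unlist(v))   # yaml reads vectors as lists
  cohort <- NULL
  if (!is.null(x$cohort) && length(x$cohort)) {
    ch <- x$cohort
    tn <- if (is.data.frame(ch$traits)) nrow(ch$traits) else length(ch$traits)
    traits <- lapply(seq_len(tn), function(i) {
      tr <- if (is.data.frame(ch$traits)) as.list(ch$traits[i, ]) else
        ch$traits[[i]]
      trait_architecture(h2 = tr$h2, n_causal = tr$n_causal,
                         effect_model = tr$effect_model,
                         tail_fraction = tr$tail_fraction,
                         tail_var_ratio = tr$tail_var_ratio,
                         maf_bin_breaks = unlist(tr$maf_bin_breaks),
                         maf_bin_var = unlist(tr$maf_bin_var),
                         name = tr$name)
    })
    cohort <- cohort_config(
      n_samples = setNames(unlist(ch$n_samples), names(ch$n_samples)),
      n_variants = ch$n_variants, n_chromosomes = ch$n_chromosomes,
      ld_block_size = ch$ld_block_size,
      within_block_r = ch$within_block_r,
      maf_distribution = as.list(ch$maf_distribution), fst = num(ch$fst),
      n_sib_pairs = ch$n_sib_pairs,
      platform_missing_rates = num(ch$platform_missing_rates),
      biased_variant_fraction = ch$biased_variant_fraction,
      biased_missing_rate = ch$biased_missing_rate,
      traits = traits,
      genetic_correlation = matrix(num(ch$genetic_correlation), tn, tn),
      environmental_correlation = matrix(num(ch$environmental_correlation),
                                         tn, tn),
      sex_effect = num(ch$sex_effect), age_effect = num(ch$age_effect),
      age_range = num(ch$age_range), n_x_variants = ch$n_x_variants,
      seed = ch$seed)
  }
  pipeline_config(cohort = cohort, qc = lapply(as.list(x$qc), unlist),
                  cv_folds = x$cv_folds,
                  p_thresholds = num(x$p_thresholds),
                  extrapolate_n = x$extrapolate_n,
                  subsample_fractions = num(x$subsample_fractions),
                  holdout_fraction = x$holdout_fraction, seed = x$seed)
}

#' Packaged demonstration configuration
#'
#' A cohort small enough for a single workstation yet rich enough to
#' exercise every pipeline stage: ~3,000 samples over four ancestry
#' groups plus sib pairs, ~20,000 LD-blocked variants, two correlated
#' traits, platform-structured missingness and an X-like block.
#'
#' @param seed master seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  cohort <- cohort_config(
    n_samples = c(ref = 2200, white = 300, asian = 220, black = 180),
    n_variants = 20000, n_chromosomes = 20, ld_block_size = 10,
    within_block_r = 0.8,
    maf_distribution = list(type = "uniform", min = 0.01, max = 0.5),
    fst = c(0.003, 0.02, 0.06),
    n_sib_pairs = 100,
    platform_missing_rates = c(0.002, 0.004),
    biased_variant_fraction = 0.005, biased_missing_rate = 0.5,
    traits = list(
      trait_architecture(0.5, 2000, name = "height"),
      trait_architecture(0.3, 2000, name = "bmr")),
    genetic_correlation = matrix(c(1, 0.6, 0.6, 1), 2),
    environmental_correlation = matrix(c(1, 0.2, 0.2, 1), 2),
    sex_effect = c(1.0, 0.8), age_effect = c(0.01, -0.01),
    n_x_variants = 300, seed = seed)
  ## at ~3,000 samples only the leading PCs carry ancestry; trailing
  ## components pick up families and noise, so the demonstration uses 6
  pipeline_config(cohort = cohort,
                  qc = list(min_group_size = 100, n_pcs = 6),
                  cv_folds = 10, seed = seed)
}

stage_msg <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

write_stage_json <- function(dir, stage, obj) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, paste0(stage, ".json"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' Run the whole analysis end to end
#'
#' Simulates (or accepts) a cohort, applies sample and variant QC,
#' derives principal components and ancestry groups, splits the
#' reference ancestry into unrelated training and related validation
#' sets, fits the single-component model and scores every validation
#' group, refits with effect-size-grouped and MAF-stratified
#' components and a multivariate model, profiles the
#' clump-and-threshold GWAS predictor, and fits the
#' accuracy-vs-sample-size extrapolation.
#'
#' @param config a [pipeline_config()] with a cohort description.
#' @param cohort optional pre-simulated cohort (overrides
#'   `config$cohort`).
#' @param output_dir optional directory for per-stage JSON/TSV
#'   artifacts and a provenance block.
#' @param verbose print stage progress.
#' @return A list with the per-stage results: `qc`, `split`,
#'   `fit` (single component), `accuracy` (Table-1/2 analogue),
#'   `two_component`, `maf_stratified`, `multivariate`, `ct_profile`,
#'   `extrapolation`, `provenance`.
#' @export
run_pipeline <- function(config, cohort = NULL, output_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  set.seed(config$seed)
  thr <- config$qc

  ## -- simulate ------------------------------------------------------
  if (is.null(cohort)) {
    if (is.null(config$cohort)) stop("no cohort configured", call. = FALSE)
    stage_msg(verbose, "simulating cohort (seed %d)", config$seed)
    cohort <- simulate_cohort(config$cohort)
  }
  geno <- cohort$genotypes
  phen <- cohort$phenotypes
  trait_names <- vapply(cohort$config$traits, `[[`, "", "name")
  set.seed(config$seed + 1L)

  ## -- sample + variant QC ------------------------------------------
  stage_msg(verbose, "sample QC on %d samples", nrow(geno$geno))
  sqc <- sample_qc(geno, thr, sex_check = cohort$config$n_x_variants > 0)
  geno <- subset_genotypes(geno, samples = sqc$samples)
  phen <- phen[match(sqc$samples, phen$id), , drop = FALSE]

  stage_msg(verbose, "variant QC on %d variants", ncol(geno$geno))
  vqc <- variant_qc(geno, thr)
  geno_qc <- vqc$genotypes
  auto <- which(geno_qc$variants$chrom != "X")
  geno_qc <- subset_genotypes(geno_qc, variants = auto)
  vqc$genotypes <- NULL
  rm(geno); gc(FALSE)

  ## -- phenotype QC --------------------------------------------------
  for (tr in trait_names) {
    phen <- phenotype_outlier_filter(phen, tr, n_sd = thr$phenotype_sd)
  }

  ## -- PCA + ancestry filter ----------------------------------------
  stage_msg(verbose, "LD pruning + PCA")
  pruned <- ld_prune(geno_qc)
  zp <- standardize(subset_genotypes(geno_qc, variants = pruned))$z
  n_pcs <- min(thr$n_pcs, nrow(zp) - 1L, ncol(zp))
  pca <- pca_grm(zp, k = n_pcs)
  rm(zp); gc(FALSE)
  anc <- ancestry_filter(pca$projections, geno_qc$samples$population,
                         k = n_pcs, z = thr$pc_sd,
                         min_group_size = thr$min_group_size)
  ref_pop <- geno_qc$samples$population[1]
  in_ref <- geno_qc$samples$population == ref_pop
  ## PC outliers of the reference group = the "self-reported" analogue
  selfrep <- which(in_ref & anc$outlier)
  core_ref <- which(in_ref & anc$retained)

  ## -- GRM + relatedness split within the reference group -----------
  stage_msg(verbose, "GRM + relatedness split (%d reference samples)",
            length(core_ref))
  z_ref <- standardize(subset_genotypes(geno_qc, samples = core_ref))$z
  grm_ref <- compute_grm(z_ref)
  rm(z_ref); gc(FALSE)
  rownames(grm_ref) <- colnames(grm_ref) <- geno_qc$samples$id[core_ref]
  spl <- relatedness_split(grm_ref, threshold = thr$relatedness)
  unrel <- match(spl$unrelated, geno_qc$samples$id)
  related <- match(spl$related, geno_qc$samples$id)

  ## within-ancestry holdout carved from the unrelated set
  n_hold <- round(config$holdout_fraction * length(unrel))
  hold <- sample(unrel, n_hold)
  train <- setdiff(unrel, hold)

  groups <- list(holdout = hold,
                 related = related,
                 selfreported = selfrep)
  for (g in setdiff(unique(geno_qc$samples$population), ref_pop)) {
    rows <- which(geno_qc$samples$population == g & anc$retained)
    if (length(rows) >= 4L) groups[[g]] <- rows
  }

  ## -- training fit: single component -------------------------------
  stage_msg(verbose, "REML + SNP-BLUP on %d training samples",
            length(train))
  g_train <- subset_genotypes(geno_qc, samples = train)
  sz <- standardize(g_train)
  k_train <- compute_grm(sz$z)
  eig <- grm_eigen(k_train)
  cov_train <- as.matrix(phen[match(geno_qc$samples$id[train], phen$id),
                              c("sex", "age")])
  fits <- list(); effects <- list()
  for (tr in trait_names) {
    ytr <- phen[[tr]][match(geno_qc$samples$id[train], phen$id)]
    ok <- !is.na(ytr)
    if (all(ok)) {
      fit <- reml_fit(ytr, k_train, x = cov_train, eig = eig,
                      m_variants = ncol(sz$z))
      eff <- snp_blup(sz$z, ytr, fit, x = cov_train, stats = sz$stats)
    } else {
      g_ok <- subset_genotypes(g_train, samples = which(ok))
      sz_ok <- standardize(g_ok)
      fit <- reml_fit(ytr[ok], compute_grm(sz_ok$z),
                      x = cov_train[ok, , drop = FALSE],
                      m_variants = ncol(sz_ok$z))
      eff <- snp_blup(sz_ok$z, ytr[ok], fit,
                      x = cov_train[ok, , drop = FALSE],
                      stats = sz_ok$stats)
    }
    fits[[tr]] <- fit
    effects[[tr]] <- eff
  }

  ## -- score every validation group (Table 1 / Table 2 analogue) ----
  stage_msg(verbose, "scoring %d validation groups", length(groups))
  acc_rows <- list()
  for (gname in names(groups)) {
    rows <- groups[[gname]]
    if (length(rows) < 4L) next
    g_val <- subset_genotypes(geno_qc, samples = rows)
    ids <- geno_qc$samples$id[rows]
    cov_val <- as.matrix(phen[match(ids, phen$id), c("sex", "age")])
    for (tr in trait_names) {
      yv <- phen[[tr]][match(ids, phen$id)]
      ok <- !is.na(yv) & !is.na(cov_val[, 1]) & !is.na(cov_val[, 2])
      if (sum(ok) < 4L) next
      sc <- polygenic_score(g_val, effects[[tr]])
      y_adj <- adjust_phenotype(yv[ok], cov_val[ok, , drop = FALSE])
      a <- accuracy(sc[ok], y_adj)
      acc_rows[[length(acc_rows) + 1L]] <-
        data.frame(group = gname, trait = tr, n = a$n, r = a$r,
                   ci_lower = a$ci[1], ci_upper = a$ci[2])
    }
  }
  acc_tab <- do.call(rbind, acc_rows)

  ## -- two-component refit (first trait) -----------------------------
  tr1 <- trait_names[1]
  y1 <- phen[[tr1]][match(geno_qc$samples$id[train], phen$id)]
  ok1 <- !is.na(y1)
  stage_msg(verbose, "two-component refit (%s)", tr1)
  scan <- gwas_scan(y1[ok1], subset_genotypes(g_train, samples = which(ok1)),
                    covariates = cov_train[ok1, , drop = FALSE])
  grp2 <- effect_outlier_groups(scan)
  two_comp <- NULL
  if (all(c("main", "tail") %in% grp2)) {
    zs <- list(main = sz$z[ok1, grp2 == "main", drop = FALSE],
               tail = sz$z[ok1, grp2 == "tail", drop = FALSE])
    ks <- lapply(zs, compute_grm)
    fit2 <- reml_fit(y1[ok1], ks, x = cov_train[ok1, , drop = FALSE],
                     m_variants = vapply(zs, ncol, 0L))
    eff2 <- snp_blup(zs, y1[ok1], fit2, x = cov_train[ok1, , drop = FALSE],
                     stats = sz$stats)
    g_hold <- subset_genotypes(geno_qc, samples = hold)
    ids_h <- geno_qc$samples$id[hold]
    cov_h <- as.matrix(phen[match(ids_h, phen$id), c("sex", "age")])
    yh <- phen[[tr1]][match(ids_h, phen$id)]
    okh <- !is.na(yh)
    sc2 <- polygenic_score(g_hold, eff2)
    a2 <- accuracy(sc2[okh], adjust_phenotype(yh[okh],
                                              cov_h[okh, , drop = FALSE]))
    two_comp <- list(fit = fit2, n_tail = sum(grp2 == "tail"),
                     holdout_r = a2$r, holdout_ci = a2$ci)
    rm(zs, ks, eff2, g_hold); gc(FALSE)
  }
  ## standardised training matrix no longer needed; keep the stats
  sz$z <- NULL
  gc(FALSE)

  ## -- MAF-stratified refit (first trait) ----------------------------
  stage_msg(verbose, "MAF-stratified refit (%s)", tr1)
  thr_rare <- modifyList(thr, list(maf = 0.001))
  vqc_rare <- variant_qc(subset_genotypes(
    cohort$genotypes,
    samples = match(geno_qc$samples$id, cohort$genotypes$samples$id)),
    thr_rare)
  g_rare <- subset_genotypes(vqc_rare$genotypes,
                             variants = which(vqc_rare$genotypes$variants$chrom != "X"))
  g_rare_tr <- subset_genotypes(g_rare, samples = match(
    geno_qc$samples$id[train], g_rare$samples$id))
  mafs_tr <- variant_maf(g_rare_tr)
  mg <- suppressWarnings(maf_groups(mafs_tr))
  maf_fit <- NULL
  present <- unique(na.omit(mg))
  if (length(present) >= 2L) {
    sz_r <- standardize(g_rare_tr)
    zs <- lapply(present, function(g) sz_r$z[ok1, which(!is.na(mg) & mg == g),
                                             drop = FALSE])
    names(zs) <- present
    rm(sz_r); gc(FALSE)
    zs <- zs[vapply(zs, ncol, 0L) > 0]
    ks <- lapply(zs, compute_grm)
    m_per <- vapply(zs, ncol, 0L)
    rm(zs); gc(FALSE)
    maf_fit <- reml_fit(y1[ok1], ks, x = cov_train[ok1, , drop = FALSE],
                        m_variants = m_per)
    rm(ks); gc(FALSE)
  }
  rm(vqc_rare, g_rare, g_rare_tr); gc(FALSE)

  ## -- multivariate refit --------------------------------------------
  mv <- NULL
  if (length(trait_names) >= 2L) {
    stage_msg(verbose, "multivariate refit (%s)",
              paste(trait_names[1:2], collapse = " + "))
    ym <- as.matrix(phen[match(geno_qc$samples$id[train], phen$id),
                         trait_names[1:2]])
    mv <- reml_fit_multivariate(ym, k_train, x = cov_train,
                                eig = if (all(complete.cases(ym))) eig)
  }

  ## -- C+T profile (first trait) -------------------------------------
  stage_msg(verbose, "clump + threshold profile (%s)", tr1)
  cl <- clump(scan, subset_genotypes(g_train, samples = which(ok1)))
  g_hold <- subset_genotypes(geno_qc, samples = hold)
  ids_h <- geno_qc$samples$id[hold]
  cov_h <- as.matrix(phen[match(ids_h, phen$id), c("sex", "age")])
  yh <- phen[[tr1]][match(ids_h, phen$id)]
  okh <- !is.na(yh) & complete.cases(cov_h)
  profile <- threshold_profile(cl, scan, sz$stats,
                               subset_genotypes(g_hold, samples = which(okh)),
                               yh[okh], cov_h[okh, , drop = FALSE],
                               thresholds = config$p_thresholds)

  ## -- subsampling + extrapolation (first trait) ---------------------
  stage_msg(verbose, "subsampling series + extrapolation (%s)", tr1)
  sizes <- unique(round(config$subsample_fractions * length(train)))
  g_unrel <- subset_genotypes(geno_qc, samples = unrel)
  ids_u <- geno_qc$samples$id[unrel]
  cov_u <- as.matrix(phen[match(ids_u, phen$id), c("sex", "age")])
  yu <- phen[[tr1]][match(ids_u, phen$id)]
  oku <- which(!is.na(yu))
  series <- subsample_series(subset_genotypes(g_unrel, samples = oku),
                             yu[oku], cov_u[oku, , drop = FALSE],
                             sizes = pmin(sizes, round(0.8 * length(oku))))
  curve <- fit_inverse_r2(series)
  extrap <- if (curve$valid_max) {
    proj <- project_accuracy(curve, config$extrapolate_n)
    frac <- fraction_of_maximum(min(proj$r, 1), fits[[tr1]]$h2)
    list(fit = curve, projection = proj, fraction_of_maximum = frac)
  } else list(fit = curve, projection = NULL, fraction_of_maximum = NULL)

  provenance <- list(package = "snpblup",
                     version = as.character(utils::packageVersion("snpblup")),
                     seed = config$seed,
                     n_input_samples = nrow(cohort$genotypes$geno),
                     n_input_variants = ncol(cohort$genotypes$geno),
                     n_train = length(train),
                     n_variants_qc = ncol(geno_qc$geno),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(output_dir)) {
    write_qc_report(vqc$report, file.path(output_dir, "variant_qc.json"))
    write_qc_report(sqc$report, file.path(output_dir, "sample_qc.json"))
    write.table(acc_tab, file.path(output_dir, "accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(profile, file.path(output_dir, "ct_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(series, file.path(output_dir, "subsample_series.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_effects(effects[[tr1]],
                  file.path(output_dir, paste0("effects_", tr1, ".tsv")))
    write_stage_json(output_dir, "fit", lapply(fits, function(f) {
      list(h2 = f$h2, h2_se = f$h2_se, sigma2_e = f$sigma2_e,
           loglik = f$loglik, converged = f$converged)
    }))
    write_stage_json(output_dir, "extrapolation", list(
      b0 = curve$b0, b1 = curve$b1, max_accuracy = curve$max_accuracy,
      projected_r = extrap$projection$r %||% NA,
      projected_se = extrap$projection$se %||% NA,
      fraction_of_maximum = extrap$fraction_of_maximum$percent %||% NA))
    write_stage_json(output_dir, "provenance", provenance)
  }

  list(qc = list(sample = sqc$report, variant = vqc$report),
       split = list(train = geno_qc$samples$id[train],
                    holdout = geno_qc$samples$id[hold],
                    related = spl$related,
                    selfreported = geno_qc$samples$id[selfrep]),
       pca = pca, fit = fits, effects = effects, accuracy = acc_tab,
       two_component = two_comp, maf_stratified = maf_fit,
       multivariate = mv, ct_profile = profile,
       subsample = series, extrapolation = extrap,
       provenance = provenance)
}
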