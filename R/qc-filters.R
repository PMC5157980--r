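## QC filters: variant, sample, phenotype, ancestry, relatedness.

new_qc_report <- function() {
  structure(list(stages = data.frame(filter = character(0),
                                     threshold = numeric(0),
                                     input = integer(0),
                                     removed = integer(0),
                                     retained = integer(0),
                                     stringsAsFactors = FALSE)),
            class = "qc_report")
}

add_stage <- function(report, filter, threshold, input, removed) {
  report$stages <- rbind(report$stages,
                         data.frame(filter = filter, threshold = threshold,
                                    input = input, removed = removed,
                                    retained = input - removed,
                                    stringsAsFactors = FALSE))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param report a `qc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report$stages, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default QC thresholds
#'
#' The thresholds applied throughout the pipeline: variant missingness
#' 2%, platform-bias Fisher p below 1e-100, MAF strictly above 0.05
#' retained, HWE exact p below 1e-50, sample missingness 5%,
#' heterozygosity within 3 SD, sex-check X inbreeding calls at
#' F > 0.8 (male) / F < 0.2 (female), relatedness cut 0.0625,
#' ancestry outliers beyond 3 SD on the leading 20 principal
#' components, per-sex phenotype outliers beyond 3 SD, and a minimum
#' ancestry-group size of 1,000.
#'
#' @return Named list of thresholds.
#' @export
qc_defaults <- function() {
  list(variant_missingness = 0.02,
       platform_p = 1e-100,
       maf = 0.05,
       hwe_p = 1e-50,
       sample_missingness = 0.05,
       het_sd = 3,
       sex_f_male = 0.8,
       sex_f_female = 0.2,
       relatedness = 0.0625,
       n_pcs = 20,
       pc_sd = 3,
       phenotype_sd = 3,
       min_group_size = 1000)
}

## genotype counts per variant on a row subset
genotype_counts <- function(g) {
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  cbind(n0 = n0, n1 = n1, n2 = n2)
}

#' Variant quality control
#'
#' Applies, in order: removal of flagged multi-allelic variants
#' (a logical `multiallelic` column in the variant table, if present);
#' overall missingness above 2%; platform-differential missingness
#' (two-sided Fisher exact p below 1e-100, requires a `platform`
#' sample column); then, with statistics computed on the designated
#' unrelated training samples: MAF not strictly above 0.05, and
#' departure from Hardy-Weinberg equilibrium at exact p below 1e-50.
#'
#' @param geno a [genotype_matrix()].
#' @param thresholds list as from [qc_defaults()].
#' @param unrelated ids (or indices) of the unrelated training subset
#'   on which MAF and HWE are computed; defaults to all samples.
#' @return A list: `genotypes` (filtered matrix) and `report`
#'   (`qc_report`).
#' @export
variant_qc <- function(geno, thresholds = qc_defaults(), unrelated = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  thr <- modifyList(qc_defaults(), thresholds)
  for (nm in c("variant_missingness", "maf", "sample_missingness")) {
    if (thr[[nm]] < 0 || thr[[nm]] > 1) {
      stop("threshold '", nm, "' outside [0,1]", call. = FALSE)
    }
  }
  report <- new_qc_report()
  keep <- rep(TRUE, ncol(geno$geno))

  ## 1. multi-allelic
  ma <- geno$variants$multiallelic %||% rep(FALSE, ncol(geno$geno))
  drop <- keep & ma
  report <- add_stage(report, "multiallelic", NA_real_, sum(keep), sum(drop))
  keep <- keep & !drop

  ## 2. overall missingness
  miss <- colMeans(is.na(geno$geno))
  drop <- keep & miss > thr$variant_missingness
  report <- add_stage(report, "variant_missingness",
                      thr$variant_missingness, sum(keep), sum(drop))
  keep <- keep & !drop

  ## 3. platform-differential missingness
  platform <- geno$samples$platform
  if (!is.null(platform) && length(unique(na.omit(platform))) == 2L) {
    pf <- sort(unique(na.omit(platform)))
    ga <- geno$geno[platform == pf[1], , drop = FALSE]
    gb <- geno$geno[platform == pf[2], , drop = FALSE]
    ma_cnt <- colSums(is.na(ga)); mb_cnt <- colSums(is.na(gb))
    na_tot <- nrow(ga); nb_tot <- nrow(gb)
    lp_thr <- log10(thr$platform_p)
    drop <- rep(FALSE, length(keep))
    for (j in which(keep)) {
      ft <- platform_missingness_test(ma_cnt[j], na_tot - ma_cnt[j],
                                      mb_cnt[j], nb_tot - mb_cnt[j])
      drop[j] <- ft$log10_p < lp_thr
    }
    report <- add_stage(report, "platform_missingness", thr$platform_p,
                        sum(keep), sum(drop))
    keep <- keep & !drop
  }

  ## 4 + 5. MAF and HWE on the unrelated training subset
  rows <- if (is.null(unrelated)) seq_len(nrow(geno$geno)) else {
    if (is.character(unrelated)) match(unrelated, geno$samples$id)
    else unrelated
  }
  gu <- geno$geno[rows, , drop = FALSE]
  p1 <- colMeans(gu, na.rm = TRUE) / 2
  maf <- pmin(p1, 1 - p1)
  drop <- keep & !(maf > thr$maf)      # strict: only MAF > 0.05 retained
  report <- add_stage(report, "maf", thr$maf, sum(keep), sum(drop))
  keep <- keep & !drop

  cnt <- genotype_counts(gu)
  lp_thr <- log10(thr$hwe_p)
  drop <- rep(FALSE, length(keep))
  for (j in which(keep)) {
    minor_first <- cnt[j, "n2"] <= cnt[j, "n0"]
    ht <- if (minor_first) {
      hwe_exact_test(cnt[j, "n2"], cnt[j, "n1"], cnt[j, "n0"])
    } else {
      hwe_exact_test(cnt[j, "n0"], cnt[j, "n1"], cnt[j, "n2"])
    }
    drop[j] <- ht$log10_p < lp_thr
  }
  report <- add_stage(report, "hwe", thr$hwe_p, sum(keep), sum(drop))
  keep <- keep & !drop

  list(genotypes = subset_genotypes(geno, variants = which(keep)),
       report = report)
}

## per-sample X-chromosome inbreeding coefficient F = 1 - Ohet / Ehet
x_inbreeding <- function(geno) {
  xi <- which(geno$variants$chrom == "X")
  if (!length(xi)) stop("no X-like variants available for the sex check",
                        call. = FALSE)
  gx <- geno$geno[, xi, drop = FALSE]
  p <- colMeans(gx, na.rm = TRUE) / 2
  ehet_j <- 2 * p * (1 - p)
  called <- !is.na(gx)
  ohet <- rowSums(gx == 1L, na.rm = TRUE)
  ehet <- as.numeric(called %*% ehet_j)
  f <- ifelse(ehet > 0, 1 - ohet / ehet, NA_real_)
  f
}

#' Sample quality control
#'
#' Removes samples with autosomal missingness above 5%, autosomal
#' heterozygosity beyond 3 SD of the cohort mean, and (when X-like
#' variants exist and `sex_check = TRUE`) samples whose reported sex
#' contradicts the genetic sex called from the X inbreeding
#' coefficient (male if F > 0.8, female if F < 0.2, no call otherwise
#' — no-calls are never removed).
#'
#' @param geno a [genotype_matrix()] with a `sex` sample column
#'   (1 = male, 2 = female).
#' @param thresholds list as from [qc_defaults()].
#' @param sex_check whether to run the X-based sex check.
#' @return A list: `samples` (retained ids) and `report`.
#' @export
sample_qc <- function(geno, thresholds = qc_defaults(), sex_check = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  thr <- modifyList(qc_defaults(), thresholds)
  report <- new_qc_report()
  auto <- which(geno$variants$chrom != "X")
  ga <- geno$geno[, auto, drop = FALSE]
  n <- nrow(ga)
  keep <- rep(TRUE, n)

  miss <- rowMeans(is.na(ga))
  drop <- keep & miss > thr$sample_missingness
  report <- add_stage(report, "sample_missingness", thr$sample_missingness,
                      sum(keep), sum(drop))
  keep <- keep & !drop

  called <- rowSums(!is.na(ga))
  het <- rowSums(ga == 1L, na.rm = TRUE) / pmax(called, 1)
  mu <- mean(het[keep]); s <- sd(het[keep])
  drop <- keep & s > 0 & abs(het - mu) > thr$het_sd * s
  report <- add_stage(report, "heterozygosity", thr$het_sd,
                      sum(keep), sum(drop))
  keep <- keep & !drop

  if (sex_check) {
    f <- x_inbreeding(geno)
    genetic_sex <- ifelse(f > thr$sex_f_male, 1L,
                          ifelse(f < thr$sex_f_female, 2L, NA_integer_))
    reported <- geno$samples$sex
    drop <- keep & !is.na(genetic_sex) & !is.na(reported) &
      genetic_sex != reported
    report <- add_stage(report, "sex_check", thr$sex_f_male,
                        sum(keep), sum(drop))
    keep <- keep & !drop
  }

  list(samples = geno$samples$id[keep], report = report)
}

#' Per-sex phenotype outlier filter
#'
#' Sets trait values strictly outside 3 standard deviations of their
#' sex-stratum mean to missing. Means and SDs are computed once on the
#' input (not re-computed after removals), so the filter is idempotent.
#'
#' @param phenotypes data frame with `id`, `sex` and the trait column.
#' @param trait name of the trait column.
#' @param n_sd the outlier cut (default 3).
#' @return The phenotype table with outlying values set to `NA`.
#' @export
phenotype_outlier_filter <- function(phenotypes, trait, n_sd = 3) {
  if (!trait %in% names(phenotypes)) {
    stop("unknown trait column: ", trait, call. = FALSE)
  }
  y <- phenotypes[[trait]]
  sex <- phenotypes$sex
  if (any(is.na(sex) & !is.na(y))) {
    stop("sex must be available for every sample with the trait",
         call. = FALSE)
  }
  for (s in unique(na.omit(sex))) {
    ix <- which(sex == s & !is.na(y))
    if (length(ix) < 2L) {
      stop("sex stratum with fewer than 2 observations for trait ", trait,
           call. = FALSE)
    }
    mu <- mean(y[ix]); sg <- sd(y[ix])
    out <- ix[abs(y[ix] - mu) > n_sd * sg]   # strictly outside
    y[out] <- NA_real_
  }
  phenotypes[[trait]] <- y
  phenotypes
}

#' Ancestry outlier filter on principal components
#'
#' Per self-reported group, retains samples whose projections on each
#' of the leading `k` principal components fall within `z` standard
#' deviations of the group mean; groups smaller than `min_group_size`
#' are dropped entirely.
#'
#' @param projections numeric matrix, samples x components.
#' @param groups group label per sample.
#' @param k leading components to use (default 20).
#' @param z SD cut (default 3).
#' @param min_group_size minimum group size (default 1,000).
#' @return A list: `retained` (logical per sample), `outlier` (logical:
#'   removed as a PC outlier), `dropped_groups`.
#' @export
ancestry_filter <- function(projections, groups, k = 20, z = 3,
                            min_group_size = 1000) {
  projections <- as.matrix(projections)
  if (k > ncol(projections)) {
    stop("k exceeds the available number of components", call. = FALSE)
  }
  pr <- projections[, seq_len(k), drop = FALSE]
  retained <- rep(FALSE, nrow(pr))
  outlier <- rep(FALSE, nrow(pr))
  dropped <- character(0)
  for (g in unique(groups)) {
    ix <- which(groups == g)
    if (length(ix) < min_group_size) {
      dropped <- c(dropped, g)
      next
    }
    mu <- colMeans(pr[ix, , drop = FALSE])
    sg <- apply(pr[ix, , drop = FALSE], 2L, sd)
    dev <- abs(sweep(pr[ix, , drop = FALSE], 2L, mu))
    ok <- rowSums(dev > rep(z * sg, each = length(ix))) == 0L
    retained[ix[ok]] <- TRUE
    outlier[ix[!ok]] <- TRUE
  }
  list(retained = retained, outlier = outlier, dropped_groups = dropped)
}

#' Split samples into an unrelated set and a related validation set
#'
#' Greedy maximum-degree removal: while any retained pair exceeds the
#' relatedness threshold, the sample with the most above-threshold
#' partners is dropped (ties broken by larger maximum relatedness,
#' then by identifier order). Dropped samples that retain at least one
#' above-threshold link to the final unrelated set form the "related"
#' validation group.
#'
#' @param kinship symmetric relatedness matrix with sample ids as
#'   dimnames (or `ids` supplied).
#' @param threshold relatedness cut (default 0.0625, i.e. between
#'   second cousins and second cousins once removed).
#' @param ids optional sample identifiers.
#' @return A list: `unrelated` and `related` id vectors.
#' @export
relatedness_split <- function(kinship, threshold = 0.0625, ids = NULL) {
  kinship <- as.matrix(kinship)
  if (nrow(kinship) != ncol(kinship)) {
    stop("kinship matrix must be square", call. = FALSE)
  }
  n <- nrow(kinship)
  if (is.null(ids)) ids <- rownames(kinship) %||% as.character(seq_len(n))
  k <- kinship
  diag(k) <- 0
  adj <- k > threshold
  active <- rep(TRUE, n)
  deg <- rowSums(adj)
  removed <- integer(0)
  repeat {
    deg_a <- deg * active
    if (max(deg_a) == 0) break
    cand <- which(deg_a == max(deg_a))
    if (length(cand) > 1L) {
      kmax <- vapply(cand, function(i) max(k[i, active]), 0)
      cand <- cand[kmax == max(kmax)]
      cand <- cand[order(ids[cand])][1L]
    }
    cand <- cand[1L]
    active[cand] <- FALSE
    deg <- deg - adj[, cand]   # drop cand's edges from remaining degrees
    removed <- c(removed, cand)
  }
  unrelated <- which(active)
  linked <- removed[vapply(removed, function(i) {
    any(k[i, unrelated] > threshold)
  }, TRUE)]
  list(unrelated = ids[unrelated], related = ids[sort(linked)])
}
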