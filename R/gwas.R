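#' Per-SNP association scan (fixed-effect OLS)
#'
#' Regresses the phenotype on intercept + covariates + one
#' standardised genotype at a time, reporting the genotype effect, its
#' standard error and the two-sided t-test p-value. Covariates are
#' projected out once, so the scan is a single pass of matrix algebra.
#' Missing genotypes are mean-imputed; constant genotype columns get
#' effect 0 and p = 1 and are flagged.
#'
#' @param y phenotype vector (complete on analysed samples).
#' @param geno a [genotype_matrix()].
#' @param covariates optional covariate matrix/data frame (e.g. sex,
#'   age, leading principal components).
#' @return An object of class `gwas_summary`: data frame with `id`,
#'   `chrom`, `pos`, `a1`, `beta` (standardised-genotype scale), `se`,
#'   `p`, `maf`, `constant`.
#' @export
gwas_scan <- function(y, geno, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete on analysed samples", call. = FALSE)
  n <- length(y)
  if (n != nrow(geno$geno)) stop("y and genotypes disagree on samples",
                                 call. = FALSE)
  x <- build_design(covariates, n)
  p_cov <- ncol(x)
  g <- geno$geno
  mu <- colMeans(g, na.rm = TRUE)
  sg <- sqrt(pmax(colMeans(g^2, na.rm = TRUE) - mu^2, 0))
  const <- !is.finite(sg) | sg == 0
  z <- sweep(g, 2L, mu)
  z[is.na(z)] <- 0
  z <- sweep(z, 2L, ifelse(const, 1, sg), "/")
  if (p_cov == 1L) {
    ## intercept only: genotypes are already column-centred
    ry <- y - mean(y)
    rz <- z
  } else {
    qr_x <- qr(x)
    ry <- qr.resid(qr_x, y)
    rz <- qr.resid(qr_x, z)
  }
  num <- drop(crossprod(rz, ry))
  den <- colSums(rz^2)
  beta <- ifelse(den > 0, num / den, 0)
  df <- n - p_cov - 1L
  rss <- sum(ry^2) - ifelse(den > 0, num^2 / den, 0)
  se <- sqrt(pmax(rss / df, 0) / pmax(den, .Machine$double.eps))
  ## a zero-residual perfect fit has se = 0 and must not look null
  tstat <- ifelse(se > 0, beta / se, ifelse(abs(beta) > 0, Inf, 0))
  pval <- 2 * pt(-abs(tstat), df)
  pval <- pmax(pval, .Machine$double.xmin)   # underflow guard
  pval[const] <- 1
  beta[const] <- 0
  out <- data.frame(id = geno$variants$id, chrom = geno$variants$chrom,
                    pos = geno$variants$pos, a1 = geno$variants$a1,
                    beta = beta, se = se, p = pval,
                    maf = pmin(mu / 2, 1 - mu / 2), constant = const,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Greedy LD clumping of a GWAS summary
#'
#' Repeatedly takes the unassigned SNP with the smallest p-value as an
#' index SNP and absorbs every unassigned SNP on the same chromosome
#' within `window_bp` whose genotype correlation with the index
#' exceeds `sqrt(r2)`. Ties on p are broken by position, then id.
#'
#' @param gwas a `gwas_summary` from [gwas_scan()].
#' @param geno the [genotype_matrix()] the scan was run on (used for
#'   LD).
#' @param r2 squared-correlation threshold; strictly greater absorbs
#'   (default 0.05).
#' @param window_bp physical window around the index (default 1 Mb).
#' @return An object of class `clump_set`: data frame of index SNPs
#'   (`id`, `chrom`, `pos`, `p`, `n_clumped`) plus attribute
#'   `"members"` (list of absorbed ids per index).
#' @export
clump <- function(gwas, geno, r2 = 0.05, window_bp = 1e6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ix <- match(gwas$id, geno$variants$id)
  if (anyNA(ix)) stop("GWAS summary contains variants absent from the ",
                      "genotypes", call. = FALSE)
  ord <- order(gwas$p, gwas$pos, gwas$id)
  g <- geno$geno[, ix, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  gz <- sweep(g, 2L, mu)
  gz[is.na(gz)] <- 0
  sq <- colSums(gz^2)                      # precomputed column norms
  chrom_code <- match(gwas$chrom, unique(gwas$chrom))
  ## per-chromosome position-sorted lookup for the 1-Mb windows
  by_chrom <- split(seq_len(nrow(gwas)), chrom_code)
  by_chrom <- lapply(by_chrom, function(rows) rows[order(gwas$pos[rows])])
  pos_sorted <- lapply(by_chrom, function(rows) gwas$pos[rows])
  assigned <- rep(FALSE, nrow(gwas))
  idx_rows <- integer(0)
  members <- list()
  for (r in ord) {
    if (assigned[r]) next
    assigned[r] <- TRUE
    idx_rows <- c(idx_rows, r)
    cc_i <- chrom_code[r]
    ps <- pos_sorted[[cc_i]]
    rows_c <- by_chrom[[cc_i]]
    lo <- findInterval(gwas$pos[r] - window_bp, ps, left.open = TRUE) + 1L
    hi <- findInterval(gwas$pos[r] + window_bp, ps)
    near <- if (hi >= lo) rows_c[lo:hi] else integer(0)
    near <- near[!assigned[near]]
    absorbed <- character(0)
    if (length(near)) {
      cc <- drop(crossprod(gz[, near, drop = FALSE], gz[, r]))
      v0 <- sq[r]
      vn <- sq[near]
      r2_obs <- ifelse(v0 > 0 & vn > 0, cc^2 / (v0 * vn), 0)
      hit <- near[r2_obs > r2]
      if (length(hit)) {
        assigned[hit] <- TRUE
        absorbed <- gwas$id[hit]
      }
    }
    members[[gwas$id[r]]] <- absorbed
  }
  out <- gwas[idx_rows, c("id", "chrom", "pos", "p", "beta")]
  out$n_clumped <- lengths(members)[out$id]
  rownames(out) <- NULL
  attr(out, "members") <- members
  class(out) <- c("clump_set", "data.frame")
  out
}

#' Prediction accuracy across p-value thresholds (C+T profile)
#'
#' For each threshold, scores the validation samples with the index
#' SNPs whose GWAS p-value is at or below the threshold, using the
#' GWAS effect estimates and training-population standardisation, and
#' reports the accuracy against the covariate-adjusted phenotype.
#'
#' @param clumps a `clump_set` from [clump()].
#' @param gwas the `gwas_summary` the clumps came from.
#' @param train_stats `standardization_stats` of the training
#'   population covering the index SNPs.
#' @param target_geno validation [genotype_matrix()].
#' @param target_y validation phenotype vector.
#' @param target_covariates covariates used to adjust `target_y`.
#' @param thresholds ascending p-value grid; default
#'   `c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)`.
#' @return Data frame: `threshold`, `n_snps`, `r`, `ci_lower`,
#'   `ci_upper` (`r` is `NA` when no SNP passes).
#' @export
threshold_profile <- function(clumps, gwas, train_stats, target_geno,
                              target_y, target_covariates = NULL,
                              thresholds = c(5e-8, 1e-6, 1e-4, 1e-3,
                                             0.01, 0.05, 0.1, 0.5, 1)) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending",
                                    call. = FALSE)
  y_adj <- adjust_phenotype(target_y, target_covariates)
  idx <- clumps$id
  st <- train_stats[match(idx, train_stats$id), , drop = FALSE]
  betas <- gwas$beta[match(idx, gwas$id)]
  pvals <- clumps$p
  out <- lapply(thresholds, function(thr) {
    use <- which(pvals <= thr)
    if (!length(use)) {
      return(data.frame(threshold = thr, n_snps = 0L, r = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_))
    }
    eff <- data.frame(id = idx[use], a1 = st$a1[use],
                      effect = betas[use],
                      mean = st$mean[use], sd = st$sd[use],
                      stringsAsFactors = FALSE)
    class(eff) <- c("snp_effects", "data.frame")
    sc <- polygenic_score(target_geno, eff)
    acc <- accuracy(sc, y_adj)
    data.frame(threshold = thr, n_snps = length(use), r = acc$r,
               ci_lower = acc$ci[1], ci_upper = acc$ci[2])
  })
  do.call(rbind, out)
}
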