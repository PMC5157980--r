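#' Polygenic score from a scoring file
#'
#' `score_i = sum_j a_j (s_ij - mean_j) / sd_j`, with the counted
#' allele, mean and SD taken from the *training* population. Variants
#' whose counted allele is swapped in the target are flipped
#' (`s -> 2 - s`); missing target genotypes contribute 0 (mean
#' imputation). The score is the predicted genetic value only — no
#' covariates enter.
#'
#' @param target a [genotype_matrix()] of the samples to score.
#' @param effects an `snp_effects` table (columns `id`, `a1`,
#'   `effect`, `mean`, `sd`).
#' @param max_unmatched tolerated fraction of scoring variants absent
#'   from the target (default 0.05); below it they are skipped with a
#'   warning, above it is an error.
#' @return Named numeric vector of scores, one per target sample.
#' @export
polygenic_score <- function(target, effects, max_unmatched = 0.05) {
  stopifnot(inherits(target, "genotype_matrix"))
  req <- c("id", "a1", "effect", "mean", "sd")
  if (!all(req %in% names(effects))) {
    stop("effects need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ix <- match(effects$id, target$variants$id)
  unmatched <- is.na(ix)
  if (mean(unmatched) > max_unmatched) {
    stop(sprintf("%.1f%% of scoring variants missing from target (limit %.1f%%)",
                 100 * mean(unmatched), 100 * max_unmatched), call. = FALSE)
  }
  if (any(unmatched)) {
    warning(sum(unmatched), " scoring variant(s) absent from target; skipped",
            call. = FALSE)
  }
  eff <- effects[!unmatched, , drop = FALSE]
  ix <- ix[!unmatched]
  if (any(!is.finite(eff$sd) | eff$sd <= 0)) {
    stop("scoring statistics contain sd <= 0", call. = FALSE)
  }
  g <- target$geno[, ix, drop = FALSE]
  same <- target$variants$a1[ix] == eff$a1
  swapped <- !same & target$variants$a2[ix] == eff$a1
  if (any(!same & !swapped)) {
    stop("allele mismatch for scoring variant(s): ",
         paste(head(eff$id[!same & !swapped], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(swapped)) g[, swapped] <- 2L - g[, swapped, drop = FALSE]
  z <- sweep(g, 2L, eff$mean)
  z <- sweep(z, 2L, eff$sd, "/")
  z[is.na(z)] <- 0
  setNames(drop(z %*% eff$effect), target$samples$id)
}

#' Covariate-adjust a phenotype
#'
#' Returns the residuals of an ordinary least-squares regression of
#' the phenotype on intercept + covariates, estimated on the given
#' samples (the evaluation set, when adjusting a validation
#' phenotype).
#'
#' @param y phenotype vector.
#' @param covariates covariate matrix/data frame, or `NULL` for
#'   mean-centering only.
#' @return Residual vector, `NA` where `y` is missing.
#' @export
adjust_phenotype <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  ok <- !is.na(y)
  x <- build_design(if (is.null(covariates)) NULL else
                    as.matrix(covariates)[ok, , drop = FALSE], sum(ok))
  res <- rep(NA_real_, length(y))
  res[ok] <- qr.resid(qr(x), y[ok])
  res
}

#' Prediction accuracy with a Fisher-z confidence interval
#'
#' Pearson correlation between the polygenic scores and the
#' covariate-adjusted phenotypes; the 95% CI is
#' `tanh(atanh(r) +- z * 1/sqrt(n - 3))`.
#'
#' @param scores predicted genetic values.
#' @param y_adj adjusted phenotypes (pairs with any `NA` are dropped).
#' @param level confidence level (default 0.95).
#' @return An object of class `prediction_result`: `r`, `ci`, `n`.
#' @export
accuracy <- function(scores, y_adj, level = 0.95) {
  ok <- !is.na(scores) & !is.na(y_adj)
  s <- scores[ok]; y <- y_adj[ok]
  n <- length(s)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (sd(s) == 0 || sd(y) == 0) {
    stop("cannot correlate a constant vector", call. = FALSE)
  }
  r <- cor(s, y)
  zc <- qnorm(1 - (1 - level) / 2)
  zr <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(zr + c(-1, 1) * zc / sqrt(n - 3))
  structure(list(r = r, ci = ci, n = n, level = level),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%d%% CI %.3f-%.3f), n = %d\n",
              x$r, round(100 * x$level), x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' k-fold cross-validated SNP-BLUP prediction
#'
#' Splits the samples into `k` folds; for each fold the model is
#' trained (REML + SNP-BLUP, standardisation statistics from the
#' training folds only) on the other `k - 1` folds and the held-out
#' fold is scored. Held-out samples play no role in training.
#'
#' @param geno a [genotype_matrix()] (complete phenotypes on these
#'   samples).
#' @param y phenotype vector.
#' @param covariates covariate matrix (e.g. sex, age).
#' @param k number of folds (default 10).
#' @param folds optional integer fold assignment per sample.
#' @return A list: `folds` (data frame `fold`, `n_test`, `r`,
#'   `ci_lower`, `ci_upper`), `mean_r`, `sd_r`, and `fold_assignment`.
#' @export
kfold_cv <- function(geno, y, covariates = NULL, k = 10, folds = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$geno)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (is.null(folds)) {
    folds <- sample(rep_len(seq_len(k), n))
  }
  if (min(table(folds)) < 10L) stop("each fold needs at least 10 samples",
                                    call. = FALSE)
  covariates <- if (!is.null(covariates)) as.matrix(covariates)
  res <- lapply(sort(unique(folds)), function(f) {
    test <- which(folds == f)
    train <- which(folds != f)
    g_train <- subset_genotypes(geno, samples = train)
    sz <- standardize(g_train)
    fit <- reml_fit(y[train], compute_grm(sz$z),
                    x = covariates[train, , drop = FALSE])
    eff <- snp_blup(sz$z, y[train], fit,
                    x = covariates[train, , drop = FALSE], stats = sz$stats)
    g_test <- subset_genotypes(geno, samples = test)
    sc <- polygenic_score(g_test, eff)
    y_adj <- adjust_phenotype(y[test], covariates[test, , drop = FALSE])
    acc <- accuracy(sc, y_adj)
    data.frame(fold = f, n_test = length(test), r = acc$r,
               ci_lower = acc$ci[1], ci_upper = acc$ci[2])
  })
  tab <- do.call(rbind, res)
  list(folds = tab, mean_r = mean(tab$r), sd_r = sd(tab$r),
       fold_assignment = folds)
}

#' Accuracy as a function of training sample size
#'
#' Trains on random subsets of the training samples at each requested
#' size and evaluates every model on one fixed held-out set, yielding
#' the `(n, r)` points that feed the inverse-squared-accuracy
#' extrapolation.
#'
#' @param geno a [genotype_matrix()].
#' @param y phenotype vector.
#' @param covariates covariate matrix.
#' @param sizes training sizes (at least 3 distinct values).
#' @param holdout indices of the fixed evaluation set (default: a
#'   random 20% of the samples).
#' @param n_reps random subsets per size (default 1).
#' @return Data frame: `n`, `rep`, `r`.
#' @export
subsample_series <- function(geno, y, covariates = NULL, sizes,
                             holdout = NULL, n_reps = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$geno)
  if (length(unique(sizes)) < 3L) {
    stop("need at least 3 distinct training sizes", call. = FALSE)
  }
  if (is.null(holdout)) holdout <- sample.int(n, round(0.2 * n))
  pool <- setdiff(seq_len(n), holdout)
  if (max(sizes) > length(pool)) {
    stop("requested training size exceeds available samples", call. = FALSE)
  }
  covariates <- if (!is.null(covariates)) as.matrix(covariates)
  g_hold <- subset_genotypes(geno, samples = holdout)
  y_hold_adj <- adjust_phenotype(y[holdout],
                                 covariates[holdout, , drop = FALSE])
  out <- list()
  for (sz in sizes) {
    for (rep_i in seq_len(n_reps)) {
      train <- sample(pool, sz)
      g_train <- subset_genotypes(geno, samples = train)
      szd <- standardize(g_train)
      fit <- reml_fit(y[train], compute_grm(szd$z),
                      x = covariates[train, , drop = FALSE])
      eff <- snp_blup(szd$z, y[train], fit,
                      x = covariates[train, , drop = FALSE],
                      stats = szd$stats)
      sc <- polygenic_score(g_hold, eff)
      r <- accuracy(sc, y_hold_adj)$r
      out[[length(out) + 1L]] <- data.frame(n = sz, rep = rep_i, r = r)
    }
  }
  do.call(rbind, out)
}
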