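## REML variance-component estimation.
##
## Single genomic component: exact profile likelihood over the variance
## ratio after a one-time eigendecomposition of the GRM (no iterative
## matrix inversions). Several components: average-information REML
## with EM fallback steps whenever the AI update proposes a variance
## below the floor.

#' Eigendecomposition of a GRM, reusable across fits
#' @param k symmetric kinship matrix.
#' @return `eigen()` result (symmetric).
#' @export
grm_eigen <- function(k) {
  es <- eigen(k, symmetric = TRUE)
  if (min(es$values) < -1e-6 * max(abs(es$values), 1)) {
    stop("kinship matrix is not positive semi-definite within tolerance",
         call. = FALSE)
  }
  es$values <- pmax(es$values, 0)
  es
}

## restricted log-likelihood pieces for the single-component path
.reml1_profile <- function(log_lambda, d, yt, xt) {
  lambda <- exp(log_lambda)
  n <- length(yt); p <- ncol(xt)
  w <- 1 / (lambda * d + 1)
  xtw <- xt * w
  xtx <- crossprod(xt, xtw)
  xty <- crossprod(xtw, yt)
  beta <- solve(xtx, xty)
  r <- sum(yt^2 * w) - sum(xty * beta)
  sigma_e <- r / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma_e) + sum(log(lambda * d + 1)) +
                determinant(xtx, logarithm = TRUE)$modulus + (n - p))
  list(ll = as.numeric(ll), sigma_e = sigma_e, lambda = lambda,
       beta = beta, xtx = xtx)
}

reml_fit_single <- function(y, x, k, eig = NULL, tol = 1e-6) {
  n <- length(y)
  if (is.null(eig)) eig <- grm_eigen(k)
  d <- eig$values
  yt <- drop(crossprod(eig$vectors, y))
  xt <- crossprod(eig$vectors, x)
  obj <- function(ll) .reml1_profile(ll, d, yt, xt)$ll
  opt <- optimize(obj, c(-12, 12), maximum = TRUE, tol = 1e-9)
  ## guard against a boundary optimum
  cand <- c(opt$maximum, -12, 12)
  lls <- vapply(cand, obj, 0)
  best <- cand[which.max(lls)]
  at <- .reml1_profile(best, d, yt, xt)
  sigma_e <- at$sigma_e
  sigma_g <- at$lambda * sigma_e
  ## average-information SEs at the optimum, in (sigma_g, sigma_e)
  vt <- sigma_g * d + sigma_e
  pv <- function(v) {
    w <- v / vt
    xtv <- xt / vt
    w - xtv %*% solve(crossprod(xt, xtv), crossprod(xtv, v))
  }
  py <- pv(yt)
  u1 <- d * py      # K P y in the eigenbasis
  u2 <- py          # I P y
  pu1 <- pv(u1); pu2 <- pv(u2)
  ai <- 0.5 * matrix(c(sum(u1 * pu1), sum(u1 * pu2),
                       sum(u1 * pu2), sum(u2 * pu2)), 2, 2)
  cov_theta <- tryCatch(solve(ai), error = function(e) matrix(NA_real_, 2, 2))
  h2 <- sigma_g / (sigma_g + sigma_e)
  grad <- c(sigma_e, -sigma_g) / (sigma_g + sigma_e)^2
  h2_se <- sqrt(max(drop(t(grad) %*% cov_theta %*% grad), 0))
  ## GLS fixed effects at the optimum
  xtv <- xt / vt
  xvx <- crossprod(xt, xtv)
  beta <- drop(solve(xvx, crossprod(xtv, yt)))
  beta_se <- sqrt(diag(solve(xvx)))
  list(sigma_g = sigma_g, sigma_e = sigma_e, h2 = h2, h2_se = h2_se,
       cov_theta = cov_theta, beta = beta, beta_se = beta_se,
       loglik = at$ll, iterations = NA_integer_, converged = TRUE)
}

reml_fit_ai <- function(y, x, k_list, tol = 1e-6, max_iter = 100) {
  n <- length(y)
  m <- length(k_list)
  vy <- var(y)
  floor_v <- 1e-8 * vy

  ## one full evaluation: restricted logL, scores, AI matrix
  eval_state <- function(theta) {
    v <- diag(rep(theta[m + 1], n))
    for (c in seq_len(m)) v <- v + theta[c] * k_list[[c]]
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    vinv <- chol2inv(ch)
    xtv <- vinv %*% x
    xvx <- crossprod(x, xtv)
    pmat <- vinv - xtv %*% solve(xvx, t(xtv))
    py <- pmat %*% y
    ll <- as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                             determinant(xvx, logarithm = TRUE)$modulus +
                             sum(y * py)))
    kpy <- vector("list", m + 1L)
    trs <- numeric(m + 1L)
    for (c in seq_len(m)) {
      kpy[[c]] <- k_list[[c]] %*% py
      trs[c] <- sum(pmat * k_list[[c]])
    }
    kpy[[m + 1L]] <- py
    trs[m + 1L] <- sum(diag(pmat))
    score <- vapply(seq_len(m + 1L), function(c) {
      -0.5 * (trs[c] - sum(py * kpy[[c]]))
    }, 0)
    pu <- lapply(kpy, function(u) pmat %*% u)
    ai <- matrix(0, m + 1L, m + 1L)
    for (r in seq_len(m + 1L)) {
      for (s in r:(m + 1L)) {
        ai[r, s] <- ai[s, r] <- 0.5 * sum(kpy[[r]] * pu[[s]])
      }
    }
    list(ll = ll, score = score, ai = ai, py = py, kpy = kpy, trs = trs,
         vinv = vinv, xvx = xvx)
  }

  theta <- c(rep(0.5 * vy / m, m), 0.5 * vy)
  st <- eval_state(theta)
  if (is.null(st)) stop("initial covariance is singular", call. = FALSE)
  converged <- FALSE
  iter_used <- max_iter
  for (iter in seq_len(max_iter)) {
    ## components at the floor with a negative score stay pinned and
    ## leave the AI system; the residual variance is never pinned
    pinned <- theta <= floor_v * 1.01 & st$score < 0
    pinned[m + 1L] <- FALSE
    free <- which(!pinned)
    delta_full <- rep(0, m + 1L)
    delta <- tryCatch(solve(st$ai[free, free, drop = FALSE], st$score[free]),
                      error = function(e) NULL)
    new_st <- NULL
    if (!is.null(delta)) {
      delta_full[free] <- delta
      ## AI step with negatives clamped to the floor; halve on a
      ## likelihood decrease
      step <- 1
      for (half in 1:6) {
        prop <- pmax(theta + step * delta_full, floor_v)
        prop[pinned] <- floor_v
        cand <- eval_state(prop)
        if (!is.null(cand) && cand$ll >= st$ll - 1e-10) {
          new_st <- cand
          break
        }
        step <- step / 2
      }
    }
    if (is.null(new_st)) {
      ## EM fallback: always moves uphill and stays positive
      prop <- theta
      prop[free] <- pmax(vapply(free, function(c) {
        theta[c] + theta[c]^2 * (sum(st$py * st$kpy[[c]]) - st$trs[c]) / n
      }, 0), floor_v)
      prop[pinned] <- floor_v
      new_st <- eval_state(prop)
      if (is.null(new_st)) break
    }
    done <- abs(new_st$ll - st$ll) < tol
    theta <- prop
    st <- new_st
    if (done) {
      converged <- TRUE
      iter_used <- iter
      break
    }
  }
  ll <- st$ll
  ai <- st$ai
  xvx <- st$xvx
  vinv <- st$vinv
  if (!converged) {
    warning("AI-REML did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  cov_theta <- tryCatch(solve(ai), error = function(e) {
    matrix(NA_real_, m + 1L, m + 1L)
  })
  sigma_g <- theta[seq_len(m)]
  sigma_e <- theta[m + 1L]
  tot <- sum(sigma_g) + sigma_e
  h2 <- sum(sigma_g) / tot
  grad <- c(rep(sigma_e, m), -sum(sigma_g)) / tot^2
  h2_se <- sqrt(max(drop(t(grad) %*% cov_theta %*% grad), 0))
  beta <- drop(solve(xvx, crossprod(x, vinv %*% y)))
  beta_se <- sqrt(diag(solve(xvx)))
  list(sigma_g = sigma_g, sigma_e = sigma_e, h2 = h2, h2_se = h2_se,
       cov_theta = cov_theta, beta = beta, beta_se = beta_se,
       loglik = ll, iterations = iter_used, converged = converged)
}

#' REML fit of one or more genomic variance components
#'
#' Fits `y = X b + sum_c g_c + e` with `g_c ~ N(0, K_c sigma2_g(c))`
#' and `e ~ N(0, I sigma2_e)` by restricted maximum likelihood. With a
#' single kinship matrix the fit is an exact one-dimensional profile
#' likelihood over the variance ratio after one eigendecomposition;
#' with several components it is average-information REML with EM
#' fallback steps and a variance floor. Standard errors come from the
#' inverse average-information matrix; the SNP-heritability is
#' `h2 = sum_c sigma2_g(c) / (sum_c sigma2_g(c) + sigma2_e)` with a
#' delta-method SE.
#'
#' @param y numeric response (no missing values; drop them first).
#' @param kinship one kinship matrix, or a named list of per-component
#'   kinship matrices.
#' @param x fixed-effect design matrix; an intercept column is added if
#'   absent. `NULL` means intercept only.
#' @param m_variants optional named vector: number of variants behind
#'   each component, recorded so per-SNP variances
#'   `sigma2_u = sigma2_g / M` can be reported.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter AI-REML iteration cap.
#' @param eig optional precomputed [grm_eigen()] of the single kinship
#'   matrix (ignored for multi-component fits).
#' @return An object of class `variance_components`: per-component
#'   `sigma2_g` with SEs, `sigma2_e`, `h2` and `h2_se`, fixed effects
#'   with SEs, the REML log-likelihood, and convergence information.
#' @export
reml_fit <- function(y, kinship, x = NULL, m_variants = NULL,
                     tol = 1e-6, max_iter = 100, eig = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete; drop missing phenotypes first",
                     call. = FALSE)
  n <- length(y)
  x <- build_design(x, n)
  single <- is.matrix(kinship) || (is.list(kinship) && length(kinship) == 1L)
  if (is.list(kinship) && length(kinship) == 1L) kinship <- kinship[[1L]]
  if (single) {
    if (!all(dim(kinship) == n)) stop("kinship dimensions must match y",
                                      call. = FALSE)
    fit <- reml_fit_single(y, x, kinship, eig = eig, tol = tol)
    comp_names <- "all"
  } else {
    if (!length(kinship)) stop("no kinship matrices supplied", call. = FALSE)
    for (k in kinship) {
      if (!all(dim(k) == n)) stop("kinship dimensions must match y",
                                  call. = FALSE)
    }
    fit <- reml_fit_ai(y, x, kinship, tol = tol, max_iter = max_iter)
    comp_names <- names(kinship) %||% paste0("comp", seq_along(kinship))
  }
  m <- length(fit$sigma_g)
  se_g <- sqrt(pmax(diag(fit$cov_theta)[seq_len(m)], 0))
  se_e <- sqrt(max(diag(fit$cov_theta)[m + 1L], 0))
  mv <- if (is.null(m_variants)) rep(NA_integer_, m) else {
    as.integer(m_variants[seq_len(m)])
  }
  comp <- data.frame(component = comp_names,
                     sigma2_g = fit$sigma_g, se = se_g,
                     m_variants = mv,
                     sigma2_u = fit$sigma_g / mv,
                     stringsAsFactors = FALSE)
  structure(list(components = comp,
                 sigma2_e = fit$sigma_e, sigma2_e_se = se_e,
                 h2 = fit$h2, h2_se = fit$h2_se,
                 beta = setNames(fit$beta, colnames(x)),
                 beta_se = setNames(fit$beta_se, colnames(x)),
                 loglik = fit$loglik, converged = fit$converged,
                 iterations = fit$iterations,
                 cov_theta = fit$cov_theta, n = n),
            class = "variance_components")
}

build_design <- function(x, n) {
  if (is.null(x)) {
    x <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  } else {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("design matrix rows must match y", call. = FALSE)
    has_int <- any(apply(x, 2L, function(col) all(col == col[1L] & col != 0)))
    if (!has_int) {
      x <- cbind(intercept = 1, x)
    }
    if (qr(x)$rank < ncol(x)) stop("collinear fixed-effect design",
                                   call. = FALSE)
  }
  x
}

#' @export
print.variance_components <- function(x, ...) {
  cat("REML variance components (n =", x$n, ")\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("sigma2_e = %.4f (SE %.4f)\n", x$sigma2_e, x$sigma2_e_se))
  cat(sprintf("h2 = %.4f (SE %.4f); logL = %.3f; converged: %s\n",
              x$h2, x$h2_se, x$loglik, x$converged))
  invisible(x)
}

#' Back-solve SNP-BLUP effects from a fitted model
#'
#' Computes the best linear unbiased predictions of the per-SNP
#' effects, `a_c = sigma2_u(c) Z_c' V^-1 (y - X bhat)` with
#' `V = sum_c sigma2_u(c) Z_c Z_c' + sigma2_e I` — equivalent to the
#' ridge solution with shrinkage `sigma2_e / sigma2_u` per component,
#' and to GBLUP genetic values via `Z a`.
#'
#' @param z standardised genotype matrix, or a named list of matrices
#'   (one per fitted component, in component order).
#' @param y phenotype vector used in the fit.
#' @param fit a `variance_components` object from [reml_fit()].
#' @param x fixed-effect design (same convention as [reml_fit()]).
#' @param stats optional `standardization_stats` (row-bound in
#'   component order) to attach; enables writing a scoring file.
#' @return An `snp_effects` data frame: `id`, `a1`, `effect`, `mean`,
#'   `sd`, `component`.
#' @export
snp_blup <- function(z, y, fit, x = NULL, stats = NULL) {
  stopifnot(inherits(fit, "variance_components"))
  if (is.matrix(z)) z <- list(z)
  m <- nrow(fit$components)
  if (length(z) != m) {
    stop("need one standardised matrix per fitted component", call. = FALSE)
  }
  n <- length(y)
  x <- build_design(x, n)
  sigma_u <- fit$components$sigma2_g / vapply(z, ncol, 0L)
  v <- diag(rep(fit$sigma2_e, n))
  for (c in seq_len(m)) {
    v <- v + sigma_u[c] * tcrossprod(z[[c]])
  }
  w <- solve(v, y - drop(x %*% fit$beta))
  eff <- lapply(seq_len(m), function(c) sigma_u[c] * drop(crossprod(z[[c]], w)))
  comp_names <- fit$components$component
  ids <- unlist(lapply(z, colnames), use.names = FALSE)
  out <- data.frame(id = ids %||% sprintf("v%d", seq_along(unlist(eff))),
                    effect = unlist(eff, use.names = FALSE),
                    component = rep(comp_names, vapply(z, ncol, 0L)),
                    stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    ix <- match(out$id, stats$id)
    if (anyNA(ix)) stop("standardisation stats missing some variants",
                        call. = FALSE)
    out$a1 <- stats$a1[ix]
    out$mean <- stats$mean[ix]
    out$sd <- stats$sd[ix]
    out <- out[, c("id", "a1", "effect", "mean", "sd", "component")]
  }
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Two-group component assignment by GWAS effect size
#'
#' Splits SNPs into a main distribution and an outlier tail: the tail
#' holds SNPs whose fixed-effect GWAS estimate lies more than `n_sd`
#' standard deviations from the mean effect across all SNPs.
#'
#' @param gwas a `gwas_summary` (or any data frame with a `beta`
#'   column) of per-SNP fixed-effect estimates on the
#'   standardised-genotype scale.
#' @param n_sd the outlier cut (default 3).
#' @return Character vector (`"main"` / `"tail"`) per SNP.
#' @export
effect_outlier_groups <- function(gwas, n_sd = 3) {
  beta <- gwas$beta %||% stop("need a 'beta' column", call. = FALSE)
  mu <- mean(beta); s <- sd(beta)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in GWAS effects; all SNPs assigned to 'main'",
            call. = FALSE)
    return(rep("main", length(beta)))
  }
  ifelse(abs(beta - mu) > n_sd * s, "tail", "main")
}

#' MAF-stratified component assignment
#'
#' Three groups with the strict boundaries: common (`MAF > 0.05`),
#' low-frequency (`0.01 < MAF < 0.05`), and rare
#' (`0.001 < MAF < 0.01`). Variants exactly on a boundary or at
#' `MAF <= 0.001` are left unassigned (`NA`) and reported via a
#' warning.
#'
#' @param mafs vector of minor allele frequencies in `[0, 0.5]`.
#' @return Character vector (`"common"`, `"lowfreq"`, `"rare"`, or
#'   `NA`) per variant.
#' @export
maf_groups <- function(mafs) {
  if (any(mafs < 0 | mafs > 0.5, na.rm = TRUE)) {
    stop("MAFs must lie in [0, 0.5]", call. = FALSE)
  }
  grp <- rep(NA_character_, length(mafs))
  grp[mafs > 0.05] <- "common"
  grp[mafs > 0.01 & mafs < 0.05] <- "lowfreq"
  grp[mafs > 0.001 & mafs < 0.01] <- "rare"
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " variant(s) unassigned (MAF on a strict ",
            "boundary or <= 0.001)", call. = FALSE)
  }
  grp
}
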