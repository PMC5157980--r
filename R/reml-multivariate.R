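## Multivariate REML: T traits, one genomic component.
##
## After the one-time eigendecomposition K = U D U', the rotated
## observations decouple across eigenvectors: the i-th rotated T-vector
## has covariance V_i = d_i * Sigma_g + Sigma_e. The restricted
## likelihood is maximised directly over Cholesky factors of Sigma_g
## and Sigma_e (log-scale diagonals), which enforces positive
## semi-definiteness by construction; fixed effects are profiled out
## by GLS at every evaluation.

## parameter vector <-> (Sigma_g, Sigma_e)
.mv_unpack <- function(par, tt) {
  np <- tt * (tt + 1) / 2
  mk <- function(p) {
    l <- matrix(0, tt, tt)
    l[lower.tri(l, diag = TRUE)] <- p
    diag(l) <- exp(diag(l))
    tcrossprod(l)
  }
  list(sg = mk(par[seq_len(np)]), se = mk(par[np + seq_len(np)]))
}

.mv_pack <- function(sg, se) {
  pk <- function(m) {
    l <- t(chol(m + diag(1e-8, nrow(m))))
    diag(l) <- log(diag(l))
    l[lower.tri(l, diag = TRUE)]
  }
  c(pk(sg), pk(se))
}

## vectorised inverses and log-determinants of V_i = d_i Sg + Se
.mv_vinv <- function(d, sg, se) {
  n <- length(d); tt <- nrow(sg)
  if (tt == 2L) {
    v11 <- d * sg[1, 1] + se[1, 1]
    v12 <- d * sg[1, 2] + se[1, 2]
    v22 <- d * sg[2, 2] + se[2, 2]
    det <- v11 * v22 - v12^2
    if (any(det <= 0)) return(NULL)
    w <- array(0, c(n, 2L, 2L))
    w[, 1, 1] <- v22 / det
    w[, 2, 2] <- v11 / det
    w[, 1, 2] <- w[, 2, 1] <- -v12 / det
    list(w = w, logdet = sum(log(det)))
  } else {
    w <- array(0, c(n, tt, tt))
    logdet <- 0
    for (i in seq_len(n)) {
      vi <- d[i] * sg + se
      ch <- tryCatch(chol(vi), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      w[i, , ] <- chol2inv(ch)
      logdet <- logdet + 2 * sum(log(diag(ch)))
    }
    list(w = w, logdet = logdet)
  }
}

## negative restricted log-likelihood in the rotated basis
.mv_negll <- function(par, d, yt, xt, tt) {
  vp <- .mv_unpack(par, tt)
  vi <- .mv_vinv(d, vp$sg, vp$se)
  if (is.null(vi)) return(1e10)
  w <- vi$w
  n <- nrow(yt); p <- ncol(xt)
  ## GLS: A vec(B) = rhs with A[(t1,j1),(t2,j2)] = sum_i x_ij1 x_ij2 W_i[t1,t2]
  a <- matrix(0, tt * p, tt * p)
  rhs <- numeric(tt * p)
  for (t1 in seq_len(tt)) {
    for (t2 in seq_len(tt)) {
      wts <- w[, t1, t2]
      blk <- crossprod(xt * wts, xt)
      a[(t1 - 1) * p + seq_len(p), (t2 - 1) * p + seq_len(p)] <- blk
      rhs[(t1 - 1) * p + seq_len(p)] <- rhs[(t1 - 1) * p + seq_len(p)] +
        drop(crossprod(xt, wts * yt[, t2]))
    }
  }
  b <- tryCatch(solve(a, rhs), error = function(e) NULL)
  if (is.null(b)) return(1e10)
  bm <- matrix(b, p, tt)        # column t = coefficients for trait t
  r <- yt - xt %*% bm
  quad <- 0
  for (t1 in seq_len(tt)) {
    for (t2 in seq_len(tt)) {
      quad <- quad + sum(w[, t1, t2] * r[, t1] * r[, t2])
    }
  }
  lda <- determinant(a, logarithm = TRUE)$modulus
  0.5 * (vi$logdet + as.numeric(lda) + quad)
}

#' Multivariate REML: genetic and environmental covariances across traits
#'
#' Fits `y_t = X b_t + g_t + e_t` jointly for `T >= 2` traits with
#' per-SNP effect vectors sharing a `T x T` genetic covariance
#' (`cov(g) = Sigma_g (x) K`) and residuals sharing `Sigma_e (x) I`.
#' Samples missing any trait are dropped listwise. Genetic correlations
#' are `r_g = Sigma_g[t1,t2] / sqrt(Sigma_g[t1,t1] Sigma_g[t2,t2])`;
#' their SEs come from the numerical Hessian at the optimum via the
#' delta method.
#'
#' @param y_mat numeric matrix, samples x traits (T >= 2).
#' @param kinship the GRM.
#' @param x fixed-effect design shared across traits (see
#'   [reml_fit()]); intercept added if absent.
#' @param tol convergence tolerance passed to the optimiser.
#' @param eig optional precomputed [grm_eigen()] of `kinship`.
#' @return An object of class `variance_components_mv`: `sigma_g`,
#'   `sigma_e` (T x T), `r_g` and `r_e` correlation matrices,
#'   `r_g_se`, per-trait `h2`, `beta`, `loglik`, `converged`.
#' @export
reml_fit_multivariate <- function(y_mat, kinship, x = NULL, tol = 1e-8,
                                  eig = NULL) {
  y_mat <- as.matrix(y_mat)
  tt <- ncol(y_mat)
  if (tt < 2L) stop("use reml_fit() for a single trait", call. = FALSE)
  keep <- complete.cases(y_mat)
  if (!all(keep)) {
    y_mat <- y_mat[keep, , drop = FALSE]
    kinship <- kinship[keep, keep]
    if (!is.null(x)) x <- as.matrix(x)[keep, , drop = FALSE]
    eig <- NULL
  }
  n <- nrow(y_mat)
  x <- build_design(x, n)
  if (is.null(eig)) eig <- grm_eigen(kinship)
  d <- eig$values
  yt <- crossprod(eig$vectors, y_mat)
  xt <- crossprod(eig$vectors, x)
  ## moment start values: half the phenotypic covariance each
  cy <- cov(y_mat)
  par0 <- .mv_pack(cy / 2, cy / 2)
  opt <- optim(par0, .mv_negll, d = d, yt = yt, xt = xt, tt = tt,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = tol))
  opt <- optim(opt$par, .mv_negll, d = d, yt = yt, xt = xt, tt = tt,
               method = "BFGS",
               control = list(maxit = 200, reltol = tol))
  vp <- .mv_unpack(opt$par, tt)
  sg <- vp$sg; se <- vp$se
  trait_names <- colnames(y_mat) %||% paste0("trait", seq_len(tt))
  dimnames(sg) <- dimnames(se) <- list(trait_names, trait_names)
  rg <- cov2cor(sg)
  re <- cov2cor(se)
  h2 <- diag(sg) / (diag(sg) + diag(se))
  ## delta-method SEs for every genetic correlation
  hess <- tryCatch(optimHess(opt$par, .mv_negll, d = d, yt = yt, xt = xt,
                             tt = tt),
                   error = function(e) NULL)
  rg_se <- matrix(NA_real_, tt, tt, dimnames = dimnames(sg))
  if (!is.null(hess)) {
    cov_par <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_par)) {
      for (t1 in seq_len(tt - 1L)) {
        for (t2 in (t1 + 1L):tt) {
          fn <- function(p) {
            s <- .mv_unpack(p, tt)$sg
            s[t1, t2] / sqrt(s[t1, t1] * s[t2, t2])
          }
          gr <- numeric(length(opt$par))
          h <- 1e-5
          for (j in seq_along(gr)) {
            pp <- opt$par; pp[j] <- pp[j] + h
            pm <- opt$par; pm[j] <- pm[j] - h
            gr[j] <- (fn(pp) - fn(pm)) / (2 * h)
          }
          v <- drop(t(gr) %*% cov_par %*% gr)
          rg_se[t1, t2] <- rg_se[t2, t1] <- sqrt(max(v, 0))
        }
      }
    }
  }
  structure(list(sigma_g = sg, sigma_e = se, r_g = rg, r_e = re,
                 r_g_se = rg_se, h2 = setNames(h2, trait_names),
                 loglik = -opt$value, converged = opt$convergence == 0,
                 n = n, traits = trait_names),
            class = "variance_components_mv")
}

#' @export
print.variance_components_mv <- function(x, ...) {
  cat("Multivariate REML (n =", x$n, ", traits:",
      paste(x$traits, collapse = ", "), ")\n")
  cat("genetic correlations:\n")
  print(round(x$r_g, 3))
  cat("h2:", paste(sprintf("%.3f", x$h2), collapse = ", "), "\n")
  invisible(x)
}

#' Per-trait SNP effects from a multivariate fit
#'
#' Back-solves the multivariate BLUP: with `w_t` the rows of
#' `V^-1 (y - X B)` per trait (computed in the eigenbasis of K), the
#' effect of SNP j on trait t is
#' `a_jt = sum_s (Sigma_g[t,s]/M) z_j' w_s`.
#'
#' @param z standardised genotype matrix used to build the GRM.
#' @param y_mat trait matrix as passed to [reml_fit_multivariate()]
#'   (complete cases only).
#' @param fit the `variance_components_mv` object.
#' @param x fixed-effect design used in the fit.
#' @param eig optional precomputed [grm_eigen()] of the GRM.
#' @return Matrix of effects, variants x traits.
#' @export
snp_blup_multivariate <- function(z, y_mat, fit, x = NULL, eig = NULL) {
  stopifnot(inherits(fit, "variance_components_mv"))
  y_mat <- as.matrix(y_mat)
  tt <- ncol(y_mat)
  n <- nrow(y_mat)
  x <- build_design(x, n)
  m <- ncol(z)
  if (is.null(eig)) eig <- grm_eigen(compute_grm(z))
  d <- eig$values
  yt <- crossprod(eig$vectors, y_mat)
  xt <- crossprod(eig$vectors, x)
  vi <- .mv_vinv(d, fit$sigma_g, fit$sigma_e)
  if (is.null(vi)) stop("singular covariance in multivariate BLUP",
                        call. = FALSE)
  w <- vi$w
  ## GLS fixed effects under the fitted covariances
  p <- ncol(xt)
  a <- matrix(0, tt * p, tt * p); rhs <- numeric(tt * p)
  for (t1 in seq_len(tt)) {
    for (t2 in seq_len(tt)) {
      wts <- w[, t1, t2]
      a[(t1 - 1) * p + seq_len(p), (t2 - 1) * p + seq_len(p)] <-
        crossprod(xt * wts, xt)
      rhs[(t1 - 1) * p + seq_len(p)] <- rhs[(t1 - 1) * p + seq_len(p)] +
        drop(crossprod(xt, wts * yt[, t2]))
    }
  }
  bm <- matrix(solve(a, rhs), p, tt)
  r <- yt - xt %*% bm
  wt <- matrix(0, n, tt)     # rotated V^-1 residuals per trait
  for (t1 in seq_len(tt)) {
    for (t2 in seq_len(tt)) {
      wt[, t1] <- wt[, t1] + w[, t1, t2] * r[, t2]
    }
  }
  wback <- eig$vectors %*% wt
  (crossprod(z, wback) %*% fit$sigma_g) / m
}
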