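# internal numerical helpers

## log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## multivariate normal draws via Cholesky; sigma must be symmetric PSD
rmvn <- function(n, sigma) {
  d <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) {
    ## PSD within tolerance: project up the tiny negative eigenvalues
    es <- eigen(sigma, symmetric = TRUE)
    if (min(es$values) < -1e-8 * max(abs(es$values), 1)) {
      stop("covariance matrix is not positive semi-definite", call. = FALSE)
    }
    vals <- pmax(es$values, 0)
    chol(es$vectors %*% (vals * t(es$vectors)) + diag(1e-10, d))
  })
  matrix(rnorm(n * d), n, d) %*% ch
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

stopifnot_scalar01 <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must be a single value in [0,%s)", name,
                 if (open_upper) "1" else "1]"), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
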