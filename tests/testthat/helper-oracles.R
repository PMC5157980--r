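# independent oracles used by several test files

## brute-force REML oracle: nested grid search over (sigma2_g, sigma2_e)
grid_reml <- function(y, k, x = NULL, rounds = 6, width = c(0.01, 2)) {
  n <- length(y)
  if (is.null(x)) x <- matrix(1, n, 1)
  ll <- function(sg, se) {
    v <- sg * k + diag(se, n)
    vi <- solve(v)
    xvx <- t(x) %*% vi %*% x
    p <- vi - vi %*% x %*% solve(xvx, t(x) %*% vi)
    -0.5 * as.numeric(determinant(v)$modulus + determinant(xvx)$modulus +
                      drop(y %*% p %*% y))
  }
  lo <- c(width[1], width[1]); hi <- c(width[2], width[2])
  for (r in seq_len(rounds)) {
    sgs <- seq(lo[1], hi[1], length.out = 21)
    ses <- seq(lo[2], hi[2], length.out = 21)
    vals <- outer(sgs, ses, Vectorize(ll))
    ix <- arrayInd(which.max(vals), dim(vals))
    sg <- sgs[ix[1]]; se <- ses[ix[2]]
    span_g <- (hi[1] - lo[1]) / 10; span_e <- (hi[2] - lo[2]) / 10
    lo <- pmax(c(sg - span_g, se - span_e), 1e-6)
    hi <- c(sg + span_g, se + span_e)
  }
  c(sigma_g = sg, sigma_e = se)
}

## direct enumeration of the conditional HWE distribution using plain
## choose()/factorial() arithmetic (no log-space tricks)
hwe_oracle <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  n_minor <- 2 * n_hom_minor + n_het
  if (n_minor > n) n_minor <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  w <- vapply(hets, function(h) {
    hom1 <- (n_minor - h) / 2
    hom2 <- n - hom1 - h
    2^h / (factorial(hom1) * factorial(h) * factorial(hom2))
  }, 0)
  obs <- w[match(n_het, hets)]
  sum(w[w <= obs * (1 + 1e-12)]) / sum(w)
}
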