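#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed minor-allele count, every
#' compatible heterozygote count is enumerated and the p-value is the
#' total probability of configurations no more probable than the
#' observed one. All arithmetic is in log space, so the far tail
#' (p near 1e-50 and below) is computed without underflow.
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts (nonnegative
#'   integers, total > 0).
#' @return A list: `p` (p-value, exact 1 for monomorphic sites),
#'   `log10_p`, and `n_configs` (number of enumerated configurations).
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  counts <- c(n_hom_minor, n_het, n_hom_major)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  n_minor <- 2 * n_hom_minor + n_het
  if (n_minor > n) {  # orient so the enumerated allele is the minor one
    n_minor <- 2 * n - n_minor
  }
  ## heterozygote counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  hom1 <- (n_minor - hets) / 2
  hom2 <- n - hom1 - hets
  ## log multinomial weight: n! 2^h / (hom1! h! hom2!)
  lw <- hets * log(2) - lgamma(hom1 + 1) - lgamma(hets + 1) - lgamma(hom2 + 1)
  lz <- logsumexp(lw)
  lobs <- lw[match(n_het, hets)]
  if (is.na(lobs)) stop("inconsistent genotype counts", call. = FALSE)
  keep <- lw <= lobs + 1e-10
  lp <- logsumexp(lw[keep]) - lz
  lp <- min(lp, 0)
  list(p = exp(lp), log10_p = lp / log(10), n_configs = length(hets))
}

#' Two-sided Fisher exact test for platform-differential missingness
#'
#' Tests the 2x2 table of (missing, called) by platform. The two-sided
#' p-value sums hypergeometric point masses no larger than the observed
#' one; the summation is done in log space so that p-values far below
#' the 1e-100 exclusion threshold remain finite on the log scale.
#'
#' @param missing_a,called_a,missing_b,called_b cell counts.
#' @return A list: `p` (underflows to 0 below ~1e-308; use `log10_p`
#'   there) and `log10_p`.
#' @export
platform_missingness_test <- function(missing_a, called_a,
                                      missing_b, called_b) {
  cells <- c(missing_a, called_a, missing_b, called_b)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  m1 <- missing_a + called_a      # platform A total
  m2 <- missing_b + called_b      # platform B total
  k <- missing_a + missing_b      # missing margin
  lo <- max(0, k - m2)
  hi <- min(k, m1)
  supp <- lo:hi
  lpm <- dhyper(supp, m1, m2, k, log = TRUE)
  lobs <- lpm[match(missing_a, supp)]
  keep <- lpm <= lobs + 1e-7
  lp <- min(logsumexp(lpm[keep]), 0)
  list(p = exp(lp), log10_p = lp / log(10))
}
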