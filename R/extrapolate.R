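#' Fit the accuracy-vs-sample-size law
#'
#' Ordinary least squares of `1/r^2` on `1/n` across `(n, r)` points.
#' Under the standard expectation `r^2 = h2 / (1 + Me/(n h2))` this
#' relationship is exactly linear with intercept `1/h2` and slope
#' `Me/h2^2`, so the intercept bounds the achievable accuracy: the
#' maximum accuracy is `1/sqrt(b0)` (delta-method SE reported).
#'
#' @param points data frame with columns `n` and `r` (all `r > 0`,
#'   at least 3 distinct `n`).
#' @return An object of class `accuracy_curve_fit`: `b0`, `b1`, their
#'   SEs, `max_accuracy` (+ SE; `NA` and flagged when `b0 <= 0`), and
#'   the input points.
#' @export
fit_inverse_r2 <- function(points) {
  if (!all(c("n", "r") %in% names(points))) {
    stop("points need columns 'n' and 'r'", call. = FALSE)
  }
  if (any(points$r <= 0)) stop("all accuracies must be positive",
                               call. = FALSE)
  if (any(points$n <= 0)) stop("all sample sizes must be positive",
                               call. = FALSE)
  if (length(unique(points$n)) < 3L) {
    stop("need at least 3 distinct sample sizes", call. = FALSE)
  }
  x <- 1 / points$n
  y <- 1 / points$r^2
  fit <- lm(y ~ x)
  b <- coef(fit)
  ## noise-free inputs give a zero residual; vcov would warn
  vc <- suppressWarnings(vcov(fit))
  se <- sqrt(diag(vc))
  b0 <- unname(b[1]); b1 <- unname(b[2])
  if (b0 > 0) {
    max_acc <- 1 / sqrt(b0)
    max_acc_se <- 0.5 * b0^(-1.5) * se[1]   # |d(1/sqrt(b0))/db0| * SE(b0)
    valid <- TRUE
  } else {
    max_acc <- NA_real_
    max_acc_se <- NA_real_
    valid <- FALSE
  }
  structure(list(b0 = b0, b1 = b1, b0_se = unname(se[1]),
                 b1_se = unname(se[2]), max_accuracy = max_acc,
                 max_accuracy_se = max_acc_se, valid_max = valid,
                 vcov = vc, points = points),
            class = "accuracy_curve_fit")
}

#' @export
print.accuracy_curve_fit <- function(x, ...) {
  cat(sprintf("1/r^2 = %.4f + %.1f / n  (SEs %.4f, %.1f)\n",
              x$b0, x$b1, x$b0_se, x$b1_se))
  if (x$valid_max) {
    cat(sprintf("maximum accuracy 1/sqrt(b0) = %.4f (SE %.4f)\n",
                x$max_accuracy, x$max_accuracy_se))
  } else {
    cat("intercept <= 0: maximum accuracy undefined\n")
  }
  invisible(x)
}

#' Project accuracy to a target training size
#'
#' `r(n) = 1/sqrt(b0 + b1/n)`, with a delta-method SE from the OLS
#' coefficient covariance.
#'
#' @param fit an [fit_inverse_r2()] result with positive intercept.
#' @param n_target training sample size to project to.
#' @return A list: `r`, `se`, `n_target`.
#' @export
project_accuracy <- function(fit, n_target) {
  stopifnot(inherits(fit, "accuracy_curve_fit"))
  if (n_target <= 0) stop("n_target must be positive", call. = FALSE)
  if (!fit$valid_max) stop("fit has nonpositive intercept; cannot project",
                           call. = FALSE)
  q <- fit$b0 + fit$b1 / n_target
  if (q <= 0) stop("projected 1/r^2 is nonpositive at this n", call. = FALSE)
  r <- 1 / sqrt(q)
  grad <- -0.5 * q^(-1.5) * c(1, 1 / n_target)
  se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  list(r = r, se = se, n_target = n_target)
}

#' Fraction of the maximum achievable accuracy
#'
#' The ceiling on accuracy given the SNP-heritability is `sqrt(h2)`;
#' the fraction attained is `100 * r / sqrt(h2)` percent, rounded to
#' the nearest integer in reports.
#'
#' @param r observed (or projected) prediction accuracy.
#' @param h2 SNP-heritability of the trait.
#' @param slack tolerated excess of `r` over `sqrt(h2)` before warning
#'   (default 0.05, roughly a CI half-width).
#' @return A list: `percent` (rounded), `raw` (unrounded).
#' @export
fraction_of_maximum <- function(r, h2, slack = 0.05) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]", call. = FALSE)
  if (r < 0 || r > 1) stop("r must be in [0, 1]", call. = FALSE)
  ceiling_r <- sqrt(h2)
  if (r > ceiling_r + slack) {
    warning("accuracy exceeds its theoretical ceiling sqrt(h2)",
            call. = FALSE)
  }
  raw <- 100 * r / ceiling_r
  list(percent = round(raw), raw = raw)
}

#' Expected squared accuracy at a given training size
#'
#' The closed-form expectation `r^2 = h2 / (1 + Me / (n h2))` for a
#' trait of SNP-heritability `h2` predicted from `Me` effective loci
#' with `n` training samples; used as the theory oracle for the
#' simulation tests and the subsampling fits.
#'
#' @param h2 SNP-heritability in (0, 1].
#' @param n training sample size.
#' @param me effective number of loci.
#' @return Expected `r^2`.
#' @export
daetwyler_r2 <- function(h2, n, me) {
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must be in (0, 1]", call. = FALSE)
  if (any(n <= 0) || any(me <= 0)) stop("n and me must be positive",
                                        call. = FALSE)
  h2 / (1 + me / (n * h2))
}
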