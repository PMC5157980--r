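#' Standardise genotypes
#'
#' Converts counted-allele counts to `z = (s - mean) / sd` per variant,
#' using the *population* SD (divisor `n`), so that columns have mean
#' exactly zero when statistics come from the same data. Missing calls
#' become `z = 0` (mean imputation). When `stats` is supplied (scoring
#' a validation set with training-population statistics), variants are
#' matched by id and counted allele; a variant whose alleles are
#' swapped relative to training is flipped (`s -> 2 - s`) when
#' `allow_flip` is `TRUE`, otherwise it is an error.
#'
#' @param geno a [genotype_matrix()].
#' @param stats optional `standardization_stats` (data frame `id`,
#'   `a1`, `a2`, `mean`, `sd`) from a training population.
#' @param allow_flip flip swapped alleles instead of failing.
#' @return A list: `z` (numeric matrix, samples x variants) and
#'   `stats` (`standardization_stats` of the variants actually used).
#' @export
standardize <- function(geno, stats = NULL, allow_flip = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  g <- geno$geno
  v <- geno$variants
  if (is.null(stats)) {
    mu <- colMeans(g, na.rm = TRUE)
    s2 <- colMeans(g^2, na.rm = TRUE) - mu^2
    sg <- sqrt(pmax(s2, 0))
    mono <- which(!is.finite(sg) | sg <= 0)
    if (length(mono)) {
      stop("monomorphic variant(s) cannot be standardised: ",
           paste(head(v$id[mono], 5), collapse = ", "),
           if (length(mono) > 5) " ..." else "", call. = FALSE)
    }
    stats <- data.frame(id = v$id, a1 = v$a1, a2 = v$a2,
                        mean = unname(mu), sd = unname(sg),
                        stringsAsFactors = FALSE)
    class(stats) <- c("standardization_stats", "data.frame")
  } else {
    ix <- match(stats$id, v$id)
    if (anyNA(ix)) {
      stop("training variants missing from target: ",
           paste(head(stats$id[is.na(ix)], 5), collapse = ", "),
           call. = FALSE)
    }
    same <- v$a1[ix] == stats$a1
    swapped <- v$a1[ix] == stats$a2 & v$a2[ix] == stats$a1
    bad <- !(same | swapped)
    if (any(bad)) {
      stop("allele mismatch between training and target for: ",
           paste(head(stats$id[bad], 5), collapse = ", "), call. = FALSE)
    }
    if (any(swapped) && !allow_flip) {
      stop("counted allele swapped relative to training for: ",
           paste(head(stats$id[swapped], 5), collapse = ", "),
           call. = FALSE)
    }
    g <- g[, ix, drop = FALSE]
    if (any(swapped)) {
      g[, swapped] <- 2L - g[, swapped, drop = FALSE]
    }
    if (any(!is.finite(stats$sd) | stats$sd <= 0)) {
      stop("training statistics contain sd <= 0", call. = FALSE)
    }
  }
  z <- sweep(g, 2L, stats$mean)
  z <- sweep(z, 2L, stats$sd, "/")
  z[is.na(z)] <- 0          # mean imputation of missing calls
  list(z = z, stats = stats)
}

#' Genomic relationship matrix
#'
#' `K = Z Z' / M` over the standardised genotypes: the average
#' standardised-genotype product between each pair of samples. The
#' expectation is ~1 on the diagonal for outbred samples, ~0.5 for
#' full sibs and ~0 for unrelated pairs.
#'
#' @param z standardised genotype matrix (from [standardize()]).
#' @return Symmetric `n x n` matrix with sample ids as dimnames.
#' @export
compute_grm <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) == 0L) stop("no variants to compute a GRM from", call. = FALSE)
  k <- tcrossprod(z) / ncol(z)
  (k + t(k)) / 2
}

#' Principal components of the standardised genotypes
#'
#' Projections are the `sqrt(n)`-scaled left singular vectors of `Z`
#' (equivalently, eigenvectors of the GRM), with a deterministic sign
#' convention: the entry of largest magnitude in each component is
#' positive. Typically run on an LD-pruned variant set.
#'
#' @param z standardised (pruned) genotype matrix.
#' @param k number of leading components.
#' @return An object of class `pca_result`: `projections`
#'   (`n x k`), `values` (leading eigenvalues of the GRM,
#'   nonincreasing).
#' @export
pca_grm <- function(z, k = 20) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (k > min(n - 1L, ncol(z))) {
    stop("k exceeds the available number of components", call. = FALSE)
  }
  grm <- compute_grm(z)
  es <- eigen(grm, symmetric = TRUE)
  vals <- pmax(es$values[seq_len(k)], 0)
  proj <- es$vectors[, seq_len(k), drop = FALSE] * sqrt(n)
  for (j in seq_len(k)) {
    i <- which.max(abs(proj[, j]))
    if (proj[i, j] < 0) proj[, j] <- -proj[, j]
  }
  rownames(proj) <- rownames(z)
  structure(list(projections = proj, values = vals), class = "pca_result")
}

#' Greedy sliding-window LD pruning
#'
#' Within each window, while any variant pair exceeds `r2_max` in
#' genotype correlation, the member of the worst offending pair with
#' the lower MAF is dropped (ties: the later position). Windows slide
#' by `step` variants; chromosomes are processed independently. The
#' procedure is deterministic.
#'
#' @param geno a [genotype_matrix()].
#' @param window_snps window size in variants (default 50).
#' @param step slide in variants (default 5).
#' @param r2_max maximum tolerated squared correlation (default 0.2).
#' @return Integer indices of retained variants.
#' @export
ld_prune <- function(geno, window_snps = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0,1]",
                                      call. = FALSE)
  g <- geno$geno
  maf <- variant_maf(geno)
  keep <- rep(TRUE, ncol(g))
  for (cc in unique(geno$variants$chrom)) {
    cols <- which(geno$variants$chrom == cc)
    ord <- cols[order(geno$variants$pos[cols])]
    start <- 1L
    while (start <= length(ord)) {
      win <- ord[start:min(start + window_snps - 1L, length(ord))]
      win <- win[keep[win]]
      if (length(win) > 1L) {
        gw <- g[, win, drop = FALSE]
        gw[is.na(gw)] <- rep(colMeans(gw, na.rm = TRUE),
                             each = nrow(gw))[is.na(gw)]
        cm <- suppressWarnings(cor(gw))
        cm[!is.finite(cm)] <- 0
        diag(cm) <- 0
        repeat {
          r2 <- cm^2
          mx <- max(r2)
          if (mx <= r2_max) break
          w <- which(r2 == mx, arr.ind = TRUE)[1L, ]
          a <- win[w[1L]]; b <- win[w[2L]]
          drop_v <- if (maf[a] < maf[b]) a
                    else if (maf[b] < maf[a]) b
                    else if (geno$variants$pos[a] > geno$variants$pos[b]) a
                    else b
          keep[drop_v] <- FALSE
          di <- match(drop_v, win)
          cm[di, ] <- 0; cm[, di] <- 0
        }
      }
      start <- start + step
    }
  }
  which(keep)
}
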