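#' Genotype matrix container
#'
#' Holds biallelic allele counts together with variant and sample
#' metadata. Counts are copies of the *counted* allele (`a1`), so a value
#' of 2 means two copies of `a1`; missing genotypes are `NA`.
#'
#' @param geno integer matrix, samples in rows, variants in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `chrom`, `pos` (1-based),
#'   `id`, `a1` (counted allele), `a2`.
#' @param samples data frame with at least a column `id`; typically also
#'   `sex` (1 = male, 2 = female), `platform`, `population`, `family`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(variants) != ncol(geno)) {
    stop("variants table and genotype columns disagree", call. = FALSE)
  }
  if (nrow(samples) != nrow(geno)) {
    stop("samples table and genotype rows disagree", call. = FALSE)
  }
  req_v <- c("chrom", "pos", "id", "a1", "a2")
  if (!all(req_v %in% names(variants))) {
    stop("variants table needs columns: ", paste(req_v, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(samples)) stop("samples table needs an 'id' column",
                                      call. = FALSE)
  if (anyDuplicated(variants$id)) stop("duplicate variant ids", call. = FALSE)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids", call. = FALSE)
  if (any(variants$a1 == variants$a2)) {
    stop("counted and other allele must differ", call. = FALSE)
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("allele counts must be 0, 1, 2 or NA", call. = FALSE)
  }
  rownames(geno) <- samples$id
  colnames(geno) <- variants$id
  structure(list(geno = geno,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$geno), ncol(x$geno)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = " ")))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples,variants indices (integer, logical or character ids)
#'   selecting rows / columns; `NULL` keeps all.
#' @return A `genotype_matrix` with the selected rows and columns.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$geno)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$geno)) else variants
  if (is.character(si)) si <- match(si, x$samples$id)
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  genotype_matrix(x$geno[si, vi, drop = FALSE],
                  x$variants[vi, , drop = FALSE],
                  x$samples[si, , drop = FALSE])
}

#' Per-variant minor allele frequency
#'
#' Computed from non-missing counted-allele frequencies; the MAF is the
#' smaller of the counted-allele frequency and its complement.
#'
#' @param x a [genotype_matrix()].
#' @return Numeric vector of MAFs, one per variant.
#' @export
variant_maf <- function(x) {
  p <- colMeans(x$geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-variant and per-sample missingness rates
#' @param x a [genotype_matrix()].
#' @return `variant_missingness()` and `sample_missingness()` return the
#'   fraction of missing calls per variant / per sample.
#' @export
variant_missingness <- function(x) colMeans(is.na(x$geno))

#' @rdname variant_missingness
#' @export
sample_missingness <- function(x) rowMeans(is.na(x$geno))
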