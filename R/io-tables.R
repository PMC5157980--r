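#' Read and write phenotype/covariate tables
#'
#' Tab-separated with a header; first column must be `id`, remaining
#' columns are covariates (`sex`, `age`) and trait values. Missing
#' phenotypes are the literal string `NA`.
#'
#' @param path file path.
#' @param required columns that must be present beyond `id`.
#' @return `read_phenotypes()` returns a data frame with one row per
#'   sample; `write_phenotypes()` returns `path` invisibly.
#' @export
read_phenotypes <- function(path, required = character(0)) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
  if (!"id" %in% names(tab)) {
    stop("phenotype file must have an 'id' column: ", path, call. = FALSE)
  }
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("phenotype file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$id)) stop("duplicate sample ids in ", path,
                                  call. = FALSE)
  tab$id <- as.character(tab$id)
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes data frame with an `id` column.
#' @export
write_phenotypes <- function(phenotypes, path) {
  if (!"id" %in% names(phenotypes)) stop("need an 'id' column", call. = FALSE)
  write.table(phenotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write SNP-effect scoring files
#'
#' Tab-separated scoring files carry, per variant: `id`, the counted
#' allele `a1`, the standardised-scale effect `effect`, and the
#' training-population standardisation statistics `mean` and `sd` of
#' the counted-allele count. Rows with `sd <= 0` (monomorphic in
#' training) are rejected on read. Unknown extra columns are kept with
#' a warning.
#'
#' @param path file path.
#' @return `read_effects()` returns an object of class `snp_effects`
#'   (a data frame); `write_effects()` returns `path` invisibly.
#' @export
read_effects <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("id", "a1", "effect", "mean", "sd")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("scoring file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), c(req, "component", "trait"))
  if (length(extra)) {
    warning("ignoring unknown scoring-file column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$sd) | tab$sd <= 0)) {
    stop("scoring file contains rows with sd <= 0 (monomorphic variants)",
         call. = FALSE)
  }
  class(tab) <- c("snp_effects", "data.frame")
  tab
}

#' @rdname read_effects
#' @param effects an `snp_effects` data frame (columns `id`, `a1`,
#'   `effect`, `mean`, `sd`, optionally `component`).
#' @export
write_effects <- function(effects, path) {
  req <- c("id", "a1", "effect", "mean", "sd")
  miss <- setdiff(req, names(effects))
  if (length(miss)) {
    stop("effects are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  write.table(as.data.frame(effects), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
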