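## PLINK 1 binary genotype files (.bed/.bim/.fam), SNP-major layout.
## Each variant packs 4 samples per byte, two bits per call, low bits
## first: 00 = two copies of allele1, 10 = one copy, 11 = zero copies,
## 01 = missing. The counted allele of genotype_matrix maps to allele1.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

## decode table: code -> count (NA for 01)
.bed_count <- c(2L, NA_integer_, 1L, 0L)

#' Read a PLINK binary fileset
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must
#'   exist. The bim's allele 1 becomes the counted allele.
#' @return A [genotype_matrix()]; fam columns map to sample `id`
#'   (IID), `sex`, and `family` (FID, `NA` when 0).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("fid", "id", "pat", "mat", "sex", "phen"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_variant <- (n + 3L) %/% 4L
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || !identical(raw[1:2], BED_MAGIC)) {
    stop("not a PLINK bed file (bad magic bytes): ", bed_path, call. = FALSE)
  }
  if (raw[3L] != BED_SNP_MAJOR) {
    stop("sample-major bed files are unsupported", call. = FALSE)
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_variant * m) {
    stop(sprintf("truncated bed payload: expected %d bytes, found %d",
                 bytes_per_variant * m, length(payload)), call. = FALSE)
  }
  ## unpack all 2-bit codes at once
  lo <- as.integer(payload) %% 4L
  b2 <- (as.integer(payload) %/% 4L) %% 4L
  b3 <- (as.integer(payload) %/% 16L) %% 4L
  hi <- as.integer(payload) %/% 64L
  codes <- matrix(rbind(lo, b2, b3, hi), nrow = 4L * bytes_per_variant)
  counts <- .bed_count[codes[seq_len(n), , drop = FALSE] + 1L]
  geno <- matrix(counts, n, m)
  variants <- data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                         a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE)
  samples <- data.frame(id = fam$id, sex = fam$sex,
                        family = ifelse(fam$fid %in% c("0", 0), NA, fam$fid),
                        stringsAsFactors = FALSE)
  genotype_matrix(geno, variants, samples)
}

#' Write a PLINK binary fileset
#'
#' @param geno a [genotype_matrix()]; must be non-empty.
#' @param prefix output path prefix for `.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$geno); m <- ncol(geno$geno)
  if (n == 0L || m == 0L) stop("cannot write an empty genotype matrix",
                               call. = FALSE)
  v <- geno$variants
  bim <- data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- geno$samples
  fam_col <- s$family %||% rep(NA_character_, n)
  fam <- data.frame(fid = ifelse(is.na(fam_col), "0", fam_col),
                    iid = s$id, pat = "0", mat = "0",
                    sex = s$sex %||% rep(0L, n), phen = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bytes_per_variant <- (n + 3L) %/% 4L
  g <- geno$geno
  codes <- matrix(0L, 4L * bytes_per_variant, m)
  gi <- g
  gi[is.na(gi)] <- -1L
  ## lookup over {-1, 0, 1, 2} -> {01 missing, 11, 10, 00}
  code <- c(1L, 3L, 2L, 0L)[gi + 2L]
  codes[seq_len(n), ] <- code
  ## pack 4 codes per byte, low bits first; padding bits stay zero
  packed <- codes[seq(1L, nrow(codes), 4L), , drop = FALSE] +
    4L * codes[seq(2L, nrow(codes), 4L), , drop = FALSE] +
    16L * codes[seq(3L, nrow(codes), 4L), , drop = FALSE] +
    64L * codes[seq(4L, nrow(codes), 4L), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR), con)
  writeBin(as.raw(packed), con)
  invisible(prefix)
}
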