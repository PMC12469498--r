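#' Construct a bit-encoded case-control genotype dataset
#'
#' Builds the packed-bit representation used by all scoring routines: for
#' each locus and each genotype code (0/1/2 copies of the minor allele),
#' one bit-vector per phenotype class marks which samples carry that
#' genotype.  Contingency tables over SNP combinations then reduce to
#' word-wise AND plus popcount.
#'
#' @param geno integer matrix, samples x SNPs, entries in \{0, 1, 2\}.
#' @param pheno integer vector of length `nrow(geno)`, 0 = control,
#'   1 = case.
#' @param snp_names character vector of locus identifiers; defaults to
#'   `colnames(geno)` or `SNP1..SNPN`.
#' @return An object of class `genotype_dataset` with fields `n_snps`,
#'   `n_controls`, `n_cases`, `snp_names`, `control_masks`, `case_masks`
#'   and the precomputed log-factorial table used by [k2_score()].
#' @export
genotype_dataset <- function(geno, pheno, snp_names = NULL) {
  geno <- as.matrix(geno)
  if (!is.numeric(geno)) stop("genotype matrix must be numeric")
  storage.mode(geno) <- "integer"
  pheno <- as.integer(pheno)
  if (length(pheno) != nrow(geno))
    stop("phenotype length (", length(pheno), ") != number of samples (",
         nrow(geno), ")")
  if (anyNA(geno) || anyNA(pheno))
    stop("missing genotype or phenotype values are not supported")
  if (!all(pheno %in% c(0L, 1L)))
    stop("phenotype class must be 0 (control) or 1 (case)")
  bad <- which(!(geno %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(geno)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(geno)) + 1L
    stop("invalid genotype code ", geno[bad[1]], " at sample row ", i,
         ", SNP column ", j, " (must be 0, 1 or 2)")
  }
  if (ncol(geno) < 2L) stop("need at least 2 SNPs")
  n_controls <- sum(pheno == 0L)
  n_cases <- sum(pheno == 1L)
  if (n_controls == 0L || n_cases == 0L)
    stop("each phenotype class needs at least one sample (controls = ",
         n_controls, ", cases = ", n_cases, ")")
  if (is.null(snp_names)) snp_names <- colnames(geno)
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(geno)))
  if (length(snp_names) != ncol(geno))
    stop("snp_names length != number of SNPs")

  m <- n_controls + n_cases
  structure(
    list(
      n_snps = ncol(geno),
      n_controls = n_controls,
      n_cases = n_cases,
      snp_names = as.character(snp_names),
      control_masks = pack_genotype_masks(geno[pheno == 0L, , drop = FALSE]),
      case_masks = pack_genotype_masks(geno[pheno == 1L, , drop = FALSE]),
      # lnfact[i] = ln((i-1)!), up to ln((m+1)!), for the K2 score
      lnfact = lgamma(seq_len(m + 2L))
    ),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Case-control genotype dataset (bit-encoded)\n")
  cat("  SNPs:     ", x$n_snps, "\n", sep = "")
  cat("  controls: ", x$n_controls, "\n", sep = "")
  cat("  cases:    ", x$n_cases, "\n", sep = "")
  invisible(x)
}

#' Read a case-control genotype table
#'
#' Canonical plain-text layout: one header row of SNP identifiers plus a
#' final class column, one row per sample, genotype codes 0/1/2 and class
#' 0 (control) / 1 (case).  Samples keep file order within each class.
#'
#' @param path file path.
#' @param sep field separator: `"auto"` sniffs tab vs comma from the
#'   header line, or give `"\t"` / `","` explicitly.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, sep = "auto") {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (identical(sep, "auto")) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "integer")
  if (ncol(df) < 3L)
    stop("expected at least 2 SNP columns plus a class column in ", path)
  cls <- df[[ncol(df)]]
  geno <- as.matrix(df[, -ncol(df), drop = FALSE])
  if (anyNA(geno)) {
    idx <- which(is.na(geno), arr.ind = TRUE)[1L, ]
    stop("missing or unparseable genotype at row ", idx[1L], ", column ",
         colnames(geno)[idx[2L]], " of ", path,
         " (missing data are rejected, not imputed)")
  }
  genotype_dataset(geno, cls, snp_names = colnames(geno))
}

#' Recover the genotype matrix and phenotype from a dataset
#'
#' Inverts the bit packing; used by the writer and to verify lossless
#' round-tripping.
#'
#' @param ds a [genotype_dataset()].
#' @return list with `geno` (samples x SNPs integer matrix, controls first)
#'   and `pheno` (0/1 vector).
#' @export
as_genotype_matrix <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  unpack <- function(masks, n_samples) {
    w <- nrow(masks) %/% 3L
    out <- matrix(0L, n_samples, ncol(masks))
    for (g in 1:2) {                       # genotype 0 is the default
      rows <- (g * w + 1L):((g + 1L) * w)
      for (loc in seq_len(ncol(masks))) {
        bits <- unpack_bits(masks[rows, loc], n_samples)
        out[bits, loc] <- g
      }
    }
    out
  }
  geno <- rbind(unpack(ds$control_masks, ds$n_controls),
                unpack(ds$case_masks, ds$n_cases))
  colnames(geno) <- ds$snp_names
  list(geno = geno,
       pheno = rep(c(0L, 1L), c(ds$n_controls, ds$n_cases)))
}

# positions of set bits in a packed 32-bit word vector (little-endian
# within each word, matching the C++ packing)
unpack_bits <- function(words, n_bits) {
  bits <- as.logical(intToBits(words))
  which(bits[seq_len(n_bits)])
}

#' Write a genotype dataset in the canonical table layout
#'
#' @param x a [genotype_dataset()] or a list with `geno` and `pheno`.
#' @param path output file path.
#' @param sep `"\t"` (default) or `","`.
#' @export
write_genotypes <- function(x, path, sep = "\t") {
  if (inherits(x, "genotype_dataset")) x <- as_genotype_matrix(x)
  df <- as.data.frame(x$geno)
  df$Class <- as.integer(x$pheno)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
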