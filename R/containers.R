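#' Genotype matrix container
#'
#' Samples-by-SNPs minor-allele dosage matrix (0/1/2, NA for missing) with
#' SNP metadata.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns; row
#'   names are sample ids, column names SNP ids.
#' @param snps Data frame with at least `snp`, `chrom`, `pos` (1-based).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  stopifnot(is.matrix(dosage), is.data.frame(snps))
  req <- c("snp", "chrom", "pos")
  miss <- setdiff(req, names(snps))
  if (length(miss)) stopf("snps table missing column(s): %s", paste(miss, collapse = ", "))
  if (ncol(dosage) != nrow(snps)) stopf("dosage columns (%d) != snp rows (%d)", ncol(dosage), nrow(snps))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) stopf("dosages must be 0, 1, 2 or NA")
  colnames(dosage) <- snps$snp
  rownames(snps) <- NULL
  structure(list(dosage = dosage, snps = snps,
                 samples = rownames(dosage) %||% paste0("S", seq_len(nrow(dosage)))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Expression matrix container
#'
#' Probes-by-samples expression values on the log2 scale together with a
#' processing-stage tag.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param stage One of `"raw"`, `"normalized"`, `"adjusted"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, stage = c("raw", "normalized", "adjusted")) {
  stopifnot(is.matrix(values))
  stage <- match.arg(stage)
  if (is.null(rownames(values))) stopf("expression matrix requires probe row names")
  if (anyDuplicated(rownames(values))) stopf("duplicated probe id: %s",
                                             rownames(values)[duplicated(rownames(values))][1])
  if (is.null(colnames(values))) colnames(values) <- paste0("S", seq_len(ncol(values)))
  structure(list(values = values, probes = rownames(values),
                 samples = colnames(values), stage = stage),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d probes x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

## Check genotype / expression sample alignment; returns common order.
align_samples <- function(geno, expr) {
  common <- intersect(rownames(geno$dosage), colnames(expr$values))
  if (length(common) == 0) {
    stopf("genotype and expression matrices share no sample names")
  }
  common
}
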