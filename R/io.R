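#' Read genotypes from VCF or dosage TSV
#'
#' Dosages are re-oriented to count the *minor* allele per sample,
#' recomputed from the observed allele frequencies (not taken from the
#' VCF ALT column). Ties at frequency 0.5 orient to the alphabetically
#' first allele. Multiallelic VCF records are skipped with a warning;
#' `./.` genotypes become NA.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`. The TSV layout is SNPs in rows with
#'   columns `snp`, `chrom`, `pos` followed by one column per sample.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    req <- c("snp", "chrom", "pos")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stopf("dosage TSV missing column(s): %s", paste(miss, collapse = ", "))
    d <- t(as.matrix(tab[, setdiff(names(tab), req), drop = FALSE]))
    colnames(d) <- tab$snp
    return(orient_minor(genotype_matrix(d, tab[, req])))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warnf("skipping %d multiallelic record(s)", sum(multi))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  count_alt <- function(x) {
    ifelse(grepl("\\.", x) | is.na(x), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  d <- t(apply(gt, 1, count_alt))
  colnames(d) <- colnames(gt)
  snps <- data.frame(snp = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                     stringsAsFactors = FALSE)
  orient_minor(genotype_matrix(t(d), snps), ref = snps$ref, alt = snps$alt)
}

## Flip dosages so each SNP counts its minor allele; frequency-0.5 ties
## orient to the alphabetically first allele when allele labels are known.
orient_minor <- function(geno, ref = NULL, alt = NULL) {
  d <- geno$dosage
  af <- colMeans(d, na.rm = TRUE) / 2     # counted-allele frequency
  flip <- !is.na(af) & af > 0.5
  if (!is.null(ref) && !is.null(alt)) {
    tie <- !is.na(af) & abs(af - 0.5) < 1e-12
    flip[tie] <- alt[tie] > ref[tie]      # count the alphabetically first
  }
  d[, flip] <- 2 - d[, flip]
  genotype_matrix(d, geno$snps)
}

#' Write genotypes as VCF and dosage TSV
#'
#' The VCF encodes dosages as GT calls on synthetic REF/ALT alleles (ALT
#' is the counted minor allele); missing dosage becomes `./.`.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  d <- geno$dosage
  gt <- matrix("./.", nrow = ncol(d), ncol = nrow(d))
  gt[t(d) == 0] <- "0/0"
  gt[t(d) == 1] <- "0/1"
  gt[t(d) == 2] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  body <- cbind(geno$snps$chrom, geno$snps$pos, geno$snps$snp, "A", "G", ".",
                "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(geno, path) {
  tab <- cbind(geno$snps[, c("snp", "chrom", "pos")],
               as.data.frame(t(geno$dosage)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix as TSV (probes x samples)
#'
#' The TSV has a `probe` column followed by one column per sample.
#' Duplicated probe ids are rejected: duplicate spots must be collapsed
#' by [collapse_duplicates()] before this point.
#'
#' @param path File path.
#' @param stage Stage tag for the returned matrix.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, stage = "normalized") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"probe" %in% names(tab)) stopf("expression TSV missing column: probe")
  if (anyDuplicated(tab$probe)) {
    stopf("duplicated probe id in expression TSV: %s",
          tab$probe[duplicated(tab$probe)][1])
  }
  m <- as.matrix(tab[, setdiff(names(tab), "probe"), drop = FALSE])
  rownames(m) <- tab$probe
  expression_matrix(m, stage = stage)
}

#' @rdname read_expression
#' @param expr An `expression_matrix`.
#' @export
write_expression <- function(expr, path) {
  tab <- cbind(data.frame(probe = expr$probes, stringsAsFactors = FALSE),
               as.data.frame(expr$values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe/gene annotation table
#'
#' @param path TSV with mandatory columns `probe`, `gene_id`, `symbol`,
#'   `rna_class`, `chrom`, `start`, `end`, `strand`.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe", "gene_id", "symbol", "rna_class", "chrom", "start",
           "end", "strand")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("annotation missing column(s): %s", paste(miss, collapse = ", "))
  tab
}

#' Read / write FASTA sequences
#'
#' Sequences are uppercased on read.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(toupper(seqs), names(seqs))), path)
  invisible(path)
}

#' Read a GWAS catalog TSV
#'
#' @param path TSV with columns `record`, `snp`, `trait`,
#'   `reported_genes` (semicolon-separated), `p`.
#' @return Data frame.
#' @export
read_gwas_catalog <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("record", "snp", "trait", "reported_genes", "p")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("GWAS catalog missing column(s): %s", paste(miss, collapse = ", "))
  tab
}

#' Write / read an eQTL result table (round-trip safe)
#'
#' @param eqtls Data frame of eQTL records.
#' @param path File path.
#' @return `write_eqtls` returns `path` invisibly; `read_eqtls` the table.
#' @export
write_eqtls <- function(eqtls, path) {
  write.table(eqtls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtls
#' @export
read_eqtls <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Convert between 1-based inclusive intervals and BED (0-based half-open)
#'
#' @param df Data frame with `start`, `end`.
#' @return Data frame with converted coordinates; the two conversions are
#'   inverse bijections.
#' @export
to_bed <- function(df) {
  df$start <- df$start - 1L
  df
}

#' @rdname to_bed
#' @export
from_bed <- function(df) {
  df$start <- df$start + 1L
  df
}
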