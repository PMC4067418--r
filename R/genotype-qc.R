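#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the observed
#' allele counts. The P value is the total probability of heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote labels are interchangeable; the test is symmetric).
#' @return Exact P value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal heterozygote count -> P = 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stopf("all genotype counts are zero")
  n_minor <- 2L * min(n_AA, n_aa) + n_Aa
  ## feasible heterozygote counts share the parity of the minor allele count
  h_all <- seq.int(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  logp <- vapply(h_all, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(h + 1) -
      lgamma(hom_minor + 1) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[h_all == n_Aa]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

#' Per-SNP summary statistics
#'
#' Computes minor allele frequency (after missing exclusion), exact
#' Hardy-Weinberg P, and missing rate for every SNP of a genotype matrix.
#'
#' @param geno A `genotype_matrix` (see [simulate_genotypes()] or
#'   [read_genotypes()]).
#' @return Data frame with columns `snp`, `chrom`, `pos`, `maf`, `hwe_p`,
#'   `missing_rate`.
#' @export
snp_stats <- function(geno) {
  d <- geno$dosage
  n <- nrow(d)
  miss <- colSums(is.na(d)) / n
  stats <- t(vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(c(NA_real_, NA_real_))
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    tab <- tabulate(g + 1L, nbins = 3L)
    c(maf, hwe_exact_test(tab[1], tab[2], tab[3]))
  }, numeric(2)))
  data.frame(
    snp = geno$snps$snp, chrom = geno$snps$chrom, pos = geno$snps$pos,
    maf = stats[, 1], hwe_p = stats[, 2], missing_rate = miss,
    stringsAsFactors = FALSE
  )
}

#' SNP quality-control filter
#'
#' Retains autosomal SNPs with missing rate not above `missing_max`, exact
#' Hardy-Weinberg P not below `hwe_min`, and minor allele frequency not
#' below `maf_min` (a SNP at exactly the MAF boundary is kept: the
#' exclusion rule is "MAF < threshold").
#'
#' @param geno A `genotype_matrix`.
#' @param config An [eqtl_config()].
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return The filtered `genotype_matrix`, with a `qc_report` attribute: a
#'   data frame of per-SNP statistics and per-criterion pass flags.
#' @export
qc_filter <- function(geno, config = eqtl_config(),
                      sex_chroms = c("chrX", "chrY", "X", "Y")) {
  st <- snp_stats(geno)
  st$pass_missing <- st$missing_rate <= config$missing_max
  st$pass_hwe <- !is.na(st$hwe_p) & st$hwe_p >= config$hwe_min
  st$pass_maf <- !is.na(st$maf) & st$maf >= config$maf_min
  st$pass_autosomal <- !(st$chrom %in% sex_chroms)
  st$pass <- st$pass_missing & st$pass_hwe & st$pass_maf & st$pass_autosomal
  if (!any(st$pass)) {
    stopf("no SNP passed quality control; review thresholds (maf_min=%g, missing_max=%g, hwe_min=%g)",
          config$maf_min, config$missing_max, config$hwe_min)
  }
  keep <- which(st$pass)
  out <- genotype_matrix(geno$dosage[, keep, drop = FALSE],
                         geno$snps[keep, , drop = FALSE])
  message(sprintf(
    "qc_filter: %d/%d SNPs retained (excluded: %d missingness, %d HWE, %d MAF, %d sex-chromosome)",
    length(keep), nrow(st), sum(!st$pass_missing), sum(!st$pass_hwe),
    sum(!st$pass_maf), sum(!st$pass_autosomal)))
  attr(out, "qc_report") <- st
  out
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete samples (composite,
#' phase-free r2 on 0/1/2 dosages). Invariant under allele-label flips.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors (0/1/2, NA allowed).
#' @return List with `r2` (NA if either vector is constant), `n` complete
#'   pairs.
#' @examples
#' ld_r2(c(0, 1, 2, 0), c(0, 1, 0, 0))$r2  # 0.25
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (length(a) < 2) stopf("fewer than 2 pairwise-complete samples")
  if (var(a) == 0 || var(b) == 0) {
    return(list(r2 = NA_real_, n = length(a)))
  }
  list(r2 = cor(a, b)^2, n = length(a))
}
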