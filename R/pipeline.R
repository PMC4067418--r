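#' Run the full eQTL discovery pipeline on a study
#'
#' Composes the stages end to end: genotype QC, surrogate-variable
#' estimation and covariate adjustment, the local scan with
#' permutation-FDR cis calling, the distant scan with the Bonferroni
#' threshold and trans exclusion cascade, and (when a catalog is present)
#' GWAS record classification. Input is a study list as produced by
#' [simulate_eqtl_study()] or assembled from the readers in this package.
#'
#' @param study List with `genotypes`, `expression` (normalized),
#'   `covariates`, `annotation` (list with `probe_annotation`,
#'   `probe_seqs`, `flank_seqs`, `exon_seqs`), optional `gwas`.
#' @param config An [eqtl_config()].
#' @param n_sv Fixed surrogate-variable count (NULL = permutation rule).
#' @param n_distant_tests Override for the Bonferroni family size.
#' @return List with `qc_genotypes`, `svs`, `adjusted`, `cis`, `trans`,
#'   `eqtls` (combined retained calls with `type`), `gwas`
#'   (classification, or NULL), `config`.
#' @export
run_eqtl_pipeline <- function(study, config = eqtl_config(), n_sv = NULL,
                              n_distant_tests = NULL) {
  geno <- qc_filter(study$genotypes, config)
  svs <- estimate_surrogate_variables(study$expression, study$covariates,
                                      n_perm = config$sv_n_perm,
                                      alpha = config$sv_alpha,
                                      n_sv = n_sv, seed = config$seed)
  adj <- adjust_expression(study$expression, study$covariates, svs)
  ann <- study$annotation$probe_annotation
  cis <- map_cis(geno, adj, ann, config)
  scan_d <- scan_associations(geno, adj, ann, "distant", config)
  trans <- map_trans(scan_d, geno, adj, ann, cis,
                     probe_seqs = study$annotation$probe_seqs,
                     flank_seqs = study$annotation$flank_seqs,
                     probe_medians = attr(adj, "pre_adjust_median"),
                     config = config, n_distant_tests = n_distant_tests)
  eqtls <- combine_calls(cis, trans)
  gwas <- NULL
  if (!is.null(study$gwas) && nrow(eqtls) > 0) {
    gwas <- classify_gwas(study$gwas$catalog, eqtls, geno, adj,
                          aliases = study$gwas$aliases, config = config)
  }
  list(qc_genotypes = geno, svs = svs, adjusted = adj, cis = cis,
       trans = trans, eqtls = eqtls, gwas = gwas, config = config)
}

## Retained cis + trans calls in one table with a `type` column.
combine_calls <- function(cis, trans) {
  cols <- c("snp", "probe", "gene_id", "symbol", "rna_class", "beta",
            "r2", "p")
  keep_cis <- cis[cis$kw_pass, cols, drop = FALSE]
  if (nrow(keep_cis)) keep_cis$type <- "cis"
  keep_trans <- if (nrow(trans)) trans[trans$retained, cols, drop = FALSE] else
    trans[, intersect(cols, names(trans)), drop = FALSE]
  if (nrow(keep_trans)) keep_trans$type <- "trans"
  out <- rbind(
    if (nrow(keep_cis)) keep_cis else NULL,
    if (nrow(keep_trans)) keep_trans else NULL)
  if (is.null(out)) {
    out <- data.frame(snp = character(), probe = character(),
                      gene_id = character(), symbol = character(),
                      rna_class = character(), beta = numeric(),
                      r2 = numeric(), p = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
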