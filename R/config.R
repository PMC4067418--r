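#' Pipeline configuration
#'
#' Bundles every tunable threshold of the eQTL pipeline with the defaults
#' used throughout: MAF/missingness/HWE genotype QC cutoffs, the 500 kb
#' local window, permutation FDR settings for cis calling, the family-wise
#' alpha and filter-cascade alphas for trans calling, the Smith-Waterman
#' cross-hybridization scoring scheme, and GWAS matching parameters.
#'
#' @param maf_min Minimum minor allele frequency; SNPs with MAF strictly
#'   below this are excluded (boundary kept).
#' @param missing_max Maximum per-SNP missing genotype rate; strictly above
#'   is excluded.
#' @param hwe_min Minimum Hardy-Weinberg exact-test P; strictly below is
#'   excluded.
#' @param cis_window Local window in bp around a gene's nearest
#'   transcription start/end site; distance exactly equal counts as local.
#' @param cis_fdr FDR threshold for cis-eQTL calling.
#' @param n_perm_cis Number of sample-label permutations for the null
#'   minimum-P distribution.
#' @param trans_fwer Family-wise error rate for the Bonferroni trans
#'   threshold.
#' @param conditional_alpha Alpha for the conditional-regression filters
#'   (cis-capture, sequential prune, joint model, GWAS colocalization).
#' @param kw_alpha Kruskal-Wallis confirmation threshold; records with
#'   P above this are excluded.
#' @param ld_match_r2 LD r2 above which a GWAS SNP is matched to an eQTL.
#' @param sw_match,sw_mismatch,sw_gap_open,sw_gap_extend Smith-Waterman
#'   scoring parameters (a gap of length L costs `gap_open + L * gap_extend`).
#' @param sw_min_frac Minimum alignment score as a fraction of the maximum
#'   attainable (`match * probe length`) for a probe to count as mapped.
#' @param sw_seed_len Exact-match seed length required by the
#'   cross-hybridization screen before the score threshold applies. With a
#'   zero mismatch score an unseeded alignment accumulates matches through
#'   mismatches and any long random target reaches the score threshold;
#'   the seed requirement restores the discriminating behaviour of the
#'   seeded aligners this screen emulates.
#' @param low_expr_percentile Percentile of cis-regulated transcripts'
#'   median expression defining the low-expression cutoff.
#' @param low_expr_fallback Absolute cutoff used when no cis-regulated
#'   transcripts are available.
#' @param multi_reg_min_genes Minimum number of distinct coding genes for a
#'   multi-regulatory eQTL.
#' @param jt_permutations Permutations for the Jonckheere-Terpstra test.
#' @param sv_n_perm,sv_alpha Permutation rounds and alpha for surrogate
#'   variable significance.
#' @param seed Integer seed controlling all randomized stages.
#' @return An object of class `eqtl_config` (a named list).
#' @export
eqtl_config <- function(maf_min = 0.05,
                        missing_max = 0.01,
                        hwe_min = 1e-7,
                        cis_window = 500000L,
                        cis_fdr = 0.05,
                        n_perm_cis = 10L,
                        trans_fwer = 0.05,
                        conditional_alpha = 0.05,
                        kw_alpha = 0.00015,
                        ld_match_r2 = 0.8,
                        sw_match = 10,
                        sw_mismatch = 0,
                        sw_gap_open = -250,
                        sw_gap_extend = -100,
                        sw_min_frac = 0.30,
                        sw_seed_len = 15L,
                        low_expr_percentile = 5,
                        low_expr_fallback = -4.5,
                        multi_reg_min_genes = 3L,
                        jt_permutations = 100000L,
                        sv_n_perm = 20L,
                        sv_alpha = 0.05,
                        seed = 1L) {
  cfg <- list(
    maf_min = maf_min, missing_max = missing_max, hwe_min = hwe_min,
    cis_window = as.integer(cis_window), cis_fdr = cis_fdr,
    n_perm_cis = as.integer(n_perm_cis), trans_fwer = trans_fwer,
    conditional_alpha = conditional_alpha, kw_alpha = kw_alpha,
    ld_match_r2 = ld_match_r2, sw_match = sw_match,
    sw_mismatch = sw_mismatch, sw_gap_open = sw_gap_open,
    sw_gap_extend = sw_gap_extend, sw_min_frac = sw_min_frac,
    sw_seed_len = as.integer(sw_seed_len),
    low_expr_percentile = low_expr_percentile,
    low_expr_fallback = low_expr_fallback,
    multi_reg_min_genes = as.integer(multi_reg_min_genes),
    jt_permutations = as.integer(jt_permutations),
    sv_n_perm = as.integer(sv_n_perm), sv_alpha = sv_alpha,
    seed = as.integer(seed)
  )
  probs <- c("maf_min", "missing_max", "hwe_min", "cis_fdr", "trans_fwer",
             "conditional_alpha", "kw_alpha", "ld_match_r2", "sw_min_frac")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stopf("config '%s' must lie in (0, 1), got %s", p, format(cfg[[p]]))
    }
  }
  if (cfg$cis_window <= 0) stopf("cis_window must be positive")
  if (cfg$n_perm_cis < 1L) stopf("n_perm_cis must be at least 1")
  if (cfg$jt_permutations < 1L) stopf("jt_permutations must be at least 1")
  structure(cfg, class = "eqtl_config")
}

#' @export
print.eqtl_config <- function(x, ...) {
  cat("eQTL pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config` returns an `eqtl_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(eqtl_config, vals)
}

#' @rdname read_config
#' @param config An `eqtl_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
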