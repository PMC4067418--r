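#' Bonferroni per-test significance threshold for distant pairs
#'
#' The family of tests is every distant SNP-transcript pair:
#' `n_probes * n_snps - n_local_pairs`. The per-test alpha is the
#' family-wise alpha divided by that count.
#'
#' @param n_probes,n_snps Post-QC transcript and SNP counts.
#' @param n_local_pairs Number of local pairs excluded from the family.
#' @param family_alpha Family-wise error rate.
#' @return Per-test alpha.
#' @examples
#' bonferroni_threshold(30395, 1425832, 16986695)  # ~1.15e-12
#' @export
bonferroni_threshold <- function(n_probes, n_snps, n_local_pairs = 0,
                                 family_alpha = 0.05) {
  stopifnot(n_probes > 0, n_snps > 0, n_local_pairs >= 0)
  n_distant <- n_probes * n_snps - n_local_pairs
  if (n_distant <= 0) stopf("no distant tests: %g local pairs of %g total",
                            n_local_pairs, n_probes * n_snps)
  family_alpha / n_distant
}

#' Cis-capture filter for a trans-eQTL candidate
#'
#' A candidate on the same chromosome as its target transcript may merely
#' tag a cis effect through LD. When a cis-eQTL exists for the transcript
#' (including cis candidates that failed the Kruskal-Wallis confirmation),
#' the expression is regressed on the cis-eQTL dosage and the candidate
#' passes only if the residuals remain associated with its dosage at
#' `P < alpha`. Candidates on a different chromosome than the transcript,
#' or for transcripts without a cis-eQTL, pass by default.
#'
#' @param candidate_dosage Candidate trans SNP dosage vector.
#' @param cis_dosage Cis-eQTL dosage vector, or NULL when no cis-eQTL
#'   exists for the transcript.
#' @param expression Adjusted expression vector of the target transcript.
#' @param same_chrom Is the candidate on the transcript's chromosome?
#' @param alpha Significance level.
#' @return List with `pass` and `p` (residual-association P; NA when the
#'   filter does not apply).
#' @export
cis_capture_filter <- function(candidate_dosage, cis_dosage, expression,
                               same_chrom, alpha = 0.05) {
  if (!same_chrom || is.null(cis_dosage)) {
    return(list(pass = TRUE, p = NA_real_))
  }
  res <- residual_on(expression, cis_dosage)
  f <- fit_additive(candidate_dosage, res)
  list(pass = !is.na(f$p) && f$p < alpha, p = f$p)
}

## OLS residuals of y on one (or more) dosage columns, pairwise complete
## rows imputed to the column mean so the residual length matches y.
residual_on <- function(y, x) {
  X <- cbind(1, x)
  X[is.na(X)] <- mean(x, na.rm = TRUE)
  as.vector(y - X %*% qr.coef(qr(X), y))
}

#' Sequential conditional pruning of same-chromosome trans candidates
#'
#' Candidates for one transcript on one chromosome are visited in order
#' of ascending marginal P. Each is tested against the current residual
#' expression: if significant at `alpha` it is kept and the residuals are
#' updated by regressing out its dosage; otherwise it is dropped and the
#' residuals stand.
#'
#' @param candidates Data frame with `snp` and `p` (marginal), rows for
#'   one transcript-chromosome group.
#' @param dosages Samples-by-SNPs dosage matrix covering the candidates.
#' @param expression Adjusted expression vector of the transcript.
#' @param alpha Significance level.
#' @return `candidates` with added columns `conditional_p` and `kept`.
#' @export
sequential_conditional_prune <- function(candidates, dosages, expression,
                                         alpha = 0.05) {
  ord <- order(candidates$p)
  res <- expression
  cond_p <- rep(NA_real_, nrow(candidates))
  kept <- logical(nrow(candidates))
  for (i in ord) {
    g <- dosages[, candidates$snp[i]]
    f <- fit_additive(g, res)
    cond_p[i] <- f$p
    if (!is.na(f$p) && f$p < alpha) {
      kept[i] <- TRUE
      res <- residual_on(res, g)
    }
  }
  candidates$conditional_p <- cond_p
  candidates$kept <- kept
  candidates
}

#' Joint multiple-regression check of retained trans candidates
#'
#' Fits the transcript's expression on all retained candidate dosages
#' together and drops terms with `P > alpha` in a single pass (no
#' re-iteration). Collinear terms that the fit cannot estimate are
#' dropped with a message.
#'
#' @param candidates Data frame with `snp` (the retained set).
#' @param dosages Samples-by-SNPs dosage matrix.
#' @param expression Adjusted expression vector.
#' @param alpha Significance level.
#' @return `candidates` with added columns `joint_p` and `joint_kept`.
#' @export
joint_model_check <- function(candidates, dosages, expression, alpha = 0.05) {
  if (nrow(candidates) == 0) {
    candidates$joint_p <- numeric(0)
    candidates$joint_kept <- logical(0)
    return(candidates)
  }
  df <- as.data.frame(dosages[, candidates$snp, drop = FALSE])
  names(df) <- make.names(candidates$snp, unique = TRUE)
  df$.y <- expression
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  cf <- coef(fit)[-1]
  est <- !is.na(cf)
  if (any(!est)) {
    message("joint_model_check: dropping collinear term(s): ",
            paste(candidates$snp[!est], collapse = ", "))
  }
  joint_p <- rep(NA_real_, nrow(candidates))
  joint_p[est] <- sm[match(names(df)[seq_len(nrow(candidates))][est],
                           rownames(sm)), "Pr(>|t|)"]
  candidates$joint_p <- joint_p
  candidates$joint_kept <- est & !is.na(joint_p) & joint_p <= alpha
  candidates
}

#' Low-expression filter for trans-regulated transcripts
#'
#' The cutoff is the configured percentile (default 5th, linear
#' interpolation) of the cis-regulated transcripts' median normalized
#' expression; candidate transcripts with a median below the cutoff fail.
#' Without any cis-regulated transcript the configured absolute fallback
#' cutoff applies.
#'
#' @param candidate_medians Named vector of candidate transcripts' median
#'   normalized expression.
#' @param cis_medians Vector of cis-regulated transcripts' medians.
#' @param percentile Percentile (0-100) defining the cutoff.
#' @param fallback Absolute cutoff when `cis_medians` is empty.
#' @return List with `pass` (named logical) and `cutoff`.
#' @export
low_expression_filter <- function(candidate_medians, cis_medians,
                                  percentile = 5, fallback = -4.5) {
  if (length(cis_medians) == 0) {
    message("low_expression_filter: no cis-regulated transcripts; using fallback cutoff ",
            fallback)
    cutoff <- fallback
  } else {
    cutoff <- percentile(cis_medians, percentile / 100)
  }
  list(pass = candidate_medians >= cutoff, cutoff = cutoff)
}

#' Call trans-eQTLs through the exclusion cascade
#'
#' Thresholds the distant scan at the Bonferroni per-test alpha, then
#' applies, in order: the cis-capture conditional filter, per
#' transcript-chromosome sequential conditional pruning, a joint
#' multiple-regression check, the probe cross-hybridization screen
#' against each candidate SNP's flank sequence, the low-expression
#' filter, and a final Kruskal-Wallis confirmation. Each step only ever
#' removes candidates.
#'
#' @param scan Distant scan results from [scan_associations()].
#' @param geno A `genotype_matrix`.
#' @param expr Adjusted `expression_matrix`.
#' @param annot Probe annotation.
#' @param cis Cis candidate table from [map_cis()] (all FDR-passing rows,
#'   including Kruskal-Wallis failures).
#' @param probe_seqs Named character vector of probe sequences.
#' @param flank_seqs Named character vector of flank sequences per
#'   candidate SNP (missing flanks fail with an error naming the SNP).
#' @param probe_medians Named per-probe median normalized expression
#'   (e.g. the `pre_adjust_median` attribute of [adjust_expression()]).
#' @param config An [eqtl_config()].
#' @param n_distant_tests Number of distant tests for the Bonferroni
#'   family; defaults to the scanned pair count, but should be the full
#'   post-QC count when the scan was restricted.
#' @return Data frame of candidates with one column per filter flag
#'   (`pass_cis_capture`, `pass_ld_prune`, `pass_joint`, `pass_cross_hyb`,
#'   `pass_low_expr`, `pass_kw`) and `retained`.
#' @export
map_trans <- function(scan, geno, expr, annot, cis, probe_seqs, flank_seqs,
                      probe_medians, config = eqtl_config(),
                      n_distant_tests = NULL) {
  samples <- align_samples(geno, expr)
  n_distant_tests <- n_distant_tests %||% nrow(scan)
  alpha <- config$trans_fwer / n_distant_tests
  cand <- scan[!is.na(scan$p) & scan$p < alpha, , drop = FALSE]
  if (nrow(cand) == 0) {
    message("map_trans: no distant pair below the Bonferroni threshold ",
            format(alpha, digits = 3))
    cand$fwer_threshold <- numeric(0)
    return(cand)
  }
  cand$fwer_threshold <- alpha
  cand$chrom_snp <- geno$snps$chrom[match(cand$snp, geno$snps$snp)]
  cand$chrom_probe <- annot$chrom[match(cand$probe, annot$probe)]

  ## 1. cis-capture conditional filter
  cand$pass_cis_capture <- TRUE
  cand$cis_capture_p <- NA_real_
  for (i in seq_len(nrow(cand))) {
    cis_row <- cis[cis$probe == cand$probe[i], , drop = FALSE]
    cis_dos <- if (nrow(cis_row)) geno$dosage[samples, cis_row$snp[1]] else NULL
    r <- cis_capture_filter(
      geno$dosage[samples, cand$snp[i]], cis_dos,
      expr$values[cand$probe[i], samples],
      same_chrom = cand$chrom_snp[i] == cand$chrom_probe[i],
      alpha = config$conditional_alpha)
    cand$pass_cis_capture[i] <- r$pass
    cand$cis_capture_p[i] <- r$p
  }

  ## 2. sequential conditional prune per (transcript, SNP chromosome)
  cand$pass_ld_prune <- FALSE
  live <- cand$pass_cis_capture
  groups <- split(which(live), paste(cand$probe[live], cand$chrom_snp[live]))
  for (idx in groups) {
    pr <- sequential_conditional_prune(
      cand[idx, c("snp", "p")], geno$dosage[samples, , drop = FALSE],
      expr$values[cand$probe[idx[1]], samples], config$conditional_alpha)
    cand$pass_ld_prune[idx] <- pr$kept
  }

  ## 3. joint model per transcript
  cand$pass_joint <- FALSE
  live <- cand$pass_cis_capture & cand$pass_ld_prune
  for (prb in unique(cand$probe[live])) {
    idx <- which(live & cand$probe == prb)
    jm <- joint_model_check(cand[idx, c("snp", "p")],
                            geno$dosage[samples, , drop = FALSE],
                            expr$values[prb, samples],
                            config$conditional_alpha)
    cand$pass_joint[idx] <- jm$joint_kept
  }

  ## 4. cross-hybridization screen
  cand$pass_cross_hyb <- TRUE
  live <- cand$pass_cis_capture & cand$pass_ld_prune & cand$pass_joint
  for (i in which(live)) {
    if (!cand$probe[i] %in% names(probe_seqs)) {
      stopf("no probe sequence for %s", cand$probe[i])
    }
    cand$pass_cross_hyb[i] <- !probe_maps_to_flank(
      probe_seqs[[cand$probe[i]]], cand$snp[i], flank_seqs, config)
  }

  ## 5. low-expression filter
  cis_retained <- cis[cis$kw_pass, , drop = FALSE]
  lef <- low_expression_filter(
    setNames(probe_medians[cand$probe], cand$probe),
    probe_medians[cis_retained$probe],
    percentile = config$low_expr_percentile,
    fallback = config$low_expr_fallback)
  cand$pass_low_expr <- unname(lef$pass)

  ## 6. Kruskal-Wallis confirmation
  cand$kw_p <- NA_real_
  cand$pass_kw <- FALSE
  live <- cand$pass_cis_capture & cand$pass_ld_prune & cand$pass_joint &
    cand$pass_cross_hyb & cand$pass_low_expr
  for (i in which(live)) {
    cand$kw_p[i] <- kruskal_wallis(geno$dosage[samples, cand$snp[i]],
                                   expr$values[cand$probe[i], samples])$p
    cand$pass_kw[i] <- cand$kw_p[i] <= config$kw_alpha
  }
  cand$retained <- live & cand$pass_kw
  meta <- annot[match(cand$probe, annot$probe), c("gene_id", "symbol", "rna_class")]
  out <- cbind(cand[, c("snp", "probe")], meta,
               cand[, setdiff(names(cand), c("snp", "probe", "chrom_snp", "chrom_probe"))])
  rownames(out) <- NULL
  message(sprintf("map_trans: %d candidate(s) below threshold, %d retained after the cascade",
                  nrow(out), sum(out$retained)))
  out
}
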