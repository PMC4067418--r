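#' Match a GWAS record's SNP to eQTLs by identity or LD
#'
#' Returns all cis/trans eQTLs whose SNP is identical to, or in LD
#' (r2 > `r2_min`) with, the record's SNP.
#'
#' @param gwas_snp SNP id of the GWAS record (must exist in the genotype
#'   panel).
#' @param eqtls Data frame of eQTLs with at least `snp`, `probe`,
#'   `gene_id`, `symbol`, `p`, `type` (`"cis"`/`"trans"`).
#' @param geno A `genotype_matrix`.
#' @param r2_min LD threshold.
#' @return Subset of `eqtls` with an added `ld_r2` column, ordered by
#'   ascending `p`.
#' @export
match_record <- function(gwas_snp, eqtls, geno, r2_min = 0.8) {
  if (!gwas_snp %in% geno$snps$snp) {
    stopf("GWAS SNP %s is not in the genotype panel", gwas_snp)
  }
  g0 <- geno$dosage[, gwas_snp]
  ld <- vapply(eqtls$snp, function(s) {
    if (s == gwas_snp) return(1.0)
    if (!s %in% colnames(geno$dosage)) return(NA_real_)
    ld_r2(g0, geno$dosage[, s])$r2
  }, numeric(1))
  hit <- !is.na(ld) & (eqtls$snp == gwas_snp | ld > r2_min)
  out <- eqtls[hit, , drop = FALSE]
  out$ld_r2 <- unname(ld[hit])
  out[order(out$p), , drop = FALSE]
}

#' Colocalization filter by conditional regression on the GWAS SNP
#'
#' Regresses the eQTL's target expression on the GWAS SNP dosage and
#' tests the residuals against the eQTL dosage. A small conditional P
#' means the eQTL signal persists after accounting for the GWAS SNP -
#' i.e. the two are distinct genetic factors - and the record is
#' excluded.
#'
#' @param gwas_dosage,eqtl_dosage Dosage vectors.
#' @param expression Adjusted expression vector of the eQTL's target.
#' @param alpha Exclusion threshold.
#' @return List with `keep` and `conditional_p`.
#' @export
colocalization_filter <- function(gwas_dosage, eqtl_dosage, expression,
                                  alpha = 0.05) {
  res <- residual_on(expression, gwas_dosage)
  f <- fit_additive(eqtl_dosage, res)
  p <- if (is.na(f$p)) 1 else f$p
  list(keep = p >= alpha, conditional_p = p)
}

## Resolve symbols through the alias table (alias -> symbol).
resolve_symbols <- function(symbols, aliases = NULL) {
  if (is.null(aliases) || nrow(aliases) == 0) return(symbols)
  hit <- match(symbols, aliases$alias)
  ifelse(is.na(hit), symbols, aliases$symbol[hit])
}

#' Classify one GWAS record into interpretive Cases 1-4
#'
#' Given the record's colocalization-surviving eQTL matches: Case 2 when
#' the cis-suggested gene is among the reported genes and it is the only
#' reported gene; Case 3 when several genes were reported and the eQTL
#' map singles out one of them; Case 1 when the suggested gene differs
#' from every reported gene; Case 4 when the only match is a trans-eQTL
#' and no same-chromosome cis match exists. Records without matches are
#' uninformative. When several cis matches suggest different genes, the
#' smallest-P match determines the suggested gene.
#'
#' @param reported_genes Character vector of reported gene symbols.
#' @param matches Matched eQTL rows (from [match_record()], after the
#'   colocalization filter), with `symbol`, `p`, `type`, `ld_r2`.
#' @param aliases Optional alias table (`alias`, `symbol`).
#' @return List with `case` (`1:4` or `"uninformative"`),
#'   `suggested_genes`, `ld_r2`.
#' @export
classify_case <- function(reported_genes, matches, aliases = NULL) {
  reported <- unique(resolve_symbols(reported_genes, aliases))
  if (nrow(matches) == 0) {
    return(list(case = "uninformative", suggested_genes = character(0),
                ld_r2 = NA_real_))
  }
  cis <- matches[matches$type == "cis", , drop = FALSE]
  if (nrow(cis) == 0) {
    top <- matches[1, ]
    return(list(case = "4", suggested_genes = top$symbol, ld_r2 = top$ld_r2))
  }
  top <- cis[1, ]  # smallest P decides the suggestion
  suggested <- resolve_symbols(top$symbol, aliases)
  case <- if (!suggested %in% reported) {
    "1"
  } else if (length(reported) > 1) {
    "3"
  } else {
    "2"
  }
  list(case = case, suggested_genes = suggested, ld_r2 = top$ld_r2)
}

#' Classify every GWAS catalog record against an eQTL map
#'
#' For each record: match the SNP to eQTLs by identity or LD, apply the
#' colocalization conditional-regression filter, and classify the
#' surviving matches into Cases 1-4.
#'
#' @param catalog Data frame with `record`, `snp`, `trait`,
#'   `reported_genes` (semicolon-separated), `p`. Records whose SNP is
#'   absent from the genotype panel are dropped with a message.
#' @param eqtls Combined eQTL table (`snp`, `probe`, `gene_id`, `symbol`,
#'   `p`, `type`).
#' @param geno A `genotype_matrix`.
#' @param expr Adjusted `expression_matrix`.
#' @param aliases Optional alias table.
#' @param config An [eqtl_config()].
#' @return Data frame with one row per examined record: `record`, `snp`,
#'   `trait`, `case`, `suggested_genes`, `ld_r2`, `conditional_p`.
#' @export
classify_gwas <- function(catalog, eqtls, geno, expr, aliases = NULL,
                          config = eqtl_config()) {
  samples <- align_samples(geno, expr)
  in_panel <- catalog$snp %in% geno$snps$snp
  if (any(!in_panel)) {
    message(sprintf("classify_gwas: dropping %d record(s) whose SNP is not in the panel",
                    sum(!in_panel)))
  }
  catalog <- catalog[in_panel, , drop = FALSE]
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    m <- match_record(rec$snp, eqtls, geno, r2_min = config$ld_match_r2)
    cond_p <- NA_real_
    if (nrow(m) > 0) {
      keep <- logical(nrow(m))
      cps <- numeric(nrow(m))
      for (j in seq_len(nrow(m))) {
        cf <- colocalization_filter(
          geno$dosage[samples, rec$snp],
          geno$dosage[samples, m$snp[j]],
          expr$values[m$probe[j], samples],
          alpha = config$conditional_alpha)
        keep[j] <- cf$keep
        cps[j] <- cf$conditional_p
      }
      cond_p <- if (any(keep)) cps[which(keep)[1]] else max(cps)
      m <- m[keep, , drop = FALSE]
    }
    cls <- classify_case(strsplit(rec$reported_genes, ";")[[1]], m, aliases)
    data.frame(record = rec$record, snp = rec$snp, trait = rec$trait,
               case = cls$case,
               suggested_genes = paste(cls$suggested_genes, collapse = ";"),
               ld_r2 = cls$ld_r2, conditional_p = cond_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize GWAS case classifications
#'
#' @param classifications Output of [classify_gwas()].
#' @param n_records Total number of examined records (defaults to the
#'   classification rows).
#' @return List with `counts` (named, Cases 1-4), `informative`,
#'   `fraction_informative`.
#' @export
summarize_cases <- function(classifications, n_records = nrow(classifications)) {
  cases <- c("1", "2", "3", "4")
  counts <- vapply(cases, function(cc) sum(classifications$case == cc),
                   integer(1))
  names(counts) <- paste0("case", cases)
  informative <- sum(counts)
  list(counts = counts, informative = informative,
       fraction_informative = if (n_records > 0) informative / n_records else 0)
}
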