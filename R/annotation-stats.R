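#' Gene-structure category of a SNP relative to its target gene
#'
#' Categories are evaluated only against the target gene: a SNP outside
#' the target gene and its 1 kb flanks is `intergenic` even when it lies
#' inside another gene. Within the gene, a position 2 bp or less from an
#' exon-intron junction on the intron side is `splicing`; exonic
#' positions are `5utr`/`3utr` inside the untranslated regions and
#' `exonic` otherwise; remaining intronic positions are `intronic`.
#' Within 1 kb outside the gene the SNP is `upstream` or `downstream` in
#' the gene's transcriptional direction. Genes without exon structure
#' yield `na` for in-gene positions.
#'
#' @param snp_chrom,snp_pos SNP chromosome and position.
#' @param gene One-row gene model with `chrom`, `start`, `end`, `strand`.
#' @param exons Exon table (`gene_id`, `start`, `end`) or NULL.
#' @param utrs UTR table (`gene_id`, `utr5_start`, `utr5_end`,
#'   `utr3_start`, `utr3_end`) or NULL.
#' @param flank Flank width for upstream/downstream (1 kb).
#' @param splice_bp Junction distance defining `splicing` (2 bp).
#' @return One of `"intergenic"`, `"exonic"`, `"splicing"`, `"intronic"`,
#'   `"3utr"`, `"5utr"`, `"upstream"`, `"downstream"`, `"na"`.
#' @export
assign_category <- function(snp_chrom, snp_pos, gene, exons = NULL,
                            utrs = NULL, flank = 1000, splice_bp = 2) {
  if (snp_chrom != gene$chrom) return("intergenic")
  pos <- snp_pos
  inside <- pos >= gene$start & pos <= gene$end
  if (!inside) {
    if (pos < gene$start - flank || pos > gene$end + flank) return("intergenic")
    before <- pos < gene$start
    upstream <- if (gene$strand == "+") before else !before
    return(if (upstream) "upstream" else "downstream")
  }
  ex <- if (is.null(exons)) NULL else exons[exons$gene_id == gene$gene_id, , drop = FALSE]
  if (is.null(ex) || nrow(ex) == 0) return("na")
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    ## intron side: within splice_bp of a junction?
    near <- any(abs(pos - (ex$start - 1)) < splice_bp |
                  abs(pos - (ex$end + 1)) < splice_bp)
    return(if (near) "splicing" else "intronic")
  }
  u <- if (is.null(utrs)) NULL else utrs[utrs$gene_id == gene$gene_id, , drop = FALSE]
  if (!is.null(u) && nrow(u) == 1) {
    if (pos >= u$utr5_start && pos <= u$utr5_end) return("5utr")
    if (pos >= u$utr3_start && pos <= u$utr3_end) return("3utr")
  }
  "exonic"
}

#' Enrichment fold of a category among eQTLs relative to local SNPs
#'
#' The fold change in the proportion a category constitutes among eQTLs
#' compared to among all local SNPs:
#' `(n_eqtl/total_eqtl) / (n_local/total_local)`.
#'
#' @param n_eqtl,total_eqtl Category and total eQTL counts.
#' @param n_local,total_local Category and total local SNP counts.
#' @return Fold enrichment (NA when a denominator is 0).
#' @examples
#' enrichment_fold(1370, 2995, 716576, 11028260)  # ~7.04
#' @export
enrichment_fold <- function(n_eqtl, total_eqtl, n_local, total_local) {
  ifelse(n_local > 0 & total_eqtl > 0 & total_local > 0,
         (n_eqtl / total_eqtl) / (n_local / total_local), NA_real_)
}

#' Category enrichment table for cis-eQTLs
#'
#' Counts eQTLs and local SNPs per gene-structure category, computes the
#' fold enrichment per category and for the genic/intergenic rollup, and
#' reports mean |beta| and mean R2 per category. Categories absent from
#' the local SNP background have undefined enrichment (NA).
#'
#' @param eqtl_categories Character vector of categories, one per eQTL.
#' @param local_categories Character vector of categories, one per local
#'   SNP.
#' @param eqtl_beta,eqtl_r2 Optional effect vectors aligned with
#'   `eqtl_categories`.
#' @return Data frame with `category`, `n_local`, `pct_local`, `n_eqtl`,
#'   `pct_eqtl`, `enrichment`, `mean_abs_beta`, `mean_r2`. The rollup rows
#'   are labelled `genic` and `intergenic`.
#' @export
enrichment_table <- function(eqtl_categories, local_categories,
                             eqtl_beta = NULL, eqtl_r2 = NULL) {
  genic_cats <- c("exonic", "splicing", "intronic", "3utr", "5utr",
                  "upstream", "downstream", "na")
  cats <- c("intergenic", "genic", genic_cats)
  row_of <- function(cat) {
    in_cat <- function(x) {
      if (cat == "genic") x %in% genic_cats else x == cat
    }
    ne <- sum(in_cat(eqtl_categories))
    nl <- sum(in_cat(local_categories))
    data.frame(
      category = cat, n_local = nl,
      pct_local = 100 * nl / length(local_categories),
      n_eqtl = ne, pct_eqtl = 100 * ne / length(eqtl_categories),
      enrichment = enrichment_fold(ne, length(eqtl_categories),
                                   nl, length(local_categories)),
      mean_abs_beta = if (is.null(eqtl_beta) || ne == 0) NA_real_ else
        mean(abs(eqtl_beta[in_cat(eqtl_categories)])),
      mean_r2 = if (is.null(eqtl_r2) || ne == 0) NA_real_ else
        mean(eqtl_r2[in_cat(eqtl_categories)]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(cats, row_of))
  rownames(out) <- NULL
  out
}

#' Compare effect sizes across categories by ANOVA and Tukey HSD
#'
#' Log-transforms the (positive) effect values, excludes categories with
#' fewer than `min_n` members, and runs one-way ANOVA followed by Tukey's
#' honest-significant-difference pairwise comparisons.
#'
#' @param effects Positive effect values (|beta| or R2).
#' @param categories Category labels aligned with `effects`.
#' @param min_n Minimum category size.
#' @return List with `f` (ANOVA F), `p` (ANOVA P), `n_categories`, and
#'   `pairwise` (Tukey table: `comparison`, `diff`, `p_adj`).
#' @export
compare_categories <- function(effects, categories, min_n = 5) {
  stopifnot(length(effects) == length(categories))
  ok <- !is.na(effects) & !is.na(categories) & effects > 0
  effects <- effects[ok]
  categories <- categories[ok]
  sizes <- table(categories)
  keep_cats <- names(sizes)[sizes >= min_n]
  dropped <- setdiff(names(sizes), keep_cats)
  if (length(dropped)) {
    message("compare_categories: dropping small categor(ies): ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep_cats) < 2) stopf("need at least 2 categories with >= %d members", min_n)
  sel <- categories %in% keep_cats
  df <- data.frame(y = log(effects[sel]), g = factor(categories[sel]))
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       n_categories = length(keep_cats),
       pairwise = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                             p_adj = tk[, "p adj"], row.names = NULL,
                             stringsAsFactors = FALSE))
}

#' Jonckheere-Terpstra permutation trend test
#'
#' Tests for a monotone increasing trend of `values` across the ordered
#' classes. The statistic is the sum over class pairs i < j of the count
#' of cross-pairs with the later-class value larger, counting ties as
#' one half. The one-sided P is estimated by label permutation:
#' `(1 + #[JT_perm >= JT_obs]) / (n_perm + 1)`.
#'
#' @param values Numeric observations.
#' @param classes Ordered class labels (ordered factor, or values sorted
#'   by their natural order).
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return List with `statistic` (JT), `p`, `n_perm`.
#' @export
jonckheere_terpstra <- function(values, classes, n_perm = 10000L, seed = 1L) {
  cls <- if (is.ordered(classes)) classes else factor(classes)
  if (nlevels(cls) < 2) stopf("need at least 2 ordered classes")
  if (any(table(cls) == 0)) cls <- droplevels(cls)
  obs <- jt_statistic(values, cls)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      jt_statistic(values, cls[sample(length(cls))])
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p = p, n_perm = n_perm)
}

jt_statistic <- function(values, classes) {
  lev <- levels(classes)
  groups <- split(values, classes)
  jt <- 0
  for (i in seq_len(length(lev) - 1)) {
    for (j in (i + 1):length(lev)) {
      x <- groups[[lev[i]]]
      y <- groups[[lev[j]]]
      if (!length(x) || !length(y)) next
      cmp <- outer(x, y, function(a, b) (b > a) + 0.5 * (a == b))
      jt <- jt + sum(cmp)
    }
  }
  jt
}

#' Distance profile of cis-eQTLs
#'
#' Summarizes how cis-eQTLs distribute around their target genes:
#' cumulative fractions at distance 0 (inside the gene) and within 17,
#' 50, 100 and 500 kb, and the Spearman correlation between absolute
#' distance and effect size among eQTLs outside genes.
#'
#' @param distances Signed distances (bp; 0 = inside gene).
#' @param effects Effect sizes (|beta| or R2), aligned.
#' @param breaks Distance thresholds (bp) for cumulative fractions.
#' @return List with `cumulative` (data frame `threshold`, `fraction`),
#'   `fraction_in_gene`, `spearman_rho`, `spearman_p` (NA when fewer than
#'   3 eQTLs lie outside genes).
#' @export
distance_profile <- function(distances, effects = NULL,
                             breaks = c(0, 17000, 50000, 100000, 500000)) {
  d <- abs(distances)
  cumfrac <- vapply(breaks, function(b) mean(d <= b), numeric(1))
  out <- list(
    cumulative = data.frame(threshold = breaks, fraction = cumfrac),
    fraction_in_gene = mean(d == 0),
    spearman_rho = NA_real_, spearman_p = NA_real_
  )
  outside <- d > 0
  if (!is.null(effects) && sum(outside) >= 3) {
    ct <- suppressWarnings(cor.test(d[outside], effects[outside],
                                    method = "spearman"))
    out$spearman_rho <- unname(ct$estimate)
    out$spearman_p <- ct$p.value
  }
  out
}

#' Multi-regulatory eQTL detection
#'
#' Groups eQTL calls by SNP and counts the distinct protein-coding
#' (mRNA-class) genes each SNP regulates, after removing probes whose
#' sequence cross-hybridizes (Smith-Waterman screen, pipeline scoring) to
#' the exon sequence of another counted gene. SNPs reaching `min_genes`
#' distinct genes are flagged; the per-gene effect signs and a
#' direction-consistency flag are reported.
#'
#' @param eqtls Data frame with `snp`, `probe`, `gene_id`, `rna_class`,
#'   `beta`.
#' @param probe_seqs Named probe sequences.
#' @param exon_seqs Named (by gene id) concatenated exon sequences.
#' @param min_genes Minimum distinct coding genes.
#' @param config An [eqtl_config()] carrying the alignment scoring.
#' @return Data frame with `snp`, `n_genes`, `genes`
#'   (semicolon-separated), `multi_regulatory`, `direction_consistent`.
#' @export
find_multi_regulatory <- function(eqtls, probe_seqs, exon_seqs,
                                  min_genes = 3L, config = eqtl_config()) {
  coding <- eqtls[eqtls$rna_class == "mRNA", , drop = FALSE]
  empty <- data.frame(snp = character(), n_genes = integer(),
                      genes = character(), multi_regulatory = logical(),
                      direction_consistent = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(coding) == 0) return(empty)
  out <- lapply(split(coding, coding$snp), function(df) {
    df <- df[!duplicated(df$probe), , drop = FALSE]
    counted <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!df$probe[i] %in% names(probe_seqs)) {
        message("find_multi_regulatory: no sequence for probe ", df$probe[i],
                "; excluded from counting")
        counted[i] <- FALSE
        next
      }
      others <- setdiff(unique(df$gene_id), df$gene_id[i])
      for (g in others) {
        if (!g %in% names(exon_seqs)) next
        if (cross_hybridizes(probe_seqs[[df$probe[i]]], exon_seqs[[g]],
                             config)) {
          counted[i] <- FALSE
          break
        }
      }
    }
    genes <- unique(df$gene_id[counted])
    signs <- sign(df$beta[counted])
    data.frame(
      snp = df$snp[1], n_genes = length(genes),
      genes = paste(genes, collapse = ";"),
      multi_regulatory = length(genes) >= min_genes,
      direction_consistent = length(unique(signs[signs != 0])) <= 1,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
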