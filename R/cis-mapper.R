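#' Null minimum-P matrix by sample-label permutation
#'
#' For each permutation round the expression sample labels are shuffled
#' relative to the genotypes (one global shuffle per round, preserving the
#' correlation structure among transcripts), the local scan is re-run, and
#' the per-transcript minimum P is recorded.
#'
#' @param geno A `genotype_matrix` (post-QC).
#' @param expr An adjusted `expression_matrix`.
#' @param annot Probe annotation (see [scan_associations()]).
#' @param config An [eqtl_config()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the shuffles.
#' @param permutations Optional list of explicit sample permutations
#'   (test hook; each an integer vector of length n samples).
#' @return Transcripts-by-permutations matrix of null minimum P values.
#' @export
permute_min_p <- function(geno, expr, annot, config = eqtl_config(),
                          n_perm = config$n_perm_cis, seed = config$seed,
                          permutations = NULL) {
  if (is.null(permutations) && n_perm < 1) stopf("n_perm must be at least 1")
  ctx <- local_scan_context(geno, expr, annot, config)
  perms <- permutations %||% with_seed(seed + 101L, {
    lapply(seq_len(n_perm), function(i) sample(length(ctx$samples)))
  })
  out <- vapply(perms, function(ix) {
    local_min_p(ctx, ctx$Y[, ix, drop = FALSE])
  }, numeric(length(ctx$probes)))
  out <- matrix(out, nrow = length(ctx$probes),
                dimnames = list(ctx$probes, NULL))
  out
}

## Precompute per-probe local SNP index lists and aligned matrices.
local_scan_context <- function(geno, expr, annot, config) {
  samples <- align_samples(geno, expr)
  G <- geno$dosage[samples, , drop = FALSE]
  Y <- expr$values[, samples, drop = FALSE]
  probes <- intersect(rownames(Y), annot$probe)
  local_idx <- lapply(probes, function(pr) {
    gene <- annot[annot$probe == pr, ][1, ]
    eligible_snps(geno$snps, gene, "local", config$cis_window)
  })
  names(local_idx) <- probes
  keep <- lengths(local_idx) > 0
  list(G = G, Y = Y[probes[keep], , drop = FALSE], probes = probes[keep],
       local_idx = local_idx[keep], samples = samples,
       snps = geno$snps)
}

## Per-probe minimum P over the probe's local SNPs for an expression
## matrix Yp (probes x samples, columns aligned to ctx$G rows).
local_min_p <- function(ctx, Yp) {
  vapply(seq_along(ctx$probes), function(i) {
    st <- assoc_stats(ctx$G[, ctx$local_idx[[i]], drop = FALSE],
                      Yp[ctx$probes[i], ])
    if (all(is.na(st$p))) NA_real_ else min(st$p, na.rm = TRUE)
  }, numeric(1))
}

#' Permutation-based FDR at observed per-transcript minimum P values
#'
#' For each observed minimum P value `p`, the FDR estimate is the mean
#' number of null minimum P values at or below `p` per permutation,
#' divided by the number of observed minimum P values at or below `p`;
#' the curve is then monotonized to be non-decreasing in `p` and clipped
#' to `[0, 1]`.
#'
#' @param observed Named vector of observed per-transcript minimum P.
#' @param null_matrix Transcripts-by-permutations null minimum-P matrix.
#' @return Named vector of FDR estimates, aligned with `observed`.
#' @export
estimate_fdr <- function(observed, null_matrix) {
  if (length(null_matrix) == 0) stopf("null matrix is empty")
  ok <- !is.na(observed)
  p <- observed[ok]
  nulls <- sort(as.vector(null_matrix[!is.na(null_matrix)]))
  n_perm <- ncol(null_matrix)
  ord <- order(p)
  ps <- p[ord]
  null_le <- findInterval(ps, nulls) / n_perm
  ## ties in p share the largest observed count
  obs_le <- vapply(ps, function(q) sum(ps <= q), numeric(1))
  fdr_sorted <- pmin(pmax(null_le / obs_le, 0), 1)
  ## monotone non-decreasing in p
  fdr_sorted <- rev(cummin(rev(fdr_sorted)))
  fdr <- rep(NA_real_, length(observed))
  fdr[ok][ord] <- fdr_sorted
  names(fdr) <- names(observed)
  fdr
}

#' Representative SNP among tied top associations
#'
#' When several SNPs in perfect LD (r2 = 1) attain the same smallest P for
#' a transcript, the SNP at the middle genomic position represents the
#' eQTL (even-sized tie sets take the lower of the two middle positions).
#' Tied SNPs that are not all in pairwise perfect LD fall back to the
#' smallest position and are flagged.
#'
#' @param snp_ids SNP ids of the tie set.
#' @param positions Genomic positions, aligned with `snp_ids`.
#' @param dosages Optional samples-by-SNPs dosage matrix for the tie set,
#'   used to verify pairwise perfect LD.
#' @return List with `snp` (chosen id) and `perfect_ld` flag.
#' @export
select_representative <- function(snp_ids, positions, dosages = NULL) {
  stopifnot(length(snp_ids) == length(positions))
  if (length(snp_ids) == 1) {
    return(list(snp = snp_ids[1], perfect_ld = TRUE))
  }
  perfect <- TRUE
  if (!is.null(dosages)) {
    for (i in seq_len(ncol(dosages) - 1)) {
      r2 <- ld_r2(dosages[, i], dosages[, i + 1])$r2
      if (is.na(r2) || r2 < 1 - 1e-9) { perfect <- FALSE; break }
    }
  }
  ord <- order(positions)
  if (!perfect) {
    return(list(snp = snp_ids[ord[1]], perfect_ld = FALSE))
  }
  mid <- ord[ceiling(length(ord) / 2)]
  list(snp = snp_ids[mid], perfect_ld = TRUE)
}

#' Kruskal-Wallis confirmation test for one eQTL
#'
#' Rank-based test of expression across observed genotype classes, with
#' tie correction. When every expression value is tied the statistic is 0
#' and P is 1 by convention.
#'
#' @param dosage 0/1/2 dosage vector.
#' @param expression Expression vector.
#' @return List with `statistic` (H) and `p`.
#' @export
kruskal_wallis <- function(dosage, expression) {
  ok <- !is.na(dosage) & !is.na(expression)
  g <- factor(dosage[ok])
  y <- expression[ok]
  if (nlevels(g) < 2) stopf("only one genotype group present")
  if (length(unique(y)) == 1) {
    return(list(statistic = 0, p = 1))
  }
  kt <- kruskal.test(y, g)
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Map cis-eQTLs by permutation FDR
#'
#' Runs the local scan, takes the per-transcript minimum P (with the
#' perfect-LD middle-SNP tie-break), estimates FDR from permuted null
#' minimum P values, and confirms calls at `fdr < config$cis_fdr` with a
#' Kruskal-Wallis test (records with P above `config$kw_alpha` are
#' flagged, not silently dropped: the trans cis-capture filter also
#' considers them). At most one cis-eQTL is reported per transcript.
#'
#' @param geno,expr,annot,config As for [scan_associations()].
#' @param scan Optional precomputed local scan result (saves one pass).
#' @return Data frame with one row per FDR-passing transcript: `snp`,
#'   `probe`, `gene_id`, `symbol`, `rna_class`, `relation`, `distance`,
#'   `beta`, `r2`, `p`, `n`, `fdr`, `kw_p`, `kw_pass`, `perfect_ld_tie`.
#'   Rows with `kw_pass == TRUE` are the retained cis-eQTLs.
#' @export
map_cis <- function(geno, expr, annot, config = eqtl_config(), scan = NULL) {
  if (is.null(scan)) scan <- scan_associations(geno, expr, annot, "local", config)
  if (nrow(scan) == 0) stopf("no local associations to map")
  samples <- align_samples(geno, expr)
  top <- lapply(split(scan, scan$probe), function(df) {
    pmin_ <- min(df$p)
    ties <- df[df$p <= pmin_ * (1 + 1e-12), , drop = FALSE]
    pos <- geno$snps$pos[match(ties$snp, geno$snps$snp)]
    rep_ <- select_representative(ties$snp, pos,
                                  geno$dosage[samples, ties$snp, drop = FALSE])
    row <- ties[ties$snp == rep_$snp, , drop = FALSE][1, ]
    row$perfect_ld_tie <- nrow(ties) > 1 && rep_$perfect_ld
    row$tie_fallback <- nrow(ties) > 1 && !rep_$perfect_ld
    row
  })
  top <- do.call(rbind, top)
  observed <- setNames(top$p, top$probe)
  null_mat <- permute_min_p(geno, expr, annot, config)
  null_mat <- null_mat[match(top$probe, rownames(null_mat)), , drop = FALSE]
  top$fdr <- unname(estimate_fdr(observed, null_mat))
  hits <- top[!is.na(top$fdr) & top$fdr < config$cis_fdr, , drop = FALSE]
  if (nrow(hits) == 0) {
    message("map_cis: no transcript passed FDR < ", config$cis_fdr)
  }
  if (nrow(hits) > 0) {
    kw <- t(vapply(seq_len(nrow(hits)), function(i) {
      res <- kruskal_wallis(geno$dosage[samples, hits$snp[i]],
                            expr$values[hits$probe[i], samples])
      c(res$statistic, res$p)
    }, numeric(2)))
    hits$kw_p <- kw[, 2]
    hits$kw_pass <- hits$kw_p <= config$kw_alpha
  } else {
    hits$kw_p <- numeric(0)
    hits$kw_pass <- logical(0)
  }
  meta <- annot[match(hits$probe, annot$probe), c("gene_id", "symbol", "rna_class")]
  out <- cbind(hits[, c("snp", "probe")], meta,
               hits[, setdiff(names(hits), c("snp", "probe"))])
  rownames(out) <- NULL
  message(sprintf("map_cis: %d candidate(s) at FDR < %g; %d confirmed by Kruskal-Wallis",
                  nrow(out), config$cis_fdr, sum(out$kw_pass)))
  attr(out, "min_p_observed") <- observed
  attr(out, "min_p_null") <- null_mat
  out
}
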