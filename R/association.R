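#' Classify a SNP-gene pair as local or distant
#'
#' A SNP is *local* to a gene when it lies on the same chromosome and
#' within `window` bp of the nearest transcription start/end site
#' (boundary inclusive); otherwise it is *distant*. The signed distance is
#' 0 inside the gene body, negative upstream and positive downstream of
#' the gene in its transcriptional direction, and NA across chromosomes.
#'
#' @param snp_chrom,snp_pos SNP chromosome and 1-based position.
#' @param gene One-row data frame (or list) with `chrom`, `start`, `end`
#'   (genomic, start <= end) and `strand` (`"+"` or `"-"`).
#' @param window Local window in bp (default 500 kb).
#' @return List with `relation` (`"local"`/`"distant"`) and `distance`
#'   (signed bp, NA when on different chromosomes).
#' @export
classify_pair <- function(snp_chrom, snp_pos, gene, window = 500000) {
  if (snp_chrom != gene$chrom) {
    return(list(relation = "distant", distance = NA_real_))
  }
  d <- signed_gene_distance(snp_pos, gene$start, gene$end, gene$strand)
  list(relation = if (abs(d) <= window) "local" else "distant", distance = d)
}

## Vectorized signed distance of positions to one gene.
signed_gene_distance <- function(pos, start, end, strand) {
  d <- numeric(length(pos))
  before <- pos < start
  after <- pos > end
  d[before] <- pos[before] - start           # negative
  d[after] <- pos[after] - end               # positive
  if (strand == "-") d <- -d                 # upstream = negative in gene direction
  d
}

#' Additive single-SNP association fit
#'
#' Simple least squares of (adjusted) expression on minor-allele dosage:
#' slope `beta` in log2 units per allele, `r2` = squared Pearson
#' correlation (variance explained), and a two-sided t test on the slope
#' with n - 2 degrees of freedom. Missing dosages are dropped pairwise.
#'
#' @param dosage Numeric 0/1/2 dosage vector (NA allowed).
#' @param expression Numeric expression vector.
#' @return List with `beta`, `r2`, `p`, `n`; all NA (flagged untestable)
#'   when the dosage is constant or fewer than 3 complete pairs remain.
#' @examples
#' fit_additive(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 2, 2, 3))  # beta = 1
#' @export
fit_additive <- function(dosage, expression) {
  ok <- !is.na(dosage) & !is.na(expression)
  g <- dosage[ok]
  y <- expression[ok]
  n <- length(g)
  if (n < 3 || var(g) == 0) {
    return(list(beta = NA_real_, r2 = NA_real_, p = NA_real_, n = n))
  }
  gc <- g - mean(g)
  yc <- y - mean(y)
  sxx <- sum(gc^2)
  syy <- sum(yc^2)
  sxy <- sum(gc * yc)
  beta <- sxy / sxx
  if (syy == 0) {
    return(list(beta = beta, r2 = NA_real_, p = NA_real_, n = n))
  }
  r2 <- min(sxy^2 / (sxx * syy), 1)
  p <- p_from_r2(r2, n)
  list(beta = beta, r2 = r2, p = p, n = n)
}

## Two-sided t-test P from squared correlation.
p_from_r2 <- function(r2, n) {
  if (r2 >= 1) return(0)
  tstat <- sqrt(r2 * (n - 2) / (1 - r2))
  2 * stats::pt(-tstat, df = n - 2)
}

#' Scan SNP-transcript pairs for additive associations
#'
#' Fits the additive model for every eligible SNP-probe pair. `mode`
#' restricts the scan to local pairs (within `config$cis_window` of the
#' target gene), distant pairs, or all pairs.
#'
#' @param geno A `genotype_matrix`.
#' @param expr An `expression_matrix` (normally stage `"adjusted"`).
#' @param annot Probe annotation: data frame with `probe`, `gene_id`,
#'   `symbol`, `rna_class`, `chrom`, `start`, `end`, `strand`.
#' @param mode `"local"`, `"distant"` or `"all"`.
#' @param config An [eqtl_config()].
#' @return Data frame with one row per tested pair: `snp`, `probe`,
#'   `relation`, `distance`, `beta`, `r2`, `p`, `n`.
#' @export
scan_associations <- function(geno, expr, annot,
                              mode = c("local", "distant", "all"),
                              config = eqtl_config()) {
  mode <- match.arg(mode)
  samples <- align_samples(geno, expr)
  if (length(samples) < nrow(geno$dosage) || length(samples) < ncol(expr$values)) {
    stopf("genotype and expression sample names do not fully match")
  }
  G <- geno$dosage[samples, , drop = FALSE]
  Y <- expr$values[, samples, drop = FALSE]
  probes <- intersect(rownames(Y), annot$probe)
  out <- vector("list", length(probes))
  for (i in seq_along(probes)) {
    pr <- probes[i]
    gene <- annot[annot$probe == pr, ][1, ]
    sel <- eligible_snps(geno$snps, gene, mode, config$cis_window)
    if (!length(sel)) next
    dist <- rep(NA_real_, length(sel))
    same <- geno$snps$chrom[sel] == gene$chrom
    if (any(same)) {
      dist[same] <- signed_gene_distance(geno$snps$pos[sel][same],
                                         gene$start, gene$end, gene$strand)
    }
    st <- assoc_stats(G[, sel, drop = FALSE], Y[pr, ])
    out[[i]] <- data.frame(
      snp = geno$snps$snp[sel], probe = pr,
      relation = ifelse(same & abs(dist) <= config$cis_window, "local", "distant"),
      distance = dist,
      beta = st$beta, r2 = st$r2, p = st$p, n = st$n,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) {
    warnf("scan_associations: no eligible %s pairs", mode)
    return(data.frame(snp = character(), probe = character(),
                      relation = character(), distance = numeric(),
                      beta = numeric(), r2 = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res[!is.na(res$p), , drop = FALSE]
}

## Indices of SNPs eligible for a probe under the scan mode.
eligible_snps <- function(snps, gene, mode, window) {
  if (mode == "all") return(seq_len(nrow(snps)))
  same <- snps$chrom == gene$chrom
  local <- rep(FALSE, nrow(snps))
  if (any(same)) {
    d <- signed_gene_distance(snps$pos[same], gene$start, gene$end, gene$strand)
    local[same] <- abs(d) <= window
  }
  which(if (mode == "local") local else !local)
}

## Vectorized additive fit of one expression vector against many dosages.
## Returns list of vectors beta, r2, p, n; NA where untestable.
assoc_stats <- function(G, y) {
  k <- ncol(G)
  if (!anyNA(G) && !anyNA(y)) {
    n <- length(y)
    yc <- y - mean(y)
    Gc <- sweep(G, 2, colMeans(G))
    sxx <- colSums(Gc^2)
    syy <- sum(yc^2)
    sxy <- as.vector(crossprod(Gc, yc))
    beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
    r2 <- ifelse(sxx > 0 & syy > 0, pmin(sxy^2 / (sxx * syy), 1), NA_real_)
    p <- rep(NA_real_, k)
    testable <- !is.na(r2) & n >= 3
    p[testable] <- vapply(r2[testable], p_from_r2, numeric(1), n = n)
    return(list(beta = beta, r2 = r2, p = p, n = rep(n, k)))
  }
  beta <- r2 <- p <- numeric(k)
  nn <- integer(k)
  for (j in seq_len(k)) {
    f <- fit_additive(G[, j], y)
    beta[j] <- f$beta; r2[j] <- f$r2; p[j] <- f$p; nn[j] <- f$n
  }
  list(beta = beta, r2 = r2, p = p, n = nn)
}
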