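#' Collapse duplicated probe spots by mean intensity
#'
#' @param intensities Spots-by-samples matrix of raw intensities, row
#'   names are spot ids.
#' @param probe_map Data frame with `spot`, `probe` grouping duplicate
#'   spots under one probe id.
#' @return Probes-by-samples intensity matrix (arithmetic mean per probe).
#' @export
collapse_duplicates <- function(intensities, probe_map) {
  stopifnot(is.matrix(intensities))
  probe <- probe_map$probe[match(rownames(intensities), probe_map$spot)]
  if (anyNA(probe)) stopf("spots without a probe mapping: %s",
                          paste(utils::head(rownames(intensities)[is.na(probe)], 3), collapse = ", "))
  groups <- split(seq_len(nrow(intensities)), probe)
  if (any(lengths(groups) == 0)) stopf("empty duplicate group")
  out <- do.call(rbind, lapply(groups, function(idx) {
    colMeans(intensities[idx, , drop = FALSE])
  }))
  dimnames(out) <- list(names(groups), colnames(intensities))
  out
}

#' 75th-percentile-shift normalization
#'
#' Floors intensities at 1, log2-transforms, and subtracts each sample's
#' 75th percentile (linear-interpolation convention), so every sample's
#' 75th percentile becomes 0. Idempotent on the log2 scale output when
#' re-applied via the returned matrix.
#'
#' @param intensities Probes-by-samples matrix of linear-scale
#'   intensities.
#' @return An `expression_matrix` with stage `"normalized"`.
#' @export
normalize_75th <- function(intensities) {
  stopifnot(is.matrix(intensities))
  if (any(!is.finite(intensities))) {
    bad <- which(!is.finite(intensities), arr.ind = TRUE)[1, ]
    stopf("non-finite intensity at probe '%s', sample '%s'",
          rownames(intensities)[bad[1]] %||% bad[1],
          colnames(intensities)[bad[2]] %||% bad[2])
  }
  x <- log2(pmax(intensities, 1))
  q75 <- apply(x, 2, percentile, prob = 0.75)
  expression_matrix(sweep(x, 2, q75), stage = "normalized")
}

#' Probe filtering by mappability, chromosome and polymorphic sites
#'
#' Drops probes lacking genomic coordinates, probes on sex chromosomes,
#' and probes whose target interval contains any supplied polymorphic
#' site. No abundance filter is applied.
#'
#' @param expr An `expression_matrix`.
#' @param annot Probe annotation with `probe`, `chrom`, and probe target
#'   interval columns `probe_start`, `probe_end` (NA when unmapped). If
#'   the interval columns are absent the gene `start`/`end` are used.
#' @param polymorphic_sites Optional data frame with `chrom`, `pos`.
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return The filtered `expression_matrix` with a `filter_report`
#'   attribute of per-probe exclusion reasons.
#' @export
filter_probes <- function(expr, annot, polymorphic_sites = NULL,
                          sex_chroms = c("chrX", "chrY", "X", "Y")) {
  a <- annot[match(expr$probes, annot$probe), ]
  ps <- a[[if ("probe_start" %in% names(a)) "probe_start" else "start"]]
  pe <- a[[if ("probe_end" %in% names(a)) "probe_end" else "end"]]
  unmapped <- is.na(a$probe) | is.na(a$chrom) | is.na(ps) | is.na(pe)
  sexchr <- !unmapped & a$chrom %in% sex_chroms
  poly <- rep(FALSE, length(expr$probes))
  if (!is.null(polymorphic_sites) && nrow(polymorphic_sites) > 0) {
    for (i in which(!unmapped)) {
      hit <- polymorphic_sites$chrom == a$chrom[i] &
        polymorphic_sites$pos >= ps[i] & polymorphic_sites$pos <= pe[i]
      poly[i] <- any(hit)
    }
  }
  keep <- !unmapped & !sexchr & !poly
  report <- data.frame(probe = expr$probes, unmapped = unmapped,
                       sex_chrom = sexchr, polymorphic = poly, kept = keep,
                       stringsAsFactors = FALSE)
  message(sprintf("filter_probes: %d/%d probes retained (%d unmapped, %d sex-chromosome, %d polymorphic-site)",
                  sum(keep), length(keep), sum(unmapped), sum(sexchr), sum(poly)))
  out <- expression_matrix(expr$values[keep, , drop = FALSE], stage = expr$stage)
  attr(out, "filter_report") <- report
  out
}

#' Estimate surrogate variables by SVD with a permutation stopping rule
#'
#' Residualizes each probe on the known covariates, takes the singular
#' value decomposition of the residual matrix, and keeps the leading
#' components whose variance share exceeds the `1 - alpha` quantile of a
#' null built by permuting residuals independently within probes
#' (parallel-analysis style). Returned surrogate variables are orthonormal
#' sample-level vectors.
#'
#' @param expr An `expression_matrix` (normalized).
#' @param covariates Data frame with `sample`, `age`, `sex` (rows matched
#'   to the expression samples).
#' @param n_perm Permutation rounds for the null variance shares.
#' @param alpha Significance level for keeping a component.
#' @param n_sv Optional fixed number of components (skips the stopping
#'   rule).
#' @param seed Seed for the permutation null.
#' @return Samples-by-K matrix of surrogate variables (K may be 0).
#' @export
estimate_surrogate_variables <- function(expr, covariates, n_perm = 20L,
                                         alpha = 0.05, n_sv = NULL,
                                         seed = 1L) {
  Y <- expr$values
  cov <- covariates[match(colnames(Y), covariates$sample), ]
  if (anyNA(cov$sample)) stopf("covariates missing for some samples")
  X <- stats::model.matrix(~ age + sex, data = cov)
  n <- ncol(Y)
  if (n < ncol(X) + 2) stopf("need at least %d samples", ncol(X) + 2)
  R <- residualize_rows(Y, X)
  sv <- svd(R)
  kmax <- min(dim(R)) - 1
  if (is.null(n_sv)) {
    share <- sv$d[seq_len(kmax)]^2 / sum(sv$d^2)
    null_share <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        Rp <- t(apply(R, 1, sample))
        dp <- svd(Rp, nu = 0, nv = 0)$d
        (dp^2 / sum(dp^2))[seq_len(kmax)]
      }, numeric(kmax))
    })
    crit <- apply(null_share, 1, quantile, probs = 1 - alpha, type = 7)
    sig <- share > crit
    k <- if (sig[1]) which.min(c(sig, FALSE)) - 1L else 0L  # leading run
  } else {
    k <- min(n_sv, kmax)
  }
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  svs <- sv$v[, seq_len(k), drop = FALSE]
  rownames(svs) <- colnames(Y)
  colnames(svs) <- paste0("SV", seq_len(k))
  ## guard against re-capturing a supplied covariate
  for (j in seq_len(k)) {
    for (cc in c("age", "sex")) {
      if (sd(cov[[cc]]) > 0 && abs(cor(svs[, j], cov[[cc]])) > 0.99) {
        warnf("surrogate variable %d nearly duplicates covariate '%s'", j, cc)
      }
    }
  }
  svs
}

## OLS residuals of each row of Y (probes x samples) on design X (samples x p).
residualize_rows <- function(Y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s", paste(drop, collapse = ", "))
  }
  Q <- qr.Q(qrX)
  Yt <- t(Y)                       # samples x probes
  t(Yt - Q %*% crossprod(Q, Yt))
}

#' Adjust expression for known covariates and surrogate variables
#'
#' Per-probe ordinary least-squares residuals from
#' `expression ~ age + sex + SV1 + ... + SVK`. The residuals are exactly
#' orthogonal to every design column. Each probe's pre-adjustment median
#' is carried as metadata for the downstream low-expression filter.
#'
#' @param expr An `expression_matrix` (normalized).
#' @param covariates Data frame with `sample`, `age`, `sex`.
#' @param svs Optional samples-by-K surrogate variable matrix.
#' @return An `expression_matrix` with stage `"adjusted"` and attribute
#'   `pre_adjust_median` (named per-probe medians on the input scale).
#' @export
adjust_expression <- function(expr, covariates, svs = NULL) {
  Y <- expr$values
  cov <- covariates[match(colnames(Y), covariates$sample), ]
  if (anyNA(cov$sample)) stopf("covariates missing for some samples")
  X <- stats::model.matrix(~ age + sex, data = cov)
  if (!is.null(svs) && ncol(svs) > 0) {
    X <- cbind(X, svs[match(colnames(Y), rownames(svs)), , drop = FALSE])
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(v) var(v) == 0)
  if (any(const)) stopf("constant covariate column(s): %s",
                        paste(colnames(X)[-1][const], collapse = ", "))
  R <- residualize_rows(Y, X)
  dimnames(R) <- dimnames(Y)
  out <- expression_matrix(R, stage = "adjusted")
  attr(out, "pre_adjust_median") <- apply(Y, 1, median)
  out
}
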