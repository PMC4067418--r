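#' Fold change implied by an additive log2 effect size
#'
#' Under the additive model on log2 expression, a per-allele coefficient
#' `beta` separates the two homozygote classes by `2 * |beta|` log2 units,
#' i.e. a fold change of `2^(2 |beta|)`.
#'
#' @param beta Per-minor-allele regression coefficient on log2 expression
#'   (log2 units per allele). May be a vector.
#' @return Fold change between the two homozygote genotype classes.
#' @examples
#' fold_change(0.3)  # ~1.5
#' @export
fold_change <- function(beta) {
  2^(2 * abs(beta))
}

## Linear-interpolation percentile (quantile type 7); the package-wide
## percentile convention.
percentile <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 7, names = FALSE))
}

## Uppercase DNA, validate alphabet.
clean_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  x
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
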