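## Encode a DNA string as integers 0..3 (A,C,G,T), 4 = N.
encode_dna <- function(x) {
  codes <- match(strsplit(clean_dna(x), "")[[1]], c("A", "C", "G", "T", "N")) - 1L
  as.integer(codes)
}

#' Smith-Waterman local alignment of a probe against a target
#'
#' Optimal local alignment score by affine-gap dynamic programming. A gap
#' of length L costs `gap_open + L * gap_extend`. Both the target and its
#' reverse complement are scanned (probes may hybridize either strand)
#' unless `both_strands = FALSE`. `N` bases never match. The score is
#' reported as a fraction of the maximum attainable
#' (`match * nchar(probe)`); the probe counts as mapped when the fraction
#' reaches `min_frac`.
#'
#' @param probe,target Nucleotide strings over `{A,C,G,T,N}` (case
#'   insensitive).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults:
#'   10, 0, -250, -100).
#' @param min_frac Mapping threshold as a fraction of the maximum score.
#' @param both_strands Also scan the reverse complement of the target.
#' @return List with `score`, `max_possible`, `fraction`, `mapped`.
#' @examples
#' smith_waterman("ACGTACGT", "TTACGTACGTTT")$fraction  # 1.0
#' @export
smith_waterman <- function(probe, target, match = 10, mismatch = 0,
                           gap_open = -250, gap_extend = -100,
                           min_frac = 0.30, both_strands = TRUE) {
  if (nchar(probe) == 0 || nchar(target) == 0) {
    return(list(score = 0, max_possible = max(match * nchar(probe), 0),
                fraction = 0, mapped = FALSE))
  }
  a <- encode_dna(probe)
  score <- .sw_score_cpp(a, encode_dna(target), match, mismatch,
                         gap_open, gap_extend)
  if (both_strands) {
    score_rc <- .sw_score_cpp(a, encode_dna(revcomp(target)), match,
                              mismatch, gap_open, gap_extend)
    score <- max(score, score_rc)
  }
  max_possible <- match * length(a)
  fraction <- if (max_possible > 0) score / max_possible else 0
  list(score = score, max_possible = max_possible, fraction = fraction,
       mapped = fraction >= min_frac)
}

## Any exact k-mer of the probe present in the target or its reverse
## complement? This is the seed requirement of the cross-hybridization
## screen (see cross_hybridizes).
has_exact_seed <- function(probe, target, k) {
  probe <- clean_dna(probe)
  target <- clean_dna(target)
  if (nchar(probe) < k || nchar(target) < k) return(FALSE)
  kmers <- unique(substring(probe, 1:(nchar(probe) - k + 1), k:nchar(probe)))
  kmers <- kmers[!grepl("N", kmers)]
  if (!length(kmers)) return(FALSE)
  any(vapply(kmers, function(s) grepl(s, target, fixed = TRUE), logical(1))) ||
    any(vapply(kmers, function(s) grepl(s, revcomp(target), fixed = TRUE),
               logical(1)))
}

#' Cross-hybridization screen: seeded Smith-Waterman mapping decision
#'
#' A probe counts as cross-hybridizing to a target when (a) an exact seed
#' match of `config$sw_seed_len` nt exists on either strand, and (b) the
#' Smith-Waterman score reaches `config$sw_min_frac` of the maximum. The
#' seed requirement emulates the seeded aligners this screen stands for:
#' with a zero mismatch score, an unseeded optimal alignment against any
#' long target accumulates enough chance matches to reach the score
#' threshold, which would make the screen non-discriminating.
#'
#' @param probe_seq,target_seq Nucleotide strings.
#' @param config An [eqtl_config()] carrying the scoring scheme.
#' @return Logical.
#' @export
cross_hybridizes <- function(probe_seq, target_seq, config = eqtl_config()) {
  if (!has_exact_seed(probe_seq, target_seq, config$sw_seed_len)) {
    return(FALSE)
  }
  smith_waterman(probe_seq, target_seq,
                 match = config$sw_match, mismatch = config$sw_mismatch,
                 gap_open = config$sw_gap_open,
                 gap_extend = config$sw_gap_extend,
                 min_frac = config$sw_min_frac)$mapped
}

#' Does a probe cross-hybridize to a trans-eQTL's flanking sequence?
#'
#' Applies [cross_hybridizes()] to the supplied flank sequence of the SNP
#' (the sequence standing for the +/-500 kb window).
#'
#' @param probe_seq Probe nucleotide string.
#' @param snp SNP id (names the flank).
#' @param flank_seqs Named character vector of flank sequences.
#' @param config An [eqtl_config()] carrying the scoring scheme.
#' @return Logical: TRUE when the probe maps into the flank.
#' @export
probe_maps_to_flank <- function(probe_seq, snp, flank_seqs,
                                config = eqtl_config()) {
  if (!snp %in% names(flank_seqs)) {
    stopf("no flank sequence available for SNP %s", snp)
  }
  cross_hybridizes(probe_seq, flank_seqs[[snp]], config)
}
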