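## Independent oracles used across test files. These deliberately avoid the
## package's own code paths.

## Exact HWE P by the classic recurrence on heterozygote probabilities
## (ratios of adjacent multinomial terms), independent of the package's
## direct log-factorial evaluation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nm <- 2 * min(n_AA, n_aa) + n_Aa
  h_min <- nm %% 2
  h_max <- min(nm, 2 * n - nm)
  hs <- seq(h_min, h_max, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    hom_minor <- (nm - h) / 2
    hom_major <- n - h - hom_minor
    probs[k] <- probs[k - 1] * 4 * hom_minor * hom_major / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hs == n_Aa]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Best ungapped local alignment score by diagonal scanning. With the
## pipeline scoring (match 10, mismatch 0, minimum gap cost 350) a gap can
## never gain enough on probes up to ~60 nt, so this is a full oracle for
## the DP at those sizes. Scans both strands like the implementation.
ungapped_oracle <- function(probe, target, match = 10, mismatch = 0) {
  one_strand <- function(a, b) {
    an <- strsplit(a, "")[[1]]
    bn <- strsplit(b, "")[[1]]
    best <- 0
    for (off in seq(-(length(an) - 1), length(bn) - 1)) {
      i <- max(1, 1 - off)
      j <- i + off
      run <- 0
      while (i <= length(an) && j <= length(bn)) {
        s <- if (an[i] == bn[j] && an[i] != "N") match else mismatch
        run <- max(run + s, 0)
        best <- max(best, run)
        i <- i + 1; j <- j + 1
      }
    }
    best
  }
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", target), "")[[1]]),
              collapse = "")
  max(one_strand(probe, target), one_strand(probe, rc))
}

## Exhaustive affine local alignment on tiny sequences: enumerate every
## (substring of a) x (substring of b) pair and every monotone alignment
## path between them by brute recursion, charging open + L*extend per gap.
brute_local_affine <- function(a, b, match = 10, mismatch = 0,
                               gap_open = -250, gap_extend = -100) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ## global score of full vectors x vs y, all paths
  glob <- function(i, j, x, y, state) {
    if (i > length(x) && j > length(y)) return(0)
    best <- -Inf
    if (i <= length(x) && j <= length(y)) {
      s <- if (x[i] == y[j]) match else mismatch
      best <- max(best, s + glob(i + 1, j + 1, x, y, "m"))
    }
    if (i <= length(x)) {
      cost <- gap_extend + if (state == "gx") 0 else gap_open
      best <- max(best, cost + glob(i + 1, j, x, y, "gx"))
    }
    if (j <= length(y)) {
      cost <- gap_extend + if (state == "gy") 0 else gap_open
      best <- max(best, cost + glob(i, j + 1, x, y, "gy"))
    }
    best
  }
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av)) {
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      best <- max(best, glob(1, 1, av[i1:i2], bv[j1:j2], "m"))
    }
  }
  best
}

## Jonckheere-Terpstra exact one-sided P by enumerating all permutations
## of the observations across the class layout.
jt_exact_oracle <- function(values, classes) {
  classes <- factor(classes)
  stat <- function(v) {
    lev <- levels(classes)
    total <- 0
    for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
      x <- v[classes == lev[i]]
      y <- v[classes == lev[j]]
      total <- total + sum(outer(x, y, function(p, q) (q > p) + 0.5 * (p == q)))
    }
    total
  }
  obs <- stat(values)
  perms <- all_permutations(length(values))
  stats <- apply(perms, 1, function(ix) stat(values[ix]))
  list(statistic = obs, p = mean(stats >= obs - 1e-12))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
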