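## Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Simulation plan for a synthetic eQTL study
#'
#' Describes the full generative model: cohort size, chromosome layout, SNPs
#' with LD structure, gene models, planted cis/trans effects on log2
#' expression, known covariates (age, sex), latent batch factors, and noise.
#' The plan plus its seed fully determine every generated artifact.
#'
#' @param n_samples Number of individuals.
#' @param chromosomes Data frame with `name`, `length` (bp).
#' @param snps Data frame with `snp`, `chrom`, `pos`, `maf` and optional
#'   columns `ld_to` (id of the causal SNP this one copies; NA =
#'   independent), `r2` (target LD with `ld_to`), `missing_rate`,
#'   `force_het` (plants an all-heterozygote SNP to violate HWE).
#' @param genes Data frame with `gene_id`, `symbol`, `rna_class`
#'   (`mRNA`/`lincRNA`/`other`), `chrom`, `start`, `end`, `strand`,
#'   `n_probes`, optional `n_exons` (default 3).
#' @param cis_effects,trans_effects Data frames with `snp`, `probe`, `beta`
#'   (log2 units per minor allele). Every cis SNP must be local to its
#'   probe's gene (within `cis_window`); every trans SNP must not be.
#' @param covariate_effects Optional data frame with `probe`, `age_beta`,
#'   `sex_beta`.
#' @param n_latent Number of latent batch factors.
#' @param latent_loading_sd SD of per-probe latent-factor loadings (or a
#'   probes-by-K matrix supplied as `latent_loadings`).
#' @param latent_loadings Optional explicit loading matrix.
#' @param noise_sd Residual SD on the log2 scale (> 0).
#' @param age_range Inclusive integer range for discrete-uniform age.
#' @param sex_prob Probability of sex code 1 (cohort default 196/298).
#' @param probe_length Probe sequence length in nt.
#' @param flank_length Length of the generated flank sequence standing in
#'   for a trans-eQTL's +/-500 kb window (desk scale).
#' @param flank_all_snps Generate a flank sequence for every SNP rather
#'   than only the planted trans-effect SNPs (needed when chance distant
#'   candidates may reach the trans threshold and face the
#'   cross-hybridization screen).
#' @param planted_copies Optional data frame with `probe`, `snp`,
#'   `mismatches`, `offset` (1-based position in the flank), `strand`
#'   (`"+"`/`"-"`): plants a mutated copy of the probe in that SNP's flank.
#' @param cis_window Window used to validate effect placement.
#' @param seed Integer master seed.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_samples,
                            chromosomes,
                            snps,
                            genes,
                            cis_effects = NULL,
                            trans_effects = NULL,
                            covariate_effects = NULL,
                            n_latent = 0L,
                            latent_loading_sd = 1,
                            latent_loadings = NULL,
                            noise_sd = 0.5,
                            age_range = c(32L, 66L),
                            sex_prob = 196 / 298,
                            probe_length = 60L,
                            flank_length = 10000L,
                            flank_all_snps = FALSE,
                            planted_copies = NULL,
                            cis_window = 500000L,
                            seed = 1L) {
  stopifnot(n_samples >= 1, is.data.frame(chromosomes), is.data.frame(snps),
            is.data.frame(genes))
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (any(snps$maf <= 0 | snps$maf > 0.5)) stopf("MAF values must lie in (0, 0.5]")
  if (!"ld_to" %in% names(snps)) snps$ld_to <- NA_character_
  if (!"r2" %in% names(snps)) snps$r2 <- NA_real_
  if (!"missing_rate" %in% names(snps)) snps$missing_rate <- 0
  if (!"force_het" %in% names(snps)) snps$force_het <- FALSE
  partners <- !is.na(snps$ld_to)
  if (any(partners)) {
    if (any(snps$r2[partners] < 0 | snps$r2[partners] > 1, na.rm = TRUE)) {
      stopf("LD r2 targets must lie in [0, 1]")
    }
    causal_maf <- snps$maf[match(snps$ld_to[partners], snps$snp)]
    if (anyNA(causal_maf)) stopf("ld_to references unknown SNP")
    diff_maf <- abs(snps$maf[partners] - causal_maf) > 1e-12
    if (any(diff_maf & snps$r2[partners] == 1)) {
      stopf("target r2 = 1 with a different MAF is unattainable")
    }
  }
  if (anyDuplicated(snps$snp)) stopf("duplicated SNP ids in plan")
  if (!"n_exons" %in% names(genes)) genes$n_exons <- 3L
  probes <- plan_probes(genes)
  plan <- structure(list(
    n_samples = as.integer(n_samples), chromosomes = chromosomes,
    snps = snps, genes = genes, probes = probes,
    cis_effects = cis_effects, trans_effects = trans_effects,
    covariate_effects = covariate_effects,
    n_latent = as.integer(n_latent),
    latent_loading_sd = latent_loading_sd,
    latent_loadings = latent_loadings,
    noise_sd = noise_sd, age_range = as.integer(age_range),
    sex_prob = sex_prob, probe_length = as.integer(probe_length),
    flank_length = as.integer(flank_length),
    flank_all_snps = isTRUE(flank_all_snps),
    planted_copies = planted_copies,
    cis_window = as.integer(cis_window), seed = as.integer(seed)
  ), class = "simulation_plan")
  validate_effect_placement(plan)
  plan
}

## One probe row per gene probe slot, with a deterministic baseline slot.
plan_probes <- function(genes) {
  n <- genes$n_probes
  idx <- rep(seq_len(nrow(genes)), n)
  data.frame(
    probe = paste0(rep(genes$gene_id, n), "_p",
                   unlist(lapply(n, seq_len), use.names = FALSE)),
    gene_id = genes$gene_id[idx],
    stringsAsFactors = FALSE
  )
}

validate_effect_placement <- function(plan) {
  check <- function(effects, want_local, label) {
    if (is.null(effects) || nrow(effects) == 0) return(invisible())
    if (!all(effects$snp %in% plan$snps$snp)) stopf("%s references unknown SNP", label)
    if (!all(effects$probe %in% plan$probes$probe)) stopf("%s references unknown probe", label)
    for (i in seq_len(nrow(effects))) {
      s <- plan$snps[plan$snps$snp == effects$snp[i], ]
      g <- plan$genes[plan$genes$gene_id ==
                        plan$probes$gene_id[plan$probes$probe == effects$probe[i]], ]
      rel <- classify_pair(s$chrom, s$pos, g, window = plan$cis_window)$relation
      if (want_local && rel != "local") {
        stopf("%s: SNP %s is not local to probe %s's gene", label, s$snp, effects$probe[i])
      }
      if (!want_local && rel == "local") {
        stopf("%s: SNP %s is local to probe %s's gene", label, s$snp, effects$probe[i])
      }
    }
  }
  check(plan$cis_effects, TRUE, "cis_effects")
  check(plan$trans_effects, FALSE, "trans_effects")
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf(
    "simulation_plan: %d samples, %d SNPs, %d genes (%d probes), %d cis + %d trans effects, K=%d, noise_sd=%g, seed=%d\n",
    x$n_samples, nrow(x$snps), nrow(x$genes), nrow(x$probes),
    if (is.null(x$cis_effects)) 0L else nrow(x$cis_effects),
    if (is.null(x$trans_effects)) 0L else nrow(x$trans_effects),
    x$n_latent, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate genotypes from a simulation plan
#'
#' Independent SNPs are drawn as the sum of two Bernoulli(MAF) allele
#' draws. LD partners are generated per haplotype by copying the causal
#' allele and re-drawing it at the causal MAF with switch probability
#' `s = 1 - sqrt(r2)`, so the realized haplotype correlation approximates
#' `sqrt(r2)` and the dosage r2 the target. Deterministic given the plan
#' seed.
#'
#' @param plan A [simulation_plan()].
#' @return A `genotype_matrix`.
#' @export
simulate_genotypes <- function(plan) {
  with_seed(plan$seed + 11L, {
    n <- plan$n_samples
    snps <- plan$snps
    hap <- vector("list", nrow(snps))
    names(hap) <- snps$snp
    ## causal / independent SNPs first, partners after (one pass each)
    indep <- which(is.na(snps$ld_to))
    for (j in indep) {
      hap[[j]] <- matrix(rbinom(2 * n, 1, snps$maf[j]), nrow = n, ncol = 2)
    }
    for (j in which(!is.na(snps$ld_to))) {
      src <- hap[[snps$ld_to[j]]]
      if (is.null(src)) stopf("LD partner %s generated before its causal SNP", snps$snp[j])
      s <- 1 - sqrt(snps$r2[j])
      switch_mask <- matrix(rbinom(2 * n, 1, s) == 1, nrow = n, ncol = 2)
      h <- src
      h[switch_mask] <- rbinom(sum(switch_mask), 1, snps$maf[j])
      hap[[j]] <- h
    }
    d <- vapply(hap, function(h) h[, 1] + h[, 2], numeric(n))
    dimnames(d) <- list(paste0("S", seq_len(n)), snps$snp)
    forced <- which(snps$force_het)
    if (length(forced)) d[, forced] <- 1
    for (j in which(snps$missing_rate > 0)) {
      hit <- runif(n) < snps$missing_rate[j]
      d[hit, j] <- NA
    }
    genotype_matrix(d, snps[, c("snp", "chrom", "pos", "maf")])
  })
}

#' Generate log2 expression and covariates from genotypes
#'
#' Expression on the normalized log2 scale is a per-probe baseline plus
#' planted additive cis/trans genetic effects, age and sex covariate
#' terms, latent-factor terms, and Gaussian noise. Age is discrete-uniform
#' over the plan's range; sex is Bernoulli. Deterministic given the plan
#' seed.
#'
#' @param geno A `genotype_matrix` generated from the same plan.
#' @param plan A [simulation_plan()].
#' @param baseline Optional named per-probe baseline vector (defaults to
#'   N(-2, 2) draws, emulating the left-shifted normalized intensity scale).
#' @return List with `expression` (an `expression_matrix`, stage
#'   `"normalized"`), `covariates` (data frame `sample`, `age`, `sex`),
#'   and `factors` (samples-by-K latent factor matrix).
#' @export
simulate_expression <- function(geno, plan, baseline = NULL) {
  with_seed(plan$seed + 23L, {
    n <- plan$n_samples
    probes <- plan$probes$probe
    P <- length(probes)
    if (is.null(baseline)) {
      baseline <- setNames(rnorm(P, mean = -2, sd = 2), probes)
    }
    age <- sample(seq(plan$age_range[1], plan$age_range[2]), n, replace = TRUE)
    sex <- rbinom(n, 1, plan$sex_prob)
    K <- plan$n_latent
    factors <- if (K > 0) matrix(rnorm(n * K), n, K) else matrix(0, n, 0)
    loadings <- plan$latent_loadings
    if (K > 0 && is.null(loadings)) {
      loadings <- matrix(rnorm(P * K, sd = plan$latent_loading_sd), P, K)
    }
    Y <- matrix(rep(baseline[probes], n), nrow = P, ncol = n) # probes x samples
    dimnames(Y) <- list(probes, rownames(geno$dosage))
    add_effects <- function(effects) {
      if (is.null(effects) || nrow(effects) == 0) return(invisible())
      for (i in seq_len(nrow(effects))) {
        g <- geno$dosage[, effects$snp[i]]
        g[is.na(g)] <- mean(g, na.rm = TRUE)   # planted signal unaffected by missingness
        Y[effects$probe[i], ] <<- Y[effects$probe[i], ] + effects$beta[i] * g
      }
    }
    add_effects(plan$cis_effects)
    add_effects(plan$trans_effects)
    if (!is.null(plan$covariate_effects) && nrow(plan$covariate_effects) > 0) {
      ce <- plan$covariate_effects
      for (i in seq_len(nrow(ce))) {
        Y[ce$probe[i], ] <- Y[ce$probe[i], ] +
          ce$age_beta[i] * (age - mean(plan$age_range)) + ce$sex_beta[i] * sex
      }
    }
    if (K > 0) Y <- Y + loadings[match(probes, plan$probes$probe), , drop = FALSE] %*% t(factors)
    Y <- Y + matrix(rnorm(P * n, sd = plan$noise_sd), P, n)
    list(
      expression = expression_matrix(Y, stage = "normalized"),
      covariates = data.frame(sample = rownames(geno$dosage), age = age,
                              sex = sex, stringsAsFactors = FALSE),
      factors = factors
    )
  })
}

#' Export raw chip intensities from simulated log2 expression
#'
#' Applies per-sample multiplicative chip offsets (drawn log-uniformly)
#' and a global shift so the 75th-percentile-shift normalization has a
#' real artifact to remove: `raw = 2^(log2 value + shift + offset_sample)`.
#'
#' @param expr An `expression_matrix` on the log2 scale.
#' @param plan The generating [simulation_plan()].
#' @param shift Global additive log2 shift into positive intensity range.
#' @return List with `intensities` (probes x samples, linear scale) and
#'   `offsets` (per-sample log2 chip offsets).
#' @export
simulate_raw_intensities <- function(expr, plan, shift = 8) {
  with_seed(plan$seed + 31L, {
    offsets <- runif(ncol(expr$values), min = -1, max = 1)
    raw <- 2^(sweep(expr$values + shift, 2, offsets, `+`))
    dimnames(raw) <- dimnames(expr$values)
    list(intensities = raw, offsets = offsets)
  })
}

#' Generate gene models, SNP annotations and sequences
#'
#' Builds exon structure and UTRs for every gene (exons and introns
#' alternate across the gene span; the outer thirds of the terminal exons
#' are the UTRs, strand-aware), assigns each SNP a RegulomeDB-style class
#' 1-7 and, for exonic SNPs, a protein consequence; draws random probe
#' sequences; and emits one random flank sequence per trans-effect SNP,
#' optionally planting mutated probe copies per `plan$planted_copies`.
#'
#' @param plan A [simulation_plan()].
#' @return List with `gene_models` (genes + `tss`/`tes`), `exons`, `utrs`,
#'   `probe_annotation` (scan-ready probe table), `snp_annotation`
#'   (`snp`, `regulome_class`, `consequence`), `probe_seqs` (named
#'   character), `flank_seqs` (named by SNP id), `exon_seqs` (named by
#'   gene id; concatenated exonic sequence).
#' @export
simulate_annotation <- function(plan) {
  with_seed(plan$seed + 47L, {
    genes <- plan$genes
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
    ex <- build_exons(genes)
    probes <- plan$probes
    ann <- merge(probes, genes[, c("gene_id", "symbol", "rna_class", "chrom",
                                   "start", "end", "strand")],
                 by = "gene_id", sort = FALSE)
    ann <- ann[match(probes$probe, ann$probe),
               c("probe", "gene_id", "symbol", "rna_class", "chrom",
                 "start", "end", "strand")]
    rownames(ann) <- NULL
    snp_ann <- data.frame(
      snp = plan$snps$snp,
      regulome_class = sample(1:7, nrow(plan$snps), replace = TRUE,
                              prob = c(1, 2, 3, 6, 10, 30, 48) / 100),
      consequence = sample(c("nonsyn", "syn", "stopgain", "stoploss", "na"),
                           nrow(plan$snps), replace = TRUE,
                           prob = c(0.45, 0.50, 0.02, 0.005, 0.025)),
      stringsAsFactors = FALSE
    )
    probe_seqs <- setNames(random_dna(nrow(probes), plan$probe_length), probes$probe)
    exon_seqs <- setNames(vapply(genes$gene_id, function(g) {
      e <- ex$exons[ex$exons$gene_id == g, ]
      paste(random_dna(nrow(e), pmax(e$end - e$start + 1, 1)), collapse = "")
    }, character(1)), genes$gene_id)
    trans_snps <- if (isTRUE(plan$flank_all_snps)) plan$snps$snp else
      unique(if (is.null(plan$trans_effects)) character(0) else plan$trans_effects$snp)
    flank_seqs <- setNames(random_dna(length(trans_snps), plan$flank_length), trans_snps)
    if (!is.null(plan$planted_copies) && nrow(plan$planted_copies) > 0) {
      pc <- plan$planted_copies
      for (i in seq_len(nrow(pc))) {
        if (!pc$snp[i] %in% names(flank_seqs)) {
          ## flanks exist only for trans-effect SNPs; create one on demand
          flank_seqs[pc$snp[i]] <- random_dna(1, plan$flank_length)
        }
        target <- flank_seqs[[pc$snp[i]]]
        copy <- mutate_seq(probe_seqs[[pc$probe[i]]], pc$mismatches[i])
        strand <- if ("strand" %in% names(pc)) pc$strand[i] else "+"
        if (strand == "-") copy <- revcomp(copy)
        off <- pc$offset[i]
        if (off < 1 || off + nchar(copy) - 1 > nchar(target)) {
          stopf("planted copy of %s does not fit in the %d nt flank of %s",
                pc$probe[i], nchar(target), pc$snp[i])
        }
        substr(target, off, off + nchar(copy) - 1) <- copy
        flank_seqs[pc$snp[i]] <- target
      }
    }
    list(gene_models = genes, exons = ex$exons, utrs = ex$utrs,
         probe_annotation = ann, snp_annotation = snp_ann,
         probe_seqs = probe_seqs, flank_seqs = flank_seqs,
         exon_seqs = exon_seqs)
  })
}

## Alternating exon/intron layout: n_exons exons, n_exons - 1 equal introns.
build_exons <- function(genes) {
  rows <- list()
  utrs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    k <- max(g$n_exons, 1L)
    span <- g$end - g$start + 1
    piece <- span / (2 * k - 1)
    starts <- g$start + round((seq_len(k) - 1) * 2 * piece)
    ends <- pmin(starts + round(piece) - 1, g$end)
    ends[k] <- g$end
    rows[[i]] <- data.frame(gene_id = g$gene_id, exon = seq_len(k),
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
    first <- c(starts[1], starts[1] + floor((ends[1] - starts[1]) / 3))
    last <- c(ends[k] - floor((ends[k] - starts[k]) / 3), ends[k])
    if (g$strand == "+") {
      u5 <- first; u3 <- last
    } else {
      u5 <- last; u3 <- first
    }
    utrs[[i]] <- data.frame(gene_id = g$gene_id,
                            utr5_start = u5[1], utr5_end = u5[2],
                            utr3_start = u3[1], utr3_end = u3[2],
                            stringsAsFactors = FALSE)
  }
  list(exons = do.call(rbind, rows), utrs = do.call(rbind, utrs))
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

## Mutate exactly `k` distinct positions to a different base.
mutate_seq <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (k > length(chars)) stopf("cannot mutate %d positions of a %d nt sequence", k, length(chars))
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic GWAS catalog exercising every interpretive case
#'
#' Emits records engineered against the plan's truth table: a reported
#' gene different from the cis-regulated gene (Case 1), equal to it
#' (Case 2), the regulated gene among several reported (Case 3), a SNP
#' with only a trans effect (Case 4), plus records matching no eQTL.
#' Some reported symbols are replaced by aliases to exercise alias
#' resolution; the alias table is returned alongside.
#'
#' @param plan A [simulation_plan()].
#' @param truth Truth table from [simulate_eqtl_study()] (columns `snp`,
#'   `probe`, `gene_id`, `symbol`, `beta`, `type`).
#' @param n_null Number of no-eQTL noise records.
#' @return List with `catalog` (data frame `record`, `snp`, `trait`,
#'   `reported_genes` semicolon-separated, `p`, `planted_case`) and
#'   `aliases` (data frame `alias`, `symbol`).
#' @export
simulate_gwas_catalog <- function(plan, truth, n_null = 3L) {
  with_seed(plan$seed + 59L, {
    cis <- truth[truth$type == "cis", , drop = FALSE]
    trans <- truth[truth$type == "trans", , drop = FALSE]
    trans_only <- trans[!(trans$snp %in% cis$snp), , drop = FALSE]
    all_symbols <- plan$genes$symbol
    recs <- list()
    add <- function(snp, genes, case) {
      recs[[length(recs) + 1]] <<- data.frame(
        record = sprintf("rec%02d", length(recs) + 1), snp = snp,
        trait = sprintf("trait_%s", case),
        reported_genes = paste(genes, collapse = ";"),
        p = 10^-runif(1, 8, 20), planted_case = case,
        stringsAsFactors = FALSE)
    }
    aliased <- utils::head(all_symbols, max(1, length(all_symbols) %/% 3))
    alias_of <- function(sym) {
      ifelse(sym %in% aliased, paste0(sym, "_ALT"), sym)
    }
    if (nrow(cis) >= 1) {
      other <- setdiff(all_symbols, cis$symbol[1])
      add(cis$snp[1], other[1], "case1")
      ## the case-2 record reports the regulated gene under its alias when
      ## one exists, exercising alias resolution downstream
      add(cis$snp[1], alias_of(cis$symbol[1]), "case2")
    }
    if (nrow(cis) >= 2) {
      other <- setdiff(all_symbols, cis$symbol[2])
      add(cis$snp[2], c(cis$symbol[2], other[1]), "case3")
    }
    if (nrow(trans_only) >= 1) {
      add(trans_only$snp[1], setdiff(all_symbols, trans_only$symbol[1])[1], "case4")
    }
    free_snps <- setdiff(plan$snps$snp, truth$snp)
    for (s in utils::head(free_snps, n_null)) {
      add(s, sample(all_symbols, 1), "none")
    }
    catalog <- do.call(rbind, recs)
    aliases <- data.frame(alias = paste0(aliased, "_ALT"), symbol = aliased,
                          stringsAsFactors = FALSE)
    list(catalog = catalog, aliases = aliases)
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing genotypes, expression, covariates,
#' annotation, sequences, GWAS catalog, and the truth table that all
#' parameter-recovery tests reference.
#'
#' @param plan A [simulation_plan()].
#' @param gwas Whether to generate the GWAS catalog.
#' @param baseline Optional named per-probe baseline vector forwarded to
#'   [simulate_expression()] (fixtures use it to control probe medians).
#' @return List with components `genotypes`, `expression`, `covariates`,
#'   `factors`, `annotation` (list from [simulate_annotation()]), `gwas`,
#'   `truth`, and the `plan` itself.
#' @export
simulate_eqtl_study <- function(plan, gwas = TRUE, baseline = NULL) {
  geno <- simulate_genotypes(plan)
  ex <- simulate_expression(geno, plan, baseline = baseline)
  ann <- simulate_annotation(plan)
  truth <- rbind(
    effect_truth(plan$cis_effects, plan, "cis"),
    effect_truth(plan$trans_effects, plan, "trans")
  )
  gw <- if (gwas) simulate_gwas_catalog(plan, truth) else NULL
  list(genotypes = geno, expression = ex$expression,
       covariates = ex$covariates, factors = ex$factors,
       annotation = ann, gwas = gw, truth = truth, plan = plan)
}

effect_truth <- function(effects, plan, type) {
  if (is.null(effects) || nrow(effects) == 0) {
    return(data.frame(snp = character(), probe = character(),
                      gene_id = character(), symbol = character(),
                      beta = numeric(), type = character(),
                      stringsAsFactors = FALSE))
  }
  gene_id <- plan$probes$gene_id[match(effects$probe, plan$probes$probe)]
  data.frame(snp = effects$snp, probe = effects$probe, gene_id = gene_id,
             symbol = plan$genes$symbol[match(gene_id, plan$genes$gene_id)],
             beta = effects$beta, type = type, stringsAsFactors = FALSE)
}

#' Lay out a regular synthetic study design
#'
#' Builds a [simulation_plan()] with genes spaced evenly along
#' chromosomes (far enough apart that each gene's local SNPs are local to
#' it alone), `snps_per_gene` SNPs scattered within the local window of
#' each gene, and optional planted cis effects on the first
#' `n_cis_effects` genes (SNP = the gene's first local SNP).
#'
#' @param n_samples Cohort size.
#' @param n_chrom Number of autosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param snps_per_gene Local SNPs per gene.
#' @param maf Minor allele frequency for all SNPs (or vector recycled).
#' @param n_cis_effects Number of genes receiving a planted cis effect.
#' @param cis_beta Planted effect size(s), recycled.
#' @param rna_class RNA class assigned to all genes.
#' @param ... Passed through to [simulation_plan()] (e.g. `noise_sd`,
#'   `n_latent`, `seed`).
#' @return A [simulation_plan()].
#' @export
grid_plan <- function(n_samples = 300L, n_chrom = 2L, genes_per_chrom = 10L,
                      snps_per_gene = 4L, maf = 0.3, n_cis_effects = 0L,
                      cis_beta = 0.5, rna_class = "mRNA", ...) {
  spacing <- 2e6
  gene_len <- 10000
  chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                       length = genes_per_chrom * spacing + spacing,
                       stringsAsFactors = FALSE)
  n_genes <- n_chrom * genes_per_chrom
  gi <- seq_len(n_genes)
  gene_chrom <- rep(chroms$name, each = genes_per_chrom)
  gene_start <- rep(spacing * (seq_len(genes_per_chrom) - 1) + 1e6, n_chrom)
  genes <- data.frame(
    gene_id = sprintf("G%03d", gi), symbol = sprintf("GENE%03d", gi),
    rna_class = rna_class, chrom = gene_chrom, start = gene_start,
    end = gene_start + gene_len, strand = rep_len(c("+", "-"), n_genes),
    n_probes = 1L, stringsAsFactors = FALSE
  )
  snp_off <- round(seq(-200000, 200000, length.out = snps_per_gene))
  snps <- do.call(rbind, lapply(gi, function(i) {
    data.frame(
      snp = sprintf("rs%03d_%d", i, seq_len(snps_per_gene)),
      chrom = genes$chrom[i], pos = genes$start[i] + snp_off,
      maf = rep_len(maf, snps_per_gene), stringsAsFactors = FALSE)
  }))
  cis <- NULL
  if (n_cis_effects > 0) {
    idx <- seq_len(min(n_cis_effects, n_genes))
    cis <- data.frame(snp = sprintf("rs%03d_1", idx),
                      probe = sprintf("G%03d_p1", idx),
                      beta = rep_len(cis_beta, length(idx)),
                      stringsAsFactors = FALSE)
  }
  simulation_plan(n_samples = n_samples, chromosomes = chroms, snps = snps,
                  genes = genes, cis_effects = cis, ...)
}
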