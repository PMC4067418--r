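test_that("generation is deterministic given plan and seed", {
  plan <- grid_plan(n_samples = 50, n_chrom = 1, genes_per_chrom = 3,
                    n_cis_effects = 1, seed = 99)
  s1 <- simulate_eqtl_study(plan)
  s2 <- simulate_eqtl_study(plan)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$annotation$probe_seqs, s2$annotation$probe_seqs)
  expect_identical(s1$gwas$catalog, s2$gwas$catalog)
})

test_that("LD partner generation hits its r2 targets", {
  base <- data.frame(
    snp = c("c1", "p_copy", "p_indep", "p_half"),
    chrom = "chr1", pos = c(1e5, 1.1e5, 1.2e5, 1.3e5), maf = 0.3,
    ld_to = c(NA, "c1", "c1", "c1"), r2 = c(NA, 1.0, 0.0, 0.5),
    stringsAsFactors = FALSE)
  plan <- simulation_plan(
    n_samples = 1000, chromosomes = data.frame(name = "chr1", length = 1e6),
    snps = base,
    genes = data.frame(gene_id = "G1", symbol = "G1", rna_class = "mRNA",
                       chrom = "chr1", start = 5e5, end = 5.1e5,
                       strand = "+", n_probes = 1L),
    seed = 5)
  g <- simulate_genotypes(plan)
  d <- g$dosage
  ## r2 = 1 with equal MAF: zero switch probability, exact copy
  expect_identical(d[, "p_copy"], d[, "c1"])
  ## r2 = 0: independent within Monte-Carlo error at n = 1000
  expect_lt(ld_r2(d[, "c1"], d[, "p_indep"])$r2, 3 / 1000 * 10)
  ## intermediate target approximately realized
  expect_equal(ld_r2(d[, "c1"], d[, "p_half"])$r2, 0.5, tolerance = 0.15)
})

test_that("realized MAF converges to the plan value", {
  plan <- simulation_plan(
    n_samples = 10000,
    chromosomes = data.frame(name = "chr1", length = 1e6),
    snps = data.frame(snp = "m1", chrom = "chr1", pos = 100, maf = 0.3),
    genes = data.frame(gene_id = "G1", symbol = "G1", rna_class = "mRNA",
                       chrom = "chr1", start = 5e5, end = 5.1e5,
                       strand = "+", n_probes = 1L),
    seed = 21)
  g <- simulate_genotypes(plan)
  expect_equal(mean(g$dosage[, 1]) / 2, 0.3, tolerance = 0.02)
})

test_that("a target r2 of 1 with a different MAF is rejected", {
  snps <- data.frame(snp = c("a", "b"), chrom = "chr1", pos = c(1, 2),
                     maf = c(0.3, 0.2), ld_to = c(NA, "a"), r2 = c(NA, 1))
  expect_error(
    simulation_plan(n_samples = 10,
                    chromosomes = data.frame(name = "chr1", length = 1e3),
                    snps = snps,
                    genes = data.frame(gene_id = "G", symbol = "G",
                                       rna_class = "mRNA", chrom = "chr1",
                                       start = 10, end = 20, strand = "+",
                                       n_probes = 1L)),
    "unattainable")
})

test_that("noiseless single-effect expression recovers the planted beta exactly", {
  plan <- grid_plan(n_samples = 60, n_chrom = 1, genes_per_chrom = 2,
                    snps_per_gene = 1, n_cis_effects = 1, cis_beta = 0.5,
                    noise_sd = 1e-9, seed = 3)
  st <- simulate_eqtl_study(plan, gwas = FALSE)
  f <- fit_additive(st$genotypes$dosage[, "rs001_1"],
                    st$expression$values["G001_p1", ])
  expect_equal(f$beta, 0.5, tolerance = 1e-6)
  ## planted beta = 0.3 corresponds to a 1.5-fold homozygote difference
  expect_equal(fold_change(0.3), 2^0.6)
  expect_equal(round(fold_change(0.3), 1), 1.5)
})

test_that("a planted latent factor dominates the leading principal component", {
  plan <- grid_plan(n_samples = 200, n_chrom = 2, genes_per_chrom = 50,
                    snps_per_gene = 1, noise_sd = 0.5, n_latent = 1,
                    latent_loadings = matrix(1, 100, 1), seed = 17)
  st <- simulate_eqtl_study(plan, gwas = FALSE)
  Y <- st$expression$values
  Yc <- Y - rowMeans(Y)
  pc1 <- svd(Yc)$v[, 1]
  expect_gt(abs(cor(pc1, st$factors[, 1])), 0.9)
})

test_that("planted flank copies are controllable down to the alignment threshold", {
  plan0 <- two_chrom_plan(
    n_samples = 20, seed = 2,
    trans_effects = data.frame(snp = "transB", probe = "GA_p1", beta = 0.9),
    planted_copies = data.frame(probe = "GA_p1", snp = "transB",
                                mismatches = 0L, offset = 500L,
                                strand = "+"))
  ann0 <- simulate_annotation(plan0)
  expect_true(probe_maps_to_flank(ann0$probe_seqs[["GA_p1"]], "transB",
                                  ann0$flank_seqs))
  ## 45 of 60 positions mutated: best alignment under 30% of maximum
  plan45 <- two_chrom_plan(
    n_samples = 20, seed = 2,
    trans_effects = data.frame(snp = "transB", probe = "GA_p1", beta = 0.9),
    planted_copies = data.frame(probe = "GA_p1", snp = "transB",
                                mismatches = 45L, offset = 500L,
                                strand = "+"))
  ann45 <- simulate_annotation(plan45)
  ## exactly 15 of 60 positions survive the mutation; position-wise
  ## identity is below the 30% screen threshold and no seed remains
  planted <- substr(ann45$flank_seqs[["transB"]], 500, 559)
  ident <- sum(strsplit(ann45$probe_seqs[["GA_p1"]], "")[[1]] ==
                 strsplit(planted, "")[[1]])
  expect_equal(ident, 15)
  expect_false(cross_hybridizes(ann45$probe_seqs[["GA_p1"]], planted))
  expect_false(probe_maps_to_flank(ann45$probe_seqs[["GA_p1"]], "transB",
                                   ann45$flank_seqs))
  ## a copy that does not fit the flank is rejected
  bad <- two_chrom_plan(
    n_samples = 20, seed = 2,
    trans_effects = data.frame(snp = "transB", probe = "GA_p1", beta = 0.9),
    planted_copies = data.frame(probe = "GA_p1", snp = "transB",
                                mismatches = 0L, offset = 99999L,
                                strand = "+"))
  expect_error(simulate_annotation(bad), "does not fit")
})

test_that("effect placement invariants are enforced", {
  expect_error(
    two_chrom_plan(n_samples = 10,
                   cis_effects = data.frame(snp = "farA", probe = "GA_p1",
                                            beta = 0.5)),
    "not local")
  expect_error(
    two_chrom_plan(n_samples = 10,
                   trans_effects = data.frame(snp = "cisA", probe = "GA_p1",
                                              beta = 0.5)),
    "is local")
  expect_error(
    two_chrom_plan(n_samples = 10,
                   cis_effects = data.frame(snp = "nope", probe = "GA_p1",
                                            beta = 0.5)),
    "unknown SNP")
})

test_that("the GWAS catalog generator plants each interpretive case", {
  plan <- grid_plan(n_samples = 30, n_chrom = 2, genes_per_chrom = 3,
                    n_cis_effects = 2, cis_beta = 0.6, seed = 8,
                    trans_effects = data.frame(snp = "rs001_1",
                                               probe = "G004_p1",
                                               beta = 0.8))
  st <- simulate_eqtl_study(plan)
  cat_ <- st$gwas$catalog
  expect_setequal(
    intersect(c("case1", "case2", "case3", "case4"), cat_$planted_case),
    c("case1", "case2", "case3"))
  ## a SNP with only a trans effect yields a case-4 record
  plan2 <- grid_plan(n_samples = 30, n_chrom = 2, genes_per_chrom = 3,
                     n_cis_effects = 2, cis_beta = 0.6, seed = 8,
                     trans_effects = data.frame(snp = "rs006_2",
                                                probe = "G001_p1",
                                                beta = 0.8))
  st2 <- simulate_eqtl_study(plan2)
  c4 <- st2$gwas$catalog[st2$gwas$catalog$planted_case == "case4", ]
  expect_equal(c4$snp, "rs006_2")
  expect_false(c4$reported_genes == "GENE001")
})

test_that("raw-intensity export round-trips through normalization", {
  plan <- grid_plan(n_samples = 40, n_chrom = 1, genes_per_chrom = 4,
                    seed = 13)
  st <- simulate_eqtl_study(plan, gwas = FALSE)
  raw <- simulate_raw_intensities(st$expression, plan)
  norm <- normalize_75th(raw$intensities)
  ## chip offsets are removed: per-sample 75th percentile is exactly 0
  expect_equal(unname(apply(norm$values, 2, quantile, 0.75)),
               rep(0, 40), tolerance = 1e-9)
})
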