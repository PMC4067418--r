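test_that("Bonferroni threshold follows the distant-test family size", {
  expect_equal(signif(bonferroni_threshold(30395, 1425832, 16986695), 3),
               1.15e-12)
  expect_equal(bonferroni_threshold(1, 1, 0), 0.05)
  expect_equal(bonferroni_threshold(10, 10, 50), 0.001)
  expect_error(bonferroni_threshold(1, 1, 1), "no distant tests")
})

test_that("cis-capture filter removes pure LD shadows and spares true effects", {
  set.seed(202)
  n <- 300
  g_cis <- rbinom(n, 2, 0.3)
  y <- 0.7 * g_cis + rnorm(n, sd = 0.5)
  ## candidate identical to the cis-eQTL: nothing left after conditioning
  r <- cis_capture_filter(g_cis, g_cis, y, same_chrom = TRUE)
  expect_false(r$pass)
  expect_gt(r$p, 0.5)
  ## independent true trans effect passes
  passes <- 0
  for (s in 1:20) {
    set.seed(s)
    gc_ <- rbinom(n, 2, 0.3)
    gt_ <- rbinom(n, 2, 0.3)
    yy <- 0.5 * gc_ + 0.6 * gt_ + rnorm(n, sd = 0.5)
    passes <- passes + cis_capture_filter(gt_, gc_, yy, TRUE)$pass
  }
  expect_gte(passes, 19)
  ## different chromosome: filter not applied
  expect_true(cis_capture_filter(g_cis, g_cis, y, same_chrom = FALSE)$pass)
  expect_true(cis_capture_filter(g_cis, NULL, y, same_chrom = TRUE)$pass)
})

test_that("sequential conditional pruning drops redundant LD candidates", {
  set.seed(7)
  n <- 300
  g1 <- rbinom(n, 2, 0.3)
  y <- 0.6 * g1 + rnorm(n, sd = 0.5)
  dos <- cbind(s1 = g1, s2 = g1)  # perfect LD pair
  cand <- data.frame(snp = c("s1", "s2"), p = c(1e-20, 2e-20))
  out <- sequential_conditional_prune(cand, dos, y)
  expect_true(out$kept[out$snp == "s1"])
  expect_false(out$kept[out$snp == "s2"])
  ## two independent true effects are both kept
  both <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    ga <- rbinom(n, 2, 0.3); gb <- rbinom(n, 2, 0.3)
    yy <- 0.6 * ga + 0.6 * gb + rnorm(n, sd = 0.5)
    pa <- fit_additive(ga, yy)$p
    pb <- fit_additive(gb, yy)$p
    res <- sequential_conditional_prune(
      data.frame(snp = c("a", "b"), p = c(pa, pb)),
      cbind(a = ga, b = gb), yy)
    both <- both + all(res$kept)
  }
  expect_gte(both, 18)
  ## single marginally significant candidate is kept vacuously
  one <- sequential_conditional_prune(data.frame(snp = "s1", p = 1e-20),
                                      dos, y)
  expect_true(one$kept)
})

test_that("joint model check keeps orthogonal effects and drops shadows", {
  set.seed(8)
  n <- 400
  ga <- rbinom(n, 2, 0.3)
  gb <- rbinom(n, 2, 0.3)
  y <- 0.5 * ga + 0.5 * gb + rnorm(n, sd = 0.5)
  out <- joint_model_check(data.frame(snp = c("a", "b")),
                           cbind(a = ga, b = gb), y)
  expect_true(all(out$joint_kept))
  ## empty input -> empty output
  e <- joint_model_check(data.frame(snp = character(0)),
                         cbind(a = ga), y)
  expect_equal(nrow(e), 0)
  ## correlated null effect is dropped in most seeds
  drops <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    g1 <- rbinom(n, 2, 0.3)
    g2 <- ifelse(runif(n) < 0.5, g1, rbinom(n, 2, 0.3))  # r2 ~ 0.5 shadow
    yy <- 0.6 * g1 + rnorm(n, sd = 0.5)
    res <- joint_model_check(data.frame(snp = c("g1", "g2")),
                             cbind(g1 = g1, g2 = g2), yy)
    drops <- drops + (res$joint_kept[1] && !res$joint_kept[2])
  }
  expect_gte(drops, 14)
})

test_that("low-expression cutoff is the 5th percentile of cis medians", {
  ## degenerate: all cis medians equal
  expect_equal(low_expression_filter(c(a = 0), rep(2, 10))$cutoff, 2)
  ## evenly spaced medians: linear-interpolation percentile
  meds <- seq(-8, 2, length.out = 100)
  cutoff <- low_expression_filter(c(a = 0), meds)$cutoff
  expect_equal(cutoff, unname(quantile(meds, 0.05, type = 7)))
  ## transcript below the fallback cutoff fails
  r <- suppressMessages(
    low_expression_filter(c(lo = -5.0, hi = 0), numeric(0)))
  expect_equal(r$cutoff, -4.5)
  expect_false(r$pass[["lo"]])
  expect_true(r$pass[["hi"]])
})

test_that("the trans cascade excludes planted artifacts and keeps true effects", {
  plan <- two_chrom_plan(
    n_samples = 300, seed = 33, noise_sd = 0.5,
    cis_effects = data.frame(snp = "cisA", probe = "GA_p1", beta = 0.7),
    trans_effects = data.frame(snp = c("transB", "free1"),
                               probe = c("GA_p1", "GB_p1"),
                               beta = c(0.9, 0.9)),
    planted_copies = data.frame(probe = "GB_p1", snp = "free1",
                                mismatches = 0L, offset = 100L,
                                strand = "+"))
  ## make farA a perfect-LD shadow of the cis SNP (distant, same chrom)
  plan$snps$ld_to[plan$snps$snp == "farA"] <- "cisA"
  plan$snps$r2[plan$snps$snp == "farA"] <- 1
  st <- simulate_eqtl_study(plan, gwas = FALSE)
  adj <- adjust_expression(st$expression, st$covariates)
  ann <- st$annotation$probe_annotation
  cfg <- eqtl_config(seed = 33)
  cis <- suppressMessages(map_cis(st$genotypes, adj, ann, cfg))
  sc <- scan_associations(st$genotypes, adj, ann, "distant", cfg)
  trans <- suppressMessages(map_trans(
    sc, st$genotypes, adj, ann, cis,
    probe_seqs = st$annotation$probe_seqs,
    flank_seqs = st$annotation$flank_seqs,
    probe_medians = attr(adj, "pre_adjust_median"),
    config = cfg))
  ## the pure LD shadow of the cis effect is removed by the conditional filter
  shadow <- trans[trans$snp == "farA" & trans$probe == "GA_p1", ]
  expect_true(nrow(shadow) >= 1)
  expect_false(any(shadow$pass_cis_capture))
  ## the cross-hybridizing probe is removed at the alignment screen
  xhyb <- trans[trans$snp == "free1" & trans$probe == "GB_p1", ]
  expect_true(nrow(xhyb) == 1)
  expect_false(xhyb$pass_cross_hyb)
  expect_false(xhyb$retained)
  ## the genuine trans effect survives the whole cascade
  true_ <- trans[trans$snp == "transB" & trans$probe == "GA_p1", ]
  expect_true(nrow(true_) == 1)
  expect_true(true_$retained)
  ## cascade never expands: every retained row passed every filter
  expect_true(all(trans$retained <= (trans$pass_cis_capture &
                                       trans$pass_ld_prune &
                                       trans$pass_joint &
                                       trans$pass_cross_hyb &
                                       trans$pass_low_expr &
                                       trans$pass_kw)))
})
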