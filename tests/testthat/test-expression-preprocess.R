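test_that("duplicate spots collapse to the probe mean", {
  m <- matrix(c(4, 6, 1, 2, 3, 7), ncol = 1,
              dimnames = list(paste0("spot", 1:6), "S1"))
  map <- data.frame(spot = paste0("spot", 1:6),
                    probe = c("A", "A", "B", "B", "B", "C"))
  out <- collapse_duplicates(m, map)
  expect_equal(out["A", 1], 5)
  expect_equal(out["B", 1], 2)
  expect_equal(out["C", 1], 7)   # single-spot probe unchanged
})

test_that("75th-percentile-shift normalization follows the floor/log2/shift contract", {
  m <- matrix(c(0.5, 2, 4, 8), ncol = 1,
              dimnames = list(paste0("p", 1:4), "S1"))
  out <- normalize_75th(m)
  expect_equal(unname(out$values[, 1]), c(-2.25, -1.25, -0.25, 0.75))
  ## all-equal intensities shift to exactly 0
  m2 <- matrix(5, nrow = 3, ncol = 2, dimnames = list(paste0("p", 1:3), NULL))
  expect_true(all(normalize_75th(m2)$values == 0))
  ## sub-unity values are floored to 1 (log2 = 0) before the shift
  m3 <- matrix(c(0.25, 1), ncol = 1, dimnames = list(c("a", "b"), "S1"))
  expect_equal(diff(normalize_75th(m3)$values[, 1]), 0, ignore_attr = TRUE)
  ## idempotent on its own output (re-exponentiated)
  again <- normalize_75th(2^out$values)
  ## floor at 1 clips the already-negative values; check the shift is stable
  expect_equal(unname(apply(again$values, 2, quantile, 0.75)), 0)
  expect_error(normalize_75th(matrix(c(1, Inf), 2, 1,
                                     dimnames = list(c("a", "b"), "S1"))),
               "non-finite")
})

test_that("probe filtering drops unmapped, sex-chromosome and polymorphic probes only", {
  vals <- matrix(0, nrow = 4, ncol = 2,
                 dimnames = list(c("p1", "p2", "p3", "p4"), c("S1", "S2")))
  expr <- expression_matrix(vals, "normalized")
  annot <- data.frame(
    probe = c("p1", "p2", "p3", "p4"),
    chrom = c("chr1", NA, "chrX", "chr1"),
    probe_start = c(100, NA, 100, 500), probe_end = c(160, NA, 160, 560))
  poly <- data.frame(chrom = "chr1", pos = 520)
  out <- suppressMessages(filter_probes(expr, annot, poly))
  ## p1 kept despite being "low expressed": no abundance filter
  expect_equal(out$probes, "p1")
  rep_ <- attr(out, "filter_report")
  expect_true(rep_$unmapped[2])
  expect_true(rep_$sex_chrom[3])
  expect_true(rep_$polymorphic[4])
})

test_that("surrogate-variable estimation finds planted factors and not noise", {
  set.seed(300)
  n <- 50; p <- 100
  cov <- data.frame(sample = paste0("S", 1:n),
                    age = sample(32:66, n, TRUE), sex = rbinom(n, 1, 0.5))
  ## pure noise: K = 0 expected in most seeds
  k0 <- 0
  for (s in 1:5) {
    Y <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("g", 1:p), cov$sample))
    svs <- estimate_surrogate_variables(expression_matrix(Y, "normalized"),
                                        cov, n_perm = 20, seed = s)
    k0 <- k0 + (ncol(svs) == 0)
  }
  expect_gte(k0, 4)
  ## planted batch factor: K >= 1 and SV1 tracks it
  batch <- rnorm(n)
  Yb <- matrix(rnorm(p * n, sd = 0.5), p, n,
               dimnames = list(paste0("g", 1:p), cov$sample)) +
    outer(rep(1, p), batch)
  svs <- estimate_surrogate_variables(expression_matrix(Yb, "normalized"),
                                      cov, n_perm = 20, seed = 1)
  expect_gte(ncol(svs), 1)
  expect_gt(abs(cor(svs[, 1], batch)), 0.9)
  ## forced component count returns exactly K orthonormal vectors
  svs2 <- estimate_surrogate_variables(expression_matrix(Yb, "normalized"),
                                       cov, n_sv = 2, seed = 1)
  expect_equal(dim(svs2), c(n, 2))
  expect_equal(crossprod(svs2), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("covariate adjustment produces residuals orthogonal to the design", {
  set.seed(77)
  n <- 40
  cov <- data.frame(sample = paste0("S", 1:n),
                    age = sample(32:66, n, TRUE), sex = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("p", 1:5), cov$sample))
  ## probe exactly linear in age: residuals are all (numerically) zero
  Y[1, ] <- 3 + 0.1 * cov$age
  svs <- matrix(rnorm(n * 2), n, 2, dimnames = list(cov$sample, c("SV1", "SV2")))
  svs <- qr.Q(qr(svs))
  rownames(svs) <- cov$sample
  adj <- adjust_expression(expression_matrix(Y, "normalized"), cov, svs)
  expect_lt(max(abs(adj$values[1, ])), 1e-10)
  for (v in list(cov$age, cov$sex, svs[, 1], svs[, 2])) {
    ip <- abs(adj$values %*% v)
    norms <- pmax(sqrt(rowSums(adj$values^2)), 1) * sqrt(sum(v^2))
    expect_lt(max(ip / norms), 1e-8)
  }
  expect_equal(attr(adj, "pre_adjust_median"), apply(Y, 1, median))
  ## constant covariate columns are rejected
  cov0 <- cov; cov0$sex <- 0
  expect_error(adjust_expression(expression_matrix(Y, "normalized"), cov0),
               "constant|collinear")
})

test_that("a planted cis effect survives covariate adjustment", {
  plan <- grid_plan(n_samples = 300, n_chrom = 1, genes_per_chrom = 5,
                    n_cis_effects = 1, cis_beta = 0.5, noise_sd = 1,
                    n_latent = 1, seed = 41)
  st <- simulate_eqtl_study(plan, gwas = FALSE)
  svs <- estimate_surrogate_variables(st$expression, st$covariates,
                                      n_sv = 1, seed = 41)
  adj <- adjust_expression(st$expression, st$covariates, svs)
  g <- st$genotypes$dosage[, "rs001_1"]
  f <- fit_additive(g, adj$values["G001_p1", ])
  se <- sqrt((1 - f$r2) / (f$n - 2)) * sd(adj$values["G001_p1", ]) / sd(g)
  expect_lt(abs(f$beta - 0.5), 3 * se)
})
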