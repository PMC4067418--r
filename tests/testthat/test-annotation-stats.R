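make_gene <- function(strand = "+") {
  ## gene span 1000-1999 with exons 1000-1199, 1400-1599, 1800-1999
  list(
    gene = data.frame(gene_id = "G", chrom = "chr1", start = 1000, end = 1999,
                      strand = strand, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "G", start = c(1000, 1400, 1800),
                       end = c(1199, 1599, 1999)),
    utrs = data.frame(gene_id = "G",
                      utr5_start = if (strand == "+") 1000 else 1950,
                      utr5_end = if (strand == "+") 1049 else 1999,
                      utr3_start = if (strand == "+") 1950 else 1000,
                      utr3_end = if (strand == "+") 1999 else 1049)
  )
}

test_that("gene-structure categories follow the target-gene precedence rules", {
  g <- make_gene("+")
  cat_of <- function(pos, chrom = "chr1") {
    assign_category(chrom, pos, g$gene, g$exons, g$utrs)
  }
  expect_equal(cat_of(500), "upstream")           # 500 bp before TSS
  expect_equal(cat_of(2500), "downstream")
  expect_equal(cat_of(1100), "exonic")            # mid first exon, past UTR
  expect_equal(cat_of(1025), "5utr")
  expect_equal(cat_of(1975), "3utr")
  expect_equal(cat_of(1300), "intronic")
  expect_equal(cat_of(3500), "intergenic")        # beyond the 1 kb flank
  expect_equal(cat_of(1500, "chr2"), "intergenic")
  ## minus strand swaps upstream/downstream
  gm <- make_gene("-")
  expect_equal(assign_category("chr1", 500, gm$gene, gm$exons, gm$utrs),
               "downstream")
  expect_equal(assign_category("chr1", 2500, gm$gene, gm$exons, gm$utrs),
               "upstream")
  ## a SNP inside a DIFFERENT gene but outside the target is intergenic
  expect_equal(cat_of(30000), "intergenic")
  ## no exon structure: in-gene positions are na
  expect_equal(assign_category("chr1", 1100, g$gene, NULL, NULL), "na")
})

test_that("splicing covers the two intron-side bases at each junction", {
  g <- make_gene("+")
  cats <- vapply(c(1200, 1201, 1202, 1203, 1397, 1398, 1399),
                 function(p) assign_category("chr1", p, g$gene, g$exons, g$utrs),
                 character(1))
  expect_equal(cats, c("splicing", "splicing", "intronic", "intronic",
                       "intronic", "splicing", "splicing"))
})

test_that("enrichment folds follow the proportion-ratio definition", {
  expect_equal(round(enrichment_fold(1370, 2995, 716576, 11028260), 2), 7.04)
  expect_equal(enrichment_fold(10, 100, 100, 1000), 1.0)
  expect_true(is.na(enrichment_fold(5, 100, 0, 1000)))
  tab <- enrichment_table(
    eqtl_categories = c(rep("upstream", 2), rep("intergenic", 8)),
    local_categories = c(rep("upstream", 20), rep("intergenic", 80)),
    eqtl_beta = rep(0.5, 10), eqtl_r2 = rep(0.2, 10))
  expect_equal(tab$enrichment[tab$category == "upstream"], 1.0)
  expect_equal(tab$enrichment[tab$category == "intergenic"], 1.0)
  ## category proportions total 100% over the disjoint categories
  disjoint <- !(tab$category == "genic")
  expect_equal(sum(tab$pct_eqtl[disjoint]), 100)
  expect_equal(sum(tab$pct_local[disjoint]), 100)
  ## absent category: undefined enrichment reported as NA
  expect_true(is.na(tab$enrichment[tab$category == "5utr"]))
})

test_that("category comparison runs ANOVA/Tukey on log effects with the size rule", {
  set.seed(50)
  ## same distribution: P roughly uniform
  ps <- replicate(40, {
    e <- exp(rnorm(200))
    compare_categories(e, rep(c("a", "b"), each = 100))$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.12)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 1e-3)
  ## shifted category detected (log-scale spread 0.5)
  hits <- replicate(20, {
    e <- c(exp(rnorm(100, sd = 0.5)), exp(rnorm(100, sd = 0.5) + 0.5))
    compare_categories(e, rep(c("a", "b"), each = 100))$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
  ## categories under min_n are dropped before testing
  e <- exp(rnorm(104))
  out <- suppressMessages(
    compare_categories(e, c(rep("a", 50), rep("b", 50), rep("tiny", 4))))
  expect_equal(out$n_categories, 2)
  expect_equal(nrow(out$pairwise), 1)
  expect_error(compare_categories(exp(rnorm(8)), rep(c("a", "b"), each = 4)),
               "at least 2")
})

test_that("Jonckheere-Terpstra matches full enumeration on a tiny instance", {
  vals <- c(1, 2, 3, 4, 5, 6)
  cls <- rep(1:3, each = 2)
  oracle <- jt_exact_oracle(vals, cls)
  expect_equal(oracle$statistic, 12)
  expect_equal(oracle$p, 1 / 90)
  jt <- jonckheere_terpstra(vals, cls, n_perm = 20000, seed = 4)
  expect_equal(jt$statistic, 12)
  expect_lt(abs(jt$p - oracle$p), 0.005)
  ## pure ties: statistic is half the cross-pair count, P near 1
  jt_t <- jonckheere_terpstra(rep(7, 6), cls, n_perm = 2000, seed = 4)
  expect_equal(jt_t$statistic, 12 / 2 * 1)  # 12 cross pairs, all half-ties
  expect_gt(jt_t$p, 0.99)
  ## reversed ordering: one-sided P near 1
  jt_r <- jonckheere_terpstra(rev(vals), cls, n_perm = 2000, seed = 4)
  expect_gt(jt_r$p, 0.95)
  ## a second random instance against the enumeration oracle
  set.seed(88)
  v2 <- sample(1:9)
  c2 <- rep(1:3, each = 3)
  o2 <- jt_exact_oracle(v2, c2)
  j2 <- jonckheere_terpstra(v2, c2, n_perm = 20000, seed = 9)
  expect_equal(j2$statistic, o2$statistic)
  expect_lt(abs(j2$p - o2$p), 0.02)
  expect_error(jonckheere_terpstra(1:3, rep(1, 3)), "2 ordered classes")
})

test_that("distance profile reports cumulative fractions and the distance-effect trend", {
  prof <- distance_profile(c(0, 10000, 40000, 200000))
  expect_equal(prof$cumulative$fraction, c(0.25, 0.5, 0.75, 0.75, 1.0))
  expect_equal(prof$fraction_in_gene, 0.25)
  all_in <- distance_profile(rep(0, 5))
  expect_equal(all_in$fraction_in_gene, 1.0)
  ## planted decay: effect shrinks with distance -> negative Spearman rho
  set.seed(12)
  d <- seq(1000, 400000, length.out = 200)
  eff <- exp(-d / 1e5) + rnorm(200, sd = 0.02)
  prof2 <- distance_profile(d, eff)
  expect_lt(prof2$spearman_rho, -0.5)
  expect_lt(prof2$spearman_p, 1e-6)
})

test_that("multi-regulatory detection counts coding genes after cross-hybridization removal", {
  set.seed(23)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  probe_seqs <- setNames(seqs[1:4], paste0("P", 1:4))
  exon_seqs <- setNames(
    vapply(1:4, function(i) {
      paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    }, character(1)), paste0("g", 1:4))
  eqtls <- data.frame(
    snp = c(rep("rsM", 4), "rs2", "rs2", "rs3", "rs3", "rs3"),
    probe = c("P1", "P2", "P3", "P4", "P1", "P2", "P1", "P2", "P3"),
    gene_id = c("g1", "g2", "g3", "g4", "g1", "g2", "g1", "g2", "g3"),
    rna_class = "mRNA",
    beta = c(0.5, 0.4, 0.6, 0.3, 0.5, -0.2, 0.5, 0.4, 0.6),
    stringsAsFactors = FALSE)
  out <- find_multi_regulatory(eqtls, probe_seqs, exon_seqs)
  expect_true(out$multi_regulatory[out$snp == "rsM"])   # 4 coding genes
  expect_equal(out$n_genes[out$snp == "rsM"], 4)
  expect_false(out$multi_regulatory[out$snp == "rs2"])  # only 2 genes
  expect_true(out$direction_consistent[out$snp == "rsM"])
  expect_false(out$direction_consistent[out$snp == "rs2"])
  ## plant P3's sequence inside g2's exons: rs3 drops to 2 counted genes
  exon_seqs2 <- exon_seqs
  s <- exon_seqs2[["g2"]]
  substr(s, 100, 159) <- probe_seqs[["P3"]]
  exon_seqs2[["g2"]] <- s
  out2 <- find_multi_regulatory(eqtls, probe_seqs, exon_seqs2)
  expect_equal(out2$n_genes[out2$snp == "rs3"], 2)
  expect_false(out2$multi_regulatory[out2$snp == "rs3"])
  ## non-coding transcripts never count
  linc <- eqtls
  linc$rna_class <- "lincRNA"
  expect_equal(nrow(find_multi_regulatory(linc, probe_seqs, exon_seqs)), 0)
})
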