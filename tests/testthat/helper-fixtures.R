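## Shared fixture builders.

## Two-chromosome plan with one gene per chromosome and hand-placed SNPs;
## used by trans-cascade and GWAS tests.
two_chrom_plan <- function(n_samples = 300, seed = 1, ...) {
  chroms <- data.frame(name = c("chr1", "chr2"), length = c(8e6, 8e6))
  genes <- data.frame(
    gene_id = c("GA", "GB"), symbol = c("SYMA", "SYMB"),
    rna_class = "mRNA", chrom = c("chr1", "chr2"),
    start = c(1e6, 1e6), end = c(1.01e6, 1.01e6), strand = "+",
    n_probes = 1L, stringsAsFactors = FALSE
  )
  snps <- data.frame(
    snp = c("cisA", "cisA_ld", "farA", "transB", "free1"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(0.995e6, 0.990e6, 6e6, 2e6, 6e6),
    maf = 0.3, stringsAsFactors = FALSE
  )
  simulation_plan(n_samples = n_samples, chromosomes = chroms, snps = snps,
                  genes = genes, seed = seed, ...)
}

## Deterministic tiny expression matrix.
tiny_expr <- function(values, stage = "normalized") {
  expression_matrix(values, stage = stage)
}
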