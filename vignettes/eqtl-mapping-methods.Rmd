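---
title: "Methods: cis/trans eQTL mapping with permutation FDR and a filter cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis/trans eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlscan)
```

## The model

`eqtlscan` maps expression quantitative trait loci (eQTLs) in a cohort of
unrelated individuals genotyped at dense SNP panels and profiled on
expression microarrays. The association model is additive on the log2
expression scale: for a SNP coded as the count of its minor allele
$g \in \{0, 1, 2\}$ and an adjusted expression phenotype $y$,

$$ y = \alpha + \beta\, g + \varepsilon, $$

with $\beta$ in log2 units per minor allele. The two homozygote classes
therefore differ by $2|\beta|$ log2 units, i.e. a fold change of
$2^{2|\beta|}$ (`fold_change()`): $|\beta| = 0.3$ corresponds to a
1.5-fold difference. $R^2$ is the squared genotype-expression correlation
and equals the fraction of the transcript's (adjusted) variance explained.

A SNP is **local** to a gene when it lies on the same chromosome within
500 kb of the nearest transcription start/end site (boundary inclusive;
"within 500 kb" is read as $\le$); otherwise it is **distant**. Signed
distances are 0 inside the gene body, negative upstream and positive
downstream with respect to the gene's transcriptional direction.

## Preprocessing

Genotype QC retains autosomal SNPs with missing rate $\le$ 1%, exact
Hardy-Weinberg $P \ge 10^{-7}$, and MAF $\ge$ 5% (the boundary is kept:
the exclusion rule is "MAF below 5%"). The Hardy-Weinberg test is the
exact conditional test on the heterozygote count; dosages always count
the minor allele, recomputed from observed frequencies, with
frequency-0.5 ties oriented to the alphabetically first allele.

Expression intensities are floored at 1, log2-transformed, and shifted so
each sample's 75th percentile is 0. All percentiles in the package use
the linear-interpolation convention (R's quantile type 7); the upstream
description of the normalization does not pin the convention down, so
this is a package choice, applied consistently. Duplicate probe spots are
averaged *before* flooring, matching the order in which the steps are
described. Probes without genomic coordinates, on sex chromosomes, or
overlapping known polymorphic sites are dropped; no abundance filter is
applied at this stage.

Known covariates (age in years, sex coded 0/1) and estimated surrogate
variables are removed per probe by ordinary least squares; the residuals
are exactly orthogonal to every design column. Surrogate variables are
estimated by a two-step procedure: residualize on the known covariates,
take the SVD of the residual matrix, and keep the leading components
whose variance share exceeds the 95th percentile of a null obtained by
permuting residuals independently within probes (parallel-analysis
style). This is deliberately simpler than the iteratively re-weighted
surrogate-variable algorithm: it is deterministic given a seed, cheap,
and its operating characteristic (recovering planted batch factors,
returning zero components on pure noise) is what the test suite
verifies. It is *not* expected to reproduce any particular component
count on real cohort data. Surrogate variables are only meaningful when
the probe panel is much larger than the number of true factors; on
panels of a handful of probes the leading component simply absorbs the
strongest genetic effect, so small fixtures adjust for known covariates
only.

## cis mapping

For every transcript the local scan records the minimum association P
over its local SNPs. Ten global permutations of the expression sample
labels (one shuffle per round, preserving the correlation structure
across transcripts) provide a null minimum-P distribution. The FDR at an
observed minimum P value $p$ is

$$ \widehat{FDR}(p) = \frac{\tfrac{1}{B}\sum_b \#\{p^{null}_{t,b} \le p\}}
   {\#\{p^{obs}_t \le p\}}, $$

monotonized to be non-decreasing in $p$ and clipped to $[0,1]$.
Transcripts with $\widehat{FDR} < 0.05$ yield at most one cis-eQTL each.
When several SNPs in perfect LD ($r^2 = 1$) tie at the minimum P, the
middle SNP by genomic position represents the eQTL; an even-sized tie
takes the lower of the two middle positions (only the odd case is defined
upstream, so the even rule is a package decision). Ties *not* in perfect
LD should not occur for identical P values; the fallback takes the
smallest position and flags the record. Calls are confirmed by a
Kruskal-Wallis test across the observed genotype classes; records with
$P > 1.5\times10^{-4}$ are flagged as failing confirmation but kept in
the candidate table, because the trans cis-capture filter must condition
on them too.

## trans mapping

Distant pairs are thresholded at a Bonferroni per-test alpha of
$0.05 / (\#\text{probes}\times\#\text{SNPs} - \#\text{local pairs})$,
computed from the actual post-QC dimensions. Survivors pass through an
ordered, non-expanding cascade:

1. **cis-capture filter** - for same-chromosome candidates whose
   transcript has a cis-eQTL (including Kruskal-Wallis failures), the
   candidate must remain associated with the residuals after regressing
   expression on the cis dosage ($P < 0.05$).
2. **Sequential conditional pruning** - per transcript and candidate
   chromosome, candidates are visited by ascending marginal P; each must
   be significant against the current residuals to be kept, and only
   kept candidates update the residuals.
3. **Joint model** - all kept candidates enter one multiple regression;
   terms with $P > 0.05$ are dropped in a single pass (no re-iteration;
   whether the original procedure iterated is not stated).
4. **Cross-hybridization screen** - the probe sequence is aligned to the
   candidate SNP's flanking sequence; a mapped probe disqualifies the
   candidate (the signal may come from a near-copy under the probe).
5. **Low-expression filter** - transcripts whose median normalized
   expression falls below the 5th percentile of the cis-regulated
   transcripts' medians are removed (absolute fallback cutoff -4.5 when
   no cis-regulated transcripts exist).
6. **Kruskal-Wallis confirmation** at $P \le 1.5\times10^{-4}$.

## The alignment screen and its seed requirement

`smith_waterman()` is an exact affine-gap local alignment (match 10,
mismatch 0, gap open -250, gap extend -100; a length-$L$ gap costs
$250 + 100L$; both strands scanned; `N` never matches). A probe "maps"
when the score reaches 30% of the maximum attainable
($10 \times$ probe length).

These scores have a consequence worth understanding: because mismatches
cost nothing, an optimal local alignment extends through them, and the
score of the best alignment against a long random target is 10 times the
best per-diagonal match count. For a 60-nt probe a diagonal holds
Binomial(60, 0.25) chance matches, so the 18 matches needed for 30% are
exceeded somewhere on any target beyond a few hundred bases. An unseeded
screen at these parameters would therefore flag every probe against
every flank. The aligners this screen emulates are seeded: they evaluate
alignments only around exact seed matches. `cross_hybridizes()` (used by
`probe_maps_to_flank()` and the multi-regulatory counting) accordingly
requires an exact seed match of `sw_seed_len` nt (default 15, either
strand) before the 30% rule applies. A planted exact or lightly mutated
probe copy passes the seed easily; a 60-mer sharing only chance identity
with a 10-kb flank contains a common 15-mer with probability well under
1%. `smith_waterman()` itself stays literal, and its tests compare it
against an exhaustive path-enumeration oracle and an independent
affine-gap implementation.

## Annotation statistics

SNP gene-structure categories are assigned relative to the *target* gene
only: a SNP outside the target gene $\pm$1 kb is intergenic even when
inside another gene. Within the gene, the two intron-side bases at each
junction are `splicing`; exonic positions split into `5utr`/`3utr`/
`exonic`; the rest are `intronic`; the 1-kb flanks are
`upstream`/`downstream` in transcriptional direction. Genes without exon
structure yield `na` for in-gene positions. Enrichment of a category is
the ratio of its share among eQTLs to its share among all local SNPs.
Effect-size comparisons across categories use one-way ANOVA with Tukey
HSD on natural-log-transformed $|\beta|$ or $R^2$ (categories under 5
members excluded); ordered trends across RegulomeDB classes use a
one-sided Jonckheere-Terpstra permutation test (ties count one half;
$P = (1 + \#\{JT_{perm} \ge JT_{obs}\})/(B+1)$).

A multi-regulatory eQTL is a SNP associated with at least three distinct
protein-coding genes after removing probes that cross-hybridize to
another counted gene's exon sequence (same screen as above). Direction
consistency of the per-gene effect signs is reported, not enforced.

## GWAS integration

Catalog records whose SNP is in the genotype panel are matched to eQTLs
by identity or LD $r^2 > 0.8$. For each match, a conditional regression
of the target expression on the GWAS SNP dosage tests whether the eQTL
signal persists in the residuals; if it does ($P < 0.05$) the eQTL and
the GWAS SNP are two distinct factors and the match is discarded.
Surviving matches classify the record: Case 1 when the eQTL-suggested
gene differs from every reported gene, Case 2 when it confirms the single
reported gene, Case 3 when it singles out one of several reported genes,
Case 4 when only a trans-eQTL matches. When several cis matches disagree,
the smallest-P match supplies the suggested gene (the upstream account
shows single suggestions without stating the rule). Reported symbols are
resolved through an alias table before comparison.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the structure the
pipeline assumes, with a truth table that parameter-recovery tests
reference:

* **Genotypes** - causal SNPs are sums of two Bernoulli(MAF) allele
  draws. LD partners copy the causal allele per haplotype and re-draw it
  at the causal MAF with switch probability $s = 1 - \sqrt{r^2_{target}}$,
  a closed form that makes realized $r^2$ converge to the target (exact
  copy at $r^2 = 1$). Partners share the causal MAF; a target of
  $r^2 = 1$ with a different MAF is rejected as unattainable.
* **Expression** - per-probe baseline (default N(-2, 2), emulating the
  left-shifted normalized intensity scale) plus planted additive
  cis/trans effects, age and sex terms, latent factor terms, and Gaussian
  noise. Default cohort shape: age discrete-uniform on [32, 66], sex
  ratio 102:196 - the study-cohort shape these defaults mirror. A raw
  intensity export applies per-chip multiplicative offsets (drawn
  log-uniformly) so normalization has a real artifact to remove.
* **Sequences** - probes default to 60 nt drawn uniformly over ACGT (the
  array's probe length is not published; 60 nt is the standard length of
  the platform class and is configurable). Flank sequences stand in for
  a trans-eQTL's $\pm$500 kb window at a configurable desk-scale length
  (default 10 kb); mutated probe copies can be planted at controlled
  positions and strands.
* **GWAS catalog** - records engineered to exercise each Case, plus
  no-eQTL noise records; some reported symbols are replaced by aliases.

What the generator does *not* emulate: population structure and
relatedness, coalescent LD patterns (blocks are pairwise copies, not
haplotype mosaics), sex chromosomes, non-Gaussian expression noise, and
probe GC/affinity biases. Passing tests therefore demonstrate the
pipeline's correctness under its own model assumptions, not robustness
to every artifact of real cohort data.

## Numerical and design choices

* Association P values use the t distribution with $n-2$ df on the
  simple regression of *adjusted* residuals - the two-stage
  adjust-then-associate procedure, not per-pair covariate refits.
* Missing dosages are handled pairwise complete-case per SNP.
* LD $r^2$ is the squared Pearson correlation of dosages (composite,
  phase-free), not haplotype EM $r^2$.
* Degenerate Kruskal-Wallis input (all expression values tied) returns
  $H = 0$, $P = 1$.
* `estimate_fdr` is evaluated only at observed minimum-P values and
  monotonized from the largest P downward.
* All randomized stages (simulation, permutations, surrogate-variable
  null) take explicit seeds and restore the caller's RNG state.

## Problem sizes used in validation

The packaged checks run at deliberately desk-scale sizes chosen to give
stable Monte-Carlo behavior: null-calibration fixtures of 300 samples,
2,000 SNPs and 500 transcripts with 10 permutations over 10-20 seeds;
recovery fixtures with 100 planted effects ($\beta \ge 0.5$, MAF 0.3,
$n = 300$, noise SD 1); and a two-chromosome truth-table fixture for the
trans cascade. At these sizes the observed behavior is: no cis calls on
null data beyond the nominal FDR, over 90% recovery of planted cis
effects with mean $\hat\beta$ bias under 0.02, and exact separation of
planted trans artifacts from genuine effects.

## Known limitations

* The permutation FDR uses 10 permutations, as in the procedure it
  implements; the FDR estimate at very small P is coarse and relies on
  pooling across transcripts.
* The cross-hybridization screen's seed length is a package parameter
  with no published counterpart; 15 nt makes chance seeds rare at
  desk-scale flank lengths while catching copies with a few mismatches.
* Case definitions for GWAS records implement the published examples;
  borderline configurations (e.g. several reported genes all regulated
  by distinct eQTLs) follow the smallest-P rule and may differ from the
  original supplementary definitions.
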