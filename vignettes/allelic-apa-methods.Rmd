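---
title: "Methods: allele-specific APA quantification and divergence calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific APA quantification and divergence calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelicAPA)
```

## The analysis in one paragraph

Most mammalian genes carry several annotated polyadenylation sites (PASs), so
a single gene yields 3'-end isoforms whose relative usage can differ between
tissues and, in an F1 hybrid, between the two parental alleles. This package
quantifies PAS usage from 3'-end read counts split into three allele
channels (reference-allele B6, alternative-allele SPR, and unassignable
"common" reads), measures within-tissue APA diversity and its reliability
against a resampling null, partitions multi-PAS genes into functional
groups, and calls cis-regulatory divergence between alleles. Because both
alleles of an F1 hybrid share one nucleus, an allelic usage difference is
direct evidence of cis-regulatory divergence, uncontaminated by trans
effects.

## Core definitions and filters

Counts are organized as sample x gene x PAS x channel. All thresholds below
are exposed in `apa_thresholds()` and logged into every report.

* **Expressed gene** (per tissue): at least 20 PAS reads (all channels) in
  *every* replicate of that tissue. Twenty 3'-end reads make relative usage
  estimates meaningful at the 5-read PAS level; requiring every replicate
  protects the replicate-variability statistics from missing data.
* **Used PAS**: at least 5 reads in at least one sample anywhere in the
  study. Unused PASs are removed before any usage computation and their
  reads leave the denominators.
* **Usage**: reads at a PAS divided by the gene's total PAS reads at the
  requested scope. Tissue-scope usage pools replicate counts before
  normalizing (reads, not replicate means, are the unit of evidence — the
  same convention the resampling mocks are built on).
* **Expression**: RPM, i.e. `1e6 * gene reads / sample total`. 3'-end
  protocols sequence one read per transcript, so no length normalization is
  applied.
* **Dominant PAS** (gene x tissue): highest usage in that tissue.
  **Major PAS**: highest unweighted mean usage across the gene's expressing
  tissues. Ties break to the smaller cleavage coordinate — arbitrary, but a
  deterministic rule is required for reproducible labels.

## Diversity, variability, and switch statistics

Within-tissue APA diversity is the Shannon entropy of the usage vector,
$H = -\sum_i p_i \ln p_i$ (natural log; the base only rescales and every
downstream use is rank-based). Between usage vectors we use the Chebyshev
(maximum-component) distance; across the three replicates of a tissue the
**replicate variability** is the largest pairwise Chebyshev distance.

Raw variability confounds measurement noise with biology: genes with more
PASs and fewer reads are noisier. The package therefore subtracts a
resampling null: the gene's reads are pooled over replicates and randomly
re-partitioned into groups with the original per-replicate totals (an exact
multivariate-hypergeometric draw, equivalent to shuffling labelled reads
without materializing them), and

$$\mathrm{adjustvar}_j = \mathrm{var}_j - \frac{1}{100}\sum_{l=1}^{100}
\mathrm{var}^{mock}_{j,l}.$$

The same construction applied to two tissues (pool both, re-partition
preserving per-tissue totals) gives the **adjusted tissue difference**, and
the **switch score** of a gene is the maximum adjusted difference over all
pairs of expressing tissues. 100 mock iterations bound the Monte-Carlo
error of the null mean at roughly 0.01 usage units for typical depths; the
tissue-pair mocks use the same 100 iterations for symmetry.

## Gene groups

Multi-PAS genes partition into:

* **F1** — dominant usage >= 90% in every expressing tissue: one tightly
  regulated functional PAS; remaining usage is treated as molecular error.
* **F2** — some tissue where the rank-2 PAS trails the dominant PAS by
  <= 20%: two PASs plausibly functional. The boundary is inclusive
  (`f2_gap = 0.20`), matching the phrasing "not larger than 20%"; it is
  configurable.
* **FU** — the rest: functional status unresolved.

F1 precedence over F2 is stated for determinism but vacuous at the default
thresholds (a >= 90% dominant PAS leaves a gap >= 80%). A gene is
**switched** when its switch score reaches 0.50. The mock-adjusted score is
used by default — the raw maximum difference is available via the `pairs`
table — because the raw statistic inflates for low-depth genes, which is
exactly what the adjustment exists to remove. **Functional type** genes are
the union of F2 genes and switched FU genes.

The **high-confidence** subset of functional-type genes requires expression
support for the secondary PAS (the rank-2 PAS in the tissue meeting the F2
criterion, or the most-changing PAS of a switched gene): either Spearman
rho between tissue RPM and secondary usage positive with p < 0.05 across at
least three expressing tissues, or RPM above the tissue median where the
secondary PAS peaks. The p < 0.05 operationalization of "positive
correlation" is a package choice and is configurable (`cor_alpha`); genes
expressed in fewer than three tissues use the median arm only.

## Allelic analyses

Allelic usage uses only allele-assigned reads. Three filters precede any
test: exclusion-listed genes (imprinted, sex-linked, mitochondrial) leave
the analysis; a gene x tissue is dropped when any sample has fewer than 10
allele-specific reads for either allele; and a PAS whose usage estimated
from allelic reads alone differs by more than 10% from the estimate using
allelic plus common reads is removed (its allele-assignable reads are not
representative of the locus).

Per-PAS divergence is tested with a replicate-stratified
Cochran-Mantel-Haenszel chi-square on (this PAS vs rest of gene) x
(B6 vs SPR) tables — replicates are strata, so depth differences between
replicates cannot masquerade as allelic signal. The statistic follows the
standard convention (hypergeometric variance, Yates correction only when it
cannot overshoot), reducing on one stratum to the continuity-corrected
chi-square. P-values are BH-adjusted within each tissue; a PAS is
**divergent** iff adjusted p < 0.05 *and* |usage difference| > 10% — the
effect-size gate carries most of the selectivity at high depth. A gene is
divergent in a tissue iff its dominant PAS there is divergent, and genes
classify as non/some/all-divergent across their testable tissues.

Supporting analyses: `scaling_law_table()` bins genes by B6-allele
major-PAS usage (default bins from 0.5, where a two-PAS dominant site must
sit) and summarizes |delta| per bin with adjacent-bin Mann-Whitney tests;
`variant_density()` counts allelic sequence variants in the strand-oriented
(-200, +100) window (301 bases, inclusive) around each cleavage site;
`allelic_clustering()` clusters tissue x allele samples with average
linkage on 1 - Pearson correlation of the per-gene feature (allelic usage
of the maximum-average-usage PAS measurable in every tissue, or allelic
log2 RPM). Allelic *expression* divergence (fold change > 2, BH FDR < 0.05)
is assessed with per-replicate binomial z-scores against a 1/2 split
combined by Stouffer's method — a deliberately simple, dependency-light
test whose inferential target matches the question asked of it.

## The synthetic-data generator

`simulate_apa_dataset()` produces annotations, ground truth and counts with
the statistical structure the analysis assumes. Defaults describe the study
conditions: nine tissues, three replicates, log-normal expected expression
(sdlog 1) around 2,000 reads per gene and replicate, 30% allele-assignable
reads (an F1 cross of two well-diverged strains), and truth classes in
proportions `single 0.20 / f1 0.31 / f2 0.41 / switch 0.08` — the observed
composition of expressed genes renormalized over the four representable
archetypes.

Counts are drawn hierarchically: per replicate a log-normal gene total
(sdlog 0.25), a Binomial(n, 1/2) parental split (autosomal, no imprinting —
imprinting exclusion is exercised through the exclusion list instead),
per-read allele-channel assignment with probability `allelic_rate`, and
multinomial PAS identity from the originating allele's true usage vector.
Reads are simulated at count level only; the thin `simulate_read_ends()`
emitter exists to exercise read assignment.

Notable construction choices:

* The PAS count of a gene is drawn from `pas_per_gene_dist`; truth class
  `single` is realized by the k = 1 genes, and multi-PAS genes draw their
  class from the remaining fractions renormalized. The defaults make the
  two settings agree (mass 0.20 at k = 1).
* F1-like genes place 0.93-0.995 usage on one PAS; the residual usage is
  rank-skewed (a rank-2 minor carries 70% of it) so that minor PASs of
  moderately expressed genes remain observable under the 5-read used-PAS
  filter, as real minor PASs are.
* The expression-error coupling shrinks dominance as expected expression
  falls (logistic in log-expression, rate `error_slope`), producing the
  positive expression-vs-dominant-usage correlation the statistics must
  recover.
* Allelic divergence subtracts `divergence_effect` from the SPR allele's
  per-tissue dominant PAS, redistributing proportionally. An additive shift
  of 0.3 is not realizable on a 0.95-usage PAS without destroying the F1
  guarantee in the allele mixture, so divergence is assigned among f2-like
  genes — consistent with the empirical pattern that allelic usage
  differences concentrate at moderate major-PAS usage.

What the generator does **not** emulate: sequence-level artifacts (internal
priming, polyA stretches), fragment-length or GC bias, correlated usage
across genes, imprinting, and mapping bias between parental genomes.
Passing the recovery tests therefore demonstrates the statistical machinery
is correct under the assumed sampling model, not that real libraries meet
those assumptions.

## Numerical and testing choices

Determinism: every stochastic stage derives its seed from one master seed
through a counter-based fan-out (`fan_seed`), so stage order and per-gene
iteration cannot perturb downstream draws; two runs at one seed are
bit-identical. Degenerate inputs are handled explicitly: zero-denominator
usage vectors are flagged missing rather than NaN; single-PAS genes have
variability and switch contributions of exactly zero; degenerate CMH tables
(a zero margin in every stratum) return p = 1 with a flag. The affine-gap
aligner charges the full -11 on the first gapped residue and -1 per
extension, penalizes end gaps (true global alignment), and the alternative
open-plus-extend convention is a flag away. Conservation-track bases absent
from a bedGraph score 0 and are counted and reported.

The test suite checks every statistic against an independent oracle (exact
enumeration for the aligner, brute force for the Chebyshev norm, a step-up
oracle for BH, closed forms for CMH and the hypergeometric moments) and
runs the full pipeline on seeded bundles of 500 genes x 9 tissues x 3
replicates; calibration experiments use 2,000 genes at 2,000 reads per
allele. These sizes give the recovery and calibration estimates standard
errors comfortably below the margins tested while keeping a full run in a
few minutes.

## Known limitations

The CMH test treats reads as independent draws within a replicate;
overdispersion beyond multinomial sampling (e.g. from PCR duplicates) will
inflate its statistic, and the 10% effect-size gate is the main guard. The
high-confidence correlation arm has little power below five expressing
tissues. The allelic consistency filter compares pooled estimates per
tissue and cannot detect replicate-specific assignment artifacts. The
aligner is quadratic-time R code, adequate for C-terminal peptides but not
for proteome-scale scans.
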