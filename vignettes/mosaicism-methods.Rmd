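---
title: "Methods: single-cell quantification of Y-chromosome mosaicism"
author: "mosaicY"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell quantification of Y-chromosome mosaicism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicY)
```

## Scope and model

`mosaicY` quantifies mosaicism between a Y-free lineage (45,X) and a
Y-bearing lineage (48,XYYY in the motivating case; any Y-positive
karyotype fits the same machinery) from droplet scRNA-seq UMI counts of
PBMCs, and cross-validates the mosaic fraction with digital droplet PCR.
This vignette records the statistical choices and their rationale; the
README shows the user-facing workflow.

### Gene panels

Genotyping and dosage both rest on which genes can witness a Y
chromosome. The Y panel is every annotated chromosome-Y gene *outside*
the pseudoautosomal regions; the X panel likewise for X. PAR genes are
excluded from both panels — reads from a PAR gene cannot identify their
chromosome of origin, so a PAR UMI in a 45,X cell is expected and must
not trigger a Y call. This exclusion is conservative: it costs a little
sensitivity (fewer witness genes) and buys exactness of the
"complete absence" rule. PAR intervals default to the GRCh38 PAR1/PAR2
coordinates (`par_regions_grch38()`); overlap by a single base flags a
gene, the standard inclusive convention for 1-based annotations.

### Per-cell genotyping and dropout correction

A cell is called Y-bearing iff its Y-panel UMI total reaches `min_y_umi`
(default 1: expression of any single Y-linked gene). Every cell receives
a binary call; there is no "ambiguous" class. Uncertainty is instead
handled at the population level: truly Y-bearing cells can show zero
Y-panel UMIs through dropout, with probability q (the false-negative
rate), so the observed Y-bearing fraction has expectation f(1 − q) and

$$\hat f = \min\!\bigl(1,\; f_{\mathrm{obs}} / (1 - q)\bigr).$$

q is estimated as the zero-Y fraction among reference cells that all
carry Y, with a Clopper-Pearson interval; a bootstrap over both the case
calls and the reference zero-count propagates its uncertainty into
$\hat f$. Two caveats are deliberate:

* False positives are assumed negligible. This holds exactly when
  ambient contamination is absent; with ambient Y molecules the
  presence/absence rule degrades, which is why `min_y_umi` is exposed
  (≥ 2 tolerates sporadic ambient UMIs) and why the simulator has an
  `ambient_y_rate` knob to characterize the failure mode.
* q depends on Y expression dosage. A 48,XYYY cell expresses Y genes at
  roughly three times the single-copy level, so its dropout probability
  is *lower* than that of a 46,XY reference cell. A matched reference
  (same dosage) estimates the correct q; calibrating on normal male
  PBMCs overestimates q for a triple-Y lineage and overcorrects the
  fraction. The package's validation uses matched references; users with
  only 46,XY references should treat $\hat f$ as an upper bound on the
  correction.

### Composition test

For cell type $c$ with $n_c$ cells of which $k_c$ are Y-bearing, the
statistic is $T_c = |p_c - \bar p|$, $p_c = k_c/n_c$, with $\bar p$ the
pooled fraction — the simplest two-sided measure of compositional
imbalance. The null distribution shuffles the observed genotype calls
across all cells while keeping each type's size fixed. Internally the
shuffle is realized as sequential multivariate-hypergeometric draws of
per-type Y-bearing counts (the last type takes the remainder), which is
distribution-identical to permuting labels, preserves the genotype
multiset by construction, and vectorizes over all permutations. P-values
use the add-one estimator $(b+1)/(n_{\mathrm{perm}}+1)$ so no finite
Monte Carlo run reports zero, and a permuted $T \ge T_{\mathrm{obs}}$
counts as extreme (conservative tie-breaking). FDR control across cell
types is Benjamini-Hochberg at $\alpha = 0.05$.

`exact_enumeration_test()` enumerates all $\binom{N}{K}$ assignments for
instances up to 12 cells and is used in the tests as the oracle the
Monte Carlo version must match.

One honest note on the uniformity property: with 500 simulated null
replicates, the per-type Kolmogorov-Smirnov distance from uniformity has
sampling fluctuation of order $1.36/\sqrt{500} \approx 0.06$ even for
perfectly uniform p-values, so the test suite checks KS distance on the
p-values pooled across the eight types (4000 values) and per-type
binomial bounds on $P(p < 0.05)$ instead of a per-type KS at 0.05.

### Y/X dosage

The dosage ratio is pseudobulk: $r = \sum_{\text{cells}} Y\text{-panel
UMIs} / \sum_{\text{cells}} X\text{-panel UMIs}$. The ratio of sums is
invariant to uniform library-size scaling and robust to per-cell zeros;
means of per-cell ratios are neither (they are offered with a pseudocount
for plotting only). Against single-Y male references, a triple-Y lineage
should show close to a 3-fold elevated $r$; `compare_to_reference()`
reports the case's rank among references and an `elevated` flag (case
above every reference), matching how few-donor comparisons are actually
read.

### Differential expression

Counts are log-normalized per cell, $\ln(1 + 10^4\,x_{gc}/N_c)$ — the
convention of the major single-cell toolkits. Within a cell type, genes
expressed in ≥ 10% of either genotype group are compared by a two-sided
Wilcoxon rank-sum test (exact for small untied samples, normal
approximation with tie correction otherwise), with Bonferroni correction
over the genes actually tested in that comparison — the multiplier
convention of the framework this mirrors. No fold-change threshold is
applied by default; significance is purely the adjusted p < 0.05. Both
per-cell-type and pooled comparisons are supported (`de_test_all_types()`
vs `de_test(target_type = NULL)`), since aggregate analyses of this kind
are sometimes reported either way. Significant genes are annotated
against a curated list of hematological-malignancy-associated genes
(including *TCL1A*, *JAK2*, *DNMT3A*, …; `inst/extdata/`), because
lineage-specific dysregulation of such genes is the clinically actionable
output of the comparison.

Rank-sum tests on single cells treat cells as independent replicates;
with one donor this measures lineage-associated expression differences
within that donor, not population-level effects. Mixed-model or
pseudobulk-replicate designs are out of scope.

### ddPCR estimation

Droplet digital PCR partitions genomic DNA into ~20,000 droplets; a
droplet is positive when it received ≥ 1 target copy, so the positive
fraction $\hat p$ gives the mean copies per droplet
$\lambda = -\ln(1-\hat p)$ (Clopper-Pearson CI pushed through the same
transform; all-positive wells are a saturation error, not a number).
Wells are pooled by summing droplets per channel before inversion — the
merged-well estimator, lower-variance than averaging per-well λ. With
the AMELX/AMELY assay, AMELX counts genomes (one X per genome in both
lineages here) and AMELY counts Y copies, so the Y-bearing *cell*
fraction is

$$f_{\mathrm{ddPCR}} = \frac{\lambda_{\mathrm{AMELY}} / c_Y}{\lambda_{\mathrm{AMELX}}},$$

with $c_Y = 3$ for a 48,XYYY lineage. Skipping the copy-number divisor
would triple the apparent Y-lineage fraction; $c_Y$ is a parameter (set
1 for a per-allele fraction). The CI combines the two channel CIs
conservatively (low-Y/high-X and high-Y/low-X bounds).

## The simulator

`simulate_pbmc()` generates the ground-truth datasets every stage is
validated against. Its structure:

* **Cell types**: eight immune types with PBMC-like global proportions
  (CD4/CD8 T, NK, B, two monocyte classes, dendritic cells,
  megakaryocytes); per-type or global Y-bearing lineage fractions.
* **Counts**: gamma-Poisson (negative binomial, dispersion 0.1) with
  mean = library size × relative gene expression. Library sizes are
  log-normal (median 7400 UMIs); per-gene relative expression is
  log-normal within chromosome-class budgets (autosomes the remainder;
  X 3%; Y 0.04% per copy; PAR 0.2%; MT 5% of the transcriptome).
  Dropout arises from low means — no separate zero-inflation knob, which
  matches droplet-data behaviour with fewer parameters.
* **Lineages**: 45,X cells have zero Y-gene means; Y means in Y-bearing
  cells scale with `y_dosage_multiplier` (3 by default). Both lineages
  carry one X, so X expression is lineage-invariant; XIST receives no
  special model. PAR copy-number differences between the lineages (1 vs
  4 copies) are *not* modelled — PAR genes are excluded from every panel
  downstream, so nothing consumes them.
* **Optional structure**: planted low-quality cells (for QC tests),
  planted autosomal fold changes in the Y-bearing lineage (for DE
  tests), and additive Poisson ambient Y contamination spread uniformly
  over the Y panel and added to all cells (expectation `ambient_y_rate`
  per cell) — nonzero values deliberately break the complete-absence
  genotyping rule to expose its sensitivity to ambient RNA.

Defaults were fixed once against the study-scale descriptive statistics
(~3000 cells, median ≈ 2066 genes and ≈ 7400 UMIs per cell, a
near-balanced 48.43% lineage split; the log-normal spread of gene
weights, `base_mean_sdlog = 1`, was chosen to land the detected-genes
median) and are not tuned per analysis.

What the simulator does **not** emulate: batch effects, doublets,
cell-cycle structure, realistic gene-gene correlation, UMI saturation,
or ambient contamination of non-Y genes. Passing tests therefore show
the estimators are correct under a well-specified droplet-like
generative model — they do not certify performance on real data with
those artefacts, which is precisely why `min_y_umi`, `ambient_y_rate`
and the q-correction exist as explicit, inspectable knobs.

`simulate_ddpcr()` draws per-well positives as
Binomial$(n, 1 - e^{-\lambda_{\text{channel}}})$ with
$\lambda_{\mathrm{AMELX}} = \lambda_{\mathrm{gDNA}}$ and
$\lambda_{\mathrm{AMELY}} = 3 f \lambda_{\mathrm{gDNA}}$ — the same
Poisson partitioning model the estimator inverts, so end-to-end recovery
checks are meaningful but share the partitioning assumption.

## Numerical and design notes

* Matrices are cells × genes everywhere in memory; 10x MatrixMarket
  files are genes × cells on disk and transposed on IO. This single
  orientation rule removes a chronic source of silent bugs.
* QC defaults: ≥ 200 genes, ≥ 500 UMIs, ≤ 10% mitochondrial UMIs — all
  overridable; filtering is idempotent and metrics are recomputed from
  the matrix so the cell table can never drift out of sync.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from one master seed (a small hash
  of the stage name), so a whole report is reproducible from one
  integer and stages remain independently reproducible.
* Tie-breaks: permuted statistics equal to the observed value (within
  1e-12) count as extreme; corrected fractions are clamped to [0, 1]
  with the clamping reported.
* Degenerate inputs fail loudly with classed conditions (`format_error`,
  `config_error`, `saturation_error`, …): empty Y panels, all-positive
  ddPCR wells, zero X-panel sums, all-cells-filtered QC.
* Test and validation problem sizes: replicate-heavy checks (type-I
  error at 200 replicates × 2000 cells, power at 100 × 1000, null-DE at
  100 × 400) run on a reduced ~100-gene catalogue, since genotype-call
  behaviour depends on the Y panel and not on transcriptome width;
  single-run checks and the acceptance script use the full ~3000-gene
  catalogue at ~3000 cells. The moderate-dropout recovery checks set the
  Y expression budget to `y_frac = 1.2e-4`, chosen from the
  negative-binomial zero-mass closed form so that roughly 10% of
  Y-bearing cells show no Y expression — a regime where the correction
  visibly matters.

## Known limitations

* A single `min_y_umi` threshold cannot separate ambient contamination
  from true low expression; droplet-level ambient modelling is out of
  scope.
* The q-correction assumes false negatives only; a symmetric two-error
  model (false positives from ambient RNA) is not implemented.
* Only two karyotype classes are called. Distinguishing 46,XY from
  47,XYY/48,XYYY by expression *magnitude* (rather than presence) would
  need a different, dosage-based classifier.
* Reference-male comparisons are empirical (rank/elevated), not a formal
  test — appropriate for the few-donor settings this targets.
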