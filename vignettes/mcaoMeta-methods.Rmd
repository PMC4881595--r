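---
title: "Methods: cross-study meta-analysis of MCAO expression profiles"
author: "mcaoMeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study meta-analysis of MCAO expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analytical problem

Rodent middle cerebral artery occlusion (MCAO) experiments measure brain
gene expression after an induced ischemic stroke against sham-operated
controls. Individual microarray series are small (3 to 24 animals per
arm) and sit on different platforms, so single-study differential
expression is noisy and poorly reproducible. `mcaoMeta` implements the
standard remedy: combine several series per species with formal
meta-analysis, cross-check the pooled calls against the individual
studies, intersect the survivors across species, and interpret the final
list with gene-set enrichment and protein-interaction context.

The package is organized around a `StudyExpression` container (a
`SummarizedExperiment` carrying one study's genes-by-samples matrix, the
MCAO/sham group factor and a probe/gene level flag), and the stages
below. Every stage is also exercised end-to-end by `runPipeline()` on
synthetic collections with known ground truth, which is how the test
suite validates the whole chain offline.

# Preprocessing

`preprocessStudies()` runs, in order: log2 transform (identity when the
input is flagged as already log-scale), quantile normalization, k-nearest
neighbour imputation, probe-to-gene collapse by the mean, restriction to
the common-gene intersection, and per-gene standardization. The order is
a design choice the underlying methods literature leaves open: we impute
on normalized log-scale values so distances are comparable across
samples, and collapse probes after imputation so probe means never
average over missing cells.

Numerical conventions:

* **Quantile normalization** replaces each column's sorted values by the
  row means of the column-sorted matrix; tied values receive the mean of
  the reference values at their tied ranks (the "average ties" dialect,
  delegated to `limma::normalizeQuantiles(ties = TRUE)`).
* **KNN imputation** (`k = 10`, the classic default) measures Euclidean
  distance over mutually observed columns, rescaled by
  `sqrt(n_total / n_shared)` so a pair of rows sharing two columns is
  not spuriously closer than a pair sharing twelve. Rows with no
  observed values are an error; observed cells are returned
  bit-identical.
* **Standardization** uses the sample variance (denominator n − 1),
  which matters at n = 3; constant rows are an error naming the gene.
* **Background correction** is deliberately a no-op: inputs are assumed
  to be summarized intensities, not raw array images. Array quality is
  summarized numerically by per-sample relative log expression
  (`qcRLE()`: median and IQR of deviations from gene-wise medians),
  reported but never used to drop samples automatically.

Fold changes are computed on the **unstandardized** gene-level log2
matrix and test statistics on the standardized one. Standardization is a
per-gene affine map, so t-statistics and standardized effect sizes are
identical either way, but a fold change taken after standardization
would lose its log2 units; keeping both matrices resolves the tension
explicitly.

# Per-study differential expression

`deAnalyze()` computes per-gene two-sample t-tests (Welch by default —
group sizes are tiny and variances need not be equal; the pooled-variance
variant is a flag) and log2 fold changes (MCAO minus sham). A gene is
called up when `log2fc >= 1.5` and its p-value is below 0.05, down
symmetrically. The 1.5 bound is on the log2 difference itself (about a
2.8-fold change), following the literal inequality |log2 FC| >= 1.5.

Whether the p-value gate should use raw or BH-adjusted p-values is
genuinely ambiguous in this field's reporting; both are supported
(`useFdr`). The default is the raw p < 0.05 reading, for a concrete
reason: at 3–8 animals per arm with ~5% truly changed genes, BH-adjusted
p-values of genuine 2-SD effects sit far above 0.05, so the FDR reading
makes the per-study consensus and everything downstream of it
structurally empty. The adjusted values are always reported alongside.

`consensusDEGs()` keeps genes called in at least 3 of 4 studies.
Presence, not direction, is what is counted; direction conflicts are
retained but flagged.

# The five meta-analytic methods

All methods run per gene on the common-gene intersection, so the number
of studies k is constant across genes (partial-k genes are rejected by
construction).

1. **Fisher's sum of logs.** S = −2 Σ ln pᵢ over the per-study
   two-sided t-test p-values; the combined p is the upper χ²₂ₖ tail.
   Zero p-values are clamped to 1e−300 rather than propagated.
2. **Random-effects model.** Hedges' g per study — g = J·(m₁−m₂)/s_p
   with J = 1 − 3/(4(n₁+n₂−2)−1) and var(g) = (n₁+n₂)/(n₁n₂) +
   g²/(2(n₁+n₂)) — pooled by DerSimonian–Laird: Q = Σwᵢ(gᵢ−ĝ_FE)²,
   τ² = max(0, (Q−(k−1))/(Σw−Σw²/Σw)), then inverse-variance pooling
   with weights 1/(varᵢ+τ²).
3. **RankProduct.** Genes ranked by log2 fold change per study (rank 1 =
   most up-regulated, ties averaged); RP is the geometric mean of ranks.
   Significance comes from B = 1000 independent shuffles of each study's
   rank vector: p(g) = (1 + #{null RP ≤ RP_g})/(B·n + 1), with a
   percentage-of-false-positives column pfp = p·n/rank(RP). Both
   directions are run and the smaller tail doubled. The rank-shuffle
   scheme (rather than full data resampling) keeps desk-scale runs fast;
   the seed is mandatory.
4. **Weighted Stouffer Z.** zᵢ = Φ⁻¹(1−pᵢ) on one-sided p-values
   oriented toward over-expression in MCAO; Z = Σwᵢzᵢ/√Σwᵢ².
5. **Fixed-effect model.** Inverse-variance pooling of the unmoderated
   Hedges' g with a normal reference.

A gene is a **meta-DEG** when at least 4 of the 5 methods give p < 0.05
(`voteCount()`); both thresholds are parameters.

## Calibration-driven defaults

Two choices inside the method suite were left open by the design and
were settled by null calibration (simulated global null, 2000 genes,
k = 4, 5 + 5 samples — the same check the acceptance suite performs):

* **Moderation is off by default in the REM route.** An empirical-Bayes
  moderated variance (`moderatedVariance()`: scaled inverse-χ² prior
  estimated by method of moments on log sample variances, shrunken
  variance (d₀s₀²+df·s²)/(d₀+df)) is available and tested, including
  hyperparameter recovery. But plugging the shrunken variance into g
  while keeping the analytic var(g) leaves g under-dispersed relative to
  its nominal variance and collapses the REM null rejection rate to
  ~1%; the unmoderated route is markedly better calibrated.
* **Stouffer weights default to √n.** Weighting by 1/var(g) looks
  natural but var(g) contains g²/(2(n₁+n₂)), so the weights
  anti-correlate with the evidence and drag the null rate to 2.5–4%.
  With equal designs √n weighting is the classic equal-weight Stouffer
  and sits near nominal. `weights = "invvar"` remains available.

Two residual calibration facts are worth knowing and are visible in the
acceptance output rather than hidden: inverse-variance pooling of
standardized mean differences is intrinsically conservative at these
group sizes (a formula-level simulation with g = J·√(2/n)·T_df gives
FEM ≈ 3.1% and REM ≈ 2.4% at a nominal 5%), and the vote rule is far
more conservative than any single method because the five statistics are
positively correlated. Neither is an implementation artifact; both
follow from the stated formulas.

# Integration, cross-species intersection, enrichment, network

`integrateSets()` filters meta-DEGs to those additionally called in at
least 3 individual studies — pooled evidence must be visible in the
single datasets. `crossSpeciesCommon()` intersects the two species'
integrated sets by upper-cased symbol (mouse "Timp1" matches rat
"Timp1" and a human-centric "TIMP1" collection); real orthology mapping
is out of scope.

`hypergeomEnrich()` computes, per gene set, P(X ≥ x) for X
hypergeometric(N, K, n) with N the **analyzed universe** — the
common-gene intersection, not the genome, because genes outside the
measured matrices could never have been selected. The raw p < 0.05 gate
is the reported criterion, with a BH-adjusted column alongside.
`extractSubnetwork()` takes the induced subgraph of the DEG list on a
confidence-weighted interaction graph (edges ≥ 0.4 by default, the
common mid-confidence convention) and reports the maximum-degree node(s)
as the hub — degree is the simplest quantitative hub notion and is
flagged as an interpretation, not a claim about biology.

# The synthetic-data generator

`simulateCollection()` is first-class, tested code, not a fixture. Per
species it emulates: k = 4 studies of 8 MCAO + 5 sham samples (the mean
group sizes of the motivating eight-series collection), unit
within-group SD on the log2 scale with gene-specific baselines, 5% true
DEGs (half up, half down) shifting the MCAO mean by δ = 2 SD with
between-study heterogeneity τ² = 0.05, 5% platform-specific gene
dropout per study, optional probe multiplicity (probe noise SD 0.1,
small against the unit within-group SD so collapse is near-lossless),
and 2% missing cells. A second species reuses the first's true DEG
memberships (shared truth) while redrawing all noise. Positive effect =
higher in MCAO = up-regulated.

What it does **not** emulate: array-image artifacts, RNA degradation,
batch effects beyond τ², correlated genes, platform-specific intensity
response, or real orthology structure. Passing tests therefore
demonstrate statistical correctness and wiring of the pipeline, not
performance on real arrays.

The end-to-end recovery metric counts recovered shared true DEGs among
those present in **both** species' common-gene universes — a gene no
platform measured cannot be recovered by any method.

A sobering and intended property of the full chain: with δ = 2 and the
|log2FC| ≥ 1.5 gate, the true effect sits only 0.5 SD above the
fold-change threshold, so each study calls a true DEG with probability
near 0.8, the 3-of-4 consensus lands near 0.8 per species, and the
cross-species intersection (two independent such filters) recovers
roughly half to two-thirds of the analyzable truth. The acceptance run
reports this number as computed; it is a property of the stacked
filtering criteria at realistic sample sizes, not a tuning failure —
single-study fold-change gates are expensive, which is much of the
argument for meta-analysis in the first place.

# Problem sizes and runtime choices

The test suite runs the statistical checks at 2000 genes (null
calibration, power), the pipeline tests at 300–500 genes with B = 150
permutations, and the acceptance suite at the full default scale
(2000 genes per species, B = 1000). These sizes keep a complete run in
the low minutes on one core while leaving binomial error on estimated
rates at a few tenths of a percent. RankProduct cost is linear in
B × n × k; B = 1000 is the default, and the exhaustive two-study oracle
used in tests is exact for any fixture small enough to enumerate.

# Known limitations

* The DL τ² estimator is noisy at k = 4; REM inference is conservative
  there (see above), and no Knapp–Hartung-type correction is applied.
* Vote counting treats the five methods as exchangeable voters although
  they are correlated; the 4-of-5 rule is a reproducibility heuristic,
  not an error-rate guarantee.
* Enrichment uses flat gene sets: no GO topology, term propagation, or
  annotation bias correction.
* Cross-species matching by symbol will silently miss genes whose
  orthologs are named differently.
* The per-study analysis supports exactly two groups; time-course
  structure (reperfusion periods) is collapsed into the MCAO group.
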