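# mcaoMeta

Cross-study meta-analysis of rodent brain-ischemia expression profiles.

Middle cerebral artery occlusion (MCAO) is the standard rodent surgical
model of ischemic stroke; expression microarray series comparing MCAO to
sham-operated animals are numerous but individually tiny (3–24 animals
per arm) and sit on heterogeneous platforms. `mcaoMeta` is for analysts
who want to combine such series the way the stroke transcriptomics
literature does — formally, per species, and with every threshold
explicit — and for methodologists who want the combination statistics
with their calibration measurable on synthetic data.

The package implements, as tested reusable stages:

* **Preprocessing** — log2 transform, quantile normalization
  (average-ties dialect), KNN imputation over mutually observed columns,
  probe-to-gene collapse by the mean, common-gene intersection, per-gene
  standardization, and a numeric RLE quality summary.
* **Five meta-analytic statistics per gene**, combined by vote counting
  (meta-DEG = significant for ≥ 4 of 5 methods at α = 0.05):
  1. Fisher's sum of logs: S = −2 Σ ln pᵢ ~ χ²₂ₖ;
  2. DerSimonian–Laird random-effects pooling of Hedges'
     g = J·(m̄₁−m̄₂)/s_p, J = 1 − 3/(4(n₁+n₂−2)−1),
     var(g) = (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂)),
     τ̂² = max(0, (Q−(k−1))/(Σw−Σw²/Σw));
  3. RankProduct, RP = (Πᵢ rankᵢ)^{1/k}, with rank-shuffle permutation
     p-values and a PFP column;
  4. weighted Stouffer Z = Σwᵢzᵢ/√Σwᵢ² on one-sided p-values;
  5. fixed-effect (inverse-variance) pooling of g.
* **Per-study differential expression** — Welch or Student t,
  BH-adjusted p reported, calls gated by p < 0.05 and |log2FC| ≥ 1.5,
  with ≥ 3-of-4 cross-study consensus.
* **Integration** — meta-DEGs filtered by per-study support,
  case-insensitive cross-species symbol intersection, hypergeometric
  gene-set enrichment against GMT collections over the analyzed-universe
  background, and DEG-induced subnetwork extraction (hub = maximum
  degree) from weighted edge lists.
* **A synthetic multi-study generator** with known ground truth (shared
  true DEGs across species, between-study heterogeneity, platform
  dropout, probe multiplicity, missing values) so the whole pipeline is
  testable offline, plus readers/writers for manifests, expression
  matrices, GMT, edge lists and result tables.

See `vignettes/mcaoMeta-methods.Rmd` for the model details, default
parameters and the reasoning behind every open design choice.

## Worked example

Simulate four mouse studies (8 MCAO vs 5 sham each, 5% true DEGs at
δ = 2 SD), preprocess, meta-analyze, and cross-check against per-study
calls:

```r
library(mcaoMeta)
sim  <- simulateCollection(simConfig(n_genes = 1000, seed = 42))
sim$studies[[1]]
#> StudyExpression 'mouse_S1' (gene level)
#>  940 features x 13 samples (8 MCAO / 5 sham)
#>   missing entries: 258

prep <- preprocessStudies(sim$studies)
length(prep$common)          # genes measured in all four studies
#> [1] 807

meta <- metaAnalyze(prep, B = 500, seed = 43)
as.data.frame(meta[order(meta$p_fem)[1:4],
                   c("p_fisher", "p_rem", "p_rankprod", "p_stouffer",
                     "p_fem", "pooled_g", "votes")])
#>           p_fisher    p_rem p_rankprod p_stouffer    p_fem pooled_g votes
#> Gene00049 5.80e-08 1.70e-10   4.96e-06   1.43e-09 1.70e-10     2.36     5
#> Gene00146 7.03e-09 2.45e-05   4.96e-06   2.05e-10 2.71e-10     2.44     5
#> Gene00314 2.04e-08 1.96e-05   4.96e-06   4.37e-10 2.84e-10    -2.43     5
#> Gene00622 1.04e-07 3.12e-10   4.96e-06   1.55e-09 3.12e-10     2.31     5
sum(meta$is_meta_deg)
#> [1] 46

de <- lapply(names(prep$studies), function(id)
    deAnalyze(exprs(prep$studies[[id]]), groups(prep$studies[[id]]),
              testMatrix = prep$standardized[[id]], studyId = id))
integ <- integrateSets(metaDegs(meta), de, minSupport = 3)
length(integ)                              # meta-DEGs seen in >= 3 studies
#> [1] 24
mean(integ %in% c(sim$truth$degUp, sim$truth$degDown))
#> [1] 1
```

Of 46 meta-DEGs, the 24 that are also called in at least three
individual studies are all true positives: per-gene pooled effects
(`pooled_g` ≈ ±2.4, the simulated δ after bias correction), five
near-unanimous p-values, and the integration step trading recall for
precision exactly as designed. `runPipeline()` chains the same stages
for two species sharing a simulated truth and adds consensus,
enrichment, subnetwork extraction and the cross-species intersection,
writing every stage table plus a machine-readable run log.

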