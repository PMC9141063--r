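# nestedSelect

Nested feature selection and classification for multi-site case/control
bulk RNA-seq cohorts.

Whole-blood transcriptome cohorts for disease classification are
imbalanced (roughly 2:1 cases to controls), collected across many clinical
sites, confounded by technical covariates (site, sex, RNA integrity), and
carry a per-gene disease signal that is individually very weak even when a
multivariate classifier over thousands of genes discriminates usefully.
`nestedSelect` packages that analysis end to end for R users working with
Bioconductor containers:

* **Preprocessing** (`preprocessCounts()` and its stages): biotype
  filtering to protein-coding genes + lincRNAs, blacklist removal,
  low-expression filtering (more than 5 counts in ≥10% of samples),
  median-of-ratios size factors, label-independent filtering on mean
  normalized count, the closed-form variance stabilizing transformation
  for the negative-binomial trend α(μ) = a₁/μ + a₀,

  v(n) = log₂[ (1 + a₁ + 2a₀n + 2√(a₀n(1 + a₁ + a₀n))) / 4a₀ ],

  exclusion of sites with fewer than two controls, control-anchored
  site-batch removal (jackknife-matched, so the correction leaves no
  class-asymmetric imprint a classifier could exploit), and sex/RIN
  residualization.
* **Univariate baseline** (`nbWaldTest()`): per-gene NB GLM with log link,
  size-factor offsets, trend dispersions, Wald z for the disease
  coefficient (lfc = β/ln 2, positive = up in cases), BH adjustment.
* **Nested learning scheme** (`runNestedCv()`): repeated stratified
  k-fold cross-validation; inside every training fold, B seeded random
  forests (√f features per split, impurity importance) are averaged into a
  gene ranking, and an XGBoost classifier on the top-C genes is evaluated
  on the held-out fold for each C in a sweep. The result is the median
  AUC-versus-C curve with its mean absolute deviation and the maximizer
  C\*.
* **Stability and evaluation**: selection frequency of genes across
  repetitions with the ≥70% signature rule (`selectionFrequency()`,
  `frequentGenes()`), confusion-matrix metrics, pair-counting ROC AUC,
  and Wilcoxon comparisons of predicted probabilities between
  endophenotype subgroups (`endophenotypeTest()`).
* **Synthetic cohorts with ground truth** (`simulateCohort()`):
  negative-binomial counts with a dispersion–mean trend, multi-site batch
  offsets, sex/RIN effects, log-normal library sizes, endophenotype
  fields, and a small planted set of informative genes — so every stage is
  testable without access-controlled data.

`runPipeline()` orchestrates all stages into one reproducible run (TSV/JSON
outputs plus a manifest) under a single master seed.

## Worked example

```r
library(nestedSelect)

se <- simulateCohort(simConfig(nCases = 60, nControls = 40, nGenes = 250,
                               nSites = 4, nInformative = 15,
                               lfcRange = c(1, 1.5), fracSmallSites = 0.25,
                               seed = 19))
pp <- preprocessCounts(se)          # logs each stage's gene/sample counts
cv <- runNestedCv(correctedExpr(pp), pp$label, cGrid = c(10, 30, 80),
                  rfCfg = rfConfig(nTrees = 60, nRepetitions = 2),
                  boostPar = boostParams(nRounds = 40),
                  k = 4, nRep = 2, seed = 3)
cvCurve(cv)
#> AucCurve over C in {10, 30, 80}, 2 repetition(s)
#>   max median AUC 0.944 (MAD 0.003) at C* = 10
```

The cohort has 15 planted genes with |log2 fold-change| in [1, 1.5] among
250; after preprocessing, cross-validated classification peaks at a median
AUC of 0.944 (mean absolute deviation 0.003 across the two repetitions)
using the 10 top-ranked genes per training fold — the planted signal is
found, and the curve's maximizer sits near the true signal size. The
univariate baseline on the same cohort ranks planted genes first:

```r
de <- nbWaldTest(pp, sizeFactors = S4Vectors::metadata(pp)$sizeFactors,
                 dispersionTrend = S4Vectors::metadata(pp)$dispersionTrend)
head(de[order(de$adj_p), c("gene_id", "lfc", "lfc_se", "adj_p")], 3)
#>        gene_id       lfc    lfc_se        adj_p
#> G00157  G00157  1.516142 0.2306501 6.297408e-09
#> G00106  G00106 -1.427040 0.2306949 3.274890e-08
#> G00216  G00216  1.350203 0.2194917 3.274890e-08
```

Estimated fold-changes (1.52, −1.43, 1.35) sit within one standard error
of the planted magnitudes, with the sign convention positive = higher in
cases. Selection stability across the cross-validation repetitions is
summarized by `selectionFrequency(cv@topSets)`, whose `frequency` column
feeds the ≥70% signature rule.

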