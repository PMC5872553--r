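# blockselect

Bayesian feature selection for two-class Gaussian data with block-diagonal
covariance structure, aimed at biomarker discovery from expression data
where markers act in correlated groups and individually weak genes matter.

## The model and the algorithms

Features are partitioned into blocks: features within a block are
dependent, blocks are independent, and each block is either *good* (its
joint distribution differs between the classes — a marker block) or *bad*
(identical in both classes). Blocks are jointly Gaussian with
Normal-Inverse-Wishart priors on (mean, covariance), so every block has a
closed-form marginal likelihood; for a feature set *G* the package scores

    log H(G) = -1/2 ( κ*₀ log|S₀*| + κ*₁ log|S₁*| − κ* log|S*| ),

the class-split versus pooled evidence ratio built from the conjugate
posterior scatter matrices S* and degrees of freedom κ*. Normalizing H
over all feature pairs yields approximate set posteriors π̃\*(G), feature
marginals π̃\*(f) (which sum to 2), and the posterior factor
β̃(f) = mean over f′ of π̃\*({f,f′})/π̃\*({f′}) — a Bayes-factor-like score
of what f adds to a model that already contains another feature.

Five selectors are implemented on top of these scores:

| function           | algorithm    | output |
|--------------------|--------------|--------|
| `cmnc_obf()`       | CMNC-OBF     | top-D features by closed-form independent-feature posterior |
| `two_mnc_robust()` | 2MNC-Robust  | top-D features by pair-marginal π̃\*(f) |
| `remain()`         | REMAIN       | variable-size set via recursive marginal posterior inflation (thresholds T₁, T₂) |
| `pofac()`          | POFAC        | top-D features by posterior factor β̃ |
| `spm()`            | SPM          | family of detected good blocks, grown by the seed-growing GSG criterion C₁ with threshold T₃ = t₁·n^(t₂·\|U\|), stopping when all β̃ < T₄ |

Both the Jeffreys (non-informative) and a proper NIW prior are supported
(`niw_prior_spec()`). Two synthetic generators —
`simulate_bayesian_dataset()` (the hierarchical NIW block model) and
`simulate_microarray_dataset()` (global/heterogeneous markers,
low/high-variance non-markers) — and a replicated evaluation harness
(`run_replicates()`, `score_selection()`) support calibration studies.
The pairwise engine is vectorized in C++ and handles 5000-feature working
sets (12.5 million pair evidences) in a few seconds.

## Worked example

```r
library(blockselect)

ds <- simulate_microarray_dataset(
  microarray_config(n_features = 1000, n_gm = 10, n_hm = 20, n_hv = 400, k = 5),
  n = 100, seed = 42)
ds
#> simulated_dataset (microarray model): 100 x 1000, 30 marker(s)

eng <- score_engine(ds$sample)          # shared O(p^2) score tables

sel <- spm(ds$sample, t1 = 100, t2 = 2, T4 = 1e4, engine = eng)
sel
#> spm: 30 feature(s) selected in 6 block(s)
#>   top: f228, f146, f49, f128, f634, f561, f997, f321, f74, f153, ...
head(sel$blocks, 2)
#> [[1]]
#> [1] "f228" "f146" "f49"  "f128" "f634"
#> [[2]]
#> [1] "f561" "f997" "f321" "f74"  "f153"

score_selection(sel$selected, ds$truth)
#>   markers_found nonmarkers_found correctly_labeled n_selected n_markers n_features
#> 1            30                0              1000         30        30       1000
```

SPM recovered all 30 planted markers, grouped into exactly the six
generating blocks of five correlated features, with no false positives:
`markers_found` counts true markers selected, `nonmarkers_found` the
non-markers selected, and `correctly_labeled` = TP + TN is the number of
features whose good/bad label is correct (1000 = perfect). The same engine
serves the other selectors:

```r
rem <- remain(ds$sample, T1 = 0.05, engine = eng)   # T2 defaults to n
score_selection(rem$selected, ds$truth)
#>   markers_found nonmarkers_found correctly_labeled n_selected n_markers n_features
#> 1            23               25               968         48        30       1000

round(sort(posterior_factor(ds$sample, engine = eng), decreasing = TRUE)[1:5], 1)
#>         f228         f561         f128         f153         f165
#> 1.540510e+21 1.279480e+20 1.004449e+12 1.538965e+11 6.413960e+10
```

Marker posterior factors sit 10–20 orders of magnitude above the ~1 level
of null features, which is what makes fixed thresholds such as T₄ = 10⁴
workable across sample sizes.

A thin command-line wrapper over these functions ships in
`inst/scripts/blockselect` (`simulate` and `select` subcommands).

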