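---
title: "Causal-metric biomarker panel selection: models and methods"
author: "CausalPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-metric biomarker panel selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CausalPanel)
```

# The problem

High-throughput antibody arrays measure reactivity against thousands of
proteins per serum sample. For a diagnostic product only a handful of
those analytes can be used, so the statistical task is: given a samples
× analytes matrix of non-negative reactivities and a case/control label
per sample, pick a small panel of K biomarkers and quantify how well a
classifier built on that panel discriminates cases from controls.
CausalPanel implements a pairwise *causal metric* for this selection
step, a chi-square univariate baseline for ablation, and a
leave-one-out cross-validated (LOOCV) evaluation pipeline reporting AUC
and sensitivity at fixed specificity.

# The causal metric

All causal scoring operates on γ-binarized data: indicator
b[s, i] = 1 exactly when the reactivity of analyte i in sample s
*strictly exceeds* the threshold γ. Reactivities on these arrays are
normalized so that typical values sit near 1; the package's default grid
for γ is {0.6, 1.0, 1.4, 1.8} with 1.4 the usual default. Strict
inequality is the documented contract; an observation exactly at γ is
negative.

Three quantities are computed per analyte:

1. **s² score.** Treat the indicator as a case-predictor:
   s²(i) = sensitivity × specificity = (TP/#cases) × (TN/#controls).
   An all-zero indicator scores 0; an indicator identical to the label
   scores 1.

2. **Eligibility.** Analyte i is eligible when s²(i) ≥ mean(s²) over
   all analytes. The comparison is deliberately *inclusive*: in the
   package's 4×4 worked example (`workedExample()`), an analyte whose
   s² equals the mean (0.25) is counted eligible, and the downstream
   selection depends on that. With all s² equal, every analyte is
   eligible.

3. **Relatedness.** R_i is the set of analytes j ≠ i, both i and j
   eligible, such that at least one *case* sample is indicator-positive
   for both. The relation is symmetric. Restricting both sides to the
   eligible set follows the rule that only above-average analytes
   participate in causal scoring at all.

The causal metric is the average increase of a composite score when the
analyte is present, taken over its related analytes:

causal(i) = Σ_{j ∈ R_i} [ f(i, j) − f(¬i, j) ] / |R_i|

with f(a, j) = s²(¬a ∨ j), i.e. each term is
s²(¬i ∨ j) − s²(i ∨ j). This is a sensitivity×specificity analogue of
average pairwise causal significance: instead of conditional
probabilities of an effect, the composite indicator's diagnostic score
plays the role of the response function. Analytes that are ineligible
or have an empty R_i receive NaN, are excluded from ranking, and are
never padded in as zeros.

**Choice of f.** The literature this metric descends from defines the
score only as "based on" the s² measure, and several Boolean
compositions are conceivable. The package's default ("or") is the one
composition that reproduces both signed values of the worked example
(+0.25 for B1, −0.25 for B3), and is therefore the reference
definition. Two alternatives are exposed as configuration knobs on
`pairMeasure()` and `causalScores()`: "and" (s²(i∧j) − s²(¬i∧j)) and
"conditional" (s² of i restricted to samples with j = 1 minus j = 0;
NaN when a restriction loses a class). They are provided for
sensitivity analysis, not as defaults.

**Ranking.** Valid analytes are ordered by |causal| descending. Using
the magnitude rather than the signed value is again anchored to the
worked example, where the analyte with causal = −0.25 and higher s² is
picked ahead of the one with +0.25: a large negative average change is
evidence of association just as a large positive one is. Ties on
|causal| break by s² descending, then by analyte position ascending, so
rankings are fully deterministic and column-permutation equivariant.
`selectTopK()` truncates to K and warns when fewer than K valid
analytes exist.

**Computation.** Per-analyte scores are independent, and for the
default variant every pairwise term depends only on four analyte ×
analyte count matrices (case/control co-absence and one-sided
exceedance), so `causalScores()` computes the full score set from four
`crossprod()` calls. The test suite asserts bit-identity between this
vectorized path and the literal pair-by-pair evaluation.

# The univariate baseline

The ablation baseline scores each analyte by the chi-square statistic
on per-class value totals: O_c = Σ of the analyte's values in class c,
E_c = total × n_c/n, score = Σ_c (O_c − E_c)²/E_c. This is the
feature-selection convention for non-negative features; on a binarized
matrix it reduces to the goodness-of-fit chi-square of the per-class
positive counts against the class proportions (no continuity
correction). The statistic is used for ranking only — selection is
top-K, not significance-gated — so no p-value threshold is applied.
Degenerate analytes (zero total) score NaN and rank last. The "(B)"
variants score the binarized matrix; the default scores raw values.

# Classifiers

Five classifier families share one train/score contract
(`fitModel()` / `predictScore()`, case-probabilities in [0, 1]):

| kind | implementation | defaults |
|------|----------------|----------|
| LR   | `stats::glm.fit`, binomial IRLS | — |
| RF   | `randomForest` | 10 trees, seed 0 |
| MLP  | `nnet` | 1 hidden layer × 32 logistic units, decay 1e-4, maxit 300, standardized inputs, seed 1 |
| GBT  | `xgboost` | depth 2, learning rate 1.0, 10 rounds, exact greedy splits, no L2 penalty, seed 0 |
| XGB  | `xgboost` | depth 2, learning rate 1.0, 10 rounds, library defaults, seed 0 |

Design notes. The boosted-tree defaults (depth 2, learning rate 1.0,
10 estimators) are the package's reference configuration for both
boosting variants; GBT mirrors classic gradient boosting (exact
splits, unregularized), XGB keeps XGBoost's regularized defaults, and
the two demonstrably produce different models. The MLP is R's
established single-hidden-layer feed-forward network; deeper
ReLU stacks belong to GPU frameworks outside this package's dependency
footprint, and at n ≈ 100 samples a 4-layer network is badly
overparameterized anyway — the hidden-layer size, decay and iteration
cap are exposed as hyperparameters. The iteration cap guarantees
deterministic termination. Probabilities are not calibrated: every
reported metric is rank-based (ROC-derived), so calibration would not
change any result.

Determinism: each model's seed is part of its `modelSpec()`; fitting
saves and restores the caller's RNG state, so identical spec + data
give bit-identical score vectors and whole LOOCV runs are reproducible
run to run.

# Evaluation

`loocvRun()` holds out each sample once. *Feature selection is
recomputed inside every fold* from the n−1 training samples only — the
single most important guard against selection leakage, asserted
directly by a test that re-derives fold panels from scratch. The
classifier sees raw, binarized, or min-max scaled inputs according to
`selectionParams()`; scaling parameters are fit on the training fold
and applied to the held-out sample (values below the training minimum
clamp at 0).

- **Test AUC** pools the n out-of-fold scores into one ROC (standard
  for LOOCV, which yields a single score per sample) and integrates by
  trapezoid over the exhaustively enumerated thresholds; this equals
  pairwise concordance with ties at one half, and the suite checks the
  identity to 1e-12 against an O(n²) oracle.
- **Train AUC** is the mean of per-fold training AUCs (the refit-on-all
  alternative would mix selection into evaluation).
- **Sen@90 / Sen@80** is the maximum sensitivity over achievable
  operating points with specificity ≥ the target, without
  interpolation — conservative and exactly reproducible; a degenerate
  constant score vector yields 0.
- **Selection frequency** is the fraction of folds whose panel contains
  each analyte, the stability diagnostic for small-K panels.
- **`rocBand()`** is a class-stratified percentile bootstrap (default
  1000 resamples) of the ROC step function evaluated on the observed
  FPR grid; "5% error" bands are alpha = 0.05. The construction is the
  package's own choice — resampling whole samples within class keeps
  the case/control ratio fixed and never produces a single-class
  resample.
- **`probabilityIncrease()`** reports
  100 × (P(case | panel present) − P(case)) / P(case), with presence
  defined as *all* panel indicators positive (default) or *any*; both
  modes are exposed because the secondary-analysis definition is not
  pinned down in the source literature. It errors, rather than
  returning 0, when no sample shows presence.

`sweepGrid()` crosses classifiers × selection methods × binarization
flags (× γ × K): the canonical 5 × 2 × 2 grid is the "20 approaches"
comparison. Cell failures are recorded per row, and a checkpoint file
makes interrupted sweeps resumable.

# The synthetic generator

`simulateAnalytes()` emulates the structure of a balanced
antibody-array screen rather than any particular dataset: 50 cases + 50
controls × 3440 analytes by default. Background reactivity is
log-normal with meanlog 0 — pinning the median at 1, as in normalized
array data — and sdlog 0.3, so values concentrate near 1, roughly 13%
of background entries exceed γ = 1.4 and about 1% exceed the
seropositivity cutoff of 2. Informative analytes follow seropositivity
semantics, because binarization-based selection is the method under
test: a per-sample Bernoulli presence (defaults p_case = 0.8,
p_control = 0.1) switches the draw to an elevated log-normal component
(median 4, sdlog 0.5), whose mass sits above the entire γ grid.
Analytes are independent; planted positions are randomized and returned
separately so recovery tests cannot leak into the pipeline.

What the generator does *not* emulate — and therefore what passing
recovery tests do not establish about real data: the extreme right tail
of raw arrays (hundreds of units; the generator's maxima are in the
tens), correlation among analytes (IgG/IgA pairs against the same
protein are strongly dependent in reality), batch structure, and any
relationship between analytes and organisms. Recovery results here
certify the machinery, not field performance.

Problem sizes used by the shipped checks were chosen to exercise the
stated recovery conditions at comfortable runtime: 100 samples × 300
analytes with 5 planted markers for recovery and LOOCV (20 generator
seeds for the recovery rate), 16–20 samples × 25–60 analytes for
contract and grid-shape tests.

# Numerical and degenerate-input conventions

- Binarization: strict `>`; monotone in γ; idempotent on 0/1 input.
- Min-max scaling: constant columns map to all zeros.
- s² requires both classes; single-class inputs error everywhere rather
  than returning a default.
- NaN causal scores are exclusions, not zeros; `rankCausal()` errors
  when nothing is rankable (a fold of an LOOCV run propagates that
  error; the sweep records it per cell).
- All tie-breaks (ranking, thresholds) are documented and
  deterministic; no operation depends on hash or insertion order.
- File round trips write 17 significant digits so values survive
  bit-for-bit.

# Limitations

- The default pair measure is anchored to a single worked example; with
  richer published reference computations a different composition might
  prove intended. The variant knob exists for exactly that reason.
- Pooled-LOOCV test AUC on null data is noisy and slightly pessimistic
  at small n (in-fold selection anti-correlates the held-out score);
  interpret single-run AUCs on small cohorts with care.
- The chi-square-on-sums statistic is scale-equivariant, not
  scale-invariant: multiplying one analyte's unit rescales its score.
  Min-max scaling (`minmaxScale = TRUE`) is the provided remedy.
- No combinatorial panel search: ranking is marginal, top-K.
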