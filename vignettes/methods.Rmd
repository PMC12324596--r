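---
title: "Methods: from raw aptamer fluorescence to five-class disease probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw aptamer fluorescence to five-class disease probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`proteoclass` turns a multi-cohort aptamer-proteomics study — samples ×
analytes of relative fluorescence units (RFU), with per-sample diagnosis,
age, sex, batch and optional CSF biomarkers — into calibrated five-class
disease probabilities (CO, AD, PD, FTD, DLB), with quality control,
biomarker-based label refinement, feature selection, class rebalancing,
Shapley explanation and zero-shot scoring of unseen diagnostic groups.
This vignette records the model, its assumptions, the tunable parameters,
and the design decisions taken where the design was genuinely open.

## The data model and its assumptions

RFU intensities are treated as log-normal: all modelling happens on
`log10(RFU)`, where analyte spreads are approximately symmetric and
additive structure (batch offsets, disease effects, covariate effects) is a
reasonable first-order description. The synthetic generator
(`sim_config()`, `simulate_study()`) makes exactly this structure true:

log10(RFU) = analyte baseline + batch offset + disease effect
           + age/sex terms + N(0, noise_sd),

anti-logged to the RFU scale, with buffer (blank) wells drawn ~2 decades
below the analyte baseline, independent of disease. This is deliberate:
under the generator, the downstream linear differential-abundance model is
*correctly specified*, so calibration tests (null p-value uniformity,
coverage of effect estimates) have exact expectations. Zero-shot groups are
generated as convex mixtures of trained-class effect vectors (e.g. PD
dementia = 0.7·PD + 0.3·AD); the mixture weights are simulation parameters,
not claims about biology.

What the generator does *not* emulate: vendor-side normalization
(hybridization controls, plate-median correction — assumed done upstream),
plate layouts, longitudinal sampling, heavy-tailed or analyte-dependent
noise, and correlated analytes beyond the shared disease effects. Passing
tests therefore demonstrate that the pipeline's logic and statistics are
correct under its stated assumptions — not that real cohort performance
will match.

### Generator defaults (the study conditions)

200 samples for each of CO/AD/PD and 30 for FTD/DLB (severe imbalance of
the rare dementias), 500 analytes, 3 batches with per-batch-per-analyte
offsets of SD 0.2 log10 units, per-disease effects of 1.0 log10 unit on 20
analytes of which 5 are shared by all four diseases (signs random),
residual SD 0.3, ages uniform on 50–90, sex Bernoulli(0.5), age slope
0.002 log10/year and sex effect 0.1 log10 on a random 10% of analytes
each, 2% missingness and 0.5% injected multiplicative outliers where
artifacts are requested, 10 buffer wells. Biomarkers: Aβ42 components at
1000 (normal) vs 450 (pathological, SD 120), pTau at 20 vs 60 (SD 8), with
pathological fractions 0.95 (AD), 0.15 (CO), 0.25–0.40 (others). These
were chosen once as a realistic regime for a mid-sized multi-cohort CSF
study with clearly separable biomarker components, and are not revisited
per test.

## Quality control

One QC sweep applies, in order: non-human-target / scale-factor (> 0.5) /
median-CV (> 0.15) filters; the limit-of-detection filter in plasma mode
(LOD = buffer mean + 2·sample SD per analyte; an analyte is removed when
≥ 85% of samples read below its LOD; CSF skips the filter because CSF
protein abundance is low); per-analyte Tukey-fence outlier masking; then
the two-pass call-rate filter (analytes then samples below 65%; recompute;
analytes then samples below 85%). Boundary conventions follow the
narrations that define them: CV and scale-factor comparisons are strict
(`>`), call-rate comparisons strict (`<`), the LOD fail-fraction is `>=`.
Masking precedes call-rate computation so masked outliers count as missing.

Numerical choices worth recording:

* **Quantile convention** — type 7 (linear interpolation), a config field.
* **IQR masking scale** — fences are computed on `log10` intensities by
  default (`iqr_scale = "log10"`). On the raw scale, Tukey fences applied
  to log-normal data flag ~6% of every analyte's upper tail as "outliers",
  and an up-shifted disease subpopulation in a rare class can be masked
  wholesale and then dropped by the call-rate filter — the mask destroys
  exactly the biology the pipeline is meant to find. Log-scale fences are
  symmetric, still catch injected technical outliers (≥ 95% at 10× the
  fence in tests), and spare biological shifts. `iqr_scale = "raw"` is
  available for strict comparability.
* **Fixed-point cascade** — masking changes the quantiles a second
  application would see, and removing samples shifts per-analyte
  distributions, so a single sweep is not idempotent. `qc_pipeline()`
  therefore repeats the sweep until the matrix stabilizes (sweep index
  recorded in the decision ledger; almost always 1–2 sweeps). Each sweep
  performs exactly one call-rate recalculation; the repetition makes the
  full pipeline a fixed point, so running it on its own output changes
  nothing.
* **Degenerate inputs** — analytes with < 4 observed values skip the mask
  with a record; constant-in-batch analytes are z-scored to 0 with a
  record; an entirely filtered matrix is an explicit error.

Harmonization across assay panels intersects analyte sets, concatenates
samples and re-applies the 85% analyte call-rate filter. Normalization is
log10 followed by per-batch, per-analyte z-scoring (batch key defaults to
the batch label; mean 0, SD 1 over non-missing entries). PCA for
diagnostics and covariates substitutes per-analyte means for missing values
*for that computation only*, and exposes rotation/center so held-out
samples are projected, never refit.

## Biomarker dichotomization and eligibility

CSF Aβ42 and pTau are dichotomized by univariate two-component Gaussian
mixtures (`mclust`, equal- and unequal-variance models, best BIC; its
deterministic hierarchical initialization replaces random restarts).
Assignment is by maximum posterior; the crossing point of the two weighted
component densities is reported for audit. "Positive" is the *low*
component for Aβ42 (amyloid) and the *high* component for pTau (tau).
Samples with fitted component means closer than half the pooled SD get a
unimodality warning. A caution on separations: at 3 SD between component
means, the Bayes-optimal assignment error of an equal mixture is already
≈ 6.7%, so high-agreement recovery is only expected for well-separated
markers (the defaults are ≈ 4.6 SD for Aβ42 and 5 SD for pTau).

Training eligibility encodes biomarker confirmation: in CSF, AD cases must
be A+T+ and controls A−T−; PD, FTD and DLB enter on clinical diagnosis
alone (no validated fluid biomarkers exist for them). In plasma, AD cases
need at least one positive among CSF AT status, amyloid PET and plasma
pTau217; controls must be negative on all *available* markers (the
alternative "any one negative" reading is a config switch, since the
source wording is a disjunction). Intermediate AT profiles and unconfirmed
AD/CO are kept for benchmarking only. GMMs are fitted pooled per fluid;
per-cohort fitting can be done by calling `gmm_dichotomize()` per subset.

## Feature selection

Three stages, fitted on the training partition only (see "leakage" below):

1. **Differential abundance** per disease:
   `protein ~ status + age + sex + PC1 + PC2` by OLS over that disease's
   cases plus the shared control set; β is the status coefficient on the
   z-scored log10 scale; two-sided p; BH-FDR is reported but *not* used for
   selection — the carry-forward criterion is nominal p < 0.05, and the
   union over diseases is taken. Analytes with < 10 usable observations are
   skipped with a record.
2. **Variance threshold** 0.01 (population convention, strict `>`).
3. **ANOVA F-test** across the five classes on non-missing values
   (pairwise-complete; nothing is imputed), top-k by F with ties broken by
   analyte identifier. k defaults to 400 (CSF) / 700 (plasma) at full
   panel scale; the synthetic studies use k = 130 (twice the number of
   truly affected analytes).

A property worth knowing: when disease effects are large and dense, the
leading PCs of the normalized matrix are themselves disease directions
(batch variance has already been removed by z-scoring), so adjusting for
PC1/PC2 partially absorbs the very signal being tested and the union stage
can miss a few truly affected analytes. This is an inherent feature of the
covariate model, not an implementation artifact; the F ranking, which does
not adjust for PCs, recovers the affected set essentially completely under
the study conditions.

**Leakage** — PCs and the whole selection cascade are fitted on the 70%
training partition only, and test samples are projected onto the fitted PC
axes (`selection = "split_safe"`, the default). A pooled mode
(`"pooled"`) reproduces the literal select-then-split order some analyses
use; the split-safe default was chosen because pooled selection optimistically
biases held-out metrics — visible here in the zero-effect calibration
study, whose per-class AUCs must stay at chance.

## Classification

`nd_fit()` is the package's central modelling function: stratified 70/30
split per class (deterministic given the seed), SMOTE + Tomek-link
rebalancing of the training partition, boosted-tree training, held-out
scoring. The test partition is never rebalanced, imputed or otherwise
altered.

* **SMOTE** interpolates synthetic minority samples between same-class
  nearest neighbours (k = 5, reduced to class size − 1 with a warning)
  until every class reaches the majority count; **Tomek links**
  (cross-class mutual nearest neighbours) are then removed on both sides.
  SMOTE needs complete vectors, so missing entries are filled with the
  per-class training median *inside the rebalancing step only*; the
  trained model itself passes missing values through the trees natively at
  prediction time (default split directions), and a feature column missing
  in every training row is an explicit error.
* **Engine** — the ensemble is trained with xgboost under the fixed
  hyperparameters (rounds 300/400 by fluid, depth 20, η = 0.05, seed 42,
  single thread for bitwise determinism). The minimum-leaf-size control is
  mapped to `min_child_weight = 10`; xgboost thresholds the leaf *hessian
  sum* rather than a sample count, so this is an approximate translation
  of a count-based parameter — conservative late in training, when
  per-sample hessians shrink. Probabilities are renormalized by their row
  sum in double precision so the simplex invariant holds to 1e-9.
* **Ties** at argmax break in the fixed class order (CO, AD, PD, FTD,
  DLB), which is serialized with the model.

`zero_shot_apply()` scores samples from labels outside the five classes
with the frozen model and summarizes each group by per-class mean
probability with a percentile bootstrap 95% CI (1000 resamples,
seed-controlled) and the argmax assignment fractions.

## Explanation

Shapley attributions are computed tree-exactly (TreeSHAP,
tree-path-dependent expectations, no reference dataset) on the model's
margin (pre-softmax) scale, where the values are additive and the
efficiency identity Σ_i φ_(n,i,k) + base_k = margin_(n,k) holds. The
margin scale was chosen because tree-exact values are defined there;
probability-scale attributions would require a further approximation.
Contributions are stored by the tree library in single precision, so the
efficiency identity is verified relative to the margin magnitude (residuals
are at the 1e-7 relative level). Overall importance is
I_i = (1/K) Σ_k (1/N) Σ_n |φ_(n,i,k)|, ranked descending with identifier
tie-breaks; per-class rankings export per-sample values for beeswarm-style
plotting.

## Evaluation

One-vs-rest ROC AUC uses the class's probability column as the score
(`pROC`; the test suite cross-checks against O(n²) Mann–Whitney pair
counting). PR AUC is average precision (step interpolation). Macro AUC is
the unweighted mean of per-class AUCs; weighted AUC weights by test-set
class prevalence — the standard convention, recorded here because
"weighted" is otherwise ambiguous. One-vs-all binarization calls a sample
positive for the target class iff that class is its argmax, so the five
positive sets partition the samples. The benchmark logistic regression
(AD vs CO on age, sex F=0/M=1, and one binary marker; complete cases;
stratified 70/30) provides the biomarker comparison standard.
Concordance tests route by phenotype type: Pearson for continuous,
rank-sum for two ordinal groups, Kruskal–Wallis with pairwise rank-sum
follow-ups for three or more (disease-probability distributions are
non-normal), and Welch's unequal-variance t-test for approximately normal
phenotypes contrasted between predicted classes. The two-group test is the
rank-sum (Mann–Whitney) test for independent groups, even where source
descriptions name a sign-rank test, which is defined for paired data.

## Problem sizes

The bundled studies were sized so the whole test suite and the acceptance
script each run comfortably on a single CPU: 500 analytes, ~1200 samples
in the strong-signal study (including 530 zero-shot samples), 1000 samples
in the zero-effect study, GMM recovery at n = 1000, benchmark logistic at
n = 600. At these sizes the full pipeline (QC through SHAP) takes well
under a minute.

## Known limitations

* The simulator's independence and normality assumptions are favourable to
  the pipeline; real panels have correlated analytes, batch-by-analyte
  interactions and heavier tails.
* min_child_samples → min_child_weight is an approximate cross-engine
  translation (see above).
* Multi-threaded training is supported by xgboost but not used: run-to-run
  determinism is only guaranteed single-threaded.
* FTD/DLB metrics at the study's rare-class sizes (9 test samples) are
  near-degenerate point estimates; they are reported, not interpreted.
* Cox/Kaplan–Meier progression modelling, vendor normalization and figure
  styling are out of scope.
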