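---
title: "Methods: the dnamclock DNA methylation age framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dnamclock DNA methylation age framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamclock)
```

# The model

DNA methylation at many CpG dinucleotides drifts with age, some sites
gaining methylation and some losing it.  An *epigenetic clock* exploits
this: the age of a sample is estimated as a sparse weighted average of
CpG beta values (methylated fraction in $[0,1]$ from Illumina-style
arrays), mapped through a calibration function.  Formally, for a sample
with beta values $\beta_1, \dots, \beta_p$ the clock computes the linear
score

$$ s = b_0 + \sum_{i \in \mathcal{C}} w_i \beta_i $$

over the clock CpGs $\mathcal{C}$ and reports the DNAm age
$F^{-1}(s)$, where $F$ is the age calibration transform below.  The
weights are obtained by elastic-net regression of $F(\text{age})$ on the
training beta matrix, which performs variable selection (most CpGs get
weight exactly zero) and shrinkage simultaneously.

## The calibration transform and the tick rate

Methylation change per calendar year is much faster during growth than
in adulthood.  The clock is therefore linear not in years but in a
transformed age scale with a knot at `adult_age` (default 20 years):

$$ F(a) = \begin{cases}
  \log(a + 1) - \log(a_\ast + 1), & a \le a_\ast \\
  (a - a_\ast) / (a_\ast + 1),    & a > a_\ast
\end{cases} $$

with natural logarithms and $a_\ast$ = `adult_age`.  The $+1$ inside the
logarithm is required for $F(0)$ to be finite (age 0 — cord blood — is a
legitimate input); with it, both branches meet at the knot with value 0
and derivative $1/(a_\ast + 1)$, so $F$ is continuous, strictly
increasing and $C^1$.  The derivative of $F$ is the *tick rate* of the
clock: proportional to $1/(a+1)$ during development, constant
afterwards.  `inverse_transform_age()` applies the exact inverse and
deliberately does not clip: strongly accelerated samples (e.g. cancer)
may map beyond any human lifespan, and negative DNAm ages are possible
for scores below $F(0)$.  The transform's domain is chronological age
$\ge 0$; consequently the round-trip identity on the transformed scale
holds on $[F(0), \infty)$.

# Fitting

`fit_clock()` regresses $F(\text{age})$ on probes as an elastic net with
mixing parameter $\alpha = 0.5$ (equal L1/L2 blend, the standard choice
for correlated methylation predictors) and picks the penalty $\lambda$
by k-fold cross-validation (default 10) minimizing mean squared error on
the transformed scale.  The one-standard-error rule is *off*: the
original multi-tissue clock was tuned to the CV minimum, and on our
synthetic scenarios the 1-SE rule prunes genuinely causal CpGs.
Decisions that matter in practice:

* **Standardization.**  Predictors are standardized internally for the
  penalty to act evenly, but coefficients are reported on the raw beta
  scale, so a serialized coefficient table plus intercept is sufficient
  for prediction anywhere.
* **Fold assignment.**  Folds are drawn from the run seed and stratified
  by `dataset_id` when present, so every fold sees every batch;
  otherwise a plain random split.  Identical inputs and seed give
  bit-identical models (solver tolerance pinned at `thresh = 1e-10`).
* **Missing values.**  Probes with `max_missing` (default 10) or more
  missing training values are dropped; remaining holes are imputed with
  training probe means before fitting.
* **Degenerate inputs.**  A matrix with no variable probe yields an
  intercept-only model whose intercept is the mean transformed age;
  fewer usable samples than folds is a configuration error.

The number of nonzero coefficients is data-dependent; on the reference
synthetic scenario it lands near 100–150 CpGs.  Along the penalty path
the active set grows essentially monotonically as $\lambda$ decreases,
but coordinate descent may transiently drop a variable that re-enters
later — the sparsity-vs-penalty trend is monotone only up to small local
dips, and the package's tests treat it accordingly.

## Shrinking the clock

Published clocks often ship a smaller companion predictor.  The original
work does not state how its reduced CpG subset was chosen;
`shrink_clock()` fixes a procedure that preserves joint calibration
rather than ranking coefficients by magnitude: refit the elastic net
restricted to the clock CpGs while increasing $\lambda$ along a
geometric grid that starts at the parent model's $\lambda$, and keep the
least-penalized fit whose active set is within the target size.  At the
parent $\lambda$ the restricted fit coincides with the parent
coefficients (the parent solution satisfies the restricted problem's
optimality conditions), so shrinking to the current size is a no-op up
to coordinate-descent tolerance (about $10^{-3}$ on the coefficient
scale — a solver property, not a modeling one).  An unreachable target
returns the closest achievable size with a warning record.

# Prediction, normalization, imputation

`predict_dnam_age()` needs only the coefficient table and the model's
*gold standard*: the training probe means plus the pooled sorted
clock-probe beta distribution.  Test-time handling, in order:

1. **Quantile normalization** (`normalize_to_gold_standard()`): per
   sample, observed clock-probe betas are mapped onto the reference
   distribution by empirical-CDF matching with linear interpolation at
   mid-rank plotting positions.  This replaces the beta-mixture
   quantile normalization used by the original pipeline with a plainly
   testable contract — match the test sample's distribution to the
   training distribution — and keeps a hook for a drop-in beta-mixture
   implementation.  The mapping preserves within-sample rank order
   exactly, keeps values in $[0,1]$, is idempotent, and leaves a sample
   already distributed like the reference unchanged.  It operates on
   the model's probe set only.
2. **Imputation** (`impute_missing()`): missing clock-probe values are
   replaced by gold-standard means — deterministic, and exactly the
   information a coefficient file can carry.  Imputation follows
   normalization (normalization skips missing cells), a fixed order this
   package documents because the original pipeline leaves it unstated.
3. Per-sample bookkeeping: imputed-probe counts; a warning flag when
   more than half the clock CpGs were imputed; an error record (and no
   prediction) when all were.

Age acceleration comes in the two standard flavors: the *difference*
DNAm age $-$ age, and the *residual* from regressing DNAm age on age
within the analyzed sample set (mean zero and uncorrelated with age by
construction; requires $\ge 3$ samples and non-constant age).

# Evaluation statistics

* **Accuracy** (`accuracy_report()`): age correlation (Pearson;
  undefined, never zero, under constant age), median absolute error in
  years, and average age acceleration.  The median error has the direct
  reading that half the subjects are predicted within that many years.
* **LOOCV** (`loocv_by_dataset()`): each data set is held out whole and
  predicted by a clock trained on the rest, giving batch-honest accuracy
  estimates; the summary table carries each set's age SD because the
  attainable correlation is governed by it.  Nothing from the held-out
  set — not even fold randomization — touches the fit, which the test
  suite asserts by corrupting held-out labels and demanding a
  bit-identical model.
* **Falconer heritability** (`falconer_heritability()`):
  $H^2 = 2(r_{MZ} - r_{DZ})$, clamped to $[0,1]$.  Co-twin correlations
  use symmetric double entry by default (each pair enters in both
  orderings), which is deterministic and equals the expectation of the
  single-random-ordering estimator; `ordering = "random"` reproduces the
  latter from a seed.
* **Biweight midcorrelation** (`biweight_midcorrelation()`): median/MAD
  centered, weights $(1 - u^2)^2$ vanishing beyond 9 MADs.  A zero-MAD
  vector falls back to mean-centering with unit weights, so the
  statistic degenerates exactly to Pearson when both vectors do.  On
  clean Gaussian data it tracks Pearson closely (within a few $10^{-3}$
  at $n = 1000$) without ever being identical — the weights are smooth,
  not binary.
* **Meta-analysis of age effects**
  (`meta_analysis_age_correlation()`): per-probe Pearson correlations
  with age computed *within* each data set (which is what removes
  tissue/batch confounding), Fisher-z transformed and combined as
  $Z = \sum_k (n_k - 3) z_k / \sqrt{\sum_k (n_k - 3)}$.  This
  inverse-variance weighting is the unique scaling of the
  $\sqrt{n_k-3}$-weighted score combination that is standard normal
  under the null — verified by a KS uniformity test on 2,000 null
  probes — and reduces to $\sqrt{n-3}\,z$ for a single data set.
* **Tissue F statistics** (`tissue_f_statistics()`): per probe, OLS of
  beta on age plus tissue indicators; F for the tissue factor by the
  extra-sum-of-squares test against the age-only model, reported
  without p-values.  Rank-deficient per-probe designs (a tissue level
  lost to missingness) are flagged, not guessed at.
* **Enrichment** (`category_enrichment()`): 2×2 Fisher exact tests of a
  probe set against annotation categories over an explicit universe,
  with the sample odds ratio; direction-split analyses (hyper- vs
  hypomethylating CpGs) are run by calling it per subset.  No
  multiple-testing correction is applied by default; apply
  `p.adjust(..., "bonferroni")` downstream when screening many
  categories.

# The synthetic methylome generator

`simulate_methylome()` emits cohorts with exactly the structure the
clock assumes, plus ground truth, so every estimator in the package can
be tested against known answers without any external data.

* **Trajectory shape.**  Causal probe $i$ in sample $j$ follows
  $\beta_{ij} = \mathrm{clamp}(b_i + s_i A_i (F_n(\text{age}_j) -
  \bar F_n) + \delta_{i,d(j)} + \tau_{i,t(j)} + \varepsilon_{ij},\,0,\,1)$
  with $F_n$ the calibration transform rescaled to $[0,1]$ over the age
  range.  The true signal is linear on the *transformed* scale, which
  embodies the fast-then-constant tick rate and makes the calibration
  identifiable in tests.
* **Effect-size law.**  Each causal probe's effect is parameterized as
  its expected absolute beta difference between old (> 55 y) and young
  (< 35 y) subjects, drawn uniformly within ±50% of a mean of 0.032 —
  the scale on which marginal clock-CpG age effects are conventionally
  reported.  The slope $A_i$ is the gap divided by the expected
  young/old contrast of $F_n$ under the configured age law (computed by
  numerical integration), so the configured gap is what the emitted data
  realize.
* **Direction split.**  193:160 hyper- to hypomethylating causal CpGs
  by default.
* **Nuisance structure.**  Baselines uniform on $(0.15, 0.85)$; beta
  noise SD 0.02; per-(probe, data set) and per-(probe, tissue) Gaussian
  offsets with SD 0.01 each across 4 data sets and 3 tissue labels —
  small, consistent with clock CpGs being relatively robust to tissue
  and batch; ages uniform over 0–101 years; optional MCAR missingness.
* **Clamping** to $[0,1]$ happens after noise rather than by
  truncated-normal sampling; at the default noise level the induced bias
  is negligible and the implementation stays transparent.

`simulate_twin_cohort()` draws per-twin age acceleration as $g + e$ with
$\mathrm{var}(g) = h^2\sigma^2$ (shared fully by MZ co-twins, with
correlation 0.5 by DZ co-twins), so $2(r_{MZ} - r_{DZ})$ has expectation
$h^2$; the default total SD is 5 years.

What the generator does *not* emulate — and hence what passing tests do
not show about real arrays: probe chemistry (type I vs II), cell-type
composition mixtures, dye bias and batch artifacts beyond additive
offsets, non-Gaussian heavy-tailed noise, and correlated probe blocks.
Performance numbers on simulated cohorts characterize the estimators
under the model's own assumptions, not clinical accuracy.

# Problem sizes and numerical choices

The package's tests and the reproduction script run, by choice, at desk
scale: the reference scenario uses 400 training and 100 test samples
over 2,000 probes with 150 causal CpGs (5 seeds); twin recovery uses
300 + 300 pairs over 20 seeds; null calibration uses 2,000 probes in 3
data sets.  These sizes make every property check re-runnable in
seconds while leaving enough power for the stated tolerances.
Correlations at $|r| = 1$ are clamped by $10^{-12}$ before Fisher
transformation; extreme meta-analysis p-values are computed on the log
scale; sample SDs use the $n-1$ denominator everywhere; CSV files use
comma separation with `NA`/empty as missing, a mandatory header, and
`# key=value` comment lines for model metadata.

# Known limitations

* The probe universe is whatever the input matrix provides; platform
  probe lists (e.g. the array-intersection set a cross-platform clock
  would use) are supplied by the caller, not hard-coded.
* Quantile normalization is empirical-CDF matching, not a beta-mixture
  model; heavily skewed type-I/type-II mixtures would need the latter.
* The heritability estimator is the classical twin-correlation formula;
  it inherits its assumptions (equal environments, no dominance
  decomposition beyond broad sense).
* The CLI writes CSV and JSON logs only; plotting is left to the caller.
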