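---
title: "Trimodal radiodensity modelling and risk classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimodal radiodensity modelling and risk classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntra)
```

## The model

A soft-tissue Hounsfield unit (HU) histogram over [−200, 200] HU is
modelled as the sum of three skew-Gaussian components,

$$\varphi(x; N, \mu, \sigma, \alpha) =
  \frac{N}{\sigma\sqrt{2\pi}} e^{-(x-\mu)^2/(2\sigma^2)}
  \,\mathrm{erfc}\!\left(\frac{\alpha (x-\mu)}{\sigma\sqrt 2}\right),$$

one per tissue type: fat, loose connective tissue, and lean muscle.
Because $\mathrm{erfc}(t) = 2\Phi(-t\sqrt 2)$, the unit-amplitude
component is exactly the skew-normal density with shape $-\alpha$, so
it integrates to 1 over the real line for every $\alpha$ and $N$ is
the component's area in the histogram's own units. Setting
$\alpha = 0$ recovers a plain Gaussian; the connective component is
constrained to $\alpha = 0$ throughout, which leaves 11 free
parameters (4 + 3 + 4). The skew-sign convention follows the fitted
cohort statistics: fat components skew toward the distribution centre
($\alpha < 0$), muscle components away from it ($\alpha > 0$).

Assumptions worth keeping in view:

* the three components are taken to exhaust the histogram — no
  background or artifact term;
* component *locations* are restricted to per-tissue ranges (fat
  [−200, −10], connective [−80, 40], muscle [41, 200] HU) and ordered
  fat < connective < muscle. The connective location range is wider
  than the connective *attenuation* window ([−9, 40] HU) on purpose:
  fitted connective locations in elderly cohorts sit at −15 to −30 HU
  (near −45 HU in women), well below the water-equivalent window that
  classifies individual pixels.

## Fitting

`fit_ntra()` minimizes the sum over bins of squared residuals between
the histogram value and the model density times the bin width, under
box constraints, with the Levenberg–Marquardt solver of minpack.lm.
The objective is ordinary least squares per CT bin; amplitudes come
out in whatever area unit the histogram carries (use
`normalize_histogram()` to pick the unit — the absolute scale of $N$
is a convention, not an estimable quantity, once a histogram is
normalized).

Default bounds: locations per tissue range; widths in [0.5, 60] HU;
amplitudes in [0, 10 × total mass]; fat skewness in [−20, 0], muscle
in [0, 20]. All are overridable, e.g. to relax the muscle skewness
bound when fitting deliberately symmetric test data.

**Initialization.** Fat and muscle start from their attenuation
domains: location at the argmax bin (ties toward the lowest HU),
amplitude at the domain mass, width at the mass-weighted SD *capped by
a half-maximum width around the peak* and floored at 1 HU. The cap
matters: neighbouring components leak mass across domain boundaries,
and the raw mass-weighted SD can be inflated several-fold, which
strands the solver in a local minimum. The connective start is then
located on the residual histogram after subtracting the fat and muscle
starting components, over the admissible connective location range —
a plain argmax inside [−9, 40] HU would often pick up the muscle
component's left tail instead of the connective peak. Starting
skewnesses are −2 (fat), 0 (connective), +2 (muscle). If the first
optimum is poor relative to the histogram's scale, `fit_ntra` retries
from a small spread of connective starting locations and keeps the
best solution; least-squares surfaces of overlapping mixtures do carry
local minima, essentially all of them tied to the connective
component.

With this scheme, all 14 published mean parameter sets (8 pooled-sex
wave × condition cells and 6 sex-specific cells) are recovered from
their own noiseless renderings to machine precision, and to under 5%
per parameter from 500,000-pixel multinomial samples.

**Numerical notes.** Convergence is declared on a 1e−10 relative
reduction tolerance (ftol/ptol). Intermediate solver iterates may
transiently violate the location ordering, so the residual function
evaluates the density directly from the parameter vector and the
ordering is enforced only on the returned profile; in the rare case
the best-found point violates it, the fit is returned unvalidated with
`converged = FALSE` rather than raising. `component_area()` splits its
quadrature at the component location so a narrow component far from
the interval midpoint cannot be missed by the adaptive rule.

## The synthetic cohort generator

The clinical cohort behind the published parameter summaries cannot be
redistributed, so every downstream stage is exercised on synthetic
cohorts. `reference_params()` exposes the published condition-specific
means and SDs of the 11 parameters (per study wave for pooled sexes;
waves pooled for the sex-specific sets), and `sample_profile()` draws
each parameter independently from a normal truncated to the admissible
ranges, with the connective location additionally truncated above the
drawn fat location so every draw is a valid profile. Only marginal
means and SDs are published, so independence (equivalently, an
identity copula correlation) is the default; a user-supplied
correlation matrix is honoured through a Gaussian copula. Truncation
shifts some means slightly (most visibly the fat skewness, truncated
at 0); the test suite checks the sampler against the closed-form
truncated-normal mean rather than the untruncated one.

`simulate_cohort()` assigns the three condition flags independently at
the configured prevalences (defaults: 628, 753, and 59 cases per
3,157 subjects, the first-wave proportions), so comorbidity arises
naturally; comorbid subjects draw their profile from the
highest-priority condition set, CHF > CHD > CVD, CHF showing the
largest published parameter separation. Ages are uniform on the
recruitment window 66–98 years (only condition-level age means are
published; a uniform draw over the recruitment range is the neutral
choice), sex is a configured split (default 42% male, the cohort's
proportion), and flags can be masked at a configured missingness rate.
`simulate_longitudinal()` reproduces the two-wave design: every
baseline subject reappears five years older, a configured fraction of
CHF-negative subjects converts (the published waves gained 124 cases
among 2,394 condition-free baseline subjects), incident subjects draw
their follow-up profile from the CHF set, everyone else redraws from
their own set with an optional aging drift. Follow-up ages may
therefore exceed 98; validation applies the recruitment bound only to
baseline rows. There is no published sex-specific row for subjects
free of *every* condition, so `condition = "none"` with a specific sex
uses the heart-failure-free rows, the largest control group.

What the generator does *not* emulate: scanner noise, beam hardening,
partial-volume effects, inter-parameter correlation, and any real
covariance between age, sex, and tissue composition. Consequently a
passing pipeline demonstrates correctness of the machinery —
recovery, balancing, fold hygiene, metric arithmetic — not the
clinical effect sizes: synthetic cohorts drawn from overlapping
marginal distributions are intrinsically harder to classify than the
real cohort, whose headline discrimination (AUCROC ≈ 0.99 for CHF)
requires the real data's correlation structure.

## Logistic models

Each condition flag is regressed on the 11 parameters plus age (years,
untransformed) and sex (female = 0, male = 1) with a binomial GLM
(logit link, IRLS, deviance tolerance 1e−8, at most 100 iterations);
rows missing the outcome or a predictor are dropped listwise.
Odds ratios exponentiate the coefficients with symmetric Wald
intervals and p-values — profile-likelihood intervals are out of
scope. Overall model significance is the null-minus-residual deviance
χ² on one degree of freedom per non-intercept predictor, and
`aic()` is deviance + 2k (identical to the standard computation for
0/1 outcomes, asserted in the tests). Diagnostics are signed deviance
residuals (their squares sum to the deviance) and Cook's distances
with a 4/n flag threshold. Complete separation is detected and
reported as `converged = FALSE` with a warning rather than an error;
zero-variance and linearly dependent predictors are named errors.

## The classification pipeline

**SMOTE.** The minority class is augmented by points
$m + u\,(nn - m)$, $u \sim \mathrm{U}(0,1)$, with $nn$ one of the $k$
nearest minority neighbours (Euclidean, default $k = 5$, reduced with
a warning when the minority class is small). Synthetic points
therefore lie on segments between real minority points; parity is
exact; originals are untouched. No installed package provides SMOTE,
so it is implemented here and property-tested (geometry, parity,
determinism).

**Cross-validation.** `run_cv()` uses stratified folds (per-class
round-robin over a shuffled order, fold sizes within one). The default
`fold_safe` mode applies SMOTE inside each training portion only, so
no synthetic point ever derives from a test subject. The
`paper_faithful` mode balances the whole set once before splitting —
the originally published protocol — and is provided for fidelity
comparisons; it leaks synthetic neighbours across folds and optimistic
scores should be expected. Accuracy is summarized per fold (mean and
best fold, matching the reported "mean/max" convention); sensitivity,
specificity, recall, precision (threshold 0.5) and AUCROC are computed
on out-of-fold scores pooled over folds, which yields a single
well-defined ROC curve per run. Pooling is a choice: boosted-model
probabilities saturate near 0/1 at fold-specific values, so pooled
AUC can sit fractionally below per-fold AUC even on perfectly
separable data (~0.996 where per-fold ranking is exact); vote-fraction
scores (RF) do not show this. Test folds containing a single class
are skipped with a warning and counted in the report.

**Ensembles.** Random forests (randomForest) and gradient boosting
(xgboost, binary logistic objective, depth 3, learning rate 0.1) wrap
established implementations; AdaBoost is implemented in-package as
SAMME over depth-2 rpart trees because no AdaBoost implementation is
available among the package's dependencies. All default to 100
trees/rounds — no published hyperparameters exist, so defaults a
practitioner would reach for are fixed in one place — run
single-threaded, and are deterministic under a fixed seed. AUCROC is
the midrank Mann–Whitney statistic, checked in the tests against a
brute-force all-pairs oracle at 1e−12.

**Typology.** `full_typology()` assembles, per condition × algorithm:
the total 11-feature score; scores for the 4/3/4 tissue-specific
feature groups; tissue-grouped feature importance (importances summed
within tissue, rescaled to percentages totalling 100); age-stratified
scores over the strata 66–75, 76–83, 84–98 (the table-header
convention; the alternative 76–84/85–98 text convention is available
via configuration); and, when a follow-up wave is supplied,
CHF-incidence prediction. The incidence index labels a subject 0 if
condition-free at both waves and 1 if free at baseline but diagnosed
at follow-up; subjects positive at baseline are excluded entirely (the
conservative reading of the published exclusion rule), as are subjects
missing at follow-up, and classification features are the baseline
parameters.

## Determinism and problem sizes

Every stochastic stage takes a seed, and a fixed configuration plus
seed gives byte-identical cohorts, fits, and JSON reports (asserted
end-to-end in the acceptance tests through the CLI). The test suite
sizes its simulations to what the checks need rather than to the
published cohort scale: parameter recovery uses the 401-bin grid and
500,000-pixel samples over 20 seeds; logistic recovery uses 100
cohorts of 5,000; null calibration uses 50 permutation seeds; the CV
and typology tests run on cohorts of 60–240 subjects with 4–12 folds,
which is ample to exercise fold accounting, balancing, and report
structure.

## Known limitations

* Absolute amplitudes are identifiable only up to the histogram's
  area unit; comparisons across differently normalized histograms
  must fix a common total mass first.
* The independence default in the generator understates real
  between-parameter correlation; classification scores on synthetic
  cohorts are conservative and not comparable to published values.
* AdaBoost feature importances inherit rpart's surrogate-split
  accounting and are coarser than the RF/GB importances.
* The fitter assumes a single subject's histogram; mixtures of
  subjects (e.g. averaged histograms) can violate the
  three-component assumption near the connective/fat boundary.
* DICOM ingestion, segmentation, and slice localization are out of
  scope; the package starts from masked pixel values or histograms.
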