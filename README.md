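# ntra

Nonlinear trimodal regression analysis (NTRA) of CT radiodensitometric
distributions, with the downstream cardiovascular-risk classification
pipeline built on the fitted parameters.

## The problem

A mid-thigh CT cross-section, after soft-tissue segmentation, yields a
distribution of Hounsfield unit (HU) pixel values over [−200, 200] HU.
That distribution is well described as the sum of three tissue
sub-distributions occupying characteristic attenuation domains: fat
(−200 to −10 HU), loose connective tissue (−9 to 40 HU), and lean
muscle (41 to 200 HU). Changes in these sub-distributions — fat
infiltrating muscle (myosteatosis), age-related loss of lean mass
(sarcopenia) — carry information about cardiovascular health in elderly
subjects.

`ntra` models each HU distribution as a quasi-probability density

$$\sum_{i=1}^{3}\varphi(x; N_i,\mu_i,\sigma_i,\alpha_i)
  = \sum_{i=1}^{3}\frac{N_i}{\sigma_i\sqrt{2\pi}}
    \, e^{-\frac{(x-\mu_i)^2}{2\sigma_i^2}}
    \,\operatorname{erfc}\!\Big(\frac{\alpha_i (x-\mu_i)}{\sigma_i\sqrt{2}}\Big)$$

where $N$ is the amplitude (the component's area), $\mu$ the location
(HU), $\sigma$ the width (HU), and $\alpha$ the skewness; the
connective component is constrained to $\alpha = 0$. Fitting this
model to a subject's histogram by bound-constrained nonlinear least
squares yields an 11-parameter soft-tissue profile (4 fat + 3
connective + 4 muscle).

On top of the fitted profiles the package provides, for cohorts of
elderly subjects with coronary heart disease (CHD), all-type
cardiovascular disease (CVD), and chronic heart failure (CHF) flags:

* a **synthetic cohort generator** calibrated to published
  condition-, wave-, and sex-specific parameter means/SDs (the source
  clinical cohort itself is not shareable), including a two-timepoint
  longitudinal design with CHF incidence;
* **logistic regression** of each condition on the 11 parameters with
  age and sex as confounders (odds ratios, Wald CIs, model χ², AIC,
  deviance-residual and Cook's-distance diagnostics);
* an **ML pipeline**: SMOTE class balancing, stratified k-fold
  cross-validation of random forests, AdaBoost, and gradient boosting,
  six evaluation metrics (accuracy mean/max, sensitivity, specificity,
  recall, precision, AUCROC), tissue-grouped feature importance,
  age-stratified analysis, and longitudinal CHF-incidence prediction;
* **file formats and a CLI** (`exec/ntra`) tying the stages together.

## Worked example

```r
library(ntra)

## a profile at the published CHF cohort means, a noisy histogram, a refit
params  <- reference_params("CHF", dataset = "AGES-I")
profile <- vector_to_profile(params$mean)
hist <- render_histogram(profile, "pixel_sampling", n_pixels = 200000, seed = 1)
hist <- normalize_histogram(hist,
                            total_mass = sum(params$mean[c("fat_N", "conn_N", "musc_N")]))
fit_ntra(hist)
#> <ntra_fit> objective 0.162495 after 9 iterations (converged)
#> <ntra_profile> (11 parameters)
#>   fat        N= 54.950  mu= -116.661  sigma=  8.492  alpha=-2.369
#>   connective N= 43.161  mu=  -21.095  sigma= 24.846  alpha= 0.000
#>   muscle     N= 78.255  mu=   61.026  sigma=  8.940  alpha= 2.981
```

The generating values were (54.8, −116.6, 8.4, −2.3 | 43.2, −21.0,
24.9 | 78.3, 61.0, 8.9, 3.0): at 200,000 pixels every parameter comes
back within ~3%.

```r
## a synthetic cohort, logistic regression, cross-validated classification
cohort <- simulate_cohort(600, prevalence = c(CHD = 0.2, CVD = 0.24, CHF = 0.1),
                          seed = 7, exact_counts = TRUE)
lr <- fit_logistic(cohort, "CHF")
model_chisq(lr)$p
#> [1] 0.0001093196

fm <- select_features(cohort, "all", "CHF")
set.seed(7)
run_cv(fm$X, fm$y, "RF", k = 12)
#> <metrics_report> RF / - / total
#>   accuracy 85.7% (max 90.0%)  sens 23.3%  spec 92.6%  prec 25.9%  AUCROC 0.702
```

The overall model χ² p-value says the 11 parameters jointly carry CHF
signal; the cross-validated AUCROC of 0.70 reflects how much the
condition-specific generating distributions overlap — synthetic
cohorts drawn from marginal summaries are deliberately harder to
classify than real subjects, whose parameters are correlated (see the
methods vignette).

```r
bal <- smote_balance(fm$X, fm$y, seed = 7)
m   <- train_ensemble(bal$X, bal$y, "RF", seed = 7)
unlist(tissue_importance(m))
#>        fat_pct connective_pct     muscle_pct
#>       46.19619       23.23331       30.57050
```

A full report over all conditions, algorithms, tissues, age strata,
and the longitudinal design comes from `full_typology()`, or from the
shell:

```sh
inst/exec/ntra simulate --config cfg.yml --seed 7 --out cohort.csv
inst/exec/ntra evaluate --in cohort.csv --seed 7 --out report.json
inst/exec/ntra report   --in report.json --out tables/
```

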