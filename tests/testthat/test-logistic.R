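# Simulate a cohort whose CHF flag follows a known logistic model on
# standardized profile parameters plus age and sex.
logistic_cohort <- function(n, beta, seed) {
  set.seed(seed)
  co <- simulate_cohort(n, prevalence = c(CHD = 0, CVD = 0, CHF = 0))
  X <- as.matrix(co[, ntra_parameter_names()])
  Xs <- scale(X)
  sexm <- as.numeric(co$sex == "male")
  age_c <- (co$age - 82) / 10
  eta <- beta["intercept"] +
    Xs %*% beta[ntra_parameter_names()] +
    beta["age"] * age_c + beta["sex"] * sexm
  co$chf <- runif(n) < 1 / (1 + exp(-eta))
  # return the design actually used, on the raw scale the fitter sees
  co
}

true_beta <- function() {
  b <- c(intercept = -1, age = 0.4, sex = 0.5,
         setNames(c(-0.5, 0.3, 0, 0, 0.4, 0, -0.3, -0.4, 0, 0.2, 0),
                  ntra_parameter_names()))
  b
}

test_that("coefficients are recovered within Wald error on a generated cohort", {
  beta <- true_beta()
  co <- logistic_cohort(4000, beta, seed = 5)
  fit <- fit_logistic(co, "CHF")
  expect_true(fit$converged)
  expect_lte(fit$deviance, fit$null_deviance)
  # compare on the standardized scale the labels were generated on
  sds <- apply(co[, ntra_parameter_names()], 2, sd)
  est <- fit$coefficients[ntra_parameter_names()] * sds
  se <- fit$standard_errors[ntra_parameter_names()] * sds
  expect_true(all(abs(est - beta[ntra_parameter_names()]) <= 3.5 * se))
  # negative generating effect for fat amplitude shows up as OR < 1
  ors <- odds_ratios(fit)
  expect_lt(ors$OR[ors$predictor == "fat_N"], 1)
})

test_that("degenerate designs raise the documented errors", {
  co <- small_cohort(n = 60, seed = 3)
  co$chf <- FALSE
  expect_error(fit_logistic(co, "CHF"), "at least one case")
  co2 <- small_cohort(n = 60, seed = 4)
  co2$fat_N <- 1  # constant column
  expect_error(fit_logistic(co2, "CHF"), "zero-variance predictor: fat_N")
  co3 <- small_cohort(n = 60, seed = 5)
  co3$fat_sigma <- co3$fat_N  # duplicated predictor
  expect_error(fit_logistic(co3, "CHF"), "rank-deficient")
})

test_that("odds ratios exponentiate Wald intervals", {
  co <- logistic_cohort(800, true_beta(), seed = 6)
  fit <- fit_logistic(co, "CHF")
  ors <- odds_ratios(fit)
  j <- match("age", ors$predictor)
  co_j <- fit$coefficients["age"]
  se_j <- fit$standard_errors["age"]
  expect_equal(ors$OR[j], exp(co_j), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ors$CI_low[j], exp(co_j - qnorm(0.975) * se_j),
               tolerance = 1e-12, ignore_attr = TRUE)
  # closed form: coef ln 2, SE 0.1
  expect_equal(exp(log(2) + c(-1, 1) * 1.96 * 0.1), c(1.644, 2.433),
               tolerance = 5e-4)
  # monotone: coefficient ordering equals OR ordering
  expect_identical(order(fit$coefficients), order(ors$OR))
})

test_that("model chi-square, AIC, and deviance identities hold", {
  co <- logistic_cohort(1500, true_beta(), seed = 7)
  fit <- fit_logistic(co, "CHF")
  cs <- model_chisq(fit)
  expect_equal(cs$chi2, fit$null_deviance - fit$deviance)
  expect_identical(cs$df, 13L)  # 11 parameters + age + sex
  expect_gte(cs$chi2, 0)
  expect_lt(cs$p, 1e-6)         # strongly informative generator
  # AIC = deviance + 2k agrees with the standard computation
  expect_equal(aic(fit), AIC(fit$glm), tolerance = 1e-9)
  # intercept-only closed form on 10 balanced outcomes:
  # logLik = 10 log(1/2), AIC = 2 + 13.8629
  bal <- co[1:10, ]
  bal$chf <- rep(c(TRUE, FALSE), 5)
  f0 <- suppressWarnings(glm(chf ~ 1, binomial(), bal))
  expect_equal(AIC(f0), 2 - 2 * 10 * log(0.5), tolerance = 1e-9)
  # deviance residuals square-sum to the deviance
  diag <- deviance_residuals(fit)
  expect_equal(sum(diag$deviance_residuals^2), fit$deviance,
               tolerance = 1e-8)
})

test_that("an injected gross outlier has the maximal Cook's distance", {
  co <- logistic_cohort(400, true_beta(), seed = 8)
  out <- co[1, ]
  out$subject_id <- "OUTLIER"
  out[ntra_parameter_names()] <- as.list(
    reference_params("none")$mean + 6 * reference_params("none")$sd *
      c(1, -1, 1, 0, 1, 1, 1, -1, 1, 1, 1))
  out$chf <- TRUE
  co2 <- rbind(out, co)
  fit <- tryCatch(fit_logistic(co2, "CHF"),
                  warning = function(w) suppressWarnings(fit_logistic(co2, "CHF")))
  diag <- deviance_residuals(fit, co2)
  expect_identical(which.max(diag$cooks_distance), 1L)
  expect_true("OUTLIER" %in% diag$flagged_ids)
})

test_that("predicted probability curves follow the coefficient sign and calibrate", {
  co <- logistic_cohort(1200, true_beta(), seed = 9)
  fit <- fit_logistic(co, "CHF")
  curve_up <- predicted_probabilities(fit, "conn_N")    # positive effect
  expect_true(all(diff(curve_up$probability) > 0))
  curve_dn <- predicted_probabilities(fit, "fat_N")     # negative effect
  expect_true(all(diff(curve_dn$probability) < 0))
  expect_error(predicted_probabilities(fit, "bmi"), "not in model")
  # canonical-link score equation: fitted probabilities average to the
  # observed prevalence
  expect_equal(mean(fitted(fit$glm)), mean(fit$data$chf), tolerance = 1e-6)
})
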