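#' Logistic regression of a cardiac condition on the trimodal profile
#'
#' Fits a binomial generalized linear model (logit link, iteratively
#' reweighted least squares) of one condition flag on the 11 profile
#' parameters with age and sex entered as confounders (sex coded
#' female = 0, male = 1; age in years, untransformed). Rows with a
#' missing outcome or missing predictors are dropped (listwise
#' deletion).
#'
#' @param cohort A cohort table (see [simulate_cohort]).
#' @param outcome `"CHD"`, `"CVD"`, or `"CHF"`.
#' @param predictors Predictor columns; defaults to the 11 canonical
#'   parameters plus `age` and `sex`.
#' @return An object of class `logistic_fit`: the underlying `glm`
#'   object plus `outcome`, `deviance`, `null_deviance`, `n_used`,
#'   `converged`, `coefficients`, `standard_errors`.
#' @export
fit_logistic <- function(cohort, outcome = c("CHD", "CVD", "CHF"),
                         predictors = c(ntra_parameter_names(), "age", "sex")) {
  cohort <- as_cohort_table(cohort)
  outcome <- match.arg(outcome)
  ycol <- tolower(outcome)
  dat <- cohort[, c(ycol, predictors)]
  if ("sex" %in% predictors)
    dat$sex <- as.numeric(dat$sex == "male")
  dat <- dat[complete.cases(dat), , drop = FALSE]
  y <- dat[[ycol]]
  if (sum(y) < 1 || sum(!y) < 1)
    stop("need at least one case and one control after dropping missing rows",
         call. = FALSE)
  for (p in predictors) {
    if (length(unique(dat[[p]])) < 2L)
      stop("zero-variance predictor: ", p, call. = FALSE)
  }
  X <- as.matrix(dat[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("rank-deficient design: predictors are linearly dependent",
         call. = FALSE)
  separation <- FALSE
  fml <- stats::as.formula(paste0(ycol, " ~ ",
                                  paste(predictors, collapse = " + ")))
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("possible complete separation; coefficients may be unstable",
            call. = FALSE)
  structure(list(
    glm = fit,
    outcome = outcome,
    data = dat,
    predictors = predictors,
    coefficients = coef(fit),
    standard_errors = sqrt(diag(vcov(fit))),
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    n_used = nrow(dat),
    converged = fit$converged && !separation), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> outcome %s: n=%d, deviance %.2f (null %.2f), %s\n",
    x$outcome, x$n_used, x$deviance, x$null_deviance,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiates the log-odds coefficients and their symmetric Wald
#' intervals, `exp(coef +/- z * SE)`, with two-sided Wald p-values.
#'
#' @param fit A [fit_logistic] result.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `predictor`, `OR`, `CI_low`, `CI_high`, `p`,
#'   and significance `stars` (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"), level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  co <- fit$coefficients
  se <- fit$standard_errors
  pvals <- 2 * pnorm(-abs(co / se))
  stars <- ifelse(pvals < 0.001, "***",
                  ifelse(pvals < 0.01, "**",
                         ifelse(pvals < 0.05, "*", "")))
  data.frame(predictor = names(co),
             OR = exp(co),
             CI_low = exp(co - z * se),
             CI_high = exp(co + z * se),
             p = pvals, stars = stars,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall model chi-square test
#'
#' Likelihood-ratio test of the fitted model against the intercept-only
#' model: the difference between null and residual deviance, referred
#' to a chi-square distribution with one degree of freedom per
#' non-intercept predictor.
#'
#' @param fit A [fit_logistic] result.
#' @return List with `chi2`, `df`, `p`.
#' @export
model_chisq <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  chi2 <- fit$null_deviance - fit$deviance
  df <- length(fit$coefficients) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Akaike information criterion of a logistic fit
#'
#' `AIC = deviance + 2k` with `k` the number of estimated coefficients;
#' for a 0/1 outcome the saturated log-likelihood is zero, so this
#' equals the usual `2k - 2 * logLik`.
#'
#' @param fit A [fit_logistic] result.
#' @return The AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  fit$deviance + 2 * length(fit$coefficients)
}

#' Deviance residuals and influence diagnostics
#'
#' Signed deviance residuals and Cook's distances per subject, with
#' subjects above the leverage threshold flagged.
#'
#' @param fit A [fit_logistic] result.
#' @param cohort Cohort table the fit came from (for subject ids);
#'   optional.
#' @param threshold Cook's distance flag threshold (default `4 / n`).
#' @return List with `deviance_residuals`, `cooks_distance`,
#'   `flagged_ids` (indices when no cohort is supplied).
#' @export
deviance_residuals <- function(fit, cohort = NULL, threshold = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  dres <- residuals(fit$glm, type = "deviance")
  cook <- cooks.distance(fit$glm)
  if (is.null(threshold)) threshold <- 4 / fit$n_used
  idx <- which(cook > threshold)
  flagged <- if (!is.null(cohort)) {
    used <- as.integer(rownames(fit$data))
    cohort$subject_id[used[idx]]
  } else {
    idx
  }
  list(deviance_residuals = unname(dres),
       cooks_distance = unname(cook),
       flagged_ids = flagged)
}

#' Predicted probability curve along one predictor
#'
#' Sweeps one predictor over a grid with all other predictors held at
#' their sample means and returns the inverse-logit of the linear
#' predictor.
#'
#' @param fit A [fit_logistic] result.
#' @param predictor Name of the predictor to vary.
#' @param grid Numeric grid of predictor values; defaults to 100 points
#'   across the observed range.
#' @return Data frame with columns `x` and `probability`.
#' @export
predicted_probabilities <- function(fit, predictor, grid = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!predictor %in% fit$predictors)
    stop("predictor not in model: ", predictor, call. = FALSE)
  obs <- fit$data[[predictor]]
  if (is.null(grid))
    grid <- seq(min(obs), max(obs), length.out = 100L)
  newdata <- as.data.frame(lapply(fit$data[fit$predictors], function(col)
    rep(mean(col), length(grid))))
  newdata[[predictor]] <- grid
  eta <- predict(fit$glm, newdata = newdata, type = "link")
  data.frame(x = grid, probability = 1 / (1 + exp(-eta)))
}
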