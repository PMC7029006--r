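# Truncated-normal draw via inverse-CDF; degenerate SD returns the mean.
rtruncnorm1 <- function(u, mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  pa <- pnorm((lower - mean) / sd)
  pb <- pnorm((upper - mean) / sd)
  qnorm(pa + u * (pb - pa)) * sd + mean
}

#' Draw one soft-tissue profile from a condition parameter set
#'
#' Samples each of the 11 parameters from a normal distribution with
#' the set's mean and SD, truncated to the profile's admissible ranges
#' (amplitudes nonnegative, widths at least 0.5 HU, locations in their
#' per-tissue ranges, fat skewness nonpositive and muscle skewness
#' nonnegative). The connective location is additionally truncated
#' above the drawn fat location so the ordering invariant always holds.
#' Parameters are drawn independently unless a correlation matrix is
#' supplied, in which case a Gaussian copula couples the draws.
#'
#' @param param_set A [condition_parameter_set].
#' @param seed Optional integer seed (draws consume the session RNG
#'   stream when omitted).
#' @param corr Optional 11 x 11 correlation matrix.
#' @return An [ntra_profile]. With all SDs zero the means are returned
#'   exactly.
#' @export
sample_profile <- function(param_set, seed = NULL, corr = NULL) {
  stopifnot(inherits(param_set, "condition_parameter_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(corr)) {
    u <- runif(11)
  } else {
    stopifnot(is.matrix(corr), all(dim(corr) == c(11L, 11L)))
    z <- drop(crossprod(chol(corr), rnorm(11)))
    u <- pnorm(z)
  }
  m <- param_set$mean
  s <- param_set$sd
  loc <- location_domains()
  v <- numeric(11)
  names(v) <- ntra_parameter_names()
  v["fat_N"] <- rtruncnorm1(u[1], m["fat_N"], s["fat_N"], 0, Inf)
  v["fat_mu"] <- rtruncnorm1(u[2], m["fat_mu"], s["fat_mu"],
                             loc$fat[1], loc$fat[2])
  v["fat_sigma"] <- rtruncnorm1(u[3], m["fat_sigma"], s["fat_sigma"], 0.5, 60)
  v["fat_alpha"] <- rtruncnorm1(u[4], m["fat_alpha"], s["fat_alpha"], -20, 0)
  v["conn_N"] <- rtruncnorm1(u[5], m["conn_N"], s["conn_N"], 0, Inf)
  v["conn_mu"] <- rtruncnorm1(u[6], m["conn_mu"], s["conn_mu"],
                              max(loc$connective[1], v["fat_mu"] + 0.5),
                              loc$connective[2])
  v["conn_sigma"] <- rtruncnorm1(u[7], m["conn_sigma"], s["conn_sigma"], 0.5, 60)
  v["musc_N"] <- rtruncnorm1(u[8], m["musc_N"], s["musc_N"], 0, Inf)
  v["musc_mu"] <- rtruncnorm1(u[9], m["musc_mu"], s["musc_mu"],
                              loc$muscle[1], loc$muscle[2])
  v["musc_sigma"] <- rtruncnorm1(u[10], m["musc_sigma"], s["musc_sigma"],
                                 0.5, 60)
  v["musc_alpha"] <- rtruncnorm1(u[11], m["musc_alpha"], s["musc_alpha"], 0, 20)
  vector_to_profile(v)
}

#' Render a histogram from a profile
#'
#' `"noiseless"` mode evaluates the trimodal density at each bin centre
#' times the bin width (bin values on the profile's own area scale).
#' `"pixel_sampling"` draws `n_pixels` HU values from the normalized
#' trimodal density (skew-normal component sampling, component chosen
#' with probability proportional to its amplitude), rejects draws
#' outside `[-200, 200]`, and bins them; the counts sum to `n_pixels`
#' exactly.
#'
#' @param profile An [ntra_profile].
#' @param mode `"noiseless"` or `"pixel_sampling"`.
#' @param n_pixels Number of pixels to draw (pixel_sampling only).
#' @param seed Optional integer seed.
#' @param bin_centers Evaluation grid; defaults to the 401-bin 1-HU grid.
#' @param bin_width Bin width in HU.
#' @return A [hu_histogram].
#' @export
render_histogram <- function(profile, mode = c("noiseless", "pixel_sampling"),
                             n_pixels = NULL, seed = NULL,
                             bin_centers = default_grid(), bin_width = 1) {
  stopifnot(inherits(profile, "ntra_profile"))
  mode <- match.arg(mode)
  if (mode == "noiseless") {
    vals <- trimodal_density(bin_centers, profile) * bin_width
    return(hu_histogram(bin_centers, vals, bin_width))
  }
  if (is.null(n_pixels) || n_pixels < 1)
    stop("pixel_sampling mode requires a positive n_pixels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- sample_pixels(profile, n_pixels)
  hist_from_pixels(x, bin_centers, bin_width)
}

# Draw HU pixel values from the normalized trimodal density, rejecting
# (and redrawing) values outside [-200, 200].
sample_pixels <- function(profile, n) {
  amps <- c(profile$fat$amplitude_N, profile$connective$amplitude_N,
            profile$muscle$amplitude_N)
  if (sum(amps) <= 0) stop("profile has zero total amplitude", call. = FALSE)
  comps <- list(profile$fat, profile$connective, profile$muscle)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    ci <- sample.int(3L, m, replace = TRUE, prob = amps / sum(amps))
    draws <- vapply(ci, function(i) rskew1(comps[[i]]), numeric(1))
    out <- c(out, draws[draws >= -200 & draws <= 200])
  }
  out
}

# One draw from the erfc-form skew component: density proportional to
# phi(z) * 2 * Phi(-alpha * z), i.e. a standard skew normal with shape
# lambda = -alpha.
rskew1 <- function(cmp) {
  lambda <- -cmp$skewness_alpha
  delta <- lambda / sqrt(1 + lambda^2)
  u <- rnorm(2)
  z <- delta * abs(u[1]) + sqrt(1 - delta^2) * u[2]
  cmp$location_mu + cmp$width_sigma * z
}

hist_from_pixels <- function(x, bin_centers, bin_width) {
  idx <- round((x - bin_centers[1]) / bin_width) + 1L
  idx <- pmin(pmax(idx, 1L), length(bin_centers))
  vals <- tabulate(idx, nbins = length(bin_centers))
  hu_histogram(bin_centers, vals, bin_width)
}

.cohort_columns <- function() {
  c("subject_id", "timepoint", "age", "sex", "chd", "cvd", "chf",
    ntra_parameter_names())
}

# Generating set priority for comorbid subjects: CHF shows the largest
# printed parameter separation, then CHD, then CVD.
.priority_condition <- function(chd, cvd, chf) {
  if (isTRUE(chf)) "CHF" else if (isTRUE(chd)) "CHD"
  else if (isTRUE(cvd)) "CVD" else "none"
}

.draw_subject_profile <- function(chd, cvd, chf, sex, dataset,
                                  use_sex_params, drift = NULL) {
  cond <- .priority_condition(chd, cvd, chf)
  set <- reference_params(cond, dataset = dataset,
                          sex = if (use_sex_params) sex else "pooled")
  if (!is.null(drift))
    set <- condition_parameter_set(set$condition, set$mean + drift, set$sd,
                                   sex = set$sex, dataset = set$dataset)
  profile_to_vector(sample_profile(set))
}

#' Simulate a cross-sectional cohort
#'
#' Builds a cohort table of elderly subjects (ages 66-98) with
#' condition flags for coronary heart disease (CHD), all-type
#' cardiovascular disease (CVD), and chronic heart failure (CHF), and
#' an 11-parameter soft-tissue profile drawn from the published
#' condition-specific summaries. Conditions are assigned independently,
#' so comorbidity arises naturally; comorbid subjects draw their
#' profile from the highest-priority condition set (CHF > CHD > CVD).
#' Default prevalences follow the first study wave (628, 753, and 59
#' cases of CHD, CVD, CHF among 3,157 subjects).
#'
#' @param n Number of subjects.
#' @param prevalence Named vector of prevalences for `CHD`, `CVD`, `CHF`.
#' @param sex_split Proportion of male subjects.
#' @param age_range Inclusive integer age range.
#' @param dataset Which wave's parameter summaries generate profiles.
#' @param use_sex_params Draw profiles from sex-specific summaries.
#' @param missingness Probability that each condition flag is missing.
#' @param exact_counts Make group counts exact rather than binomial.
#' @param timepoint Timepoint label for all rows.
#' @param seed Optional integer seed.
#' @return A `data.frame` (cohort table) with columns `subject_id`,
#'   `timepoint`, `age`, `sex`, `chd`, `cvd`, `chf` and the 11
#'   canonical parameter columns; generator settings are attached as
#'   the `"generator"` attribute.
#' @export
simulate_cohort <- function(n,
                            prevalence = c(CHD = 628 / 3157,
                                           CVD = 753 / 3157,
                                           CHF = 59 / 3157),
                            sex_split = 0.42,
                            age_range = c(66L, 98L),
                            dataset = "AGES-I",
                            use_sex_params = FALSE,
                            missingness = 0,
                            exact_counts = FALSE,
                            timepoint = "T1",
                            seed = NULL) {
  stopifnot(n >= 1, all(prevalence >= 0), all(prevalence <= 1),
            sex_split >= 0, sex_split <= 1,
            missingness >= 0, missingness <= 1,
            age_range[1] >= 66, age_range[2] <= 98,
            age_range[1] <= age_range[2])
  for (cond in c("CHD", "CVD", "CHF"))
    if (is.na(prevalence[cond]))
      stop("prevalence must name CHD, CVD and CHF", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  draw_flags <- function(p) {
    if (exact_counts) {
      k <- round(p * n)
      flags <- rep(FALSE, n)
      flags[sample.int(n, k)] <- TRUE
      flags
    } else {
      runif(n) < p
    }
  }
  chd <- draw_flags(prevalence["CHD"])
  cvd <- draw_flags(prevalence["CVD"])
  chf <- draw_flags(prevalence["CHF"])
  if (exact_counts) {
    n_male <- round(sex_split * n)
    sex <- rep("female", n)
    sex[sample.int(n, n_male)] <- "male"
  } else {
    sex <- ifelse(runif(n) < sex_split, "male", "female")
  }
  age <- sample(seq(age_range[1], age_range[2]), n, replace = TRUE)
  params <- t(vapply(seq_len(n), function(i) {
    .draw_subject_profile(chd[i], cvd[i], chf[i], sex[i], dataset,
                          use_sex_params)
  }, numeric(11)))
  colnames(params) <- ntra_parameter_names()
  if (missingness > 0) {
    chd[runif(n) < missingness] <- NA
    cvd[runif(n) < missingness] <- NA
    chf[runif(n) < missingness] <- NA
  }
  cohort <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    timepoint = timepoint, age = as.integer(age), sex = sex,
    chd = chd, cvd = cvd, chf = chf,
    params, stringsAsFactors = FALSE, row.names = NULL)
  attr(cohort, "generator") <- list(
    n = n, prevalence = prevalence, sex_split = sex_split,
    age_range = age_range, dataset = dataset,
    use_sex_params = use_sex_params, missingness = missingness,
    exact_counts = exact_counts, timepoint = timepoint, seed = seed)
  cohort
}

#' Simulate the follow-up wave of a cohort
#'
#' Every baseline (T1) subject reappears at T2 five years older. A
#' fraction `incidence_rate` of the baseline CHF-negative subjects
#' becomes CHF-positive and draws its follow-up profile from the CHF
#' parameter set; all other subjects keep their condition flags and
#' redraw from their own set (optionally shifted by `drift`). CHD and
#' CVD status is carried over unchanged.
#'
#' @param baseline Cohort table with all rows at timepoint T1.
#' @param incidence_rate Fraction of CHF-negative subjects converting.
#' @param drift Optional named 11-vector added to the generating means
#'   of non-incident subjects (aging drift).
#' @param dataset Wave whose summaries generate the T2 profiles.
#' @param exact_counts Convert exactly `round(rate * n_negative)`
#'   subjects.
#' @param seed Optional integer seed.
#' @return A cohort table at timepoint `"T2"`, same subjects and order.
#' @export
simulate_longitudinal <- function(baseline, incidence_rate, drift = NULL,
                                  dataset = "AGES-II", exact_counts = FALSE,
                                  seed = NULL) {
  baseline <- as_cohort_table(baseline)
  if (any(baseline$timepoint != "T1"))
    stop("baseline must contain only timepoint T1 rows", call. = FALSE)
  stopifnot(incidence_rate >= 0, incidence_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(baseline)
  negatives <- which(!is.na(baseline$chf) & !baseline$chf)
  if (exact_counts) {
    k <- round(incidence_rate * length(negatives))
    incident <- negatives[sample.int(length(negatives), k)]
  } else {
    incident <- negatives[runif(length(negatives)) < incidence_rate]
  }
  t2 <- baseline
  t2$timepoint <- "T2"
  t2$age <- baseline$age + 5L
  t2$chf[incident] <- TRUE
  params <- t(vapply(seq_len(n), function(i) {
    use_drift <- if (i %in% incident) NULL else drift
    .draw_subject_profile(t2$chd[i], t2$cvd[i], t2$chf[i], t2$sex[i],
                          dataset, use_sex_params = FALSE, drift = use_drift)
  }, numeric(11)))
  t2[, ntra_parameter_names()] <- params
  attr(t2, "generator") <- c(attr(baseline, "generator"),
                             list(incidence_rate = incidence_rate,
                                  t2_dataset = dataset, t2_seed = seed))
  t2
}

#' Validate and coerce a cohort table
#'
#' Checks the canonical column set, subject-id uniqueness within each
#' timepoint, and (for baseline rows) the recruitment age window 66-98;
#' follow-up rows may be up to five years older.
#'
#' @param x A data frame with the cohort schema.
#' @return The validated data frame.
#' @export
as_cohort_table <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.cohort_columns(), names(x))
  if (length(missing_cols))
    stop("cohort table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (tp in unique(x$timepoint)) {
    ids <- x$subject_id[x$timepoint == tp]
    if (anyDuplicated(ids))
      stop("duplicate subject_id within timepoint ", tp, call. = FALSE)
  }
  t1 <- x$timepoint == "T1"
  if (any(t1) && (any(x$age[t1] < 66) || any(x$age[t1] > 98)))
    stop("baseline ages must lie in the recruitment window [66, 98]",
         call. = FALSE)
  if (any(x$age < 66) || any(x$age > 103))
    stop("ages must lie in [66, 103]", call. = FALSE)
  x
}
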