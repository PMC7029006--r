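#' Default box constraints for the trimodal fit
#'
#' Lower and upper bounds for the 11 free parameters in canonical order.
#' Locations are bounded per tissue, widths lie in `[0.5, 60]` HU,
#' amplitudes in `[0, 10 * total_mass]`, fat skewness in `[-20, 0]` and
#' muscle skewness in `[0, 20]` (the sign convention of the fitted
#' cohort parameters: fat skews toward the connective domain, muscle
#' away from it).
#'
#' @param total_mass Total histogram mass, used to cap amplitudes.
#' @return List with named numeric `lower` and `upper` 11-vectors.
#' @export
default_fit_bounds <- function(total_mass) {
  stopifnot(is.numeric(total_mass), total_mass > 0)
  loc <- location_domains()
  nm <- ntra_parameter_names()
  lower <- setNames(c(0, loc$fat[1], 0.5, -20,
                      0, loc$connective[1], 0.5,
                      0, loc$muscle[1], 0.5, 0), nm)
  upper <- setNames(c(10 * total_mass, loc$fat[2], 60, 0,
                      10 * total_mass, loc$connective[2], 60,
                      10 * total_mass, loc$muscle[2], 60, 20), nm)
  list(lower = lower, upper = upper)
}

# Peak/width/mass summary of a weighted bin range. The mass-weighted SD
# is inflated by neighbouring components leaking into the range, so it
# is capped by a half-maximum width taken around the peak, which
# ignores far tails.
.peak_stats <- function(x, w, bin_width) {
  mass <- sum(w)
  pk <- which.max(w)             # which.max takes the first (lowest HU) tie
  m1 <- sum(w * x) / mass
  sig_sd <- sqrt(sum(w * (x - m1)^2) / mass)
  above <- w >= w[pk] / 2
  lo <- pk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk
  while (hi < length(w) && above[hi + 1L]) hi <- hi + 1L
  sig_fwhm <- (x[hi] - x[lo] + bin_width) / 2.3548
  list(mu = x[pk], sigma = max(1, min(sig_sd, sig_fwhm)), N = mass)
}

#' Feasible starting profile for the trimodal fit
#'
#' Fat and muscle start from their attenuation domains: location at the
#' argmax bin (ties broken toward the lowest HU), amplitude at the
#' domain mass, width at the mass-weighted standard deviation capped by
#' a half-maximum width and floored at 1 HU. The connective component
#' is then located on the residual histogram left after subtracting the
#' fat and muscle starting components, over the admissible connective
#' location range: connective peaks often sit below the water-equivalent
#' attenuation window, where a domain argmax would instead pick up the
#' muscle tail. Skewness starts at -2 (fat), 0 (connective), +2
#' (muscle). Ranges with no mass get a small positive amplitude floor
#' so the start is feasible.
#'
#' @param hist A [hu_histogram] with positive total mass.
#' @return An [ntra_profile].
#' @export
initialize_profile <- function(hist) {
  stopifnot(inherits(hist, "hu_histogram"))
  total <- sum(hist$values)
  if (total <= 0)
    stop("degenerate input: histogram has no mass", call. = FALSE)
  dom <- tissue_domains()
  loc <- location_domains()
  side <- function(tis, alpha0) {
    sel <- hist$bin_centers >= dom[[tis]][1] & hist$bin_centers <= dom[[tis]][2]
    w <- hist$values[sel]
    if (sum(w) > 0) {
      st <- .peak_stats(hist$bin_centers[sel], w, hist$bin_width)
    } else {
      st <- list(mu = mean(dom[[tis]]), sigma = diff(dom[[tis]]) / 6,
                 N = 1e-3 * total)  # positive floor keeps the start feasible
    }
    mu <- min(max(st$mu, loc[[tis]][1]), loc[[tis]][2])
    skew_component(st$N, mu, max(st$sigma, 1), alpha0)
  }
  fat <- side("fat", -2)
  muscle <- side("muscle", 2)
  resid <- hist$values -
    (component_density(hist$bin_centers, fat) +
       component_density(hist$bin_centers, muscle)) * hist$bin_width
  resid <- pmax(resid, 0)
  csel <- hist$bin_centers >= max(loc$connective[1], fat$location_mu + 1) &
    hist$bin_centers <= loc$connective[2]
  if (sum(resid[csel]) > 0.01 * total) {
    st <- .peak_stats(hist$bin_centers[csel], resid[csel], hist$bin_width)
    cmu <- min(max(st$mu, fat$location_mu + 0.5), loc$connective[2])
    connective <- skew_component(st$N, cmu, max(st$sigma, 1), 0)
  } else {
    connective <- skew_component(1e-3 * total, mean(c(-30, 10)), 15, 0)
  }
  ntra_profile(fat, connective, muscle)
}

#' Fit the trimodal model to an HU histogram
#'
#' Bound-constrained nonlinear least squares: minimizes the sum over
#' bins of `(value - trimodal_density(center) * bin_width)^2` with a
#' Levenberg-Marquardt solver ([minpack.lm::nls.lm]). Amplitudes are
#' therefore reported in the histogram's own area units: fitting a
#' count histogram yields count-scale amplitudes, fitting a
#' density-mass histogram yields amplitudes on that scale (use
#' [normalize_histogram] to choose the unit).
#'
#' @param hist A [hu_histogram].
#' @param init Optional starting [ntra_profile]; defaults to
#'   [initialize_profile].
#' @param bounds Optional list with `lower` and `upper` numeric
#'   11-vectors in canonical order; defaults to [default_fit_bounds].
#' @param tol Convergence tolerance on the relative reduction of the
#'   objective (and on parameter change).
#' @param max_iter Maximum solver iterations.
#' @return An object of class `ntra_fit` with elements `profile`,
#'   `objective_value` (sum of squared residuals), `converged`,
#'   `n_iterations`, `residuals`.
#' @examples
#' p <- vector_to_profile(c(54.8, -116.6, 8.4, -2.3, 43.2, -21.0, 24.9,
#'                          78.3, 61.0, 8.9, 3.0))
#' h <- render_histogram(p)
#' fit <- fit_ntra(h)
#' fit$objective_value   # ~0: noiseless self-rendered histogram
#' @export
fit_ntra <- function(hist, init = NULL, bounds = NULL, tol = 1e-10,
                     max_iter = 200L) {
  stopifnot(inherits(hist, "hu_histogram"), tol > 0)
  auto_init <- is.null(init)
  if (auto_init) init <- initialize_profile(hist)
  stopifnot(inherits(init, "ntra_profile"))
  if (is.null(bounds)) bounds <- default_fit_bounds(sum(hist$values))
  lower <- as.numeric(bounds$lower)
  upper <- as.numeric(bounds$upper)
  if (length(lower) != 11L || length(upper) != 11L)
    stop("bounds must supply lower and upper 11-vectors", call. = FALSE)
  par0 <- profile_to_vector(init)
  if (any(par0 < lower - 1e-12) || any(par0 > upper + 1e-12)) {
    bad <- ntra_parameter_names()[par0 < lower - 1e-12 | par0 > upper + 1e-12]
    stop("infeasible initialization outside bounds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  par0 <- pmin(pmax(par0, lower), upper)
  # evaluate straight from the parameter vector: intermediate solver
  # iterates may transiently violate the profile ordering invariant
  raw_density <- function(x, par) {
    comp <- function(N, mu, sig, al) {
      z <- (x - mu) / sig
      N / (sig * sqrt(2 * pi)) * exp(-z^2 / 2) * erfc(al * z / sqrt(2))
    }
    comp(par[1], par[2], par[3], par[4]) +
      comp(par[5], par[6], par[7], 0) +
      comp(par[8], par[9], par[10], par[11])
  }
  resid_fn <- function(par) {
    hist$values - raw_density(hist$bin_centers, par) * hist$bin_width
  }
  solve_from <- function(p0) minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = tol, ptol = tol, gtol = 0, maxiter = min(max_iter, 1024L)))
  res <- solve_from(par0)
  # multi-start safety net: least-squares surfaces of overlapping
  # mixtures carry local minima, mostly tied to the connective start.
  # With an automatic start and a poor optimum, retry from a spread of
  # connective locations and keep the best solution found.
  if (auto_init && sum(res$fvec^2) > 1e-9 * sum(hist$values^2)) {
    for (cmu in c(-40, -20, 0, 20)) {
      p0 <- par0
      if (cmu <= max(lower[6], par0[2] + 0.5)) next
      p0[6] <- cmu
      p0[7] <- min(max(20, lower[7]), upper[7])
      alt <- solve_from(p0)
      if (sum(alt$fvec^2) < sum(res$fvec^2)) res <- alt
      if (sum(res$fvec^2) <= 1e-9 * sum(hist$values^2)) break
    }
  }
  profile <- tryCatch(vector_to_profile(res$par), error = function(e) NULL)
  invalid <- is.null(profile)
  if (invalid) {
    # best-found point violates the ordering invariant: return it
    # unvalidated rather than raising, flagged as non-converged
    v <- res$par
    profile <- structure(list(
      fat = structure(list(amplitude_N = v[1], location_mu = v[2],
                           width_sigma = v[3], skewness_alpha = v[4]),
                      class = "skew_component"),
      connective = structure(list(amplitude_N = v[5], location_mu = v[6],
                                  width_sigma = v[7], skewness_alpha = 0),
                             class = "skew_component"),
      muscle = structure(list(amplitude_N = v[8], location_mu = v[9],
                              width_sigma = v[10], skewness_alpha = v[11]),
                         class = "skew_component")), class = "ntra_profile")
  }
  structure(list(
    profile = profile,
    objective_value = sum(res$fvec^2),
    converged = (res$info %in% 1:4) && !invalid,
    n_iterations = res$niter,
    residuals = res$fvec,
    message = res$message), class = "ntra_fit")
}

#' @export
print.ntra_fit <- function(x, ...) {
  cat(sprintf("<ntra_fit> objective %.6g after %d iterations (%s)\n",
              x$objective_value, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$profile)
  invisible(x)
}
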