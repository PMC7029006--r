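#' Skew-Gaussian tissue component
#'
#' One tissue component of the trimodal soft-tissue model: a Gaussian
#' density scaled by amplitude `N` and multiplied by the complementary
#' error function term `erfc(alpha * (x - mu) / (sigma * sqrt(2)))`,
#' which introduces asymmetry. `alpha = 0` recovers the plain Gaussian;
#' the unit-amplitude component integrates to 1 over the real line for
#' any `alpha`, so `N` is the component area.
#'
#' @param amplitude_N Nonnegative amplitude, in histogram-area units.
#' @param location_mu Location (peak of the underlying Gaussian), HU.
#' @param width_sigma Positive width, HU.
#' @param skewness_alpha Dimensionless skewness; fixed at 0 for the
#'   connective component.
#' @return An object of class `skew_component`.
#' @examples
#' fat <- skew_component(51.5, -118.0, 9.6, -2.8)
#' component_density(-118, fat)  # N / (sigma * sqrt(2*pi)) since erfc(0) = 1
#' @export
skew_component <- function(amplitude_N, location_mu, width_sigma,
                           skewness_alpha = 0) {
  vals <- c(amplitude_N, location_mu, width_sigma, skewness_alpha)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("skew_component parameters must be finite scalars", call. = FALSE)
  if (amplitude_N < 0) stop("amplitude_N must be >= 0", call. = FALSE)
  if (width_sigma <= 0) stop("width_sigma must be > 0", call. = FALSE)
  structure(
    list(amplitude_N = amplitude_N, location_mu = location_mu,
         width_sigma = width_sigma, skewness_alpha = skewness_alpha),
    class = "skew_component")
}

#' @export
print.skew_component <- function(x, ...) {
  cat(sprintf("<skew_component> N=%.4g  mu=%.4g HU  sigma=%.4g HU  alpha=%.4g\n",
              x$amplitude_N, x$location_mu, x$width_sigma, x$skewness_alpha))
  invisible(x)
}

# erfc via the normal CDF: erfc(t) = 2 * pnorm(-t * sqrt(2))
erfc <- function(t) 2 * pnorm(-t * sqrt(2))

#' Evaluate one skew-Gaussian component density
#'
#' Computes
#' \deqn{\varphi(x) = \frac{N}{\sigma\sqrt{2\pi}}
#'   e^{-(x-\mu)^2 / (2\sigma^2)}
#'   \,\mathrm{erfc}\!\left(\frac{\alpha(x-\mu)}{\sigma\sqrt{2}}\right).}
#' At `x = mu` the value is `N / (sigma * sqrt(2*pi))` for any `alpha`,
#' because `erfc(0) = 1`.
#'
#' @param x Numeric vector of HU values.
#' @param params A [skew_component].
#' @return Nonnegative density values, one per element of `x`.
#' @export
component_density <- function(x, params) {
  stopifnot(inherits(params, "skew_component"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("x must be finite numeric", call. = FALSE)
  z <- (x - params$location_mu) / params$width_sigma
  params$amplitude_N / (params$width_sigma * sqrt(2 * pi)) *
    exp(-z^2 / 2) * erfc(params$skewness_alpha * z / sqrt(2))
}

#' Integrate a component over the HU range
#'
#' Adaptive quadrature of [component_density] over `[-200, 200]`. For a
#' component whose mass lies well inside the range this returns the
#' amplitude `N`, since the erfc-form skew normal integrates to its
#' amplitude over the real line.
#'
#' @param params A [skew_component].
#' @param lower,upper Integration limits, HU.
#' @return The component area (histogram-area units).
#' @export
component_area <- function(params, lower = -200, upper = 200) {
  stopifnot(inherits(params, "skew_component"))
  if (params$amplitude_N == 0) return(0)
  # split at the location so the quadrature always has a node at the
  # peak: a narrow component far from the interval midpoint can
  # otherwise be missed entirely by the adaptive rule
  mid <- min(max(params$location_mu, lower), upper)
  piece <- function(a, b) {
    if (b <= a) return(0)
    integrate(component_density, a, b, params = params,
              rel.tol = 1e-10, subdivisions = 500L)$value
  }
  piece(lower, mid) + piece(mid, upper)
}
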