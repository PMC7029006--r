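#' Tissue HU domains
#'
#' The HU attenuation intervals assumed for the three tissue types:
#' fat `[-200, -10]`, loose connective tissue `[-9, 40]`, lean muscle
#' `[41, 200]`. These partition the histogram for initialization.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
tissue_domains <- function() {
  list(fat = c(-200, -10), connective = c(-9, 40), muscle = c(41, 200))
}

# Admissible ranges for component *locations*. Fitted connective
# locations sit well below the connective attenuation window (cohort
# means near -15 to -28 HU, female subgroups near -45 HU), so the
# connective location range is wider than its attenuation domain.
location_domains <- function() {
  list(fat = c(-200, -10), connective = c(-80, 40), muscle = c(41, 200))
}

#' 11-parameter trimodal soft-tissue profile
#'
#' Bundles the three tissue components into one profile. Locations must
#' be ordered fat < connective < muscle and lie in admissible per-tissue
#' ranges (fat `[-200, -10]`, connective `[-80, 40]`, muscle
#' `[41, 200]` HU); the connective skewness is identically zero (it is
#' not a free parameter), so the profile carries exactly 11 free
#' parameters.
#'
#' @param fat,connective,muscle [skew_component] objects.
#' @return An object of class `ntra_profile`.
#' @examples
#' p <- ntra_profile(
#'   fat        = skew_component(51.5, -118.0, 9.6, -2.8),
#'   connective = skew_component(43.6, -14.5, 24.3, 0),
#'   muscle     = skew_component(82.4, 61.5, 8.5, 2.9))
#' profile_to_vector(p)
#' @export
ntra_profile <- function(fat, connective, muscle) {
  for (cmp in list(fat, connective, muscle))
    stopifnot(inherits(cmp, "skew_component"))
  if (connective$skewness_alpha != 0)
    stop("connective skewness_alpha must be identically 0", call. = FALSE)
  dom <- location_domains()
  locs <- c(fat$location_mu, connective$location_mu, muscle$location_mu)
  if (!(locs[1] < locs[2] && locs[2] < locs[3]))
    stop("component locations must satisfy fat < connective < muscle",
         call. = FALSE)
  for (i in seq_along(dom)) {
    if (locs[i] < dom[[i]][1] || locs[i] > dom[[i]][2])
      stop(sprintf("%s location %.3g HU outside its tissue domain [%g, %g]",
                   names(dom)[i], locs[i], dom[[i]][1], dom[[i]][2]),
           call. = FALSE)
  }
  structure(list(fat = fat, connective = connective, muscle = muscle),
            class = "ntra_profile")
}

#' @export
print.ntra_profile <- function(x, ...) {
  cat("<ntra_profile> (11 parameters)\n")
  for (tis in c("fat", "connective", "muscle")) {
    cmp <- x[[tis]]
    cat(sprintf("  %-10s N=%7.3f  mu=%9.3f  sigma=%7.3f  alpha=%6.3f\n",
                tis, cmp$amplitude_N, cmp$location_mu, cmp$width_sigma,
                cmp$skewness_alpha))
  }
  invisible(x)
}

#' Canonical parameter names for the flat 11-vector
#' @return Character vector of length 11.
#' @export
ntra_parameter_names <- function() {
  c("fat_N", "fat_mu", "fat_sigma", "fat_alpha",
    "conn_N", "conn_mu", "conn_sigma",
    "musc_N", "musc_mu", "musc_sigma", "musc_alpha")
}

#' Flatten a profile to the canonical 11-vector
#'
#' Order: fat N, mu, sigma, alpha; connective N, mu, sigma;
#' muscle N, mu, sigma, alpha. Inverse of [vector_to_profile].
#'
#' @param profile An [ntra_profile].
#' @return Named numeric vector of length 11.
#' @export
profile_to_vector <- function(profile) {
  stopifnot(inherits(profile, "ntra_profile"))
  setNames(
    c(profile$fat$amplitude_N, profile$fat$location_mu,
      profile$fat$width_sigma, profile$fat$skewness_alpha,
      profile$connective$amplitude_N, profile$connective$location_mu,
      profile$connective$width_sigma,
      profile$muscle$amplitude_N, profile$muscle$location_mu,
      profile$muscle$width_sigma, profile$muscle$skewness_alpha),
    ntra_parameter_names())
}

#' Rebuild a profile from the canonical 11-vector
#' @param v Numeric vector of length 11 in canonical order.
#' @return An [ntra_profile].
#' @export
vector_to_profile <- function(v) {
  if (!is.numeric(v) || length(v) != 11L)
    stop("expected a numeric vector of length 11", call. = FALSE)
  v <- unname(v)
  ntra_profile(
    fat        = skew_component(v[1], v[2], v[3], v[4]),
    connective = skew_component(v[5], v[6], v[7], 0),
    muscle     = skew_component(v[8], v[9], v[10], v[11]))
}

#' Trimodal model density
#'
#' The sum of the three component densities of a profile, evaluated at
#' HU values `x`.
#'
#' @param x Numeric vector of HU values.
#' @param profile An [ntra_profile].
#' @return Nonnegative density values.
#' @export
trimodal_density <- function(x, profile) {
  stopifnot(inherits(profile, "ntra_profile"))
  component_density(x, profile$fat) +
    component_density(x, profile$connective) +
    component_density(x, profile$muscle)
}
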