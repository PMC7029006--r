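#' Binned HU histogram
#'
#' A radiodensitometric distribution binned on an equally spaced grid
#' inside `[-200, 200]` HU. The default grid is 401 integer-centred
#' 1-HU bins from -200 to 200.
#'
#' @param bin_centers Strictly increasing, equally spaced bin centres (HU).
#' @param values Nonnegative bin values (counts or density mass), same
#'   length as `bin_centers`.
#' @param bin_width Positive bin width (HU); inferred from the centres
#'   when omitted.
#' @return An object of class `hu_histogram`.
#' @export
hu_histogram <- function(bin_centers, values, bin_width = NULL) {
  if (!is.numeric(bin_centers) || !is.numeric(values))
    stop("bin_centers and values must be numeric", call. = FALSE)
  if (length(bin_centers) != length(values) || length(bin_centers) < 2L)
    stop("bin_centers and values must have equal length >= 2", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("histogram values must be nonnegative and non-missing", call. = FALSE)
  d <- diff(bin_centers)
  if (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d))
    stop("bin_centers must be strictly increasing with constant spacing",
         call. = FALSE)
  if (is.null(bin_width)) bin_width <- mean(d)
  if (abs(bin_width - mean(d)) > 1e-8 * bin_width)
    stop("bin_width inconsistent with bin_centers spacing", call. = FALSE)
  if (min(bin_centers) < -200 || max(bin_centers) > 200)
    stop("bin_centers must lie within [-200, 200] HU", call. = FALSE)
  structure(list(bin_centers = as.numeric(bin_centers),
                 values = as.numeric(values),
                 bin_width = bin_width),
            class = "hu_histogram")
}

#' @export
print.hu_histogram <- function(x, ...) {
  cat(sprintf("<hu_histogram> %d bins of %g HU on [%g, %g]; total mass %.4g\n",
              length(x$bin_centers), x$bin_width, min(x$bin_centers),
              max(x$bin_centers), sum(x$values)))
  invisible(x)
}

#' The default 1-HU evaluation grid
#' @return Integer bin centres -200, -199, ..., 200.
#' @export
default_grid <- function() seq(-200, 200, by = 1)

#' Rescale a histogram to a target total mass
#'
#' Multiplies the bin values so that `sum(values)` equals `total_mass`.
#' Useful for putting count histograms on a density-like scale before
#' fitting, so fitted amplitudes come out in the requested area units.
#'
#' @param hist A [hu_histogram].
#' @param total_mass Positive target for the summed bin values.
#' @return A rescaled [hu_histogram].
#' @export
normalize_histogram <- function(hist, total_mass = 1) {
  stopifnot(inherits(hist, "hu_histogram"), total_mass > 0)
  s <- sum(hist$values)
  if (s <= 0) stop("cannot normalize an all-zero histogram", call. = FALSE)
  hu_histogram(hist$bin_centers, hist$values * (total_mass / s),
               hist$bin_width)
}
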