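#' Construct an absorption spectrum
#'
#' A `spectrum` is the universal observable of pigment spectroscopy: a pair of
#' equal-length vectors, wavelength in nm (strictly increasing) and absorbance
#' in absorbance units (AU). An optional `label` identifies the sample or
#' state and an optional `time_s` time-stamps the spectrum relative to a light
#' exposure.
#'
#' @param wavelength Numeric vector of wavelengths (nm), strictly increasing,
#'   length >= 2.
#' @param absorbance Numeric vector of absorbances (AU), same length; may be
#'   negative for difference spectra.
#' @param label Optional character label.
#' @param time_s Optional time stamp in seconds after irradiation.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength, absorbance, label = NULL, time_s = NULL) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two points")
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have equal length")
  if (!all(is.finite(wavelength)) || !all(is.finite(absorbance)))
    stop("spectrum values must be finite")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(
    list(wavelength = wavelength, absorbance = absorbance,
         label = label, time_s = time_s),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  lab <- if (is.null(x$label)) "<unlabelled>" else x$label
  cat(sprintf("spectrum '%s': %d points, %.1f-%.1f nm", lab,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  if (!is.null(x$time_s)) cat(sprintf(", t = %g s", x$time_s))
  cat(sprintf(", max A = %.4g AU\n", max(x$absorbance)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength) == length(b$wavelength) &&
    max(abs(a$wavelength - b$wavelength)) <= tol
}

#' Difference spectrum (pointwise a - b)
#'
#' Light-induced spectral changes are isolated by subtracting two absorption
#' spectra recorded on the same wavelength grid, e.g. the spectrum after
#' yellow-light irradiation from the spectrum after subsequent UV
#' irradiation. The grids must agree exactly; align with [resample()] first
#' if they do not (silent interpolation inside a subtraction hides errors).
#'
#' @param a,b `spectrum` objects on identical wavelength grids.
#' @return A `difference_spectrum` (also a `spectrum`; values may be
#'   negative) carrying `minuend` and `subtrahend` labels.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!same_grid(a, b))
    stop("spectra are on different wavelength grids; resample() first")
  out <- spectrum(a$wavelength, a$absorbance - b$absorbance,
                  label = paste0(a$label %||% "a", " - ", b$label %||% "b"))
  out$minuend <- a$label
  out$subtrahend <- b$label
  class(out) <- c("difference_spectrum", "spectrum")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the only sanctioned way to align grids before
#' arithmetic. Extrapolation beyond the recorded span is refused.
#'
#' @param s A `spectrum`.
#' @param grid New wavelength grid (nm), strictly increasing, within the
#'   span of `s`.
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < min(s$wavelength) || max(grid) > max(s$wavelength))
    stop("resample would extrapolate beyond the recorded wavelength span")
  a <- stats::approx(s$wavelength, s$absorbance, xout = grid)$y
  spectrum(grid, a, label = s$label, time_s = s$time_s)
}

#' Subtract a constant baseline estimated from a flat region
#'
#' Purified-pigment spectra often carry a small constant offset; estimate it
#' as the mean absorbance over a wavelength region where the pigment does not
#' absorb and subtract it.
#'
#' @param s A `spectrum`.
#' @param flat_region Length-2 nm interval assumed absorbance-free
#'   (default 680-700 nm).
#' @return Baseline-corrected `spectrum`.
#' @export
baseline_correct <- function(s, flat_region = c(680, 700)) {
  stopifnot(inherits(s, "spectrum"), length(flat_region) == 2)
  sel <- s$wavelength >= flat_region[1] & s$wavelength <= flat_region[2]
  if (!any(sel)) stop("flat region contains no grid points")
  spectrum(s$wavelength, s$absorbance - mean(s$absorbance[sel]),
           label = s$label, time_s = s$time_s)
}

#' Estimate the wavelength of maximal absorbance
#'
#' Finds the maximum of the spectrum inside `search_window` and refines it by
#' fitting a parabola through the maximal point and its two neighbours
#' (3-point quadratic interpolation), returning a continuous nm value. The
#' default window (420-600 nm) targets the visible band of a dark-state
#' pigment and excludes the UV meta II band and the protein band.
#'
#' The estimate is invariant under positive scaling and constant offsets of
#' the absorbance.
#'
#' @param s A `spectrum`.
#' @param search_window Length-2 nm interval; must lie within the grid and
#'   contain at least 5 grid points.
#' @return Estimated lambda-max in nm.
#' @export
estimate_lambda_max <- function(s, search_window = c(420, 600)) {
  stopifnot(inherits(s, "spectrum"), length(search_window) == 2)
  if (search_window[1] < min(s$wavelength) ||
      search_window[2] > max(s$wavelength))
    stop("search window extends beyond the wavelength grid")
  sel <- which(s$wavelength >= search_window[1] &
               s$wavelength <= search_window[2])
  if (length(sel) < 5L) stop("search window contains fewer than 5 points")
  wl <- s$wavelength[sel]
  ab <- s$absorbance[sel]
  i <- which.max(ab)
  if (i == 1L || i == length(ab))
    stop("maximum lies at the window edge; peak not bracketed")
  # quadratic through the three bracketing points; exact on a parabola and
  # valid on non-uniform grids
  x <- wl[(i - 1L):(i + 1L)]
  y <- ab[(i - 1L):(i + 1L)]
  co <- solve(cbind(1, x, x^2), y)
  if (co[3] >= 0) stop("local curvature is not concave; peak not resolved")
  as.numeric(-co[2] / (2 * co[3]))
}
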