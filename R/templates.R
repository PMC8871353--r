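#' Nomogram constants for A1 visual-pigment templates
#'
#' Constants of the standard A1 (retinal-based) visual pigment absorbance
#' template. The alpha band is
#' \deqn{S(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D),
#'       \quad x = \lambda_{max}/\lambda,}
#' with the position parameter
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}}; the beta
#' (cis-) band is a Gaussian
#' \eqn{A_\beta \exp[-((\lambda - \lambda_{m\beta})/b_\beta)^2]} with
#' \eqn{\lambda_{m\beta} = 189 + 0.315\,\lambda_{max}} and
#' \eqn{b_\beta = -40.5 + 0.195\,\lambda_{max}}.
#'
#' All constants are configurable so alternative template families can be
#' swapped in without touching the evaluation code.
#'
#' @return Named list with `alpha` (A, B, C, D, b, c and the `a0`, `a1`,
#'   `a2` coefficients of the lambda-max-dependent `a`) and `beta`
#'   (`amplitude`, `peak_intercept`, `peak_slope`, `band_intercept`,
#'   `band_slope`) constant sets.
#' @export
nomogram_constants <- function() {
  list(
    alpha = list(A = 69.7, B = 28, C = -14.9, D = 0.674,
                 b = 0.922, c = 1.104,
                 a0 = 0.8795, a1 = 0.0459, a2 = 11940),
    beta = list(amplitude = 0.26,
                peak_intercept = 189, peak_slope = 0.315,
                band_intercept = -40.5, band_slope = 0.195))
}

validate_template_params <- function(lambda_max, constants) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      !is.finite(lambda_max))
    stop("lambda_max must be a single finite number")
  if (lambda_max < 300 || lambda_max > 700)
    stop("lambda_max outside the template validity range [300, 700] nm")
  cn <- unlist(constants)
  if (!all(is.finite(cn))) stop("nomogram constants must be finite")
  if (constants$beta$amplitude < 0)
    stop("beta-band amplitude must be non-negative")
  invisible(TRUE)
}

alpha_band <- function(lambda, lambda_max, k) {
  a <- k$a0 + k$a1 * exp(-(lambda_max - 300)^2 / k$a2)
  x <- lambda_max / lambda
  1 / (exp(k$A * (a - x)) + exp(k$B * (k$b - x)) +
       exp(k$C * (k$c - x)) + k$D)
}

beta_band <- function(lambda, lambda_max, k) {
  lm_beta <- k$peak_intercept + k$peak_slope * lambda_max
  b_beta <- k$band_intercept + k$band_slope * lambda_max
  k$amplitude * exp(-((lambda - lm_beta) / b_beta)^2)
}

#' Model absorption spectrum of a visual pigment state
#'
#' Evaluates the lambda-max-parameterised nomogram (alpha band, optionally
#' plus beta band) pointwise on `grid` and peak-normalises the result to 1.
#' Evaluation is pointwise, never interpolated, so refining the grid does not
#' change values at shared wavelengths (up to the peak normalisation, which
#' uses the grid maximum).
#'
#' @param lambda_max Peak wavelength of the alpha band (nm), in
#'   \[300, 700\].
#' @param grid Wavelength grid (nm), strictly increasing, within
#'   \[250, 800\], and covering `lambda_max`.
#' @param include_beta Include the beta (cis-) band? Typically `TRUE` for
#'   states absorbing in the visible (dark state, meta III) and `FALSE` for
#'   meta II, whose alpha band already sits in the UV.
#' @param constants Nomogram constant set, see [nomogram_constants()].
#' @param label Optional label attached to the returned spectrum.
#' @return A peak-normalised, non-negative `spectrum` on `grid`.
#' @export
template_spectrum <- function(lambda_max, grid,
                              include_beta = TRUE,
                              constants = nomogram_constants(),
                              label = NULL) {
  validate_template_params(lambda_max, constants)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) < 250 || max(grid) > 800)
    stop("grid must lie within 250-800 nm")
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("grid does not cover lambda_max")
  y <- alpha_band(grid, lambda_max, constants$alpha)
  if (include_beta) y <- y + beta_band(grid, lambda_max, constants$beta)
  spectrum(grid, y / max(y), label = label)
}

#' Default lambda-max and beta-band settings per photocycle state
#'
#' Meta II absorbs at 380 nm (unprotonated Schiff base), meta III near
#' 470 nm, meta I (optional, relevant for aspartate mutants) near 478 nm.
#' The beta band is included for visible-absorbing states and omitted for
#' meta II.
#'
#' @return Named list: per-state `lambda_max` defaults for the intermediate
#'   states and per-state `include_beta` flags.
#' @export
state_defaults <- function() {
  list(lambda_max = c(metaI = 478, metaII = 380, metaIII = 470),
       include_beta = c(dark = TRUE, metaI = TRUE, metaII = FALSE,
                        metaIII = TRUE))
}

#' Build a set of state templates on a shared grid
#'
#' Bundles one peak-normalised template per photocycle state, all on one
#' wavelength grid, to serve as the basis for spectral unmixing.
#'
#' @param lambda_max_by_state Named numeric vector, e.g.
#'   `c(dark = 500, metaII = 380, metaIII = 470)`. Names must be unique and
#'   drawn from `dark`, `metaI`, `metaII`, `metaIII`.
#' @param grid Shared wavelength grid (nm); default 250-700 nm, 1-nm step.
#' @param include_beta Optional named logical vector overriding the
#'   per-state beta-band defaults of [state_defaults()].
#' @param constants Nomogram constant set.
#' @return A `template_set`: list with `grid`, `basis` (wavelength x state
#'   matrix of peak-normalised curves) and `lambda_max`.
#' @export
build_template_set <- function(lambda_max_by_state, grid = seq(250, 700, 1),
                               include_beta = NULL,
                               constants = nomogram_constants()) {
  states <- names(lambda_max_by_state)
  if (length(lambda_max_by_state) == 0L)
    stop("lambda_max_by_state must be non-empty")
  if (is.null(states) || any(states == ""))
    stop("lambda_max_by_state must be fully named")
  if (anyDuplicated(states)) stop("duplicate state names")
  known <- c("dark", "metaI", "metaII", "metaIII")
  if (!all(states %in% known))
    stop("unknown state name(s): ",
         paste(setdiff(states, known), collapse = ", "))
  beta_flags <- state_defaults()$include_beta[states]
  if (!is.null(include_beta)) beta_flags[names(include_beta)] <- include_beta
  basis <- vapply(states, function(s) {
    template_spectrum(lambda_max_by_state[[s]], grid,
                      include_beta = beta_flags[[s]],
                      constants = constants, label = s)$absorbance
  }, numeric(length(grid)))
  structure(list(grid = as.numeric(grid), basis = basis,
                 lambda_max = lambda_max_by_state),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set: %s on %.0f-%.0f nm (%d points)\n",
              paste(sprintf("%s(%g nm)", colnames(x$basis), x$lambda_max),
                    collapse = ", "),
              min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' Extract one state's template as a spectrum
#'
#' @param templates A `template_set`.
#' @param state State name.
#' @return A `spectrum`.
#' @export
template_as_spectrum <- function(templates, state) {
  stopifnot(inherits(templates, "template_set"))
  if (!state %in% colnames(templates$basis))
    stop("no template for state '", state, "'")
  spectrum(templates$grid, templates$basis[, state], label = state)
}
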