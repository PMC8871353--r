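#' @importFrom pracma lsqnonneg
NULL

window_index <- function(grid, fit_window) {
  stopifnot(length(fit_window) == 2, fit_window[1] < fit_window[2])
  sel <- which(grid >= fit_window[1] & grid <= fit_window[2])
  if (length(sel) < 2L) stop("fit window contains fewer than 2 grid points")
  sel
}

check_basis_rank <- function(B) {
  if (qr(B)$rank < ncol(B))
    stop("template matrix is rank deficient (collinear templates, e.g. two ",
         "states with equal lambda_max); refusing to fit")
}

new_mixture_estimate <- function(fractions, residual_rms, fit_window, scale,
                                 warning_flag = NULL) {
  stopifnot(all(fractions >= -1e-12), residual_rms >= 0)
  structure(list(fractions = pmax(fractions, 0),
                 residual_rms = residual_rms,
                 fit_window = fit_window, scale = scale,
                 warning_flag = warning_flag),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("mixture estimate (fractions, %):\n")
  print(round(100 * x$fractions, 1))
  cat(sprintf("residual rms = %.3g AU over %g-%g nm; scale = %.4g AU\n",
              x$residual_rms, x$fit_window[1], x$fit_window[2],
              if (is.null(x$scale)) NA else x$scale))
  if (!is.null(x$warning_flag)) cat("warning:", x$warning_flag, "\n")
  invisible(x)
}

# Non-negative least squares with an optional exact sum-to-<=1 constraint.
# The inequality sum(f) <= 1 is recast with a slack state as the equality
# sum(f) + slack = 1, f, slack >= 0, and the equality is imposed through a
# heavily weighted extra row; the active-set NNLS solves the augmented
# system exactly, so the constraint holds to the weight's resolution.
nnls_simplex <- function(B, y, sum_leq_one = FALSE) {
  if (!sum_leq_one) return(pracma::lsqnonneg(B, y)$x)
  w <- 1e7 * max(1, max(abs(B)))
  A <- rbind(cbind(B, 0), w)
  f <- pracma::lsqnonneg(A, c(y, w))$x
  f <- f[-length(f)]
  tot <- sum(f)
  if (tot > 1) f <- f / tot
  f
}

#' Decompose a spectrum into non-negative state fractions
#'
#' Least-squares fit of an observed absorption spectrum as a non-negative
#' combination of state templates over a fit window. The default window
#' (330-650 nm) covers the meta II UV band through the dark-state and
#' meta III visible bands while excluding the protein band.
#'
#' Coefficients are returned as fractions of a total pigment scale: if
#' `scale` (total pigment absorbance at unit template height, typically the
#' dark-state peak absorbance before irradiation) is supplied the
#' coefficients are divided by it; otherwise they are normalised by their
#' sum (and the sum is reported as the scale).
#'
#' @param observed A `spectrum` on the template grid.
#' @param templates A `template_set`.
#' @param fit_window Length-2 nm interval (default `c(330, 650)`).
#' @param scale Optional total pigment absorbance scale (AU).
#' @return A `mixture_estimate` with per-state `fractions`, `residual_rms`
#'   (AU, over the fit window), `fit_window` and `scale`.
#' @export
fit_components <- function(observed, templates, fit_window = c(330, 650),
                           scale = NULL) {
  stopifnot(inherits(observed, "spectrum"), inherits(templates, "template_set"))
  if (ncol(templates$basis) < 2L) stop("need at least 2 templates")
  if (!same_grid(observed, list(wavelength = templates$grid)))
    stop("observed spectrum and templates are on different grids")
  sel <- window_index(templates$grid, fit_window)
  B <- templates$basis[sel, , drop = FALSE]
  y <- observed$absorbance[sel]
  check_basis_rank(B)
  if (all(y == 0)) {
    f <- stats::setNames(numeric(ncol(B)), colnames(B))
    return(new_mixture_estimate(f, 0, fit_window, scale %||% 0))
  }
  coef <- pracma::lsqnonneg(B, y)$x
  names(coef) <- colnames(B)
  total <- scale %||% sum(coef)
  resid <- y - B %*% coef
  new_mixture_estimate(coef / total, sqrt(mean(resid^2)), fit_window, total)
}

#' Fit a UV-induced difference spectrum as a photoconversion from one state
#'
#' Models the difference spectrum (post-UV minus post-yellow) as conversion
#' of a fraction of the photolysed reference pool (meta II) into the other
#' states:
#' \deqn{\Delta A(\lambda) = s \sum_{k \ne ref} f_k
#'   (T_k(\lambda) - T_{ref}(\lambda)),}
#' with \eqn{f_k \ge 0} and \eqn{\sum f_k \le 1}. The remainder
#' \eqn{1 - \sum f_k} stays in the reference state, so the returned
#' composition is the full post-UV state population and sums to one exactly
#' -- the semantics of a component-ratio table row.
#'
#' The absorbance scale `s` cannot be inferred from a difference spectrum
#' alone; pass the total pigment scale measured on the pre-irradiation
#' dark-state spectrum (absorbance at lambda-max divided by the template
#' peak of 1). Fitting without a scale is refused.
#'
#' @param dsp A `difference_spectrum` (or `spectrum`) on the template grid.
#' @param templates A `template_set` containing the reference state.
#' @param reference_state Name of the photolysed pool (default `"metaII"`).
#' @param fit_window Length-2 nm interval (default `c(330, 650)`).
#' @param scale Total pigment absorbance scale (AU); required.
#' @return A `mixture_estimate` whose fractions cover all template states
#'   (reference included) and sum to 1.
#' @export
fit_photoconversion <- function(dsp, templates, reference_state = "metaII",
                                fit_window = c(330, 650), scale) {
  stopifnot(inherits(dsp, "spectrum"), inherits(templates, "template_set"))
  if (missing(scale) || is.null(scale))
    stop("scale is required: difference-only fitting with unknown total ",
         "pigment absorbance is refused rather than guessed")
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  states <- colnames(templates$basis)
  if (!reference_state %in% states)
    stop("reference state '", reference_state, "' not in template set")
  if (!same_grid(dsp, list(wavelength = templates$grid)))
    stop("difference spectrum and templates are on different grids")
  sel <- window_index(templates$grid, fit_window)
  others <- setdiff(states, reference_state)
  B <- templates$basis[sel, others, drop = FALSE] -
    templates$basis[sel, reference_state]
  check_basis_rank(B)
  y <- dsp$absorbance[sel] / scale
  warn <- NULL
  if (max(abs(dsp$absorbance[sel])) < 1e-12 * scale)
    warn <- "difference spectrum is ~0; composition is the reference state"
  f <- nnls_simplex(B, y, sum_leq_one = TRUE)
  names(f) <- others
  fractions <- c(f, stats::setNames(max(0, 1 - sum(f)), reference_state))
  fractions <- fractions[states]
  resid <- (y - B %*% f) * scale
  new_mixture_estimate(fractions, sqrt(mean(resid^2)), fit_window, scale,
                       warning_flag = warn)
}

#' Bootstrap confidence intervals for photoconversion fractions
#'
#' Residual-resampling bootstrap around [fit_photoconversion()]: residuals
#' of the point fit are resampled with replacement, added back to the fitted
#' difference spectrum, and the fit repeated. Deterministic for a fixed
#' seed; a noiseless input yields zero-width intervals.
#'
#' @inheritParams fit_photoconversion
#' @param n_boot Number of bootstrap replicates (>= 100 recommended,
#'   >= 2 required).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `point` (the `mixture_estimate`), `ci` (state x
#'   c(lower, upper) matrix) and `draws` (replicate x state matrix).
#' @export
bootstrap_fractions <- function(dsp, templates, reference_state = "metaII",
                                fit_window = c(330, 650), scale,
                                n_boot = 500, seed = 1, level = 0.95) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  point <- fit_photoconversion(dsp, templates, reference_state, fit_window,
                               scale)
  sel <- window_index(templates$grid, fit_window)
  states <- colnames(templates$basis)
  others <- setdiff(states, reference_state)
  B <- templates$basis[sel, others, drop = FALSE] -
    templates$basis[sel, reference_state]
  fitted <- as.numeric(B %*% point$fractions[others]) * scale
  resid <- dsp$absorbance[sel] - fitted
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(states),
                  dimnames = list(NULL, states))
  wl <- templates$grid[sel]
  for (b in seq_len(n_boot)) {
    yb <- fitted + sample(resid, length(resid), replace = TRUE)
    db <- spectrum(wl, yb)
    sub <- build_subset_grid(templates, sel)
    fb <- fit_photoconversion(db, sub, reference_state,
                              fit_window = range(wl), scale = scale)
    draws[b, ] <- fb$fractions[states]
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  # percentile intervals can exclude a boundary point estimate; widen to
  # contain it so the interval always covers the reported value
  ci[, "lower"] <- pmin(ci[, "lower"], point$fractions[states])
  ci[, "upper"] <- pmax(ci[, "upper"], point$fractions[states])
  list(point = point, ci = ci, draws = draws)
}

build_subset_grid <- function(templates, sel) {
  structure(list(grid = templates$grid[sel],
                 basis = templates$basis[sel, , drop = FALSE],
                 lambda_max = templates$lambda_max),
            class = "template_set")
}
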