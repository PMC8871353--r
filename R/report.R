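#' Component ratios of one pigment from its dark / post-yellow / post-UV spectra
#'
#' The full per-pigment analysis behind a component-ratio table row:
#' estimate the dark-state lambda-max, read the total pigment scale off the
#' dark spectrum, build nomogram templates (dark at the estimated
#' lambda-max, meta II at 380 nm, meta III at 470 nm), form the UV-minus-
#' yellow difference spectrum, and unmix it into post-UV state fractions
#' with [fit_photoconversion()].
#'
#' @param dark,post_yellow,post_uv `spectrum` objects on one shared grid:
#'   before irradiation, after yellow-light irradiation (the photolysed
#'   meta II pool), and after subsequent UV irradiation.
#' @param lambda_max_window Search window for the dark-state lambda-max.
#' @param fit_window Unmixing window (nm).
#' @param intermediate_lm Named lambda-max values for the intermediate
#'   templates.
#' @return List with `lambda_max` (nm), `fractions` (the
#'   `mixture_estimate`) and `scale` (AU).
#' @export
pigment_components <- function(dark, post_yellow, post_uv,
                               lambda_max_window = c(420, 600),
                               fit_window = c(330, 650),
                               intermediate_lm = c(metaII = 380,
                                                   metaIII = 470)) {
  lm <- estimate_lambda_max(dark, lambda_max_window)
  scale <- stats::approx(dark$wavelength, dark$absorbance, xout = lm)$y
  tpl <- build_template_set(c(dark = lm, intermediate_lm),
                            grid = dark$wavelength)
  dsp <- difference_spectrum(post_uv, post_yellow)
  est <- fit_photoconversion(dsp, tpl, reference_state = "metaII",
                             fit_window = fit_window, scale = scale)
  list(lambda_max = lm, fractions = est, scale = scale)
}

#' Component-ratio report over a directory of pigments
#'
#' Expects one subdirectory per pigment, each containing `dark.csv`,
#' `post_yellow.csv` and `post_uv.csv` two-column spectra. Produces one row
#' per pigment: lambda-max (nm) and the post-UV dark / meta II / meta III
#' percentages. Pigments with a missing spectrum role are skipped with a
#' warning; an empty directory yields an empty table with a warning.
#'
#' @param spectra_dir Directory of per-pigment subdirectories.
#' @param out Optional path; when given, the table is also written as CSV
#'   with percentages rounded to 1 decimal.
#' @inheritParams pigment_components
#' @return Data frame with columns `pigment`, `lambda_max_nm`,
#'   `dark_percent`, `metaII_percent`, `metaIII_percent`, `residual_rms`.
#' @export
pigment_report <- function(spectra_dir, out = NULL,
                           lambda_max_window = c(420, 600),
                           fit_window = c(330, 650)) {
  dirs <- list.dirs(spectra_dir, recursive = FALSE)
  empty <- data.frame(pigment = character(), lambda_max_nm = numeric(),
                      dark_percent = numeric(), metaII_percent = numeric(),
                      metaIII_percent = numeric(), residual_rms = numeric())
  if (!length(dirs)) {
    warning("no pigment subdirectories found in ", spectra_dir)
    return(empty)
  }
  rows <- list()
  for (d in dirs) {
    roles <- file.path(d, c("dark.csv", "post_yellow.csv", "post_uv.csv"))
    if (!all(file.exists(roles))) {
      warning("pigment '", basename(d), "' skipped: missing ",
              paste(basename(roles[!file.exists(roles)]), collapse = ", "))
      next
    }
    sp <- lapply(roles, read_spectrum)
    res <- pigment_components(sp[[1]], sp[[2]], sp[[3]],
                              lambda_max_window, fit_window)
    f <- res$fractions$fractions
    rows[[basename(d)]] <- data.frame(
      pigment = basename(d), lambda_max_nm = res$lambda_max,
      dark_percent = 100 * f[["dark"]],
      metaII_percent = 100 * f[["metaII"]],
      metaIII_percent = 100 * f[["metaIII"]],
      residual_rms = res$fractions$residual_rms)
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else empty
  if (!is.null(out)) {
    w <- tab
    num <- c("lambda_max_nm", "dark_percent", "metaII_percent",
             "metaIII_percent")
    w[num] <- lapply(w[num], function(x) sprintf("%.1f", x))
    utils::write.csv(w, out, row.names = FALSE, quote = FALSE)
  }
  tab
}
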