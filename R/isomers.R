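#' Default mapping of photocycle states to retinal isomers
#'
#' The dark state carries 11-cis-15-anti retinal; meta I and meta II carry
#' all-trans-15-anti; meta III carries all-trans-15-syn (the thermal
#' Schiff-base isomerisation product).
#'
#' @return Named character vector: state -> isomer label.
#' @export
default_isomer_map <- function() {
  c(dark = "11-cis-15-anti",
    metaI = "all-trans-15-anti",
    metaII = "all-trans-15-anti",
    metaIII = "all-trans-15-syn")
}

isomer_classes <- c("11-cis", "9-cis", "13-cis", "all-trans")

#' Convert state populations to a retinal isomer composition
#'
#' Percentages are 100 x the summed populations per isomer, the quantity an
#' HPLC retinal-configuration analysis reports after chromophore extraction.
#' Populations are renormalised only in the sense that they must already sum
#' to 1; every populated state must be mapped.
#'
#' @param populations Named population vector (sums to 1).
#' @param mapping Named character state -> isomer map; default
#'   [default_isomer_map()]. Isomer labels must start with one of `11-cis`,
#'   `9-cis`, `13-cis`, `all-trans`, optionally suffixed `-15-syn` or
#'   `-15-anti`.
#' @return An `isomer_composition`: named numeric percentages over the
#'   detailed isomer labels, with a `by_class` attribute collapsing the
#'   15-syn/anti annotation (summing to 100).
#' @export
state_to_isomer <- function(populations, mapping = default_isomer_map()) {
  pop <- populations[populations != 0]
  unmapped <- setdiff(names(pop), names(mapping))
  if (length(unmapped))
    stop("no isomer mapping for populated state(s): ",
         paste(unmapped, collapse = ", "))
  if (any(pop < 0)) stop("populations must be non-negative")
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1")
  labels <- mapping[names(pop)]
  pct <- 100 * tapply(as.numeric(pop), labels, sum)
  pct <- stats::setNames(as.numeric(pct), names(pct))
  cls <- vapply(names(pct), function(l) {
    hit <- isomer_classes[vapply(isomer_classes,
                                 function(c) startsWith(l, c), logical(1))]
    if (!length(hit)) stop("unrecognised isomer label: ", l)
    hit[which.max(nchar(hit))]
  }, "")
  by_class <- tapply(pct, cls, sum)
  by_class <- stats::setNames(as.numeric(by_class), names(by_class))
  structure(pct, by_class = by_class, class = "isomer_composition")
}

#' @export
print.isomer_composition <- function(x, ...) {
  cat("retinal isomer composition (%):\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Check spectral dark-state fraction against HPLC 11-cis content
#'
#' The dark state is the only state carrying 11-cis retinal, so the
#' spectrally fitted dark fraction and the chromatographic 11-cis percentage
#' of the same sample must agree; this reports their absolute discrepancy in
#' percentage points.
#'
#' @param mix A `mixture_estimate` (needs a `dark` fraction).
#' @param iso An `isomer_composition` for the same sample.
#' @param tol Pass threshold in percentage points (default 3).
#' @return List with `pass`, `discrepancy` (points), `dark_percent` and
#'   `cis11_percent`.
#' @export
consistency_check <- function(mix, iso, tol = 3) {
  stopifnot(inherits(mix, "mixture_estimate"),
            inherits(iso, "isomer_composition"))
  if (!"dark" %in% names(mix$fractions))
    stop("mixture estimate has no dark-state fraction")
  dark_pct <- 100 * mix$fractions[["dark"]]
  by_class <- attr(iso, "by_class")
  cis11 <- if ("11-cis" %in% names(by_class)) by_class[["11-cis"]] else 0
  d <- abs(dark_pct - cis11)
  list(pass = d <= tol, discrepancy = d,
       dark_percent = dark_pct, cis11_percent = cis11)
}

#' Simulate an HPLC isomer table with counting noise
#'
#' HPLC quantitation noise is emulated as multinomial sampling of an
#' effective number of chromophore molecules, renormalised to 100%.
#'
#' @param composition An `isomer_composition` (or named percentage vector
#'   summing to 100).
#' @param n_molecules Effective count driving the multinomial noise.
#' @param seed Integer seed.
#' @return Named percentage vector over the same isomer labels, summing to
#'   100.
#' @export
simulate_hplc_table <- function(composition, n_molecules = 10000, seed = 1) {
  p <- unclass(composition) / 100
  stopifnot(abs(sum(p) - 1) < 1e-3, n_molecules >= 1)
  set.seed(seed)
  counts <- stats::rmultinom(1, size = n_molecules, prob = p)[, 1]
  stats::setNames(100 * counts / sum(counts), names(p))
}

#' Split the regenerated dark pool between 11-cis and 9-cis retinal
#'
#' When a pigment is regenerated from all-trans retinal, the recovered dark
#' pool can contain both 11-cis and 9-cis chromophores. This extends the
#' default state->isomer accounting by splitting the dark state's
#' population by a user-stated 11-cis share; no default is assumed.
#'
#' @param populations Named population vector summing to 1.
#' @param cis11_share Fraction (0-1) of the dark pool carrying 11-cis; the
#'   remainder is 9-cis.
#' @return An `isomer_composition`.
#' @export
state_to_isomer_with_9cis <- function(populations, cis11_share) {
  stopifnot(is.numeric(cis11_share), length(cis11_share) == 1,
            cis11_share >= 0, cis11_share <= 1)
  pop <- populations
  dark <- if ("dark" %in% names(pop)) pop[["dark"]] else 0
  pop <- pop[names(pop) != "dark"]
  pop <- c(pop, dark11 = dark * cis11_share, dark9 = dark * (1 - cis11_share))
  mapping <- c(default_isomer_map(),
               dark11 = "11-cis-15-anti", dark9 = "9-cis-15-anti")
  state_to_isomer(pop, mapping)
}
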