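#' Read and write spectra as two-column delimited text
#'
#' Files carry a header `wavelength_nm,absorbance` (comma or tab separated,
#' '.' decimal, UTF-8). Parse errors name the offending line.
#'
#' @param path File path.
#' @param label Optional label for the returned spectrum.
#' @return `read_spectrum()` returns a `spectrum`.
#' @export
read_spectrum <- function(path, label = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  sep <- detect_sep(lines[[1]])
  hdr <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  if (!identical(trimws(hdr[1:2]), c("wavelength_nm", "absorbance")))
    stop(path, ": line 1: expected header 'wavelength_nm", sep, "absorbance'")
  vals <- parse_numeric_rows(lines[-1], sep, 2L, path, offset = 1L)
  wl <- vals[, 1]
  if (any(diff(wl) <= 0)) {
    bad <- which(diff(wl) <= 0)[1] + 1L
    stop(path, ": line ", bad + 1L, ": wavelengths not strictly increasing")
  }
  spectrum(wl, vals[, 2], label = label %||% basename(path))
}

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

parse_numeric_rows <- function(lines, sep, ncol, path, offset) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(lines, sep, fixed = TRUE)
  out <- matrix(NA_real_, length(rows), ncol)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) < ncol || anyNA(v[seq_len(ncol)]))
      stop(path, ": line ", i + offset, ": expected ", ncol,
           " numeric fields, got '", lines[[i]], "'")
    out[i, ] <- v[seq_len(ncol)]
  }
  out
}

#' @rdname read_spectrum
#' @param s A `spectrum`.
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_spectrum <- function(s, path, sep = ",") {
  stopifnot(inherits(s, "spectrum"))
  lines <- c(paste("wavelength_nm", "absorbance", sep = sep),
             paste(fmt(s$wavelength), fmt(s$absorbance), sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

fmt <- function(x) sprintf("%.15g", x)

#' Read and write time-stamped spectral series
#'
#' A series file has a first header line `time_s,<t1>,...,<tn>` giving the
#' acquisition times, then one row per wavelength: the wavelength followed
#' by one absorbance column per timepoint.
#'
#' @param path File path.
#' @return `read_spectral_series()` returns a list with `times` and
#'   `spectra` (list of `spectrum`, time-stamped).
#' @export
read_spectral_series <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) stop(path, ": too short for a spectral series")
  sep <- detect_sep(lines[[1]])
  hdr <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  if (trimws(hdr[1]) != "time_s")
    stop(path, ": line 1: expected a 'time_s' header line")
  times <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(times)) stop(path, ": line 1: non-numeric time stamps")
  vals <- parse_numeric_rows(lines[-1], sep, length(times) + 1L, path, 1L)
  wl <- vals[, 1]
  if (any(diff(wl) <= 0))
    stop(path, ": wavelengths not strictly increasing")
  spectra <- lapply(seq_along(times), function(j) {
    spectrum(wl, vals[, j + 1L], label = sprintf("t=%gs", times[j]),
             time_s = times[j])
  })
  list(times = times, spectra = spectra)
}

#' @rdname read_spectral_series
#' @param times Numeric acquisition times (s).
#' @param spectra List of `spectrum` objects on one shared grid.
#' @param sep Field separator.
#' @export
write_spectral_series <- function(times, spectra, path, sep = ",") {
  stopifnot(length(times) == length(spectra), length(spectra) >= 1)
  wl <- spectra[[1]]$wavelength
  for (s in spectra) if (!same_grid(s, spectra[[1]]))
    stop("series spectra must share one wavelength grid")
  mat <- vapply(spectra, function(s) s$absorbance, numeric(length(wl)))
  lines <- c(paste(c("time_s", fmt(times)), collapse = sep),
             apply(cbind(fmt(wl), matrix(fmt(mat), nrow = length(wl))), 1,
                   paste, collapse = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write template sets as multi-column delimited text
#'
#' Header `wavelength_nm,<state>,...`; one column per state template.
#' The lambda-max map is stored in a comment-free companion convention: it
#' is re-derivable from the curves, so only curves are persisted and
#' `lambda_max` on the read object is the per-column argmax.
#'
#' @param path File path.
#' @return `read_template_set()` returns a `template_set`.
#' @export
read_template_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) stop(path, ": too short for a template set")
  sep <- detect_sep(lines[[1]])
  hdr <- trimws(strsplit(lines[[1]], sep, fixed = TRUE)[[1]])
  if (hdr[1] != "wavelength_nm")
    stop(path, ": line 1: expected 'wavelength_nm' first column")
  states <- hdr[-1]
  vals <- parse_numeric_rows(lines[-1], sep, length(hdr), path, 1L)
  grid <- vals[, 1]
  if (any(diff(grid) <= 0))
    stop(path, ": wavelengths not strictly increasing")
  basis <- vals[, -1, drop = FALSE]
  colnames(basis) <- states
  lm <- vapply(states, function(s) grid[which.max(basis[, s])], 0)
  structure(list(grid = grid, basis = basis, lambda_max = lm),
            class = "template_set")
}

#' @rdname read_template_set
#' @param templates A `template_set`.
#' @param sep Field separator.
#' @export
write_template_set <- function(templates, path, sep = ",") {
  stopifnot(inherits(templates, "template_set"))
  hdr <- paste(c("wavelength_nm", colnames(templates$basis)), collapse = sep)
  body <- apply(cbind(fmt(templates$grid),
                      matrix(fmt(templates$basis),
                             nrow = length(templates$grid))),
                1, paste, collapse = sep)
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write kinetic traces as `time_s,value` text
#'
#' @param path File path.
#' @return `read_trace()` returns a `kinetic_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sep <- detect_sep(lines[[1]])
  hdr <- trimws(strsplit(lines[[1]], sep, fixed = TRUE)[[1]])
  if (!identical(hdr[1:2], c("time_s", "value")))
    stop(path, ": line 1: expected header 'time_s", sep, "value'")
  vals <- parse_numeric_rows(lines[-1], sep, 2L, path, 1L)
  kinetic_trace(vals[, 1], vals[, 2], label = basename(path))
}

#' @rdname read_trace
#' @param trace A `kinetic_trace`.
#' @param sep Field separator.
#' @export
write_trace <- function(trace, path, sep = ",") {
  stopifnot(inherits(trace, "kinetic_trace"))
  writeLines(c(paste("time_s", "value", sep = sep),
               paste(fmt(trace$time_s), fmt(trace$value), sep = sep)),
             path, useBytes = TRUE)
  invisible(path)
}

#' Serialise photocycle models and protocols to YAML
#'
#' @param model A `photocycle_model`.
#' @param path File path.
#' @export
write_photocycle_model <- function(model, path) {
  stopifnot(inherits(model, "photocycle_model"))
  yaml::write_yaml(list(
    states = model$states,
    thermal_rates = as.list(model$thermal_rates),
    bands = lapply(model$bands, function(b)
      list(coefficient = as.list(b$coefficient %||% list()),
           branching = as.list(b$branching %||% list()))),
    condition = model$condition), path, precision = 15)
  invisible(path)
}

#' @rdname write_photocycle_model
#' @export
read_photocycle_model <- function(path) {
  x <- yaml::read_yaml(path)
  photocycle_model(
    states = unlist(x$states),
    thermal_rates = unlist(x$thermal_rates) %||% numeric(),
    bands = lapply(x$bands, function(b)
      list(coefficient = unlist(b$coefficient),
           branching = unlist(b$branching))),
    condition = x$condition)
}

#' @rdname write_photocycle_model
#' @param protocol List of irradiation events.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(lapply(protocol, unclass), path)
  invisible(path)
}

#' @rdname write_photocycle_model
#' @export
read_protocol <- function(path) {
  lapply(yaml::read_yaml(path), function(ev) {
    switch(ev$type,
           flash = flash_event(ev$band, ev$converted_fraction),
           light = light_event(ev$band, ev$intensity, ev$duration),
           dark = dark_event(ev$duration),
           stop("unknown event type: ", ev$type))
  })
}
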