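#' Define a photocycle kinetic model
#'
#' A linear first-order kinetic network over named pigment states (dark,
#' meta II, meta III, ...). Thermal transitions are first-order rate
#' constants; light acts either as an instantaneous flash (moving a stated
#' fraction of each photosensitive state along per-band branching fractions)
#' or as continuous illumination (adding intensity-scaled pseudo-first-order
#' rates to the thermal rate matrix). Quantum efficiencies and beam geometry
#' are folded into the per-band excitation coefficients.
#'
#' @param states Character vector of unique state names.
#' @param thermal_rates Named numeric vector of first-order rate constants
#'   (1/s) with names of the form `"from->to"`; may be empty.
#' @param bands Named list of light bands. Each band is a list with
#'   `coefficient` (named per-from-state photoexcitation rate, 1/s at unit
#'   intensity; only needed for continuous light) and `branching` (named
#'   `"from->to"` fractions; per from-state sums must be <= 1, the
#'   remainder returning to the starting state).
#' @param condition Informational condition label (e.g. `"37C"`).
#' @return A `photocycle_model`.
#' @export
photocycle_model <- function(states, thermal_rates = numeric(),
                             bands = list(), condition = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("state names must be unique")
  check_transitions <- function(x, what) {
    if (length(x) == 0) return(invisible())
    if (any(x < 0)) stop(what, " must be non-negative")
    ft <- parse_transitions(names(x))
    bad <- !(ft$from %in% states & ft$to %in% states)
    if (any(bad))
      stop("unknown state in ", what, ": ", paste(names(x)[bad], collapse = ", "))
    if (any(ft$from == ft$to)) stop("self-transitions are not allowed")
  }
  check_transitions(thermal_rates, "thermal rates")
  for (bn in names(bands)) {
    br <- bands[[bn]]$branching
    check_transitions(br, paste0("band '", bn, "' branching"))
    if (length(br)) {
      sums <- tapply(br, parse_transitions(names(br))$from, sum)
      if (any(sums > 1 + 1e-12))
        stop("band '", bn, "': branching fractions from a state exceed 1")
    }
    co <- bands[[bn]]$coefficient
    if (!is.null(co) && any(co < 0))
      stop("band coefficients must be non-negative")
  }
  structure(list(states = states, thermal_rates = thermal_rates,
                 bands = bands, condition = condition),
            class = "photocycle_model")
}

parse_transitions <- function(nm) {
  parts <- strsplit(nm, "->", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("transition names must have the form 'from->to'")
  list(from = trimws(vapply(parts, `[`, "", 1)),
       to = trimws(vapply(parts, `[`, "", 2)))
}

# column-stochastic-generator rate matrix: Q[to, from] = k(from->to),
# diagonal = -(outgoing sum); d p/dt = Q p conserves sum(p)
rate_matrix <- function(states, rates) {
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  if (length(rates)) {
    ft <- parse_transitions(names(rates))
    for (i in seq_along(rates)) Q[ft$to[i], ft$from[i]] <-
        Q[ft$to[i], ft$from[i]] + rates[i]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Irradiation protocol events
#'
#' An irradiation protocol is an ordered list of events driving a
#' photocycle simulation: instantaneous flashes, continuous-light periods
#' and dark periods.
#'
#' @param band Light-band name (must exist in the model).
#' @param converted_fraction Fraction (0-1) of each photosensitive state
#'   moved by the flash.
#' @param intensity Relative light intensity (multiplies the band's
#'   photoexcitation coefficients).
#' @param duration Event duration in seconds (> 0).
#' @return An event object; combine with `list()` into a protocol.
#' @export
flash_event <- function(band, converted_fraction) {
  stopifnot(converted_fraction >= 0, converted_fraction <= 1)
  structure(list(type = "flash", band = band,
                 converted_fraction = converted_fraction),
            class = "irradiation_event")
}

#' @rdname flash_event
#' @export
light_event <- function(band, intensity, duration) {
  stopifnot(intensity >= 0, duration > 0)
  structure(list(type = "light", band = band, intensity = intensity,
                 duration = duration), class = "irradiation_event")
}

#' @rdname flash_event
#' @export
dark_event <- function(duration) {
  stopifnot(duration > 0)
  structure(list(type = "dark", duration = duration),
            class = "irradiation_event")
}

apply_flash <- function(p, model, band, fraction) {
  if (!band %in% names(model$bands))
    stop("unknown light band '", band, "' in protocol")
  br <- model$bands[[band]]$branching
  if (is.null(br) || !length(br)) return(p)
  ft <- parse_transitions(names(br))
  moved <- numeric(length(p))
  names(moved) <- names(p)
  out <- p
  for (from in unique(ft$from)) {
    idx <- ft$from == from
    leave <- p[from] * fraction * sum(br[idx])
    out[from] <- out[from] - leave
    for (i in which(idx)) {
      out[ft$to[i]] <- out[ft$to[i]] + p[from] * fraction * br[i]
    }
  }
  out
}

segment_matrix <- function(model, event) {
  rates <- model$thermal_rates
  if (event$type == "light") {
    band <- model$bands[[event$band]]
    if (is.null(band))
      stop("unknown light band '", event$band, "' in protocol")
    co <- band$coefficient
    br <- band$branching
    if (length(br)) {
      ft <- parse_transitions(names(br))
      k_exc <- if (is.null(co)) stats::setNames(rep(1, length(unique(ft$from))),
                                               unique(ft$from)) else co
      add <- stats::setNames(
        event$intensity * k_exc[ft$from] * br, names(br))
      rates <- c(rates, add)
    }
  }
  rate_matrix(model$states, rates)
}

#' Simulate a photocycle under an irradiation protocol
#'
#' Integrates the linear kinetic system piecewise: within each constant-
#' coefficient segment (dark or continuous light) populations are propagated
#' with the matrix exponential; flashes are instantaneous population moves.
#' After the last protocol event the system continues in the dark. Requested
#' output times at an event boundary report the post-event populations.
#'
#' Populations remain non-negative and sum to 1 at every output time (to
#' within 1e-9), a conservation property of the rate-matrix construction.
#'
#' @param model A `photocycle_model`.
#' @param protocol List of irradiation events (see [flash_event()]); may be
#'   empty for pure dark evolution.
#' @param initial Named population vector over model states, summing to 1.
#' @param t_grid Strictly increasing output times (s), all >= 0; time 0 is
#'   the start of the protocol.
#' @return Data frame with column `time_s` and one population column per
#'   state.
#' @export
simulate_photocycle <- function(model, protocol = list(), initial, t_grid) {
  stopifnot(inherits(model, "photocycle_model"))
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (any(t_grid < 0)) stop("t_grid times must be >= 0")
  p <- stats::setNames(numeric(length(model$states)), model$states)
  if (is.null(names(initial)) || !all(names(initial) %in% model$states))
    stop("initial populations must be named with model states")
  p[names(initial)] <- initial
  if (abs(sum(p) - 1) > 1e-9) stop("initial populations must sum to 1")

  out <- matrix(NA_real_, length(t_grid), length(model$states),
                dimnames = list(NULL, model$states))
  t_cur <- 0
  emit <- function(Q, t_from, t_to, p0) {
    idx <- which(t_grid > t_from & t_grid <= t_to)
    for (i in idx) {
      out[i, ] <<- propagate(Q, p0, t_grid[i] - t_from)
    }
  }
  if (any(t_grid == 0)) out[t_grid == 0, ] <- p  # pre-event state at t = 0

  events <- c(protocol, list(NULL))  # NULL = trailing dark tail
  for (ev in events) {
    if (!is.null(ev) && ev$type == "flash") {
      p <- apply_flash(p, model, ev$band, ev$converted_fraction)
      if (any(t_grid == t_cur)) out[t_grid == t_cur, ] <- p
      next
    }
    dur <- if (is.null(ev)) Inf else ev$duration
    Q <- segment_matrix(model, ev %||% dark_event(1))
    t_end <- t_cur + dur
    emit(Q, t_cur, min(t_end, max(t_grid)), p)
    if (is.finite(t_end)) {
      if (t_end > max(t_grid)) break
      p <- propagate(Q, p, dur)
      t_cur <- t_end
    } else break
  }
  res <- data.frame(time_s = t_grid, out, check.names = FALSE)
  tot <- rowSums(res[, model$states, drop = FALSE])
  stopifnot(all(abs(tot - 1) < 1e-9))
  res
}

propagate <- function(Q, p, dt) {
  if (dt == 0 || all(Q == 0)) return(p)
  v <- as.numeric(Matrix::expm(Q * dt) %*% p)
  names(v) <- names(p)
  pmax(v, 0)
}

#' Convert state populations to an observable absorption spectrum
#'
#' The spectroscopic observable of a population mixture:
#' \eqn{A(\lambda) = s \sum_k p_k T_k(\lambda)} on the template grid. The
#' inverse of spectral unmixing.
#'
#' @param populations Named population vector (states with non-zero
#'   population must have templates).
#' @param templates A `template_set`.
#' @param scale Total pigment absorbance scale (AU).
#' @param label,time_s Passed to the returned `spectrum`.
#' @return A `spectrum` on the template grid.
#' @export
populations_to_spectrum <- function(populations, templates, scale,
                                    label = NULL, time_s = NULL) {
  stopifnot(inherits(templates, "template_set"))
  pop <- populations[populations != 0]
  missing_t <- setdiff(names(pop), colnames(templates$basis))
  if (length(missing_t))
    stop("no template for populated state(s): ",
         paste(missing_t, collapse = ", "))
  y <- as.numeric(templates$basis[, names(pop), drop = FALSE] %*% pop) * scale
  spectrum(templates$grid, y, label = label, time_s = time_s)
}

#' Kinetic trace constructor
#'
#' A time series of an observable: difference absorbance at lambda-max, or a
#' state population fraction.
#'
#' @param time_s Strictly increasing times (s).
#' @param value Finite observable values.
#' @param label Observable label.
#' @return A `kinetic_trace`.
#' @export
kinetic_trace <- function(time_s, value, label = NULL) {
  time_s <- as.numeric(time_s); value <- as.numeric(value)
  stopifnot(length(time_s) == length(value))
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(value))) stop("trace values must be finite")
  structure(list(time_s = time_s, value = value, label = label),
            class = "kinetic_trace")
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, value = x$value)
}

#' Population trace of the signalling-active state
#'
#' The meta II population is the proxy for G-protein activation capacity;
#' this extracts any single state's population as a kinetic trace from a
#' simulation result.
#'
#' @param pop_series Data frame from [simulate_photocycle()].
#' @param active_state State column to extract (default `"metaII"`).
#' @return A `kinetic_trace`.
#' @export
active_fraction_trace <- function(pop_series, active_state = "metaII") {
  if (!active_state %in% names(pop_series))
    stop("state '", active_state, "' not present in the simulation")
  kinetic_trace(pop_series$time_s, pop_series[[active_state]],
                label = active_state)
}

#' Fit a single-exponential recovery or decay
#'
#' Nonlinear least squares of
#' \eqn{y(t) = y_0 + A (1 - e^{-t/\tau})} (rising form, the shape of a
#' difference-absorbance recovery to the dark state) or
#' \eqn{y(t) = y_0 + A e^{-t/\tau}} (decaying form), via
#' Levenberg-Marquardt. The initial tau is taken from the time at which the
#' trace crosses \eqn{1 - e^{-1}} of its span; tau is bounded to
#' \[1e-3, 1e6\] s.
#'
#' @param trace A `kinetic_trace` with >= 4 points spanning at least one
#'   expected time constant (caller responsibility).
#' @param form `"rising"` or `"decaying"`.
#' @return List with `amplitude` (AU), `tau` (s), `offset` (AU),
#'   `residual_rms` and `form`.
#' @export
fit_single_exponential <- function(trace, form = c("rising", "decaying")) {
  stopifnot(inherits(trace, "kinetic_trace"))
  form <- match.arg(form)
  t <- trace$time_s; y <- trace$value
  if (length(t) < 4L) stop("need at least 4 points to fit an exponential")
  if (stats::var(y) == 0) stop("trace has zero variance; no kinetics to fit")
  span <- y[length(y)] - y[1]
  target <- y[1] + (1 - exp(-1)) * span
  crossed <- if (span >= 0) which(y >= target) else which(y <= target)
  tau0 <- if (length(crossed)) max(t[min(crossed)], 1e-3) else stats::median(t)
  start <- list(offset = y[1], amplitude = span, tau = tau0)
  d <- data.frame(t = t, y = y)
  fml <- if (form == "rising")
    y ~ offset + amplitude * (1 - exp(-t / tau))
  else
    y ~ offset + amplitude * exp(-t / tau)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start,
                      lower = c(-Inf, -Inf, 1e-3),
                      upper = c(Inf, Inf, 1e6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("single-exponential fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  list(amplitude = unname(co["amplitude"]), tau = unname(co["tau"]),
       offset = unname(co["offset"]),
       residual_rms = sqrt(mean(stats::residuals(fit)^2)), form = form)
}
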