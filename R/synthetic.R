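#' Noise model for synthetic spectra
#'
#' Additive i.i.d. Gaussian noise per spectral point with standard deviation
#' `sigma_rel` times the dark-state peak absorbance (the scale), under an
#' explicit integer seed. `sigma_rel = 0` makes every downstream estimate
#' exact to numerical tolerance.
#'
#' @param sigma_rel Noise SD as a fraction of the peak absorbance (>= 0).
#' @param seed Integer master seed.
#' @return A `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.01, seed = 1) {
  stopifnot(sigma_rel >= 0)
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed)),
            class = "noise_model")
}

# one pseudo-random stream per (master seed, scenario name), so adding
# scenarios never shifts existing ones; kept below 2^31
derive_seed <- function(master, name) {
  u <- utf8ToInt(name)
  as.integer((as.numeric(master) * 7919 + sum(u * seq_along(u))) %%
               2147483646) + 1L
}

#' Define a synthetic experiment scenario
#'
#' A scenario bundles everything one spectroscopy experiment needs: the
#' pigment's per-state lambda-max values, a photocycle model, an
#' irradiation protocol, observation times, the absorbance scale and a
#' noise model — so a figure-panel-equivalent dataset can be generated with
#' known ground truth.
#'
#' @param name Scenario identifier (drives the per-scenario random stream).
#' @param lambda_max Named per-state lambda-max vector (nm), e.g.
#'   `c(dark = 487, metaII = 380, metaIII = 470)`.
#' @param model A `photocycle_model` over the same states.
#' @param protocol List of irradiation events.
#' @param times Observation times (s).
#' @param scale Total pigment peak absorbance (AU), default 0.05 — typical
#'   for a purified pigment.
#' @param noise A `noise_model`.
#' @param initial Initial populations (default: all dark).
#' @param grid Wavelength grid for generated spectra.
#' @param tau Optional reference recovery time constant (s) recorded as
#'   ground truth for trace fitting.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name, lambda_max, model, protocol, times,
                          scale = 0.05, noise = noise_model(),
                          initial = c(dark = 1), grid = seq(250, 700, 1),
                          tau = NULL) {
  stopifnot(inherits(model, "photocycle_model"),
            all(names(lambda_max) %in% model$states))
  structure(list(name = name, lambda_max = lambda_max, model = model,
                 protocol = protocol, times = times, scale = scale,
                 noise = noise, initial = initial, grid = grid, tau = tau),
            class = "scenario_spec")
}

scenario_templates <- function(sc) {
  build_template_set(sc$lambda_max, grid = sc$grid)
}

#' Generate a noisy spectral series with known ground truth
#'
#' Simulates the scenario's photocycle, converts populations at each
#' observation time to spectra on the template grid, and adds seeded
#' Gaussian noise. The generating populations are returned alongside so
#' recovery can be scored.
#'
#' @param sc A `scenario_spec`.
#' @return List with `times`, `spectra` (list of noisy `spectrum`),
#'   `truth` (population data frame from the simulation), `templates` and
#'   `scale`.
#' @export
generate_spectral_series <- function(sc) {
  stopifnot(inherits(sc, "scenario_spec"))
  tpl <- scenario_templates(sc)
  pops <- simulate_photocycle(sc$model, sc$protocol, sc$initial, sc$times)
  set.seed(derive_seed(sc$noise$seed, sc$name))
  sd_abs <- sc$noise$sigma_rel * sc$scale
  spectra <- lapply(seq_along(sc$times), function(i) {
    p <- unlist(pops[i, sc$model$states])
    s <- populations_to_spectrum(p, tpl, sc$scale,
                                 label = sprintf("%s_t%g", sc$name,
                                                 sc$times[i]),
                                 time_s = sc$times[i])
    s$absorbance <- s$absorbance + stats::rnorm(length(s$absorbance),
                                                sd = sd_abs)
    s
  })
  list(times = sc$times, spectra = spectra, truth = pops,
       templates = tpl, scale = sc$scale)
}

#' Generate a noisy single-exponential recovery trace
#'
#' \eqn{y(t) = y_0 + A (1 - e^{-t/\tau}) + \epsilon},
#' \eqn{\epsilon \sim N(0, (\sigma_{rel} |A|)^2)}, seeded.
#'
#' @param tau Time constant (s), > 0.
#' @param amplitude Recovery amplitude (AU).
#' @param offset Baseline offset (AU).
#' @param times Sampling times (s).
#' @param sigma_rel Noise SD as a fraction of `|amplitude|`.
#' @param seed Integer seed.
#' @return List with `trace` (a `kinetic_trace`) and `truth`
#'   (the generating parameters).
#' @export
generate_recovery_trace <- function(tau, amplitude, offset, times,
                                    sigma_rel = 0.02, seed = 1) {
  stopifnot(tau > 0)
  set.seed(seed)
  y <- offset + amplitude * (1 - exp(-times / tau)) +
    stats::rnorm(length(times), sd = sigma_rel * abs(amplitude))
  list(trace = kinetic_trace(times, y, label = "recovery"),
       truth = list(tau = tau, amplitude = amplitude, offset = offset))
}

yellow_band <- list(coefficient = c(dark = 1), branching = c("dark->metaII" = 1))

uv_reversal_band <- function(to_dark, to_metaIII) {
  list(coefficient = c(metaII = 1),
       branching = c("metaII->dark" = to_dark, "metaII->metaIII" = to_metaIII))
}

#' The shipped scenario suite
#'
#' Seven scenarios spanning the experiments the package analyses:
#' \describe{
#'   \item{wt_meta3_20C}{wild-type pigment (dark 500 nm) at 20 C: yellow
#'     flash forms meta II, which decays thermally to meta III
#'     (tau 30 min); spectra at 0-120 min.}
#'   \item{g188c_recovery_20C}{photocyclic mutant (dark 487 nm) at 20 C:
#'     meta II recovers thermally to the dark state (tau 30 min);
#'     spectra at 0-120 min.}
#'   \item{g188c_recovery_37C}{same pigment at 37 C, tau = 57.4 s;
#'     spectra at 0.1-1000 s after the flash.}
#'   \item{wt_uv_reversal}{wild-type: yellow flash then UV flash; UV
#'     branching set so the post-UV composition is
#'     dark 21.6 / meta II 13.7 / meta III 64.7 (%).}
#'   \item{g188c_uv_reversal}{photocyclic mutant: post-UV composition
#'     dark 41.2 / meta II 48.5 / meta III 10.3 (%).}
#'   \item{e122q_recovery_0C}{fast-cycling double mutant (dark 480 nm)
#'     near 0 C: recovery effectively frozen (tau 10 h); spectra at
#'     0-60 min.}
#'   \item{e122q_recovery_37C}{same pigment at 37 C, tau = 5.1 s; spectra
#'     at 0.1-50 s.}
#' }
#'
#' @param noise A `noise_model` applied to every scenario (per-scenario
#'   streams are derived from its seed).
#' @return Named list of `scenario_spec`s.
#' @export
scenario_suite <- function(noise = noise_model()) {
  flash_then_watch <- list(flash_event("yellow", 0.9))
  uv_protocol <- list(dark_event(1), flash_event("yellow", 1),
                      dark_event(1), flash_event("uv", 1))
  min_times <- c(0, 300, 900, 1800, 3600, 7200)
  mk <- function(name, dark_lm, rates, bands, protocol, times, tau = NULL,
                 condition = NULL) {
    scenario_spec(
      name,
      lambda_max = c(dark = dark_lm, metaII = 380, metaIII = 470),
      model = photocycle_model(c("dark", "metaII", "metaIII"),
                               thermal_rates = rates,
                               bands = bands, condition = condition),
      protocol = protocol, times = times, noise = noise, tau = tau)
  }
  list(
    wt_meta3_20C = mk("wt_meta3_20C", 500,
                      c("metaII->metaIII" = 1 / 1800),
                      list(yellow = yellow_band),
                      flash_then_watch, min_times, condition = "20C"),
    g188c_recovery_20C = mk("g188c_recovery_20C", 487,
                            c("metaII->dark" = 1 / 1800),
                            list(yellow = yellow_band),
                            flash_then_watch, min_times, tau = 1800,
                            condition = "20C"),
    g188c_recovery_37C = mk("g188c_recovery_37C", 487,
                            c("metaII->dark" = 1 / 57.4),
                            list(yellow = yellow_band),
                            flash_then_watch,
                            c(0.1, 10, 50, 100, 1000), tau = 57.4,
                            condition = "37C"),
    wt_uv_reversal = mk("wt_uv_reversal", 500,
                        c("metaII->metaIII" = 1 / 1800),
                        list(yellow = yellow_band,
                             uv = uv_reversal_band(0.216, 0.647)),
                        uv_protocol, c(0, 1, 2), condition = "20C"),
    g188c_uv_reversal = mk("g188c_uv_reversal", 487,
                           c("metaII->dark" = 1 / 1800),
                           list(yellow = yellow_band,
                                uv = uv_reversal_band(0.412, 0.103)),
                           uv_protocol, c(0, 1, 2), condition = "20C"),
    e122q_recovery_0C = mk("e122q_recovery_0C", 480,
                           c("metaII->dark" = 1 / 36000),
                           list(yellow = yellow_band),
                           flash_then_watch, c(0, 300, 3600), tau = 36000,
                           condition = "0C"),
    e122q_recovery_37C = mk("e122q_recovery_37C", 480,
                            c("metaII->dark" = 1 / 5.1),
                            list(yellow = yellow_band),
                            flash_then_watch,
                            c(0.1, 1, 5, 10, 50), tau = 5.1,
                            condition = "37C"))
}

trace_times <- function(tau) {
  # denser sampling than the spectral series, as recovery traces are in
  # practice; spans ~ 5 time constants on a log-like grid
  unique(sort(c(0.1, tau * c(0.05, 0.1, 0.2, 0.4, 0.7, 1, 1.5, 2, 3, 5))))
}

#' Write the full fixture suite to disk
#'
#' One directory per scenario containing `series.csv` (noisy spectral
#' series), `truth.json` (generating populations, scale, lambda-max map,
#' rates, noise level and, where defined, the recovery time constant), and
#' for scenarios with a finite recovery time constant a denser noisy
#' `trace.csv` recovery trace. Deterministic: the same seed yields a
#' byte-identical tree.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param sigma_rel Noise level (fraction of peak absorbance).
#' @return Invisibly, the vector of scenario directories written.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, sigma_rel = 0.01) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  suite <- scenario_suite(noise = noise_model(sigma_rel, seed))
  dirs <- character()
  for (sc in suite) {
    d <- file.path(out_dir, sc$name)
    dir.create(d, showWarnings = FALSE)
    ser <- generate_spectral_series(sc)
    write_spectral_series(ser$times, ser$spectra, file.path(d, "series.csv"))
    truth <- list(scenario = sc$name,
                  lambda_max = as.list(sc$lambda_max),
                  scale = sc$scale,
                  sigma_rel = sigma_rel,
                  thermal_rates = as.list(sc$model$thermal_rates),
                  populations = ser$truth,
                  tau_s = sc$tau)
    jsonlite::write_json(truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    if (!is.null(sc$tau) && sc$tau <= 3600) {
      tpl <- scenario_templates(sc)
      lm_dark <- sc$lambda_max[["dark"]]
      m2_at_lm <- tpl$basis[which.min(abs(tpl$grid - lm_dark)), "metaII"]
      amp <- 0.9 * sc$scale * (1 - m2_at_lm)
      tr <- generate_recovery_trace(sc$tau, amplitude = amp, offset = 0,
                                    times = trace_times(sc$tau),
                                    sigma_rel = sigma_rel,
                                    seed = derive_seed(seed,
                                                       paste0(sc$name,
                                                              "_trace")))
      write_trace(tr$trace, file.path(d, "trace.csv"))
    }
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}
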