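test_that("noiseless generation reproduces template mixtures exactly", {
  suite <- scenario_suite(noise = noise_model(0, 1))
  sc <- suite$g188c_uv_reversal
  ser <- generate_spectral_series(sc)
  for (i in seq_along(ser$times)) {
    p <- unlist(ser$truth[i, sc$model$states])
    expected <- populations_to_spectrum(p, ser$templates, ser$scale)
    expect_equal(ser$spectra[[i]]$absorbance, expected$absorbance,
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic per seed and scenario", {
  suite1 <- scenario_suite(noise = noise_model(0.01, 7))
  suite2 <- scenario_suite(noise = noise_model(0.01, 7))
  a <- generate_spectral_series(suite1$g188c_recovery_37C)
  b <- generate_spectral_series(suite2$g188c_recovery_37C)
  expect_identical(a$spectra[[2]]$absorbance, b$spectra[[2]]$absorbance)
  c_ <- generate_spectral_series(scenario_suite(
    noise = noise_model(0.01, 8))$g188c_recovery_37C)
  expect_false(identical(a$spectra[[2]]$absorbance,
                         c_$spectra[[2]]$absorbance))
})

test_that("photocyclic scenario recovers its dark-state absorbance", {
  sc <- scenario_suite(noise = noise_model(0, 1))$g188c_recovery_37C
  ser <- generate_spectral_series(sc)
  i487 <- which.min(abs(ser$spectra[[1]]$wavelength - 487))
  at_peak <- vapply(ser$spectra, function(s) s$absorbance[i487], 0)
  expect_true(all(diff(at_peak) > 0))
  expect_gt(at_peak[length(at_peak)], 0.99 * sc$scale)
})

test_that("wild-type scenario ends near 470 nm, not at its dark peak", {
  sc <- scenario_suite(noise = noise_model(0, 1))$wt_meta3_20C
  ser <- generate_spectral_series(sc)
  last <- ser$spectra[[length(ser$spectra)]]
  lm <- estimate_lambda_max(last, c(420, 600))
  expect_lt(abs(lm - 470), 5)
  expect_gt(abs(lm - 500), 10)
})

test_that("recovery trace generator matches its closed form", {
  tr0 <- generate_recovery_trace(57.4, 0.04, 0.01, c(0.1, 57.4, 287),
                                 sigma_rel = 0, seed = 1)
  expect_equal(tr0$trace$value[2], 0.01 + 0.04 * (1 - exp(-1)),
               tolerance = 1e-12)
  # by 5 tau the trace is within 1% of plateau
  expect_lt(abs(tr0$trace$value[3] - 0.05), 0.04 * 0.01)
})

test_that("tau is recovered from 100 noisy seeded traces within 5%", {
  times <- c(0.1, 1, 5, 10, 50)
  taus <- vapply(1:100, function(seed) {
    tr <- generate_recovery_trace(5.1, 0.04, 0, times, sigma_rel = 0.02,
                                  seed = seed)
    fit_single_exponential(tr$trace)$tau
  }, 0)
  expect_lt(abs(stats::median(taus) / 5.1 - 1), 0.05)
})

test_that("fixture suite is byte-identical across runs and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_suite(d1, seed = 5)
  make_fixture_suite(d2, seed = 5)
  dirs <- list.dirs(d1, recursive = FALSE)
  expect_gte(length(dirs), 7)
  for (d in dirs) {
    for (f in list.files(d)) {
      expect_identical(readLines(file.path(d, f)),
                       readLines(file.path(d2, basename(d), f)),
                       info = file.path(basename(d), f))
    }
  }
})

test_that("fixture ground truth is recoverable by the unmixing module", {
  d <- withr::local_tempdir()
  make_fixture_suite(d, seed = 11, sigma_rel = 0.01)
  for (name in c("wt_uv_reversal", "g188c_uv_reversal")) {
    truth <- jsonlite::read_json(file.path(d, name, "truth.json"),
                                 simplifyVector = TRUE)
    ser <- read_spectral_series(file.path(d, name, "series.csv"))
    tpl <- build_template_set(unlist(truth$lambda_max))
    dsp <- difference_spectrum(ser$spectra[[3]], ser$spectra[[2]])
    est <- fit_photoconversion(dsp, tpl, scale = truth$scale)
    gen <- unlist(truth$populations[c("dark", "metaII", "metaIII")])[
      c(3, 6, 9)]  # row 3 = post-UV populations
    names(gen) <- c("dark", "metaII", "metaIII")
    expect_lt(max(abs(est$fractions[names(gen)] - gen)), 0.02)
  }
})
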