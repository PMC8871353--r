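tpl_g188c <- build_template_set(c(dark = 487, metaII = 380, metaIII = 470))

test_that("fit_components recovers basis members and exact mixtures", {
  obs <- template_as_spectrum(tpl_g188c, "dark")
  est <- fit_components(obs, tpl_g188c, scale = 1)
  expect_equal(unname(est$fractions),
               c(1, 0, 0), tolerance = 1e-6)
  expect_lt(est$residual_rms, 1e-9)

  mix <- populations_to_spectrum(c(dark = 0.5, metaIII = 0.5), tpl_g188c, 1)
  est2 <- fit_components(mix, tpl_g188c, scale = 1)
  expect_equal(unname(est2$fractions[c("dark", "metaII", "metaIII")]),
               c(0.5, 0, 0.5), tolerance = 1e-6)
})

test_that("fit_components handles degenerate inputs per contract", {
  zero <- spectrum(tpl_g188c$grid, numeric(length(tpl_g188c$grid)) + 0 *
                     tpl_g188c$grid)
  zero$absorbance[] <- 0
  est <- fit_components(zero, tpl_g188c)
  expect_true(all(est$fractions == 0))
  expect_identical(est$residual_rms, 0)

  collinear <- build_template_set(c(dark = 470, metaIII = 470))
  obs <- template_as_spectrum(tpl_g188c, "dark")
  expect_error(fit_components(obs, collinear), "rank deficient")
})

test_that("photoconversion fit recovers Table-1-style rows from noisy data", {
  cases <- list(
    list(lm = 494, f = c(dark = 0.181, metaII = 0.517, metaIII = 0.302)),
    list(lm = 509, f = c(dark = 0.309, metaII = 0.677, metaIII = 0.014)),
    list(lm = 493, f = c(dark = 0.024, metaII = 0.055, metaIII = 0.921)))
  for (cs in cases) {
    tpl <- build_template_set(c(dark = cs$lm, metaII = 380, metaIII = 470))
    scale <- 0.05
    rec <- vapply(1:25, function(seed) {
      set.seed(seed)
      obs <- noisy_mixture(cs$f, tpl, scale, 0.01)
      est <- fit_photoconversion(uv_difference(obs, tpl, scale), tpl,
                                 scale = scale)
      est$fractions[names(cs$f)]
    }, numeric(3))
    expect_lt(max(abs(rowMeans(rec) - cs$f)), 0.02)
    sums <- colSums(rec)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("zero difference spectrum means no photoconversion", {
  zero <- spectrum(tpl_g188c$grid, rep(0, length(tpl_g188c$grid)))
  est <- fit_photoconversion(zero, tpl_g188c, scale = 0.05)
  expect_equal(unname(est$fractions[c("metaII", "dark", "metaIII")]),
               c(1, 0, 0))
  expect_false(is.null(est$warning_flag))
})

test_that("photoconversion fitting without a scale is refused", {
  zero <- spectrum(tpl_g188c$grid, rep(0, length(tpl_g188c$grid)))
  expect_error(fit_photoconversion(zero, tpl_g188c), "scale is required")
})

test_that("noiseless round trip over random simplex draws is exact to 1e-4", {
  set.seed(11)
  for (i in 1:100) {
    f <- random_simplex_fractions()
    obs <- populations_to_spectrum(f, tpl_g188c, 0.05)
    est <- fit_photoconversion(uv_difference(obs, tpl_g188c, 0.05),
                               tpl_g188c, scale = 0.05)
    expect_lt(max(abs(est$fractions[names(f)] - f)), 1e-4)
  }
})

test_that("estimates are invariant to joint positive rescaling", {
  f <- c(dark = 0.3, metaII = 0.5, metaIII = 0.2)
  obs <- populations_to_spectrum(f, tpl_g188c, 0.05)
  dsp <- uv_difference(obs, tpl_g188c, 0.05)
  e1 <- fit_photoconversion(dsp, tpl_g188c, scale = 0.05)
  dsp2 <- spectrum(dsp$wavelength, dsp$absorbance * 37)
  e2 <- fit_photoconversion(dsp2, tpl_g188c, scale = 0.05 * 37)
  expect_equal(e1$fractions, e2$fractions, tolerance = 1e-9)
})

test_that("NNLS photoconversion solution matches dense simplex grid search", {
  set.seed(21)
  sel <- which(tpl_g188c$grid >= 330 & tpl_g188c$grid <= 650)
  B <- tpl_g188c$basis[sel, c("dark", "metaIII")] -
    tpl_g188c$basis[sel, "metaII"]
  for (i in 1:5) {
    f <- random_simplex_fractions()
    obs <- noisy_mixture(f, tpl_g188c, 0.05, 0.01)
    dsp <- uv_difference(obs, tpl_g188c, 0.05)
    est <- fit_photoconversion(dsp, tpl_g188c, scale = 0.05)
    oracle <- grid_search_simplex(B, dsp$absorbance[sel] / 0.05, 0.005)
    expect_lt(abs(est$fractions[["dark"]] - oracle[["f1"]]), 0.005 + 1e-9)
    expect_lt(abs(est$fractions[["metaIII"]] - oracle[["f2"]]), 0.005 + 1e-9)
  }
})

test_that("bootstrap intervals are deterministic, contain the point, and
           collapse without noise", {
  f <- c(dark = 0.4, metaII = 0.45, metaIII = 0.15)
  obs <- populations_to_spectrum(f, tpl_g188c, 0.05)
  dsp0 <- uv_difference(obs, tpl_g188c, 0.05)
  b0 <- bootstrap_fractions(dsp0, tpl_g188c, scale = 0.05, n_boot = 100,
                            seed = 3)
  expect_lt(max(b0$ci[, "upper"] - b0$ci[, "lower"]), 1e-9)

  set.seed(5)
  noisy <- noisy_mixture(f, tpl_g188c, 0.05, 0.01)
  dsp <- uv_difference(noisy, tpl_g188c, 0.05)
  b1 <- bootstrap_fractions(dsp, tpl_g188c, scale = 0.05, n_boot = 200,
                            seed = 7)
  b2 <- bootstrap_fractions(dsp, tpl_g188c, scale = 0.05, n_boot = 200,
                            seed = 7)
  expect_identical(b1$ci, b2$ci)
  pts <- b1$point$fractions[rownames(b1$ci)]
  expect_true(all(b1$ci[, "lower"] <= pts & pts <= b1$ci[, "upper"]))
  expect_error(bootstrap_fractions(dsp, tpl_g188c, scale = 0.05, n_boot = 1),
               "at least 2")
})

test_that("bootstrap intervals cover the generating dark fraction", {
  f <- c(dark = 0.181, metaII = 0.517, metaIII = 0.302)
  tpl <- build_template_set(c(dark = 494, metaII = 380, metaIII = 470))
  hits <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    set.seed(1000 + i)
    noisy <- noisy_mixture(f, tpl, 0.05, 0.01)
    dsp <- uv_difference(noisy, tpl, 0.05)
    b <- bootstrap_fractions(dsp, tpl, scale = 0.05, n_boot = 120,
                             seed = i)
    ci <- b$ci["dark", ]
    if (ci["lower"] <= f[["dark"]] && f[["dark"]] <= ci["upper"])
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
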