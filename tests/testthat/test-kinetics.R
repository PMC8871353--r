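g188c_model <- function(k = 1 / 57.4) {
  photocycle_model(
    c("dark", "metaII", "metaIII"),
    thermal_rates = c("metaII->dark" = k),
    bands = list(yellow = list(coefficient = c(dark = 1),
                               branching = c("dark->metaII" = 1))))
}

test_that("all-zero rates leave populations constant in the dark", {
  m <- photocycle_model(c("dark", "metaII"))
  sim <- simulate_photocycle(m, list(), c(dark = 0.7, metaII = 0.3),
                             c(1, 10, 100))
  expect_true(all(sim$dark == 0.7 & sim$metaII == 0.3))
})

test_that("two-state decay follows the closed form exp(-kt)", {
  k <- 1 / 57.4
  m <- g188c_model(k)
  sim <- simulate_photocycle(m, list(flash_event("yellow", 1)), c(dark = 1),
                             c(57.4, 114.8))
  expect_equal(sim$metaII, exp(-k * c(57.4, 114.8)), tolerance = 1e-9)
  expect_equal(sim$metaII[1], exp(-1), tolerance = 1e-9)
})

test_that("branched decay reaches the analytic terminal split k1/(k1+k2)", {
  k1 <- 0.05; k2 <- 0.02
  m <- photocycle_model(c("dark", "metaII", "metaIII"),
                        c("metaII->dark" = k1, "metaII->metaIII" = k2))
  sim <- simulate_photocycle(m, list(), c(metaII = 1), c(1, 2000))
  expect_equal(sim$dark[2], k1 / (k1 + k2), tolerance = 1e-9)
  # cross-check the transient against the Euler oracle
  Q <- photocycler:::rate_matrix(m$states, m$thermal_rates)
  p_euler <- euler_propagate(Q, c(0, 1, 0), 1, log2_steps = 24L)
  expect_lt(max(abs(unlist(sim[1, m$states]) - p_euler)), 1e-6)
})

test_that("matrix-exponential propagation matches fine-step Euler", {
  set.seed(31)
  for (i in 1:5) {
    m <- random_three_state_model()
    p0 <- random_simplex_fractions()
    Q <- photocycler:::rate_matrix(m$states, m$thermal_rates)
    for (t in c(1, 10)) {
      sim <- simulate_photocycle(m, list(), p0, t)
      expect_lt(max(abs(unlist(sim[1, m$states]) -
                          euler_propagate(Q, p0[m$states], t))), 1e-6)
    }
  }
})

test_that("populations stay conserved and non-negative over long horizons", {
  set.seed(41)
  for (i in 1:10) {
    m <- random_three_state_model()
    p0 <- random_simplex_fractions()
    sim <- simulate_photocycle(m, list(), p0, c(1, 10, 100, 1000))
    pops <- as.matrix(sim[, m$states])
    expect_true(all(pops >= 0))
    expect_true(all(abs(rowSums(pops) - 1) < 1e-9))
  }
})

test_that("flash and continuous-light events drive the expected conversions", {
  m <- g188c_model(0)  # no thermal recovery; watch the light only
  sim <- simulate_photocycle(m, list(flash_event("yellow", 0.6)),
                             c(dark = 1), c(1))
  expect_equal(unlist(sim[1, c("dark", "metaII")]),
               c(dark = 0.4, metaII = 0.6), tolerance = 1e-12)

  # continuous light: pseudo-first-order depletion of the dark state
  sim2 <- simulate_photocycle(m, list(light_event("yellow", 0.1, 10)),
                              c(dark = 1), c(10))
  expect_equal(sim2$dark[1], exp(-0.1 * 10), tolerance = 1e-9)

  expect_error(simulate_photocycle(m, list(flash_event("uv", 0.5)),
                                   c(dark = 1), c(1)), "unknown light band")
})

test_that("population-to-spectrum is the inverse of unmixing", {
  tpl <- build_template_set(c(dark = 487, metaII = 380, metaIII = 470))
  s <- populations_to_spectrum(c(dark = 1), tpl, 0.05)
  expect_equal(s$absorbance, 0.05 * tpl$basis[, "dark"])
  mix <- c(dark = 0.5, metaIII = 0.5)
  s2 <- populations_to_spectrum(mix, tpl, 0.05)
  expect_lt(max(s2$absorbance), 0.05)
  est <- fit_components(s2, tpl, scale = 0.05)
  expect_equal(unname(est$fractions[c("dark", "metaII", "metaIII")]),
               c(0.5, 0, 0.5), tolerance = 1e-6)
  expect_error(populations_to_spectrum(c(dark = 0.5, metaI = 0.5), tpl, 1),
               "no template")
})

test_that("single-exponential fits recover noiseless time constants", {
  for (tau in c(57.4, 5.1)) {
    times <- seq(0.1, 5 * tau, length.out = 30)
    tr <- kinetic_trace(times, 0.01 + 0.04 * (1 - exp(-times / tau)))
    fit <- fit_single_exponential(tr, "rising")
    expect_equal(fit$tau, tau, tolerance = 1e-3 / tau)
    expect_equal(fit$amplitude, 0.04, tolerance = 1e-6)
    expect_equal(fit$offset, 0.01, tolerance = 1e-6)
  }
  # decaying form
  times <- seq(0.5, 60, 1.5)
  tr <- kinetic_trace(times, 0.05 * exp(-times / 12))
  fit <- fit_single_exponential(tr, "decaying")
  expect_equal(fit$tau, 12, tolerance = 1e-6)
})

test_that("degenerate traces are refused", {
  expect_error(fit_single_exponential(kinetic_trace(1:10, rep(0.3, 10))),
               "zero variance")
  expect_error(fit_single_exponential(kinetic_trace(1:3, c(1, 2, 3))),
               "at least 4")
})

test_that("exponential fitting is equivariant under time and value scaling", {
  times <- c(0.1, 1, 10, 50, 100, 500, 1000)
  set.seed(8)
  y <- 0.04 * (1 - exp(-times / 57.4)) + rnorm(7, sd = 4e-4)
  f1 <- fit_single_exponential(kinetic_trace(times, y))
  f2 <- fit_single_exponential(kinetic_trace(times * 3, y))
  expect_equal(f2$tau, 3 * f1$tau, tolerance = 1e-6)
  f3 <- fit_single_exponential(kinetic_trace(times, y * 5))
  expect_equal(f3$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f3$amplitude, 5 * f1$amplitude, tolerance = 1e-6)
})

test_that("active-fraction traces distinguish photocyclic from monostable", {
  k <- 1 / 57.4
  cyc <- photocycle_model(c("dark", "metaII", "metaIII"),
                          c("metaII->dark" = k))
  mono <- photocycle_model(c("dark", "metaII", "metaIII"),
                           c("metaII->metaIII" = k))
  t_grid <- c(1, 10, 100, 600)
  sim_c <- simulate_photocycle(cyc, list(), c(metaII = 1), t_grid)
  sim_m <- simulate_photocycle(mono, list(), c(metaII = 1), t_grid)
  tr_c <- active_fraction_trace(sim_c)
  tr_m <- active_fraction_trace(sim_m)
  expect_equal(tr_c$value, exp(-k * t_grid), tolerance = 1e-9)
  # both active pools decay identically, but only the cyclic model refills
  # the dark state
  expect_equal(tr_m$value, tr_c$value, tolerance = 1e-9)
  expect_true(all(diff(tr_c$value) < 0))
  expect_gt(sim_c$dark[4], 0.99)
  expect_lt(sim_m$dark[4], 1e-6)
  expect_gt(sim_m$metaIII[4], 0.99)
  expect_error(active_fraction_trace(sim_c, "metaIV"), "not present")
})

test_that("a tau sped up by 57.4/5.1 reaches 90% recovery faster by that factor", {
  k_slow <- 1 / 57.4
  k_fast <- k_slow * (57.4 / 5.1)
  t90 <- function(k) -log(0.1) / k
  expect_equal(t90(k_slow) / t90(k_fast), 57.4 / 5.1, tolerance = 1e-12)
  m_fast <- photocycle_model(c("dark", "metaII"), c("metaII->dark" = k_fast))
  sim <- simulate_photocycle(m_fast, list(), c(metaII = 1), t90(k_fast))
  expect_equal(sim$dark[1], 0.9, tolerance = 1e-9)
})
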