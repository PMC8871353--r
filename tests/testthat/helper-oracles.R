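# Independent oracles used to cross-check the package's fitted and
# propagated quantities. These deliberately avoid the code paths they
# check: the unmixing oracle is a dense grid search over the constrained
# simplex, the kinetics oracle is fixed-step forward Euler.

# Dense grid search over {f >= 0, sum(f) <= 1} at the given step for the
# two-free-component photoconversion objective ||B f - y||^2.
grid_search_simplex <- function(B, y, step = 0.005) {
  f1 <- seq(0, 1, by = step)
  grid <- expand.grid(f1 = f1, f2 = f1)
  grid <- grid[grid$f1 + grid$f2 <= 1 + 1e-12, ]
  pred <- B %*% t(as.matrix(grid))
  rss <- colSums((pred - y)^2)
  best <- which.min(rss)
  c(f1 = grid$f1[best], f2 = grid$f2[best])
}

# Forward Euler with 2^log2_steps steps, evaluated exactly as the Euler
# iterate p_N = (I + dt Q)^N p0 via repeated squaring, which makes step
# counts like 2^24 affordable.
euler_propagate <- function(Q, p0, t, log2_steps = 24L) {
  dt <- t / 2^log2_steps
  M <- diag(nrow(Q)) + dt * Q
  for (i in seq_len(log2_steps)) M <- M %*% M
  as.numeric(M %*% p0)
}

random_three_state_model <- function() {
  states <- c("dark", "metaII", "metaIII")
  pairs <- c("metaII->dark", "metaII->metaIII", "metaIII->dark",
             "dark->metaII")
  keep <- sample(pairs, sample(2:4, 1))
  rates <- stats::setNames(stats::runif(length(keep), 0.01, 1), keep)
  photocycle_model(states, thermal_rates = rates)
}

random_simplex_fractions <- function(states = c("dark", "metaII", "metaIII")) {
  x <- stats::rgamma(length(states), 1)
  stats::setNames(x / sum(x), states)
}

# synthetic post-UV observation: mixture of templates at the given scale
# plus peak-relative Gaussian noise
noisy_mixture <- function(fractions, templates, scale, sigma_rel) {
  s <- populations_to_spectrum(fractions, templates, scale)
  s$absorbance <- s$absorbance +
    stats::rnorm(length(s$absorbance), sd = sigma_rel * scale)
  s
}

# difference of a (possibly noisy) post-UV spectrum against the pure
# photolysed reference pool at the same scale
uv_difference <- function(post_uv, templates, scale,
                          reference_state = "metaII") {
  ref <- template_as_spectrum(templates, reference_state)
  ref$absorbance <- ref$absorbance * scale
  difference_spectrum(post_uv, ref)
}
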