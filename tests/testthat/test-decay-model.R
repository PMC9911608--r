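test_that("convolved exponential reduces to a pure exponential as the IRF narrows", {
  # zero-width-IRF limit: H -> exp(-(t - t0)/tau)
  expect_equal(convolved_exponential(2 + 25, t0 = 2, tau = 2.5, tauG = 1e-6),
               exp(-10), tolerance = 1e-6)
  # no photons before excitation
  expect_lt(convolved_exponential(-48, t0 = 2, tau = 2.5, tauG = 0.2), 1e-12)
  # stays finite and non-negative over extreme inputs (log-space evaluation)
  tt <- seq(-100, 100, by = 0.5)
  v <- convolved_exponential(tt, t0 = 0, tau = 0.3, tauG = 0.01)
  expect_true(all(is.finite(v)) && all(v >= 0))
})

test_that("convolved exponential matches brute-force quadrature", {
  expect_equal(convolved_exponential(3, t0 = 2, tau = 2.5, tauG = 0.15),
               conv_quadrature(3, 2, 2.5, 0.15), tolerance = 1e-8)
  # across a parameter grid and the full window
  grid <- expand.grid(tau = c(0.4, 1.2, 2.6, 4), tauG = c(0.08, 0.15, 0.3))
  tt <- seq(0, 12.5, length.out = 40)
  for (i in seq_len(nrow(grid))) {
    ours <- convolved_exponential(tt, 2, grid$tau[i], grid$tauG[i])
    ref <- conv_quadrature(tt, 2, grid$tau[i], grid$tauG[i])
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("decay model mixes components linearly", {
  tt <- seq(0, 12.5, length.out = 100)
  p1 <- decay_params(500, 1, 1.7, 3.0, 0.15, 2)
  expect_equal(decay_model(tt, p1),
               500 * convolved_exponential(tt, 2, 1.7, 0.15))
  p <- std_params()
  p2 <- decay_params(2 * p$F0, p$P1, p$tau1, p$tau2, p$tauG, p$t0)
  expect_identical(decay_model(tt, p2), 2 * decay_model(tt, p))
  # quadrature oracle on the full mixture
  pq <- decay_params(1000, 0.4, 0.8, 2.6, 0.15, 2)
  expect_equal(decay_model(tt, pq),
               biexp_quadrature(tt, 1000, 0.4, 0.8, 2.6, 0.15, 2),
               tolerance = 1e-7)
})

test_that("parameter container validates and canonicalises", {
  p <- decay_params(10, 0.3, 3.0, 1.0, 0.15, 2) # out of order
  expect_equal(c(p$tau1, p$tau2, p$P1), c(1.0, 3.0, 0.7))
  expect_error(decay_params(10, 1.2, 1, 2, 0.15, 2),
               class = "fretclem_invalid_parameter")
  expect_error(decay_params(10, 0.5, -1, 2, 0.15, 2),
               class = "fretclem_invalid_parameter")
  expect_error(convolved_exponential(1, 0, tau = 0, tauG = 0.1),
               class = "fretclem_invalid_parameter")
})

test_that("lifetime summaries follow their closed forms", {
  expect_equal(amplitude_weighted_lifetime(1, 1.7, 9), 1.7)
  expect_equal(amplitude_weighted_lifetime(0.5, 1, 3), 2.0)
  expect_equal(amplitude_weighted_lifetime(0.25, 0.5, 2.5), 2.0)
  expect_error(amplitude_weighted_lifetime(1.5, 1, 2),
               class = "fretclem_invalid_parameter")

  expect_equal(fret_efficiency(2.6, 2.6)$efficiency, 0)
  expect_equal(fret_efficiency(1.3, 2.6)$efficiency, 0.5)
  expect_equal(fret_efficiency(2.4, 2.6)$efficiency, 1 - 2.4 / 2.6)
  expect_error(fret_efficiency(-1, 2.6), class = "fretclem_invalid_parameter")
})

test_that("Forster efficiency is 1/2 at R0 and strictly decreasing", {
  expect_identical(forster_efficiency(60, 60), 0.5)
  expect_identical(forster_efficiency(0, 60), 1.0)
  expect_equal(forster_efficiency(120, 60), 1 / 65)
  for (R0 in c(1, 12.3, 60, 500)) {
    expect_identical(forster_efficiency(R0, R0), 0.5)
  }
  r <- seq(5, 200, by = 5)
  expect_true(all(diff(forster_efficiency(r, 60)) < 0))
  expect_error(forster_efficiency(10, 0), class = "fretclem_invalid_parameter")
})

test_that("mean lifetime is the first moment minus the reference", {
  edges <- seq(0, 10, by = 0.5)
  counts <- rep(0, 20)
  counts[9] <- 100 # single bin centered at 4.25
  h <- decay_histogram(edges, counts)
  expect_equal(mean_lifetime(h, t_reference = 2)$tau_mean, 4.25 - 2)

  sym <- dnorm(seq(0.25, 9.75, by = 0.5), mean = 5, sd = 1)
  hs <- decay_histogram(edges, sym * 1000)
  expect_equal(mean_lifetime(hs)$tau_mean, 5.0, tolerance = 1e-9)

  # noise-free bi-exponential: first moment -> photon-weighted lifetime
  # (P1 tau1^2 + (1-P1) tau2^2) / tau_a, here 2.5 ns; long window, tiny IRF
  p <- decay_params(1000, 0.5, 1, 3, 1e-4, 0)
  edges2 <- seq(0, 60, length.out = 4001)
  mu <- expected_decay_counts(p, edges2, periods = 0)
  hm <- decay_histogram(edges2, mu)
  expect_equal(mean_lifetime(hm)$tau_mean, 2.5, tolerance = 1e-3)

  expect_error(mean_lifetime(decay_histogram(edges, rep(0, 20))),
               class = "fretclem_insufficient_photons")
})

test_that("histograms validate their grid", {
  expect_error(decay_histogram(c(0, 1, 2.5), c(1, 1)),
               class = "fretclem_invalid_parameter")
  expect_error(decay_histogram(c(0, 1, 2), c(1, -1)),
               class = "fretclem_invalid_parameter")
  expect_error(decay_histogram(c(0, 1, 2), c(1, 1, 1)),
               class = "fretclem_invalid_parameter")
})
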