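# Independent oracles and shared fixtures for the test suite.

# Brute-force quadrature convolution of a one-sided exponential decay with a
# unit-area Gaussian of sd tauG: the reference for the closed-form kernel.
conv_quadrature <- function(t, t0, tau, tauG) {
  vapply(t, function(ti) {
    stats::integrate(
      function(s) exp(-(s - t0) / tau) * (s >= t0) *
        stats::dnorm(ti - s, sd = tauG),
      lower = t0 - 12 * tauG,
      upper = max(ti + 12 * tauG, t0 + 12 * tauG),
      rel.tol = 1e-12, subdivisions = 2000L)$value
  }, numeric(1))
}

# Reference bi-exponential decay via the same quadrature
biexp_quadrature <- function(t, F0, P1, tau1, tau2, tauG, t0) {
  F0 * (P1 * conv_quadrature(t, t0, tau1, tauG) +
          (1 - P1) * conv_quadrature(t, t0, tau2, tauG))
}

# standard test decay: P1 = 0.5, tau1 = 1.2 ns, tau2 = 2.6 ns => tau_a = 1.9
std_params <- function(F0 = 1000) {
  decay_params(F0 = F0, P1 = 0.5, tau1 = 1.2, tau2 = 2.6, tauG = 0.15, t0 = 2)
}

# noise-free histogram of expected counts for given params
expected_histogram <- function(params, total = 3e4, window = 12.5,
                               n_bins = 256) {
  edges <- seq(0, window, length.out = n_bins + 1)
  mu <- expected_decay_counts(params, edges)
  decay_histogram(edges, mu * total / sum(mu))
}

# tiny affine-consistent fiducial set under (rotation deg, scale, translation)
make_fiducials <- function(n, rotation_deg, scale, translation,
                           jitter_sd = 0, seed = 1) {
  set.seed(seed)
  fl <- cbind(runif(n, 0, 64), runif(n, 0, 64))
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  em <- fl %*% t(A) + matrix(translation, n, 2, byrow = TRUE)
  if (jitter_sd > 0) em <- em + matrix(rnorm(2 * n, 0, jitter_sd), n, 2)
  data.frame(flim_x = fl[, 1], flim_y = fl[, 2],
             em_x = em[, 1], em_y = em[, 2])
}

# minimal record table for summarisation tests
make_records <- function(cell_id, classes, lifetimes, photons = 1000) {
  data.frame(structure_id = seq_along(classes), cell_id = cell_id,
             curvature_class = classes, area_nm2 = 1e4,
             centroid_x_px = 0, centroid_y_px = 0,
             mean_lifetime_ns = lifetimes, photons = photons)
}
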