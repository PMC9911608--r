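test_that("photon totals are conserved exactly and draws are seeded", {
  p <- std_params()
  for (n in c(0, 17, 1e4)) {
    h <- sample_decay_photons(p, n, background_fraction = 0.1, seed = 3)
    expect_identical(sum(h$counts), as.numeric(n))
  }
  h1 <- sample_decay_photons(p, 5000, seed = 11)
  h2 <- sample_decay_photons(p, 5000, seed = 11)
  expect_identical(h1$counts, h2$counts)
})

test_that("sampled histograms match the decay model distributionally", {
  # chi-square goodness of fit of a 1e6-photon draw against expected counts
  p <- std_params()
  n <- 1e6
  h <- sample_decay_photons(p, n, seed = 21)
  mu <- expected_decay_counts(p, h$bin_edges)
  mu <- mu * n / sum(mu)
  # lump low-expectation bins to keep the chi-square approximation valid
  keep <- mu >= 10
  obs <- h$counts[keep]
  exp_ <- mu[keep]
  if (any(!keep)) {
    obs <- c(obs, sum(h$counts[!keep]))
    exp_ <- c(exp_, sum(mu[!keep]))
  }
  stat <- sum((obs - exp_)^2 / exp_)
  pval <- stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("near-pure background pushes the mean lifetime to the window midpoint", {
  p <- std_params()
  h <- sample_decay_photons(p, 2e5, background_fraction = 0.999, seed = 5)
  expect_equal(mean_lifetime(h)$tau_mean, 12.5 / 2, tolerance = 0.02)
})

test_that("scenes without structures are pure background and seeds reproduce", {
  empty <- data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      radius_nm = numeric(0), class = character(0),
                      efficiency = numeric(0), photons = numeric(0))
  spec <- scene_spec(empty, image_shape = c(16, 16), background_rate = 2,
                     seed = 4)
  sim <- simulate_flim_scene(spec)
  expect_equal(mean(sim$image$photon_counts), 2, tolerance = 0.2)
  expect_identical(nrow(sim$truth), 0L)

  st <- demo_structures(n_per_class = 1, image_shape = c(24, 24),
                        photons = 2000, seed = 8)
  spec2 <- scene_spec(st, image_shape = c(24, 24), seed = 19)
  a <- simulate_flim_scene(spec2)
  b <- simulate_flim_scene(spec2)
  expect_identical(a$image$photon_counts, b$image$photon_counts)
  expect_identical(a$image$lifetime_sum, b$image$lifetime_sum)
  # container invariant
  expect_true(all(a$image$lifetime_sum[a$image$photon_counts == 0] == 0))
})

test_that("structures with FRET have shorter ROI lifetimes than without", {
  mk <- function(E, seed) {
    st <- demo_structures(n_per_class = 4, image_shape = c(48, 48),
                          efficiencies = c(flat = E, domed = E, sphere = E),
                          photons = 4000, seed = seed)
    spec <- scene_spec(st, image_shape = c(48, 48), seed = seed)
    sim <- simulate_flim_scene(spec)
    sapply(seq_len(nrow(sim$truth)), function(i) {
      x <- round(sim$truth$x_px[i]); y <- round(sim$truth$y_px[i])
      roi_mean_lifetime(sim$image, c(x - 4, x + 4, y - 4, y + 4),
                        t_reference = 2)$mean_lifetime
    })
  }
  with_fret <- mk(0.3, 31)
  without <- mk(0.0, 32)
  expect_lt(mean(with_fret), mean(without))
  expect_gt(stats::t.test(without, with_fret)$statistic, 3)
})

test_that("signal-to-background ratio of default scenes exceeds 100", {
  st <- demo_structures(n_per_class = 2, image_shape = c(48, 48), seed = 2)
  spec <- scene_spec(st, image_shape = c(48, 48), seed = 12)
  sim <- simulate_flim_scene(spec)
  peak <- max(sim$image$photon_counts)
  expect_gt(peak / spec$background_rate, 100)
})

test_that("frame series splits the photon budget and models acceptor bleaching", {
  st <- demo_structures(n_per_class = 1, image_shape = c(24, 24),
                        photons = 9000, seed = 6)
  spec <- scene_spec(st, image_shape = c(24, 24), n_frames = 3, seed = 44)

  # single frame == whole-scene draw with scaled photons and matching seed
  one <- simulate_frame_series(spec, n_frames = 1)[[1]]
  ref <- simulate_flim_scene(spec, photon_scale = 1, seed = spec$seed + 1)
  expect_equal(sum(one$image$photon_counts) * 1,
               sum(ref$image$photon_counts) / 1, tolerance = 0.1)

  # no bleaching: per-frame mean lifetimes show no trend across frames
  spec0 <- scene_spec(st, image_shape = c(24, 24), n_frames = 24,
                      acceptor_bleach_per_frame = 0, seed = 45)
  frames <- simulate_frame_series(spec0)
  ml <- vapply(frames, function(f) {
    sum(f$image$lifetime_sum) / sum(f$image$photon_counts)
  }, numeric(1))
  sl <- summary(stats::lm(ml ~ seq_along(ml)))$coefficients[2, ]
  expect_gt(sl["Pr(>|t|)"], 0.01)

  # with bleaching the late cumulative lifetime exceeds the early one
  # (lower acceptor fraction => lower E => longer donor lifetime)
  specb <- scene_spec(st, image_shape = c(24, 24), n_frames = 40,
                      acceptor_bleach_per_frame = 0.05, seed = 46)
  fb <- simulate_frame_series(specb)
  early <- pool_flim_images(lapply(fb[1:5], `[[`, "image"))
  late <- pool_flim_images(lapply(fb[36:40], `[[`, "image"))
  expect_gt(sum(late$lifetime_sum) / sum(late$photon_counts),
            sum(early$lifetime_sum) / sum(early$photon_counts))
})

test_that("overlapping structures are flagged as not isolated", {
  st <- data.frame(id = 1:2, x_px = c(10, 12), y_px = c(10, 10),
                   radius_nm = 150, class = "flat", efficiency = 0.2,
                   photons = 1000)
  spec <- scene_spec(st, image_shape = c(24, 24), seed = 1)
  sim <- simulate_flim_scene(spec)
  expect_false(any(sim$truth$isolated))
})
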