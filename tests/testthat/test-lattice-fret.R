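test_that("occupancy fraction follows the four-state definition", {
  expect_equal(occupancy_fraction(c(1, 1, 1, 1)), 0.25)
  expect_equal(occupancy_fraction(c(0, 0, 0, 5)), 1.0)
  expect_equal(occupancy_fraction(c(3, 1, 0, 0)), 0.0)
  expect_equal(occupancy_fraction(occupancy_model(0.2, 0.3, 0.1, 0.4)), 0.4)
  expect_error(occupancy_fraction(c(0, 0, 0, 0)),
               class = "fretclem_invalid_parameter")
  expect_error(occupancy_model(0.5, 0.5, 0.5, 0.5),
               class = "fretclem_invalid_parameter")
})

test_that("multi-acceptor efficiency is additive in transfer rate", {
  one <- lattice_scene(c(0, 0, 0), matrix(c(60, 0, 0), 1, 3), R0 = 60)
  expect_equal(multi_acceptor_efficiency(one, TRUE), 0.5)
  expect_equal(multi_acceptor_efficiency(one, FALSE), 0)
  two <- lattice_scene(c(0, 0, 0), rbind(c(60, 0, 0), c(0, 60, 0)), R0 = 60)
  expect_equal(multi_acceptor_efficiency(two, c(TRUE, TRUE)), 2 / 3)
  # donor on a site: degenerate geometry
  deg <- lattice_scene(c(60, 0, 0), matrix(c(60, 0, 0), 1, 3), R0 = 60)
  expect_warning(e <- multi_acceptor_efficiency(deg, TRUE), "coincides")
  expect_identical(e, 1)
})

test_that("expected efficiency enumerates configurations exactly", {
  ring60 <- lattice_scene(c(0, 0, 0), ring_sites(5, 60), R0 = 60)
  expect_equal(expected_lattice_efficiency(ring60, 0), 0)
  expect_equal(expected_lattice_efficiency(ring60, 1), 5 / 6) # S = 5
  # closed-form check for 1 site: p * E(site)
  one <- lattice_scene(c(0, 0, 0), matrix(c(50, 0, 10), 1, 3), R0 = 60)
  p <- 0.37
  expect_equal(expected_lattice_efficiency(one, p),
               p * multi_acceptor_efficiency(one, TRUE))
  expect_error(
    expected_lattice_efficiency(
      lattice_scene(c(0, 0, 25), matrix(rnorm(63, sd = 50), 21, 3)), 0.5),
    class = "fretclem_invalid_parameter")
})

test_that("enumeration agrees with Monte-Carlo for random geometries", {
  set.seed(99)
  for (k in 1:6) {
    sites <- cbind(runif(5, -90, 90), runif(5, -90, 90), runif(5, -20, 20))
    scene <- lattice_scene(c(0, 0, 25), sites, R0 = 60)
    p <- runif(1, 0.1, 0.9)
    exact <- expected_lattice_efficiency(scene, p)
    nd <- 2e5
    mc <- expected_lattice_efficiency(scene, p, monte_carlo = TRUE,
                                      n_draws = nd, seed = k)
    se <- sqrt(exact * (1 - exact) / nd) + 1e-12
    expect_lt(abs(mc - exact), 5 * se + 0.002)
  }
})

test_that("expected efficiency is monotone in occupancy and in proximity", {
  scene <- lattice_scene(c(0, 0, 25), ring_sites(), R0 = 60)
  occ <- seq(0, 1, by = 0.1)
  vals <- vapply(occ, function(p) expected_lattice_efficiency(scene, p),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  # near donor beats far donor at every occupancy > 0
  near <- lattice_scene(c(10, 0, 25), ring_sites(), R0 = 60)
  far <- lattice_scene(c(200, 0, 25), ring_sites(), R0 = 60)
  for (p in c(0.1, 0.5, 0.9)) {
    expect_gt(expected_lattice_efficiency(near, p),
              expected_lattice_efficiency(far, p))
  }
})

test_that("position scans honour the pentagon symmetry and locate the optimum", {
  scene <- lattice_scene(c(0, 0, 25), ring_sites(5, 70), R0 = 60)
  scan <- position_scan(lateral_spacing = 14, axial_offset = 25,
                        lateral_bounds = c(140, 140))
  emap <- scan_nterm_positions(scene, scan, 0.4)
  expect_identical(dim(emap$efficiency), c(11L, 11L))

  # 1x1 grid degenerates to a single expected-efficiency evaluation
  tiny <- scan_nterm_positions(scene, position_scan(14, 25, c(0, 0)), 0.4)
  expect_equal(dim(tiny$efficiency), c(1L, 1L))
  expect_equal(tiny$efficiency[1, 1],
               expected_lattice_efficiency(
                 lattice_scene(c(0, 0, 25), ring_sites(5, 70), R0 = 60), 0.4))

  # rotating the pentagon by 72 degrees leaves the map invariant
  rot <- lattice_scene(c(0, 0, 25), ring_sites(5, 70, phase = 2 * pi / 5),
                       R0 = 60)
  emap_rot <- scan_nterm_positions(rot, scan, 0.4)
  expect_equal(emap$efficiency, emap_rot$efficiency, tolerance = 1e-9)

  # grid maximum equals the brute-force argmax over grid points
  pts <- expand.grid(x = emap$x, y = emap$y)
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    expected_lattice_efficiency(
      lattice_scene(c(pts$x[i], pts$y[i], 25), ring_sites(5, 70), R0 = 60),
      0.4)
  }, numeric(1))
  expect_equal(max(emap$efficiency), max(brute), tolerance = 1e-12)
  i_map <- which(emap$efficiency == max(emap$efficiency), arr.ind = TRUE)[1, ]
  i_brute <- which.max(brute)
  expect_equal(c(emap$x[i_map[2]], emap$y[i_map[1]]),
               c(pts$x[i_brute], pts$y[i_brute]))
})
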