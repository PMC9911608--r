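test_that("affine registration is exact for consistent fiducials", {
  ident <- data.frame(flim_x = c(0, 10, 3, 7), flim_y = c(0, 2, 9, 5))
  ident$em_x <- ident$flim_x; ident$em_y <- ident$flim_y
  reg <- fit_affine(ident)
  expect_equal(reg$transform$A, diag(2), tolerance = 1e-12)
  expect_equal(reg$transform$b, c(0, 0), tolerance = 1e-12)
  expect_lt(reg$rms_residual, 1e-12)

  # the FLIM/EM pixel-scale ratio 80 / 1.2 with rotation and translation
  fid <- make_fiducials(12, rotation_deg = 17, scale = 80 / 1.2,
                        translation = c(500, -300))
  reg2 <- fit_affine(fid)
  th <- 17 * pi / 180
  A_true <- (80 / 1.2) * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(max(abs(reg2$transform$A - A_true)), 0, tolerance = 1e-9)
  expect_equal(max(abs(reg2$transform$b - c(500, -300))), 0, tolerance = 1e-9)
  expect_lt(reg2$rms_residual, 1e-9)
})

test_that("degenerate fiducial sets are rejected", {
  two <- data.frame(flim_x = c(0, 1), flim_y = c(0, 1),
                    em_x = c(0, 1), em_y = c(0, 1))
  expect_error(fit_affine(two), class = "fretclem_degenerate_fiducials")
  coll <- data.frame(flim_x = c(0, 1, 2), flim_y = c(0, 1, 2),
                     em_x = c(0, 2, 4), em_y = c(1, 3, 5))
  expect_error(fit_affine(coll), class = "fretclem_degenerate_fiducials")
  missing_col <- data.frame(flim_x = 1:3, flim_y = 1:3, em_x = 1:3)
  expect_error(fit_affine(missing_col), class = "fretclem_parse_error")
})

test_that("registration residual grows monotonically with fiducial jitter", {
  rms <- vapply(c(0.5, 1, 2, 4), function(j) {
    fit_affine(make_fiducials(300, 10, 5, c(50, 80), jitter_sd = j,
                              seed = 42))$rms_residual
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("nearest-neighbour resampling preserves lattice-aligned maps", {
  set.seed(7)
  counts <- matrix(rpois(12 * 10, 5), 12, 10)
  lsum <- counts * runif(120, 1, 3)
  lsum[counts == 0] <- 0
  img <- flim_image(counts, lsum, pixel_size_nm = 80)

  ident <- affine_transform(diag(2), c(0, 0))
  out <- transform_image_nn(img, ident, dim(counts))
  expect_identical(out$photon_counts, img$photon_counts)
  expect_identical(out$lifetime_sum, img$lifetime_sum)

  # integer translation: shifted copy, photon total conserved in overlap
  tr <- affine_transform(diag(2), c(3, 2))
  sh <- transform_image_nn(img, tr, c(20, 20))
  expect_identical(sh$photon_counts[2 + 1:12, 3 + 1:10], img$photon_counts)
  # round trip back
  back <- transform_image_nn(sh, invert_affine(tr), dim(counts))
  expect_identical(back$photon_counts, img$photon_counts)
})

test_that("ROI lifetimes pool photons and compose additively", {
  counts <- matrix(100, 8, 8); counts[, 5:8] <- 300
  lsum <- matrix(100 * 2.0, 8, 8); lsum[, 5:8] <- 300 * 3.0
  img <- flim_image(counts, lsum, 80)
  # uniform region
  expect_equal(roi_mean_lifetime(img, c(0, 3, 0, 3))$mean_lifetime, 2.0)
  # half at 2.0 ns / 100 photons-per-pixel, half at 3.0 ns / 300: 2.75 ns
  expect_equal(roi_mean_lifetime(img, c(0, 7, 0, 7))$mean_lifetime, 2.75)
  # additivity: union equals photon-weighted mean of disjoint parts
  a <- roi_mean_lifetime(img, c(0, 3, 0, 7))
  b <- roi_mean_lifetime(img, c(4, 7, 0, 7))
  u <- roi_mean_lifetime(img, c(0, 7, 0, 7))
  expect_equal(u$mean_lifetime,
               (a$mean_lifetime * a$photons + b$mean_lifetime * b$photons) /
                 (a$photons + b$photons))
  expect_error(roi_mean_lifetime(img, c(0, 9, 0, 3)),
               class = "fretclem_invalid_parameter")
  empty <- flim_image(matrix(0, 4, 4), matrix(0, 4, 4), 80)
  expect_error(roi_mean_lifetime(empty, c(0, 3, 0, 3)),
               class = "fretclem_insufficient_photons")
})

test_that("cell summaries normalise against the flat-class mean", {
  rec <- make_records("c1", c("flat", "flat", "sphere", "sphere"),
                      c(2.35, 2.45, 2.45, 2.55))
  s <- summarize_cell(rec)
  expect_equal(s$mean_flat_ns, 2.40)
  expect_equal(s$delta_sphere_ns, 0.10)
  expect_identical(s$delta_flat_ns, 0)
  expect_true(is.na(s$delta_domed_ns)) # absent class: NA, not 0

  same <- make_records("c2", c("flat", "domed", "sphere"), rep(2.2, 3))
  s2 <- summarize_cell(same)
  expect_equal(c(s2$delta_domed_ns, s2$delta_sphere_ns), c(0, 0))

  noflat <- make_records("c3", c("domed", "sphere"), c(2.2, 2.3))
  expect_error(summarize_cell(noflat), class = "fretclem_no_reference")
})

test_that("the acceptor-expression filter uses a strict 2.1 ns boundary", {
  s <- data.frame(cell_id = c("a", "b", "c"),
                  cellular_average_lifetime_ns = c(2.09, 2.10, 2.11))
  kept <- filter_cells_by_lifetime(s)
  expect_identical(kept$cell_id, "a")
  expect_identical(nrow(filter_cells_by_lifetime(s, Inf)), 3L)
})

test_that("lifetime filter separates acceptor-positive from donor-only cells", {
  mk <- function(id, tau) data.frame(cell_id = id,
                                     cellular_average_lifetime_ns = tau)
  set.seed(3)
  pos <- do.call(rbind, lapply(1:5, function(i) {
    mk(paste0("pos", i), rnorm(1, 1.9, 0.05))
  }))
  neg <- do.call(rbind, lapply(1:5, function(i) {
    mk(paste0("neg", i), rnorm(1, 2.5, 0.05))
  }))
  kept <- filter_cells_by_lifetime(rbind(pos, neg), 2.1)
  expect_setequal(kept$cell_id, pos$cell_id)
})

test_that("morphometrics follow the occupied-area definition and conserve area", {
  mask <- matrix(0L, 40, 40)
  mask[1:10, 1:10] <- 1L  # 100 px
  mask[21:30, 21:30] <- 2L
  ct <- data.frame(label = 1:2, class = c("flat", "flat"))
  mo <- morphometrics(mask, ct, membrane_area_nm2 = 1000, pixel_size_nm = 1)
  expect_equal(mo$occupied_pct[mo$class == "flat"], 20)
  expect_equal(mo$mean_area_nm2[mo$class == "flat"], 100)
  expect_equal(mo$n[mo$class == "flat"], 2)

  # empty mask: all zeros
  mo0 <- morphometrics(matrix(0L, 5, 5), ct[0, ], 1e4, 1)
  expect_true(all(mo0$n == 0) && all(mo0$occupied_pct == 0))

  # per-class occupied areas sum to the total structure area exactly
  mask[35:38, 2:5] <- 3L
  ct3 <- data.frame(label = 1:3, class = c("flat", "domed", "sphere"))
  mo3 <- morphometrics(mask, ct3, membrane_area_nm2 = 40 * 40 * 4,
                       pixel_size_nm = 2)
  expect_identical(sum(mo3$occupied_pct) / 100 * (40 * 40 * 4),
                   sum(mask > 0) * 4)

  expect_error(morphometrics(mask, ct, 1e6, 1), "label 3")
  expect_error(morphometrics(mask, ct3, 10, 1),
               class = "fretclem_invalid_parameter")
})
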