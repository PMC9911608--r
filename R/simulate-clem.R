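#' Simulate a matched FLIM + EM scene
#'
#' Produces everything one correlative acquisition yields: the FLIM image
#' ([simulate_flim_scene()]), the paired EM segmentation mask rendered in the
#' EM frame under the ground-truth affine transform, the per-label curvature
#' class table, and fiducial pairs (flat and domed structure centroids in
#' both frames; sphere structures are excluded from fiducial candidates
#' because they can shift during critical point drying).
#'
#' @param spec A [scene_spec()].
#' @param fiducial_jitter_px Gaussian jitter (EM pixels, sd) added to the EM
#'   side of the fiducial pairs; 0 gives affine-consistent fiducials.
#' @param cell_id Cell identifier.
#' @param seed Overrides `spec$seed` when not `NULL`.
#' @return List of class `clem_scene`: `flim` ([flim_image()]), `truth`
#'   (ground-truth data.frame), `transform` (true FLIM-to-EM affine),
#'   `em_mask` (labelled matrix), `class_table`, `fiducials`,
#'   `em_pixel_size_nm`, `membrane_area_nm2`.
#' @export
simulate_clem_scene <- function(spec, fiducial_jitter_px = 0,
                                cell_id = "cell1", seed = NULL) {
  sim <- simulate_flim_scene(spec, seed = seed)
  sim$image$cell_id <- cell_id
  truth <- sim$truth
  transform <- attr(truth, "em_transform")

  # EM frame sized to hold the transformed FLIM field of view
  corners <- apply_affine(transform, cbind(
    c(0, spec$image_shape[2] - 1, 0, spec$image_shape[2] - 1),
    c(0, 0, spec$image_shape[1] - 1, spec$image_shape[1] - 1)))
  nc <- ceiling(max(corners[, 1])) + 2L
  nr <- ceiling(max(corners[, 2])) + 2L
  mask <- matrix(0L, nr, nc)

  n_str <- nrow(truth)
  if (n_str > 0) {
    em_xy <- apply_affine(transform, cbind(truth$x_px, truth$y_px))
    r_em <- truth$radius_nm / spec$em_pixel_size_nm
    for (i in seq_len(n_str)) {
      x0 <- max(floor(em_xy[i, 1] - r_em[i]), 0)
      x1 <- min(ceiling(em_xy[i, 1] + r_em[i]), nc - 1)
      y0 <- max(floor(em_xy[i, 2] - r_em[i]), 0)
      y1 <- min(ceiling(em_xy[i, 2] + r_em[i]), nr - 1)
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      disk <- outer(ys - em_xy[i, 2], xs - em_xy[i, 1],
                    function(a, b) a^2 + b^2 <= r_em[i]^2)
      sub <- mask[ys + 1L, xs + 1L, drop = FALSE]
      sub[disk & sub == 0L] <- truth$id[i]
      mask[ys + 1L, xs + 1L] <- sub
    }
    truth$em_x_px <- em_xy[, 1]
    truth$em_y_px <- em_xy[, 2]
  }

  fid_sel <- truth$class %in% c("flat", "domed")
  fiducials <- data.frame(flim_x = truth$x_px[fid_sel],
                          flim_y = truth$y_px[fid_sel],
                          em_x = truth$em_x_px[fid_sel],
                          em_y = truth$em_y_px[fid_sel])
  if (fiducial_jitter_px > 0 && nrow(fiducials) > 0) {
    fiducials$em_x <- fiducials$em_x +
      stats::rnorm(nrow(fiducials), 0, fiducial_jitter_px)
    fiducials$em_y <- fiducials$em_y +
      stats::rnorm(nrow(fiducials), 0, fiducial_jitter_px)
  }

  structure(list(
    flim = sim$image,
    truth = truth,
    transform = transform,
    em_mask = mask,
    class_table = data.frame(label = truth$id,
                             class = truth$class),
    fiducials = fiducials,
    em_pixel_size_nm = spec$em_pixel_size_nm,
    membrane_area_nm2 = nr * nc * spec$em_pixel_size_nm^2,
    cell_id = cell_id
  ), class = "clem_scene")
}

#' Structure layout helper for synthetic scenes
#'
#' Lays out `n_per_class` structures of each curvature class on a jittered
#' grid with the given true efficiencies, sized so neighbours stay isolated.
#'
#' @param n_per_class Structures per class.
#' @param efficiencies Named numeric vector of true efficiencies for classes
#'   `flat`, `domed`, `sphere`.
#' @param image_shape FLIM raster shape `c(rows, cols)`.
#' @param radius_nm Structure radius (nm); flat lattices are drawn slightly
#'   larger than spheres, echoing their larger projected areas.
#' @param photons Expected photons per structure (default 10000, the typical
#'   per-structure photon budget of a 150-frame acquisition).
#' @param margin_px Border kept free of centroids.
#' @param seed Seed for the layout jitter.
#' @return `data.frame` suitable for [scene_spec()].
#' @export
demo_structures <- function(n_per_class = 4,
                            efficiencies = c(flat = 0.30, domed = 0.25,
                                             sphere = 0.20),
                            image_shape = c(48, 48),
                            radius_nm = c(flat = 180, domed = 140,
                                          sphere = 100),
                            photons = 10000,
                            margin_px = 6,
                            seed = 1L) {
  set.seed(seed)
  classes <- rep(c("flat", "domed", "sphere"), each = n_per_class)
  n <- length(classes)
  ngrid <- ceiling(sqrt(n))
  gx <- seq(margin_px, image_shape[2] - 1 - margin_px, length.out = ngrid)
  gy <- seq(margin_px, image_shape[1] - 1 - margin_px, length.out = ngrid)
  pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  ord <- sample.int(n)
  data.frame(id = seq_len(n),
             x_px = pos$x + stats::runif(n, -1, 1),
             y_px = pos$y + stats::runif(n, -1, 1),
             radius_nm = unname(radius_nm[classes[ord]]),
             class = classes[ord],
             efficiency = unname(efficiencies[classes[ord]]),
             photons = photons)
}
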