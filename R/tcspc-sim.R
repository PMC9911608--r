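#' FLIM image container
#'
#' A FLIM raster holds two planes: per-pixel photon counts and the per-pixel
#' sum of photon arrival times (ns x photons). The photon-weighted mean
#' lifetime of any pixel set is then the ratio of summed planes, which makes
#' ROI statistics exact pooling of photons.
#'
#' Matrices are indexed `[row, col]`; pixel coordinates used throughout the
#' package are 0-based with `x` = column and `y` = row, pixel centers on
#' integer coordinates, origin at the top-left pixel.
#'
#' @param photon_counts Integer-valued matrix of photon counts.
#' @param lifetime_sum Matrix of summed arrival times (ns·photons); must be 0
#'   wherever `photon_counts` is 0.
#' @param pixel_size_nm Pixel pitch in nm (default 80).
#' @param cell_id Optional identifier of the cell / membrane the image
#'   belongs to.
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(photon_counts, lifetime_sum,
                       pixel_size_nm = 80, cell_id = NA_character_) {
  if (!is.matrix(photon_counts) || !is.matrix(lifetime_sum) ||
      !all(dim(photon_counts) == dim(lifetime_sum))) {
    stop_invalid("photon_counts and lifetime_sum must be matrices of equal dimension")
  }
  storage.mode(photon_counts) <- "double"
  storage.mode(lifetime_sum) <- "double"
  if (any(photon_counts < 0)) stop_invalid("photon counts must be >= 0")
  if (any(lifetime_sum[photon_counts == 0] != 0)) {
    stop_invalid("lifetime_sum must be 0 wherever photon_counts is 0")
  }
  if (pixel_size_nm <= 0) stop_invalid("pixel_size_nm must be > 0")
  structure(list(photon_counts = photon_counts, lifetime_sum = lifetime_sum,
                 pixel_size_nm = pixel_size_nm, cell_id = cell_id),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf("<flim_image> %d x %d px @ %.3g nm/px, %.0f photons, cell %s\n",
              nrow(x$photon_counts), ncol(x$photon_counts), x$pixel_size_nm,
              sum(x$photon_counts), x$cell_id))
  invisible(x)
}

#' Sample photon arrival times from an IRF-convolved decay
#'
#' Draws `n_photons` arrival times: each signal photon picks decay component 1
#' with the photon fraction implied by amplitude fraction `P1` (components
#' contribute photons in proportion to amplitude times lifetime), then
#' arrives at `t0 + Exp(tau_k) + N(0, tauG)`;
#' background photons are uniform over the window. Times outside the window
#' are wrapped modulo the window, emulating periodic pulsed excitation, so
#' the histogram total always equals `n_photons` exactly.
#'
#' @param params A [decay_params()]; `F0` is ignored (totals are set by
#'   `n_photons`).
#' @param n_photons Number of photons to draw (`>= 0`).
#' @param background_fraction Expected fraction of uniform background photons,
#'   in `[0, 1)`. The realised background count is binomial; the *expected*
#'   per-bin background is recorded on the returned histogram for use by the
#'   fit model.
#' @param window Acquisition window / excitation period (ns), default 12.5.
#' @param n_bins Number of histogram bins, default 256.
#' @param seed Optional integer seed for reproducibility.
#' @return A [decay_histogram()].
#' @export
sample_decay_photons <- function(params, n_photons, background_fraction = 0,
                                 window = 12.5, n_bins = 256, seed = NULL) {
  if (!inherits(params, "decay_params")) {
    stop_invalid("params must be a decay_params object")
  }
  if (window <= 0) stop_invalid("window must be > 0")
  if (n_photons < 0) stop_invalid("n_photons must be >= 0")
  if (background_fraction < 0 || background_fraction >= 1) {
    stop_invalid("background_fraction must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  edges <- seq(0, window, length.out = n_bins + 1L)
  bg_per_bin <- n_photons * background_fraction / n_bins
  if (n_photons == 0) {
    return(decay_histogram(edges, rep(0, n_bins), bg_per_bin))
  }
  n_bg <- stats::rbinom(1L, n_photons, background_fraction)
  n_sig <- n_photons - n_bg
  times <- numeric(0)
  if (n_sig > 0) {
    # photon fraction of component 1: each component contributes photons in
    # proportion to amplitude x lifetime (the integral of its decay)
    q1 <- params$P1 * params$tau1 /
      (params$P1 * params$tau1 + (1 - params$P1) * params$tau2)
    comp1 <- stats::runif(n_sig) < q1
    tau <- ifelse(comp1, params$tau1, params$tau2)
    times <- params$t0 + stats::rexp(n_sig, rate = 1) * tau +
      stats::rnorm(n_sig, 0, params$tauG)
  }
  if (n_bg > 0) times <- c(times, stats::runif(n_bg, 0, window))
  times <- times %% window
  idx <- pmin(floor(times / (window / n_bins)) + 1L, n_bins)
  decay_histogram(edges, tabulate(idx, nbins = n_bins), bg_per_bin)
}

#' Specification of a synthetic FLIM scene
#'
#' Describes one synthetic unroofed-membrane field of view: clathrin-coated
#' structures with curvature class, position, size, true FRET efficiency and
#' photon budget, over a uniform background, imaged at the FLIM pixel scale.
#'
#' @param structures `data.frame` with columns `id`, `x_px`, `y_px` (0-based
#'   FLIM pixel centroid), `radius_nm`, `class` (one of `"flat"`, `"domed"`,
#'   `"sphere"`), `efficiency` (true FRET efficiency, `0 <= E < 1`), and
#'   `photons` (expected photons emitted by the structure).
#' @param image_shape `c(rows, cols)` of the FLIM raster.
#' @param pixel_size_nm FLIM pixel pitch (default 80 nm).
#' @param donor_only_tau_a Donor-only amplitude-weighted lifetime (ns,
#'   default 2.6); a structure with efficiency `E` decays with
#'   `tau = (1 - E) * donor_only_tau_a`.
#' @param tauG,t0 IRF width and pulse offset (ns).
#' @param window,n_bins TCSPC window (ns) and binning.
#' @param background_rate Expected background photons per pixel (default 0.5;
#'   with the default photon budgets this keeps the signal-to-background
#'   ratio well above 100).
#' @param psf_sigma_px Gaussian PSF width in FLIM pixels (default 1.3); the
#'   structure intensity profile is a hard disk of the structure radius
#'   convolved with this PSF.
#' @param n_frames Number of acquisition frames (default 150); used by
#'   [simulate_frame_series()].
#' @param acceptor_bleach_per_frame Fractional loss of acceptor-bearing sites
#'   per frame (default 0).
#' @param em_pixel_size_nm,em_rotation_deg,em_translation_px Parameters of the
#'   ground-truth affine transform linking this FLIM frame to the paired
#'   synthetic EM frame.
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(structures,
                       image_shape = c(64, 64),
                       pixel_size_nm = 80,
                       donor_only_tau_a = 2.6,
                       tauG = 0.15, t0 = 2,
                       window = 12.5, n_bins = 256,
                       background_rate = 0.5,
                       psf_sigma_px = 1.3,
                       n_frames = 150,
                       acceptor_bleach_per_frame = 0,
                       em_pixel_size_nm = 8,
                       em_rotation_deg = 3,
                       em_translation_px = c(40, 25),
                       seed = 1L) {
  req <- c("id", "x_px", "y_px", "radius_nm", "class", "efficiency", "photons")
  if (!is.data.frame(structures)) stop_invalid("structures must be a data.frame")
  miss <- setdiff(req, names(structures))
  if (length(miss)) {
    stop_invalid(paste0("structures is missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(structures) > 0) {
    if (!all(structures$class %in% c("flat", "domed", "sphere"))) {
      stop_invalid("class must be one of flat, domed, sphere")
    }
    if (any(structures$efficiency < 0 | structures$efficiency >= 1)) {
      stop_invalid("true efficiency must satisfy 0 <= E < 1")
    }
    if (any(structures$photons <= 0)) stop_invalid("expected photons must be > 0")
  }
  if (acceptor_bleach_per_frame < 0 || acceptor_bleach_per_frame >= 1) {
    stop_invalid("acceptor_bleach_per_frame must be in [0, 1)")
  }
  structure(list(structures = structures, image_shape = image_shape,
                 pixel_size_nm = pixel_size_nm,
                 donor_only_tau_a = donor_only_tau_a,
                 tauG = tauG, t0 = t0, window = window, n_bins = n_bins,
                 background_rate = background_rate,
                 psf_sigma_px = psf_sigma_px, n_frames = n_frames,
                 acceptor_bleach_per_frame = acceptor_bleach_per_frame,
                 em_pixel_size_nm = em_pixel_size_nm,
                 em_rotation_deg = em_rotation_deg,
                 em_translation_px = em_translation_px,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# pixel-integrated profile of a hard disk convolved with a Gaussian PSF,
# normalised to sum 1; returned as (rows, cols, values) over a local window
disk_psf_profile <- function(cx, cy, radius_px, sigma_px, shape,
                             oversample = 4L) {
  half <- ceiling(radius_px + 4 * sigma_px) + 1L
  xs <- seq(floor(cx) - half, floor(cx) + half)
  ys <- seq(floor(cy) - half, floor(cy) + half)
  os <- oversample
  sub <- (seq_len(os) - 0.5) / os - 0.5
  fx <- rep(xs, each = os) + rep(sub, length(xs))
  fy <- rep(ys, each = os) + rep(sub, length(ys))
  disk <- outer(fy - cy, fx - cx, function(a, b) (a^2 + b^2) <= radius_px^2) * 1
  # separable Gaussian convolution at subpixel resolution
  kr <- ceiling(4 * sigma_px * os)
  kx <- stats::dnorm(seq(-kr, kr) / os, sd = sigma_px)
  kx <- kx / sum(kx)
  sm <- apply(disk, 2, function(col) {
    stats::convolve(col, rev(kx), type = "open")[(kr + 1):(kr + length(col))]
  })
  sm <- t(apply(sm, 1, function(row) {
    stats::convolve(row, rev(kx), type = "open")[(kr + 1):(kr + length(row))]
  }))
  # block-average back to pixel resolution
  npx <- length(xs)
  px <- matrix(0, npx, npx)
  for (i in seq_len(npx)) {
    ri <- ((i - 1) * os + 1):(i * os)
    for (j in seq_len(npx)) {
      px[i, j] <- mean(sm[ri, ((j - 1) * os + 1):(j * os)])
    }
  }
  keep_r <- ys >= 0 & ys <= shape[1] - 1
  keep_c <- xs >= 0 & xs <= shape[2] - 1
  px <- pmax(px[keep_r, keep_c, drop = FALSE], 0) # FFT ringing can go ~-1e-14
  s <- sum(px)
  if (s <= 0) stop_invalid("structure profile falls entirely outside the image")
  list(rows = ys[keep_r] + 1L, cols = xs[keep_c] + 1L, values = px / s)
}

#' Simulate one FLIM scene with matched ground truth
#'
#' Renders every structure as a PSF-blurred disk of its expected photon
#' budget, draws per-pixel Poisson photon counts for structures and uniform
#' background separately, samples an arrival time for every photon from the
#' structure's decay (`tau = (1 - E) * donor_only_tau_a`, IRF-convolved,
#' wrapped at the window) or uniformly for background, and accumulates counts
#' and arrival-time sums per pixel. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @param photon_scale Multiplier on every structure's expected photons and
#'   the background rate (used by [simulate_frame_series()] to split frames).
#' @param efficiency_scale Multiplier on true efficiencies (acceptor
#'   photobleaching lowers the acceptor-bearing fraction and hence the
#'   effective efficiency).
#' @param seed Overrides `spec$seed` when not `NULL`.
#' @return A list with `image` ([flim_image()]) and `truth`: a `data.frame`
#'   of per-structure ground truth (`id`, `class`, `efficiency`, `tau_ns`,
#'   `x_px`, `y_px`, `radius_nm`, `photons_emitted`, `isolated`) plus the
#'   ground-truth FLIM-to-EM affine transform as attribute `"em_transform"`.
#'   Structures whose centroids lie closer than twice the sum of their radii
#'   are flagged `isolated = FALSE` (the analysis contract assumes single
#'   isolated structures).
#' @export
simulate_flim_scene <- function(spec, photon_scale = 1, efficiency_scale = 1,
                                seed = NULL) {
  if (!inherits(spec, "scene_spec")) stop_invalid("spec must be a scene_spec")
  set.seed(if (is.null(seed)) spec$seed else seed)
  shape <- spec$image_shape
  counts <- matrix(0, shape[1], shape[2])
  lsum <- matrix(0, shape[1], shape[2])
  st <- spec$structures
  n_str <- nrow(st)

  truth <- st
  truth$efficiency <- st$efficiency * efficiency_scale
  truth$tau_ns <- (1 - truth$efficiency) * spec$donor_only_tau_a
  truth$photons_emitted <- numeric(n_str)
  truth$isolated <- rep(TRUE, n_str)
  if (n_str > 1) {
    r_px <- st$radius_nm / spec$pixel_size_nm
    for (i in seq_len(n_str - 1)) {
      for (j in (i + 1):n_str) {
        d <- sqrt((st$x_px[i] - st$x_px[j])^2 + (st$y_px[i] - st$y_px[j])^2)
        if (d < 2 * (r_px[i] + r_px[j])) {
          truth$isolated[c(i, j)] <- FALSE
        }
      }
    }
  }

  if (n_str > 0) {
    for (i in seq_len(n_str)) {
      prof <- disk_psf_profile(st$x_px[i], st$y_px[i],
                               st$radius_nm[i] / spec$pixel_size_nm,
                               spec$psf_sigma_px, shape)
      lambda <- prof$values * st$photons[i] * photon_scale
      n_px <- stats::rpois(length(lambda), lambda)
      total <- sum(n_px)
      truth$photons_emitted[i] <- total
      if (total == 0) next
      # one decay draw per photon, assigned to its pixel
      tt <- (spec$t0 + stats::rexp(total) * truth$tau_ns[i] +
               stats::rnorm(total, 0, spec$tauG)) %% spec$window
      pix <- rep(seq_along(n_px), n_px)
      dim(n_px) <- dim(prof$values)
      counts[prof$rows, prof$cols] <- counts[prof$rows, prof$cols] + n_px
      add_t <- rowsum(tt, pix)
      tmat <- matrix(0, length(prof$rows), length(prof$cols))
      tmat[as.integer(rownames(add_t))] <- add_t
      lsum[prof$rows, prof$cols] <- lsum[prof$rows, prof$cols] + tmat
    }
  }

  n_bg <- stats::rpois(length(counts), spec$background_rate * photon_scale)
  tot_bg <- sum(n_bg)
  if (tot_bg > 0) {
    tb <- stats::runif(tot_bg, 0, spec$window)
    pixb <- rep(seq_along(n_bg), n_bg)
    counts <- counts + matrix(n_bg, shape[1], shape[2])
    add_b <- rowsum(tb, pixb)
    bmat <- matrix(0, shape[1], shape[2])
    bmat[as.integer(rownames(add_b))] <- add_b
    lsum <- lsum + bmat
  }

  img <- flim_image(counts, lsum, spec$pixel_size_nm)
  attr(truth, "em_transform") <- scene_em_transform(spec)
  list(image = img, truth = truth)
}

# ground-truth affine from FLIM pixel coordinates to EM pixel coordinates
scene_em_transform <- function(spec) {
  s <- spec$pixel_size_nm / spec$em_pixel_size_nm
  th <- spec$em_rotation_deg * pi / 180
  A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affine_transform(A, spec$em_translation_px)
}

#' Simulate a frame series with optional acceptor photobleaching
#'
#' Splits the scene's photon budget over `spec$n_frames` frames. In frame `f`
#' (1-based) the acceptor-bearing fraction has decayed by
#' `(1 - bleach)^(f - 1)`, scaling every structure's effective FRET
#' efficiency by the same factor; with `bleach = 0` all frames are
#' statistically identical.
#'
#' @param spec A [scene_spec()]; `spec$acceptor_bleach_per_frame` sets the
#'   per-frame bleach fraction.
#' @param n_frames Overrides `spec$n_frames` when not `NULL`.
#' @return List of per-frame results as returned by [simulate_flim_scene()].
#' @export
simulate_frame_series <- function(spec, n_frames = NULL) {
  if (!inherits(spec, "scene_spec")) stop_invalid("spec must be a scene_spec")
  nf <- if (is.null(n_frames)) spec$n_frames else n_frames
  bleach <- spec$acceptor_bleach_per_frame
  if (bleach < 0 || bleach >= 1) {
    stop_invalid("acceptor_bleach_per_frame must be in [0, 1)")
  }
  lapply(seq_len(nf), function(f) {
    simulate_flim_scene(spec,
                        photon_scale = 1 / nf,
                        efficiency_scale = (1 - bleach)^(f - 1),
                        seed = spec$seed + f)
  })
}

#' Pool a list of FLIM images photon-wise
#'
#' @param images List of [flim_image()] objects with identical geometry.
#' @return A single [flim_image()] with summed planes.
#' @export
pool_flim_images <- function(images) {
  counts <- Reduce(`+`, lapply(images, `[[`, "photon_counts"))
  lsum <- Reduce(`+`, lapply(images, `[[`, "lifetime_sum"))
  flim_image(counts, lsum, images[[1]]$pixel_size_nm, images[[1]]$cell_id)
}
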