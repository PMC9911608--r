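# Interchange formats. All CSVs are comma-separated UTF-8 with a mandatory
# header row and '.' decimal; TIFFs are little-endian, uncompressed.

check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_parse(sprintf("%s: missing column(s): %s", path,
                       paste(miss, collapse = ", ")))
  }
}

#' Read / write a decay histogram CSV
#'
#' Two-column CSV `(bin_start_ns, counts)`; bins must be uniform. The last
#' bin's width is taken from the grid. `background_per_bin`, if present as a
#' third column, is read back (constant per file).
#'
#' @param path File path.
#' @return A [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("bin_start_ns", "counts"), path)
  starts <- df$bin_start_ns
  if (length(starts) < 2) stop_parse(sprintf("%s: need at least 2 bins", path))
  w <- diff(starts)
  if (any(w <= 0) || max(w) - min(w) > 1e-9 * max(w)) {
    stop_parse(sprintf("%s: bin_start_ns must form a uniform increasing grid", path))
  }
  bg <- if ("background_per_bin" %in% names(df)) df$background_per_bin[1] else 0
  decay_histogram(c(starts, starts[length(starts)] + w[1]), df$counts, bg)
}

#' @rdname read_decay_csv
#' @param hist A [decay_histogram()].
#' @export
write_decay_csv <- function(hist, path) {
  df <- data.frame(bin_start_ns = hist$bin_edges[-length(hist$bin_edges)],
                   counts = hist$counts,
                   background_per_bin = hist$background_per_bin)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write fiducial pair CSVs
#'
#' Columns `flim_x, flim_y, em_x, em_y` (pixel coordinates).
#'
#' @param path File path.
#' @return `data.frame` of fiducial pairs.
#' @export
read_fiducials_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("flim_x", "flim_y", "em_x", "em_y"), path)
  df
}

#' @rdname read_fiducials_csv
#' @param pairs Fiducial `data.frame`.
#' @export
write_fiducials_csv <- function(pairs, path) {
  check_columns(pairs, c("flim_x", "flim_y", "em_x", "em_y"), "fiducial table")
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

# FLIM planes are stored as 32-bit samples mapped onto [0, 1]. The photon
# counts plane uses the fixed power-of-two scale 2^-24, which round-trips
# integer counts below 2^24 exactly under the writer's uint32 quantisation;
# the lifetime-sum plane is scaled by its own maximum (recorded in the JSON
# sidecar), giving ~2e-10 relative quantisation.
.flim_tiff_scale <- 2^-24

#' Write / read a FLIM image as a 2-plane 32-bit TIFF
#'
#' Plane 1 holds photon counts (exact round trip), plane 2 the
#' photon-weighted lifetime sums (ns·photons; ~1e-9 relative precision).
#' Pixel size, cell id and the lifetime-plane scale travel in a JSON sidecar
#' (`<path>.json`).
#'
#' @param img A [flim_image()].
#' @param path Output TIFF path.
#' @export
write_flim_tiff <- function(img, path) {
  lsum_scale <- max(img$lifetime_sum, 1e-12)
  suppressWarnings(tiff::writeTIFF(
    list(img$photon_counts * .flim_tiff_scale,
         img$lifetime_sum / lsum_scale),
    path, bits.per.sample = 32, compression = "none", reduce = FALSE))
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size_nm,
                            cell_id = img$cell_id,
                            lifetime_sum_scale = lsum_scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flim_tiff
#' @export
read_flim_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 2) {
    stop_parse(sprintf("%s: expected a 2-plane TIFF, found %d plane(s)",
                       path, length(planes)))
  }
  meta <- list(pixel_size_nm = 80, cell_id = NA_character_,
               lifetime_sum_scale = 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  counts <- round(planes[[1]] / .flim_tiff_scale)
  lsum <- planes[[2]] * meta$lifetime_sum_scale
  lsum[counts == 0] <- 0
  flim_image(counts, lsum, pixel_size_nm = meta$pixel_size_nm,
             cell_id = if (is.null(meta$cell_id)) NA_character_
                       else as.character(meta$cell_id))
}

#' Write / read a labelled EM mask as 16-bit TIFF
#'
#' Labels must be integers in `[0, 65535]`; exact round trip.
#'
#' @param mask Labelled integer matrix.
#' @param path Output TIFF path.
#' @export
write_labeled_mask <- function(mask, path) {
  if (any(mask < 0) || any(mask > 65535)) {
    stop_invalid("labels must be in [0, 65535] for 16-bit storage")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_labeled_mask
#' @export
read_labeled_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) != 2) stop_parse(sprintf("%s: expected a single-plane mask", path))
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read / write a label-class table CSV
#'
#' Columns `label`, `class`.
#' @param path File path.
#' @export
read_class_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("label", "class"), path)
  df
}

#' @rdname read_class_table
#' @param class_table `data.frame` with `label`, `class`.
#' @export
write_class_table <- function(class_table, path) {
  utils::write.csv(class_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a paired-lifetime CSV for quencher ranking
#'
#' Columns `construct`, `condition` (control/dpa), `tau_mean_ns`, optionally
#' `cell_id`.
#' @param path File path.
#' @export
read_paired_lifetimes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("construct", "condition", "tau_mean_ns"), path)
  df
}

#' Write one fit result row per ROI
#'
#' Flat CSV with columns `roi_id, F0, P1, tau1_ns, tau2_ns, tauG_ns, t0_ns,
#' tau_a_ns, tau_mean_ns, photons, redchi`.
#'
#' @param fits Named list of `biexp_fit` objects (names = ROI ids).
#' @param tau_means Optional named numeric vector of center-of-mass lifetimes.
#' @param path Output CSV path.
#' @export
write_fit_results_csv <- function(fits, path, tau_means = NULL) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(roi_id = id, F0 = f$params$F0, P1 = f$params$P1,
               tau1_ns = f$params$tau1, tau2_ns = f$params$tau2,
               tauG_ns = f$params$tauG, t0_ns = f$params$t0,
               tau_a_ns = f$tau_a,
               tau_mean_ns = if (!is.null(tau_means)) tau_means[[id]] else NA_real_,
               photons = f$photons, redchi = f$diagnostics$redchi)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "fretclem-run",
    n_cells = 6L,
    n_per_class = 4L,
    image_shape = c(48L, 48L),
    pixel_size_nm = 80,
    em_pixel_size_nm = 8,
    donor_only_tau_a = 2.6,
    tauG = 0.15,
    t0 = 2,
    window = 12.5,
    n_bins = 256L,
    background_rate = 0.5,
    psf_sigma_px = 1.3,
    n_frames = 150L,
    acceptor_bleach_per_frame = 0,
    photons_per_structure = 10000,
    efficiency_flat = 0.30,
    efficiency_domed = 0.25,
    efficiency_sphere = 0.20,
    R0 = 60,
    lifetime_threshold_ns = 2.1,
    acceptor_mode = TRUE,
    roi_margin_px = 2L,
    min_photons_fit = 10000,
    fit_decays = FALSE,
    scan_spacing_A = 0.6,
    axial_offset_A = 25
  )
}

#' Run configuration with documented defaults
#'
#' Builds the pipeline configuration, starting from the package defaults and
#' overriding with the supplied values. Unknown keys are rejected. Defaults:
#' FLIM 80 nm/px, EM 8 nm/px (desk-scale EM raster), donor-only lifetime
#' 2.6 ns, IRF 0.15 ns, window 12.5 ns / 256 bins, 150 frames, 10000 photons
#' per structure, acceptor-mode lifetime threshold 2.1 ns, Förster radius
#' 60 Å, scan spacing 0.6 Å, axial offset 25 Å, ROI margin 2 px, minimum
#' 10000 photons for bi-exponential fits.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_invalid(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML config file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
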