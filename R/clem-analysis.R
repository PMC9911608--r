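#' Photon-weighted mean lifetime within a rectangular ROI
#'
#' Pools all photons of the ROI: mean lifetime = (sum of arrival-time sums) /
#' (sum of photon counts) minus the reference time. Equivalent to computing
#' the center-of-mass lifetime of the pooled ROI histogram.
#'
#' @param img A [flim_image()].
#' @param roi Length-4 vector `c(xmin, xmax, ymin, ymax)`, inclusive 0-based
#'   pixel coordinates.
#' @param t_reference Reference time (ns) subtracted from the first moment.
#' @return List with `mean_lifetime` (ns) and `photons`.
#' @export
roi_mean_lifetime <- function(img, roi, t_reference = 0) {
  if (!inherits(img, "flim_image")) stop_invalid("img must be a flim_image")
  roi <- as.numeric(roi)
  if (length(roi) != 4) stop_invalid("roi must be c(xmin, xmax, ymin, ymax)")
  if (roi[1] > roi[2] || roi[3] > roi[4] ||
      roi[1] < 0 || roi[3] < 0 ||
      roi[2] > ncol(img$photon_counts) - 1 ||
      roi[4] > nrow(img$photon_counts) - 1) {
    stop_invalid("roi must lie within image bounds")
  }
  rows <- (roi[3]:roi[4]) + 1L
  cols <- (roi[1]:roi[2]) + 1L
  photons <- sum(img$photon_counts[rows, cols])
  if (photons <= 0) stop_insufficient_photons("ROI contains no photons")
  list(mean_lifetime = sum(img$lifetime_sum[rows, cols]) / photons - t_reference,
       photons = photons)
}

#' Extract per-structure records from a registered FLIM image and EM mask
#'
#' For every labelled structure in the EM segmentation mask, measures the
#' projected area and centroid from the mask, builds a square ROI around the
#' structure's bounding box (plus a margin) in the registered FLIM image, and
#' records the photon-weighted mean lifetime and photon count of the ROI.
#'
#' @param flim_em A [flim_image()] already resampled into the EM frame (see
#'   [transform_image_nn()]); its geometry must match `mask`.
#' @param mask Integer matrix: 0 = background, `k` = structure label `k`.
#' @param class_table `data.frame` with columns `label`, `class`; every label
#'   present in the mask must appear.
#' @param pixel_size_nm EM pixel size (nm).
#' @param cell_id Cell identifier copied into the records.
#' @param margin_px ROI margin beyond the structure bounding box (EM pixels,
#'   default 2).
#' @param t_reference Reference time (ns) for the mean lifetime.
#' @return `data.frame` of structure records: `structure_id`, `cell_id`,
#'   `curvature_class`, `area_nm2`, `centroid_x_px`, `centroid_y_px`,
#'   `mean_lifetime_ns`, `photons`.
#' @export
extract_ccs_records <- function(flim_em, mask, class_table, pixel_size_nm,
                                cell_id = NA_character_, margin_px = 2,
                                t_reference = 0) {
  labels <- sort(unique(mask[mask > 0]))
  class_of <- stats::setNames(as.character(class_table$class),
                              as.character(class_table$label))
  out <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    cls <- class_of[as.character(lab)]
    if (is.na(cls)) {
      stop_data(sprintf("label %d missing from the class table", lab))
    }
    idx <- which(mask == lab, arr.ind = TRUE)
    x <- idx[, 2] - 1L # 0-based
    y <- idx[, 1] - 1L
    roi <- c(max(min(x) - margin_px, 0),
             min(max(x) + margin_px, ncol(mask) - 1),
             max(min(y) - margin_px, 0),
             min(max(y) + margin_px, nrow(mask) - 1))
    ml <- roi_mean_lifetime(flim_em, roi, t_reference = t_reference)
    out[[k]] <- data.frame(
      structure_id = lab, cell_id = cell_id, curvature_class = cls,
      area_nm2 = nrow(idx) * pixel_size_nm^2,
      centroid_x_px = mean(x), centroid_y_px = mean(y),
      mean_lifetime_ns = ml$mean_lifetime, photons = ml$photons)
  }
  do.call(rbind, out)
}

#' Per-cell curvature-class lifetime summary
#'
#' Groups one cell's structure records by curvature class and compares each
#' class mean lifetime to the mean of the flat class of the same cell:
#' \eqn{\Delta(\mathrm{class}) = \bar\tau(\mathrm{class}) -
#' \bar\tau(\mathrm{flat})} in ns, so \eqn{\Delta(\mathrm{flat}) = 0} by
#' construction. Within-cell differences remove the cell-to-cell variation in
#' expression levels that shifts absolute lifetimes. Classes absent from the
#' cell yield `NA`, not 0.
#'
#' @param records Structure records of one cell (see [extract_ccs_records()]).
#' @return One-row `data.frame`: `cell_id`, `n_flat`, `n_domed`, `n_sphere`,
#'   `mean_flat_ns`, `mean_domed_ns`, `mean_sphere_ns`, `delta_flat_ns`,
#'   `delta_domed_ns`, `delta_sphere_ns`, `cellular_average_lifetime_ns`
#'   (photon-weighted over all structures).
#' @export
summarize_cell <- function(records) {
  if (nrow(records) == 0) stop_data("no structure records")
  if (length(unique(records$cell_id)) > 1) {
    stop_invalid("summarize_cell expects records from a single cell")
  }
  classes <- c("flat", "domed", "sphere")
  if (!any(records$curvature_class == "flat")) {
    stop_fretclem(sprintf("cell %s has no flat structures; no reference for normalisation",
                          records$cell_id[1]),
                  c("fretclem_no_reference", "fretclem_data_error"))
  }
  m <- vapply(classes, function(cl) {
    v <- records$mean_lifetime_ns[records$curvature_class == cl]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n <- vapply(classes, function(cl) sum(records$curvature_class == cl),
              numeric(1))
  cav <- sum(records$mean_lifetime_ns * records$photons) / sum(records$photons)
  data.frame(cell_id = records$cell_id[1],
             n_flat = unname(n[1]), n_domed = unname(n[2]),
             n_sphere = unname(n[3]),
             mean_flat_ns = unname(m[1]), mean_domed_ns = unname(m[2]),
             mean_sphere_ns = unname(m[3]),
             delta_flat_ns = 0,
             delta_domed_ns = unname(m[2] - m[1]),
             delta_sphere_ns = unname(m[3] - m[1]),
             cellular_average_lifetime_ns = cav,
             row.names = NULL)
}

#' Keep cells whose average lifetime confirms acceptor expression
#'
#' In donor + acceptor experiments the acceptor (ShadowY) is dark, so its
#' expression is confirmed indirectly: only cells whose cellular average
#' lifetime is strictly below the threshold (default 2.1 ns) are analysed.
#'
#' @param summaries `data.frame` of cell summaries (see [summarize_cell()]).
#' @param threshold_ns Threshold (ns), strict `<`; default 2.1.
#' @return The kept rows of `summaries`.
#' @export
filter_cells_by_lifetime <- function(summaries, threshold_ns = 2.1) {
  summaries[summaries$cellular_average_lifetime_ns < threshold_ns, ,
            drop = FALSE]
}

#' EM morphometrics of classified clathrin lattices
#'
#' Per curvature class: mean projected area (pixel count times squared pixel
#' size), structure density per µm² of measured membrane, and percentage of
#' occupied membrane area (summed class area / membrane area x 100).
#'
#' @param mask Labelled integer matrix (0 = background).
#' @param class_table `data.frame` with columns `label`, `class`.
#' @param membrane_area_nm2 Total measured membrane area (nm²); must be at
#'   least the total structure area.
#' @param pixel_size_nm EM pixel size (nm).
#' @return `data.frame` with one row per class (always including flat, domed,
#'   sphere): `class`, `n`, `mean_area_nm2`, `density_per_um2`,
#'   `occupied_pct`.
#' @export
morphometrics <- function(mask, class_table, membrane_area_nm2,
                          pixel_size_nm) {
  if (pixel_size_nm <= 0) stop_invalid("pixel_size_nm must be > 0")
  labels <- sort(unique(mask[mask > 0]))
  class_of <- stats::setNames(as.character(class_table$class),
                              as.character(class_table$label))
  areas <- numeric(length(labels))
  cls <- character(length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    cl <- class_of[as.character(lab)]
    if (is.na(cl)) stop_data(sprintf("label %d missing from the class table", lab))
    areas[k] <- sum(mask == lab) * pixel_size_nm^2
    cls[k] <- cl
  }
  if (membrane_area_nm2 < sum(areas)) {
    stop_invalid("membrane_area_nm2 must be at least the total structure area")
  }
  all_classes <- union(c("flat", "domed", "sphere"),
                       unique(as.character(class_table$class)))
  out <- lapply(all_classes, function(cl) {
    sel <- cls == cl
    data.frame(class = cl,
               n = sum(sel),
               mean_area_nm2 = if (any(sel)) mean(areas[sel]) else 0,
               density_per_um2 = sum(sel) / (membrane_area_nm2 / 1e6),
               occupied_pct = sum(areas[sel]) / membrane_area_nm2 * 100)
  })
  do.call(rbind, out)
}

#' One-way ANOVA and pairwise comparisons of per-cell lifetime shifts
#'
#' Thin reporting wrapper over `stats::aov` + `stats::TukeyHSD` applied to
#' the per-cell class-vs-flat lifetime differences, the statistical treatment
#' used for curvature-class comparisons. Not part of the bespoke core.
#'
#' @param summaries Cell summaries (see [summarize_cell()]).
#' @return List with the `aov` fit and the Tukey HSD table for classes
#'   domed and sphere (flat is the zero reference and is excluded).
#' @export
compare_classes <- function(summaries) {
  long <- rbind(
    data.frame(cell_id = summaries$cell_id, class = "domed",
               delta = summaries$delta_domed_ns),
    data.frame(cell_id = summaries$cell_id, class = "sphere",
               delta = summaries$delta_sphere_ns))
  long <- long[!is.na(long$delta), ]
  long$class <- factor(long$class)
  fit <- stats::aov(delta ~ class, data = long)
  list(anova = fit, tukey = stats::TukeyHSD(fit))
}
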