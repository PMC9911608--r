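#' 2-D affine transform
#'
#' Maps FLIM pixel coordinates to EM pixel coordinates as
#' `em = A %*% flim + b`. Coordinates are 0-based pixel centers,
#' `x` = column, `y` = row.
#'
#' @param A 2x2 linear part, non-singular (`|det| > 1e-12`).
#' @param b Length-2 translation.
#' @return An object of class `affine_transform_2d`.
#' @export
affine_transform <- function(A, b) {
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  if (length(b) != 2 || any(!is.finite(A)) || any(!is.finite(b))) {
    stop_invalid("A must be a finite 2x2 matrix and b a finite length-2 vector")
  }
  if (abs(det(A)) <= 1e-12) stop_invalid("linear part is singular")
  structure(list(A = A, b = b), class = "affine_transform_2d")
}

#' @export
print.affine_transform_2d <- function(x, ...) {
  cat("<affine_transform_2d>\n  A =", sprintf("[%.6g %.6g; %.6g %.6g]",
      x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]),
      " b =", sprintf("(%.6g, %.6g)", x$b[1], x$b[2]),
      sprintf(" scale = %.6g\n", sqrt(abs(det(x$A)))))
  invisible(x)
}

#' Apply / invert an affine transform
#'
#' @param transform An [affine_transform()].
#' @param xy `n x 2` matrix (or length-2 vector) of coordinates.
#' @return Transformed `n x 2` matrix.
#' @export
apply_affine <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  xy %*% t(transform$A) + matrix(transform$b, nrow(xy), 2, byrow = TRUE)
}

#' @rdname apply_affine
#' @export
invert_affine <- function(transform) {
  Ai <- solve(transform$A)
  affine_transform(Ai, -as.vector(Ai %*% transform$b))
}

#' Least-squares affine registration from fiducial pairs
#'
#' Fits the 6-parameter affine transform minimising
#' \eqn{\sum_i \| A f_i + b - e_i \|^2} over fiducial pairs
#' \eqn{(f_i, e_i)}. Flat and domed lattices serve as fiducials in practice
#' (sphere lattices can shift during critical point drying and are excluded
#' from fiducial candidates). The fit is exact (zero residual) when the pairs
#' are affine-consistent.
#'
#' @param pairs `data.frame` with columns `flim_x`, `flim_y`, `em_x`, `em_y`
#'   (pixel coordinates); at least 3 non-collinear pairs.
#' @return List with `transform` ([affine_transform()]) and `rms_residual`
#'   (EM pixels).
#' @export
fit_affine <- function(pairs) {
  req <- c("flim_x", "flim_y", "em_x", "em_y")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) {
    stop_parse(paste0("fiducial table is missing column(s): ",
                      paste(miss, collapse = ", ")))
  }
  n <- nrow(pairs)
  if (n < 3) {
    stop_fretclem("at least 3 fiducial pairs are required",
                  c("fretclem_degenerate_fiducials", "fretclem_data_error"))
  }
  X <- cbind(pairs$flim_x, pairs$flim_y, 1)
  if (qr(X)$rank < 3) {
    stop_fretclem("fiducials are collinear; affine fit is degenerate",
                  c("fretclem_degenerate_fiducials", "fretclem_data_error"))
  }
  Y <- cbind(pairs$em_x, pairs$em_y)
  beta <- qr.solve(X, Y) # 3 x 2
  A <- t(beta[1:2, ])
  b <- beta[3, ]
  resid <- X %*% beta - Y
  list(transform = affine_transform(A, b),
       rms_residual = sqrt(mean(rowSums(resid^2))))
}

#' Resample a FLIM image into the EM frame by nearest neighbour
#'
#' Inverse mapping: every output (EM-frame) pixel takes the value of the
#' nearest input (FLIM) pixel under the inverse transform. Nearest-neighbour
#' interpolation keeps photon counts integer; pixels mapping outside the
#' input are 0. The output pixel size is the input pixel size divided by the
#' isotropic scale of the transform.
#'
#' @param img A [flim_image()].
#' @param transform FLIM-to-EM [affine_transform()].
#' @param out_shape `c(rows, cols)` of the output raster.
#' @return A [flim_image()] in the EM frame.
#' @export
transform_image_nn <- function(img, transform, out_shape) {
  if (!inherits(img, "flim_image")) stop_invalid("img must be a flim_image")
  inv <- invert_affine(transform)
  nr <- out_shape[1]; nc <- out_shape[2]
  ox <- rep(0:(nc - 1), each = nr)
  oy <- rep(0:(nr - 1), times = nc)
  src <- apply_affine(inv, cbind(ox, oy))
  sx <- round(src[, 1]); sy <- round(src[, 2])
  ok <- sx >= 0 & sx <= ncol(img$photon_counts) - 1 &
        sy >= 0 & sy <= nrow(img$photon_counts) - 1
  counts <- matrix(0, nr, nc)
  lsum <- matrix(0, nr, nc)
  src_idx <- sy[ok] + 1L + sx[ok] * nrow(img$photon_counts)
  out_idx <- oy[ok] + 1L + ox[ok] * nr
  counts[out_idx] <- img$photon_counts[src_idx]
  lsum[out_idx] <- img$lifetime_sum[src_idx]
  flim_image(counts, lsum,
             pixel_size_nm = img$pixel_size_nm / sqrt(abs(det(transform$A))),
             cell_id = img$cell_id)
}
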