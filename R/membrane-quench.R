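#' Membrane quenching plane
#'
#' Geometry of a fluorophore above a plane of membrane-embedded dark
#' acceptors (dipicrylamine, DPA). DPA quenches the fluorophore by FRET with
#' an efficiency that falls steeply with axial distance, which is what makes
#' it a reporter of height above the plasma membrane.
#'
#' @param sigma Acceptor surface density (acceptors per Å^2), `>= 0`;
#'   proportional to the DPA concentration via a calibration constant that is
#'   supplied by the user, not fitted.
#' @param R0_dpa Förster radius of the fluorophore-DPA pair (Å), `> 0`.
#' @param z Axial distance of the fluorophore above the acceptor plane (Å),
#'   `> 0`; may be a vector.
#' @return An object of class `quench_plane`.
#' @export
quench_plane <- function(sigma, R0_dpa, z) {
  if (any(sigma < 0)) stop_invalid("sigma must be >= 0")
  if (R0_dpa <= 0) stop_invalid("R0_dpa must be > 0")
  if (any(z <= 0)) stop_invalid("z must be > 0")
  structure(list(sigma = sigma, R0_dpa = R0_dpa, z = z),
            class = "quench_plane")
}

#' FRET efficiency of a fluorophore above an acceptor plane
#'
#' Integrating the point-to-point transfer rate \eqn{(R_0/r)^6} over an
#' infinite plane of acceptors at surface density \eqn{\sigma} gives the
#' summed rate \eqn{S = \pi \sigma R_0^6 / (2 z^4)}, hence
#' \eqn{E = S / (1 + S)}: strictly decreasing in the axial distance `z` and
#' strictly increasing in `sigma`. Only relative comparisons (orderings of
#' constructs) are drawn from this model.
#'
#' @param plane A [quench_plane()].
#' @return Efficiency (vectorised over `plane$z`).
#' @export
plane_quench_efficiency <- function(plane) {
  if (!inherits(plane, "quench_plane")) stop_invalid("plane must be a quench_plane")
  S <- pi * plane$sigma * plane$R0_dpa^6 / (2 * plane$z^4)
  S / (1 + S)
}

#' Acceptor density giving 50% quenching at a target height
#'
#' Closed form from \eqn{S(z) = 1}: \eqn{\sigma = 2 z^4 / (\pi R_0^6)}.
#' Useful for choosing simulated DPA densities, mirroring the experimental
#' titration of DPA concentration to ~50% efficiency.
#'
#' @param z Axial distance (Å).
#' @param R0_dpa Förster radius (Å).
#' @return Surface density (acceptors per Å^2).
#' @export
sigma_for_half_quench <- function(z, R0_dpa) {
  if (any(z <= 0) || R0_dpa <= 0) stop_invalid("z and R0_dpa must be > 0")
  2 * z^4 / (pi * R0_dpa^6)
}

#' Rank constructs by lifetime drop under membrane quenching
#'
#' For each construct with paired lifetimes measured without and with the
#' membrane quencher, computes \eqn{\Delta\tau = \tau(\mathrm{no\,DPA}) -
#' \tau(\mathrm{DPA})} and ranks constructs by \eqn{\Delta\tau} descending:
#' a larger drop means the fluorophore sits closer to the membrane. Only the
#' ordering is contractual; no absolute height is reported.
#'
#' @param records `data.frame` with columns `construct`, `condition` (one of
#'   `"control"`, `"dpa"`), and `tau_mean_ns`; repeated measurements (e.g.
#'   cells) are averaged per construct and condition. An optional `cell_id`
#'   column is ignored by the computation.
#' @return `data.frame` with one row per construct: `construct`,
#'   `tau_control_ns`, `tau_dpa_ns`, `delta_tau_ns`, `rank` (1 = largest
#'   drop = closest to the membrane). Ties keep first-appearance order.
#' @export
delta_lifetime_axial_rank <- function(records) {
  req <- c("construct", "condition", "tau_mean_ns")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop_parse(paste0("records is missing column(s): ",
                      paste(miss, collapse = ", ")))
  }
  if (!all(records$condition %in% c("control", "dpa"))) {
    stop_invalid("condition must be 'control' or 'dpa'")
  }
  constructs <- unique(records$construct)
  ctrl <- dpa <- rep(NA_real_, length(constructs))
  for (i in seq_along(constructs)) {
    rc <- records[records$construct == constructs[i], ]
    tc <- rc$tau_mean_ns[rc$condition == "control"]
    td <- rc$tau_mean_ns[rc$condition == "dpa"]
    if (length(tc) == 0 || length(td) == 0) {
      stop_fretclem(sprintf("construct '%s' lacks a paired measurement",
                            constructs[i]),
                    c("fretclem_missing_pair", "fretclem_data_error"))
    }
    ctrl[i] <- mean(tc)
    dpa[i] <- mean(td)
  }
  delta <- ctrl - dpa
  ord <- order(-delta) # stable: ties keep input order
  out <- data.frame(construct = constructs[ord],
                    tau_control_ns = ctrl[ord],
                    tau_dpa_ns = dpa[ord],
                    delta_tau_ns = delta[ord])
  out$rank <- seq_len(nrow(out))
  out
}
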