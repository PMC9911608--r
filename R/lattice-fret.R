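#' Donor/acceptor geometry of a clathrin lattice FRET scene
#'
#' One donor fluorophore (the EGFP on a light-chain terminus) surrounded by
#' candidate acceptor sites: the light-chain binding sites of the neighbouring
#' clathrin heavy chains (five in the canonical lattice geometry), each of
#' which may or may not carry an acceptor-labelled light chain.
#'
#' @param donor_position Numeric length-3 donor coordinate (Å).
#' @param acceptor_sites Numeric matrix, one row per candidate acceptor site,
#'   columns x/y/z (Å).
#' @param R0 Förster radius (Å), default 60 (EGFP-ShadowY).
#' @param donor_tau Unquenched donor lifetime (ns), default 2.6.
#' @return An object of class `lattice_scene`.
#' @export
lattice_scene <- function(donor_position, acceptor_sites, R0 = 60,
                          donor_tau = 2.6) {
  donor_position <- as.numeric(donor_position)
  if (length(donor_position) != 3 || any(!is.finite(donor_position))) {
    stop_invalid("donor_position must be a finite length-3 coordinate")
  }
  acceptor_sites <- as.matrix(acceptor_sites)
  if (ncol(acceptor_sites) != 3 || nrow(acceptor_sites) < 1 ||
      any(!is.finite(acceptor_sites))) {
    stop_invalid("acceptor_sites must be a finite n x 3 matrix with n >= 1")
  }
  if (R0 <= 0) stop_invalid("R0 must be > 0")
  structure(list(donor_position = donor_position,
                 acceptor_sites = acceptor_sites,
                 R0 = R0, donor_tau = donor_tau),
            class = "lattice_scene")
}

#' Four-state heavy-chain occupancy model
#'
#' Each clathrin heavy chain is in one of four states: no light chain bound,
#' endogenous light chain, EGFP-labelled light chain, or acceptor
#' (ShadowY)-labelled light chain. Only the last state contributes an
#' acceptor.
#'
#' @param p_none,p_endogenous,p_egfp,p_shadowy State probabilities, `>= 0`,
#'   summing to 1 within `1e-9`.
#' @return An object of class `occupancy_model`.
#' @export
occupancy_model <- function(p_none, p_endogenous, p_egfp, p_shadowy) {
  p <- c(p_none, p_endogenous, p_egfp, p_shadowy)
  if (any(p < 0)) stop_invalid("state probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop_invalid("state probabilities must sum to 1")
  structure(list(p_none = p_none, p_endogenous = p_endogenous,
                 p_egfp = p_egfp, p_shadowy = p_shadowy),
            class = "occupancy_model")
}

#' Acceptor occupancy fraction of the four heavy-chain states
#'
#' Fraction of heavy chains carrying an acceptor-labelled light chain:
#' `shadowy / (none + endogenous + egfp + shadowy)`. Accepts unnormalised
#' weights (e.g. molecule counts) or an [occupancy_model()].
#'
#' @param weights Length-4 non-negative weights in the order (none,
#'   endogenous, egfp, shadowy), or an [occupancy_model()].
#' @return Occupancy fraction in `[0, 1]`.
#' @examples
#' occupancy_fraction(c(1, 1, 1, 1)) # 0.25
#' @export
occupancy_fraction <- function(weights) {
  if (inherits(weights, "occupancy_model")) {
    weights <- c(weights$p_none, weights$p_endogenous,
                 weights$p_egfp, weights$p_shadowy)
  }
  if (length(weights) != 4 || any(weights < 0)) {
    stop_invalid("weights must be 4 non-negative values (none, endogenous, egfp, shadowy)")
  }
  s <- sum(weights)
  if (s == 0) stop_invalid("weights must not all be zero")
  weights[4] / s
}

#' FRET efficiency of a donor facing several occupied acceptor sites
#'
#' Independent acceptors quench the donor additively in rate: with
#' \eqn{S = \sum_i (R_0 / r_i)^6} over occupied sites at distances
#' \eqn{r_i}, the transfer efficiency is \eqn{E = S / (1 + S)}.
#'
#' @param scene A [lattice_scene()].
#' @param occupied_site_mask Logical vector, one entry per acceptor site.
#' @return Efficiency in `[0, 1)`; returns 1 with a warning if the donor
#'   coincides with an occupied site (degenerate geometry).
#' @export
multi_acceptor_efficiency <- function(scene, occupied_site_mask) {
  if (!inherits(scene, "lattice_scene")) {
    stop_invalid("scene must be a lattice_scene")
  }
  if (length(occupied_site_mask) != nrow(scene$acceptor_sites)) {
    stop_invalid("mask length must equal the number of acceptor sites")
  }
  occ <- which(as.logical(occupied_site_mask))
  if (length(occ) == 0) return(0)
  d <- scene$acceptor_sites[occ, , drop = FALSE] -
    matrix(scene$donor_position, length(occ), 3, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) {
    warning("donor coincides with an occupied acceptor site; efficiency is 1")
    return(1)
  }
  S <- sum((scene$R0 / r)^6)
  S / (1 + S)
}

# per-site rate terms (R0 / r_i)^6 for a donor at `pos`
site_rate_terms <- function(pos, sites, R0) {
  d <- sites - matrix(pos, nrow(sites), 3, byrow = TRUE)
  r2 <- rowSums(d^2)
  (R0^2 / r2)^3
}

#' Expected lattice FRET efficiency under an occupancy model
#'
#' Site occupancies are independent Bernoulli draws with probability equal to
#' the acceptor occupancy fraction (the four-state model collapses to
#' acceptor present/absent per site, since only acceptor-labelled light
#' chains transfer). The expectation is taken by exact enumeration of all
#' `2^n` occupied-site configurations, weighting each configuration's
#' [multi_acceptor_efficiency()] by its Bernoulli probability; for `n > 20`
#' sites exact enumeration is refused and `monte_carlo = TRUE` must be used.
#'
#' @param scene A [lattice_scene()].
#' @param occupancy An [occupancy_model()], length-4 weight vector, or a bare
#'   occupancy fraction in `[0, 1]`.
#' @param monte_carlo Use Monte-Carlo averaging instead of enumeration.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Optional seed for Monte-Carlo.
#' @return Expected efficiency in `[0, 1)`; monotone non-decreasing in the
#'   occupancy fraction.
#' @export
expected_lattice_efficiency <- function(scene, occupancy,
                                        monte_carlo = FALSE,
                                        n_draws = 1e5, seed = NULL) {
  if (!inherits(scene, "lattice_scene")) {
    stop_invalid("scene must be a lattice_scene")
  }
  p <- occupancy_as_fraction(occupancy)
  n <- nrow(scene$acceptor_sites)
  s <- site_rate_terms(scene$donor_position, scene$acceptor_sites, scene$R0)
  if (monte_carlo) {
    if (!is.null(seed)) set.seed(seed)
    M <- matrix(stats::runif(n_draws * n) < p, n_draws, n)
    S <- as.vector(M %*% s)
    return(mean(S / (1 + S)))
  }
  if (n > 20) {
    stop_invalid("exact enumeration refused for > 20 sites; set monte_carlo = TRUE")
  }
  masks <- config_masks(n)
  S <- as.vector(masks %*% s)
  k <- rowSums(masks)
  w <- p^k * (1 - p)^(n - k)
  sum(w * S / (1 + S))
}

occupancy_as_fraction <- function(occupancy) {
  if (inherits(occupancy, "occupancy_model") || length(occupancy) == 4) {
    occupancy_fraction(occupancy)
  } else if (is.numeric(occupancy) && length(occupancy) == 1 &&
             occupancy >= 0 && occupancy <= 1) {
    occupancy
  } else {
    stop_invalid("occupancy must be a fraction, 4 weights, or an occupancy_model")
  }
}

# all 2^n binary masks as an (2^n x n) 0/1 matrix
config_masks <- function(n) {
  m <- 2L^n
  masks <- matrix(0L, m, n)
  for (j in seq_len(n)) {
    masks[, j] <- bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  }
  masks
}

#' Lateral scan grid for the donor position
#'
#' @param lateral_spacing Grid spacing (Å), default 0.6.
#' @param axial_offset Donor height above the acceptor-site plane (Å),
#'   default 25 (N-terminus assumed 25 Å above the C-terminus plane).
#' @param lateral_bounds Length-2 extent of the scan box (Å) in x and y,
#'   centered on the origin.
#' @return An object of class `position_scan`.
#' @export
position_scan <- function(lateral_spacing = 0.6, axial_offset = 25,
                          lateral_bounds = c(120, 120)) {
  if (lateral_spacing <= 0) stop_invalid("lateral_spacing must be > 0")
  if (length(lateral_bounds) != 2 || any(lateral_bounds < 0)) {
    stop_invalid("lateral_bounds must be two non-negative extents")
  }
  structure(list(lateral_spacing = lateral_spacing,
                 axial_offset = axial_offset,
                 lateral_bounds = lateral_bounds),
            class = "position_scan")
}

#' Map expected FRET efficiency over lateral donor positions
#'
#' Places the donor at every point of a lateral grid, at `axial_offset` above
#' the acceptor-site plane (the mean z of the sites), and evaluates
#' [expected_lattice_efficiency()] at each point. This reproduces the
#' position-scan analysis in which the light-chain N-terminus is stepped
#' laterally at 0.6 Å spacing.
#'
#' @param scene_template A [lattice_scene()] providing sites, `R0` and donor
#'   lifetime; its donor position is ignored.
#' @param scan A [position_scan()].
#' @param occupancy Occupancy (see [expected_lattice_efficiency()]).
#' @return A list of class `efficiency_map` with `x`, `y` (grid coordinates,
#'   Å) and `efficiency` (matrix `[i, j]` = value at `y[i]`, `x[j]`).
#' @export
scan_nterm_positions <- function(scene_template, scan, occupancy) {
  if (!inherits(scan, "position_scan")) stop_invalid("scan must be a position_scan")
  if (!inherits(scene_template, "lattice_scene")) {
    stop_invalid("scene_template must be a lattice_scene")
  }
  p <- occupancy_as_fraction(occupancy)
  sites <- scene_template$acceptor_sites
  R0 <- scene_template$R0
  nxy <- floor(scan$lateral_bounds / scan$lateral_spacing) + 1L
  if (any(nxy < 1)) stop_invalid("empty scan bounds")
  xs <- (seq_len(nxy[1]) - 1) * scan$lateral_spacing - scan$lateral_bounds[1] / 2
  ys <- (seq_len(nxy[2]) - 1) * scan$lateral_spacing - scan$lateral_bounds[2] / 2
  z <- mean(sites[, 3]) + scan$axial_offset

  n <- nrow(sites)
  masks <- config_masks(n)
  k <- rowSums(masks)
  w <- p^k * (1 - p)^(n - k)

  pts_x <- rep(xs, times = length(ys))
  pts_y <- rep(ys, each = length(xs))
  # rate terms for all grid points x all sites
  S_terms <- matrix(0, length(pts_x), n)
  for (i in seq_len(n)) {
    r2 <- (pts_x - sites[i, 1])^2 + (pts_y - sites[i, 2])^2 + (z - sites[i, 3])^2
    S_terms[, i] <- (R0^2 / r2)^3
  }
  S <- S_terms %*% t(masks)            # npts x 2^n
  E <- (S / (1 + S)) %*% w             # npts x 1
  eff <- matrix(E, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  structure(list(x = xs, y = ys, efficiency = eff), class = "efficiency_map")
}

#' Canonical five-site ring geometry
#'
#' A documented fixture geometry: `n` acceptor sites evenly spaced on a ring
#' in the z = 0 plane, standing in for the light-chain binding sites of the
#' five heavy chains surrounding a donor. Users with structural coordinates
#' can supply their own site table instead.
#'
#' @param n Number of sites (default 5).
#' @param radius Ring radius (Å), default 70.
#' @param phase Angular offset (radians).
#' @return An `n x 3` coordinate matrix (Å).
#' @export
ring_sites <- function(n = 5, radius = 70, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = 0)
}
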