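#' Parameters of an IRF-convolved bi-exponential fluorescence decay
#'
#' Container for the six parameters of the TCSPC decay model
#' \deqn{F(t) = F_0 [P_1 H(t, t_0, \tau_1, \tau_G) + (1 - P_1) H(t, t_0, \tau_2, \tau_G)]}
#' where \eqn{H} is a one-sided exponential convolved with a Gaussian
#' instrument response function (IRF) of width \eqn{\tau_G}
#' (see [convolved_exponential()]).
#'
#' Components are stored in canonical order \eqn{\tau_1 \le \tau_2}; if the
#' arguments violate this the components are swapped and `P1` is replaced by
#' `1 - P1`, which leaves the model unchanged (label switching).
#'
#' @param F0 Peak amplitude before convolution (photons per bin), `>= 0`.
#' @param P1 Fraction of the first decay component, in `[0, 1]`.
#' @param tau1,tau2 Component lifetimes (ns), `> 0`.
#' @param tauG Gaussian IRF width (ns), `> 0`.
#' @param t0 Time offset of the excitation pulse (ns).
#' @return An object of class `decay_params` (a named list).
#' @examples
#' p <- decay_params(F0 = 1000, P1 = 0.4, tau1 = 2.6, tau2 = 0.8,
#'                   tauG = 0.15, t0 = 2)
#' p$tau1 # 0.8: components re-ordered, P1 swapped to 0.6
#' @export
decay_params <- function(F0, P1, tau1, tau2, tauG, t0) {
  for (v in list(F0, P1, tau1, tau2, tauG, t0)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_invalid("all decay parameters must be finite numeric scalars")
    }
  }
  if (F0 < 0) stop_invalid("F0 must be >= 0")
  if (P1 < 0 || P1 > 1) stop_invalid("P1 must be in [0, 1]")
  if (tau1 <= 0 || tau2 <= 0) stop_invalid("component lifetimes must be > 0")
  if (tauG <= 0) stop_invalid("tauG must be > 0")
  if (tau1 > tau2) {
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    P1 <- 1 - P1
  }
  structure(list(F0 = F0, P1 = P1, tau1 = tau1, tau2 = tau2,
                 tauG = tauG, t0 = t0),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf(
    "<decay_params> F0=%.4g  P1=%.3f  tau1=%.4g ns  tau2=%.4g ns  tauG=%.4g ns  t0=%.4g ns\n",
    x$F0, x$P1, x$tau1, x$tau2, x$tauG, x$t0))
  invisible(x)
}

#' Binned photon-arrival histogram
#'
#' A TCSPC histogram: photon counts over a uniform time grid covering one
#' excitation period. `background_per_bin` carries the expected (not observed)
#' uniform background count per bin, used by the Poisson fit model; it is not
#' subtracted from the data anywhere.
#'
#' @param bin_edges Strictly increasing uniform grid of bin edges (ns),
#'   length `length(counts) + 1`.
#' @param counts Non-negative photon counts per bin. Measured data are
#'   integers; non-integer values are accepted so that noise-free expected
#'   counts can be analysed with the same machinery.
#' @param background_per_bin Expected background counts per bin (default 0).
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(bin_edges, counts, background_per_bin = 0) {
  if (length(bin_edges) != length(counts) + 1L) {
    stop_invalid("length(counts) must equal length(bin_edges) - 1")
  }
  w <- diff(bin_edges)
  if (any(w <= 0)) stop_invalid("bin_edges must be strictly increasing")
  if (max(w) - min(w) > 1e-9 * max(w)) {
    stop_invalid("bin widths must be uniform (within 1e-9 relative tolerance)")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("counts must be finite and non-negative")
  }
  if (background_per_bin < 0) stop_invalid("background_per_bin must be >= 0")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts),
                 background_per_bin = background_per_bin),
            class = "decay_histogram")
}

bin_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

bin_width <- function(hist) {
  e <- hist$bin_edges
  (e[length(e)] - e[1]) / (length(e) - 1L)
}

# complementary error function via the normal CDF (exact relation)
erfc_ <- function(x) 2 * stats::pnorm(-x * sqrt(2))

# scaled complementary error function exp(x^2) erfc(x), stable for large x.
# Moderate x: evaluate in log space through pnorm's log tail. Large x: the
# standard asymptotic series 1/(x sqrt(pi)) * sum_k (-1)^k (2k-1)!!/(2x^2)^k,
# whose truncation error at x >= 20 is far below double precision.
erfcx_ <- function(x) {
  out <- numeric(length(x))
  lo <- x < 20
  if (any(lo)) {
    out[lo] <- exp(x[lo]^2 + log(2) +
                     stats::pnorm(-x[lo] * sqrt(2), log.p = TRUE))
  }
  if (any(!lo)) {
    xi2 <- 1 / (2 * x[!lo]^2)
    s <- 1 - xi2 * (1 - 3 * xi2 * (1 - 5 * xi2 * (1 - 7 * xi2)))
    out[!lo] <- s / (x[!lo] * sqrt(pi))
  }
  out
}

#' Exponential decay convolved with a Gaussian IRF
#'
#' Evaluates the exGaussian kernel
#' \deqn{H(t) = \tfrac12 \exp\!\left(\frac{\tau_G^2}{2\tau^2} -
#'   \frac{t - t_0}{\tau}\right)
#'   \mathrm{erfc}\!\left(\frac{\tau_G^2 - \tau (t - t_0)}{\sqrt{2}\,\tau\,\tau_G}\right)}
#' i.e. the convolution of the one-sided exponential
#' \eqn{e^{-(t - t_0)/\tau}\,\theta(t - t_0)} with a unit-area Gaussian of
#' standard deviation \eqn{\tau_G}. Evaluation is numerically stable for
#' arbitrarily small `tauG` (large exponent arguments) by switching to the
#' scaled complementary error function `erfcx` on the rising edge, where the
#' kernel reduces to \eqn{\tfrac12 e^{-(t-t_0)^2/(2\tau_G^2)}\,
#' \mathrm{erfcx}(b)} with the same argument \eqn{b}.
#'
#' @param t Time(s) at which to evaluate (ns); vectorised.
#' @param t0 Pulse time offset (ns).
#' @param tau Decay lifetime (ns), `> 0`.
#' @param tauG Gaussian IRF width (ns), `> 0`.
#' @return Numeric vector of non-negative intensities (dimensionless; peak of
#'   order 1).
#' @examples
#' convolved_exponential(3, t0 = 2, tau = 2.5, tauG = 0.15)
#' @export
convolved_exponential <- function(t, t0, tau, tauG) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop_invalid("tau must be a positive finite scalar")
  }
  if (!is.numeric(tauG) || length(tauG) != 1L || !is.finite(tauG) || tauG <= 0) {
    stop_invalid("tauG must be a positive finite scalar")
  }
  dt <- t - t0
  b <- tauG / (sqrt(2) * tau) - dt / (sqrt(2) * tauG)
  out <- numeric(length(dt))
  up <- b > 0 # rising edge / early times: erfc(b) may underflow, use erfcx
  if (any(up)) {
    out[up] <- 0.5 * exp(-dt[up]^2 / (2 * tauG^2)) * erfcx_(b[up])
  }
  if (any(!up)) {
    out[!up] <- 0.5 * exp(tauG^2 / (2 * tau^2) - dt[!up] / tau) *
      erfc_(b[!up])
  }
  out
}

#' Bi-exponential decay model
#'
#' The full TCSPC model intensity
#' \eqn{F(t) = F_0 [P_1 H(t; \tau_1) + (1 - P_1) H(t; \tau_2)]} with both
#' components convolved with the same Gaussian IRF.
#'
#' @param times Time grid (ns).
#' @param params A [decay_params()] object.
#' @return Non-negative intensities, same length as `times`.
#' @export
decay_model <- function(times, params) {
  if (!inherits(params, "decay_params")) {
    stop_invalid("params must be a decay_params object")
  }
  params$F0 * (params$P1 *
                 convolved_exponential(times, params$t0, params$tau1, params$tauG) +
               (1 - params$P1) *
                 convolved_exponential(times, params$t0, params$tau2, params$tauG))
}

#' Expected Poisson bin counts under the decay model
#'
#' Expected counts per histogram bin: model intensity at the bin center times
#' the bin width, summed over adjacent excitation periods (periodic
#' excitation wraps late photons back into the acquisition window), plus the
#' expected uniform background.
#'
#' @param params A [decay_params()] object.
#' @param bin_edges Uniform bin edges (ns) spanning one excitation period.
#' @param background_per_bin Expected background counts per bin.
#' @param periods Integer vector of period offsets summed over; the default
#'   `-1:2` covers IRF leakage below 0 and two wrap-arounds of the tail.
#' @return Expected counts per bin.
#' @export
expected_decay_counts <- function(params, bin_edges, background_per_bin = 0,
                                  periods = -1:2) {
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  width <- (bin_edges[length(bin_edges)] - bin_edges[1]) / (length(bin_edges) - 1L)
  window <- bin_edges[length(bin_edges)] - bin_edges[1]
  mu <- rep(background_per_bin, length(centers))
  for (k in periods) {
    mu <- mu + width * decay_model(centers + k * window, params)
  }
  mu
}

#' Amplitude-weighted fluorescence lifetime
#'
#' \eqn{\tau_a = P_1 \tau_1 + (1 - P_1) \tau_2}, the amplitude-fraction
#' weighted mean of the two component lifetimes. This is the donor lifetime
#' summary used for FRET efficiency estimation.
#'
#' @param P1 Fraction of the first component, in `[0, 1]`.
#' @param tau1,tau2 Component lifetimes (ns), `> 0`.
#' @return Lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(P1, tau1, tau2) {
  if (any(P1 < 0) || any(P1 > 1)) stop_invalid("P1 must be in [0, 1]")
  if (any(tau1 <= 0) || any(tau2 <= 0)) stop_invalid("lifetimes must be > 0")
  P1 * tau1 + (1 - P1) * tau2
}

#' FRET efficiency from donor lifetimes
#'
#' \eqn{E = 1 - \tau_{a,DA} / \tau_{a,D}}: fractional shortening of the
#' donor's amplitude-weighted lifetime in the presence of the acceptor.
#' Values are not clamped; noise can produce slightly negative efficiencies.
#'
#' @param tau_a_DA Donor lifetime with acceptor (ns), `> 0`.
#' @param tau_a_D Donor-only reference lifetime (ns), `> 0`.
#' @return An object of class `fret_result` with fields `efficiency`,
#'   `tau_a_donor_only`, `tau_a_with_acceptor`. Use `$efficiency` or
#'   `as.numeric()` for the bare value.
#' @export
fret_efficiency <- function(tau_a_DA, tau_a_D) {
  if (any(tau_a_DA <= 0) || any(tau_a_D <= 0)) {
    stop_invalid("lifetimes must be > 0")
  }
  structure(list(efficiency = 1 - tau_a_DA / tau_a_D,
                 tau_a_donor_only = tau_a_D,
                 tau_a_with_acceptor = tau_a_DA),
            class = "fret_result")
}

#' @export
as.numeric.fret_result <- function(x, ...) x$efficiency

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("<fret_result> E = %.4f  (tau_a DA = %.4g ns, tau_a D = %.4g ns)\n",
              x$efficiency[1], x$tau_a_with_acceptor[1], x$tau_a_donor_only[1]))
  invisible(x)
}

#' Pairwise Förster transfer efficiency
#'
#' \eqn{E(r) = 1 / (1 + (r / R_0)^6)} for a single donor-acceptor pair at
#' separation `r`; `R0` is the Förster radius, the separation of 50%
#' efficiency (60 Å for the EGFP-ShadowY pair).
#'
#' @param r Donor-acceptor separation (Å), `>= 0`; vectorised.
#' @param R0 Förster radius (Å), `> 0`.
#' @return Efficiency in `(0, 1]`, strictly decreasing in `r`.
#' @examples
#' forster_efficiency(60, 60) # 0.5 by definition of R0
#' @export
forster_efficiency <- function(r, R0) {
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0) {
    stop_invalid("R0 must be a positive finite scalar")
  }
  if (any(r < 0)) stop_invalid("r must be >= 0")
  1 / (1 + (r / R0)^6)
}

#' Mean (center-of-mass) fluorescence lifetime of a histogram
#'
#' First moment of the photon-arrival histogram minus a reference time:
#' \eqn{\bar\tau = \sum_i c_i t_i / \sum_i c_i - t_{ref}} over the full
#' acquisition window, with no background subtraction. This is the robust
#' low-photon surrogate for FRET efficiency used when bi-exponential fitting
#' is not supported by the photon budget.
#'
#' @param hist A [decay_histogram()].
#' @param t_reference Reference time subtracted from the first moment (ns);
#'   typically the fitted per-cell `t0`. All downstream comparisons are
#'   within-cell differences, so any consistent reference works.
#' @return A `lifetime_summary` list with `tau_mean` (ns), `total_photons`,
#'   and `tau_a = NA` (not defined for a moment estimate).
#' @export
mean_lifetime <- function(hist, t_reference = 0) {
  if (!inherits(hist, "decay_histogram")) {
    stop_invalid("hist must be a decay_histogram")
  }
  total <- sum(hist$counts)
  if (total <= 0) {
    stop_insufficient_photons("histogram contains no photons")
  }
  tau_mean <- sum(hist$counts * bin_centers(hist)) / total - t_reference
  structure(list(tau_a = NA_real_, tau_mean = tau_mean,
                 total_photons = total),
            class = "lifetime_summary")
}
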