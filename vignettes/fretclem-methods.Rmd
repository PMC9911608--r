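---
title: "Models and methods behind fretclem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretclem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretclem)
```

`fretclem` implements the computational core of FRET-CLEM: correlating
fluorescence-lifetime FRET measurements (FLIM) with platinum replica electron
micrographs (PREM) of clathrin-coated structures (CCSs) on unroofed plasma
membranes. This vignette is the package's own account of the models it uses,
the parameters that matter, the numerical choices made, and what its
synthetic-data tests do and do not demonstrate about real data.

## The TCSPC decay model

Time-correlated single photon counting histograms the arrival times of single
fluorescence photons after pulsed excitation. We model the per-structure decay
as a bi-exponential convolved with a Gaussian instrument response function
(IRF):

$$F(t) = F_0\left[P_1 H(t, t_0, \tau_1, \tau_G) +
  (1 - P_1) H(t, t_0, \tau_2, \tau_G)\right]$$

where $H$ is the convolution of a one-sided exponential with a unit-area
Gaussian of width $\tau_G$ (the exGaussian kernel):

$$H(t, t_0, \tau, \tau_G) = \tfrac12
  \exp\!\left(\frac{\tau_G^2}{2\tau^2} - \frac{t - t_0}{\tau}\right)
  \operatorname{erfc}\!\left(\frac{\tau_G^2 - \tau(t - t_0)}
  {\sqrt{2}\,\tau\,\tau_G}\right).$$

Two summaries matter downstream. The *amplitude-weighted lifetime*
$\tau_a = P_1\tau_1 + (1 - P_1)\tau_2$ converts to FRET efficiency against a
donor-only reference, $E = 1 - \tau_{a,DA}/\tau_{a,D}$; and the *mean
(center-of-mass) lifetime*, the first moment of the histogram minus a
reference time, is the robust surrogate used for dim structures, computed
over the full window with no background subtraction. Pairwise transfer
follows the Förster relation $E(r) = 1/(1 + (r/R_0)^6)$ with $R_0 = 60$ Å
for the EGFP–ShadowY pair.

Numerical evaluation of $H$ switches to the scaled complementary error
function on the rising edge, where $H = \tfrac12 e^{-(t-t_0)^2/(2\tau_G^2)}
\operatorname{erfcx}(b)$: the naive product overflows there. `erfcx` itself
is computed through the log-space normal CDF for arguments below 20 and by
the standard asymptotic series beyond, where the series truncation error is
far below double precision. The closed form is verified in the test suite
against brute-force quadrature convolution to better than $10^{-6}$ relative
across a parameter grid.

## Fitting: Poisson likelihood, multistart, and parsimony

Bin counts are Poisson; weighted least squares mis-weights the nearly empty
late bins, so `fit_biexponential()` maximises the Poisson likelihood of the
counts under the model plus the known expected uniform background. Expected
bin counts sum the model over adjacent excitation periods (offsets $-1$ to
$2$), because periodic pulsed excitation wraps the late tail of slow decays
back into the acquisition window; the photon sampler implements exactly the
same wrap, keeping simulation and fit self-consistent.

Design choices, in order of consequence:

* **Model selection.** A second decay component is reported only when a
  likelihood-ratio test against the nested mono-exponential fit is
  significant ($\alpha = 0.01$, 2 df). Without this guard, effectively
  mono-exponential data let the optimiser park a spurious near-zero-lifetime
  component under the IRF: it changes the likelihood by $\sim 1$ unit but can
  corrupt $\tau_a$ by several percent, because amplitude weighting is very
  sensitive to fast components with negligible photon contributions.
* **Multistart.** The likelihood is multimodal, so the fit starts from
  $(\tau_1, \tau_2) \in \{(0.5, 2.5), (1.0, 3.0)\}\times P_1 \in
  \{0.3, 0.7\}$ (ns), with $t_0$ and $\tau_G$ seeded from the histogram peak
  position and rise width.
* **Instrument parameters.** $\tau_G$ and $t_0$ are properties of the
  instrument, not of the structure; in routine use they are fitted once per
  cell and fixed for all ROIs of that cell (`fix_tauG`, `fix_t0`).
* **Profiling.** With no expected background, the overall scale $F_0$ has a
  closed-form maximum-likelihood solution and is profiled out.
* **Photon budget.** Bi-exponential fits are refused below 10,000 total
  photons by default — the budget below which such fits are unreliable —
  and `mean_lifetime()` is the supported estimator for dimmer structures.
* **Reference time.** The mean lifetime subtracts a caller-supplied
  reference ($t_0$ by convention here). All biological comparisons in the
  pipeline are within-cell differences, so any consistent reference cancels.

Uncertainties come from the observed information (numerical Hessian at the
optimum, delta method back to the natural scale); the reduced Pearson
chi-square is reported as a fit-quality diagnostic.

## The synthetic-data generator

The generator replaces the microscope for all tests. One scene is a field of
CCSs over uniform background, imaged at 80 nm/pixel:

* **Intensity profile**: a hard disk of the structure's radius convolved
  with a Gaussian PSF of $\sigma = 1.3$ pixels (confocal aperture optics are
  deliberately not modelled).
* **Noise**: per-pixel Poisson counts for structures and background
  separately; no read noise (photon-counting detector).
* **Decays**: a structure of true efficiency $E$ emits photons with
  $\tau = (1 - E) \cdot \tau_{a,D}$ (donor-only $\tau_{a,D} = 2.6$ ns by
  default), through the IRF, wrapped at the 12.5 ns window (256 bins). The
  per-photon component draw uses the *photon* fraction implied by the
  amplitude fraction $P_1$ — components contribute photons in proportion to
  amplitude × lifetime — so sampled histograms agree with the decay model
  distributionally (chi-square tested at $10^6$ photons).
* **Budgets**: 10,000 expected photons per structure (the typical yield of a
  150-frame acquisition) and 0.5 background photons per pixel, giving a
  signal-to-background ratio well above 100.
* **Frames and bleaching**: `simulate_frame_series()` splits the budget over
  frames; the acceptor-bearing fraction decays by $(1-b)^{f-1}$ per frame,
  scaling the effective efficiency, so acceptor photobleaching lowers the
  apparent FRET at late frames.
* **Pile-up** is not simulated: acquisitions are assumed to keep the peak
  count per pulse low enough to avoid it.

Everything is seeded and bit-reproducible. Photon totals are exact by
construction (wrap, not truncation).

## Lattice FRET geometry

A donor (EGFP on a light-chain terminus) faces the light-chain binding sites
of the five surrounding clathrin heavy chains. Each heavy chain is in one of
four states — no light chain, endogenous, EGFP-labelled, acceptor-labelled —
and only the acceptor-labelled state quenches; the *occupancy* is the
acceptor-bearing fraction of the four states. Per configuration of occupied
sites, independent acceptors add in rate: $E = S/(1+S)$ with
$S = \sum_i (R_0/r_i)^6$. The expected efficiency enumerates all $2^n$
configurations under independent Bernoulli occupancy and averages the
per-configuration efficiencies (averaging efficiencies, not rates — the
choice is stated here because either convention is defensible). Enumeration
is exact up to 20 sites and is cross-checked against Monte-Carlo in the
tests; a Monte-Carlo path covers larger geometries. The orientation factor
$\kappa^2 = 2/3$ is absorbed into $R_0$, appropriate for fluorophores on
flexible linkers.

`scan_nterm_positions()` steps the donor over a lateral grid (0.6 Å spacing
by default) at a fixed axial offset (25 Å) above the acceptor-site plane,
reproducing the position-scan analysis used to triangulate the light-chain
N-terminus. A documented fixture geometry — five sites on a 70 Å ring —
ships in code (`ring_sites()`); users with structural models supply their own
coordinate tables.

## Membrane quenching by DPA

Dipicrylamine is a dark, membrane-embedded FRET acceptor: quenching reports
the fluorophore's height above the membrane plane. No quenching equation is
canonical for this assay, so the package adopts the standard
point-to-infinite-plane Förster integral,

$$E(z) = \frac{S}{1+S}, \qquad S = \frac{\pi\,\sigma\,R_0^6}{2\,z^4},$$

with $\sigma$ the acceptor surface density (proportional to DPA
concentration via a user-supplied calibration constant, never fitted) and $z$
the axial distance. Only the *ordering* of constructs by lifetime drop
$\Delta\tau = \tau_{\text{no DPA}} - \tau_{\text{DPA}}$ is contractual —
larger drop means closer to the membrane — which is all the downstream
conclusions require; the single-plane model (one leaflet) is therefore
sufficient. The closed form is validated against 2-D numerical integration
over a discretised acceptor plane, and monotonicity in both $z$ and $\sigma$
is property-tested.

## Registration and per-structure statistics

FLIM-to-EM registration is a least-squares affine fit to fiducial pairs
(≥ 3, non-collinear). Flat and domed lattices serve as fiducials; sphere
lattices are excluded because they can shift during critical point drying.
The FLIM image is resampled *into* the EM frame (the higher-resolution
target) by inverse-mapped nearest-neighbour interpolation, which keeps
photon counts integral. Pixel centers sit on integer coordinates, origin
top-left, x = column, y = row, 0-based — stated once here and used
everywhere.

Per structure, a square ROI (bounding box + 2-pixel margin, configurable)
pools all photons: the ROI mean lifetime is the ratio of summed
arrival-time sums to summed counts, exactly the center-of-mass lifetime of
the pooled histogram. Structures are analysed only if isolated (no
neighbouring centroid within twice the summed radii; flagged by the
generator). Because absolute lifetimes vary cell-to-cell with expression
levels and probe densities, each curvature class is compared with the
*flat-class mean of the same cell*: $\Delta(\text{class})$ in ns, with
$\Delta(\text{flat}) \equiv 0$. In donor + acceptor experiments the dark
acceptor's expression is confirmed indirectly by keeping only cells with a
cellular average lifetime strictly below 2.1 ns. Differences in ns (not
ratios) are used, matching how such results are conventionally displayed.
Group comparisons over per-cell deltas go through standard one-way ANOVA
plus Tukey HSD (`compare_classes()`), a thin wrapper over `stats`.

EM morphometrics are bookkeeping: projected area = pixel count × pixel
size², density per µm² of measured membrane, and percentage of occupied
membrane area = summed class area / membrane area × 100.

## Problem sizes and numerical tolerances

The test suite and the demo pipeline run at desk scale, chosen so a complete
run takes seconds while every code path is exercised: 48 × 48 FLIM pixels at
80 nm, a synthetic EM frame at 8 nm/pixel (the registration mathematics is
scale-free and is separately verified at the 80/1.2 microscope scale on
fiducial coordinates), 6 cells with 4 structures per curvature class, and
5,000–10,000 photons per structure. The TCSPC window defaults to 12.5 ns
with 256 bins. Expected bin counts are evaluated at bin centers (bin width
≪ IRF width, so midpoint error is negligible against Poisson noise).
Enumeration-vs-Monte-Carlo agreement is asserted within 3 standard errors;
the decay model matches quadrature within $10^{-6}$ relative; affine
recovery from exact fiducials is asserted to $10^{-9}$ pixels.

## What passing tests do and do not show

The synthetic generator emulates Poisson photon statistics, IRF convolution,
periodic wrap, uniform background, acceptor photobleaching across frames,
PSF-blurred structure profiles, matched EM geometry, and
curvature-dependent true efficiencies. It does not emulate: non-Gaussian
instrument responses, detector afterpulsing or pile-up, autofluorescence,
chromatic or field-dependent registration distortion beyond affine, manual
segmentation ambiguity, or biological variability beyond per-cell efficiency
offsets. Recovery results here therefore demonstrate the correctness of the
estimators under their stated model, not the accuracy of the microscope's
calibration. Known limitations: the DPA plane model yields orderings, not
absolute heights; lattice FRET assumes independent site occupancy and rate
additivity; and curvature classes are taken as given (automated
classification from EM texture is out of scope).
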