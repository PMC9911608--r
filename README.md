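# fretclem

Computational toolkit for **FRET-CLEM**: correlative fluorescence-lifetime
FRET (FLIM) and platinum replica electron microscopy (PREM) analysis of
clathrin-coated structures (CCSs) on unroofed plasma membranes.

Clathrin lattices at the plasma membrane curve from flat plaques through
domes into spheres during endocytosis, and conformational changes in the
clathrin light chain accompany that curvature. FRET between fluorophores on
the light chain — or between a fluorophore and the membrane-embedded dark
quencher dipicrylamine (DPA) — shortens the donor's fluorescence lifetime in
proportion to proximity, while PREM reveals each structure's curvature class
at nanometre resolution. Correlating the two modalities yields per-structure,
curvature-resolved distance information. This package provides the complete
computational chain for such experiments, aimed at microscopists and image
analysts who have (or want to simulate) TCSPC/FLIM data paired with EM
segmentations.

## What it computes

**Decay modelling and fitting** (`decay_params`, `decay_model`,
`fit_biexponential`, `mean_lifetime`). TCSPC decays are modelled as a
bi-exponential convolved with a Gaussian instrument response:

    F(t) = F0 [ P1 H(t, t0, tau1, tauG) + (1 - P1) H(t, t0, tau2, tauG) ]

with the exGaussian kernel `H` and amplitude-weighted lifetime
`tau_a = P1 tau1 + (1 - P1) tau2`. Fits maximise the Poisson likelihood of
bin counts, are multi-started, and accept a second component only when a
likelihood-ratio test demands it. FRET efficiency follows
`E = 1 - tau_a(DA) / tau_a(D)`, and pairwise transfer follows the Förster
relation `E(r) = 1 / (1 + (r/R0)^6)` with `R0 = 60 Å` for EGFP–ShadowY. For
structures too dim to fit (< 10,000 photons), the center-of-mass mean
lifetime is the supported surrogate.

**Synthetic data** (`sample_decay_photons`, `simulate_flim_scene`,
`simulate_frame_series`, `simulate_clem_scene`). A seeded photon-level
generator replaces the microscope: Poisson pixel statistics, IRF-convolved
arrival times wrapped at the excitation period, PSF-blurred structures,
uniform background at signal-to-background > 100, acceptor photobleaching
across frames, and matched EM masks with ground-truth affine geometry.

**Lattice FRET simulation** (`expected_lattice_efficiency`,
`scan_nterm_positions`). Multi-acceptor transfer from a donor to the five
surrounding heavy-chain sites under a four-state occupancy model, by exact
configuration enumeration with rate additivity `E = S/(1+S)`,
`S = Σ (R0/ri)^6`; plus lateral position scans of the donor at 0.6 Å
spacing.

**Membrane quenching** (`plane_quench_efficiency`,
`delta_lifetime_axial_rank`). Point-to-plane Förster integral
`S = π σ R0^6 / (2 z^4)` for DPA quenching versus axial distance, and
ranking of constructs by their lifetime drop with and without quencher.

**Correlation engine** (`fit_affine`, `transform_image_nn`,
`roi_mean_lifetime`, `summarize_cell`, `filter_cells_by_lifetime`,
`morphometrics`, `run_pipeline`). Least-squares affine FLIM→EM registration
from fiducials, nearest-neighbour resampling into the EM frame, rectangular
per-structure ROIs, per-cell normalisation against the flat-class mean, the
2.1 ns acceptor-expression filter, and EM morphometrics (areas, densities,
occupied membrane fraction).

## Worked example

Simulate a tandem donor–acceptor construct at 50 Å separation (closer than
the 60 Å Förster radius), fit its decay, and recover the FRET efficiency:

```r
library(fretclem)

E_true <- forster_efficiency(50, 60)          # 0.7491209
tau_da <- (1 - E_true) * 2.6                  # quenched donor lifetime, ns

pair <- decay_params(F0 = 1, P1 = 1, tau1 = tau_da, tau2 = tau_da,
                     tauG = 0.15, t0 = 2)
h <- sample_decay_photons(pair, n_photons = 1e5,
                          background_fraction = 0.005, seed = 1)
fit <- fit_biexponential(h, fix_tauG = 0.15)
fret_efficiency(fit$tau_a, 2.6)
#> <fret_result> E = 0.7494  (tau_a DA = 0.6516 ns, tau_a D = 2.6 ns)
```

The fitted efficiency (0.7494) recovers the constructed truth (0.7491): the
donor lifetime collapses from 2.6 ns to 0.65 ns.

Run the full synthetic FRET-CLEM pipeline — scene simulation, registration,
ROI extraction, per-cell normalisation, morphometrics — for three cells:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "demo", n_cells = 3,
                               n_per_class = 4,
                               photons_per_structure = 5000))
round(res$summaries[, c("delta_domed_ns", "delta_sphere_ns",
                        "cellular_average_lifetime_ns")], 4)
#>        delta_domed_ns delta_sphere_ns cellular_average_lifetime_ns
#> cell01         0.0834          0.2411                       1.8728
#> cell02         0.1095          0.1968                       1.8787
#> cell03         0.1117          0.1905                       1.8822
```

`delta_*_ns` are each class's mean ROI lifetime minus the same cell's
flat-class mean. The positive, ordered deltas show lifetimes lengthening
from flat to domed to sphere — the curvature-dependent FRET signature the
scenes were generated with (true efficiencies 0.30/0.25/0.20) — and every
cellular average sits below the 2.1 ns acceptor-expression threshold.

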