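# memprobe

Quantitative workflows for environment-sensitive (solvatochromic) membrane
probes such as Pro12A, NR12S and NR12A. These dyes red-shift their emission
as their lipid environment becomes more polar and more mobile; reading that
shift out quantitatively takes three distinct toolchains, all implemented
here:

1. **Spectral-image GP analysis** — hyperspectral vesicle stacks →
   pixel-wise generalized polarization maps, GP = (I_B − I_R)/(I_B + I_R)
   at a blue/red reference-wavelength pair (423/494 nm for Pro12A, 557/664
   for NR12S, 583/673 for NR12A), automatic vesicle detection (Otsu
   threshold, DBSCAN clustering, eccentricity ≥ 0.5 filter), per-vesicle GP
   median/s.d., membrane GP profiles with a 3 × 1 px sliding element, phase
   contrast ΔGP, and the internalization index of cell line profiles.
2. **TDFS** — wavelength-resolved TCSPC decays (10 nm steps, 5000-count
   peaks) → reconvolution fits, reconstructed time-resolved emission
   spectra, the dynamic Stokes shift Δν = ν(0) − ν(∞) (polarity) and the
   integrated relaxation time τ_R = ∫ (ν(t) − ν(∞))/Δν dt (mobility), with
   time-zero estimation from a Lippert–Mataga solvent series,
   Δf = (ε − 1)/(2ε + 1) − (n² − 1)/(2n² + 1).
3. **Bilayer-trajectory observables** — probe tilt-angle distributions
   relative to the membrane normal (0° = along the normal, 90° = in the
   membrane plane) and partial density profiles along the bilayer normal.

Raw microscope, TCSPC and molecular-dynamics data are not desk-recomputable,
so the package includes seeded generators (`make_vesicle_image`,
`make_decay_set`, `make_trajectory`, `make_internalization_profile`) that
emulate each data source with ground truth attached; every pipeline stage is
validated by parameter recovery against them.

## Worked example

A synthetic scene with three circular vesicles (one phase-separated) and two
elongated 2:1 decoys, analyzed with the Pro12A configuration:

```r
library(memprobe)
cfg <- gp_config("pro12a")
ves <- list(
  list(center = c(40, 40),  radius = 16,
       phases = list(list(peak = 440, width = 30, amplitude = 2000),
                     list(peak = 490, width = 30, amplitude = 2000)),
       boundaries = c(0, 180)),                       # Janus vesicle
  list(center = c(40, 120), radius = 18,
       phases = list(list(peak = 450, width = 35, amplitude = 1800))),
  list(center = c(120, 40), radius = 14,
       phases = list(list(peak = 470, width = 30, amplitude = 2200))),
  list(center = c(120, 120), radius = 12, axis_ratio = 2, angle_deg = 30,
       phases = list(list(peak = 450, width = 30, amplitude = 2000))),
  list(center = c(80, 80),  radius = 10, axis_ratio = 2, angle_deg = 100,
       phases = list(list(peak = 450, width = 30, amplitude = 2000))))
scene <- make_vesicle_image(160, ves, channel_grid("pro12a"), cfg,
                            background = 20, seed = 3)
det <- detect_vesicles(scene$image, cfg)
det$vesicles
#>   label centroid_row centroid_col n_pixels eccentricity   gp_median      gp_sd retained
#> 1     1           40           40      308    0.0000000 -0.07414136 0.76825573     TRUE
#> 2     2          120           40      260    0.0000000 -0.37723747 0.02146921     TRUE
#> 3     3           80           80      264    0.8674765  0.40859570 0.02127712    FALSE
#> 4     4           40          120      340    0.0000000  0.31011812 0.02137101     TRUE
#> 5     5          120          120      330    0.8623775  0.41061289 0.02163315    FALSE
```

The two planted ellipses (eccentricity ≈ 0.87 ≥ 0.5) are discarded; the
uniform vesicles' GP medians (−0.377, +0.310) match the generator's analytic
GP of their emission spectra to better than ±0.002; the Janus vesicle's
near-zero median with large s.d. reflects its two phases, which
`membrane_profile()` resolves as a two-level step around the ring.

A TDFS recovery at the acquisition conditions (peak 5000 counts, lifetime
4 ns), planted Δν = 1500 cm⁻¹ and τ_rel = 1 ns:

```r
sim <- make_decay_set(nu_inf = 17000, delta_nu = 1500, tau_rel = 1,
                      lifetime = 4, peak_counts = 5000, seed = 2)
analyze_decay_set(sim$decays, sim$steady_state, nu0 = sim$truth$nu0)
#> relaxation_result: nu0 = 18500 cm-1, nu_inf = 16998 cm-1
#>   delta_nu = 1502 cm-1, tau_R = 0.997 ns
```

Both parameters land within the intrinsic uncertainties of the method
(50 cm⁻¹ for Δν, 0.05 ns for τ_R).

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

* `01_vesicle_gp.R` — vesicle detection and ΔGP recovery for all three
  probe configurations; internalization-index recovery.
* `02_tdfs.R` — TDFS parameter recovery over a 3 × 3 grid of planted
  (Δν, τ_rel), the slow-relaxation underestimation case, and Lippert–Mataga
  time-zero estimation.
* `03_trajectory.R` — tilt distributions for the three probe orientation
  archetypes, the cholesterol-induced mean-tilt reduction, and depth
  localization by partial density profiles.

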