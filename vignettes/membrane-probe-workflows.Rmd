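---
title: "Quantifying environment-sensitive membrane probes: GP imaging, TDFS and bilayer observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying environment-sensitive membrane probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprobe)
```

Solvatochromic membrane probes such as Pro12A, NR12S and NR12A red-shift
their emission as their lipid environment becomes more polar and more mobile.
This package implements the three quantitative workflows used to read those
shifts out: generalized-polarization (GP) analysis of hyperspectral vesicle
images, time-dependent fluorescence shift (TDFS) analysis of
wavelength-resolved TCSPC decays, and tilt/depth observables on bilayer
trajectories. Because the raw microscope, photon-counting and molecular
dynamics data are not re-creatable at desk scale, every workflow ships with a
seeded generator that emulates its data with ground truth attached; all
validation in this package is parameter recovery against those generators.

## Spectral imaging and the GP statistic

A spectral confocal detector collects emission in ~9 nm bands; the package
represents this as a channel × row × column stack with explicit channel
centers (`spectral_image`). Default grids are 20 channels over 423–601 nm
(Pro12A, 405 nm excitation) and 22 channels over 503–700 nm (NR12S/NR12A,
488 nm excitation). Background is corrected by subtracting, per channel, the
mean over a user-chosen background region; negative differences clamp to
zero so the GP stays within its theoretical range.

The generalized polarization of a pixel is

$$\mathrm{GP} = \frac{I_B - I_R}{I_B + I_R},$$

where $I_B$ and $I_R$ are the intensities at a blue- and a red-shifted
reference wavelength. GP runs from $+1$ (all intensity blue; ordered, apolar
environment) to $-1$. Reference pairs are data, not code
(`inst/extdata/probes.json`): 423/494 nm for Pro12A, 557/664 nm for NR12S,
583/673 nm for NR12A; any other pair can be configured, which changes the
absolute GP but not its ordering. Pixels with zero intensity in both
reference channels are undefined and are excluded from statistics rather
than set to 0, since 0 is a meaningful GP value.

Vesicle detection follows the classic automated recipe: per-image Otsu
threshold on the total-intensity projection (the threshold maximizes
between-class variance on a 256-bin histogram), density-based clustering of
foreground pixels into objects (DBSCAN; defaults `eps = 3` px,
`min_samples = 8`, chosen to bridge 1-px gaps in a membrane ring without
merging neighbouring vesicles at typical GUV scales), and a shape filter
that discards objects whose moment-ellipse eccentricity is at least 0.5 —
this removes vesicle clumps, tubes and out-of-focus debris while keeping
near-circular vesicles. Per-vesicle statistics (median and standard
deviation of GP) are taken over all defined GP pixels of the object; the
membrane-ring-only alternative was considered and rejected because rings are
what the generator plants and what the threshold isolates anyway.

Membrane GP profiles mimic the sliding-window readout of a linearized
vesicle: an algebraic circle fit to the object's pixels gives the membrane
centerline, and a 3 px (radial) × 1 px (tangential) integrating element is
slid along it at 1° steps. The two reference-channel intensities are summed
over the element *before* the GP is formed; summing first is shot-noise
optimal, whereas averaging per-pixel GPs would propagate the noisiest
pixels' ratios. Non-circular membranes are out of scope for profiles — the
eccentricity filter has already restricted objects to near-circles.

The internalization index divides the mean internal intensity of a line
profile through a cell by the mean membrane-peak intensity (after background
subtraction); 1 means the probe has fully equilibrated into internal
membranes.

## TDFS: reconvolution, TRES and relaxation parameters

Fluorescence decays are recorded at emission wavelengths spanning the
steady-state spectrum in 10 nm steps, each until its histogram peak reaches
5000 counts, together with the instrument response function (IRF). The
spectral relaxation observables come from time-resolved emission spectra
(TRES) reconstructed from fitted decays and the steady-state spectrum: at
each wavelength the deconvolved model decay is scaled so its time integral
equals the steady-state intensity there,

$$S(\lambda, t) = \hat{D}(\lambda, t)\,
  \frac{SS(\lambda)}{\int \hat{D}(\lambda, t)\,dt},$$

which makes the per-wavelength conservation identity exact by construction.
The wavelength axis is converted to wavenumber with the $\lambda^2$ Jacobian
(a configuration flag, on by default, since peak positions per unit
wavenumber are what the relaxation parameters refer to). The surface stays
on the wavenumber grid implied by the 10 nm wavelength grid; the log-normal
peak fit below does not need a uniform grid, and resampling would break the
conservation identity.

Two fitting routes are provided. `fit_decay_reconvolution` fits a single
decay with a multi-exponential model convolved with the (sub-bin shiftable)
IRF — three components by default, escalated only until the fit is
satisfactory, mirroring standard TCSPC practice of deconvolving without
over-parameterizing. Red-edge decays of relaxing systems *rise* before they
fall, so amplitudes are unconstrained and may be negative. The default
analysis route, `fit_decay_set_global`, instead ties one lifetime basis
across all wavelengths and solves the per-wavelength amplitudes by weighted
linear least squares at every optimizer step (variable projection). The
rationale is empirical and structural: spectral relaxation moves intensity
between wavelengths while the set as a whole evolves on a common kinetic
basis, and independent per-wavelength fits leave small correlated model
errors whose effect on the reconstructed spectrum grows toward late times,
exactly where the relaxed-state position $\nu(\infty)$ must be read off.
Numerical choices that matter, each exposed as an argument:

* basis size 9 with neighbouring lifetimes at least a factor 1.3 apart and
  capped at twice the acquisition window — dense enough to represent a
  strongly non-exponential relaxing surface, while near-degenerate or
  data-free slow components (which let the tail spectrum wander) are
  excluded by construction;
* Pearson weighting, i.e. Poisson weights taken from the model rather than
  the observed counts: observed-count weighting systematically pulls
  low-count bins down, which masquerades as slowed relaxation;
* analysis times cover the first 40% of the acquisition window — beyond
  that the histograms are essentially empty and any model value is an
  extrapolation;
* amplitude covariances are propagated into per-slice uncertainties of the
  TRES surface and weight the subsequent lineshape fits.

Each time slice is fitted with a log-normal (Fraser–Suzuki) lineshape
parameterized by exact peak position and FWHM; a Gaussian is its zero-skew
limit. If a slice peaks on the grid edge, the argmax is reported unfitted
with a warning. From the peak trace $\nu(t)$ the pipeline derives the total
dynamic Stokes shift $\Delta\nu = \nu(0) - \nu(\infty)$ (polarity readout)
and the integrated relaxation time

$$\tau_R = \int_0^\infty \frac{\nu(t) - \nu(\infty)}{\Delta\nu}\, dt$$

(mobility readout), evaluated by the trapezoid rule plus an analytic
exponential-tail correction fitted to the last decade of the correlation
function — the tail is only accepted when its fitted time constant is
resolvable within the window.

$\nu(\infty)$ is estimated by an uncertainty-weighted exponential fit of the
whole $\nu(t)$ curve (one or two relaxation components, the second admitted
only when it reduces the weighted residual substantially). A plateau mean
over the last tenth of the window was tried first and abandoned: for a small
shift (500 cm$^{-1}$) integrated over a 20 ns window, a 0.05 ns accuracy on
$\tau_R$ requires $\nu(\infty)$ to ~1 cm$^{-1}$, which no short plateau
average can deliver against the reconstruction noise floor. When the fit
predicts that a substantial fraction of the relaxation is still pending at
the window end, the last observed value is used instead and the result is
flagged — $\tau_R$ is then an underestimate, the documented behaviour when
relaxation outlasts the fluorescence lifetime (the slowest, most ordered
bilayers).

$\nu(0)$, the emission maximum before any solvent relaxation, is not taken
from the TRES surface by default in recovery runs: extrapolating
multi-exponential fits to exactly $t = 0$ is the least stable point of the
whole chain. Instead the package implements the standard independent
estimate: the probe's Stokes shift measured in a solvent series is regressed
on the Lippert–Mataga polarity function

$$\Delta f = \frac{\varepsilon - 1}{2\varepsilon + 1}
           - \frac{n^2 - 1}{2n^2 + 1},$$

and the intercept at $\Delta f \to 0$ subtracted from the system's
absorption maximum gives $\nu(0)$. The arithmetic path for deep-temperature
glass estimates (a directly supplied $\nu(0)$) is the `nu0` argument. When
neither is available, the $t=0$ TRES peak is used, and the correlation
function then starts exactly at 1.

## Trajectory observables

For planar bilayers the membrane normal is the box z axis. The tilt of a
probe is the angle between its fluorophore long axis (a head→tail atom pair
named in a role map, since force-field atom naming is system-specific) and
the *inward* leaflet normal, so 0° points at the membrane centre and 90°
lies in the membrane plane; leaflet assignment is by the head atom's side of
the midplane, recomputed per frame. Angles are folded to [0, 90°] by
default — the reported experimental maxima and means live there — with the
unfolded [0, 180°] convention available. Distributions are 2.5°-bin
histograms; modes are local maxima after a 3-bin moving average, with tied
plateaus collapsed to their highest-frequency bin.

Partial density profiles histogram selected atoms' z coordinates after
recentering each frame on the bilayer midplane (mean z of the chain-terminal
reference atoms), normalized by bin volume. Profiles are not symmetrized
across leaflets, because probes may occupy one leaflet only. A composition
helper expresses the probe content of a simulated bilayer in mol% (200
lipids + 8 probes ≈ 4 mol%).

## What the generators emulate — and what they do not

`make_vesicle_image` renders circular or elliptical membrane rings whose
per-channel intensities follow Gaussian emission spectra sampled at the
channel centers, over a uniform background, with Poisson shot noise
(optionally Gaussian read noise and Gaussian blur). Planted amplitudes of
2000 counts over a background of 20 give a peak S/N above 40, comparable to
a well-exposed confocal frame. It does not model a realistic PSF, depth
attenuation, or spectral bleed-through, so passing recovery tests shows the
analysis chain is correct, not that real microscope images are this clean.

`make_decay_set` builds the continuous time-resolved surface
$\nu(t) = \nu_\infty + \Delta\nu\,C(t)$ with mono- or multi-exponential
$C(t)$, a log-normal instantaneous lineshape with constant FWHM (2500
cm$^{-1}$, slight red skew) — FWHM(t) passing through a maximum, as real
relaxation probes show, is not emulated by default — a single fluorescence
lifetime, a Gaussian IRF (50 ps width), binning, per-decay scaling to the
5000-count acquisition target, and Poisson noise. Detector afterpulsing and
background are not modeled. The analytic $\tau_R$ of the planted $C(t)$ is
carried as ground truth.

`make_trajectory` samples probe axes from (mixtures of) normals around
planted tilts with uniform azimuth, reflected into range, and atom depths
from Gaussians about the midplane. There is no actual dynamics — frames are
independent draws — which is exactly what the tilt/density estimators need
and nothing more.

Default problem sizes (160 px scenes; 2000-bin, ~25-wavelength decay sets;
10³–10⁴-frame trajectories) were chosen so that each recovery sits well
inside its statistical tolerance while a full validation run completes in
minutes on a laptop core.

## Known limitations

* The GP pipeline assumes near-circular vesicles; membrane profiles are
  unavailable for irregular shapes by design.
* TDFS accuracy degrades gracefully but measurably when the relaxation time
  approaches the analysis window; beyond the fluorescence lifetime it is an
  acknowledged underestimate.
* The global-analysis route assumes all wavelengths share one IRF shift;
  wavelength-dependent transit-time spread is not modeled.
* Trajectory readers cover minimal GRO/XYZ files with a JSON role map, not
  general topology formats.
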