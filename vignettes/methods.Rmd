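---
title: "Methods: simulating breast-HIFU focal error on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating breast-HIFU focal error on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-intensity focused ultrasound (HIFU) ablates breast tumours by
converging a 2 MHz beam from a spherical-cap phased array onto a focal
spot a few millimetres across. Breast tissue is acoustically mild — no
bone, no gas — yet the fibroglandular network (sound speed 1547 m/s
against 1465 m/s for fat) refracts and scatters the converging wave
enough to displace and smear the focus. This package reproduces that
analysis chain end to end on synthetic data: digital breast phantoms,
histogram-based tissue segmentation, finite-difference time-domain (FDTD)
wave propagation through the segmented property maps, time-reversal
focus control, and a set of focal-quality metrics including an
impedance-gradient indicator intended to rank transducer arrangements
before treatment.

## Models and procedures

### Phantom generator

`synthesize_breast_mri()` draws a T1-like brightness volume at the
emulated acquisition resolution (0.625 x 0.625 mm in plane, 0.8 mm
slices): a half-ellipsoid breast on the chest plane surrounded by air, a
dark-fat / bright-gland bimodal interior, and additive Gaussian noise
applied last. The gland compartment is the connected superlevel set of a
Gaussian-correlated random field (correlation length
`gland_correlation_mm`, default 1.5 mm — the feature scale is deliberately
comparable to the 0.74 mm wavelength) multiplied by a duct-like envelope
that decays radially from the chest–nipple axis and is modulated into
spokes. The set is grown voxel by voxel from the field maximum with a
max-heap over the 26-connected frontier until the target voxel count is
reached, which guarantees two invariants by construction: the gland
fraction matches `gland_fraction_target` almost exactly, and the
compartment is a single 26-connected component. The envelope weight (0.6
times the unit-variance field) keeps the texture network-like rather than
blob-like; with a dominant envelope every ray through the breast sees a
similar gland thickness and the phantom under-aberrates.

Brightness ordering is air < fat < gland. On conventional T1 images fat
is bright; here the contrast-enhanced convention is used because the
fat/gland threshold sweep must behave monotonically — raising the
threshold converts gland to fat.

One integer seed drives every stochastic draw; identical recipes give
bit-identical volumes.

### Segmentation

`segment_pipeline()` follows the classical four-step chain: a 3x3x3
median filter (edge-replicated); an air/breast threshold at the minimum
of the smoothed brightness histogram between its first two local maxima
(256 equal-width bins, 5-bin moving average, ties toward the lower bin —
the binning is our choice, as the procedure itself does not prescribe
one); zeroing of sub-threshold voxels as air; interface detection by
line scans from all six domain faces against a threshold of 50 % of the
mean non-air brightness (the scan directions are our choice; a
single-direction scan misses overhanging surface); and a 1.5 mm skin
layer grown from the interface into the former air region by Euclidean
distance, with sub-voxel thicknesses rounded up to one layer. The
interface voxels themselves are restored to breast brightness once the
skin is added, so the skin shell is exactly the air-side layer of the
requested thickness. Fat and fibroglandular tissue are then split at the
brightness cut whose below-fraction is closest to the assumed 66.5 %
fat fraction, and the working volume maps totally onto
\{WATER, SKIN, FAT, GLAND\} (air is treated as the water coupling bath).
Acoustic properties are assigned per voxel — water (998.2 kg/m^3,
1482 m/s, 0.22 dB/m/MHz), skin (1090, 1615), fat (985, 1465, 40), gland
(1032, 1547, 60) — with attenuation converted to Np/m at the drive
frequency. The skin attenuation is not tabulated; we default it to the
fibroglandular value, a harmless choice since the skin is a 1.5 mm layer
and its absorption share is negligible.

### Acoustic solver

The solver integrates the standard first-order heterogeneous
pressure–velocity system (momentum equation plus a fluid constitutive
relation; shear is irrelevant at soft-tissue shear speeds) on a staggered
grid: 6th-order central differences in space, leapfrog in time at
CFL 0.4 (2D) / 0.3 (3D), split-field perfectly matched layers (20 cells,
cubic grading, nominal reflection 1e-6), harmonic density averaging onto
velocity nodes, and a 3-cycle cosine source ramp. Mean-square pressure
and peak |p| maps are accumulated over the final five drive cycles.

Attenuation is a frequency-independent relaxation term on the pressure
update with rate `gamma = 2 alpha c`, calibrated so a plane wave decays
at exactly `alpha0 x f` at the drive frequency; under the optional
quadratic (B/A) nonlinearity (off by default, placeholder B/A values)
harmonics would be under-attenuated relative to the linear-in-frequency
table, a documented simplification. All reported metrics are field
ratios, so the linear default is the appropriate operating point.

Sources and receivers are sampled on the exact transducer surface at
half-cell spacing and spread over neighbouring cells with multilinear
weights; a cell-rounded source biases arrival phases across the array by
up to a quarter radian, which the weighting removes (element recordings
of a focal point source then agree to 0.1 % at 15 points per
wavelength).

Independent references: an axisymmetric Rayleigh quadrature over the
spherical cap (`linear_focus_oracle()`, checked against the concave-
radiator closed form to 0.1 %), and a cylindrical-wave arc oracle for 2D
(`arc_field_2d()`, large-argument Hankel form, relative error below 1e-3
at the distances used).

### Focal metrics

With the target at the geometric focus, `localized_heating_ratio()` and
`focusing_ratio()` integrate `Q = alpha p^2 / (rho c)` and
`p^2/(rho c)` over concentric spheres r = 2.5 mm and R = 10 mm
(voxel-center membership; partial-volume weighting changes the ratios by
under 1 % at the default resolutions). `Phi` normalizes the focusing
ratio by its free-field value. `primary_peak()` reports the global
maximum of the peak-pressure map with ties broken toward the target.
`local_acoustic_inhomogeneity()` computes
`chi = sqrt(mean |grad(rho c)|^2) / (rho_w c_w / lambda_w)` by central
differences over a beam-path region: the triangle (truncated cone) from
the active aperture rim to the target, restricted to non-water voxels.
The region choice is configurable; the averaging region and the
integration region are taken to be the same set.

### Time-reversal focus control

A forward run with a point emitter at the target records each element;
per-element lags come from the cross-correlation with the element
nearest the beam axis, restricted to one drive period and refined by
parabolic interpolation, and the drive phase advances what arrived late.
For the amplitudes we depart from inverse RMS compensation
(`ref/elem`, available as `amp_mode = "rms_ratio"`): measured on the
ensemble it *lowers* the focusing ratio (e.g. `Phi` 0.90 -> 0.52),
because it boosts exactly the shadowed, scattering-prone channels. The
default is the matched weighting `elem/ref` (normalized, capped at 4):
emit proportionally to what was received, the weighting true time
reversal implies and the one that makes focus control consistently
beneficial.

## Study conditions

The paper-scale production run (2560^3 voxels at 0.05 mm) is
configuration-reachable but not a desk target. The package's standard
conditions (`study_setup()`, stated here as our choices) are:

* 2D cross-sectional runs at 2 MHz on a 0.12 mm grid (6.2 points per
  wavelength in water, the solver's accuracy floor; the free-field
  focusing ratio changes by < 1 % on halving the spacing);
* a geometrically similar arc: focal distance 55 mm, aperture 66 mm,
  hole 19.25 mm — the f-number 5/6 preserved — over breasts of 35 mm
  radius, keeping a realistic 15–20 mm tissue path;
* the evaluation spheres at the standard r = 2.5 / R = 10 mm. These are
  *not* scaled with the transducer: the focal-lobe dimensions are set by
  wavelength and f-number, which are unchanged, so the absolute
  integration scales remain the right ones (scaling them down makes the
  heating ratio hypersensitive to the tissue right at the target);
* the ensemble (`default_ensemble_plan()`): 12 phantoms at the fixed
  66.5 % fat fraction — structure varied through the gland feature scale
  (0.8 / 1.5 / 3 mm), gland position and independent realizations — each
  treated at two tumour-like targets (`gland_target()` embeds each
  target in solid gland at a fixed depth, as tumours segment into the
  fibroglandular class), 24 runs in total;
* free-field references computed once per configuration and cached.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the segmentation and
acoustics stages rely on: a closed breast surface against air, a bimodal
interior histogram, a connected wavelength-scale gland network, and
noise that exercises the median filter. It does not attempt anatomically
realistic ductal trees, pectoral muscle, lung, MRI bias fields or coil
profiles. Passing tests therefore demonstrate that the pipeline is
implemented correctly and that the qualitative physics (aberration by
the gland network, its removal by ablation or time reversal, the
negative inhomogeneity–quality relationship) emerges under controlled
conditions — not that patient-specific focal errors are predicted.

Two quantitative consequences of the desk scale are worth stating
plainly. First, 2D cross-sections cannot azimuthally average the beam
cone: the intensity-weighted mean attenuation of the 10 mm region
fluctuates with the slice's local fat/gland arrangement, which puts the
heating-ratio/focusing-ratio correlation near 0.92 on the ensemble,
short of the 0.99 coupling a full 3D treatment-scale ensemble exhibits.
Second, the plane-wave dispersion check runs at CFL 0.2: at the default
CFL 0.4 the second-order temporal term alone contributes
`(omega dt)^2 / 24 ~ 0.12 %` of phase-speed error, which would mask the
6th-order spatial accuracy the check is about.

## Numerical choices and degenerate inputs

Histogram thresholding fails loudly on unimodal histograms (constant
volumes, empty interiors). The fat-fraction cut picks the closest
achievable below-fraction among realized brightness values, so the
fraction -> 1 limit returns the maximum (gland keeps only the top ties).
Exact peak ties resolve toward the target. Zero-energy elements get zero
drive amplitude with a warning. Sphere sums reject an all-zero field
rather than return 0/0. FDTD runs abort with a diagnostic on non-finite
pressure, warn when the simulated time cannot cover the source-to-focus
distance, and refuse grids below 6 points per wavelength or anisotropic
spacings. Subnormal pressures in the decaying wavefront tail are flushed
to zero inside the solver kernels — a pure performance measure (about
20x) with no effect above the 1e-308 scale.

## Problem sizes used by the test suite

Unit tests run on compact phantoms (~34 mm domains), 1600-cell 1D
strips, and 2D grids up to about 1000 x 700 cells; the ensemble is the
24-case plan above (a few seconds per case); the small-3D validation
uses a 141 x 141 x 131 grid at 6.6 points per wavelength. The
acceptance script evaluates the full-geometry (100/120/35 mm) free-field
oracle on a 0.15 mm half-plane grid and a 9.4-million-voxel uniform-heat
lattice.

## Known limitations

Temperature fields and bioheat coupling are out of scope (all reported
metrics derive from Q directly); shear waves, cavitation and element
directivity are not modelled; the attenuation model is exact only at the
fundamental; the 2D ensemble understates both absolute aberration and
the beta–phi coupling relative to 3D treatment scale; and chi depends on
the chosen beam-path region — it is reported alongside the region's
voxel count so alternative regions can be compared.
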