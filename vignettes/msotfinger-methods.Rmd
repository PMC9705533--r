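---
title: "Models and methods behind msotfinger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msotfinger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msotfinger)
```

# The problem

Multispectral optoacoustic tomography (MSOT) of the fingers images the
digital arteries through the absorption contrast of haemoglobin: pulsed
near-infrared light absorbed by blood generates ultrasound, and acquiring
at several wavelengths lets the two haemoglobin species be separated
spectrally. From a reconstructed image cube this package derives the two
quantities of clinical interest in digital vasculopathy (for example in
systemic sclerosis, SSc): *vascular volume*, the physical volume of tissue
segmented as vessel, and *oxygen saturation* (sO2), in arbitrary units
because the instrument is uncalibrated. A cuff-occlusion challenge adds a
functional axis: baseline sO2, the trough reached during a two-minute
arterial occlusion, and the hyperaemic peak after release.

Because no patient data ship with the package, a seeded phantom generator
stands in for every acquisition type, with exact ground truth, so each
stage of the pipeline is testable end to end.

# The forward model (phantom)

A phantom is a set of cylindrical "digital arteries" with homogeneous
concentrations `[Hb]` and `[HbO2]` (arbitrary units; the vessel's true
saturation is `[HbO2] / ([Hb] + [HbO2])`), rasterised onto the voxel grid
by voxel-centre inclusion in the finite cylinder. The per-voxel,
per-wavelength signal is

    I(v, w) = exp(-k * depth(v)) * ln(10) * (eps_Hb(w) [Hb] + eps_HbO2(w) [HbO2])
              + background + noise,

i.e. initial-pressure contrast proportional to the absorption coefficient
of the haemoglobin mixture under a depth-only exponential fluence. No
acoustic propagation, bandlimiting or reconstruction artefacts are
modelled: the phantom emulates an *already reconstructed* cube, which is
where the analysis pipeline starts.

Key parameters and defaults:

* **Grid**: 250 × 250 × 200 voxels at 80 µm lateral / 50 µm depth spacing
  (2 × 2 × 1 cm), matching the acquisition system; tests use reduced grids
  purely for speed. The voxel volume is 0.08 × 0.08 × 0.05 = 3.2 × 10⁻⁴ mm³.
* **Wavelengths**: 700, 730, 760, 800, 850 nm.
* **Fluence decay** `k = 0.25 mm⁻¹`: a soft-tissue near-infrared
  effective-attenuation scale (µ_eff = sqrt(3 µa (µa + µs')) with typical
  µa ≈ 0.02 mm⁻¹, µs' ≈ 1 mm⁻¹ gives ≈ 0.25 mm⁻¹). The value is a nuisance
  parameter: it cancels out of sO2 (a per-voxel ratio) and only shapes
  intensity with depth.
* **Noise**: additive, zero-mean, Gaussian, independent per voxel and
  wavelength — the simplest model sufficient for testing noise-floor
  masking and recovery tolerances. No noise statistics are published for
  the acquisition system, so defaults are 0 and each test states its own
  (typically a fraction of the peak vessel signal).
* **Seeding**: identical spec + seed is bit-identical; the generator
  restores the caller's RNG state.

Two deliberate geometric choices: rasterisation is a *finite cylinder*
(radial distance to the axis line ≤ r and axial projection inside the
segment) rather than a capsule, so the voxelised volume converges to the
analytic π r² L; and overlapping vessels add their concentrations, which
is unambiguous and keeps ground truth well-defined.

What the phantom does **not** emulate: limited-view and bandlimit
artefacts, speed-of-sound errors, skin melanin, motion, or fluence
spectral colouring. A green recovery test therefore establishes
correctness of the *analysis*, not robustness to every physical
confounder of real acquisitions.

# Spectral unmixing and sO2

Unmixing solves, per voxel, the least-squares system `A c = s` where the
design matrix `A` holds the molar extinction coefficients of Hb and HbO2
at the acquisition wavelengths and `s` is the voxel's spectrum. The
solution is the Moore–Penrose pseudo-inverse; negative concentrations are
retained by the solver and clamped to zero only when sO2 is formed, which
keeps the solver a pure linear operator while guaranteeing sO2 ∈ [0, 1].
Voxels whose clamped total haemoglobin is zero, or whose total signal does
not exceed the noise floor, are masked out rather than silently zeroed.
The noise floor is an absolute threshold on `[Hb] + [HbO2]`, with an
"auto" mode equal to mean + 3 SD over a user-designated background
region.

The extinction table bundled under `inst/extdata/` is a *synthetic*
compilation representative of standard literature tabulations (650–900 nm,
10 nm grid): it reproduces the features the pipeline relies on — the
deoxy-Hb shoulder near 760 nm, the isosbestic crossing near 797 nm, and
opposite signs of `eps_Hb − eps_HbO2` at 760 vs 850 nm — but is not a
verbatim copy of any published dataset (none could be redistributed
verifiably here). Since the system is uncalibrated and sO2 is a ratio,
only the *shape* of the spectra matters; absolute scale is immaterial.

One numerical subtlety is documented rather than hidden: the forward
model converts decadic extinction to an absorption coefficient with a
factor ln(10), while the unmixing design uses the raw extinction
coefficients. Noiseless unmixing therefore recovers `ln(10) ×` the
generator's concentrations — exactly, and the tests assert exactly that —
while sO2, a ratio, is recovered identically. In arbitrary-unit data the
constant is unobservable.

# Vessel segmentation and volumetry

Structural segmentation thresholds the 800 nm volume — the isosbestic
wavelength, so the image is independent of oxygenation — with the
moment-preserving criterion: choose the two-level image that preserves
the first three raw moments m₁, m₂, m₃ of the intensity histogram.
Solving the moment system yields two representative levels z₀ < z₁ and a
below-fraction p₀ = (z₁ − m₁)/(z₁ − z₀); the threshold is the p₀ quantile
of the histogram. Conventions, each chosen once and tested:

* 256 equal-width bins over the data range (the 8-bit convention of the
  method's origin); configurable.
* Left-continuous empirical CDF inversion: the smallest bin whose CDF
  reaches p₀, with the *upper edge* of that bin returned, so that the
  strict `>` comparison truncates the below population including the
  selected level itself ("truncating low intensity pixels").
* Degenerate histograms (zero variance, or no two distinct levels) raise
  an explicit error: no threshold separates anything.

The test suite carries an independent brute-force oracle: for a candidate
fraction p, the two levels preserving m₁ and m₂ exactly are closed-form,
and the m₃ mismatch is strictly monotone in p, so bisection recovers p₀
without the cubic — the closed form and the scan must agree bin-for-bin.

Vascular volume is voxel counting: `n_above_threshold × voxel volume`,
reported exactly in machine output and rounded to 1 decimal place (mm³)
in formatted tables. Thresholding defaults to per-cube (each image is
thresholded on its own histogram); a fixed global threshold can be passed
instead. Per-subject summaries average over the up-to-eight imaged
fingers, excluding missing fingers from numerator and denominator with a
logged warning.

# Occlusion dynamics

The time axis is a series of spatially averaged sO2 values with per-frame
validity flags; frames lost to noise or artefacts are flagged, never
dropped, and no interpolation is performed across gaps. The three windows
partition the series: baseline `[0, cuff_on)`, occlusion
`[cuff_on, cuff_off)` (default duration 120 s, the cuff protocol),
release `[cuff_off, end]`. Baseline is a window *mean* — it is a steady
state, so averaging is robust — while the occlusion trough and
post-release peak are window *extrema*, matching how the challenge is
summarised clinically. The baseline window length and the mean-vs-single-
frame choice are not prescribed anywhere; the full pre-cuff mean is this
package's documented default. A 3-frame moving median is available as an
artefact-rejection knob and is off by default.

A known statistical limitation, deliberately not papered over: under
per-frame noise the window extrema are extreme-value statistics, biased
away from the true trough/peak by roughly twice the noise SD when the
noiseless trajectory plateaus near the extremum (as a 2-minute occlusion
physiologically does). Recovery tests for the *baseline* are an order of
magnitude tighter than for the extrema; see the decisions ledger shipped
with the development notes for the measured figures.

The occlusion-series generator produces a flat baseline, an exponential
approach that attains the trough exactly at the last occlusion frame, a
rise to the peak (attained exactly at one release frame) and a slow
relaxation toward baseline (τ = 30 s). Frame interval defaults to 2 s,
a realistic multispectral frame period for a 50 Hz system cycling five
wavelengths with averaging.

# Whole-finger mosaics

Whole-finger scans are sequences of a few hundred full-depth projections
taken while the probe slides along the finger. "Full depth projection"
is implemented as a maximum-intensity projection along depth (vessels are
bright; MIP is the standard vascular projection), with sum projection
behind a flag. Consecutive frames are registered by the integer shift
along the travel axis maximising normalised cross-correlation; the peak
correlation doubles as a reliability score. Pairs below the reliability
threshold have the median reliable offset imputed and are flagged; if no
pair is reliable the stitcher refuses and asks for manual offsets.
Overlapping pixels blend by per-pixel maximum — this avoids seams, and
when offsets are misestimated it reproduces the characteristic duplicate
"ghosting" of vessels rather than masking the failure. Stitching is
best-effort and qualitative by design: no quantitative measure is derived
from a mosaic.

# Cohort statistics

Group tables report n, median and IQR (linear-interpolation quantiles,
R type 7) per group, compared either at finger level or as the mean of
eight fingers per subject. The HC-vs-SSc comparison is a two-sided
Mann–Whitney U test: exact (full rank-permutation null, valid without
ties, the mode of record at small n) or asymptotic (normal approximation
with tie and continuity corrections), with the mode recorded in the
output since published tables rarely state it. SSc subgroup rows (history
of severe digital ischaemia vs not) are descriptive only — subgroup
numbers are too small for formal testing, so test fields are `NA` by
design. No multiple-testing correction is applied, mirroring standard
practice in small clinical imaging studies; this is a documented
limitation, not an endorsement.

The exact two-sided p value is defined as `min(1, 2 min(P(U ≤ u),
P(U ≥ u)))`, which equals the enumeration answer on tie-free data (e.g.
`{1,2,3}` vs `{4,5,6}`: U = 0, p = 2/20 = 0.1).

# The demo study

`run_demo_study()` wires everything together at desk scale: 32 healthy
controls and 22 SSc subjects (6 with ischaemia history), eight two-artery
phantom fingers each, analysed cube by cube (moment threshold → volume;
unmixing → noise floor → mean sO2), plus an occlusion challenge for a
17/10 subset mirroring the attrition real occlusion videos suffer. The
stated world is: true sO2 ~ N(0.381, 0.009) per subject (spread set from
the healthy-control IQR width of the mean-of-8 tables), shifted down by
0.008 in SSc; vessel radii ~ N(0.96, 0.10) mm common to both groups
(vascular volume did not differ between groups, so none is simulated),
giving per-finger volumes near 115 mm³; occlusion landmarks
0.377/0.364/0.382 with small SSc shifts; phantom noise 2% of peak signal.
Fingers run on a 48 × 48 × 32 grid over the same physical field of view,
which keeps the full cohort under a minute — physical volumes are
grid-independent up to voxelisation error, so comparisons are unaffected.

Two honest caveats. First, the mean sO2 over noise-floor-masked voxels
carries a small upward bias (~0.03 here): voxels that pass the floor but
are noise-dominated unmix to saturations pulled toward 0.5. The group
*comparison* is unaffected (both groups share the bias), which is exactly
the situation of an uncalibrated instrument reporting arbitrary units.
Second, whether the original analysis averaged sO2 over all valid voxels
or only segmented-vessel voxels is unstated; `mean_so2()` accepts any
mask, and the pipeline default is the noise-floor mask.

# Numerical and interface choices

* Spatial units are mm internally; µm at boundaries (voxel spacings).
  Depth is the third axis, increasing away from the probe; voxel-centre
  geometry with 0-based conceptual indices.
* Volumetric I/O: a plain-text format (full-precision values plus a JSON
  sidecar) whose round trips are bit-identical, and a minimal NIfTI-1
  writer/reader (FLOAT64, spacings in the header) validated against an
  independent neuroimaging reader in the test suite. TIFF and HDF5 are
  not supported because no R bindings are available in the target
  environment; the interface accepts a `format` argument so adding them
  is additive.
* All stochastic stages take explicit integer seeds; deterministic stages
  are reproducible bit-for-bit, and the run manifest records MD5
  checksums so re-runs can be verified.
* CSV interchange: comma-separated, UTF-8, header row, `.` decimal.

# Known limitations

* The phantom's noise and fluence models are deliberately minimal (see
  above); absolute sO2 accuracy on real data is limited by fluence
  spectral colouring, which is out of scope (no fluence correction).
* Mosaic registration is 1-D rigid; non-rigid motion produces ghosting,
  which is reported, not corrected.
* Exact Mann–Whitney requires tie-free data; discretised measurements
  fall back to the corrected asymptotic mode (recorded in the output).
* Printed-table formatting rounds volumes to 0.1 mm³ and sO2 to 0.001,
  so formatted output is for reading, not for further computation.
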