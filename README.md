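# msotfinger

Analysis of multispectral optoacoustic tomography (MSOT) finger imaging:
from reconstructed multispectral image cubes to digital-artery volume,
oxygen-saturation (sO2) maps, occlusion-challenge dynamics, whole-finger
mosaics, and cohort comparison tables. The package targets studies of
digital vasculopathy — for example systemic sclerosis (SSc), where
reduced digital-artery oxygenation is a candidate functional biomarker —
and ships a seeded synthetic phantom generator with exact ground truth so
the entire pipeline is testable without patient data.

## What it computes

* **Spectral unmixing.** Per voxel, the least-squares solution of
  `A c = s`: `A` is the `n_wavelengths x 2` matrix of Hb/HbO2 molar
  extinction coefficients (bundled table, 650–900 nm, linear
  interpolation), `s` the measured spectrum, and `c = (pinv A) s` the
  chromophore concentrations via the Moore–Penrose pseudo-inverse.
  Saturation follows the standard ratio
  `sO2 = [HbO2] / ([Hb] + [HbO2])`, in arbitrary units (uncalibrated
  system), restricted to voxels whose total haemoglobin signal exceeds a
  noise floor.
* **Vessel segmentation & volumetry.** Moment-preserving (Tsai)
  histogram thresholding of the 800 nm (isosbestic) volume — the
  binarisation preserving the first three raw moments m1, m2, m3, cut at
  the below-fraction `p0 = (z1 - m1)/(z1 - z0)` — then
  `volume = n_voxels x voxel volume` (3.2e-4 mm³ per 80 x 80 x 50 µm
  voxel).
* **Occlusion dynamics.** From an sO2 time series with cuff events:
  baseline (pre-cuff mean), occlusion minimum, post-release maximum.
* **Mosaics.** Maximum-intensity depth projections stitched by
  normalised cross-correlation with reliability flags (qualitative use).
* **Cohort tables.** Median (IQR) per group and two-sided Mann–Whitney U
  (exact enumeration or tie-corrected asymptotic), at finger level or as
  the mean of eight fingers; SSc subgroup rows are descriptive only.

## Worked example

A two-artery phantom finger (2 x 2 x 1 cm field of view), analysed by the
single-cube pipeline:

```r
library(msotfinger)

g <- voxel_geometry(c(64, 64, 40), 20000/64, 10000/40)   # reduced grid
vessels <- list(
  vessel_spec(c(0, 8, 4),  c(20, 8, 4),  0.95, hb = 0.62, hbo2 = 0.38),
  vessel_spec(c(0, 12, 5), c(20, 12, 5), 0.85, hb = 0.62, hbo2 = 0.38))
ph <- make_finger_phantom(phantom_spec(g, vessels, noise_sigma = 12, seed = 7))
ph$truth$total_vessel_volume_mm3
#> [1] 100.0342

bg <- array(FALSE, g$shape); bg[, , 31:40] <- TRUE   # vessel-free depths
res <- analyse_finger_cube(ph$cube, background_region = bg)
res$volume
#> vascular volume: 95.3 mm^3 (3903 voxels x 0.0244141 mm^3)
res$mean_so2
#> [1] 0.4118823
```

The segmented volume (95.3 mm³) recovers the 100.0 mm³ ground truth to
within the voxelisation/threshold error at this grid; the mean sO2 over
noise-floor-masked voxels (0.412 vs the true 0.38) carries the documented
upward noise bias that cancels in group comparisons (see the methods
vignette).

A full seeded cohort study (32 healthy controls, 22 SSc with true sO2
shifted down by 0.008), producing the three results-table-shaped CSVs:

```r
res <- run_demo_study(seed = 1, outdir = "runs/demo")
writeLines(format_comparison_table(res$tables$baseline_so2))
#> metric: baseline_so2 (mean_of_8)
#> HC_vs_SSc    HC           n=32  0.411 (0.404-0.417)  p=7e-04*
#> HC_vs_SSc    SSc          n=22  0.400 (0.393-0.405)  p=7e-04*
#> SSc_subgroups SSc_isch     n=6   0.395 (0.388-0.409)
#> SSc_subgroups SSc_no_isch  n=16  0.402 (0.395-0.405)
#> *p < 0.05 is significant; subgroup rows are descriptive only
```

The SSc median sits below the healthy-control median with a significant
two-sided Mann–Whitney p, reproducing the shape of the study's baseline
oxygenation table; re-running with the same seed reproduces every CSV
bit-for-bit (checksums in `runs/demo/manifest.json`).

The same stages are scriptable from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "msotfinger.R", package = "msotfinger"))')
Rscript "$CLI" run-all --out runs/demo --seed 1
Rscript "$CLI" segment --in cube.txt --out seg        # mask + volume CSV
```

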