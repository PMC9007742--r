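# opmtools

Image processing for single-objective oblique-plane light-sheet
microscopy (OPM), in R.

An oblique-plane microscope illuminates the sample with a light sheet
tilted by an angle θ (typically 45°) relative to the coverslip and
detects fluorescence from that same plane through a single objective,
while the stage (or a galvo) scans the sample laterally. The raw data —
camera frames indexed (scan position *s*, row *y*, column *x′*) — live on
a sheared lattice: a sample at (s, y, x′) sits at world coordinates

    x = s·Δs + σ·x′·p·cosθ,   y = y·p,   z = x′·p·sinθ

with scan step Δs, pixel size p, and σ = ±1 for the two mirrored
illumination views. `opmtools` implements the full computational chain
that turns such stacks into clean, drift-free, dual-view-fused volumes,
plus the synthetic forward models needed to validate every step against
known ground truth:

* **geometry** — `deskew()`, `forward_sample()`, `flip_view()`,
  `resample_to()`
* **synthesis** — `make_bead_phantom()`, `make_two_view_scene()`
  (Beer–Lambert attenuation along each view's illumination path, opaque
  occluders casting hard shadows), `make_drift_series()`
* **PSF characterization** — `detect_beads()`, `fit_psf()` (1D Gaussian
  fits along the tilted principal axes x″, y, z″), `summarize_psf()`
* **restoration** — `dehaze()` (iterated lower-envelope background
  removal), `correct_illumination()` (Gaussian sheet profile along y)
* **registration** — `phase_correlation()` (3D, subvoxel by locally
  upsampled DFT), `multiscale_warp_register()` (iterative chunked warp:
  2^i chunks per axis at iteration i, translation per chunk,
  spline-interpolated vector field), `apply_warp()`
* **fusion** — `compute_blend_map()` (Sobel-gradient quality metric,
  feathered argmax selection), `fuse_views()`
* **stabilization** — `pairwise_shifts()` (each time point against its
  2n neighbors), `solve_trajectory()` (L1-robust inversion of the band
  system R = M·A by IRLS), `stabilize_series()`
* **scan timing** — `scan_timing()`, `residual_blur()`,
  `simulate_scan()`, `acquisition_rate()` for light-sheet stabilized
  stage scanning (a galvo cancels stage motion during each exposure)
* **interface** — multi-page 16-bit TIFF with JSON sidecars
  (`read_stack()`, `write_volume()`, ...), a zarr-v2-compatible chunked
  store (`write_chunked_store()`), `run_pipeline()`, and a thin CLI
  (`exec/opmtools`)

## Worked example

Characterize the point-spread function of a noisy synthetic bead field
generated at the instrument's calibration pixel size:

```r
library(opmtools)

spec <- bead_phantom_spec(12, fwhm_um = c(0.480, 0.379, 1.865),
                          psf_tilt_deg = 20, min_separation_voxels = 30,
                          noise_model = "poisson", background_counts = 50,
                          peak_counts = 1000, seed = 11)
ph  <- make_bead_phantom(spec, shape = c(140, 180, 180),
                         voxel_size_um = c(0.103, 0.146, 0.146))
summarize_psf(characterize_psf(ph$volume, threshold = 300))
#> <psf_summary> n = 7 beads, tilt 20.0 deg
#>   FWHM x'': 485.2 +/- 10.9 nm
#>   FWHM y'': 384.6 +/- 15.6 nm
#>   FWHM z'': 1870.7 +/- 11.7 nm
```

The fitted widths recover the generator's FWHM (480, 379, 1865 nm) to
about 1% and the 20° tilt of the PSF's long axis exactly; flagged fits
(e.g. overlapping beads) are excluded from the summary automatically.

Scan-timing bookkeeping for a 2 mm stage scan at the stored axial
sampling of 1.806 µm per frame:

```r
tm <- scan_timing(exposure_ms = 5, readout_ms = 5,
                  stage_speed_um_per_s = 180.6)
acquisition_rate(tm, scan_range_um = 2000)
#> $n_frames
#> [1] 1108
#> $scan_step_um
#> [1] 1.806
#> $seconds_per_volume
#> [1] 11.08
#> $duty_cycle
#> [1] 0.5
```

A full dual-view pipeline run — deskew both views, mirror and register
view 2 onto view 1, fuse by local sharpness, stabilize over time — is a
single call, `run_pipeline(pipeline_config(...), time_points)`; see
`?run_pipeline` and the vignette in `vignettes/` for the model behind
each stage.

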