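---
title: "Processing oblique-plane light-sheet data with opmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing oblique-plane light-sheet data with opmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmtools)
```

## The imaging geometry

A single-objective oblique-plane microscope illuminates the sample with a
light sheet tilted by an angle $\theta$ (typically 45°) with respect to the
coverslip and detects fluorescence from that same oblique plane through one
objective. Raw data arrive as a stack of camera frames indexed by scan
position $s$, camera row $y$ and column $x'$, where $x'$ runs along the
sheet-propagation direction. A camera sample maps to world (coverslip)
coordinates as

$$x = s\,\Delta s + \sigma\, x' p \cos\theta,\qquad
  y = y\,p,\qquad
  z = x' p \sin\theta,$$

with $\Delta s$ the scan step, $p$ the camera pixel size at sample space and
$\sigma = \pm 1$ for the two illumination views. `deskew()` inverts this map
by trilinear interpolation onto an orthogonal $(z, y, x)$ grid; the default
output voxel is $(p\sin\theta,\; p,\; \Delta s)$, which makes the resampling
volume-preserving (the camera sampling lattice has cell volume
$\Delta s \cdot p \cdot p\sin\theta$). Any other grid can be requested.
`forward_sample()` implements the same map in the forward direction and is
the workhorse of every synthetic test: anything the pipeline claims to
recover was first placed into a world volume and pushed through this model.

The stored axial voxel of real acquisitions reflects whatever resampling the
operator chose; we default to $p\sin\theta$ because it neither invents nor
discards axial information relative to the camera sampling.

Dual-view acquisition alternates the sheet between $+\theta$ and $-\theta$.
The optical image-flipping module mirrors the second view's recorded image,
so the synthetic view-2 stream is generated as the oblique sampling of the
x-mirrored scene; processing then mirrors it back (`flip_view()`, an exact
involution with world-coordinate bookkeeping) after deskewing, leaving only
genuine sample-induced misregistration for the warp registration to remove.

## What the generators emulate — and what they do not

`make_bead_phantom()` renders sub-diffraction beads as anisotropic 3D
Gaussians with exactly the requested FWHM along tilted principal axes
$(x'', y, z'')$ — the measured point-spread function of this instrument
class has its long axis $z''$ tilted about 20° from the optical axis, with
FWHM defaults of 480, 379 and 1865 nm. Poisson counting noise and Gaussian
read noise are available; the defaults (peak 1000 counts over a background
of 100) put single beads at a signal-to-noise ratio of roughly 30.

`make_two_view_scene()` adds the two optical nuisances dual illumination is
meant to defeat: Beer–Lambert attenuation $e^{-\mu L}$ along each view's
entry path (the path length $L$ is computed analytically to the entry
boundary along the $\pm\theta$ sheet direction) and opaque ellipsoidal
occluders casting hard shadows (marched at one voxel-diagonal per step).
Hard, binary shadows make the fusion assertions unambiguous.

`make_drift_series()` translates a fixed template by a known trajectory.
Two choices deserve comment. First, the template is tapered to zero at the
volume faces: a drifting sample carries its entire neighborhood with it, so
a physically sensible drift fixture must not contain bright static edges.
Second, subvoxel shifts use Fourier (sinc) interpolation: the trilinear
kernel's blur varies with the fractional shift phase, which biases even an
ideal shift estimator by a few tenths of a voxel and would make honest
sub-0.1-voxel stabilization assertions impossible against this generator.

None of the generators model diffraction, refraction, scattering beyond
single-path absorption, or camera-specific artifacts. Passing tests
therefore demonstrate the correctness of the *computational* chain under
known geometry and noise, not the performance of the instrument on tissue.

## Restoration

`dehaze()` estimates the large-scale background (scattered illumination and
out-of-focus light) as a lower envelope — greyscale opening with a box
element of half-width `scale_voxels` (default 40), then Gaussian smoothing
at half that scale — and subtracts it, clamping at zero. The operator is
monotone under intensity scaling, idempotent within ~2%, and preserves
structures much smaller than the scale. Only the goal of dehazing is
fixed by the method; the envelope estimator itself is this package's
choice (one scale parameter, separable, predictable).

`correct_illumination()` divides out the known Gaussian light-sheet profile
along $y$; the width is a calibration input, not estimated from data. The
division is clamped where the profile falls below `epsilon` (default 0.05)
and the clamped planes are reported.

## Registration

`phase_correlation()` maximizes the inverse transform of the normalized
cross-power spectrum. Two accuracy-critical details:

* **Subvoxel refinement.** The correlation is re-evaluated on a locally
  upsampled grid (matrix DFT in a ±1 voxel window, default 1/20 voxel)
  around the integer peak. A three-point parabolic fit is also available
  (`refine = "parabola"`), but its bias on sharp or resampled content —
  up to a few tenths of a voxel — is incompatible with sub-0.1-voxel
  stabilization targets, so the upsampled evaluation is the default.
* **Windowing.** Inside the multi-scale registration, chunks are Hann
  windowed before the FFT to suppress leakage from non-periodic chunk
  boundaries; direct calls default to no window so that integer circular
  shifts are recovered exactly.

`multiscale_warp_register()` follows the iterative chunked scheme: at
iteration $i$ each axis is divided into $2^i$ chunks (a dyadic pyramid;
`2*i` selectable), chunk pairs are registered with a translation model,
accepted vectors form a node field that is spline-interpolated to full
resolution and composed with the running field, and the moving volume is
re-warped before the next refinement. Iteration stops at `max_iterations`
(default 4) or once chunks would fall below 32 voxels per axis; volumes too
small to split at all are registered globally as one chunk. Chunks overlap
by 25% per axis to stabilize edge vectors.

Per-chunk confidence is the correlation peak value. Because the peak of a
whitened correlation — for genuine matches and for unrelated content alike —
shrinks roughly as $1/\sqrt{N}$ with chunk size $N$, the acceptance floor is
referenced to a $32^3$ chunk (default 0.02) and scaled by
$\sqrt{32^3/N}$. Rejected and low-variance chunks receive vectors
interpolated from accepted neighbors (inverse-distance weighting); if no
chunk is accepted the registration aborts with a diagnostic.

`apply_warp()` warps backward — the output at $x$ samples the moving image
at $x + F(x)$ — with the node field upsampled by natural cubic splines
(linear when fewer than 4 nodes per axis, constant extrapolation beyond the
node range). A zero field is a bit-exact identity. Backward warping with
cubic node interpolation is the conventional choice here because it makes
field composition and approximate inversion straightforward.

## Fusion

The blend map compares per-view quality $q_v$, the Gaussian-smoothed
(default $\sigma = 8$ voxels) magnitude of the 3D Sobel gradient. The
fused image picks regions from whichever view is locally sharper:
selection is binary ($w_1 = [q_1 \ge
q_2]$, exact ties 0.5) and then feathered with a Gaussian (default
$\sigma = 4$ voxels); because feathering is linear and edge-renormalized,
the two weights sum to exactly one at every voxel, and the fused image
$w_1 v_1 + w_2 v_2$ is pointwise bounded by the two views. The smoothing
scales are declared package defaults, not calibrated constants.
Frequency-domain fusion variants are out of scope.

## Temporal stabilization

Each time point is phase-correlated against its $2n$ nearest neighbors
(default $n = 7$, clipped at the series ends). The relative measurements
$R$ relate to the absolute trajectory $A$ through the band system
$R = M A$, each row carrying $-1$ at $t$ and $+1$ at $t+k$. The system is
solved per axis (it is separable) by iteratively reweighted least squares —
50 iterations, residual smoothing $10^{-6}$ — which minimizes the $L_1$ norm
of the residuals. The robust criterion is interpreted as $L_1$ data
fidelity, not as a sparsity penalty on $A$: the stated motivation is noisy
relative measurements, and a handful of grossly wrong pairwise shifts should
not corrupt the whole trajectory (the plain least-squares inversion, kept as
`method = "l2"`, demonstrably does get corrupted at a 10% outlier rate).
The gauge is fixed by anchoring the first frame at zero — stabilization
compensates drift relative to the start of the series. Phase-correlation
confidences pre-weight the rows.

`stabilize_series()` applies $-A_t$ per frame, by Fourier shift by default
(sharpness-preserving; integer shifts reduce to exact rolls) with a
trilinear option.

## Scan-timing simulation

During each exposure the galvo translates the light sheet at
`galvo_rate_um_per_s` while the stage moves continuously; the residual blur
is $|v_\text{stage} - v_\text{galvo}|\, t_\text{exp}$, identically zero when
the rates match, and $v_\text{stage} t_\text{exp}$ without compensation. The
galvo returns during readout (modeled as a raised cosine; only its
completion before the next exposure matters, the shape is cosmetic) and the
effective scan step is $v_\text{stage}$ times the frame period. A ±150 µm
galvo excursion limit triggers a warning. Simulator defaults are
illustrative; match them to the camera at hand for real planning.

## Numerical choices and degenerate inputs

* Tilt angles of exactly 0° or 90° are rejected (degenerate shear).
* Trilinear interpolation returns 0 outside the support (images) or clamps
  at the edge (field evaluation); exact integer positions reproduce stored
  values bit-exactly, which is what makes zero-field warps and zero-shift
  translations exact identities.
* Constant volumes phase-correlate to zero shift with zero confidence.
* Full-volume warping and field composition run in ~2-million-voxel slabs,
  bounding temporary memory on large volumes.
* Bead fits flag any axis whose 1D Gaussian fit has $r^2 < 0.9$ (a package
  default: bead averages should not be dragged by failed fits)
  and summaries use unflagged records only. The in-plane tilt is estimated
  from the second moments of the connected 25%-of-peak core around the
  detected peak, which is exact for a truncated Gaussian and robust to
  noise spikes and to neighboring beads reaching into crop corners.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script size their fixtures to what the
assertions need rather than to instrument scale: bead fields of 12 beads in
a $140 \times 180 \times 180$ volume at the PSF-calibration pixel size
(0.146 µm laterally), registration phantoms of $96^3$ for translations and
$256^3$ for the smooth sinusoidal warp (amplitude 4 voxels, wavelength 128),
drift series of 50 time points for the solver and 8 for image round trips,
and a $48 \times 64 \times 64$ two-view occlusion scene. These choices keep
a full run on a single CPU within minutes while leaving every quantitative
target at its stated tolerance.

## Known limitations

* Attenuation in the scene generator is anchored to the volume grid, so a
  drifting scene should be rendered by translating the truth before
  illumination (as the drift fixtures do), not by drifting the lit volume.
* The chunked warp model is translation-only per chunk; rotations or
  shears within a chunk are approximated piecewise.
* Registration confidence separates matches from garbage reliably only for
  textured content; uniform regions rely on neighbor interpolation.
* The pipeline assumes the two views differ by the mirror plus a smooth
  warp; gross view misalignment beyond ~10% of the volume extent should be
  corrected with a global translation first.
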