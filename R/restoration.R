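# Restoration: removal of large-scale background light (dehazing) and
# flat-fielding of the Gaussian light-sheet profile along y.

#' Remove large-scale background light (dehaze)
#'
#' Estimates a smooth lower envelope of the image -- greyscale opening
#' with a box element of half-width `scale_voxels` followed by Gaussian
#' smoothing at `scale_voxels / 2` -- and subtracts it, clamping at 0.
#' The envelope step is iterated to convergence (the smoothing slightly
#' under-tracks curved backgrounds, so a single pass leaves a small
#' smooth residue; iterating makes the operator idempotent in practice).
#' The scale should be much larger than the feature size so that real
#' structures (beads, nuclei) survive while scattered and out-of-focus
#' light is removed.
#'
#' @param volume an [ortho_volume()] or 3D array.
#' @param scale_voxels envelope scale in voxels (> 0). Default 40.
#' @param tol stop iterating once an envelope pass removes less than
#'   this fraction of the remaining RMS. Default 0.005.
#' @param max_passes upper bound on envelope iterations. Default 10.
#' @return same class as the input, everywhere `>= 0` and `<= input`.
#' @export
dehaze <- function(volume, scale_voxels = 40, tol = 0.005, max_passes = 10L) {
  if (scale_voxels <= 0) stop("scale_voxels must be > 0")
  v <- vol_data(volume)
  r <- pmin(ceiling(scale_voxels), dim(v) - 1L)
  out <- v
  for (pass in seq_len(max_passes)) {
    background <- gaussian_smooth(grey_opening(out, r), scale_voxels / 2)
    out <- pmax(out - background, 0)
    if (sqrt(mean(background^2)) < tol * max(sqrt(mean(out^2)),
                                             .Machine$double.eps)) break
  }
  if (inherits(volume, "ortho_volume")) {
    ortho_volume(out, volume$voxel_size_um, volume$origin_um)
  } else {
    out
  }
}

#' Correct the Gaussian light-sheet illumination profile along y
#'
#' Divides each y plane by the normalized Gaussian profile value at that
#' y. Planes where the profile falls below `epsilon` are scaled by at
#' most `1/epsilon` and reported in the `"clamped_y_planes"` attribute
#' rather than amplified without bound.
#'
#' @param volume an [ortho_volume()].
#' @param profile a [light_sheet_profile()].
#' @param epsilon clamp floor for the profile denominator (> 0).
#'   Default 0.05.
#' @return the corrected [ortho_volume()].
#' @export
correct_illumination <- function(volume, profile, epsilon = 0.05) {
  stopifnot(inherits(volume, "ortho_volume"),
            inherits(profile, "light_sheet_profile"), epsilon > 0)
  y_um <- vol_axis_um(volume, 2L)
  gvals <- profile_values(profile, y_um)
  gvals <- gvals / max(gvals)
  denom <- pmax(gvals, epsilon)
  d <- dim(volume$data)
  out <- volume$data / rep(rep(denom, each = d[1L]), times = d[3L])
  res <- ortho_volume(out, volume$voxel_size_um, volume$origin_um)
  attr(res, "clamped_y_planes") <- which(gvals < epsilon)
  res
}
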