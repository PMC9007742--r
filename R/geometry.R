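# Acquisition geometry and the deskew transform between the oblique camera
# frame (s, y, x') and coverslip-aligned world coordinates (x, y, z).
#
# World frame: right-handed, z = optical axis (depth, 0 at the coverslip),
# x = scan axis, y = sheet-width axis. A camera sample at scan index s,
# row y, column x' (all 0-based) sits at
#   x = scan_origin + s * scan_step + sigma * x' * pixel * cos(theta)
#   y = y * pixel
#   z = x' * pixel * sin(theta)
# where theta is the light-sheet tilt and sigma = +1 for view 1, -1 for
# view 2 (the image-flipping module mirrors the propagation direction).

#' Acquisition geometry for an oblique light-sheet stack
#'
#' Describes how raw camera frames relate to world coordinates: the
#' light-sheet tilt relative to the coverslip, the scan step between
#' frames, the camera pixel size at sample space, the scan mode and
#' which of the two illumination views the stack belongs to.
#'
#' @param scan_step_um stage/galvo step along the scan (x) axis between
#'   consecutive frames, micrometres.
#' @param pixel_size_um camera pixel size at sample space, micrometres
#'   (typical values 0.146, 0.265, 0.440).
#' @param tilt_angle_deg light-sheet angle with respect to the coverslip
#'   plane, degrees; strictly between 0 and 90. Default 45.
#' @param scan_mode `"stage"` or `"galvo"`.
#' @param view_id 1 or 2; view 2 is illuminated from the mirrored direction.
#' @param frame_shape integer c(rows = y, cols = x') of one camera frame,
#'   or NULL to take it from the data.
#' @param scan_origin_um world x coordinate of scan position s = 0.
#'   Default 0; synthetic forward sampling sets it so the scan covers a
#'   target volume.
#' @return an object of class `acq_geometry`.
#' @export
#' @examples
#' g <- acq_geometry(scan_step_um = 0.8, pixel_size_um = 0.146)
#' g$tilt_angle_deg
acq_geometry <- function(scan_step_um, pixel_size_um, tilt_angle_deg = 45,
                         scan_mode = c("stage", "galvo"), view_id = 1L,
                         frame_shape = NULL, scan_origin_um = 0) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(is.numeric(tilt_angle_deg), length(tilt_angle_deg) == 1L,
            is.numeric(scan_step_um), length(scan_step_um) == 1L,
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L)
  if (!(tilt_angle_deg > 0 && tilt_angle_deg < 90)) {
    stop("tilt_angle_deg must lie strictly between 0 and 90 degrees")
  }
  if (scan_step_um <= 0) stop("scan_step_um must be > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (!view_id %in% c(1L, 2L)) stop("view_id must be 1 or 2")
  if (!is.null(frame_shape)) {
    stopifnot(length(frame_shape) == 2L, all(frame_shape >= 1))
    frame_shape <- as.integer(frame_shape)
  }
  structure(list(tilt_angle_deg = tilt_angle_deg,
                 scan_step_um = scan_step_um,
                 pixel_size_um = pixel_size_um,
                 scan_mode = scan_mode,
                 view_id = as.integer(view_id),
                 frame_shape = frame_shape,
                 scan_origin_um = scan_origin_um),
            class = "acq_geometry")
}

view_sign <- function(geometry) if (geometry$view_id == 1L) 1 else -1

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    "<acq_geometry> view %d (%s scan): tilt %g deg, step %g um, pixel %g um\n",
    x$view_id, x$scan_mode, x$tilt_angle_deg, x$scan_step_um, x$pixel_size_um))
  invisible(x)
}

#' Raw oblique stack of camera frames
#'
#' Wraps a 3D array of nonnegative intensity counts indexed
#' (scan position s, row y, column x') together with its acquisition
#' geometry.
#'
#' @param data 3D numeric array, dimensions (n_frames, rows, cols),
#'   nonnegative and finite.
#' @param geometry an [acq_geometry()].
#' @return an object of class `oblique_stack` with elements `data`,
#'   `geometry` and `n_frames`.
#' @export
oblique_stack <- function(data, geometry) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(geometry, "acq_geometry"))
  if (!all(is.finite(data))) stop("stack intensities must be finite")
  if (any(data < 0)) stop("stack intensities must be nonnegative")
  d <- dim(data)
  if (is.null(geometry$frame_shape)) {
    geometry$frame_shape <- d[2:3]
  } else if (!all(geometry$frame_shape == d[2:3])) {
    stop("data shape does not match geometry$frame_shape")
  }
  structure(list(data = data, geometry = geometry, n_frames = d[1L]),
            class = "oblique_stack")
}

#' @export
print.oblique_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oblique_stack> %d frames of %d x %d (y, x'), view %d\n",
              d[1L], d[2L], d[3L], x$geometry$view_id))
  invisible(x)
}

#' Coverslip-aligned orthogonal volume
#'
#' A deskewed volume on an orthogonal (z, y, x) grid with voxel sizes in
#' micrometres and a world-coordinate origin for voxel (1, 1, 1).
#'
#' @param data 3D numeric array indexed (z, y, x); finite.
#' @param voxel_size_um numeric c(vz, vy, vx) > 0.
#' @param origin_um numeric c(z0, y0, x0) world offset of the first voxel.
#' @return an object of class `ortho_volume`.
#' @export
ortho_volume <- function(data, voxel_size_um, origin_um = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(voxel_size_um) == 3L, length(origin_um) == 3L)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin_um)),
            class = "ortho_volume")
}

#' @export
print.ortho_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ortho_volume> %d x %d x %d (z, y, x), voxel %s um\n",
              d[1L], d[2L], d[3L],
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  invisible(x)
}

# World y/z coordinate vectors of a volume's voxel centers
vol_axis_um <- function(vol, axis) {
  d <- dim(vol$data)[axis]
  vol$origin_um[axis] + (seq_len(d) - 1) * vol$voxel_size_um[axis]
}

#' Deskew an oblique stack onto the coverslip-aligned grid
#'
#' Resamples the raw camera frames, acquired along oblique planes tilted
#' by the light-sheet angle, onto an orthogonal (z, y, x) voxel grid.
#' The default output voxel is (pixel * sin(theta), pixel, scan_step);
#' voxels outside the sampled oblique support are 0. For view 2 the
#' in-plane axis runs against the scan axis and the returned origin
#' accounts for the negative x extent.
#'
#' On the default-aligned grid every output voxel coincides with a
#' camera row and column exactly and only the scan coordinate is
#' fractional; that single axis is then interpolated with a cubic
#' (Catmull-Rom) kernel, whose response varies far less with the
#' fractional phase than a linear one and so leaves much weaker
#' resampling texture. Off-grid targets fall back to trilinear
#' interpolation.
#'
#' @param stack an [oblique_stack()].
#' @param target_voxel_um optional c(vz, vy, vx) output voxel sizes.
#' @return an [ortho_volume()].
#' @export
#' @examples
#' g <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, frame_shape = c(8, 8))
#' st <- oblique_stack(array(1, c(6, 8, 8)), g)
#' deskew(st)
deskew <- function(stack, target_voxel_um = NULL) {
  stopifnot(inherits(stack, "oblique_stack"))
  geom <- stack$geometry
  theta <- geom$tilt_angle_deg * pi / 180
  p <- geom$pixel_size_um
  ds <- geom$scan_step_um
  so <- geom$scan_origin_um
  sg <- view_sign(geom)
  d <- dim(stack$data)                    # (ns, ny, nxp)
  ns <- d[1L]; ny <- d[2L]; nxp <- d[3L]

  if (is.null(target_voxel_um)) {
    target_voxel_um <- c(p * sin(theta), p, ds)
  }
  stopifnot(length(target_voxel_um) == 3L, all(target_voxel_um > 0))
  vz <- target_voxel_um[1L]; vy <- target_voxel_um[2L]; vx <- target_voxel_um[3L]

  xp_reach <- sg * (nxp - 1) * p * cos(theta)
  x_min <- so + min(0, xp_reach)
  x_max <- so + (ns - 1) * ds + max(0, xp_reach)
  z_max <- (nxp - 1) * p * sin(theta)
  y_max <- (ny - 1) * p

  nz <- floor(z_max / vz + 1e-9) + 1
  nyo <- floor(y_max / vy + 1e-9) + 1
  nx <- floor((x_max - x_min) / vx + 1e-9) + 1

  zw <- (seq_len(nz) - 1) * vz
  yw <- (seq_len(nyo) - 1) * vy
  xw <- x_min + (seq_len(nx) - 1) * vx

  # invert the forward map for every output voxel
  xp_i <- zw / (p * sin(theta)) + 1          # depends on z only
  y_i  <- yw / p + 1                         # depends on y only
  # s index depends on (z, x): s = (x - so - sigma*z/tan(theta)) / ds
  s_zx <- outer(-sg * zw / tan(theta), xw - so, "+") / ds + 1   # nz x nx

  aligned <- max(abs(xp_i - round(xp_i))) < 1e-9 &&
    max(abs(y_i - round(y_i))) < 1e-9 &&
    max(round(xp_i)) <= nxp && max(round(y_i)) <= ny
  if (aligned) {
    # shear-aligned: cubic interpolation along the scan axis only
    out <- array(0, c(nz, nyo, nx))
    pad <- 3L                                 # s = 0 maps to padded row 3
    for (iz in seq_len(nz)) {
      S <- stack$data[, seq_len(nyo), round(xp_i[iz])]   # ns x ny
      Spad <- rbind(matrix(0, 2L, nyo), S, matrix(0, 2L, nyo))
      s_pos <- s_zx[iz, ] - 1                 # 0-based fractional scan pos
      s0 <- floor(s_pos)
      wts <- cr_weights(s_pos - s0)           # nx x 4
      acc <- matrix(0, nx, nyo)
      for (k in 0:3) {
        rows <- pmin(pmax(s0 - 1L + k + pad, 1L), ns + 4L)
        acc <- acc + wts[, k + 1L] * Spad[rows, , drop = FALSE]
      }
      out[iz, , ] <- t(acc)
    }
  } else {
    i1 <- aperm(array(s_zx, c(nz, nx, nyo)), c(1L, 3L, 2L))
    i2 <- array(rep(y_i, each = nz), c(nz, nyo, nx))
    i3 <- array(xp_i, c(nz, nyo, nx))
    out <- array(interp3(stack$data, as.vector(i1), as.vector(i2),
                         as.vector(i3)), c(nz, nyo, nx))
  }
  ortho_volume(out, target_voxel_um, origin_um = c(0, 0, x_min))
}

# Scan origin and frame count needed for a scan to cover `vol` fully
frames_to_cover <- function(vol, geometry) {
  theta <- geometry$tilt_angle_deg * pi / 180
  sg <- view_sign(geometry)
  x_rng <- range(vol_axis_um(vol, 3L))
  z_rng <- range(vol_axis_um(vol, 1L))
  corners <- outer(x_rng, -sg * z_rng / tan(theta), "+")
  so <- min(corners)
  n_frames <- floor((max(corners) - so) / geometry$scan_step_um + 1e-9) + 1
  list(scan_origin_um = so, n_frames = as.integer(n_frames))
}

#' Sample a volume along oblique planes (synthetic forward model)
#'
#' Inverse of [deskew()]: produces the raw camera stack a scan of the
#' given geometry would record from a known world volume, sampling the
#' volume by trilinear interpolation along each oblique plane. Samples
#' falling outside the volume are 0. By default the scan origin and
#' frame count are chosen to cover the volume completely (the scan
#' starts before the volume so that tilted planes reach every corner).
#'
#' @param volume an [ortho_volume()].
#' @param geometry an [acq_geometry()]; `frame_shape` defaults to the
#'   smallest frame covering the volume's y and z extents.
#' @param n_frames optional number of scan positions; default covers the
#'   volume given `geometry$scan_origin_um` (which itself defaults to
#'   the covering origin rather than 0).
#' @return an [oblique_stack()].
#' @export
forward_sample <- function(volume, geometry, n_frames = NULL) {
  stopifnot(inherits(volume, "ortho_volume"), inherits(geometry, "acq_geometry"))
  theta <- geometry$tilt_angle_deg * pi / 180
  p <- geometry$pixel_size_um
  ds <- geometry$scan_step_um
  sg <- view_sign(geometry)
  vz <- volume$voxel_size_um[1L]; vy <- volume$voxel_size_um[2L]
  vx <- volume$voxel_size_um[3L]
  d <- dim(volume$data)

  if (is.null(geometry$frame_shape)) {
    z_span <- (d[1L] - 1) * vz
    y_span <- (d[2L] - 1) * vy
    geometry$frame_shape <- c(floor(y_span / p + 1e-9) + 1,
                              floor(z_span / (p * sin(theta)) + 1e-9) + 1)
  }
  cover <- frames_to_cover(volume, geometry)
  if (is.null(n_frames)) {
    geometry$scan_origin_um <- cover$scan_origin_um
    n_frames <- cover$n_frames
  }
  so <- geometry$scan_origin_um
  ny <- geometry$frame_shape[1L]; nxp <- geometry$frame_shape[2L]
  ns <- as.integer(n_frames)

  s_idx <- seq_len(ns) - 1
  y_idx <- seq_len(ny) - 1
  xp_idx <- seq_len(nxp) - 1

  zw <- xp_idx * p * sin(theta)
  yw <- y_idx * p
  # world x depends on (s, x'): so + s*ds + sigma * x' * p * cos(theta)
  x_sxp <- outer(so + s_idx * ds, sg * xp_idx * p * cos(theta), "+") # ns x nxp

  i1 <- array(rep((zw - volume$origin_um[1L]) / vz + 1, each = ns * ny),
              c(ns, ny, nxp))
  i2 <- array(rep((yw - volume$origin_um[2L]) / vy + 1, each = ns),
              c(ns, ny, nxp))
  i3 <- aperm(array((x_sxp - volume$origin_um[3L]) / vx + 1,
                    c(ns, nxp, ny)), c(1L, 3L, 2L))

  out <- interp3(volume$data, as.vector(i1), as.vector(i2), as.vector(i3))
  oblique_stack(array(out, c(ns, ny, nxp)), geometry)
}

#' Mirror a volume along the scan (x) axis
#'
#' The dual-view image-flipping module mirrors view 2 with respect to
#' view 1 along x; applying this to a deskewed view-2 volume brings it
#' into the view-1 frame up to residual misregistration. The world x
#' coordinate maps to -x (origin updated accordingly), so the operation
#' is an exact involution.
#'
#' @param volume an [ortho_volume()].
#' @return the mirrored [ortho_volume()].
#' @export
flip_view <- function(volume) {
  stopifnot(inherits(volume, "ortho_volume"))
  d <- dim(volume$data)
  data <- volume$data[, , rev(seq_len(d[3L])), drop = FALSE]
  ox <- volume$origin_um[3L]
  new_ox <- -(ox + (d[3L] - 1) * volume$voxel_size_um[3L])
  ortho_volume(data, volume$voxel_size_um,
               c(volume$origin_um[1:2], new_ox))
}

#' Resample a volume onto a reference grid
#'
#' Trilinear resampling of `volume` onto the voxel grid (sizes, origin,
#' dimensions) of `reference`; world coordinates are preserved and
#' uncovered voxels are 0. Used to place two deskewed views on a common
#' grid before registration.
#'
#' @param volume an [ortho_volume()].
#' @param reference an [ortho_volume()] defining the target grid.
#' @return an [ortho_volume()] on the reference grid.
#' @export
resample_to <- function(volume, reference) {
  stopifnot(inherits(volume, "ortho_volume"), inherits(reference, "ortho_volume"))
  d <- dim(reference$data)
  g <- index_grid(d)
  w1 <- reference$origin_um[1L] + (g$i1 - 1) * reference$voxel_size_um[1L]
  w2 <- reference$origin_um[2L] + (g$i2 - 1) * reference$voxel_size_um[2L]
  w3 <- reference$origin_um[3L] + (g$i3 - 1) * reference$voxel_size_um[3L]
  vals <- interp3(volume$data,
                  (w1 - volume$origin_um[1L]) / volume$voxel_size_um[1L] + 1,
                  (w2 - volume$origin_um[2L]) / volume$voxel_size_um[2L] + 1,
                  (w3 - volume$origin_um[3L]) / volume$voxel_size_um[3L] + 1)
  ortho_volume(array(vals, d), reference$voxel_size_um, reference$origin_um)
}
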