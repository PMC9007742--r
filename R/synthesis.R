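# Synthetic data generators. Every generator is a pure function of its
# specification and seed, and returns ground truth alongside the data, so
# the whole processing chain can be exercised without any downloaded
# fixtures. Defaults mirror the instrument characterization: an
# anisotropic PSF with FWHM (480, 379, 1865) nm whose long axis is tilted
# about 20 degrees from the optical axis.

#' Specification of a bead-calibration phantom
#'
#' Describes a field of sub-diffraction beads rendered as anisotropic 3D
#' Gaussians whose long (z'') axis is rotated in the xz plane, emulating
#' the tilted point-spread function of an oblique-plane microscope.
#'
#' @param n_beads number of beads.
#' @param fwhm_um Gaussian FWHM c(x'', y, z'') in micrometres.
#'   Default `c(0.480, 0.379, 1.865)`, the instrument-scale values.
#' @param psf_tilt_deg rotation of the z'' axis from z in the xz plane,
#'   degrees in [0, 90). Default 20.
#' @param min_separation_voxels minimum pairwise bead distance in voxels.
#' @param peak_counts bead peak amplitude above background, counts.
#' @param background_counts constant background level, counts.
#' @param noise_model `"none"`, `"poisson"`, or `"gaussian"`.
#' @param gaussian_sd read-noise s.d. in counts (used when
#'   `noise_model = "gaussian"`, or added after Poisson if > 0).
#' @param seed integer seed fixing all randomness.
#' @return an object of class `bead_phantom_spec`.
#' @export
bead_phantom_spec <- function(n_beads, fwhm_um = c(0.480, 0.379, 1.865),
                              psf_tilt_deg = 20, min_separation_voxels = 16,
                              peak_counts = 1000, background_counts = 100,
                              noise_model = c("none", "poisson", "gaussian"),
                              gaussian_sd = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_beads >= 0, length(fwhm_um) == 3L, all(fwhm_um > 0),
            psf_tilt_deg >= 0, psf_tilt_deg < 90,
            min_separation_voxels >= 0, peak_counts > 0,
            background_counts >= 0, gaussian_sd >= 0)
  structure(list(n_beads = as.integer(n_beads), fwhm_um = as.numeric(fwhm_um),
                 psf_tilt_deg = psf_tilt_deg,
                 min_separation_voxels = min_separation_voxels,
                 peak_counts = peak_counts,
                 background_counts = background_counts,
                 noise_model = noise_model, gaussian_sd = gaussian_sd,
                 seed = as.integer(seed)),
            class = "bead_phantom_spec")
}

# Add one tilted anisotropic Gaussian bead to `vol` (in place semantics via
# return). Positions and widths in micrometres; center = c(z, y, x) um.
add_tilted_bead <- function(vol, voxel_size_um, center_um, fwhm_um,
                            tilt_deg, peak) {
  d <- dim(vol)
  phi <- tilt_deg * pi / 180
  # per-axis reach of the rotated ellipsoid; 1.8 x FWHM ~ 4.2 sigma, so the
  # truncated tail is ~1e-4 of the peak
  reach <- 1.8 * (abs(cos(phi)) * c(fwhm_um[3L], fwhm_um[2L], fwhm_um[1L]) +
                  abs(sin(phi)) * c(fwhm_um[1L], 0, fwhm_um[3L]))
  lo <- pmax(1L, floor((center_um - reach) / voxel_size_um + 1))
  hi <- pmin(d, ceiling((center_um + reach) / voxel_size_um + 1))
  if (any(lo > hi)) return(vol)
  iz <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; ix <- lo[3L]:hi[3L]
  dz <- (iz - 1) * voxel_size_um[1L] - center_um[1L]
  dy <- (iy - 1) * voxel_size_um[2L] - center_um[2L]
  dx <- (ix - 1) * voxel_size_um[3L] - center_um[3L]
  nz <- length(iz); ny <- length(iy); nx <- length(ix)
  DZ <- array(dz, c(nz, ny, nx))
  DY <- array(rep(dy, each = nz), c(nz, ny, nx))
  DX <- aperm(array(rep(dx, each = nz), c(nz, nx, ny)), c(1L, 3L, 2L))
  xpp <- DX * cos(phi) - DZ * sin(phi)   # x'' coordinate
  zpp <- DX * sin(phi) + DZ * cos(phi)   # z'' coordinate
  g <- peak * exp(-4 * log(2) * ((xpp / fwhm_um[1L])^2 +
                                 (DY / fwhm_um[2L])^2 +
                                 (zpp / fwhm_um[3L])^2))
  vol[iz, iy, ix] <- vol[iz, iy, ix] + g
  vol
}

#' Generate a bead-calibration phantom volume
#'
#' Renders `spec$n_beads` tilted anisotropic Gaussian beads at uniformly
#' random positions (subject to a minimum separation and a border margin
#' sized to the bead reach) on a constant background, then applies the
#' requested noise model. Deterministic for a given spec and seed.
#'
#' @param spec a [bead_phantom_spec()].
#' @param shape integer c(nz, ny, nx) of the output volume.
#' @param voxel_size_um numeric c(vz, vy, vx) in micrometres.
#' @param border_margin_um bead centers keep this distance from the
#'   volume faces; default 2x the largest FWHM, i.e. half the standard
#'   4x-FWHM fit crop window, so generated beads are always croppable.
#' @return list with `volume` (an [ortho_volume()]) and `positions`
#'   (data.frame of true bead centers, columns `z_um`, `y_um`, `x_um`).
#' @export
#' @examples
#' ph <- make_bead_phantom(bead_phantom_spec(3, fwhm_um = c(0.4, 0.4, 0.8), seed = 7),
#'                         shape = c(48, 48, 48),
#'                         voxel_size_um = c(0.2, 0.2, 0.2))
#' nrow(ph$positions)
make_bead_phantom <- function(spec, shape, voxel_size_um,
                              border_margin_um = NULL) {
  stopifnot(inherits(spec, "bead_phantom_spec"), length(shape) == 3L,
            length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  shape <- as.integer(shape)
  d_um <- (shape - 1) * voxel_size_um
  if (is.null(border_margin_um)) border_margin_um <- 2 * max(spec$fwhm_um)
  margin_um <- rep_len(border_margin_um, 3L)
  if (spec$n_beads > 0 && any(d_um <= 2 * margin_um)) {
    stop("volume too small for the requested bead size and margin")
  }

  withr::with_seed(spec$seed, {
    pos <- matrix(NA_real_, spec$n_beads, 3L)   # (z, y, x) um
    if (spec$n_beads > 0) {
      placed <- 0L
      tries <- 0L
      max_tries <- 1000L * spec$n_beads
      while (placed < spec$n_beads) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop(sprintf(
            "bead packing failed: placed %d of %d beads after %d tries",
            placed, spec$n_beads, max_tries))
        }
        cand <- margin_um + stats::runif(3) * (d_um - 2 * margin_um)
        if (placed > 0L) {
          sep <- sqrt(colSums(((t(pos[seq_len(placed), , drop = FALSE]) - cand) /
                                 voxel_size_um)^2))
          if (min(sep) < spec$min_separation_voxels) next
        }
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
    }

    vol <- array(0, shape)
    for (b in seq_len(spec$n_beads)) {
      vol <- add_tilted_bead(vol, voxel_size_um, pos[b, ], spec$fwhm_um,
                             spec$psf_tilt_deg, spec$peak_counts)
    }
    vol <- vol + spec$background_counts

    if (spec$noise_model == "poisson") {
      vol <- array(stats::rpois(length(vol), lambda = vol), shape)
      if (spec$gaussian_sd > 0) {
        vol <- vol + array(stats::rnorm(length(vol), sd = spec$gaussian_sd), shape)
      }
    } else if (spec$noise_model == "gaussian") {
      vol <- vol + array(stats::rnorm(length(vol), sd = spec$gaussian_sd), shape)
    }
    vol <- pmax(vol, 0)
  })

  list(volume = ortho_volume(vol, voxel_size_um),
       positions = data.frame(z_um = pos[, 1L], y_um = pos[, 2L],
                              x_um = pos[, 3L]))
}

#' Gaussian light-sheet intensity profile along y
#'
#' @param sigma_y_um Gaussian waist (s.d.) of the illumination along the
#'   sheet-width axis, micrometres; > 0.
#' @param center_y_um center of the profile; NULL means the mid-plane of
#'   whatever volume the profile is applied to.
#' @return an object of class `light_sheet_profile`.
#' @export
light_sheet_profile <- function(sigma_y_um, center_y_um = NULL) {
  stopifnot(sigma_y_um > 0)
  structure(list(sigma_y_um = sigma_y_um, center_y_um = center_y_um),
            class = "light_sheet_profile")
}

profile_values <- function(profile, y_um) {
  c0 <- if (is.null(profile$center_y_um)) mean(range(y_um)) else profile$center_y_um
  exp(-(y_um - c0)^2 / (2 * profile$sigma_y_um^2))
}

#' Two-view scene phantom specification
#'
#' A known fluorophore distribution plus the optical nuisances the dual
#' illumination is meant to defeat: Beer-Lambert attenuation along each
#' view's illumination path and opaque occluders casting hard shadows.
#'
#' @param truth an [ortho_volume()] of true fluorophore density
#'   (nonnegative).
#' @param attenuation_mu_per_um absorption coefficient mu (per
#'   micrometre) for Beer-Lambert path loss; >= 0.
#' @param occluders list of opaque ellipsoids, each a list with
#'   `center_um` = c(z, y, x) and `radii_um` = c(rz, ry, rx).
#' @param seed integer seed (reserved for stochastic scene elements).
#' @return an object of class `scene_phantom`.
#' @export
scene_phantom <- function(truth, attenuation_mu_per_um = 0,
                          occluders = list(), seed = 1L) {
  stopifnot(inherits(truth, "ortho_volume"), attenuation_mu_per_um >= 0)
  if (any(truth$data < 0)) stop("truth must be nonnegative")
  for (oc in occluders) {
    stopifnot(length(oc$center_um) == 3L, length(oc$radii_um) == 3L,
              all(oc$radii_um > 0))
  }
  structure(list(truth = truth, attenuation_mu_per_um = attenuation_mu_per_um,
                 occluders = occluders, seed = as.integer(seed)),
            class = "scene_phantom")
}

# Transmission (attenuation x occluder shadow) for one view.
# Illumination propagates along (sigma*cos(theta), 0, sin(theta)): it enters
# at the z = 0 face (or the upstream x face) and advances into depth.
view_transmission <- function(phantom, geometry) {
  truth <- phantom$truth
  theta <- geometry$tilt_angle_deg * pi / 180
  sg <- view_sign(geometry)
  d <- dim(truth$data)
  zc <- vol_axis_um(truth, 1L)
  yc <- vol_axis_um(truth, 2L)
  xc <- vol_axis_um(truth, 3L)

  g <- index_grid(d)
  Z <- zc[g$i1]; Y <- yc[g$i2]; X <- xc[g$i3]

  # analytic in-medium path length from the entry boundary
  t_z <- (Z - zc[1L]) / sin(theta)
  t_x <- if (sg > 0) (X - xc[1L]) / cos(theta) else (xc[length(xc)] - X) / cos(theta)
  L <- pmin(t_z, t_x)
  trans <- exp(-phantom$attenuation_mu_per_um * L)

  # hard shadows: march back along the illumination direction
  if (length(phantom$occluders) > 0) {
    inside_any <- function(z, y, x) {
      hit <- rep(FALSE, length(z))
      for (oc in phantom$occluders) {
        hit <- hit | (((z - oc$center_um[1L]) / oc$radii_um[1L])^2 +
                      ((y - oc$center_um[2L]) / oc$radii_um[2L])^2 +
                      ((x - oc$center_um[3L]) / oc$radii_um[3L])^2) <= 1
      }
      hit
    }
    step <- sqrt(sum(truth$voxel_size_um^2))   # one voxel diagonal
    n_steps <- ceiling(max(L) / step)
    shadow <- rep(FALSE, length(Z))
    # emission inside an opaque occluder is also blocked
    blocked0 <- inside_any(Z, Y, X)
    for (k in seq_len(n_steps)) {
      t <- k * step
      act <- t <= L & !shadow
      if (!any(act)) break
      shadow[act] <- inside_any(Z[act] - t * sin(theta), Y[act],
                                X[act] - t * sg * cos(theta))
    }
    trans <- trans * as.numeric(!(shadow | blocked0))
  }
  array(trans, d)
}

#' Render a two-view oblique acquisition of a scene phantom
#'
#' For each view, the true fluorophore density is attenuated by
#' `exp(-mu * L)` where `L` is the in-medium path length from the
#' illumination entry side along the oblique sheet direction, occluders
#' cast hard shadows along that path, the result is sampled with
#' [forward_sample()] and finally weighted by the light-sheet y profile.
#' The image-flipping module of the dual-view optical path mirrors the
#' recorded view-2 image, so the view-2 stack is the oblique sampling of
#' the x-mirrored attenuated scene: [deskew()] followed by [flip_view()]
#' brings it back to the view-1 world frame.
#'
#' @param phantom a [scene_phantom()].
#' @param geometry1,geometry2 [acq_geometry()] objects for views 1 and 2;
#'   they must differ only in `view_id`.
#' @param profile optional [light_sheet_profile()] applied along y.
#' @return list with `view1`, `view2` ([oblique_stack()]s), `truth`, and
#'   the per-view attenuated world volumes `lit1`, `lit2`
#'   ([ortho_volume()]s) used to build them.
#' @export
make_two_view_scene <- function(phantom, geometry1, geometry2, profile = NULL) {
  stopifnot(inherits(phantom, "scene_phantom"))
  same <- c("tilt_angle_deg", "scan_step_um", "pixel_size_um", "scan_mode")
  for (f in same) {
    if (!identical(geometry1[[f]], geometry2[[f]])) {
      stop("view geometries must differ only in view_id")
    }
  }
  if (geometry1$view_id == geometry2$view_id) {
    stop("the two geometries must have different view_id")
  }

  render <- function(geom) {
    trans <- view_transmission(phantom, geom)
    lit <- ortho_volume(phantom$truth$data * trans,
                        phantom$truth$voxel_size_um, phantom$truth$origin_um)
    # the camera records view 2 mirrored by the image-flipping module
    st <- forward_sample(if (geom$view_id == 2L) flip_view(lit) else lit, geom)
    if (!is.null(profile)) {
      y_um <- (seq_len(dim(st$data)[2L]) - 1) * geom$pixel_size_um
      w <- profile_values(profile, y_um)
      st$data <- st$data * rep(w, each = dim(st$data)[1L])
    }
    list(stack = st, lit = lit)
  }
  v1 <- render(geometry1)
  v2 <- render(geometry2)
  list(view1 = v1$stack, view2 = v2$stack, truth = phantom$truth,
       lit1 = v1$lit, lit2 = v2$lit)
}

#' Generate a drifting time series with known trajectory
#'
#' A fixed template volume is translated per time point by a known
#' trajectory; subvoxel shifts use Fourier (sinc) interpolation, so
#' every frame keeps the template's sharpness and integer shifts reduce
#' to exact rolls. The default template is a field of lightly smoothed
#' random granules tapered to zero at the volume faces, so that the
#' translation moves every structure (a drifting sample carries its
#' whole field of view with it; fixed bright edges would not drift) and
#' circular wrap-around is negligible. Gross measurement outliers are
#' not injected here: they belong at the shift-measurement level (see
#' [corrupt_shifts()]).
#'
#' @param shape integer c(nz, ny, nx) of each frame.
#' @param n_timepoints number of frames T >= 2.
#' @param drift list: `list(type = "random_walk", sd = ...)` (per-axis
#'   step s.d., voxels) or `list(type = "linear", v = c(dz, dy, dx))`
#'   (voxels per frame).
#' @param seed integer seed fixing the template and the walk.
#' @param template optional [ortho_volume()] or array to drift instead of
#'   the generated one.
#' @return list with `series` (list of 3D arrays), `trajectory`
#'   (T x 3 matrix of true shifts, voxels, first row 0) and `template`.
#' @export
make_drift_series <- function(shape, n_timepoints, drift, seed = 1L,
                              template = NULL) {
  stopifnot(length(shape) == 3L, n_timepoints >= 2)
  shape <- as.integer(shape)
  drift_type <- match.arg(drift$type, c("random_walk", "linear"))

  withr::with_seed(as.integer(seed), {
    if (is.null(template)) {
      base <- array(0, shape)
      n_spots <- max(8L, prod(shape) %/% 1500L)
      idx <- cbind(sample.int(shape[1L], n_spots, replace = TRUE),
                   sample.int(shape[2L], n_spots, replace = TRUE),
                   sample.int(shape[3L], n_spots, replace = TRUE))
      base[idx] <- stats::runif(n_spots, 500, 1500)
      template <- gaussian_smooth(base, 1)
      # cosine taper, exactly zero at every face, over a 4-voxel shell
      for (ax in 1:3) {
        n <- shape[ax]
        w <- min(4L, floor(n / 2))
        t1 <- rep(1, n)
        r <- seq_len(w)
        t1[r] <- (1 - cos(pi * (r - 1) / w)) / 2
        t1[n + 1 - r] <- t1[r]
        rep_dim <- if (ax > 1) prod(shape[seq_len(ax - 1)]) else 1L
        template <- template * rep(rep(t1, each = rep_dim),
                                   length.out = prod(shape))
        dim(template) <- shape
      }
    } else {
      template <- vol_data(template)
      stopifnot(all(dim(template) == shape))
    }
    traj <- matrix(0, n_timepoints, 3L)
    if (drift_type == "random_walk") {
      steps <- matrix(stats::rnorm(3L * (n_timepoints - 1L), sd = drift$sd),
                      n_timepoints - 1L, 3L)
      traj[-1L, ] <- apply(steps, 2L, cumsum)
    } else {
      traj <- outer(seq_len(n_timepoints) - 1, drift$v)
    }
  })
  if (any(abs(traj) > rep(shape / 2, each = n_timepoints))) {
    stop("drift exceeds half the volume extent")
  }
  series <- lapply(seq_len(n_timepoints), function(t) {
    if (all(traj[t, ] == 0)) template else fourier_shift(template, traj[t, ])
  })
  colnames(traj) <- c("dz", "dy", "dx")
  list(series = series, trajectory = traj, template = template)
}
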