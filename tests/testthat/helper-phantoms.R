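# Shared fixture builders; everything is generated in code, deterministic
# per seed.

# Smoothed random granules on a constant offset: generic textured volume
mk_textured <- function(shape, seed, density = 1 / 400, offset = 20,
                        smooth = 2) {
  shape <- rep_len(as.integer(shape), 3L)
  withr::with_seed(seed, {
    base <- array(0, shape)
    m <- max(8L, round(prod(shape) * density))
    idx <- cbind(sample.int(shape[1L], m, TRUE), sample.int(shape[2L], m, TRUE),
                 sample.int(shape[3L], m, TRUE))
    base[idx] <- stats::runif(m, 500, 1500)
    opmtools:::gaussian_smooth(base, smooth) + offset
  })
}

# Cosine taper to zero over a w-voxel shell at both ends of each axis
taper3 <- function(vol, w = 6) {
  d <- dim(vol)
  tp <- function(n) {
    t <- rep(1, n)
    r <- seq_len(min(w, floor(n / 2)))
    t[r] <- (1 - cos(pi * (r - 0.5) / w)) / 2
    t[n + 1 - r] <- t[r]
    t
  }
  g <- opmtools:::index_grid(d)
  array(vol * tp(d[1L])[g$i1] * tp(d[2L])[g$i2] * tp(d[3L])[g$i3], d)
}

# Dual-view time points of a compact, finely textured scene drifting with
# a known trajectory; per-frame shot noise gives each time point genuine
# high-frequency content. Returns raw stacks plus the truth trajectory.
mk_drift_scene_frames <- function(drift_um, shape = c(32, 48, 48),
                                  seed = 21) {
  withr::with_seed(seed, {
    base <- array(0, shape)
    m <- 250
    idx <- cbind(sample.int(shape[1L], m, TRUE), sample.int(shape[2L], m, TRUE),
                 sample.int(shape[3L], m, TRUE))
    base[idx] <- stats::runif(m, 500, 1500)
  })
  truth <- taper3(opmtools:::gaussian_smooth(base, 1))
  g1 <- acq_geometry(1, 1, view_id = 1)
  g2 <- acq_geometry(1, 1, view_id = 2)
  lapply(seq_len(nrow(drift_um)), function(t) {
    tr <- ortho_volume(opmtools:::translate_volume(truth, drift_um[t, ]),
                       c(1, 1, 1))
    s <- make_two_view_scene(scene_phantom(tr, 0), g1, g2)
    for (v in c("view1", "view2")) {
      withr::with_seed(seed + 17 * t + (v == "view2"), {
        s[[v]]$data <- array(stats::rpois(length(s[[v]]$data),
                                          s[[v]]$data + 20),
                             dim(s[[v]]$data))
      })
    }
    list(view1 = s[[1L]], view2 = s[[2L]])
  })
}

# Circular shift of a 3D array by integer s (content moves +s per axis)
circshift3 <- function(x, s) {
  d <- dim(x)
  idx <- function(n, k) ((seq_len(n) - 1 - k) %% n) + 1
  x[idx(d[1L], s[1L]), idx(d[2L], s[2L]), idx(d[3L], s[3L])]
}

# Sinusoidal displacement field evaluated at index vectors (voxels)
sin_field <- function(i1, i2, i3, amplitude = 4, wavelength = 128) {
  cbind(amplitude * sin(2 * pi * i3 / wavelength),
        amplitude * sin(2 * pi * i1 / wavelength),
        amplitude * sin(2 * pi * i2 / wavelength))
}

# Deform a volume so that the field `+F` registers it back onto `vol`
# (backward-warp convention of apply_warp)
deform_by_field <- function(vol, amplitude = 4, wavelength = 128) {
  d <- dim(vol)
  g <- opmtools:::index_grid(d)
  Ft <- sin_field(g$i1, g$i2, g$i3, amplitude, wavelength)
  array(opmtools:::interp3(vol, g$i1 - Ft[, 1L], g$i2 - Ft[, 2L],
                           g$i3 - Ft[, 3L]), d)
}

# Node positions of a warp field as index vectors
field_node_grid <- function(field) {
  nn <- vapply(field$centers, length, 0L)
  list(i1 = rep(field$centers[[1L]], nn[2L] * nn[3L]),
       i2 = rep(rep(field$centers[[2L]], each = nn[1L]), nn[3L]),
       i3 = rep(field$centers[[3L]], each = nn[1L] * nn[2L]))
}

# Shift table built analytically from a known trajectory (exact
# measurements, confidence 1)
shifts_from_trajectory <- function(traj, n = 7L) {
  T <- nrow(traj)
  rows <- list()
  for (t in seq_len(T - 1L)) {
    for (k in seq_len(min(n, T - t))) {
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, t2 = t + k,
        dz = traj[t + k, 1L] - traj[t, 1L],
        dy = traj[t + k, 2L] - traj[t, 2L],
        dx = traj[t + k, 3L] - traj[t, 3L],
        confidence = 1)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_timepoints") <- T
  attr(out, "n_neighbors") <- as.integer(n)
  class(out) <- c("relative_shifts", class(out))
  out
}

# Random-walk trajectory anchored at zero
rw_trajectory <- function(T, sd, seed) {
  withr::with_seed(seed, {
    steps <- matrix(stats::rnorm(3L * (T - 1L), sd = sd), T - 1L, 3L)
  })
  rbind(0, apply(steps, 2L, cumsum))
}

# Standard two-view occlusion scene used by fusion and pipeline tests:
# textured phantom, mild attenuation, one occluder shadowing each view
mk_occlusion_scene <- function(seed = 21, shape = c(48, 64, 64),
                               n_spots = 400) {
  truth <- mk_textured(shape, seed, density = n_spots / prod(shape),
                       smooth = 1.2)
  tv <- ortho_volume(truth, c(1, 1, 1))
  occ <- list(list(center_um = c(8, shape[2L] / 2, 14),
                   radii_um = c(3, shape[2L] / 4, 5)),
              list(center_um = c(8, shape[2L] / 2, shape[3L] - 14),
                   radii_um = c(3, shape[2L] / 4, 5)))
  phantom <- scene_phantom(tv, attenuation_mu_per_um = 0.005, occluders = occ)
  g1 <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, view_id = 1)
  g2 <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, view_id = 2)
  scene <- make_two_view_scene(phantom, g1, g2)
  # per-view deep-shadow masks on the truth grid: bright regions where
  # that view lost nearly all of its signal but the other kept it
  bright <- truth > stats::quantile(truth, 0.9)
  scene$shadow1 <- scene$lit1$data < 0.25 * scene$lit2$data & bright
  scene$shadow2 <- scene$lit2$data < 0.25 * scene$lit1$data & bright
  scene
}
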