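# Synthetic generators: bead phantoms, two-view scenes, drift series.

test_that("a zero-bead phantom is the constant background", {
  spec <- bead_phantom_spec(0, background_counts = 42, noise_model = "none")
  ph <- make_bead_phantom(spec, c(16, 16, 16), c(0.5, 0.5, 0.5))
  expect_equal(unique(as.vector(ph$volume$data)), 42)
  expect_equal(nrow(ph$positions), 0)
})

test_that("generated beads carry exactly the requested FWHMs", {
  vox <- c(0.1, 0.1, 0.1)
  fw <- c(0.5, 0.4, 1.2)
  spec <- bead_phantom_spec(1, fwhm_um = fw, psf_tilt_deg = 0,
                            noise_model = "none", background_counts = 10,
                            peak_counts = 500, seed = 5)
  ph <- make_bead_phantom(spec, c(64, 64, 64), vox)
  pos <- unlist(ph$positions[1, c("z_um", "y_um", "x_um")])
  # oracle: closed-form Gaussian along each principal axis through the center
  g <- opmtools:::index_grid(dim(ph$volume$data))
  dz <- (g$i1 - 1) * vox[1] - pos[1]
  dy <- (g$i2 - 1) * vox[2] - pos[2]
  dx <- (g$i3 - 1) * vox[3] - pos[3]
  expected <- 10 + 500 * exp(-4 * log(2) * ((dx / fw[1])^2 + (dy / fw[2])^2 +
                                            (dz / fw[3])^2))
  # rendered within a finite window: tails beyond ~4 sigma are truncated
  expect_lt(max(abs(as.vector(ph$volume$data) - expected)), 0.1)

  # and a 1D Gaussian fit recovers each FWHM within 1%
  rec <- fit_psf(ph$volume)
  expect_lt(abs(rec$fwhm_x_nm / (fw[1] * 1000) - 1), 0.01)
  expect_lt(abs(rec$fwhm_y_nm / (fw[2] * 1000) - 1), 0.01)
  expect_lt(abs(rec$fwhm_z_nm / (fw[3] * 1000) - 1), 0.01)
})

test_that("phantom generation is a pure function of spec and seed", {
  spec <- bead_phantom_spec(4, fwhm_um = c(0.4, 0.4, 0.8),
                            min_separation_voxels = 8,
                            noise_model = "poisson", seed = 99)
  a <- make_bead_phantom(spec, c(48, 48, 48), c(0.2, 0.2, 0.2))
  b <- make_bead_phantom(spec, c(48, 48, 48), c(0.2, 0.2, 0.2))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$positions, b$positions)
  spec2 <- bead_phantom_spec(4, fwhm_um = c(0.4, 0.4, 0.8),
                             min_separation_voxels = 8,
                             noise_model = "poisson", seed = 100)
  c <- make_bead_phantom(spec2, c(48, 48, 48), c(0.2, 0.2, 0.2))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("infeasible bead packing is rejected with a packing error", {
  spec <- bead_phantom_spec(50, fwhm_um = c(0.4, 0.4, 0.8),
                            min_separation_voxels = 40, seed = 1)
  expect_error(make_bead_phantom(spec, c(40, 40, 40), c(0.2, 0.2, 0.2)),
               "packing|too small")
})

test_that("attenuation follows the analytic Beer-Lambert path integral", {
  mu <- 0.02
  truth <- ortho_volume(array(100, c(24, 8, 32)), c(1, 1, 1))
  ph <- scene_phantom(truth, attenuation_mu_per_um = mu)
  g1 <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, view_id = 1)
  trans <- opmtools:::view_transmission(ph, g1)
  # oracle: L = min(z / sin(theta), (x - x_min) / cos(theta))
  g <- opmtools:::index_grid(dim(truth$data))
  L <- pmin((g$i1 - 1) / sin(pi / 4), (g$i3 - 1) / cos(pi / 4))
  expect_equal(as.vector(trans), exp(-mu * L), tolerance = 1e-12)

  # deep-tissue mean intensity decreases monotonically along the path
  prof <- apply(truth$data[, 1, ] * trans[, 1, ], 1, mean)
  expect_true(all(diff(prof) < 0))
})

test_that("an occluder shadows one view but not the other", {
  sc <- mk_occlusion_scene(seed = 21)
  expect_gt(sum(sc$shadow1), 20)
  expect_gt(sum(sc$shadow2), 20)
  # view 2 keeps > 5x the intensity of view 1 in view-1's shadow
  r1 <- mean(sc$lit2$data[sc$shadow1]) / max(mean(sc$lit1$data[sc$shadow1]), 1e-9)
  r2 <- mean(sc$lit1$data[sc$shadow2]) / max(mean(sc$lit2$data[sc$shadow2]), 1e-9)
  expect_gt(r1, 5)
  expect_gt(r2, 5)
})

test_that("with no attenuation the two deskewed views agree after flipping", {
  truth <- mk_textured(c(32, 40, 40), seed = 12)
  ph <- scene_phantom(ortho_volume(truth, c(1, 1, 1)), 0)
  g1 <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, view_id = 1)
  g2 <- acq_geometry(scan_step_um = 1, pixel_size_um = 1, view_id = 2)
  sc <- make_two_view_scene(ph, g1, g2)
  d1 <- deskew(sc$view1)
  d2 <- resample_to(flip_view(deskew(sc$view2)), d1)
  core1 <- 5:27; core2 <- 5:35
  corex <- seq(round(-d1$origin_um[3]) + 5, round(-d1$origin_um[3]) + 35)
  a <- d1$data[core1, core2, corex]
  b <- d2$data[core1, core2, corex]
  expect_lt(sqrt(mean((a - b)^2)) / stats::sd(a), 0.1)
})

test_that("view geometries must differ only in view id", {
  ph <- scene_phantom(ortho_volume(array(1, c(8, 8, 8)), c(1, 1, 1)), 0)
  g1 <- acq_geometry(1, 1, view_id = 1)
  g2 <- acq_geometry(2, 1, view_id = 2)
  expect_error(make_two_view_scene(ph, g1, g2), "differ only in view_id")
  expect_error(make_two_view_scene(ph, g1, g1), "different view_id")
})

test_that("drift series construction matches its stated trajectory", {
  # zero drift: identical frames
  z <- make_drift_series(c(12, 12, 12), 3, list(type = "linear", v = c(0, 0, 0)),
                         seed = 2)
  expect_identical(z$series[[1]], z$series[[3]])

  # integer linear drift: frame t equals the rolled template (interior,
  # away from the circular wrap band)
  dr <- make_drift_series(c(16, 16, 16), 4, list(type = "linear", v = c(1, 0, 0)),
                          seed = 2)
  expect_equal(dr$trajectory[, 1], 0:3)
  shifted <- opmtools:::translate_volume(dr$template, c(2, 0, 0))
  core <- 4:13
  expect_equal(dr$series[[3]][core, , ], shifted[core, , ], tolerance = 1e-10)

  # reproducible bit-exactly per seed (volume sized to hold the walk)
  a <- make_drift_series(c(48, 48, 48), 50, list(type = "random_walk", sd = 2),
                         seed = 42)
  b <- make_drift_series(c(48, 48, 48), 50, list(type = "random_walk", sd = 2),
                         seed = 42)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$series, b$series)

  # drift beyond half the volume is rejected
  expect_error(
    make_drift_series(c(8, 8, 8), 10, list(type = "linear", v = c(1, 0, 0)),
                      seed = 1),
    "half the volume")
})
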