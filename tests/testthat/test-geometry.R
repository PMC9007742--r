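# Deskew transform, synthetic oblique sampling and view mirroring.

test_that("geometry constructors validate their invariants", {
  expect_error(acq_geometry(1, 1, tilt_angle_deg = 0), "strictly between")
  expect_error(acq_geometry(1, 1, tilt_angle_deg = 90), "strictly between")
  expect_error(acq_geometry(-1, 1), "scan_step_um")
  expect_error(acq_geometry(1, 0), "pixel_size_um")
  expect_error(acq_geometry(1, 1, view_id = 3), "view_id")
  expect_error(oblique_stack(array(-1, c(2, 2, 2)), acq_geometry(1, 1)),
               "nonnegative")
  expect_error(oblique_stack(array(NaN, c(2, 2, 2)), acq_geometry(1, 1)),
               "finite")
  expect_error(ortho_volume(array(1, c(2, 2, 2)), c(0, 1, 1)), "voxel sizes")
})

test_that("deskew fixes the camera-frame origin and row scale", {
  # a sample at scan 0, row y, column x' = 0 lands at world (0, y*p, 0)
  p <- 0.5
  g <- acq_geometry(scan_step_um = 1, pixel_size_um = p)
  dat <- array(0, c(4, 16, 8))
  dat[1, 11, 1] <- 100                      # s = 0, y = 10 px, x' = 0
  vol <- deskew(oblique_stack(dat, g))
  top <- arrayInd(which.max(vol$data), dim(vol$data))[1, ]
  expect_equal(vol$origin_um[1] + (top[1] - 1) * vol$voxel_size_um[1], 0)
  expect_equal(vol$origin_um[2] + (top[2] - 1) * vol$voxel_size_um[2], 10 * p)
  expect_equal(vol$origin_um[3] + (top[3] - 1) * vol$voxel_size_um[3], 0)
})

test_that("an oblique field of 420 um depth-projects to 300 um (nearest 10)", {
  # x' extent 420 um at 45 degrees: z extent = 420 * sin(45) ~ 297 um
  p <- 0.44
  nxp <- round(420 / p) + 1
  g <- acq_geometry(scan_step_um = 2, pixel_size_um = p)
  vol <- deskew(oblique_stack(array(1, c(2, 2, nxp)), g))
  z_extent <- max(opmtools:::vol_axis_um(vol, 1))
  expect_equal(z_extent, 420 * sin(pi / 4), tolerance = 1e-2)
  expect_equal(round(z_extent / 10) * 10, 300)
})

test_that("forward sampling of a uniform volume returns the constant", {
  vol <- ortho_volume(array(7, c(24, 24, 24)), c(1, 1, 1))
  g <- acq_geometry(scan_step_um = 1, pixel_size_um = 1)
  st <- forward_sample(vol, g)
  # interior samples (inside the volume's support) are exactly the constant
  interior <- st$data[st$data > 0]
  expect_gt(length(interior), 1000)
  expect_equal(range(st$data[abs(st$data - 7) < 1e-9]), c(7, 7))
  # samples are never above the constant and most in-support ones equal it
  expect_lte(max(st$data), 7 + 1e-9)
  expect_gt(mean(abs(interior - 7) < 1e-9), 0.8)
})

test_that("an impulse voxel is seen only by planes passing near it", {
  vox <- c(1, 1, 1)
  vol <- array(0, c(24, 8, 40))
  vol[13, 4, 21] <- 100                     # world (z, y, x) = (12, 3, 20)
  g <- acq_geometry(scan_step_um = 1, pixel_size_um = 1)
  st <- forward_sample(ortho_volume(vol, vox), g)
  seen <- which(apply(st$data, 1, max) > 0)
  # plane of scan s: x = so + s*ds + z/tan(theta); impulse at x=20, z=12
  so <- st$geometry$scan_origin_um
  s_star <- (20 - 12 / tan(pi / 4)) - so    # 0-based scan position
  expect_true(all(abs((seen - 1) - s_star) <= 2.5))
  expect_true(any(abs((seen - 1) - s_star) <= 1.5))
})

test_that("deskew inverts forward sampling: bead centroids within half a voxel", {
  vox <- c(0.5, 0.5, 0.5)
  shape <- c(40, 40, 40)
  g1 <- acq_geometry(scan_step_um = 0.5, pixel_size_um = 0.5, view_id = 1)
  g2 <- acq_geometry(scan_step_um = 0.5, pixel_size_um = 0.5, view_id = 2)
  grid <- opmtools:::index_grid(shape)
  withr::with_seed(17, {
    centers <- cbind(stats::runif(6, 8, 12), stats::runif(6, 8, 12),
                     stats::runif(6, 8, 12))
  })
  for (g in list(g1, g2)) {
    for (b in seq_len(nrow(centers))) {
      truth <- array(100 * exp(-((grid$i1 - 1) * 0.5 - centers[b, 1])^2 / 0.72 -
                               ((grid$i2 - 1) * 0.5 - centers[b, 2])^2 / 0.72 -
                               ((grid$i3 - 1) * 0.5 - centers[b, 3])^2 / 0.72),
                     shape)
      vol <- deskew(forward_sample(ortho_volume(truth, vox), g))
      w <- vol$data
      w[w < max(w) * 0.05] <- 0
      gg <- opmtools:::index_grid(dim(w))
      wv <- as.vector(w)
      cen <- c(sum(wv * (vol$origin_um[1] + (gg$i1 - 1) * vol$voxel_size_um[1])),
               sum(wv * (vol$origin_um[2] + (gg$i2 - 1) * vol$voxel_size_um[2])),
               sum(wv * (vol$origin_um[3] + (gg$i3 - 1) * vol$voxel_size_um[3]))) / sum(wv)
      err_vox <- abs(cen - centers[b, ]) / vox
      expect_lt(max(err_vox), 0.5)
    }
  }
})

test_that("deskew round trip preserves smooth content and total intensity", {
  truth <- mk_textured(32, seed = 3, offset = 0)
  # taper to zero at the faces: conservation statements concern interior
  # content, away from resampling edges
  tp <- function(n, w = 5) {
    t <- rep(1, n)
    r <- seq_len(w)
    t[r] <- (1 - cos(pi * (r - 0.5) / w)) / 2
    t[n + 1 - r] <- t[r]
    t
  }
  g <- opmtools:::index_grid(dim(truth))
  truth <- array(truth * tp(32)[g$i1] * tp(32)[g$i2] * tp(32)[g$i3], dim(truth))
  vox <- c(1, 1, 1)
  g <- acq_geometry(scan_step_um = 1, pixel_size_um = 1)
  vol <- deskew(forward_sample(ortho_volume(truth, vox), g),
                target_voxel_um = vox)
  # compare on the interior of the original support (origin at 0)
  ox <- round(-vol$origin_um[3])
  core <- 5:28
  rec <- vol$data[core, core, core + ox]
  ref <- truth[core, core, core]
  expect_lt(sqrt(mean((rec - ref)^2)) / sqrt(mean(ref^2)), 0.05)

  # world-space intensity integral conserved within 2% (default voxel)
  vol2 <- deskew(forward_sample(ortho_volume(truth, vox), g))
  tot_in <- sum(truth) * prod(vox)
  tot_out <- sum(vol2$data) * prod(vol2$voxel_size_um)
  expect_lt(abs(tot_out / tot_in - 1), 0.02)
})

test_that("deskew is linear in the stack intensities", {
  g <- acq_geometry(scan_step_um = 1, pixel_size_um = 1)
  withr::with_seed(4, {
    s1 <- array(stats::runif(20 * 12 * 14, 0, 100), c(20, 12, 14))
    s2 <- array(stats::runif(20 * 12 * 14, 0, 100), c(20, 12, 14))
  })
  va <- deskew(oblique_stack(2 * s1 + 3 * s2, g))
  vb <- deskew(oblique_stack(s1, g))
  vc <- deskew(oblique_stack(s2, g))
  expect_equal(va$data, 2 * vb$data + 3 * vc$data, tolerance = 1e-12)
})

test_that("degenerate tilt angles and non-finite input are rejected", {
  expect_error(acq_geometry(1, 1, tilt_angle_deg = 0))
  g <- acq_geometry(1, 1)
  st <- oblique_stack(array(1, c(4, 4, 4)), g)
  st$data[1] <- Inf
  expect_error(deskew(st), "finite")
})

test_that("flip_view is an exact involution that mirrors the x axis", {
  vol <- ortho_volume(mk_textured(16, 8), c(1, 1, 1), origin_um = c(0, 0, 3))
  expect_identical(flip_view(flip_view(vol)), vol)

  imp <- array(0, c(6, 6, 10))
  imp[2, 3, 4] <- 1                         # x index k = 3 (0-based)
  f <- flip_view(ortho_volume(imp, c(1, 1, 1)))
  expect_equal(unname(which(f$data > 0, arr.ind = TRUE)[1, 3]),
               10 - 3)                      # N-1-k, 1-based
})

test_that("deskewed views of a two-view scene align after flipping view 2", {
  sc <- mk_occlusion_scene(seed = 21)
  d1 <- deskew(sc$view1)
  d2 <- resample_to(flip_view(deskew(sc$view2)), d1)
  pc <- phase_correlation(d1, d2, window = "hann")
  extent <- dim(d1$data)
  expect_true(all(abs(pc$shift) < 0.1 * extent))
})
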