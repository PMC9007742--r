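# Bead detection and tilted-PSF FWHM characterization.

test_that("FWHM follows the closed form 2 sqrt(2 ln 2) sigma", {
  # sigma = 1 voxel at 100 nm voxels -> FWHM = 235.48 nm
  vox <- c(0.1, 0.1, 0.1)
  g <- opmtools:::index_grid(c(33, 33, 33))
  v <- array(200 * exp(-((g$i1 - 17)^2 + (g$i2 - 17)^2 + (g$i3 - 17)^2) / 2) + 5,
             c(33, 33, 33))
  rec <- fit_psf(ortho_volume(v, vox))
  expect_equal(rec$fwhm_x_nm, 2 * sqrt(2 * log(2)) * 100, tolerance = 1e-3)
  expect_equal(rec$fwhm_y_nm, 235.48, tolerance = 1e-3)
  expect_equal(rec$fwhm_z_nm, 235.48, tolerance = 1e-3)
  expect_false(rec$flagged)
})

test_that("instrument-scale tilted PSF parameters are recovered within 2%", {
  vox <- c(0.103, 0.146, 0.146)
  fw <- c(0.480, 0.379, 1.865)              # x'', y, z'' in um
  spec <- bead_phantom_spec(1, fwhm_um = fw, psf_tilt_deg = 20,
                            noise_model = "none", background_counts = 50,
                            peak_counts = 1000, seed = 3)
  ph <- make_bead_phantom(spec, c(120, 60, 80), vox)
  recs <- characterize_psf(ph$volume, threshold = 300)
  expect_equal(nrow(recs), 1)
  expect_lt(abs(recs$fwhm_x_nm / 480 - 1), 0.02)
  expect_lt(abs(recs$fwhm_y_nm / 379 - 1), 0.02)
  expect_lt(abs(recs$fwhm_z_nm / 1865 - 1), 0.02)
  expect_lt(abs(recs$tilt_deg - 20), 2)
})

test_that("recovery holds across a grid of widths and tilts", {
  vox <- c(0.1, 0.1, 0.1)
  for (case in list(list(fw = c(0.30, 0.30, 0.90), tilt = 0),
                    list(fw = c(0.45, 0.40, 1.50), tilt = 10),
                    list(fw = c(0.60, 0.50, 2.50), tilt = 30))) {
    spec <- bead_phantom_spec(1, fwhm_um = case$fw, psf_tilt_deg = case$tilt,
                              noise_model = "none", background_counts = 20,
                              peak_counts = 800, seed = 7)
    shape <- ceiling((4.4 * max(case$fw) + 2) / vox)   # room for margins
    ph <- make_bead_phantom(spec, shape, vox)
    rec <- fit_psf(ph$volume)
    got <- c(rec$fwhm_x_nm, rec$fwhm_y_nm, rec$fwhm_z_nm) / 1000
    expect_lt(max(abs(got / case$fw - 1)), 0.02)
    expect_lt(abs(rec$tilt_deg - case$tilt), 2)
  }
})

test_that("a zero-tilt bead needs no rotation: axis fits match", {
  vox <- c(0.1, 0.1, 0.1)
  fw <- c(0.5, 0.4, 1.4)
  spec <- bead_phantom_spec(1, fwhm_um = fw, psf_tilt_deg = 0,
                            noise_model = "none", background_counts = 10,
                            peak_counts = 500, seed = 9)
  ph <- make_bead_phantom(spec, c(96, 64, 64), vox)
  rec <- fit_psf(ph$volume)
  expect_lt(abs(rec$tilt_deg), 1)
  # oracle: direct grid-line Gaussian fits through the true center
  pos_vox <- round(unlist(ph$positions[1, c("z_um", "y_um", "x_um")]) / vox) + 1
  v <- ph$volume$data
  prof_fit <- function(s_um, y) {
    ft <- opmtools:::fit_gaussian_1d(s_um, y)
    2 * sqrt(2 * log(2)) * ft$sigma * 1000
  }
  f_z <- prof_fit((seq_len(dim(v)[1]) - pos_vox[1]) * vox[1],
                  v[, pos_vox[2], pos_vox[3]])
  f_x <- prof_fit((seq_len(dim(v)[3]) - pos_vox[3]) * vox[3],
                  v[pos_vox[1], pos_vox[2], ])
  expect_lt(abs(rec$fwhm_z_nm / f_z - 1), 0.005)
  expect_lt(abs(rec$fwhm_x_nm / f_x - 1), 0.005)
})

test_that("FWHM estimates are invariant to amplitude and offset", {
  vox <- c(0.1, 0.1, 0.1)
  spec <- bead_phantom_spec(1, fwhm_um = c(0.5, 0.4, 1.2), psf_tilt_deg = 15,
                            noise_model = "none", background_counts = 0,
                            peak_counts = 100, seed = 4)
  ph <- make_bead_phantom(spec, c(80, 64, 64), vox)
  base <- fit_psf(ph$volume)
  scaled <- fit_psf(ortho_volume(ph$volume$data * 37 + 250, vox))
  for (cl in c("fwhm_x_nm", "fwhm_y_nm", "fwhm_z_nm")) {
    expect_lt(abs(scaled[[cl]] / base[[cl]] - 1), 0.005)
  }
})

test_that("bead detection finds true maxima and honors its rules", {
  # constant volume: nothing to find
  flat <- ortho_volume(array(5, c(16, 16, 16)), c(1, 1, 1))
  expect_equal(nrow(detect_beads(flat, threshold = 10)), 0)

  # noisy phantom: all beads recovered within 1 voxel, no false positives
  vox <- c(0.2, 0.2, 0.2)
  spec <- bead_phantom_spec(12, fwhm_um = c(0.5, 0.5, 1.0), psf_tilt_deg = 0,
                            min_separation_voxels = 20,
                            noise_model = "poisson", background_counts = 25,
                            peak_counts = 500, seed = 31)
  ph <- make_bead_phantom(spec, c(72, 72, 72), vox, border_margin_um = 1.6)
  found <- detect_beads(ph$volume, threshold = 200,
                        min_separation_voxels = 6, border_margin = 4)
  expect_equal(nrow(found), 12)
  truth_vox <- as.matrix(ph$positions[, c("z_um", "y_um", "x_um")]) /
    rep(vox, each = 12) + 1
  dmat <- as.matrix(stats::dist(rbind(truth_vox,
                                      as.matrix(found[, c("z", "y", "x")]))))
  nearest <- apply(dmat[13:24, 1:12, drop = FALSE], 1, min)
  expect_true(all(nearest <= 1))

  # two close beads under a large separation: only the brighter survives
  v <- array(0, c(32, 32, 32))
  v[16, 16, 16] <- 100
  v[16, 16, 18] <- 80
  picks <- detect_beads(ortho_volume(v, c(1, 1, 1)), threshold = 10,
                        min_separation_voxels = 10)
  expect_equal(nrow(picks), 1)
  expect_equal(picks$intensity, 100)
})

test_that("PSF summaries average unflagged records only", {
  rec <- function(fx, flag = FALSE) {
    data.frame(x_um = 0, y_um = 0, z_um = 0, fwhm_x_nm = fx, fwhm_y_nm = fx,
               fwhm_z_nm = fx, tilt_deg = 20, r2_x = 1, r2_y = 1, r2_z = 1,
               flagged = flag)
  }
  single <- summarize_psf(rec(500))
  expect_equal(unname(single$mean_fwhm_nm["x"]), 500)
  expect_equal(unname(single$sd_fwhm_nm["x"]), 0)
  expect_equal(single$n_beads, 1)

  two <- summarize_psf(rbind(rec(400), rec(500)))
  expect_equal(unname(two$mean_fwhm_nm["x"]), 450)
  expect_equal(unname(two$sd_fwhm_nm["x"]), 70.71, tolerance = 1e-3)

  withflag <- summarize_psf(rbind(rec(400), rec(500), rec(9000, flag = TRUE)))
  expect_equal(unname(withflag$mean_fwhm_nm["x"]), 450)
  expect_equal(withflag$n_beads, 2)
  expect_error(summarize_psf(rec(400, flag = TRUE)), "no unflagged")
})
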