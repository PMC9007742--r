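# Bead detection and tilted-PSF characterization. The measured PSF of an
# oblique-plane microscope is an anisotropic ellipsoid whose long axis
# (z'') is tilted in the xz plane (about 20 degrees from z for this
# geometry); FWHM values are therefore measured along the tilted
# principal axes x'', y and z'' by 1D Gaussian fits of line profiles
# through each bead.

#' Detect beads as local intensity maxima
#'
#' Returns voxels that are strict neighborhood maxima above a threshold,
#' separated pairwise by at least `min_separation_voxels`, excluding a
#' border margin, sorted by descending peak intensity.
#'
#' @param volume an [ortho_volume()] or 3D array.
#' @param threshold minimum peak intensity (counts).
#' @param min_separation_voxels neighborhood radius for the maxima test
#'   and minimum pairwise peak distance, voxels.
#' @param border_margin scalar or length-3 margin (voxels per axis,
#'   order z, y, x) excluded at the volume faces; size it to the crop
#'   window of the subsequent fit.
#' @return data.frame with voxel indices `z`, `y`, `x` (1-based), world
#'   positions `z_um`, `y_um`, `x_um` and `intensity`; zero rows if
#'   nothing is found.
#' @export
detect_beads <- function(volume, threshold, min_separation_voxels = 5,
                         border_margin = 0) {
  v <- vol_data(volume)
  stopifnot(all(is.finite(v)))
  d <- dim(v)
  r <- max(1L, as.integer(min_separation_voxels))
  vmax <- box_max(v, r)
  cand <- which(v >= vmax & v > threshold)
  empty <- data.frame(z = integer(), y = integer(), x = integer(),
                      z_um = numeric(), y_um = numeric(), x_um = numeric(),
                      intensity = numeric())
  if (length(cand) == 0L) return(empty)

  ind <- arrayInd(cand, d)
  margin <- rep_len(border_margin, 3L)
  keep <- rep(TRUE, nrow(ind))
  for (ax in 1:3) {
    keep <- keep & ind[, ax] > margin[ax] & ind[, ax] <= d[ax] - margin[ax]
  }
  ind <- ind[keep, , drop = FALSE]
  if (nrow(ind) == 0L) return(empty)
  peaks <- v[ind]

  ord <- order(peaks, decreasing = TRUE)
  ind <- ind[ord, , drop = FALSE]
  peaks <- peaks[ord]

  # greedy Euclidean min-separation on the intensity-sorted candidates
  sel <- integer(0)
  for (k in seq_len(nrow(ind))) {
    if (length(sel) > 0L) {
      dd <- sqrt(colSums((t(ind[sel, , drop = FALSE]) - ind[k, ])^2))
      if (min(dd) < min_separation_voxels) next
    }
    sel <- c(sel, k)
  }
  ind <- ind[sel, , drop = FALSE]

  vox <- if (inherits(volume, "ortho_volume")) volume$voxel_size_um else c(1, 1, 1)
  org <- if (inherits(volume, "ortho_volume")) volume$origin_um else c(0, 0, 0)
  data.frame(z = ind[, 1L], y = ind[, 2L], x = ind[, 3L],
             z_um = org[1L] + (ind[, 1L] - 1) * vox[1L],
             y_um = org[2L] + (ind[, 2L] - 1) * vox[2L],
             x_um = org[3L] + (ind[, 3L] - 1) * vox[3L],
             intensity = peaks[sel])
}

# 1D Gaussian fit: A * exp(-(s - m)^2 / (2 sigma^2)) + b.
# Returns list(sigma, r2, converged). Positions `s` in micrometres.
fit_gaussian_1d <- function(s, y) {
  b0 <- min(y)
  A0 <- max(y) - b0
  if (A0 <= 0) return(list(sigma = NA_real_, r2 = 0, converged = FALSE))
  m0 <- s[which.max(y)]
  w <- pmax(y - b0, 0)
  s0 <- sqrt(sum(w * (s - m0)^2) / max(sum(w), .Machine$double.eps))
  s0 <- max(s0, diff(range(s)) / length(s))
  r2_of <- function(p) {
    res <- y - (p[1L] * exp(-(s - p[2L])^2 / (2 * p[3L]^2)) + p[4L])
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  attempt <- function(start) tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(s - m)^2 / (2 * sg^2)) + b,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- attempt(list(A = A0, m = m0, sg = s0, b = b0))
  if (is.null(fit)) {
    # exact-residual starts can trip the singular-gradient test; retry off
    # the optimum
    fit <- attempt(list(A = 0.9 * A0, m = m0, sg = 1.25 * s0, b = b0))
  }
  if (is.null(fit)) {
    # fall back to the moment estimates if they already explain the data
    r2m <- r2_of(c(A0, m0, s0, b0))
    return(list(sigma = if (r2m > 0.99) s0 else NA_real_, r2 = r2m,
                converged = r2m > 0.99))
  }
  cf <- stats::coef(fit)
  r2 <- r2_of(c(cf[["A"]], cf[["m"]], abs(cf[["sg"]]), cf[["b"]]))
  list(sigma = abs(cf[["sg"]]), r2 = r2, converged = TRUE)
}

# Sample an intensity profile along unit direction `dir` (z, y, x in um)
# through `center_um`. Axis-aligned directions are read straight off the
# voxel grid (no interpolation, so no kernel broadening of narrow
# profiles); tilted directions are sampled by tricubic interpolation at
# `step_um` spacing.
line_profile <- function(v, voxel_size_um, origin_um, center_um, dir,
                         half_len_um, step_um) {
  d <- dim(v)
  ctr_idx <- (center_um - origin_um) / voxel_size_um + 1
  ax <- which(abs(dir) > 1 - 1e-9)
  if (length(ax) == 1L) {
    idx <- seq_len(d[ax])
    other <- pmin(pmax(round(ctr_idx), 1L), d)
    vals <- switch(ax, v[, other[2L], other[3L]], v[other[1L], , other[3L]],
                   v[other[1L], other[2L], ])
    s <- (idx - ctr_idx[ax]) * voxel_size_um[ax] * sign(dir[ax])
    keep <- abs(s) <= half_len_um
    return(list(s = s[keep], y = vals[keep]))
  }
  s <- seq(-half_len_um, half_len_um, by = step_um)
  pts <- outer(s, dir)                       # n x 3, (z, y, x) um offsets
  i1 <- (center_um[1L] + pts[, 1L] - origin_um[1L]) / voxel_size_um[1L] + 1
  i2 <- (center_um[2L] + pts[, 2L] - origin_um[2L]) / voxel_size_um[2L] + 1
  i3 <- (center_um[3L] + pts[, 3L] - origin_um[3L]) / voxel_size_um[3L] + 1
  ok <- i1 >= 1 & i1 <= d[1L] & i2 >= 1 & i2 <= d[2L] & i3 >= 1 & i3 <= d[3L]
  list(s = s[ok], y = interp3_cubic(v, i1[ok], i2[ok], i3[ok]))
}

#' Fit the tilted PSF of a single bead
#'
#' Estimates the in-plane tilt of the PSF's long axis from the principal
#' axes of the intensity second-moment tensor in the xz plane, then
#' extracts 1D line profiles through the bead center along the tilted
#' principal axes (x'', y, z'') and fits each with a 1D Gaussian
#' (amplitude, center, sigma, offset). FWHM = 2 sqrt(2 ln 2) sigma.
#'
#' @param crop an [ortho_volume()] (or 3D array) containing one dominant
#'   bead.
#' @param voxel_size_um c(vz, vy, vx), required when `crop` is a bare
#'   array.
#' @param r2_floor minimum goodness of fit; any axis below it flags the
#'   record (excluded from summaries). Default 0.9.
#' @param profile_step_vox line-profile sampling step as a fraction of
#'   the smallest voxel edge. Default 0.25.
#' @return a one-row data.frame (class `psf_record`): position, FWHM per
#'   principal axis in nm, fitted tilt (degrees), per-axis r2, `flagged`.
#' @export
fit_psf <- function(crop, voxel_size_um = NULL, r2_floor = 0.9,
                    profile_step_vox = 0.25) {
  if (inherits(crop, "ortho_volume")) {
    voxel_size_um <- crop$voxel_size_um
    origin_um <- crop$origin_um
    v <- crop$data
  } else {
    stopifnot(!is.null(voxel_size_um))
    origin_um <- c(0, 0, 0)
    v <- crop
  }
  d <- dim(v)
  if (any(d < 5L)) stop("crop too small to fit a PSF")

  # background from the crop faces; robust offset for moments and fits
  face_idx <- unique(c(which(slice.index(v, 1L) %in% c(1L, d[1L])),
                       which(slice.index(v, 2L) %in% c(1L, d[2L])),
                       which(slice.index(v, 3L) %in% c(1L, d[3L]))))
  bg <- stats::median(v[face_idx])
  peak_val <- max(v)
  # second moments over the bead core only: truncating a Gaussian at an
  # intensity level keeps its principal axes, background noise never
  # reaches a quarter of the peak amplitude, and restricting to the
  # connected component containing the peak shuts out tails of neighboring
  # sources reaching into the crop corners
  core <- v > bg + 0.25 * (peak_val - bg)
  mask <- array(FALSE, d)
  mask[which.max(v)] <- TRUE
  repeat {
    grown <- (box_max(mask + 0, 1L) > 0) & core
    if (sum(grown) == sum(mask)) break
    mask <- grown
  }
  w <- pmax(v - bg - 0.25 * (peak_val - bg), 0) * mask

  g <- index_grid(d)
  zc <- origin_um[1L] + (g$i1 - 1) * voxel_size_um[1L]
  yc <- origin_um[2L] + (g$i2 - 1) * voxel_size_um[2L]
  xc <- origin_um[3L] + (g$i3 - 1) * voxel_size_um[3L]
  wt <- as.vector(w)
  sw <- sum(wt)
  center <- c(sum(wt * zc), sum(wt * yc), sum(wt * xc)) / sw

  # in-plane (xz) second-moment tensor -> tilt of the long axis from z
  dz <- zc - center[1L]; dx <- xc - center[3L]
  Szz <- sum(wt * dz * dz); Sxx <- sum(wt * dx * dx); Sxz <- sum(wt * dx * dz)
  M <- matrix(c(Szz, Sxz, Sxz, Sxx), 2L)
  ev <- eigen(M, symmetric = TRUE)
  long <- ev$vectors[, 1L]                  # (z, x) components of z'' axis
  if (long[1L] < 0) long <- -long
  tilt <- atan2(long[2L], long[1L]) * 180 / pi
  phi <- tilt * pi / 180

  e_zpp <- c(cos(phi), 0, sin(phi))         # (z, y, x) unit vectors
  e_xpp <- c(-sin(phi), 0, cos(phi))
  e_y <- c(0, 1, 0)

  step_um <- profile_step_vox * min(voxel_size_um)
  half_um <- min((d - 1) * voxel_size_um) / 2
  axes <- list(x = e_xpp, y = e_y, z = e_zpp)
  fwhm <- numeric(3L); r2 <- numeric(3L); ok <- logical(3L)
  for (k in 1:3) {
    pr <- line_profile(v, voxel_size_um, origin_um, center, axes[[k]],
                       half_um, step_um)
    ft <- fit_gaussian_1d(pr$s, pr$y)
    fwhm[k] <- 2 * sqrt(2 * log(2)) * ft$sigma * 1000   # um -> nm
    r2[k] <- ft$r2
    ok[k] <- ft$converged && ft$r2 >= r2_floor
  }

  rec <- data.frame(x_um = center[3L], y_um = center[2L], z_um = center[1L],
                    fwhm_x_nm = fwhm[1L], fwhm_y_nm = fwhm[2L],
                    fwhm_z_nm = fwhm[3L], tilt_deg = tilt,
                    r2_x = r2[1L], r2_y = r2[2L], r2_z = r2[3L],
                    flagged = !all(ok))
  class(rec) <- c("psf_record", class(rec))
  rec
}

#' Detect, crop and fit all beads in a calibration volume
#'
#' Convenience wrapper: [detect_beads()], crop a window of
#' `window_fwhm_factor` times the largest expected FWHM around each peak,
#' drop beads with a neighbor inside their crop window (a second source
#' in the window would bias the profile fits), and [fit_psf()] each
#' crop.
#'
#' @param volume an [ortho_volume()].
#' @param threshold peak detection threshold (counts).
#' @param expected_fwhm_um c(x'', y, z'') expected FWHM used to size the
#'   crop window.
#' @param window_fwhm_factor crop half-width = factor/2 x largest
#'   expected FWHM (full window = factor x FWHM). Default 4.
#' @param r2_floor passed to [fit_psf()].
#' @return data.frame of per-bead records (see [fit_psf()]).
#' @export
characterize_psf <- function(volume, threshold,
                             expected_fwhm_um = c(0.480, 0.379, 1.865),
                             window_fwhm_factor = 4, r2_floor = 0.9) {
  stopifnot(inherits(volume, "ortho_volume"))
  fmax <- max(expected_fwhm_um)
  half_vox <- ceiling(window_fwhm_factor * fmax / 2 / volume$voxel_size_um)
  beads <- detect_beads(volume, threshold,
                        min_separation_voxels = max(3, min(half_vox)),
                        border_margin = half_vox)
  if (nrow(beads) == 0L) return(beads)

  # exclude beads that have another bead inside their crop window
  pos_vox <- as.matrix(beads[, c("z", "y", "x")])
  keep <- rep(TRUE, nrow(beads))
  for (a in seq_len(nrow(beads) - 1L)) {
    for (b in seq((a + 1L), nrow(beads))) {
      if (all(abs(pos_vox[a, ] - pos_vox[b, ]) <= half_vox)) {
        keep[a] <- keep[b] <- FALSE
      }
    }
  }
  beads <- beads[keep, , drop = FALSE]

  recs <- lapply(seq_len(nrow(beads)), function(k) {
    ctr <- as.integer(beads[k, c("z", "y", "x")])
    lo <- ctr - half_vox; hi <- ctr + half_vox
    crop <- ortho_volume(volume$data[lo[1L]:hi[1L], lo[2L]:hi[2L],
                                     lo[3L]:hi[3L], drop = FALSE],
                         volume$voxel_size_um,
                         volume$origin_um + (lo - 1) * volume$voxel_size_um)
    fit_psf(crop, r2_floor = r2_floor)
  })
  do.call(rbind, recs)
}

#' Summarize PSF records
#'
#' Per-axis mean and sample standard deviation of the FWHM over all
#' unflagged records.
#'
#' @param records data.frame of records from [fit_psf()] or
#'   [characterize_psf()].
#' @return an object of class `psf_summary`: list with `mean_fwhm_nm`,
#'   `sd_fwhm_nm` (named x, y, z), `mean_tilt_deg` and `n_beads`.
#' @export
summarize_psf <- function(records) {
  recs <- records[!records$flagged, , drop = FALSE]
  if (nrow(recs) == 0L) stop("no unflagged PSF records to summarize")
  cols <- c(x = "fwhm_x_nm", y = "fwhm_y_nm", z = "fwhm_z_nm")
  m <- vapply(cols, function(cl) mean(recs[[cl]]), 0)
  s <- vapply(cols, function(cl) if (nrow(recs) > 1L) stats::sd(recs[[cl]]) else 0, 0)
  structure(list(mean_fwhm_nm = m, sd_fwhm_nm = s,
                 mean_tilt_deg = mean(recs$tilt_deg), n_beads = nrow(recs)),
            class = "psf_summary")
}

#' @export
print.psf_summary <- function(x, ...) {
  cat(sprintf("<psf_summary> n = %d beads, tilt %.1f deg\n", x$n_beads,
              x$mean_tilt_deg))
  for (ax in c("x", "y", "z")) {
    cat(sprintf("  FWHM %s'': %.1f +/- %.1f nm\n", ax,
                x$mean_fwhm_nm[[ax]], x$sd_fwhm_nm[[ax]]))
  }
  invisible(x)
}
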