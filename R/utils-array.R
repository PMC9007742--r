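# Low-level array helpers shared across the package. Volumes are dense 3D
# arrays indexed (dim1, dim2, dim3); the package-wide convention is
# (z, y, x) for coverslip-aligned volumes and (s, y, x') for raw stacks.

vol_data <- function(x) {
  if (inherits(x, "ortho_volume") || inherits(x, "oblique_stack")) x$data else x
}

#' Trilinear interpolation at fractional 1-based indices
#'
#' Samples `vol` at positions (`i1`, `i2`, `i3`). Points outside the array
#' evaluate to 0 (`clamp = FALSE`) or to the nearest edge value
#' (`clamp = TRUE`). Exact integer positions reproduce the stored values
#' bit-exactly.
#'
#' @param vol 3D numeric array.
#' @param i1,i2,i3 numeric vectors of fractional indices along each dimension.
#' @param clamp replicate edges instead of zero-padding.
#' @return numeric vector of sampled values.
#' @keywords internal
#' @noRd
interp3 <- function(vol, i1, i2, i3, clamp = FALSE) {
  d <- dim(vol)
  if (clamp) {
    i1 <- pmin(pmax(i1, 1), d[1L])
    i2 <- pmin(pmax(i2, 1), d[2L])
    i3 <- pmin(pmax(i3, 1), d[3L])
  }
  a0 <- floor(i1); b0 <- floor(i2); c0 <- floor(i3)
  fa <- i1 - a0; fb <- i2 - b0; fc <- i3 - c0
  n12 <- d[1L] * d[2L]
  gather <- function(a, b, c) {
    ok <- a >= 1 & a <= d[1L] & b >= 1 & b <= d[2L] & c >= 1 & c <= d[3L]
    v <- numeric(length(a))
    if (any(ok)) {
      idx <- (c[ok] - 1) * n12 + (b[ok] - 1) * d[1L] + a[ok]
      v[ok] <- vol[idx]
    }
    v
  }
  gather(a0,     b0,     c0    ) * (1 - fa) * (1 - fb) * (1 - fc) +
  gather(a0 + 1, b0,     c0    ) * fa       * (1 - fb) * (1 - fc) +
  gather(a0,     b0 + 1, c0    ) * (1 - fa) * fb       * (1 - fc) +
  gather(a0,     b0,     c0 + 1) * (1 - fa) * (1 - fb) * fc +
  gather(a0 + 1, b0 + 1, c0    ) * fa       * fb       * (1 - fc) +
  gather(a0 + 1, b0,     c0 + 1) * fa       * (1 - fb) * fc +
  gather(a0,     b0 + 1, c0 + 1) * (1 - fa) * fb       * fc +
  gather(a0 + 1, b0 + 1, c0 + 1) * fa       * fb       * fc
}

# Catmull-Rom cubic weights for fractional offset t in [0, 1)
cr_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
}

# Tricubic (Catmull-Rom) interpolation; edge-clamped. Meant for modest point
# counts (line profiles), not whole-volume resampling.
interp3_cubic <- function(vol, i1, i2, i3) {
  d <- dim(vol)
  a0 <- floor(i1); b0 <- floor(i2); c0 <- floor(i3)
  wa <- cr_weights(i1 - a0); wb <- cr_weights(i2 - b0); wc <- cr_weights(i3 - c0)
  n12 <- d[1L] * d[2L]
  out <- numeric(length(i1))
  for (ka in 0:3) {
    aa <- pmin(pmax(a0 - 1 + ka, 1), d[1L])
    for (kb in 0:3) {
      bb <- pmin(pmax(b0 - 1 + kb, 1), d[2L])
      wab <- wa[, ka + 1L] * wb[, kb + 1L]
      for (kc in 0:3) {
        cc <- pmin(pmax(c0 - 1 + kc, 1), d[3L])
        idx <- (cc - 1) * n12 + (bb - 1) * d[1L] + aa
        out <- out + vol[idx] * wab * wc[, kc + 1L]
      }
    }
  }
  out
}

# Full index grids (as vectors in column-major order) for a given dim
index_grid <- function(d) {
  list(i1 = rep.int(seq_len(d[1L]), d[2L] * d[3L]),
       i2 = rep.int(rep(seq_len(d[2L]), each = d[1L]), d[3L]),
       i3 = rep(seq_len(d[3L]), each = d[1L] * d[2L]))
}

#' Translate a volume by a (possibly fractional) shift
#'
#' Content moves by `+shift` voxels along (dim1, dim2, dim3); uncovered
#' voxels are zero-filled. Integer shifts reproduce values exactly.
#'
#' @param vol 3D numeric array.
#' @param shift numeric length-3 shift in voxels.
#' @return shifted array of the same dimensions.
#' @keywords internal
#' @noRd
translate_volume <- function(vol, shift) {
  d <- dim(vol)
  g <- index_grid(d)
  array(interp3(vol, g$i1 - shift[1L], g$i2 - shift[2L], g$i3 - shift[3L]), d)
}

# Apply matrix W (n_out x n_in) along one axis of a 3D array
axis_apply <- function(vol, axis, W) {
  d <- dim(vol)
  if (axis == 1L) {
    array(W %*% matrix(vol, d[1L]), c(nrow(W), d[2L], d[3L]))
  } else if (axis == 2L) {
    v <- aperm(vol, c(2L, 1L, 3L))
    v <- array(W %*% matrix(v, d[2L]), c(nrow(W), d[1L], d[3L]))
    aperm(v, c(2L, 1L, 3L))
  } else {
    v <- aperm(vol, c(3L, 2L, 1L))
    v <- array(W %*% matrix(v, d[3L]), c(nrow(W), d[2L], d[1L]))
    aperm(v, c(3L, 2L, 1L))
  }
}

# Row-normalized Gaussian smoothing matrix (edge-renormalized so that
# smoothing a constant returns the constant exactly)
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  i <- seq_len(n)
  W <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  W / rowSums(W)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Edge-renormalized: smoothing a constant array returns it unchanged.
#'
#' @param vol 3D numeric array.
#' @param sigma scalar or length-3 standard deviation in voxels per axis.
#' @keywords internal
#' @noRd
gaussian_smooth <- function(vol, sigma) {
  sigma <- rep_len(sigma, 3L)
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigma[ax] > 0) vol <- axis_apply(vol, ax, gauss_matrix(d[ax], sigma[ax]))
  }
  vol
}

# Shift along one axis with replicated (clamped) edges
axshift_rep <- function(vol, axis, off) {
  d <- dim(vol)
  idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
  switch(axis, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

# Running box min/max with half-width r per axis (separable)
box_extreme <- function(vol, r, fun) {
  r <- rep_len(as.integer(r), 3L)
  for (ax in 1:3) {
    if (r[ax] <= 0) next
    acc <- vol
    for (off in seq_len(r[ax])) {
      acc <- fun(acc, axshift_rep(vol, ax, off), axshift_rep(vol, ax, -off))
    }
    vol <- acc
  }
  vol
}

box_min <- function(vol, r) box_extreme(vol, r, function(a, b, c) pmin(a, b, c))
box_max <- function(vol, r) box_extreme(vol, r, function(a, b, c) pmax(a, b, c))

# Greyscale opening with a box structuring element of half-width r
grey_opening <- function(vol, r) box_max(box_min(vol, r), r)

# Centered 3-tap convolution along an axis with replicate padding
conv3_axis <- function(vol, axis, k) {
  k[1L] * axshift_rep(vol, axis, 1L) + k[2L] * vol +
    k[3L] * axshift_rep(vol, axis, -1L)
}

#' Sobel gradient magnitude of a 3D array
#'
#' 3D Sobel operator: central difference along each axis smoothed by the
#' (1, 2, 1)/4 binomial kernel along the two transverse axes.
#'
#' @param vol 3D numeric array.
#' @keywords internal
#' @noRd
sobel_magnitude <- function(vol) {
  ksm <- c(1, 2, 1) / 4
  kdf <- c(-0.5, 0, 0.5)
  acc <- 0
  for (ax in 1:3) {
    g <- vol
    for (bx in 1:3) g <- conv3_axis(g, bx, if (bx == ax) kdf else ksm)
    acc <- acc + g * g
  }
  sqrt(acc)
}

# Interpolation basis matrix mapping values at `pos_in` to positions
# `pos_out` (natural cubic spline when >= 4 nodes, linear otherwise;
# constant extrapolation beyond the node range).
interp_basis <- function(pos_in, pos_out) {
  n <- length(pos_in)
  pos_out <- pmin(pmax(pos_out, min(pos_in)), max(pos_in))
  if (n == 1L) return(matrix(1, length(pos_out), 1L))
  W <- matrix(0, length(pos_out), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    W[, j] <- if (n >= 4L) {
      stats::spline(pos_in, e, xout = pos_out, method = "natural")$y
    } else {
      stats::approx(pos_in, e, xout = pos_out)$y
    }
  }
  W
}

# Subvoxel translation by Fourier phase shift (sinc interpolation,
# circular boundary); exact roll for integer shifts, no interpolation
# blur for fractional ones.
fourier_shift <- function(vol, shift) {
  d <- dim(vol)
  F <- stats::fft(vol)
  for (ax in 1:3) {
    if (shift[ax] == 0) next
    k <- c(0:(ceiling(d[ax] / 2) - 1), -(floor(d[ax] / 2):1))
    ph <- exp(-2i * pi * k * shift[ax] / d[ax])
    if (d[ax] %% 2 == 0) ph[d[ax] / 2 + 1] <- Re(ph[d[ax] / 2 + 1])
    rep_dim <- c(if (ax > 1) prod(d[seq_len(ax - 1)]) else 1L, d[ax])
    F <- F * rep(rep(ph, each = rep_dim[1L]), length.out = prod(d))
  }
  Re(stats::fft(F, inverse = TRUE)) / prod(d)
}

# rms helper
rms <- function(x) sqrt(mean(x^2))
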