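# Translation estimation by 3D phase correlation and the iterative
# multi-scale chunked warp registration used to align view 2 onto view 1.
#
# Shift convention: phase_correlation(a, b) returns the vector `shift`
# such that b is (approximately) a translated by +shift, i.e.
# b ~= translate(a, shift). A warp field F applied by apply_warp() is a
# backward field: out(x) = moving(x + F(x)), so the field that registers
# `moving = translate(fixed, t)` onto `fixed` is F = t everywhere.

#' Configuration of the multi-scale warp registration
#'
#' @param max_iterations maximum number of refinement iterations (>= 1).
#'   Default 4.
#' @param min_chunk_voxels minimum chunk edge length in voxels (>= 8);
#'   iteration stops before chunks would fall below this. Default 32.
#' @param split_rule `"dyadic"` divides each axis into 2^i chunks at
#'   iteration i (2, 4, 8, ...); `"linear"` uses 2*i (2, 4, 6, ...).
#' @param confidence_floor minimum phase-correlation peak value for a
#'   chunk's vector to be accepted, referenced to a 32^3 chunk; for
#'   other chunk sizes the floor is scaled by `sqrt(32^3 / n_voxels)`,
#'   since the correlation peak of a genuine match (and of the null)
#'   shrinks with chunk size roughly as `1 / sqrt(n_voxels)`. Default
#'   0.02; rejected vectors are interpolated from accepted neighbors.
#' @param overlap_frac fractional overlap of neighboring chunks per axis.
#'   Default 0.25.
#' @param variance_floor chunks whose intensity variance falls below this
#'   get confidence 0. Default 1e-8.
#' @param window apodization applied to chunks before the FFT:
#'   `"hann"` (default; suppresses spectral leakage from non-periodic
#'   chunk boundaries) or `"none"`.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(max_iterations = 4L, min_chunk_voxels = 32L,
                                split_rule = c("dyadic", "linear"),
                                confidence_floor = 0.02, overlap_frac = 0.25,
                                variance_floor = 1e-8,
                                window = c("hann", "none")) {
  split_rule <- match.arg(split_rule)
  window <- match.arg(window)
  stopifnot(max_iterations >= 1, min_chunk_voxels >= 8,
            confidence_floor >= 0, confidence_floor <= 1,
            overlap_frac >= 0, overlap_frac < 0.5)
  structure(list(max_iterations = as.integer(max_iterations),
                 min_chunk_voxels = as.integer(min_chunk_voxels),
                 split_rule = split_rule,
                 confidence_floor = confidence_floor,
                 overlap_frac = overlap_frac,
                 variance_floor = variance_floor,
                 window = window),
            class = "registration_config")
}

splits_at <- function(config, i) {
  if (config$split_rule == "dyadic") 2L^i else 2L * i
}

#' 3D translation estimation by phase correlation
#'
#' Computes the displacement maximizing the inverse transform of the
#' normalized cross-power spectrum. The integer peak is refined to
#' subvoxel precision either by a locally upsampled DFT evaluation of
#' the correlation around the peak (default; accurate to a few
#' hundredths of a voxel) or by a parabolic fit to the peak and its
#' circular neighbors. Both inputs are mean-subtracted first; the
#' spectrum normalization is lightly regularized for numerical
#' stability. An optional Hann window suppresses the spectral leakage
#' of non-periodic content (at the cost of exactness for pure circular
#' shifts, so the default is none).
#'
#' @param a,b equal-shape 3D numeric arrays (or [ortho_volume()]s).
#' @param window `"none"` (default) or `"hann"`.
#' @param refine `"dft"` (default) or `"parabola"`.
#' @param upsample subvoxel resolution of the `"dft"` refinement
#'   (1/upsample voxels). Default 20.
#' @return list with `shift` (length-3, voxels along (dim1, dim2, dim3);
#'   `b ~= a` translated by `+shift`) and `confidence` (correlation peak
#'   in [0, 1]; 0 for constant input).
#' @export
#' @examples
#' a <- array(stats::rnorm(8^3), c(8, 8, 8))
#' b <- a[c(6:8, 1:5), , ]   # circular shift by +3 along dim1
#' phase_correlation(a, b)$shift
phase_correlation <- function(a, b, window = c("none", "hann"),
                              refine = c("dft", "parabola"), upsample = 20) {
  window <- match.arg(window)
  refine <- match.arg(refine)
  a <- vol_data(a); b <- vol_data(b)
  stopifnot(all(dim(a) == dim(b)))
  d <- dim(a)
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) {
    return(list(shift = c(0, 0, 0), confidence = 0))
  }
  if (window == "hann") {
    for (ax in 1:3) {
      w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[ax]) - 1) / (d[ax] - 1))
      wdim <- c(if (ax > 1) prod(d[seq_len(ax - 1)]) else 1, d[ax])
      wfull <- rep(rep(w, each = wdim[1L]), length.out = prod(d))
      a <- a * wfull
      b <- b * wfull
    }
  }
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  cross <- Fb * Conj(Fa)
  mag <- Mod(cross)
  r <- Re(stats::fft(cross / (mag + 1e-9 * max(mag)), inverse = TRUE)) / prod(d)
  peak <- which.max(r)
  pk <- arrayInd(peak, d)[1L, ]
  conf <- min(max(r[peak], 0), 1)

  shift <- numeric(3L)
  if (refine == "parabola") {
    for (ax in 1:3) {
      idx <- function(k) {          # circular neighbor along one axis
        j <- pk; j[ax] <- ((pk[ax] - 1 + k) %% d[ax]) + 1
        r[j[1L], j[2L], j[3L]]
      }
      r0 <- r[pk[1L], pk[2L], pk[3L]]
      rm <- idx(-1L); rp <- idx(1L)
      denom <- 2 * (2 * r0 - rp - rm)
      frac <- if (abs(denom) > .Machine$double.eps) (rp - rm) / denom else 0
      frac <- min(max(frac, -0.5), 0.5)
      s <- (pk[ax] - 1) + frac
      if (s > d[ax] / 2) s <- s - d[ax]   # map to (-N/2, N/2]
      shift[ax] <- s
    }
  } else {
    # locally upsampled DFT: evaluate the correlation on a fine grid in a
    # +/- 1 voxel neighborhood of the integer peak
    norm_cp <- cross / (mag + 1e-9 * max(mag))
    offsets <- seq(-1, 1, by = 1 / upsample)
    cur <- norm_cp
    for (ax in 1:3) {
      k <- c(0:(ceiling(d[ax] / 2) - 1), -(floor(d[ax] / 2):1))
      E <- exp(2i * pi * outer(offsets + (pk[ax] - 1), k) / d[ax])
      dm <- dim(cur)
      cur <- if (ax == 1L) {
        array(E %*% matrix(cur, dm[1L]), c(length(offsets), dm[2L], dm[3L]))
      } else if (ax == 2L) {
        aperm(array(E %*% matrix(aperm(cur, c(2L, 1L, 3L)), dm[2L]),
                    c(length(offsets), dm[1L], dm[3L])), c(2L, 1L, 3L))
      } else {
        aperm(array(E %*% matrix(aperm(cur, c(3L, 2L, 1L)), dm[3L]),
                    c(length(offsets), dm[2L], dm[1L])), c(3L, 2L, 1L))
      }
    }
    rf <- Re(cur)
    fi <- arrayInd(which.max(rf), dim(rf))[1L, ]
    nf <- length(offsets)
    for (ax in 1:3) {
      # continuous sub-grid position: parabola through the fine-grid peak
      frac <- 0
      if (fi[ax] > 1L && fi[ax] < nf) {
        j <- fi; j[ax] <- fi[ax] - 1L
        rm_ <- rf[j[1L], j[2L], j[3L]]
        j[ax] <- fi[ax] + 1L
        rp_ <- rf[j[1L], j[2L], j[3L]]
        r0_ <- rf[fi[1L], fi[2L], fi[3L]]
        den <- 2 * (2 * r0_ - rp_ - rm_)
        if (abs(den) > .Machine$double.eps) {
          frac <- min(max((rp_ - rm_) / den, -0.5), 0.5)
        }
      }
      s <- (pk[ax] - 1) + offsets[fi[ax]] + frac / upsample
      if (s > d[ax] / 2) s <- s - d[ax]
      shift[ax] <- s
    }
  }
  list(shift = shift, confidence = conf)
}

# Chunk boundaries: list of (from, to, center) per chunk along one axis
chunk_bounds <- function(n, n_chunks, overlap_frac) {
  edges <- round(seq(0, n, length.out = n_chunks + 1))
  lapply(seq_len(n_chunks), function(j) {
    len <- edges[j + 1L] - edges[j]
    o <- round(overlap_frac * len)
    list(from = max(1L, edges[j] + 1L - o),
         to = min(n, edges[j + 1L] + o),
         center = (edges[j] + edges[j + 1L] + 1) / 2)
  })
}

# Inverse-distance-weighted fill of rejected nodes from accepted ones
fill_nodes_idw <- function(values, good, centers) {
  dnode <- dim(good)
  gidx <- which(good)
  bidx <- which(!good)
  if (length(bidx) == 0L) return(values)
  gi <- arrayInd(gidx, dnode)
  bi <- arrayInd(bidx, dnode)
  gpos <- cbind(centers[[1L]][gi[, 1L]], centers[[2L]][gi[, 2L]],
                centers[[3L]][gi[, 3L]])
  bpos <- cbind(centers[[1L]][bi[, 1L]], centers[[2L]][bi[, 2L]],
                centers[[3L]][bi[, 3L]])
  nn <- prod(dnode)
  for (k in seq_along(bidx)) {
    w <- 1 / (rowSums((gpos - rep(bpos[k, ], each = nrow(gpos)))^2) + 1e-6)
    for (cmp in 1:3) {
      values[bidx[k] + (cmp - 1L) * nn] <-
        sum(w * values[gidx + (cmp - 1L) * nn]) / sum(w)
    }
  }
  values
}

# Upsample a node field component (3D array of node values at `centers`)
# to full resolution `d` via separable natural-spline interpolation
upsample_nodes <- function(node_vals, centers, d) {
  out <- node_vals
  for (ax in 1:3) {
    W <- interp_basis(centers[[ax]], seq_len(d[ax]))
    out <- axis_apply(out, ax, W)
  }
  out
}

#' Warp field on a grid of chunk-center nodes
#'
#' Displacement 3-vectors (voxels, backward convention) at the node grid
#' of the final registration iteration, with per-node confidence. The
#' zero field acts as the identity under [apply_warp()].
#'
#' @param values 4D array (n1, n2, n3, 3) of node displacement vectors.
#' @param centers list of 3 numeric vectors: node center coordinates
#'   (voxels) along each axis.
#' @param dim_full dimensions of the volume the field covers.
#' @param confidence 3D array (n1, n2, n3) of per-node confidences.
#' @return an object of class `warp_field`.
#' @export
warp_field <- function(values, centers, dim_full,
                       confidence = NULL) {
  stopifnot(length(dim(values)) == 4L, dim(values)[4L] == 3L,
            length(centers) == 3L)
  if (is.null(confidence)) confidence <- array(1, dim(values)[1:3])
  structure(list(values = values, centers = centers,
                 dim_full = as.integer(dim_full), confidence = confidence),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  dn <- dim(x$values)[1:3]
  cat(sprintf("<warp_field> %d x %d x %d nodes over a %s volume, |v| max %.3g vox\n",
              dn[1L], dn[2L], dn[3L], paste(x$dim_full, collapse = " x "),
              max(abs(x$values))))
  invisible(x)
}

# Slab size (voxels along dim3) that keeps full-volume warping and field
# composition within bounded temporary memory
slab_starts <- function(d, target = 2e6) {
  step <- max(1L, floor(target / (d[1L] * d[2L])))
  seq(1L, d[3L], by = step)
}

# Index vectors for a dim3 slab [from, to]
slab_grid <- function(d, from, to) {
  len <- to - from + 1L
  list(i1 = rep.int(seq_len(d[1L]), d[2L] * len),
       i2 = rep.int(rep(seq_len(d[2L]), each = d[1L]), len),
       i3 = rep(from:to, each = d[1L] * d[2L]),
       idx = (d[1L] * d[2L] * (from - 1L) + 1L):(d[1L] * d[2L] * to))
}

# Backward-warp a volume by a full-resolution field, slab by slab
warp_with_full_field <- function(vol, field_full) {
  d <- dim(vol)
  starts <- slab_starts(d)
  step <- if (length(starts) > 1L) diff(starts[1:2]) else d[3L]
  out <- array(0, d)
  for (from in starts) {
    to <- min(from + step - 1L, d[3L])
    g <- slab_grid(d, from, to)
    out[g$idx] <- interp3(vol, g$i1 + field_full[[1L]][g$idx],
                          g$i2 + field_full[[2L]][g$idx],
                          g$i3 + field_full[[3L]][g$idx])
  }
  out
}

# Compose: new(x) = inc(x) + old(x + inc(x)); overwrites inc slab-wise and
# returns it (old is read whole but never copied)
compose_fields <- function(inc_full, field_full) {
  d <- dim(inc_full[[1L]])
  starts <- slab_starts(d)
  step <- if (length(starts) > 1L) diff(starts[1:2]) else d[3L]
  for (from in starts) {
    to <- min(from + step - 1L, d[3L])
    g <- slab_grid(d, from, to)
    p1 <- g$i1 + inc_full[[1L]][g$idx]
    p2 <- g$i2 + inc_full[[2L]][g$idx]
    p3 <- g$i3 + inc_full[[3L]][g$idx]
    for (cmp in 1:3) {
      inc_full[[cmp]][g$idx] <- inc_full[[cmp]][g$idx] +
        interp3(field_full[[cmp]], p1, p2, p3, clamp = TRUE)
    }
  }
  inc_full
}

#' Iterative multi-scale chunked warp registration
#'
#' Registers `moving` onto `fixed`. At iteration i the volume is divided
#' into chunks along all three axes (2^i chunks per axis by default, with
#' 25% overlap); corresponding chunk pairs are registered with a
#' translation model by [phase_correlation()]; vectors below the
#' confidence floor are interpolated from accepted neighbors; the
#' resulting node field is spline-interpolated to full resolution and
#' composed with the field of the previous iterations, and the original
#' moving volume is re-warped before the next refinement. Iteration stops
#' at `max_iterations` or when chunks would fall below
#' `min_chunk_voxels`.
#'
#' @param fixed,moving equal-shape 3D arrays or [ortho_volume()]s.
#' @param config a [registration_config()].
#' @return a [warp_field()] whose nodes sit at the chunk centers of the
#'   finest iteration reached.
#' @export
multiscale_warp_register <- function(fixed, moving,
                                     config = registration_config()) {
  fixed <- vol_data(fixed); moving <- vol_data(moving)
  stopifnot(all(dim(fixed) == dim(moving)),
            inherits(config, "registration_config"))
  d <- dim(fixed)

  field_full <- NULL      # list of 3 full-resolution displacement arrays
  last_nodes <- NULL

  for (i in seq_len(config$max_iterations)) {
    nch <- splits_at(config, i)
    if (any(floor(d / nch) < config$min_chunk_voxels)) {
      # volumes too small to split register globally (one chunk, pure
      # translation, identical to a single phase correlation)
      if (i == 1L) nch <- 1L else break
    }

    moving_cur <- if (is.null(field_full)) moving else
      warp_with_full_field(moving, field_full)

    bounds <- lapply(1:3, function(ax) chunk_bounds(d[ax], nch,
                                                    config$overlap_frac))
    centers <- lapply(bounds, function(bb) vapply(bb, `[[`, 0, "center"))
    vals <- array(0, c(nch, nch, nch, 3L))
    conf <- array(0, c(nch, nch, nch))
    floor_eff <- array(Inf, c(nch, nch, nch))
    for (k3 in seq_len(nch)) for (k2 in seq_len(nch)) for (k1 in seq_len(nch)) {
      b1 <- bounds[[1L]][[k1]]; b2 <- bounds[[2L]][[k2]]; b3 <- bounds[[3L]][[k3]]
      fa <- fixed[b1$from:b1$to, b2$from:b2$to, b3$from:b3$to]
      fb <- moving_cur[b1$from:b1$to, b2$from:b2$to, b3$from:b3$to]
      floor_eff[k1, k2, k3] <- config$confidence_floor *
        sqrt(32768 / length(fa))
      if (stats::var(as.vector(fa)) < config$variance_floor ||
          stats::var(as.vector(fb)) < config$variance_floor) next
      pc <- phase_correlation(fa, fb, window = config$window)
      vals[k1, k2, k3, ] <- pc$shift
      conf[k1, k2, k3] <- pc$confidence
    }

    good <- conf >= pmin(floor_eff, 1)
    if (!any(good)) {
      stop(sprintf(
        "registration failed at iteration %d: all %d chunks below the size-scaled confidence floor (reference %.3g at 32^3; max confidence %.3g)",
        i, length(conf), config$confidence_floor, max(conf)))
    }
    vals <- fill_nodes_idw(vals, good, centers)

    # backward field increment: moving_cur(x + F_inc(x)) matches fixed,
    # and F_inc at a node is the measured shift of moving relative to fixed
    inc_full <- lapply(1:3, function(cmp)
      upsample_nodes(array(vals[, , , cmp], c(nch, nch, nch)), centers, d))
    rm(moving_cur)

    field_full <- if (is.null(field_full)) inc_full else
      compose_fields(inc_full, field_full)
    rm(inc_full)
    gc(verbose = FALSE)
    last_nodes <- list(centers = centers, conf = conf)
  }

  if (is.null(field_full)) {
    stop(sprintf(
      "volume of size %s admits no chunks of at least %d voxels with the configured split rule",
      paste(d, collapse = " x "), config$min_chunk_voxels))
  }

  centers <- last_nodes$centers
  nn <- vapply(centers, length, 0L)
  gi <- list(i1 = rep.int(centers[[1L]], nn[2L] * nn[3L]),
             i2 = rep.int(rep(centers[[2L]], each = nn[1L]), nn[3L]),
             i3 = rep(centers[[3L]], each = nn[1L] * nn[2L]))
  vals <- array(0, c(nn, 3L))
  for (cmp in 1:3) {
    vals[, , , cmp] <- array(interp3(field_full[[cmp]], gi$i1, gi$i2, gi$i3,
                                     clamp = TRUE), nn)
  }
  warp_field(vals, centers, d, last_nodes$conf)
}

#' Apply a warp field to a volume
#'
#' Backward warping: the output at voxel x is the moving volume sampled
#' at x + F(x), with both the field (spline-upsampled from its node
#' grid) and the volume interpolated linearly. A zero field is an exact
#' identity.
#'
#' @param volume 3D array or [ortho_volume()] matching the field's
#'   `dim_full`.
#' @param field a [warp_field()].
#' @return the warped volume, same class as the input.
#' @export
apply_warp <- function(volume, field) {
  stopifnot(inherits(field, "warp_field"))
  v <- vol_data(volume)
  stopifnot(all(dim(v) == field$dim_full))
  d <- dim(v)
  nn <- dim(field$values)[1:3]
  full <- lapply(1:3, function(cmp)
    upsample_nodes(array(field$values[, , , cmp], nn), field$centers, d))
  out <- warp_with_full_field(v, full)
  if (inherits(volume, "ortho_volume")) {
    ortho_volume(out, volume$voxel_size_um, volume$origin_um)
  } else {
    out
  }
}
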