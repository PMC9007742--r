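# Temporal drift stabilization. Pairwise shifts between each time point
# and its 2n nearest neighbors are measured by phase correlation; the
# absolute trajectory A is recovered from the relative measurements R by
# solving the band system R = M A, using an L1 (robust) data-fidelity
# criterion so that occasional grossly wrong measurements do not corrupt
# the trajectory.

#' Pairwise relative shifts within a time series
#'
#' For every pair (t, t+k), k = 1..n (clipped at the ends of the series),
#' the relative displacement is measured by [phase_correlation()];
#' interior time points therefore participate in 2n pairs.
#'
#' @param series list of equal-shape 3D arrays (or [ortho_volume()]s).
#' @param n neighbor radius; default 7.
#' @return data.frame of class `relative_shifts`: columns `t`, `t2`
#'   (1-based), `dz`, `dy`, `dx`, `confidence`; attribute `n_timepoints`.
#' @export
pairwise_shifts <- function(series, n = 7L) {
  T <- length(series)
  stopifnot(T >= 2, n >= 1)
  frames <- lapply(series, vol_data)
  rows <- list()
  for (t in seq_len(T - 1L)) {
    for (k in seq_len(min(n, T - t))) {
      pc <- phase_correlation(frames[[t]], frames[[t + k]])
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, t2 = t + k, dz = pc$shift[1L], dy = pc$shift[2L],
        dx = pc$shift[3L], confidence = pc$confidence)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_timepoints") <- T
  attr(out, "n_neighbors") <- as.integer(n)
  class(out) <- c("relative_shifts", class(out))
  out
}

#' Inject gross outliers into measured shifts
#'
#' Test harness for solver robustness: a fraction of the shift entries is
#' corrupted by adding `+/- magnitude` (random sign per axis) to all
#' three components. Deterministic per seed.
#'
#' @param shifts a [pairwise_shifts()] table.
#' @param fraction fraction of entries to corrupt, in [0, 1).
#' @param magnitude outlier magnitude in voxels.
#' @param seed integer seed.
#' @return the corrupted table; attribute `"corrupted"` marks the rows.
#' @export
corrupt_shifts <- function(shifts, fraction, magnitude, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1, magnitude >= 0)
  m <- nrow(shifts)
  n_bad <- round(fraction * m)
  withr::with_seed(as.integer(seed), {
    bad <- sample.int(m, n_bad)
    signs <- matrix(sample(c(-1, 1), 3L * n_bad, replace = TRUE), n_bad, 3L)
  })
  shifts[bad, c("dz", "dy", "dx")] <-
    shifts[bad, c("dz", "dy", "dx")] + magnitude * signs
  attr(shifts, "corrupted") <- sort(bad)
  shifts
}

#' Solve the absolute drift trajectory from relative shifts
#'
#' Builds the band system `R = M A` (each measurement row has -1 at t and
#' +1 at t+k) and recovers the per-axis absolute trajectory `A`, anchored
#' at `A[1] = 0`. The default `"l1"` method minimizes the L1 norm of the
#' residuals by iteratively reweighted least squares, which tolerates
#' grossly wrong measurements; `"l2"` is the plain least-squares
#' inversion, kept as a baseline. Phase-correlation confidences multiply
#' the rows as soft prior weights. Axes are solved independently (the
#' system is separable).
#'
#' @param shifts a [pairwise_shifts()] table (possibly corrupted).
#' @param method `"l1"` (robust, default) or `"l2"`.
#' @param iterations IRLS iterations for `"l1"`. Default 50.
#' @param epsilon IRLS smoothing of the residual magnitude. Default 1e-6.
#' @param use_confidence multiply rows by measurement confidence.
#' @return an object of class `drift_trajectory`: matrix T x 3 (`dz`,
#'   `dy`, `dx`) with attributes `gauge` and `method`.
#' @export
solve_trajectory <- function(shifts, method = c("l1", "l2"),
                             iterations = 50L, epsilon = 1e-6,
                             use_confidence = TRUE) {
  method <- match.arg(method)
  T <- attr(shifts, "n_timepoints")
  if (is.null(T)) T <- max(shifts$t2)
  m <- nrow(shifts)
  stopifnot(m >= 1, T >= 2)

  # connectivity of the pair graph over 1..T (monotone label propagation)
  comp <- seq_len(T)
  repeat {
    old <- comp
    for (e in seq_len(m)) {
      v <- min(comp[shifts$t[e]], comp[shifts$t2[e]])
      comp[shifts$t[e]] <- v
      comp[shifts$t2[e]] <- v
    }
    if (identical(comp, old)) break
  }
  if (length(unique(comp)) > 1L) {
    grp <- split(seq_len(T), comp)
    stop(sprintf(
      "pair graph is disconnected: time points {%s} are not linked to the rest",
      paste(grp[[2L]], collapse = ", ")))
  }

  # M with the anchored column (t = 1) removed; unknowns A[2..T]
  rows <- rep(seq_len(m), 2L)
  cols <- c(shifts$t, shifts$t2) - 1L        # column 0 = anchored A[1]
  vals <- c(rep(-1, m), rep(1, m))
  keep <- cols >= 1L
  M <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = vals[keep],
                            dims = c(m, T - 1L))
  w0 <- if (use_confidence && !is.null(shifts$confidence)) {
    pmax(shifts$confidence, 1e-3)
  } else {
    rep(1, m)
  }

  A <- matrix(0, T, 3L)
  for (ax in 1:3) {
    r <- shifts[[c("dz", "dy", "dx")[ax]]]
    wls <- function(w) {
      MtW <- Matrix::t(M * w)
      as.numeric(Matrix::solve(MtW %*% M, MtW %*% r))
    }
    if (method == "l2") {
      sol <- wls(w0)
    } else {
      sol <- wls(w0)
      for (it in seq_len(iterations)) {
        res <- as.numeric(M %*% sol) - r
        sol <- wls(w0 / pmax(abs(res), epsilon))
      }
    }
    A[-1L, ax] <- sol
  }
  colnames(A) <- c("dz", "dy", "dx")
  structure(A, gauge = "first_frame_zero", method = method,
            class = c("drift_trajectory", "matrix", "array"))
}

#' Remove drift from a time series
#'
#' Translates frame t by `-A[t, ]` so the series is stabilized to its
#' first frame. Subvoxel shifts use Fourier (sinc) interpolation by
#' default, which preserves sharpness exactly for band-limited content
#' and reduces integer shifts to exact rolls; `"linear"` uses trilinear
#' interpolation with zero fill instead.
#'
#' @param series list of equal-shape 3D arrays (or [ortho_volume()]s).
#' @param trajectory a [solve_trajectory()] result (or T x 3 matrix of
#'   absolute shifts in voxels).
#' @param method `"fourier"` (default) or `"linear"`.
#' @return list of stabilized 3D arrays.
#' @export
stabilize_series <- function(series, trajectory,
                             method = c("fourier", "linear")) {
  method <- match.arg(method)
  stopifnot(length(series) == nrow(trajectory))
  lapply(seq_along(series), function(t) {
    fr <- vol_data(series[[t]])
    if (all(trajectory[t, ] == 0)) {
      fr
    } else if (method == "fourier") {
      fourier_shift(fr, -trajectory[t, ])
    } else {
      translate_volume(fr, -trajectory[t, ])
    }
  })
}
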