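# Light-sheet stabilized stage scanning (LS3) timing simulator. The stage
# moves continuously; during each camera exposure a galvo translates the
# light sheet at the same rate so the imaging plane is motionless relative
# to the sample, and flies back during the readout. The simulator predicts
# residual motion blur, the galvo waveform and acquisition throughput.

#' Scan timing for light-sheet stabilized stage scanning
#'
#' @param exposure_ms camera exposure per frame, ms (> 0).
#' @param readout_ms camera readout per frame, ms (> 0).
#' @param stage_speed_um_per_s continuous stage speed, um/s (> 0).
#' @param galvo_rate_um_per_s light-sheet translation rate during the
#'   exposure, um/s; defaults to the stage speed (perfect compensation).
#' @param flyback_ms galvo return time; must fit within the readout.
#'   Defaults to `readout_ms`.
#' @param galvo_range_um usable optical scan range of the galvo, um
#'   (total peak-to-peak). Default 300.
#' @return an object of class `scan_timing` with the above fields plus
#'   `frame_period_ms = exposure_ms + readout_ms`.
#' @export
#' @examples
#' tm <- scan_timing(exposure_ms = 10, readout_ms = 10,
#'                   stage_speed_um_per_s = 100)
#' residual_blur(tm)
scan_timing <- function(exposure_ms, readout_ms, stage_speed_um_per_s,
                        galvo_rate_um_per_s = stage_speed_um_per_s,
                        flyback_ms = readout_ms, galvo_range_um = 300) {
  stopifnot(exposure_ms > 0, readout_ms > 0, stage_speed_um_per_s > 0,
            galvo_rate_um_per_s >= 0, flyback_ms > 0, galvo_range_um > 0)
  if (flyback_ms > readout_ms) {
    stop("flyback_ms must not exceed readout_ms (the galvo must return before the next exposure)")
  }
  structure(list(exposure_ms = exposure_ms, readout_ms = readout_ms,
                 stage_speed_um_per_s = stage_speed_um_per_s,
                 galvo_rate_um_per_s = galvo_rate_um_per_s,
                 flyback_ms = flyback_ms, galvo_range_um = galvo_range_um,
                 frame_period_ms = exposure_ms + readout_ms),
            class = "scan_timing")
}

#' @export
print.scan_timing <- function(x, ...) {
  cat(sprintf(
    "<scan_timing> exposure %g ms + readout %g ms; stage %g um/s, galvo %g um/s\n",
    x$exposure_ms, x$readout_ms, x$stage_speed_um_per_s, x$galvo_rate_um_per_s))
  invisible(x)
}

#' Residual motion blur of one frame
#'
#' Without compensation, the sample moves by `stage_speed x exposure`
#' during a frame; with the galvo tracking the stage the blur shrinks to
#' `|stage_speed - galvo_rate| x exposure` and vanishes exactly when the
#' rates match.
#'
#' @param timing a [scan_timing()].
#' @param compensated logical; apply the galvo compensation. Default TRUE.
#' @return blur length in micrometres.
#' @export
residual_blur <- function(timing, compensated = TRUE) {
  stopifnot(inherits(timing, "scan_timing"))
  rate <- if (compensated) {
    abs(timing$stage_speed_um_per_s - timing$galvo_rate_um_per_s)
  } else {
    timing$stage_speed_um_per_s
  }
  rate * timing$exposure_ms / 1000
}

#' Simulate the LS3 event schedule and galvo waveform
#'
#' Produces the per-frame exposure/readout schedule and the sampled
#' galvo position waveform: a linear ramp tracking the stage during each
#' exposure and a raised-cosine return during the readout. When
#' compensated, the sample-sheet relative displacement is zero
#' throughout every exposure window.
#'
#' @param timing a [scan_timing()].
#' @param n_frames number of frames (>= 1).
#' @param sample_rate_hz waveform sampling rate. Default 1e5.
#' @return list with `schedule` (data.frame: frame, exposure/readout
#'   start and end times in ms, effective scan step in um) and
#'   `waveform` (data.frame: `time_ms`, `stage_um`, `galvo_um`,
#'   `relative_um` = stage - sheet displacement within the current
#'   exposure, `phase`, `frame`). Warns if one exposure sweeps the galvo
#'   beyond half its optical range on either side of center.
#' @export
simulate_scan <- function(timing, n_frames, sample_rate_hz = 1e5) {
  stopifnot(inherits(timing, "scan_timing"), n_frames >= 1)
  Tf <- timing$frame_period_ms
  step_um <- timing$stage_speed_um_per_s * Tf / 1000
  amp <- timing$galvo_rate_um_per_s * timing$exposure_ms / 1000
  if (amp / 2 > timing$galvo_range_um / 2) {
    warning(sprintf(
      "galvo sweep of %.1f um per exposure exceeds the +/-%g um optical range",
      amp, timing$galvo_range_um / 2))
  }

  schedule <- data.frame(
    frame = seq_len(n_frames),
    exposure_start_ms = (seq_len(n_frames) - 1) * Tf,
    exposure_end_ms = (seq_len(n_frames) - 1) * Tf + timing$exposure_ms,
    readout_end_ms = seq_len(n_frames) * Tf,
    scan_step_um = step_um)

  dt <- 1000 / sample_rate_hz
  tms <- seq(0, n_frames * Tf, by = dt)
  frame <- pmin(floor(tms / Tf), n_frames - 1)
  tin <- tms - frame * Tf
  in_exp <- tin <= timing$exposure_ms

  galvo <- numeric(length(tms))
  galvo[in_exp] <- timing$galvo_rate_um_per_s * tin[in_exp] / 1000 - amp / 2
  tro <- tin[!in_exp] - timing$exposure_ms
  fb <- pmin(tro / timing$flyback_ms, 1)
  galvo[!in_exp] <- amp / 2 - amp * (1 - cos(pi * fb)) / 2   # raised cosine

  stage <- timing$stage_speed_um_per_s * tms / 1000
  # sample-sheet relative displacement accrued within the current exposure
  rel <- numeric(length(tms))
  rel[in_exp] <- (timing$stage_speed_um_per_s - timing$galvo_rate_um_per_s) *
    tin[in_exp] / 1000
  rel[!in_exp] <- NA_real_

  list(schedule = schedule,
       waveform = data.frame(time_ms = tms, stage_um = stage,
                             galvo_um = galvo, relative_um = rel,
                             phase = ifelse(in_exp, "exposure", "readout"),
                             frame = frame + 1L))
}

#' Acquisition throughput over a scan range
#'
#' @param timing a [scan_timing()].
#' @param scan_range_um total scan range along x, micrometres (> 0).
#' @return list with `n_frames` (= ceiling(range / step)),
#'   `scan_step_um`, `seconds_per_volume` and `duty_cycle`
#'   (= exposure / frame period).
#' @export
acquisition_rate <- function(timing, scan_range_um) {
  stopifnot(inherits(timing, "scan_timing"), scan_range_um > 0)
  step_um <- timing$stage_speed_um_per_s * timing$frame_period_ms / 1000
  n_frames <- ceiling(scan_range_um / step_um)
  list(n_frames = n_frames, scan_step_um = step_um,
       seconds_per_volume = n_frames * timing$frame_period_ms / 1000,
       duty_cycle = timing$exposure_ms / timing$frame_period_ms)
}
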