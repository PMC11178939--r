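## Beat-period estimation and selection of frames spanning one beat cycle,
## plus the motility triage used for immotile/irregularly vibrating
## flagella. The periodic observable is the tangent angle interpolated at a
## fixed arc position (default: mid-flagellum, where beat amplitude is
## largest away from the fixed head).

#' Tangent angle time series at a fixed arc position
#'
#' Linearly interpolates each frame's tangent-angle profile at `s_probe`.
#' Frames whose profile does not cover `s_probe` are excluded and flagged.
#'
#' @param profiles List of [tangent_profile()] objects (>= 2).
#' @param s_probe Arc position (um from the head).
#' @return Data frame with columns `frame_index`, `time_s`, `theta`; a
#'   `"qc"` attribute lists excluded frames.
#' @export
probe_signal <- function(profiles, s_probe) {
  stopifnot(length(profiles) >= 2)
  qc <- character()
  th <- vapply(profiles, function(pr) {
    if (s_probe < pr$s[1] || s_probe > pr$s[length(pr$s)]) return(NA_real_)
    stats::approx(pr$s, pr$theta, xout = s_probe)$y
  }, 0)
  excluded <- is.na(th)
  if (any(excluded)) {
    qc <- sprintf("probe at %.2f um outside range of %d frames",
                  s_probe, sum(excluded))
  }
  if (sum(!excluded) < 2L) {
    stop_flagwave("fewer than 2 frames cover the probe position",
                  "flagwave_probe_error")
  }
  structure(
    data.frame(
      frame_index = vapply(profiles, function(p) {
        as.integer(p$frame_index)
      }, 0L)[!excluded],
      time_s = vapply(profiles, function(p) as.numeric(p$time_s),
                      0)[!excluded],
      theta = th[!excluded]),
    qc = qc)
}

#' Estimate beat frequency from a periodic angle series
#'
#' Default method: subtract the mean, take the periodogram, locate the peak
#' and refine its position by parabolic interpolation over three bins
#' (log-power). The signal-to-noise ratio is the peak power divided by the
#' median off-peak power. A flagellum is called motile only when
#' `snr >= snr_threshold` and the beat amplitude reaches
#' `amplitude_threshold_rad` peak-to-peak; for the spectral method the
#' amplitude is that of the peak frequency component (the raw series range
#' would be inflated by frame-to-frame tracing noise on immotile
#' flagella). Otherwise the frequency is undefined (`NA`)
#' and `motile = FALSE` (no error). A zero-crossing counter is available as
#' a cross-check method.
#'
#' @param series Numeric angle series (rad), or the data frame returned by
#'   [probe_signal()].
#' @param fps Sampling rate (frames/second).
#' @param method `"spectral"` or `"zero_crossing"`.
#' @param snr_threshold,amplitude_threshold_rad Motility thresholds (see
#'   [waveform_config()]).
#' @return Object of class `beat_estimate` with fields `frequency_hz`,
#'   `period_frames`, `method`, `snr`, `motile`.
#' @export
estimate_beat_frequency <- function(series, fps,
                                    method = c("spectral", "zero_crossing"),
                                    snr_threshold = 5,
                                    amplitude_threshold_rad = 0.2) {
  method <- match.arg(method)
  if (is.data.frame(series)) series <- series$theta
  n <- length(series)
  if (n < 8L || (n - 1) / fps < 0.2) {
    stop_flagwave("series too short for beat estimation (< 0.2 s)",
                  "flagwave_series_error")
  }
  p2p <- diff(range(series))
  x <- series - mean(series)
  not_motile <- function(snr) {
    structure(list(frequency_hz = NA_real_, period_frames = NA_real_,
                   method = method, snr = snr, motile = FALSE),
              class = "beat_estimate")
  }
  if (p2p == 0) return(not_motile(NA_real_))
  if (method == "spectral") {
    ft <- stats::fft(x)
    pw <- Mod(ft)^2 / n
    k <- seq(2L, floor(n / 2) + 1L)         # positive frequencies, no DC
    pk <- pw[k]
    i_star <- which.max(pk)
    off <- setdiff(seq_along(pk), (i_star - 1L):(i_star + 1L))
    med_off <- stats::median(pk[off])
    snr <- if (length(off) && med_off > 0) pk[i_star] / med_off else Inf
    ## beat amplitude as the peak component's peak-to-peak: raw range is
    ## inflated by frame-to-frame tracing noise on immotile flagella
    p2p <- 2 * 2 * Mod(ft[k[i_star]]) / n
    ## parabolic refinement on log power over 3 bins
    delta <- 0
    if (i_star > 1L && i_star < length(pk)) {
      lp <- log(pmax(pk[(i_star - 1L):(i_star + 1L)], .Machine$double.xmin))
      den <- lp[1] - 2 * lp[2] + lp[3]
      if (is.finite(den) && den < 0) {
        delta <- max(-0.5, min(0.5, 0.5 * (lp[1] - lp[3]) / den))
      }
    }
    freq <- (i_star - 1L + 1L + delta) * fps / n   # bin k corresponds to (k-1)/n
  } else {
    sgn <- sign(x)
    sgn <- sgn[sgn != 0]
    crossings <- sum(diff(sgn) != 0)
    snr <- NA_real_
    freq <- crossings / 2 / ((n - 1) / fps)
  }
  motile <- p2p >= amplitude_threshold_rad && is.finite(freq) && freq > 0
  if (method == "spectral") {
    motile <- motile && !is.na(snr) && snr >= snr_threshold
  }
  if (!motile) return(not_motile(snr))
  structure(list(frequency_hz = freq, period_frames = fps / freq,
                 method = method, snr = snr, motile = TRUE),
            class = "beat_estimate")
}

#' @export
print.beat_estimate <- function(x, ...) {
  if (x$motile) {
    cat(sprintf("<beat_estimate> %.3f Hz (%.1f frames/period, snr %.1f, %s)\n",
                x$frequency_hz, x$period_frames, x$snr, x$method))
  } else {
    cat("<beat_estimate> not motile (frequency undefined)\n")
  }
  invisible(x)
}

#' Select frames spanning one beat cycle
#'
#' Deterministically picks `min_frames` frames from the earliest complete
#' beat period, as uniformly phase-spaced as the recording allows: for each
#' target phase `j/min_frames` the nearest unused frame is taken (ties go to
#' the earlier frame).
#'
#' @param profiles List of [tangent_profile()] objects with time stamps.
#' @param beat A motile [estimate_beat_frequency()] result.
#' @param min_frames Number of frames to select (>= 5 by convention).
#' @return The selected profiles, ordered by time.
#' @export
select_cycle_frames <- function(profiles, beat, min_frames = 5) {
  stopifnot(inherits(beat, "beat_estimate"))
  if (!isTRUE(beat$motile)) {
    stop_flagwave("beat estimate is not motile", "flagwave_cycle_error")
  }
  times <- vapply(profiles, `[[`, 0, "time_s")
  if (is.unsorted(times)) {
    o <- order(times)
    profiles <- profiles[o]; times <- times[o]
  }
  period <- 1 / beat$frequency_hz
  t0 <- times[1]
  dt <- if (length(times) > 1) min(diff(times)) else Inf
  if (max(times) - t0 < period - dt - 1e-9) {
    stop_flagwave("cannot cover one cycle: recording shorter than one period",
                  "flagwave_cycle_error")
  }
  in_cycle <- which(times - t0 < period - 1e-9)
  if (length(in_cycle) < min_frames) {
    stop_flagwave(sprintf(
      "cannot cover one cycle: %d frames within the first period, %d needed",
      length(in_cycle), min_frames), "flagwave_cycle_error")
  }
  targets <- t0 + period * (seq_len(min_frames) - 1) / min_frames
  chosen <- integer(0)
  for (tt in targets) {
    avail <- setdiff(in_cycle, chosen)
    d <- abs(times[avail] - tt)
    chosen <- c(chosen, avail[which.min(d)])   # which.min: earliest on ties
  }
  profiles[sort(chosen)]
}
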