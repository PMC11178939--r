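## Static/dynamic decomposition of the beat and the circle-fit asymmetry
## index. The static component is a single ordinary least-squares line
## fitted to the pooled (s, theta) samples of all frames spanning one beat
## cycle; its slope (rad/um) is the basal curvature, the package's central
## statistic. Subtracting the line from each frame's tangent profile leaves
## the dynamic (propagating) component.

#' Fit the static component (basal curvature)
#'
#' Ordinary least squares of the pooled tangent angles on arc length across
#' all supplied profiles. The slope is the basal curvature (rad/um).
#' Single-profile input is supported for quantifying immotile or
#' irregularly vibrating flagella from one traced frame.
#'
#' @param profiles A [tangent_profile()] or list of them (unwrapped, um).
#' @return Object of class `static_fit` with fields `slope`, `intercept`,
#'   `n_points`, `r_squared`, `shifted` (always `FALSE` here; the origin
#'   shift used for plotting is applied by [tangent_plot_data()] and never
#'   affects the slope).
#' @export
fit_static_component <- function(profiles) {
  if (inherits(profiles, "tangent_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  ## profiles are unwrapped frame by frame, so two frames can land on
  ## 2*pi-offset branches (e.g. when theta(0) straddles +/- pi); shift each
  ## frame by the 2*pi multiple bringing its mean closest to the first
  ## frame's before pooling
  if (length(profiles) > 1) {
    ref <- mean(profiles[[1]]$theta)
    profiles <- lapply(profiles, function(p) {
      k <- round((mean(p$theta) - ref) / (2 * pi))
      if (k != 0) p$theta <- p$theta - 2 * pi * k
      p
    })
  }
  s <- unlist(lapply(profiles, `[[`, "s"), use.names = FALSE)
  th <- unlist(lapply(profiles, `[[`, "theta"), use.names = FALSE)
  if (length(s) < 2L) {
    stop_flagwave("fewer than 2 pooled samples", "flagwave_fit_error")
  }
  vs <- stats::var(s)
  if (vs == 0) stop_flagwave("degenerate abscissa", "flagwave_fit_error")
  slope <- stats::cov(s, th) / vs
  intercept <- mean(th) - slope * mean(s)
  ss_res <- sum((th - slope * s - intercept)^2)
  ss_tot <- sum((th - mean(th))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 n_points = length(s), r_squared = r2, shifted = FALSE),
            class = "static_fit")
}

#' @export
print.static_fit <- function(x, ...) {
  cat(sprintf(
    "<static_fit> basal curvature %.4f rad/um, intercept %.4f rad (n = %d, R2 = %.3f)\n",
    x$slope, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' Dynamic component (residual tangent profiles)
#'
#' Subtracts the fitted static line from every tangent profile:
#' `theta'(s, t) = theta(s, t) - (slope * s + intercept)`. Adding the line
#' back reproduces the input exactly (to float rounding).
#'
#' @param profiles List of [tangent_profile()] objects.
#' @param fit A [fit_static_component()] result produced from these
#'   profiles (or a compatible grid).
#' @return List of profiles with `theta` replaced by the residuals, class
#'   `dynamic_component`.
#' @export
dynamic_component <- function(profiles, fit) {
  if (inherits(profiles, "tangent_profile")) profiles <- list(profiles)
  stopifnot(inherits(fit, "static_fit"))
  ok <- vapply(profiles, function(p) length(p$s) == length(p$theta), TRUE)
  if (!all(ok)) stop_flagwave("profile grid mismatch", "flagwave_fit_error")
  out <- lapply(profiles, function(p) {
    p$theta <- p$theta - (fit$slope * p$s + fit$intercept)
    class(p) <- c("dynamic_profile", class(p))
    p
  })
  structure(out, fit = fit, class = "dynamic_component")
}

#' Bend asymmetry index at a fixed arc position
#'
#' Interpolates each cycle frame's signed curvature at `position_um`
#' (default 10 um from the head) and takes the two signed extremes over the
#' cycle. `kappa_max` is the extreme of larger magnitude (the P-bend by the
#' working convention), `kappa_min` the opposite extreme (R-bend), and the
#' index is `|kappa_max| / |kappa_min| >= 1` (or the raw signed ratio when
#' `signed = TRUE`). Frames whose traced length does not reach
#' `position_um` are excluded with a QC flag. When the smaller extreme's
#' magnitude falls below `curvature_floor` the index is undefined.
#'
#' @param curv_profiles List of [curvature_profile()] objects, one per
#'   frame of one beat cycle.
#' @param position_um Arc position (um from the head).
#' @param min_frames Minimum frames required after exclusions.
#' @param curvature_floor Magnitude floor (1/um) for the denominator.
#' @param signed Use the raw signed ratio instead of the magnitude ratio.
#' @return Object of class `asymmetry_result` with fields `kappa_max`,
#'   `kappa_min`, `index`, `p_bend_frame`, `r_bend_frame`, `position_um`,
#'   `qc_flags`.
#' @export
asymmetry_index <- function(curv_profiles, position_um = 10, min_frames = 5,
                            curvature_floor = 1e-4, signed = FALSE) {
  stopifnot(length(curv_profiles) >= 1)
  qc <- character()
  vals <- lapply(curv_profiles, function(cp) {
    if (position_um < min(cp$s) || position_um > max(cp$s)) return(NULL)
    data.frame(frame_index = cp$frame_index,
               kappa = stats::approx(cp$s, cp$kappa, xout = position_um)$y)
  })
  short <- vapply(vals, is.null, TRUE)
  if (any(short)) {
    qc <- c(qc, sprintf("%d frames shorter than %.1f um excluded",
                        sum(short), position_um))
  }
  vals <- do.call(rbind, vals[!short])
  if (is.null(vals) || nrow(vals) < min_frames) {
    stop_flagwave(sprintf("asymmetry index needs >= %d frames at s = %.1f um",
                          min_frames, position_um), "flagwave_index_error")
  }
  i_hi <- which.max(vals$kappa)
  i_lo <- which.min(vals$kappa)
  k_hi <- vals$kappa[i_hi]   # signed maximum
  k_lo <- vals$kappa[i_lo]   # signed minimum
  if (abs(k_hi) >= abs(k_lo)) {
    kappa_max <- k_hi; kappa_min <- k_lo
    p_frame <- vals$frame_index[i_hi]; r_frame <- vals$frame_index[i_lo]
  } else {
    kappa_max <- k_lo; kappa_min <- k_hi
    p_frame <- vals$frame_index[i_lo]; r_frame <- vals$frame_index[i_hi]
  }
  if (abs(kappa_min) < curvature_floor) {
    qc <- c(qc, "near-straight recovery bend")
    index <- NA_real_
  } else if (signed) {
    index <- k_hi / k_lo
  } else {
    index <- abs(kappa_max) / abs(kappa_min)
  }
  structure(list(kappa_max = kappa_max, kappa_min = kappa_min, index = index,
                 p_bend_frame = p_frame, r_bend_frame = r_frame,
                 position_um = position_um, qc_flags = qc),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "<asymmetry_result> index %s at %.1f um (P-bend %.4f /um frame %s, R-bend %.4f /um frame %s)\n",
    format(x$index, digits = 4), x$position_um, x$kappa_max,
    format(x$p_bend_frame), x$kappa_min, format(x$r_bend_frame)))
  invisible(x)
}

#' Plot-ready tangent tables (origin-shifted)
#'
#' Exports the pooled per-frame tangent angles together with the fitted
#' static line, optionally translated so the line passes through the origin
#' (the presentation convention for tangent-angle plots). The shift never
#' affects the slope.
#'
#' @param profiles List of [tangent_profile()] objects.
#' @param fit A [fit_static_component()] result.
#' @param shift Translate so the fitted line passes through (0, 0).
#' @return Data frame with columns `frame_index`, `s`, `theta`, `fitted`.
#' @export
tangent_plot_data <- function(profiles, fit, shift = TRUE) {
  if (inherits(profiles, "tangent_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(frame_index = p$frame_index, s = p$s, theta = p$theta,
               fitted = fit$slope * p$s + fit$intercept)
  })
  df <- do.call(rbind, rows)
  if (shift) {
    ## theta -> theta - intercept puts the line through the origin
    df$theta <- df$theta - fit$intercept
    df$fitted <- df$fitted - fit$intercept
  }
  df
}

#' End-to-end analysis of one flagellum
#'
#' Runs the full per-flagellum pipeline: unit conversion, tangent (and
#' curvature) profiles, beat-frequency estimation at the mid-flagellum
#' probe, selection of frames spanning one beat cycle, the pooled static
#' fit, and the asymmetry index at the configured arc position. Flagella
#' triaged as not motile are quantified from a single frame chosen by a
#' seeded random draw (recorded in `qc_flags`); their beat frequency and
#' asymmetry index are left undefined.
#'
#' @param trace_set A `flag_trace_set` (pixel or micron units).
#' @param config A [waveform_config()].
#' @return Object of class `flagellum_result` with fields `flagellum_id`,
#'   `genotype`, `condition`, `n_frames_used`, `basal_curvature` (rad/um),
#'   `intercept`, `r_squared`, `asymmetry_index`, `beat_frequency_hz`,
#'   `snr`, `motile`, `mean_abs_curvature` (single-frame mode only), and
#'   `qc_flags`.
#' @export
analyze_flagellum <- function(trace_set, config = waveform_config()) {
  stopifnot(inherits(trace_set, "flag_trace_set"))
  qc <- trace_set$qc_flags
  ts <- to_microns(trace_set)
  if (!length(ts$traces)) {
    stop_flagwave(sprintf("trace_io: no valid traces for '%s'",
                          ts$flagellum_id), "flagwave_stage_error")
  }
  profs <- list(); kept <- integer(0)
  for (i in seq_along(ts$traces)) {
    pr <- tryCatch(
      tangent_profile(ts$traces[[i]], step_px = config$step_px,
                      window_px = config$window_px,
                      pixel_size_um = config$pixel_size_um),
      flagwave_short_trace = function(e) e)
    if (inherits(pr, "condition")) {
      qc <- c(qc, sprintf("frame %d dropped in geometry: %s",
                          ts$traces[[i]]$frame_index, conditionMessage(pr)))
    } else {
      qc <- c(qc, attr(pr, "qc"))
      profs <- c(profs, list(pr)); kept <- c(kept, i)
    }
  }
  if (!length(profs)) {
    stop_flagwave(sprintf("geometry: no usable frames for '%s'",
                          ts$flagellum_id), "flagwave_stage_error")
  }
  ## beat estimation at the mid-flagellum probe
  beat <- NULL
  n_prof <- length(profs)
  duration <- if (n_prof > 1) {
    profs[[n_prof]]$time_s - profs[[1]]$time_s
  } else 0
  if (n_prof >= 8 && duration >= 0.2) {
    s_probe <- config$probe_fraction *
      min(vapply(profs, function(p) max(p$s), 0))
    sig <- tryCatch(probe_signal(profs, s_probe),
                    flagwave_probe_error = function(e) e)
    if (!inherits(sig, "condition")) {
      qc <- c(qc, attr(sig, "qc"))
      beat <- estimate_beat_frequency(
        sig, fps = ts$fps, method = config$frequency_method,
        snr_threshold = config$snr_threshold,
        amplitude_threshold_rad = config$amplitude_threshold_rad)
    } else {
      qc <- c(qc, sprintf("kinematics: %s", conditionMessage(sig)))
    }
  } else {
    qc <- c(qc, "kinematics: recording too short for beat estimation")
  }

  asym <- NA_real_
  mean_abs_kappa <- NA_real_
  if (!is.null(beat) && beat$motile) {
    cyc <- tryCatch(
      select_cycle_frames(profs, beat,
                          min_frames = config$min_frames_per_cycle),
      flagwave_cycle_error = function(e) e)
    if (inherits(cyc, "condition")) {
      qc <- c(qc, sprintf("kinematics: %s; pooling all frames",
                          conditionMessage(cyc)))
      cyc <- profs
      cycle_complete <- FALSE
    } else {
      cycle_complete <- TRUE
    }
    fit <- fit_static_component(cyc)
    n_used <- length(cyc)
    if (cycle_complete && config$compute_asymmetry) {
      ## the index uses the same traced cycle frames as the static fit:
      ## extremes over many noisy frames are inflated symmetrically and
      ## bias the index toward 1
      cyc_frames <- vapply(cyc, `[[`, 0L, "frame_index")
      idx <- kept[match(cyc_frames,
                        vapply(profs, `[[`, 0L, "frame_index"))]
      curv <- lapply(ts$traces[idx], curvature_profile,
                     window_px = config$window_px, step_px = config$step_px,
                     pixel_size_um = config$pixel_size_um)
      ar <- tryCatch(
        asymmetry_index(curv, position_um = config$asymmetry_position_um,
                        min_frames = config$min_frames_per_cycle,
                        curvature_floor = config$curvature_floor,
                        signed = config$signed_index),
        flagwave_index_error = function(e) e)
      if (inherits(ar, "condition")) {
        qc <- c(qc, sprintf("decomposition: %s", conditionMessage(ar)))
      } else {
        qc <- c(qc, ar$qc_flags)
        asym <- ar$index
      }
    }
    freq <- beat$frequency_hz
    snr <- beat$snr
    motile <- TRUE
  } else {
    ## immotile / irregular: quantify one seeded randomly drawn frame
    seed <- config$immotile_frame_seed +
      sum(utf8ToInt(ts$flagellum_id)) %% 10000L
    pick <- with_seed(seed, sample.int(length(profs), 1L))
    qc <- c(qc, sprintf("immotile: frame %d drawn with seed %d",
                        profs[[pick]]$frame_index, seed))
    fit <- fit_static_component(profs[[pick]])
    cp <- tryCatch(curvature_profile(ts$traces[[kept[pick]]],
                                     window_px = config$window_px,
                                     step_px = config$step_px,
                                     pixel_size_um = config$pixel_size_um),
                   flagwave_short_trace = function(e) NULL)
    if (!is.null(cp)) mean_abs_kappa <- mean(abs(cp$kappa))
    n_used <- 1L
    freq <- NA_real_
    snr <- if (!is.null(beat)) beat$snr else NA_real_
    motile <- FALSE
  }
  ## aggregate repeated QC messages into counts
  if (length(qc)) {
    tab <- table(qc)[unique(qc)]
    qc <- ifelse(tab > 1, sprintf("%s (x%d)", names(tab), tab), names(tab))
  }
  structure(list(flagellum_id = ts$flagellum_id, genotype = ts$genotype,
                 condition = ts$condition, n_frames_used = n_used,
                 basal_curvature = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared, asymmetry_index = asym,
                 beat_frequency_hz = freq, snr = snr, motile = motile,
                 mean_abs_curvature = mean_abs_kappa, qc_flags = qc),
            class = "flagellum_result")
}

#' @export
print.flagellum_result <- function(x, ...) {
  cat(sprintf(
    "<flagellum_result> '%s' (%s/%s): basal curvature %.4f rad/um over %d frames\n",
    x$flagellum_id, x$genotype, x$condition, x$basal_curvature,
    x$n_frames_used))
  cat(sprintf("  beat %s Hz, asymmetry index %s, motile %s\n",
              format(x$beat_frequency_hz, digits = 4),
              format(x$asymmetry_index, digits = 4), x$motile))
  if (length(x$qc_flags)) {
    cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  }
  invisible(x)
}
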