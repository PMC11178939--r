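## Arc-length parameterization, windowed tangent angles and signed curvature
## by sliding circle fits. All angles are measured against the +x image axis
## in the image coordinate frame (origin top-left, y down); positive
## curvature means counterclockwise turning in that frame. Both profiles are
## anchored on the same arc-length grid: the first sample sits at half the
## fitting window, subsequent samples every `step_px * pixel_size_um`.

## accept a flag_trace (micron unit), 2-column matrix, or data frame
as_xy <- function(trace) {
  if (inherits(trace, "flag_trace")) {
    if (trace$unit != "micron") {
      stop_flagwave("trace must be in micron units (see to_microns())",
                    "flagwave_bad_unit")
    }
    return(list(x = trace$x, y = trace$y))
  }
  if (is.matrix(trace) || is.data.frame(trace)) {
    return(list(x = as.numeric(trace[, 1]), y = as.numeric(trace[, 2])))
  }
  stop_flagwave("cannot interpret trace coordinates", "flagwave_bad_coords")
}

#' Cumulative arc length from the head
#'
#' @param trace A micron-unit `flag_trace`, or a 2-column matrix/data frame
#'   of coordinates (assumed um).
#' @return Numeric vector `s` with `s[1] = 0`, strictly increasing.
#' @export
#' @examples
#' cumulative_arclength(cbind(c(0, 3), c(0, 4)))  # 0 5
cumulative_arclength <- function(trace) {
  p <- as_xy(trace)
  if (length(p$x) < 2L) {
    stop_flagwave("need at least 2 points", "flagwave_bad_coords")
  }
  d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  if (any(d == 0)) {
    stop_flagwave("duplicate consecutive points", "flagwave_bad_coords")
  }
  c(0, cumsum(d))
}

#' Unwrap a sequence of angles
#'
#' Adds multiples of 2*pi so that adjacent differences lie in (-pi, pi];
#' the first element is wrapped into (-pi, pi]. Output is congruent to the
#' input modulo 2*pi element-wise.
#'
#' @param theta_raw Numeric vector of angles (rad), non-empty.
#' @return Unwrapped angles (rad).
#' @export
unwrap_angles <- function(theta_raw) {
  stopifnot(length(theta_raw) >= 1)
  out <- numeric(length(theta_raw))
  out[1] <- wrap_pi(theta_raw[1])
  if (length(theta_raw) > 1L) {
    d <- wrap_pi(diff(theta_raw))
    out[-1] <- out[1] + cumsum(d)
  }
  out
}

## window bookkeeping shared by tangent_profile and curvature_profile:
## anchors on the arc-length grid plus index ranges of the points within
## +/- half a window of each anchor
window_grid <- function(s, step_um, window_um) {
  half <- window_um / 2
  S <- s[length(s)]
  if (S < window_um) stop_flagwave("trace too short", "flagwave_short_trace")
  anchors <- seq(half, S - half + 1e-12, by = step_um)
  if (length(anchors) < 2L) {
    stop_flagwave("trace too short", "flagwave_short_trace")
  }
  i_lo <- findInterval(anchors - half - 1e-9, s) + 1L
  i_hi <- findInterval(anchors + half + 1e-9, s)
  list(anchors = anchors, i_lo = i_lo, i_hi = i_hi, n = i_hi - i_lo + 1L)
}

#' Tangent-angle profile of a trace
#'
#' Samples the flagellum every `step_px * pixel_size_um` of arc length
#' (first sample at half the fitting window). At each anchor the tangent
#' direction is the total-least-squares line through all trace points within
#' half a window (`window_px * pixel_size_um / 2`) of arc length, oriented
#' toward increasing `s`; the tangent angle is measured against the +x image
#' axis and unwrapped along `s`.
#'
#' @inheritParams cumulative_arclength
#' @param step_px,window_px Sampling step and fitting window in pixels of
#'   arc length.
#' @param pixel_size_um Pixel size used to convert the pixel-denominated
#'   window/step into physical arc length.
#' @param frame_index,time_s Optional frame metadata copied to the profile
#'   (taken from the trace when it is a `flag_trace`).
#' @return Object of class `tangent_profile` with fields `s` (um), `theta`
#'   (rad, unwrapped), `frame_index`, `time_s`. Windows with fewer than 3
#'   points are dropped and flagged in the `"qc"` attribute.
#' @export
tangent_profile <- function(trace, step_px = 10, window_px = 20,
                            pixel_size_um = 0.04,
                            frame_index = NULL, time_s = NULL) {
  p <- as_xy(trace)
  if (inherits(trace, "flag_trace")) {
    frame_index <- frame_index %||% trace$frame_index
    time_s <- time_s %||% trace$time_s
  }
  s <- cumulative_arclength(trace)
  g <- window_grid(s, step_px * pixel_size_um, window_px * pixel_size_um)
  x <- p$x; y <- p$y
  c0 <- function(v) c(0, cumsum(v))
  cx <- c0(x); cy <- c0(y); cxx <- c0(x^2); cyy <- c0(y^2); cxy <- c0(x * y)
  rng <- function(cs) cs[g$i_hi + 1L] - cs[g$i_lo]
  n <- g$n
  Sx <- rng(cx); Sy <- rng(cy)
  vxx <- rng(cxx) - Sx^2 / n
  vyy <- rng(cyy) - Sy^2 / n
  vxy <- rng(cxy) - Sx * Sy / n
  phi <- 0.5 * atan2(2 * vxy, vxx - vyy)
  chx <- x[g$i_hi] - x[g$i_lo]
  chy <- y[g$i_hi] - y[g$i_lo]
  flip <- cos(phi) * chx + sin(phi) * chy < 0
  phi[flip] <- phi[flip] + pi
  keep <- n >= 3L
  qc <- character()
  if (any(!keep)) {
    qc <- sprintf("dropped %d tangent samples with < 3 points", sum(!keep))
  }
  if (sum(keep) < 2L) stop_flagwave("trace too short", "flagwave_short_trace")
  structure(list(s = g$anchors[keep], theta = unwrap_angles(phi[keep]),
                 frame_index = frame_index %||% NA_integer_,
                 time_s = time_s %||% NA_real_),
            qc = qc, class = "tangent_profile")
}

#' @export
print.tangent_profile <- function(x, ...) {
  cat(sprintf("<tangent_profile> frame %s: %d samples, s in [%.2f, %.2f] um\n",
              format(x$frame_index), length(x$s), min(x$s), max(x$s)))
  invisible(x)
}

#' Algebraic least-squares circle fit
#'
#' Kasa fit: minimizes the algebraic residual
#' \eqn{\sum (\lVert p - c \rVert^2 - r^2)^2}, a closed-form linear
#' least-squares problem. Points whose lateral deviation from their
#' total-least-squares line is below `1e-6` of the window length are
#' declared degenerate (collinear): the radius is reported as `Inf` and the
#' equivalent curvature is 0.
#'
#' @param points 2-column matrix/data frame of coordinates (um), >= 3 rows.
#' @return Object of class `circle_fit` with fields `center` (x, y),
#'   `r` (um), `rms_residual` (um, geometric), `degenerate` (logical).
#' @export
## core Kasa solve on one window, centered at the window mean for
## conditioning; `wlen` is the length scale for the collinearity tolerance
kasa_core <- function(x, y, wlen) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  suu <- sum(u^2); svv <- sum(v^2); suv <- sum(u * v)
  ## lateral spread about the TLS line = sqrt(lambda_min / n)
  lam_min <- ((suu + svv) - sqrt((suu - svv)^2 + 4 * suv^2)) / 2
  lat_rms <- sqrt(max(lam_min, 0) / n)
  degen <- list(center = c(NA_real_, NA_real_), r = Inf, lat_rms = lat_rms,
                degenerate = TRUE)
  if (!is.finite(lat_rms) || lat_rms < 1e-6 * wlen) return(degen)
  z <- u^2 + v^2
  a2 <- 2 * suu; b2 <- 2 * suv; c2 <- 2 * svv
  e1 <- sum(u * z); e2 <- sum(v * z)
  det <- a2 * c2 - b2^2
  if (!is.finite(det) || abs(det) < .Machine$double.eps * (a2 + c2)^2) {
    return(degen)
  }
  uc <- (e1 * c2 - e2 * b2) / det
  vc <- (a2 * e2 - b2 * e1) / det
  list(center = c(uc + mx, vc + my), r = sqrt(uc^2 + vc^2 + mean(z)),
       lat_rms = lat_rms, degenerate = FALSE)
}

fit_circle <- function(points) {
  p <- as_xy(points)
  x <- p$x; y <- p$y
  if (length(x) < 3L) {
    stop_flagwave("need at least 3 points", "flagwave_bad_coords")
  }
  wlen <- sum(sqrt(diff(x)^2 + diff(y)^2))
  k <- kasa_core(x, y, wlen)
  rms <- if (k$degenerate) k$lat_rms else {
    sqrt(mean((sqrt((x - k$center[1])^2 + (y - k$center[2])^2) - k$r)^2))
  }
  structure(list(center = k$center, r = k$r, rms_residual = rms,
                 degenerate = k$degenerate), class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<circle_fit> degenerate (collinear), r = Inf\n")
  } else {
    cat(sprintf("<circle_fit> center (%.3f, %.3f), r = %.4f um, rms %.2e um\n",
                x$center[1], x$center[2], x$r, x$rms_residual))
  }
  invisible(x)
}

#' Signed curvature profile by sliding circle fits
#'
#' On the same arc-length grid as [tangent_profile()], each window of trace
#' points is fitted with a circle (Kasa algebraic fit) and the curvature
#' magnitude is `1/r` (0 when the window is collinear/degenerate). The sign
#' is that of the summed z-component of cross products of successive chord
#' vectors within the window: counterclockwise turning in image coordinates
#' (y down) is positive.
#'
#' @inheritParams tangent_profile
#' @return Object of class `curvature_profile` with fields `s` (um),
#'   `kappa` (signed, 1/um), `frame_index`.
#' @export
curvature_profile <- function(trace, window_px = 20, step_px = 10,
                              pixel_size_um = 0.04, frame_index = NULL) {
  p <- as_xy(trace)
  if (inherits(trace, "flag_trace")) {
    frame_index <- frame_index %||% trace$frame_index
  }
  s <- cumulative_arclength(trace)
  g <- window_grid(s, step_px * pixel_size_um, window_px * pixel_size_um)
  x <- p$x; y <- p$y
  ## turning sign from successive chord cross products (prefix sums)
  dx <- diff(x); dy <- diff(y)
  m <- length(dx)
  cr <- c(0, cumsum(c(dx[-m] * dy[-1] - dy[-m] * dx[-1], 0)))
  keep <- g$n >= 3L
  if (sum(keep) < 2L) stop_flagwave("trace too short", "flagwave_short_trace")
  kappa <- numeric(length(g$anchors))
  for (i in which(keep)) {
    idx <- g$i_lo[i]:g$i_hi[i]
    k <- kasa_core(x[idx], y[idx], s[g$i_hi[i]] - s[g$i_lo[i]])
    if (k$degenerate || !is.finite(k$r) || k$r <= 0) next
    cross_sum <- cr[g$i_hi[i] - 1L] - cr[g$i_lo[i]]
    sgn <- if (cross_sum < 0) -1 else 1
    kappa[i] <- sgn / k$r
  }
  structure(list(s = g$anchors[keep], kappa = kappa[keep],
                 frame_index = frame_index %||% NA_integer_),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> frame %s: %d samples, |kappa| max %.4f /um\n",
              format(x$frame_index), length(x$s), max(abs(x$kappa))))
  invisible(x)
}
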