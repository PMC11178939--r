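## Kinematic simulator of planar flagellar beating: a traveling curvature
## wave kappa(s, t) = kappa0(s) + amp(s) * sin(2*pi*(s/lambda - f*t) + phi)
## superimposed on a static curvature offset, integrated to a shape with the
## head clamped at the origin, then rendered to pixel-quantized noisy traces
## that mimic manual tracing on upscaled video. Ground truth is carried
## alongside so every analysis stage can be validated by parameter
## recovery. The model is kinematic by design: no dynein/sliding-filament
## mechanics and no raster image rendering.

#' Generative parameters of the traveling curvature wave
#'
#' Defaults describe a sperm-model-scale beat: a 30 um flagellum, wavelength
#' 30 um, dynamic curvature amplitude 0.10 1/um, 2 Hz beat recorded at
#' 100 fps for 2 s, trace points every 0.2 um with 0.05 um isotropic
#' tracing noise, quantized to a 0.04 um pixel grid.
#'
#' @param length_um Flagellum length (um).
#' @param kappa0 Static curvature (1/um): a scalar, or a function of arc
#'   length `s` for piecewise/biphasic shapes.
#' @param amp Dynamic curvature amplitude (1/um): scalar or function of `s`
#'   (an envelope, e.g. zero distally for biphasic mutants).
#' @param wavelength_um Curvature wavelength lambda (um).
#' @param freq_hz Beat frequency f (Hz).
#' @param phase0 Phase offset phi (rad).
#' @param theta_head Tangent angle at the head (rad).
#' @param noise_sigma_um Isotropic Gaussian tracing noise per point (um).
#' @param pixel_size_um Pixel size of the rendered coordinates (um/px).
#' @param fps Frames per second.
#' @param duration_s Recording duration (s).
#' @param points_per_um Emitted trace point density (points/um).
#' @param seed Integer seed for noise; `NULL` leaves the RNG untouched.
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(length_um = 30, kappa0 = 0, amp = 0.10,
                        wavelength_um = 30, freq_hz = 2, phase0 = 0,
                        theta_head = 0, noise_sigma_um = 0.05,
                        pixel_size_um = 0.04, fps = 100, duration_s = 2,
                        points_per_um = 5, seed = NULL) {
  stopifnot(length_um > 0, wavelength_um > 0, freq_hz > 0, fps > 0,
            duration_s > 0, points_per_um > 0, pixel_size_um > 0,
            noise_sigma_um >= 0)
  if (!is.function(amp)) stopifnot(amp >= 0)
  structure(list(length_um = length_um, kappa0 = kappa0, amp = amp,
                 wavelength_um = wavelength_um, freq_hz = freq_hz,
                 phase0 = phase0, theta_head = theta_head,
                 noise_sigma_um = noise_sigma_um,
                 pixel_size_um = pixel_size_um, fps = fps,
                 duration_s = duration_s, points_per_um = points_per_um,
                 seed = seed), class = "wave_params")
}

#' Curvature field of the traveling wave
#'
#' `kappa(s, t) = kappa0(s) + amp(s) * sin(2*pi*(s/wavelength - f*t) + phase0)`.
#'
#' @param params A [wave_params()].
#' @param s Arc positions (um), in `[0, length_um]`.
#' @param t Time (s, scalar).
#' @return Signed curvature (1/um) at each `s`.
#' @export
curvature_field <- function(params, s, t) {
  eval_field(params$kappa0, s) + eval_field(params$amp, s) *
    sin(2 * pi * (s / params$wavelength_um - params$freq_hz * t) +
          params$phase0)
}

#' Integrate the wave to a noiseless shape at time t
#'
#' `theta(s, t) = theta_head + integral of kappa`, position by integrating
#' `(cos theta, sin theta)`; the head is clamped at the origin while the
#' head tangent is free to pivot (the head-fixed, flagellum-free observation
#' geometry). Integration uses the trapezoidal rule on a grid no coarser
#' than 0.05 um; points are emitted every `1/points_per_um` of arc length.
#'
#' @param params A [wave_params()].
#' @param t Time (s).
#' @param frame_index Frame number stored on the trace.
#' @return A micron-unit `flag_trace`.
#' @export
integrate_shape <- function(params, t, frame_index = 0L, .grid = NULL) {
  g <- .grid %||% shape_grid(params)
  kap <- curvature_field(params, g$sg, t)
  theta <- params$theta_head + cumtrapz(g$sg, kap)
  xg <- cumtrapz(g$sg, cos(theta))
  yg <- cumtrapz(g$sg, sin(theta))
  new_trace(stats::approx(g$sg, xg, xout = g$s_out)$y,
            stats::approx(g$sg, yg, xout = g$s_out)$y,
            frame_index = frame_index, time_s = t, unit = "micron",
            validate = FALSE)
}

## integration and emission grids are time independent; build once per
## recording
shape_grid <- function(params) {
  L <- params$length_um
  sg <- seq(0, L, by = min(0.05, 1 / params$points_per_um))
  if (sg[length(sg)] < L) sg <- c(sg, L)
  s_out <- seq(0, L, by = 1 / params$points_per_um)
  if (s_out[length(s_out)] < L) s_out <- c(s_out, L)
  list(sg = sg, s_out = s_out)
}

#' Render a full recording with noise and pixel quantization
#'
#' Integrates the shape at every frame, adds isotropic Gaussian tracing
#' noise, offsets the head into the image interior, converts to pixel
#' coordinates and (by default) quantizes to the integer pixel grid, as a
#' manual tracer clicking on upscaled video would. Deterministic given
#' `seed`; the generative parameters travel with the set as the
#' `"ground_truth"` attribute.
#'
#' @param params A [wave_params()].
#' @param flagellum_id,condition,genotype Labels for the trace set.
#' @param quantize Round to integer pixels (default `TRUE`).
#' @return A pixel-unit `flag_trace_set` with a `"ground_truth"` attribute.
#' @export
render_trace_set <- function(params, flagellum_id = "sim",
                             condition = "", genotype = "",
                             quantize = TRUE) {
  n_frames <- max(1L, round(params$fps * params$duration_s))
  times <- (seq_len(n_frames) - 1L) / params$fps
  margin_um <- 1.5 * params$length_um
  px <- params$pixel_size_um
  grid <- shape_grid(params)
  traces <- with_seed(params$seed, {
    lapply(seq_along(times), function(i) {
      tr <- integrate_shape(params, times[i], frame_index = i - 1L,
                            .grid = grid)
      np <- length(tr$x)
      if (params$noise_sigma_um > 0) {
        tr$x <- tr$x + stats::rnorm(np, 0, params$noise_sigma_um)
        tr$y <- tr$y + stats::rnorm(np, 0, params$noise_sigma_um)
      }
      xpx <- (tr$x + margin_um) / px
      ypx <- (tr$y + margin_um) / px
      if (quantize) { xpx <- round(xpx); ypx <- round(ypx) }
      new_trace(xpx, ypx, frame_index = tr$frame_index, time_s = tr$time_s,
                unit = "pixel")
    })
  })
  ts <- new_trace_set(traces, flagellum_id = flagellum_id, fps = params$fps,
                      pixel_size_um = px, condition = condition,
                      genotype = genotype)
  scalar_or_na <- function(v) if (is.function(v)) NA_real_ else v
  attr(ts, "ground_truth") <- list(
    kappa0 = params$kappa0, amp = params$amp, freq_hz = params$freq_hz,
    kappa0_scalar = scalar_or_na(params$kappa0),
    amp_scalar = scalar_or_na(params$amp), seed = params$seed)
  ts
}

#' Scenario presets emulating the studied phenotypes
#'
#' Named parameter bundles whose static-curvature ordering encodes the
#' qualitative biology: calcium (pCa4) induces a strong static curvature in
#' wild type, the calcium-binding-dead E130A mutant shows at most a weak
#' elevation, the calaxin knockout beats biphasically (active proximal
#' half, inactive but highly curved distal half under calcium), and the
#' OAD-less armc4 knockout is immotile - strongly curved when reactivated,
#' relaxed and straight under the dynein inhibitor vanadate.
#'
#' @param name One of `"wt_egta"`, `"wt_pca4"`, `"e130a_egta"`,
#'   `"e130a_pca4"`, `"calaxin_ko"`, `"armc4_ko_active"`,
#'   `"armc4_ko_vanadate"`.
#' @param ... Overrides passed to [wave_params()].
#' @return A list of class `scenario_preset` with elements `name`,
#'   `genotype`, `condition`, `params`.
#' @export
scenario_preset <- function(name = c("wt_egta", "wt_pca4", "e130a_egta",
                                     "e130a_pca4", "calaxin_ko",
                                     "armc4_ko_active",
                                     "armc4_ko_vanadate"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    wt_egta = list(kappa0 = 0, amp = 0.10, freq_hz = 2.0,
                   genotype = "wt", condition = "egta"),
    wt_pca4 = list(kappa0 = 0.05, amp = 0.10, freq_hz = 2.0,
                   genotype = "wt", condition = "pca4"),
    e130a_egta = list(kappa0 = 0, amp = 0.10, freq_hz = 2.0,
                      genotype = "e130a", condition = "egta"),
    e130a_pca4 = list(kappa0 = 0.005, amp = 0.10, freq_hz = 2.0,
                      genotype = "e130a", condition = "pca4"),
    calaxin_ko = list(
      kappa0 = function(s) ifelse(s < 15, 0.01, 0.08),
      amp = function(s) ifelse(s < 15, 0.10, 0.01),
      freq_hz = 2.0, genotype = "calaxin_ko", condition = "pca4"),
    armc4_ko_active = list(kappa0 = 0.15, amp = 0, freq_hz = 2.0,
                           genotype = "armc4_ko", condition = "active"),
    armc4_ko_vanadate = list(kappa0 = 0.01, amp = 0, freq_hz = 2.0,
                             genotype = "armc4_ko", condition = "vanadate"))
  genotype <- spec$genotype; condition <- spec$condition
  spec$genotype <- NULL; spec$condition <- NULL
  overrides <- list(...)
  params <- do.call(wave_params, utils::modifyList(spec, overrides))
  structure(list(name = name, genotype = genotype, condition = condition,
                 params = params), class = "scenario_preset")
}

#' Simulate a labeled cohort with per-flagellum variability
#'
#' For each preset, renders `n_per_group` flagella whose static curvature,
#' dynamic amplitude and beat frequency are each jittered by a relative
#' Gaussian SD (`jitter_rel`, default 10%) to emulate biological
#' variability. Deterministic given `seed`.
#'
#' @param presets Character vector of preset names, or a list of
#'   [scenario_preset()] objects.
#' @param n_per_group Flagella per preset (a single value or one per
#'   preset).
#' @param seed Integer master seed.
#' @param jitter_rel Relative SD of the per-flagellum jitter.
#' @param random_phase Draw each flagellum's recording phase uniformly
#'   (recordings start at an arbitrary point of the beat cycle); disable
#'   for exact single-render reproduction.
#' @param ... Shared [wave_params()] overrides (e.g. `duration_s`).
#' @return A list of class `flag_cohort`: `sets` (named list of
#'   `flag_trace_set`) and `truth` (data frame of ground-truth parameters).
#' @export
make_cohort <- function(presets, n_per_group, seed = 1L, jitter_rel = 0.1,
                        random_phase = TRUE, ...) {
  if (is.character(presets)) presets <- lapply(presets, scenario_preset, ...)
  stopifnot(n_per_group >= 1)
  n_per_group <- rep_len(as.integer(n_per_group), length(presets))
  overrides <- list(...)
  sets <- list(); truth <- list()
  with_seed(seed, {
    for (gi in seq_along(presets)) {
      pre <- presets[[gi]]
      for (i in seq_len(n_per_group[gi])) {
        p <- pre$params
        mk <- max(0.2, 1 + stats::rnorm(1, 0, jitter_rel))
        ma <- max(0.2, 1 + stats::rnorm(1, 0, jitter_rel))
        mf <- max(0.2, 1 + stats::rnorm(1, 0, jitter_rel))
        if (jitter_rel > 0) {
          p$kappa0 <- scale_field(p$kappa0, mk)
          p$amp <- scale_field(p$amp, ma)
          p$freq_hz <- p$freq_hz * mf
        }
        if (random_phase) p$phase0 <- stats::runif(1, 0, 2 * pi)
        p$seed <- sample.int(2147483646L, 1L)
        id <- sprintf("%s_%02d", pre$name, i)
        ts <- render_trace_set(p, flagellum_id = id,
                               condition = pre$condition,
                               genotype = pre$genotype)
        sets[[id]] <- ts
        truth[[id]] <- data.frame(
          flagellum_id = id, preset = pre$name, genotype = pre$genotype,
          condition = pre$condition,
          kappa0 = if (is.function(p$kappa0)) NA_real_ else p$kappa0,
          amp = if (is.function(p$amp)) NA_real_ else p$amp,
          freq_hz = p$freq_hz, phase0 = p$phase0, seed = p$seed,
          stringsAsFactors = FALSE)
      }
    }
  })
  structure(list(sets = sets, truth = do.call(rbind, truth)),
            class = "flag_cohort")
}

scale_field <- function(f, m) {
  if (is.function(f)) {
    force(f); force(m)
    function(s) m * f(s)
  } else {
    m * f
  }
}

#' @export
print.flag_cohort <- function(x, ...) {
  cat(sprintf("<flag_cohort> %d flagella in %d groups\n", length(x$sets),
              length(unique(x$truth$preset))))
  print(table(x$truth$preset))
  invisible(x)
}
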