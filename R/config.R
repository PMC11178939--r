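#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with defaults anchored to
#' the standard acquisition/analysis settings for demembranated sperm-model
#' recordings: 100 fps video upscaled so that one pixel is ~0.04 um, tangent
#' angles sampled every 10 px (~0.4 um) from a 20 px (~0.8 um) fitting
#' window, at least 5 frames per beat cycle pooled for the static fit, the
#' asymmetry index read at 10 um from the head, and significance at
#' alpha = 0.05.
#'
#' @param fps Video frame rate, frames/second.
#' @param pixel_size_um Physical pixel size, um/pixel.
#' @param window_px Tangent/circle fitting window, pixels of arc length.
#' @param step_px Sampling step along the flagellum, pixels of arc length.
#' @param min_frames_per_cycle Minimum number of frames pooled from one beat
#'   cycle for the static fit.
#' @param asymmetry_position_um Arc position (um from the head) at which the
#'   asymmetry index is evaluated.
#' @param probe_fraction Fraction of the shortest common arc length at which
#'   the beat-frequency probe signal is read.
#' @param snr_threshold Minimum periodogram peak/median-off-peak power ratio
#'   for a flagellum to be called motile.
#' @param amplitude_threshold_rad Minimum peak-to-peak tangent-angle
#'   amplitude (rad) at the probe position for motility.
#' @param frequency_method `"spectral"` (periodogram peak with parabolic
#'   refinement) or `"zero_crossing"`.
#' @param curvature_floor Curvatures below this magnitude (1/um) make the
#'   asymmetry-index denominator undefined.
#' @param signed_index If `TRUE`, report the raw signed ratio
#'   `kappa_max / kappa_min` instead of the default magnitude ratio.
#' @param shift_to_origin If `TRUE`, plot-ready exports are translated so the
#'   fitted static line passes through the origin.
#' @param immotile_frame_seed Seed for the random single-frame draw used to
#'   quantify immotile/irregular flagella.
#' @param compute_asymmetry If `FALSE`, [analyze_flagellum()] skips the
#'   circle-fit asymmetry index (faster when only basal curvature is needed).
#' @param export_plot_data If `TRUE`, [cmd_analyze()] writes per-flagellum
#'   plot-ready tangent tables.
#' @param alpha Significance level for group comparisons.
#' @param var_equal If `TRUE`, use Student's pooled-variance t test instead
#'   of the default Welch test.
#'
#' @return A named list of class `waveform_config`.
#' @export
#' @examples
#' cfg <- waveform_config(fps = 100, pixel_size_um = 0.04)
#' cfg$window_px
waveform_config <- function(fps = 100,
                            pixel_size_um = 0.04,
                            window_px = 20,
                            step_px = 10,
                            min_frames_per_cycle = 5,
                            asymmetry_position_um = 10,
                            probe_fraction = 0.5,
                            snr_threshold = 5,
                            amplitude_threshold_rad = 0.2,
                            frequency_method = c("spectral", "zero_crossing"),
                            curvature_floor = 1e-4,
                            signed_index = FALSE,
                            shift_to_origin = FALSE,
                            immotile_frame_seed = 1L,
                            compute_asymmetry = TRUE,
                            export_plot_data = FALSE,
                            alpha = 0.05,
                            var_equal = FALSE) {
  stopifnot(fps > 0, pixel_size_um > 0, window_px > 0, step_px > 0,
            min_frames_per_cycle >= 1, asymmetry_position_um > 0,
            probe_fraction > 0, probe_fraction < 1,
            alpha > 0, alpha < 1)
  structure(list(
    fps = fps, pixel_size_um = pixel_size_um,
    window_px = window_px, step_px = step_px,
    min_frames_per_cycle = as.integer(min_frames_per_cycle),
    asymmetry_position_um = asymmetry_position_um,
    probe_fraction = probe_fraction,
    snr_threshold = snr_threshold,
    amplitude_threshold_rad = amplitude_threshold_rad,
    frequency_method = match.arg(frequency_method),
    curvature_floor = curvature_floor,
    signed_index = isTRUE(signed_index),
    shift_to_origin = isTRUE(shift_to_origin),
    immotile_frame_seed = as.integer(immotile_frame_seed),
    compute_asymmetry = isTRUE(compute_asymmetry),
    export_plot_data = isTRUE(export_plot_data),
    alpha = alpha, var_equal = isTRUE(var_equal)
  ), class = "waveform_config")
}

## merge user/sidecar values (a named list) over the defaults
update_config <- function(config, values) {
  if (is.null(values) || !length(values)) return(config)
  known <- intersect(names(values), names(config))
  for (k in known) config[[k]] <- values[[k]]
  config
}
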