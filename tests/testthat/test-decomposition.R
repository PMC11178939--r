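line_profile <- function(slope, intercept, frame = 0,
                         s = seq(0.4, 28, by = 0.4)) {
  structure(list(s = s, theta = slope * s + intercept, frame_index = frame,
                 time_s = frame / 100), class = "tangent_profile")
}

test_that("static fit recovers exact lines and rejects degenerate input", {
  fit <- fit_static_component(line_profile(0.1, 0.3))
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$shifted)
  bad <- structure(list(s = rep(2, 10), theta = stats::rnorm(10),
                        frame_index = 0, time_s = 0),
                   class = "tangent_profile")
  expect_error(fit_static_component(bad), class = "flagwave_fit_error")
  one <- structure(list(s = 1, theta = 1, frame_index = 0, time_s = 0),
                   class = "tangent_profile")
  expect_error(fit_static_component(one), class = "flagwave_fit_error")
})

test_that("symmetric beating yields near-zero basal curvature", {
  slope <- recover_slope(kappa0 = 0, amp = 0.10, frames_per_cycle = 8,
                         noise = 0, seed = 3, quantize = FALSE)
  expect_lt(abs(slope), 0.005)
})

test_that("basal curvature recovers the generative static curvature", {
  slope <- recover_slope(kappa0 = 0.05, amp = 0.10, frames_per_cycle = 8,
                         noise = 0.05, seed = 7)
  expect_equal(slope, 0.05, tolerance = 0.10)
})

test_that("dynamic component is an exact residual decomposition", {
  profs <- lapply(0:4, function(f) line_profile(0.08, -0.2, frame = f))
  fit <- fit_static_component(profs)
  dyn <- dynamic_component(profs, fit)
  expect_true(all(vapply(dyn, function(p) max(abs(p$theta)), 0) < 1e-9))
  ## reconstruction identity on wavy input
  ts <- render_cycle(kappa0 = 0.03, amp = 0.1, frames_per_cycle = 8,
                     seed = 9)
  profs2 <- cycle_profiles(ts)
  fit2 <- fit_static_component(profs2)
  dyn2 <- dynamic_component(profs2, fit2)
  for (i in seq_along(profs2)) {
    rec <- dyn2[[i]]$theta + fit2$slope * dyn2[[i]]$s + fit2$intercept
    expect_lt(max(abs(rec - profs2[[i]]$theta)), 1e-9)
  }
})

test_that("dynamic component of a symmetric wave is zero-mean sinusoidal", {
  ts <- render_cycle(kappa0 = 0, amp = 0.10, frames_per_cycle = 8,
                     noise = 0, seed = 13, quantize = FALSE)
  profs <- cycle_profiles(ts)
  fit <- fit_static_component(profs)
  dyn <- dynamic_component(profs, fit)
  th <- do.call(rbind, lapply(dyn, `[[`, "theta"))  # frames x positions
  expect_lt(max(abs(colMeans(th))), 0.02)
  ## at every arc position the residual over the cycle is one harmonic
  phase <- 2 * pi * (0:7) / 8
  for (j in seq(1, ncol(th), by = 9)) {
    h <- stats::lm(th[, j] ~ sin(phase) + cos(phase))
    expect_lt(sqrt(mean(stats::resid(h)^2)), 0.02)
  }
})

kappa_profiles <- function(kappa_t, frames = seq_along(kappa_t) - 1,
                           s = seq(0.4, 28, by = 0.4)) {
  lapply(seq_along(kappa_t), function(i) {
    structure(list(s = s, kappa = rep(kappa_t[i], length(s)),
                   frame_index = frames[i]), class = "curvature_profile")
  })
}

test_that("asymmetry index matches the closed form of the extremes", {
  ph <- 2 * pi * (0:19) / 20
  ## symmetric beat: index 1
  sym <- asymmetry_index(kappa_profiles(0.1 * sin(ph)), min_frames = 5)
  expect_equal(sym$index, 1, tolerance = 1e-9)
  ## offset beat: (A + k0) / (A - k0)
  res <- asymmetry_index(kappa_profiles(0.05 + 0.1 * sin(ph)),
                         min_frames = 5)
  expect_equal(res$index, 3, tolerance = 1e-9)
  expect_equal(res$kappa_max, 0.15, tolerance = 1e-12)
  expect_equal(res$kappa_min, -0.05, tolerance = 1e-12)
  expect_equal(res$p_bend_frame, which.max(sin(ph)) - 1)
  expect_equal(res$r_bend_frame, which.min(sin(ph)) - 1)
  expect_gte(res$index, 1)
  ## signed variant returns the raw ratio
  sgn <- asymmetry_index(kappa_profiles(0.05 + 0.1 * sin(ph)),
                         min_frames = 5, signed = TRUE)
  expect_equal(sgn$index, 0.15 / -0.05, tolerance = 1e-9)
  ## near-straight recovery bend: undefined with QC flag
  flt <- asymmetry_index(kappa_profiles(0.1 + 0.1 * sin(ph)), min_frames = 5)
  expect_true(is.na(flt$index))
  expect_match(flt$qc_flags, "near-straight", all = FALSE)
  ## frames shorter than the probe position are excluded
  shortp <- kappa_profiles(0.05 + 0.1 * sin(ph), s = seq(0.4, 8, by = 0.4))
  expect_error(asymmetry_index(shortp, position_um = 10, min_frames = 5),
               class = "flagwave_index_error")
})

test_that("index is monotone in the static offset at fixed amplitude", {
  ph <- 2 * pi * (0:19) / 20
  idx <- vapply(c(0.01, 0.03, 0.05, 0.07), function(k0) {
    asymmetry_index(kappa_profiles(k0 + 0.1 * sin(ph)), min_frames = 5)$index
  }, 0)
  expect_true(all(diff(idx) > 0))
})

test_that("analyze_flagellum covers motile, immotile and determinism", {
  p <- wave_params(kappa0 = 0.05, amp = 0.10, freq_hz = 2, duration_s = 1,
                   seed = 101)
  ts <- render_trace_set(p, "happy", condition = "pca4", genotype = "wt")
  res <- analyze_flagellum(ts)
  expect_s3_class(res, "flagellum_result")
  expect_true(res$motile)
  expect_false(is.na(res$basal_curvature))
  expect_false(is.na(res$beat_frequency_hz))
  expect_false(is.na(res$asymmetry_index))
  expect_gte(res$n_frames_used, 5)
  ## same input, same config: identical output
  expect_identical(res, analyze_flagellum(ts))
  ## immotile: static curvature defined, frequency and index undefined
  pi0 <- wave_params(kappa0 = 0.15, amp = 0, duration_s = 1, seed = 55)
  tsi <- render_trace_set(pi0, "still", condition = "active",
                          genotype = "armc4_ko")
  resi <- analyze_flagellum(tsi)
  expect_false(resi$motile)
  expect_identical(resi$n_frames_used, 1L)
  expect_equal(resi$basal_curvature, 0.15, tolerance = 0.15)
  expect_true(is.na(resi$beat_frequency_hz))
  expect_true(is.na(resi$asymmetry_index))
  expect_false(is.na(resi$mean_abs_curvature))
  expect_match(resi$qc_flags, "immotile: frame", all = FALSE)
})

test_that("basal curvature is rigid-motion invariant and mirror-odd", {
  ts <- render_cycle(kappa0 = 0.05, amp = 0.1, frames_per_cycle = 8,
                     noise = 0.02, seed = 17)
  um <- to_microns(ts)
  fit0 <- fit_static_component(cycle_profiles(ts))
  a <- 0.6
  moved <- um
  moved$traces <- lapply(um$traces, function(tr) {
    x <- cos(a) * tr$x - sin(a) * tr$y + 5
    y <- sin(a) * tr$x + cos(a) * tr$y - 2
    tr$x <- x; tr$y <- y
    tr
  })
  fitr <- fit_static_component(cycle_profiles(moved))
  expect_equal(fitr$slope, fit0$slope, tolerance = 1e-10)
  mirror <- um
  mirror$traces <- lapply(um$traces, function(tr) { tr$x <- -tr$x; tr })
  fitm <- fit_static_component(cycle_profiles(mirror))
  expect_equal(fitm$slope, -fit0$slope, tolerance = 1e-10)
})

test_that("plot export shifts the fitted line through the origin", {
  profs <- lapply(0:2, function(f) line_profile(0.1, 0.3, frame = f))
  fit <- fit_static_component(profs)
  tab <- tangent_plot_data(profs, fit, shift = TRUE)
  m <- stats::lm(fitted ~ s, data = tab)
  expect_equal(unname(stats::coef(m)), c(0, 0.1), tolerance = 1e-10)
  raw <- tangent_plot_data(profs, fit, shift = FALSE)
  expect_equal(unique(raw$theta - tab$theta), fit$intercept)
})
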