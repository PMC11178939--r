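---
title: "Quantifying flagellar waveforms: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flagellar waveforms: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagwave)
```

## The measurement model

A beating flagellum confined to the image plane is described by its tangent
angle $\theta(s,t)$: the angle between the local tangent and the horizontal
image axis, as a function of arc length $s$ from the head. Planar beating
separates into

$$\theta(s,t) \;=\; \underbrace{\kappa_0\, s + \theta_0}_{\text{static
component}} \;+\; \underbrace{\theta'(s,t)}_{\text{dynamic component}},$$

where the static component is the time-averaged shape and the dynamic
component is the propagating wave. The slope $\kappa_0$ of the pooled linear
fit of $\theta$ on $s$ — the **basal curvature**, in rad/µm — quantifies
sustained one-sided bending and is the central statistic of the package.
Because species with round sperm heads offer no head axis to normalize
against, $\theta$ is measured against the image frame, from sperm whose
heads are stuck to the slide while the flagellum beats freely; a global
rotation of the cell only shifts the intercept, never the slope (this is
tested to 1e-10).

The pipeline is:

1. **Tracing input** (`read_trace_table()`): ordered head→tip point
   sequences per video frame, as CSV/TSV or ImageJ ROI polylines, in pixel
   units. Acquisition metadata (fps, µm/px) comes only from a sidecar
   configuration — silent inference would be a correctness hazard.
2. **Geometry** (`tangent_profile()`, `curvature_profile()`): tangent
   angles every `step_px` (default 10 px ≈ 0.4 µm) of arc length from a
   total-least-squares line over a `window_px` (default 20 px ≈ 0.8 µm)
   window; signed curvature from a Kåsa circle fit ($|\kappa| = 1/r$) over
   the same windows, sign = turning direction (counterclockwise in image
   coordinates positive).
3. **Kinematics** (`estimate_beat_frequency()`, `select_cycle_frames()`):
   beat frequency from the periodogram peak of $\theta$ at mid-flagellum,
   refined by parabolic interpolation; ≥ 5 uniform-phase frames selected
   from the earliest complete beat cycle.
4. **Decomposition** (`fit_static_component()`, `dynamic_component()`,
   `asymmetry_index()`): pooled OLS of all selected frames' $(s,\theta)$
   samples; residuals as the dynamic component; the asymmetry index as the
   ratio of the extreme signed curvatures at 10 µm from the head, larger
   magnitude (P-bend) over smaller (R-bend), so symmetric beats give 1.
5. **Statistics** (`compare_groups()`): unpaired two-tailed Welch tests with
   Holm–Bonferroni adjustment across the explicitly listed pairs, α = 0.05.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixel_size_um` | 0.04 | µm/px | 4×-upscaled video; "10 px ≈ 0.4 µm". Not stated exactly anywhere, hence configurable. |
| `window_px` | 20 | px | tangent/circle fitting window (≈ 0.8 µm) |
| `step_px` | 10 | px | sampling step along the flagellum (≈ 0.4 µm) |
| `min_frames_per_cycle` | 5 | frames | minimum pooled time points per beat cycle |
| `asymmetry_position_um` | 10 | µm | arc position of the asymmetry index |
| `snr_threshold` | 5 | — | periodogram peak / median off-peak power for motility |
| `amplitude_threshold_rad` | 0.2 | rad | peak-to-peak beat amplitude for motility |
| `curvature_floor` | 1e-4 | 1/µm | below this the index denominator is undefined |
| `alpha` | 0.05 | — | significance level |

## The synthetic-data generator

`wave_params()` / `render_trace_set()` implement a *kinematic* traveling
curvature wave,

$$\kappa(s,t) = \kappa_0(s) + A(s)\,\sin\!\big(2\pi(s/\lambda - f t) +
\varphi\big),$$

integrated to a shape with the head clamped at the origin (head tangent
free), then emitted as trace points every 0.2 µm with iid Gaussian point
noise (σ = 0.05 µm) and quantization to the 0.04 µm pixel grid. Defaults:
length 30 µm, λ = 30 µm, A = 0.10 µm⁻¹, f = 2 Hz, 100 fps, 2 s. The studied
phenotypes are encoded as presets whose static-curvature ordering carries
the biology: symmetric low-calcium beating (κ₀ = 0), calcium-induced
asymmetry (κ₀ = 0.05 µm⁻¹), a calcium-binding-dead mutant with at most weak
asymmetry under calcium (κ₀ = 0.005 µm⁻¹), a biphasic knockout (active
proximal half, inactive but curved distal half), and immotile
outer-arm-dynein-less models (A = 0, κ₀ high when active, ≈ 0 under the
dynein inhibitor). Reported beat magnitudes are order-of-magnitude choices
— the source figures print no numbers — and are never used as correctness
anchors. All sperm presets share f = 2 Hz: the one frequency the generator's
stated world defines. `make_cohort()` adds 10 % relative per-flagellum
jitter to κ₀, A and f and randomizes each recording's starting beat phase.

What the generator does *not* emulate: correlated (smooth) hand-tracing
error, curvature-dependent tracing difficulty, out-of-plane excursions,
drift of the head anchor, and amplitude growth along the flagellum beyond
the simple piecewise envelopes. A green recovery test therefore establishes
that the estimators are correct and well-calibrated under iid click noise
and pixel quantization — not that every property of real manual traces is
reproduced.

## Numerical choices

- **"Tangent line as an average of 20 pixels"** is implemented as a
  total-least-squares line over the points in a 20-px arc-length window,
  not a mean of segment angles: TLS is exactly rotation-equivariant and
  well-defined for unevenly spaced clicks; the two readings agree to first
  order.
- **Anchoring** is by arc length (first sample at half a window, then every
  step), not by point index: manual click spacing is uneven, while the
  physical spacing is what the 10-px convention means.
- **Circle fit**: Kåsa's algebraic fit, solved per window centered at the
  window mean (conditioning; rotation discrepancy ≤ 1e-10 on well-curved
  input). Windows whose lateral deviation from their TLS line is below
  1e-6 of the window length are collinear: $r = \infty$, κ = 0. The
  brute-force geometric fit (direct minimization of
  $\sum(\lVert p - c\rVert - r)^2$) exists only as a test oracle.
- **Unwrapping and branch alignment**: each frame's $\theta(s)$ is
  unwrapped along $s$; before pooling, frames are shifted by the 2π
  multiple that brings their means together, since two frames whose head
  angle straddles ±π would otherwise land on different branches and corrupt
  the pooled slope (this is what makes mirror antisymmetry exact).
- **Motility triage**: motile ⇔ periodogram SNR ≥ 5 *and* the peak
  component's peak-to-peak amplitude ≥ 0.2 rad. The amplitude is taken from
  the spectral peak, not the raw range: frame-to-frame tracing noise alone
  gives a static flagellum a raw range of ~0.4 rad, while its projection on
  any single frequency stays small. Immotile/irregular flagella are
  quantified from one seeded randomly drawn frame (seed recorded in the QC
  flags), mirroring the single-frame procedure for immotile sperm, with the
  mean |κ| along the flagellum carried alongside.
- **Cycle selection** is deterministic: the earliest complete period,
  frames nearest to uniform phase targets, ties to the earlier frame. How
  the ≥ 5 time points were chosen within a cycle is not specified anywhere;
  uniform phase is the choice here, and a self-consistency test bounds its
  effect (slope from 5 selected frames within 2 % of the all-frame slope).
- **Signed vs unsigned index**: the literal "maximal over minimal value" of
  a signed quantity is negative for symmetric beats, contradicting its use
  as an asymmetry measure with the P-bend on top. Default is therefore the
  magnitude ratio of the two signed extremes (symmetry → 1, and
  $(A+\kappa_0)/(A-\kappa_0)$ for an offset sinusoid); the raw signed ratio
  stays available behind `signed_index = TRUE`.
- **The origin shift** of tangent plots ("the fitted line starts at (0,0)")
  is presentation only (`tangent_plot_data()`); it cannot change the slope
  and is never applied during estimation.
- **Degenerate inputs**: duplicate consecutive points are merged at
  ingestion (QC-flagged); frames with < 21 distinct points are dropped
  (QC-flagged); an all-identical abscissa or < 2 pooled samples is a hard
  error.

## Known limitations

- **Small-window curvature under iid noise.** A 20-px window on a κ ≈
  0.1 µm⁻¹ flagellum has a sagitta of ~0.008 µm — below both the default
  click noise (0.05 µm) and the pixel quantization step. Per-frame
  circle-fit curvature on default-noise *synthetic* traces is therefore
  noise-dominated, and an extreme-ratio index computed from such traces is
  attenuated toward 1. Real manual traces are locally smooth (interpolated
  polylines), where the window fit is meaningful. The asymmetry machinery
  is calibrated on noiseless renders against the closed form
  $(A+\kappa_0)/(A-\kappa_0)$, and `analyze_flagellum()` evaluates the
  index on the ≥ 5 selected cycle frames (the traced data volume) rather
  than every frame, which limits noise-extreme inflation.
- **Kåsa flat-arc bias.** On shallow noisy arcs the algebraic fit
  underestimates the radius by more than the 1 % oracle agreement; the
  agreement bound is asserted on windows spanning ≥ 2.5 rad.
- **Biphasic flagella** are simulated (piecewise κ₀ and amplitude) but the
  pipeline deliberately reports a single global slope for them; no
  changepoint detection is attempted.
- **Planar beating only**; no attempt to normalize θ to the head direction.
- The statistics assume independent flagella; no per-animal clustering.

## Runtime scaling of the validation suite

The Monte-Carlo acceptance checks state their replicate counts (20 per grid
cell for slope recovery; 200 cohorts each for the power and null designs;
10,000 Welch null replicates). To keep the suite inside its runtime budget
the cohort replicates render one beat cycle sampled by 8 uniformly phased
frames per flagellum — the same regime as the recovery grid and the
minimum-pooling convention — while the single qualitative-contrast cohort
runs the full pipeline (beat estimation, cycle selection, triage) on 1-s,
100-fps recordings. Replicate counts are never reduced.
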