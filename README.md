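# flagwave

Quantification of planar flagellar waveforms from manually traced
coordinates.

## What problem this solves

High-speed video of beating sperm flagella (or other cilia confined to the
image plane) is commonly reduced to hand-traced head→tip polylines, one per
frame. Turning those traces into defensible numbers — how asymmetric is the
beat, how fast is it, did an intervention change it — requires a chain of
small but error-prone steps: arc-length parameterization, windowed tangent
angles, angle unwrapping, curvature estimation, beat-cycle selection, and
group statistics. `flagwave` implements that chain as a tested R package,
together with a synthetic waveform generator with known ground truth so
that every stage is validated by parameter recovery.

## The statistics at its core

Writing $\theta(s,t)$ for the angle between the flagellum's tangent at arc
length $s$ (µm from the head) and the horizontal image axis at time $t$,
planar beating decomposes as

$$\theta(s,t) = \kappa_0 s + \theta_0 + \theta'(s,t),$$

- **Basal curvature** $\kappa_0$ (rad/µm): the slope of the ordinary
  least-squares line fitted to the pooled $(s, \theta)$ samples of ≥ 5
  uniformly phased frames spanning one beat cycle. It measures sustained
  one-sided bending (the *static component*); the residuals $\theta'$ are
  the propagating *dynamic component*.
- **Asymmetry index**: signed curvature $\kappa$ (1/µm, from sliding 20-px
  circle fits, $|\kappa| = 1/r$) is read at 10 µm from the head in each
  cycle frame; the index is the magnitude ratio of the two signed extremes
  (principal over reverse bend), 1 for a symmetric beat and
  $(A+\kappa_0)/(A-\kappa_0)$ for an offset sinusoidal beat.
- **Beat frequency** (Hz): periodogram peak of $\theta$ at mid-flagellum,
  parabolically refined, with an SNR + amplitude triage that leaves
  immotile or irregularly vibrating flagella quantified from a single
  seeded randomly drawn frame.
- **Group comparisons**: unpaired two-tailed Welch t tests (Student's
  pooled-variance available), Holm–Bonferroni-adjusted across the listed
  comparison family, significance at α = 0.05.

## Worked example

Simulate one calcium-style asymmetric recording (1 s at 100 fps), analyze
it, then compare a small two-group cohort:

```r
library(flagwave)

p  <- wave_params(kappa0 = 0.05, amp = 0.10, freq_hz = 2,
                  duration_s = 1, seed = 42)
ts <- render_trace_set(p, flagellum_id = "demo",
                       genotype = "wt", condition = "pca4")
analyze_flagellum(ts, waveform_config())
#> <flagellum_result> 'demo' (wt/pca4): basal curvature 0.0461 rad/um over 5 frames
#>   beat 1.981 Hz, asymmetry index 1.996, motile TRUE
#>   qc: dropped 1 tangent samples with < 3 points (x24); ...
```

The generative static curvature (0.05 rad/µm) is recovered as 0.0461 from
five traced frames of one cycle, and the 2 Hz beat as 1.981 Hz. The
asymmetry index is attenuated below its generative value of 3.0 because the
default synthetic click noise exceeds the curvature window's sagitta — see
the methods vignette for why this is a property of the noise model, and the
noiseless calibration that pins the index to its closed form.

```r
co <- make_cohort(c("wt_egta", "wt_pca4"), n_per_group = c(14, 8),
                  seed = 1, jitter_rel = 0.1, duration_s = 1)
df <- results_to_df(lapply(co$sets, analyze_flagellum,
                           config = waveform_config(compute_asymmetry = FALSE)))
df$group <- paste(df$genotype, df$condition, sep = ":")
summarize_groups(df$basal_curvature_rad_per_um, df$group)
#>     group  n     mean       se n_missing
#> 1 wt:egta 14 0.000411 0.000318         0
#> 2 wt:pca4  8 0.047810 0.001069         0
compare_groups(df, "basal_curvature_rad_per_um",
               list(c("wt:egta", "wt:pca4")))
#>   group_a group_b n_a n_b   mean_a mean_b t_stat   p_raw p_adjusted significant
#> 1 wt:egta wt:pca4  14   8 0.000411 0.0478  -42.5 5.8e-11    5.8e-11        TRUE
```

The low-calcium group recovers a basal curvature statistically
indistinguishable from zero, the high-calcium group recovers its generative
0.05 rad/µm, and the Welch test flags the difference.

A command-line entry point mirrors this flow:

```sh
exec/flagwave simulate --preset wt_egta,wt_pca4 --n 5 --seed 1 --out sim/
exec/flagwave analyze  --in sim/ --out results/
exec/flagwave report   --results results/results.csv --out results/ \
                       --pairs wt:egta=wt:pca4
```

Every run archives its configuration (`run_config.json`) and a structured
log; reruns on identical inputs are byte-identical.

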