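# nvsacc

Saccade detection and nonparametric factorial analysis for studies of eye
movements during *non-visual* cognitive tasks.

When people rest, mentally multiply two numbers, or name as many animals
as they can, they keep making saccades with nothing to look at. Comparing
those saccades across age groups and tasks requires a specific chain of
steps: converting screen-pixel gaze samples to visual angle, smoothing,
velocity-threshold (I-VT) event detection with an explicit independence
rule, per-period aggregation of frequency / mean amplitude / mean
velocity, and — because these parameters are heavily skewed — an Aligned
Rank Transform (ART) mixed repeated-measures ANOVA with partial omega
squared effect sizes and Tukey post hoc contrasts. `nvsacc` implements
that chain end to end for a two-group (young, old) by three-period (rest,
mental arithmetic task MAT, verbal fluency task VFT) design, plus a
ground-truth-labelled synthetic cohort generator that makes every stage
testable without access to raw recordings.

## The core model

Gaze `(x, y)` in pixels is converted per axis by
`x_deg = atan((x_px - W/2) * (W_cm/W_px) / d)` for a screen of `W_px`
pixels, `W_cm` centimetres, at distance `d`. After a 3-point moving
average, component velocities are forward differences. A sample is
saccadic when its component speed is at least 100 deg/s; two
supra-threshold runs are one saccade only if separated by less than 50 ms
*and* fewer than six consecutive sub-threshold samples (the clauses
coincide at 120 Hz). Per subject `s`, period `p` and component
`c in {H, V}`:

* frequency = events / valid analysed seconds,
* mean amplitude = mean unsigned displacement onset to offset (deg),
* mean velocity = mean of within-event sample speeds (deg/s).

Each parameter is analysed with ART: align the response for one effect at
a time (subtract all other estimated cell-mean effects), midrank, and run
the classical mixed ANOVA — group over subjects-within-group error
(df 1, N-2), period and group x period over the within-subject residual
(df 2, 2(N-2)) — reading only the aligned effect from each run, with

```
omega_p^2 = (SS_eff - df_eff MS_err) / (SS_eff + (N_str - df_eff) MS_err)
```

clipped at zero for reporting.

## A worked example

```r
library(nvsacc)

cfg <- sim_config(n_young = 28, n_old = 26)   # reference study conditions
cohort <- simulate_cohort(cfg, seed = 42)
res <- analyze_cohort(cohort)

subset(res$summary, period == "REST" & component == "V")
#>    group period component  n frequency_mean frequency_sd mean_amplitude_mean
#> 4    old   REST         V 26       1.016348    0.9729986            3.370826
#> 10 young   REST         V 28       1.878111    1.5453461            2.246490
#>    mean_amplitude_sd mean_velocity_mean mean_velocity_sd
#> 4          1.6978570           155.0305         35.80633
#> 10         0.5710443           176.8491         38.76995

fit <- art_anova(res$params, "mean_velocity", component = "V")
fit
#> ART mixed ANOVA on mean_velocity [V] (50 subjects, 4 excluded)
#>        effect     F df1        p omega_sq_p
#>         group 33.49   1 5.30e-07       0.39
#>        period  2.08   2 1.31e-01       0.02
#>  group:period  0.23   2 7.98e-01       0.00
```

Reading this output: simulated at the reference conditions, older adults
make reliably slower vertical saccades than younger adults (the `group`
row, tested against subject-to-subject variation within groups), while in
this replicate the period effect and the age x period interaction are not
significant. Four subjects had a period with no detected vertical
saccades and were excluded listwise. `run_end_to_end("out", seed = 1)` performs the
whole pipeline and writes `params.csv`, `summary.csv`, `events.csv`,
`effects.csv`, `posthoc.csv`, `demographics.csv` and the resolved
configuration; `scripts/run_pipeline.R` wraps it for the shell.

## Package layout

* `R/gaze-io.R` — gaze/event file I/O, analysis windows, quality screen
* `R/geometry.R`, `R/preprocess.R` — visual angle, smoothing, velocity
* `R/detect.R` — I-VT detection with the independence/merging rule
* `R/aggregate.R` — subject x period x component parameter table
* `R/stats-two-sample.R`, `R/art.R` — Wilcoxon Z, chi-square, normality
  diagnostics; ART, mixed rmANOVA, partial omega squared, Tukey post hoc
* `R/sim-config.R`, `R/sim-calibrate.R`, `R/simulate.R` — synthetic
  cohorts with measurement-consistent kinematics and ground truth
* `R/pipeline.R`, `R/reports.R` — end-to-end runs and report tables
* `vignettes/nonvisual-saccade-analysis.Rmd` — methods notes: model,
  assumptions, generator design, numerical choices, limitations
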