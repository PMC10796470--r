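---
title: "Analysing horizontal and vertical saccades during non-visual cognitive tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing horizontal and vertical saccades during non-visual cognitive tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvsacc)
```

## The problem this package addresses

People make saccades even when there is nothing to look at. During
internally directed cognition — mental arithmetic, fluency search, memory
retrieval — saccade rates, amplitudes and velocities change, and those
changes differ between younger and older adults and between horizontal and
vertical movements. Studying this requires a chain of signal-processing and
statistical steps that are individually standard but easy to get subtly
wrong in combination: gaze traces must be converted to visual angle,
smoothed, differentiated, thresholded into events with an explicit
independence rule, aggregated per task period, and analysed with a
nonparametric factorial model, because the resulting parameters are heavily
skewed.

`nvsacc` implements that chain end to end for a two-group (young, old) by
three-period (rest, mental arithmetic, verbal fluency) design, together
with a synthetic cohort generator carrying ground-truth labels so that
every stage is testable without access to raw recordings.

## The measurement pipeline

1. **Geometry.** Gaze is recorded in screen pixels on a projected
   1024 x 768 display measuring 200 cm x 152 cm viewed from 232 cm
   (defaults of `screen_geometry()`). Conversion to degrees uses the exact
   per-axis arctangent about the screen centre; at a ~47 degree wide field
   the small-angle approximation would be off by more than a degree at the
   edges. Pixels are not square; axes are converted independently.
2. **Smoothing.** A 3-point moving average on each position axis
   (`smooth_ma3()`), endpoints kept raw. Windows touching an invalid
   (tracker-loss) sample become invalid: dropout widens by one sample per
   side rather than leaking interpolated positions into detection.
3. **Velocity.** Signed forward difference per axis
   (`component_velocity()`); the last sample has no velocity. A central
   scheme is available but the forward difference is the default because
   the detector's independence rule counts raw samples and the forward
   scheme keeps one velocity sample per inter-sample interval.
4. **Detection** (`detect_saccades()`). Samples with component speed at or
   above 100 deg/s are saccadic (I-VT). Maximal supra-threshold runs are
   candidates; two candidates count as *one* saccade only when the gap
   between them is shorter than 50 ms *and* shorter than six consecutive
   sub-threshold samples; otherwise they are independent events. The two
   clauses coincide exactly at 120 Hz (6 samples = 50 ms); both are kept so
   the rule generalises to other rates. The gap is measured from the first
   sub-threshold sample to the next supra-threshold one, the only reading
   under which "five sub-threshold samples merge, six do not" holds at
   120 Hz. Candidate runs never bridge invalid samples. Horizontal and
   vertical channels are detected independently (`mode = "per_component"`),
   because independent H and V event rates cannot arise from labelling
   each 2D event with a single direction; a 2D-magnitude mode is provided
   for sensitivity analysis.
5. **Measurement.** Per event: amplitude = unsigned component displacement
   from onset to offset (degrees); mean velocity = arithmetic mean of
   component speeds over the event's samples, merged gaps included. Signs
   are collapsed; direction is retained as a separate field but not
   analysed.
6. **Aggregation** (`aggregate_params()`). Events belong to the period
   containing their onset. Rest is a 10 s block, verbal fluency a 60 s
   block, and mental arithmetic the union of per-problem calculation
   periods (problem onset to the participant's click); problems without a
   click have no defined end and are dropped. Frequency divides event
   count by *valid* analysed time (invalid-sample time is subtracted, so
   dropout does not deflate rates; a raw-duration mode exists). Cells with
   zero events have frequency 0 and *missing* amplitude/velocity — never
   zero.

## The statistics layer

Group comparisons of demographics and per-cell parameters use the
Wilcoxon-Mann-Whitney test reported as a Z statistic (midranks,
tie-corrected variance, no continuity correction) with exact small-sample
p-values when the data are tie-free, and Pearson's uncorrected chi-square
for 2 x 2 tables. `normality_report()` provides Shapiro-Wilk W/p plus
adjusted Fisher-Pearson skewness and excess kurtosis, the usual
justification for moving to ranks.

The factorial analysis is the Aligned Rank Transform (ART) followed by a
classical mixed-design ANOVA, implemented from its defining algebra in
`align_rank_transform()` and `mixed_rmanova()`:

* For each fixed effect (group, period, group x period) the response is
  aligned — the estimated contributions of *all other* effects are
  subtracted, using observed-margin cell means — and midranked. With
  complete within-subject data and unequal group sizes the cell
  frequencies are proportional, so the weighted decomposition stays
  orthogonal and two algebraic properties hold exactly: every aligned
  column sums to zero, and an ANOVA of an aligned (unranked) column shows
  zero effect for every factor other than the aligned one. The test suite
  asserts both on every fixture.
* One mixed ANOVA runs per effect, on that effect's rank column; only
  that effect's test is read from each run. The group effect is tested
  against subjects-within-group variation (df `N - 2`), period and
  interaction against the period x subject-within-group residual
  (df `2(N - 2)`). No sphericity correction is applied by default — the
  classical F is reported with its nominal degrees of freedom — and
  Greenhouse-Geisser correction is available as an option.
* Effect sizes are partial omega squared,
  `(SS_eff - df_eff MS_err) / (SS_eff + (N_str - df_eff) MS_err)`, with
  `N_str` the number of observations in the effect's stratum (`N` subject
  means for the between stratum, `2N` within-subject contrasts for the
  within stratum). Negative estimates are clipped to zero for reporting;
  the raw value is retained.
* Post hoc period contrasts use Tukey's studentized-range method on the
  period rank column, with the within-subject error mean square and its
  degrees of freedom. The scale of the original post hoc analysis is not
  documented anywhere we could rely on; the rank scale is this package's
  documented choice, and the dominance property (adjusted p never below
  unadjusted p) is asserted in tests.
* The six response x component analyses are *not* corrected for multiple
  testing across analyses, mirroring common practice in this literature;
  `saccade_effects_table()` documents this and users should treat
  family-wise error accordingly.

Subjects with any missing cell are excluded listwise from a given
analysis: the classical ART F-tests need one observation per subject and
period. Missingness arises only from cells with zero detected events.

## The synthetic cohort generator

`simulate_cohort()` generates complete sessions — 10 s rest, a 60 s
verbal-fluency block, and an 18-problem mental-arithmetic block (six easy,
six medium, six difficult multiplications drawn from the level-specific
operand ranges, excluding multiples of ten and auditorily confusable 1/2
pairs, never more than three equal difficulties in a row), tasks in random
order per subject — as one continuous 120 Hz gaze trace per subject with
event log and ground truth.

**Cell parameters.** The default grid (`default_cohort_grid()`) fixes the
mean and SD of frequency, mean amplitude and mean velocity per group x
period x component for a reference cohort of 28 young and 26 old healthy
adults. Per-subject targets are drawn from Gamma distributions with
exactly those moments: the SDs are as large as the means, so Normal draws
would go negative, and floor-truncated Normals would shift the realised
means upward by a substantial fraction of a standard error — Gamma keeps
both configured moments exact with positive support and the right-skewed
shape that motivates the rank transform in the first place. A subject's
amplitude and velocity draws are coupled through a Gaussian copula (rank
correlation ~0.7, marginals untouched): the main-sequence relation that
larger saccades are faster. Without it, independent draws would populate a
corner (small amplitude, high velocity) that measured data cannot contain,
and velocity recovery would be biased low. Draws are independent across
periods; within-subject correlation across periods is *not* modelled, a
known simplification discussed under limitations.

**Kinematics and the measurement-consistency problem.** Each saccade is a
raised-cosine velocity profile (symmetric waveform), placed by a renewal
process (exponential gaps plus event duration plus a 100 ms refractory
interval, with the exponential rate solved so the expected event rate
equals the drawn frequency). Because the configured grid describes
*measured* quantities, the generator must invert the measurement: the mean
of supra-threshold smoothed sample speeds systematically exceeds the
profile's true mean velocity (sub-threshold tails are excluded), while
sampling at 120 Hz plus 3-point smoothing caps the measurable speed of a
displacement `D` near `D / (3 dt)`. Two consequences follow. First, the
underlying amplitude and duration are solved per event from a precomputed
dimensionless table of the full sampling + smoothing + thresholding +
merging chain so that the *expected measured* amplitude and velocity equal
the drawn targets. Second, amplitude-velocity combinations with measured
speed far above `~ 40 deg/s per degree of amplitude` are unreachable by
any smooth one-way movement, yet they occur in the reference grid; they are
reachable only by motion that reverses within the detected span. The
generator therefore appends a calibrated post-saccadic oscillation (an
overshoot that returns part of the way, as the pupil/corneal-reflection
signal of video eye trackers characteristically does) whose magnitude is
solved jointly with the primary movement. This is a statement about the
recorded signal, not about eye physiology; it is the standard mechanism by
which video-tracker recordings show inflated mean velocities at small net
amplitudes, and without it those reference cells are mathematically
impossible under the stated measurement procedure.

**Noise and dropout.** White measurement noise (default 0.12 deg per
axis, the scale of a research tracker's precision) is added to positions.
Dropout (default 5% of samples) is realised as blink-like bursts of mean
250 ms: real tracker loss is burst-like, and independent per-sample loss
at the same rate would shred most 3-4-sample saccades into undetectable
fragments, contradicting the generator's own configured event rates. A
Bernoulli mode is available. Fixation centres advance by each saccade's
net displacement and are reflected back when a movement would leave the
central 80% of the screen.

**What the generator does and does not emulate.** It reproduces the
marginal cell distributions, main-sequence coupling, session structure,
sampling, noise and burst dropout of a projected-screen recording. It does
not model smooth pursuit, microsaccades (below this tracker's resolution),
head motion, calibration drift, pupil-size artefacts, or within-subject
correlation across periods. Passing recovery tests therefore shows the
pipeline is faithful to its own measurement definition under realistic
signal conditions — not that any particular physiological claim about real
cohorts is true.

## Numerical and design choices

* Problem-list generation and all stochastic stages run off R's global
  RNG; `simulate_cohort(seed = )` makes whole cohorts bit-reproducible.
* Mental-arithmetic calculation times are LogNormal with medians 5, 10
  and 15 s (easy/medium/difficult, sdlog 0.35) and a 2.5 s answer gap —
  synthetic plumbing with no measured counterpart; they set the MAT
  analysis duration at roughly three minutes per subject. Test
  configurations scale these down (the methods are invariant to session
  length; the study-scale acceptance checks use the full sessions).
* The data-quality screen (`quality_screen()`) defaults to requiring 70%
  valid samples. The exclusion criterion behind the reference cohort is
  not documented; 0.70 is a placeholder surfaced as a parameter, not a
  reconstruction.
* Degenerate inputs are errors, not silent results: empty traces,
  repeated timestamps, zero analysed duration, constant samples in the
  normality report, zero chi-square marginals, fewer than two subjects
  per group.
* Ties anywhere in the rank machinery use midranks; the Wilcoxon variance
  is tie-corrected and the exact path is disabled under ties, exactly as
  the classical theory requires.

## Known limitations

* Independence of draws across periods makes between-group tests somewhat
  more powerful, and within-subject tests somewhat less powerful, than in
  a cohort with stable individual differences; the acceptance suite's
  pattern checks were designed with this in mind.
* The post-saccadic oscillation needed to reach some reference
  velocity/amplitude cells is larger than textbook values for real eyes;
  it emulates the recorded signal implied by those cells, and its
  magnitude is solved, not asserted, per event.
* ART interaction tests are known to inflate mildly when main effects are
  strong and distributions are skewed; interpretation of borderline
  interaction p-values should be cautious.
* The package analyses cyclopean gaze only; binocular vergence, torsion
  and eye-in-head kinematics are out of scope.
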