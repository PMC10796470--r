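#' Reference cohort parameter grid
#'
#' Default generative conditions for the synthetic cohort: mean and SD of
#' saccade frequency (events/s), mean amplitude (deg) and mean velocity
#' (deg/s) per age group (young, old) x period (REST, MAT, VFT) x component
#' (H, V). The values describe healthy younger (20-29 y) and older (60+ y)
#' adults at rest and during mental-arithmetic and verbal-fluency tasks, as
#' measured by the 100 deg/s velocity-threshold procedure this package
#' implements. These are *measured-scale* targets: the generator
#' compensates its kinematics so that the standard measurement pipeline
#' recovers them in expectation.
#'
#' @return A `data.frame` with columns `group`, `period`, `component`,
#'   `freq_mean`, `freq_sd`, `amp_mean`, `amp_sd`, `vel_mean`, `vel_sd`.
#' @export
default_cohort_grid <- function() {
  g <- expand.grid(component = c("H", "V"), group = c("young", "old"),
                   period = c("REST", "MAT", "VFT"),
                   stringsAsFactors = FALSE)[, c("group", "period", "component")]
  # columns: freq mean/sd, amp mean/sd, vel mean/sd, rows in the order of g
  vals <- rbind(
    c(0.8, 0.8, 3.9, 3.1, 171.4, 44.9),  # young REST H
    c(1.9, 1.5, 2.3, 0.9, 174.2, 48.7),  # young REST V
    c(0.8, 0.7, 3.4, 2.1, 168.1, 38.0),  # old   REST H
    c(1.4, 1.2, 2.9, 1.6, 164.2, 42.2),  # old   REST V
    c(1.6, 1.3, 2.3, 1.2, 168.5, 34.6),  # young MAT  H
    c(2.9, 2.5, 2.4, 0.7, 194.2, 47.6),  # young MAT  V
    c(1.5, 1.5, 2.3, 0.6, 168.5, 38.1),  # old   MAT  H
    c(2.3, 2.2, 2.3, 0.6, 161.8, 25.5),  # old   MAT  V
    c(1.8, 2.1, 3.1, 1.6, 172.2, 30.4),  # young VFT  H
    c(2.9, 2.8, 2.5, 0.5, 186.6, 41.9),  # young VFT  V
    c(1.7, 1.2, 3.1, 1.1, 169.1, 25.0),  # old   VFT  H
    c(2.5, 1.7, 2.4, 0.7, 159.8, 18.0))  # old   VFT  V
  colnames(vals) <- c("freq_mean", "freq_sd", "amp_mean", "amp_sd",
                      "vel_mean", "vel_sd")
  cbind(g, as.data.frame(vals))
}

#' Simulation configuration for a synthetic gaze cohort
#'
#' Full generative description of a two-group x three-period cohort:
#' per-cell parameter grid, screen geometry, sampling rate, measurement
#' noise, dropout, and session structure. Defaults reproduce the reference
#' study conditions: 28 young and 26 old subjects recorded at 120 Hz on a
#' projected 1024x768 screen, 10 s rest, 18 mental-arithmetic problems and
#' a 60 s verbal-fluency block.
#'
#' Measurement noise (`noise_sd_deg`, white, per component) emulates
#' tracker precision; the 0.12 deg default is on the scale of a research
#' tracker's RMS sample-to-sample precision (~0.24 deg). `dropout_rate` is
#' the expected fraction of invalid samples; by default it is realised as
#' blink-like bursts (mean 250 ms) rather than independent per-sample loss,
#' because real tracker loss is burst-like and independent loss at realistic
#' rates would shred short saccades into undetectable fragments
#' (`dropout_mode = "bernoulli"` gives the independent variant).
#'
#' @param n_young,n_old subjects per group.
#' @param rate_hz sampling rate (Hz).
#' @param grid parameter grid as from [default_cohort_grid()].
#' @param geometry a [screen_geometry()].
#' @param noise_sd_deg white measurement noise SD, degrees.
#' @param dropout_rate expected invalid-sample fraction, in `[0, 1)`.
#' @param dropout_mode `"blink"` (default) or `"bernoulli"`.
#' @param rest_duration_s,vft_duration_s period lengths in seconds.
#' @param mat_median_s medians (seconds) of the LogNormal calculation
#'   durations for easy/medium/difficult problems (onset to click); these
#'   are synthetic plumbing, not measured values.
#' @param mat_sdlog LogNormal sdlog of calculation durations.
#' @param answer_gap_s pause between a click and the next problem onset.
#' @param refractory_s minimum gap between consecutive ground-truth events
#'   on one component, so injected events always satisfy the independence
#'   rule.
#' @param measure_threshold_deg_s velocity threshold the generator assumes
#'   when pre-compensating event kinematics for measurement (should match
#'   the detector's threshold).
#' @param calibrate logical; compensate kinematics so measured amplitude
#'   and mean velocity match the configured targets (default `TRUE`).
#' @param amp_jitter_sdlog,vel_jitter_sdlog event-to-event LogNormal
#'   variation (mean 1) around each subject's parameter draws.
#' @param seed optional integer seed stored with the config and used by
#'   [simulate_cohort()] when no explicit seed is given.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_young = 28, n_old = 26, rate_hz = 120,
                       grid = default_cohort_grid(),
                       geometry = screen_geometry(),
                       noise_sd_deg = 0.12,
                       dropout_rate = 0.05,
                       dropout_mode = c("blink", "bernoulli"),
                       rest_duration_s = 10, vft_duration_s = 60,
                       mat_median_s = c(easy = 5, medium = 10, difficult = 15),
                       mat_sdlog = 0.35,
                       answer_gap_s = 2.5,
                       refractory_s = 0.1,
                       measure_threshold_deg_s = 100,
                       calibrate = TRUE,
                       amp_jitter_sdlog = 0.25,
                       vel_jitter_sdlog = 0.12,
                       main_sequence_rho = 0.7,
                       seed = NULL) {
  need <- c("group", "period", "component", "freq_mean", "freq_sd",
            "amp_mean", "amp_sd", "vel_mean", "vel_sd")
  stopifnot(all(need %in% names(grid)), nrow(grid) >= 1L)
  means <- unlist(grid[, c("freq_mean", "amp_mean", "vel_mean")])
  sds <- unlist(grid[, c("freq_sd", "amp_sd", "vel_sd")])
  if (any(means <= 0)) stop("all grid means must be > 0", call. = FALSE)
  if (any(sds < 0)) stop("grid SDs must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (any(grid$vel_mean < measure_threshold_deg_s)) {
    warning("configured mean velocity below the detection threshold: ",
            "such events will be undetectable by design", call. = FALSE)
  }
  structure(list(n_young = n_young, n_old = n_old, rate_hz = rate_hz,
                 grid = grid, geometry = geometry,
                 noise_sd_deg = noise_sd_deg, dropout_rate = dropout_rate,
                 dropout_mode = match.arg(dropout_mode),
                 rest_duration_s = rest_duration_s,
                 vft_duration_s = vft_duration_s,
                 mat_median_s = mat_median_s, mat_sdlog = mat_sdlog,
                 answer_gap_s = answer_gap_s, refractory_s = refractory_s,
                 measure_threshold_deg_s = measure_threshold_deg_s,
                 calibrate = calibrate,
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 vel_jitter_sdlog = vel_jitter_sdlog,
                 main_sequence_rho = main_sequence_rho,
                 seed = seed),
            class = "sim_config")
}

# Draw per-subject parameter targets for one grid cell: Gamma with exactly
# the configured mean and SD (positive support, right-skewed like measured
# saccade parameters). sd = 0 gives the constant mean.
.draw_cell_params <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

# Joint (frequency, amplitude, velocity) targets for one grid cell.
# Amplitude and velocity are coupled through a Gaussian copula with rank
# correlation ~rho (the main-sequence relation: subjects who make larger
# saccades make faster ones); marginals stay exactly Gamma(mean, sd), so
# configured cell moments are untouched. Frequency is independent.
.draw_cell_triplet <- function(n, row, rho) {
  qg <- function(u, mean, sd) {
    if (sd == 0) return(rep(mean, length(u)))
    shape <- (mean / sd)^2
    stats::qgamma(u, shape = shape, scale = sd^2 / mean)
  }
  z_a <- stats::rnorm(n)
  z_v <- rho * z_a + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    frequency = .draw_cell_params(n, row$freq_mean, row$freq_sd),
    amplitude = qg(stats::pnorm(z_a), row$amp_mean, row$amp_sd),
    velocity = qg(stats::pnorm(z_v), row$vel_mean, row$vel_sd))
}
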