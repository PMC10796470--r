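#' Analyse one subject's recording
#'
#' Quality screen, visual-angle conversion, smoothing, velocity
#' computation, saccade detection and per-period aggregation for a single
#' gaze trace with its event log.
#'
#' @param trace a [gaze_trace()].
#' @param events an [event_log()] (or precomputed `windows`).
#' @param geometry a [screen_geometry()].
#' @param detection a [detection_config()].
#' @param group group label carried into the parameter rows.
#' @param min_valid_fraction quality threshold; the subject is rejected
#'   (returns `NULL` with a warning) below it.
#' @param windows optional precomputed `period_windows`.
#' @param use_valid_time see [aggregate_params()].
#' @return list with `params` (parameter rows), `saccades` (event table
#'   with subject/group columns), `quality`; or `NULL` if screened out.
#' @export
analyze_subject <- function(trace, events = NULL, geometry = screen_geometry(),
                            detection = detection_config(), group = NA_character_,
                            min_valid_fraction = 0.70, windows = NULL,
                            use_valid_time = TRUE) {
  q <- quality_screen(trace, min_valid_fraction)
  if (!q$pass) {
    warning(sprintf("subject %s screened out (valid fraction %.2f)",
                    trace$subject_id, q$valid_fraction), call. = FALSE)
    return(NULL)
  }
  if (is.null(windows)) windows <- windows_from_events(events)
  pp <- preprocess_trace(trace, geometry)
  sacc <- detect_saccades(pp$velocity, pp$angular, detection)
  params <- aggregate_params(sacc, windows, trace, group = group,
                             use_valid_time = use_valid_time)
  if (nrow(sacc)) {
    sacc <- cbind(subject_id = trace$subject_id, group = group, sacc,
                  stringsAsFactors = FALSE)
  }
  list(params = params, saccades = sacc, quality = q)
}

#' Analyse a whole (simulated or loaded) cohort
#'
#' Runs [analyze_subject()] over every subject and stacks the results.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], or a list of
#'   per-subject lists with elements `trace`, `events` (or `windows`) and
#'   `group`.
#' @param geometry,detection,min_valid_fraction,use_valid_time passed on.
#' @return list with `params`, `saccades`, `summary` (from
#'   [cohort_table()]), `screened_out` (subject ids).
#' @export
analyze_cohort <- function(cohort, geometry = NULL,
                           detection = detection_config(),
                           min_valid_fraction = 0.70, use_valid_time = TRUE) {
  subjects <- if (inherits(cohort, "sim_cohort")) cohort$subjects else cohort
  if (is.null(geometry)) {
    geometry <- if (inherits(cohort, "sim_cohort")) cohort$config$geometry
    else screen_geometry()
  }
  params <- list(); saccs <- list(); out <- character()
  for (s in subjects) {
    res <- analyze_subject(s$trace, events = s$events, geometry = geometry,
                           detection = detection, group = s$group,
                           min_valid_fraction = min_valid_fraction,
                           windows = s$windows, use_valid_time = use_valid_time)
    if (is.null(res)) {
      out <- c(out, s$trace$subject_id)
      next
    }
    params[[length(params) + 1L]] <- res$params
    if (nrow(res$saccades)) saccs[[length(saccs) + 1L]] <- res$saccades
  }
  if (!length(params)) stop("no subjects passed the quality screen", call. = FALSE)
  params <- do.call(rbind, params)
  ct <- cohort_table(params)
  list(params = ct$params, saccades = do.call(rbind, saccs),
       summary = ct$summary, screened_out = out)
}

#' Run the full pipeline end to end
#'
#' Simulate (or load) a cohort, detect and aggregate saccades, and run the
#' complete statistics stack, writing every artifact to an output
#' directory: `params.csv`, `summary.csv`, `events.csv`,
#' `demographics.csv`, `effects.csv`, `posthoc.csv`, and the resolved
#' configuration (`run_config.yaml`). Deterministic under `seed`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the simulation.
#' @param sim a [sim_config()] (a synthetic run) — or `NULL` with `cohort`
#'   supplied.
#' @param cohort optional pre-built cohort (as for [analyze_cohort()]).
#' @param detection a [detection_config()].
#' @param min_valid_fraction quality threshold.
#' @return (invisibly) list with all in-memory results plus `out_dir`.
#' @export
run_end_to_end <- function(out_dir, seed = 1L, sim = sim_config(),
                           cohort = NULL, detection = detection_config(),
                           min_valid_fraction = 0.70) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(sim, seed = seed)
  res <- analyze_cohort(cohort, detection = detection,
                        min_valid_fraction = min_valid_fraction)
  eff <- saccade_effects_table(res$params)
  demo <- if (inherits(cohort, "sim_cohort")) cohort$demographics else NULL
  fw <- function(d, f) data.table::fwrite(d, file.path(out_dir, f))
  fw(res$params, "params.csv")
  fw(res$summary, "summary.csv")
  fw(res$saccades, "events.csv")
  fw(eff$table, "effects.csv")
  fw(eff$posthoc, "posthoc.csv")
  if (!is.null(demo)) {
    fw(demo, "demographics.csv")
    fw(demographics_table(demo), "demographics_table.csv")
  }
  cfg <- list(seed = seed,
              detection = unclass(detection),
              min_valid_fraction = min_valid_fraction,
              n_subjects = length(unique(res$params$subject_id)),
              screened_out = res$screened_out)
  if (inherits(cohort, "sim_cohort")) {
    cfg$sim <- list(n_young = cohort$config$n_young, n_old = cohort$config$n_old,
                    rate_hz = cohort$config$rate_hz,
                    noise_sd_deg = cohort$config$noise_sd_deg,
                    dropout_rate = cohort$config$dropout_rate,
                    dropout_mode = cohort$config$dropout_mode)
  }
  writeLines(yaml::as.yaml(cfg), file.path(out_dir, "run_config.yaml"))
  invisible(list(out_dir = out_dir, params = res$params, summary = res$summary,
                 effects = eff, demographics = demo,
                 screened_out = res$screened_out))
}
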