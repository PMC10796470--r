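# Synthetic gaze generation: fixations interleaved with raised-cosine
# saccades, per component, with measurement noise and blink-like dropout.

# Generate one component's ground-truth event stream over [t0, t0 + dur).
# f/a/m are the subject's target frequency, amplitude, mean velocity for
# this cell. Returns a data.frame of events (possibly empty).
.gen_events <- function(t0, dur, f, a, m, config) {
  if (f <= 0 || dur <= 0) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      amp_target = numeric(), vel_target = numeric(),
                      A = numeric(), o = numeric(), sign = integer()))
  }
  dt <- 1 / config$rate_hz
  n_max <- ceiling(dur * f * 2 + 10)
  # event-level jitter (mean-1 LogNormal) around subject targets, with
  # main-sequence coupling between amplitude and velocity
  rho <- config$main_sequence_rho
  s_a <- config$amp_jitter_sdlog; s_v <- config$vel_jitter_sdlog
  z_a <- stats::rnorm(n_max)
  z_v <- rho * z_a + sqrt(1 - rho^2) * stats::rnorm(n_max)
  a_e <- a * exp(-s_a^2 / 2 + s_a * z_a)
  m_e <- m * exp(-s_v^2 / 2 + s_v * z_v)
  if (config$calibrate) {
    cal <- .calibrate_events(m_e, a_e, dt, config$measure_threshold_deg_s)
  } else {
    cal <- list(A = a_e, T = a_e / m_e, o = numeric(n_max),
                pdet = rep(1, n_max))
  }
  # the recorded movement occupies 1.6 T1 (primary + oscillation)
  tot <- 1.6 * cal$T
  # dead-time-compensated exponential gaps; the placement rate is also
  # inflated by the expected detection probability so the *detected* event
  # rate stays on target (events the measurement model cannot see at all
  # remain lost, as they would be in a real recording)
  f_eff <- f / max(mean(cal$pdet), 0.25)
  dead <- mean(tot) + config$refractory_s
  lambda <- 1 / max(1 / f_eff - dead, 0.02)
  gaps <- stats::rexp(n_max, rate = lambda)
  onsets <- t0 + cumsum(gaps + tot + config$refractory_s) -
    tot - config$refractory_s   # first gap precedes the first event
  keep <- which(onsets + tot < t0 + dur & onsets >= t0)
  data.frame(onset = onsets[keep], duration = cal$T[keep],
             amp_target = a_e[keep], vel_target = m_e[keep],
             A = cal$A[keep], o = cal$o[keep],
             sign = rep(NA_integer_, length(keep)))
}

# Assign displacement signs so the gaze stays within +/- bound degrees,
# and return the running fixation-centre positions before each event.
# The net displacement of an event is A - o (outgoing minus overshoot).
.assign_signs <- function(events, start_pos, bound) {
  n <- nrow(events)
  sgn <- integer(n)
  pos <- start_pos
  net <- events$A - events$o
  pre <- if (n) sample(c(-1L, 1L), n, replace = TRUE) else integer()
  for (j in seq_len(n)) {
    s <- pre[j]
    if (abs(pos + s * net[j]) > bound) s <- -s
    if (abs(pos + s * net[j]) > bound) s <- if (pos > 0) -1L else 1L
    sgn[j] <- s
    pos <- pos + s * net[j]
  }
  events$sign <- sgn
  list(events = events, end_pos = pos)
}

# Evaluate one component's position (degrees) at sample times t. Events
# occupy [onset, onset + 1.6 * duration]: raised-cosine primary movement
# of amplitude A over `duration`, then the overshoot returns by o.
.component_positions <- function(t, events, centre0) {
  if (nrow(events) == 0L) return(rep(centre0, length(t)))
  net <- events$sign * (events$A - events$o)
  cumbase <- c(centre0, centre0 + cumsum(net))
  j <- findInterval(t, events$onset)
  pos <- cumbase[j + 1L]
  ja0 <- pmax(j, 1L)
  act <- which(j >= 1L & t < events$onset[ja0] + 1.6 * events$duration[ja0])
  if (length(act)) {
    ja <- j[act]
    tau <- t[act] - events$onset[ja]
    T1 <- events$duration[ja]
    rel <- events$A[ja] * .sacc_profile(tau / T1) -
      events$o[ja] * .sacc_profile((tau - T1) / (0.6 * T1))
    pos[act] <- cumbase[ja] + events$sign[ja] * rel
  }
  pos
}

#' Simulate one gaze segment with ground truth
#'
#' Generates a 120 Hz (configurable) gaze trace for a single subject and
#' period: stable fixations perturbed by white measurement noise,
#' interleaved with saccades placed by a renewal process whose expected
#' event rate equals the configured frequency (gaps are exponential plus
#' the event duration and a 100 ms refractory interval, with the
#' exponential rate compensated for that dead time). Each saccade follows
#' a raised-cosine velocity profile whose underlying amplitude and
#' duration are pre-compensated so the standard measurement procedure
#' recovers the drawn target amplitude and mean velocity in expectation.
#' Horizontal and vertical events are independent streams. Dropout is
#' applied as invalid-sample masking. Fully reproducible under a seed.
#'
#' @param config a [sim_config()].
#' @param group `"young"` or `"old"` (selects the grid row).
#' @param period `"REST"`, `"MAT"` or `"VFT"`.
#' @param duration_s segment length (defaults to the configured period
#'   length, or 30 s for MAT).
#' @param subject_id identifier for the returned trace.
#' @param params optional named list with elements `H` and `V`, each
#'   `c(frequency, amplitude, velocity)` targets; drawn from the grid cell
#'   when `NULL`.
#' @param t0 start time of the segment (seconds).
#' @param start_pos numeric length-2 start gaze position (deg, H and V).
#' @param apply_noise,apply_dropout logicals, mainly for tests.
#' @return list with `trace` (a [gaze_trace()]), `truth` (data.frame of
#'   injected events: `component`, `onset`, `duration_s`, `amplitude_deg`
#'   signed target, `vel_target`, underlying `A`), `params` (the target
#'   parameter draws used) and `end_pos`.
#' @export
simulate_trace <- function(config, group = "young", period = "REST",
                           duration_s = NULL, subject_id = "sim",
                           params = NULL, t0 = 0, start_pos = c(0, 0),
                           apply_noise = TRUE, apply_dropout = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(duration_s)) {
    duration_s <- switch(period, REST = config$rest_duration_s,
                         VFT = config$vft_duration_s, 30)
  }
  if (is.null(params)) {
    params <- list()
    for (comp in c("H", "V")) {
      row <- config$grid[config$grid$group == group &
                           config$grid$period == period &
                           config$grid$component == comp, ]
      if (nrow(row) != 1L) stop("no grid cell for ", group, "/", period, "/", comp)
      tri <- .draw_cell_triplet(1, row, config$main_sequence_rho)
      params[[comp]] <- c(frequency = tri$frequency, amplitude = tri$amplitude,
                          velocity = tri$velocity)
    }
  }
  dt <- 1 / config$rate_hz
  t <- t0 + seq(0, by = dt, length.out = round(duration_s / dt))
  geom <- config$geometry
  half_deg <- c(atan2(geom$width_cm / 2, geom$viewing_distance_cm),
                atan2(geom$height_cm / 2, geom$viewing_distance_cm)) * 180 / pi
  pos_deg <- matrix(0, length(t), 2)
  truth <- list(); end_pos <- start_pos
  for (ci in 1:2) {
    comp <- c("H", "V")[ci]
    pr <- params[[comp]]
    ev <- .gen_events(t0, duration_s, pr[["frequency"]], pr[["amplitude"]],
                      pr[["velocity"]], config)
    si <- .assign_signs(ev, start_pos[ci], 0.8 * half_deg[ci])
    ev <- si$events
    end_pos[ci] <- si$end_pos
    pos_deg[, ci] <- .component_positions(t, ev, start_pos[ci])
    if (nrow(ev)) {
      truth[[comp]] <- data.frame(component = comp, onset = ev$onset,
                                  duration_s = ev$duration,
                                  amplitude_deg = ev$sign * ev$amp_target,
                                  vel_target = ev$vel_target, A = ev$A,
                                  stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(component = character(), onset = numeric(), duration_s = numeric(),
               amplitude_deg = numeric(), vel_target = numeric(), A = numeric())
  rownames(truth) <- NULL
  if (apply_noise && config$noise_sd_deg > 0) {
    pos_deg <- pos_deg + matrix(stats::rnorm(2 * length(t), 0, config$noise_sd_deg),
                                ncol = 2)
  }
  px <- degrees_to_pixels(pos_deg[, 1], pos_deg[, 2], geom)
  valid <- rep(TRUE, length(t))
  if (apply_dropout && config$dropout_rate > 0) {
    valid <- !.dropout_mask(length(t), config, dt)
  }
  x <- px$x; y <- px$y
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  tr <- gaze_trace(t, x, y, valid, subject_id = subject_id,
                   rate_hz = config$rate_hz)
  pdf <- do.call(rbind, lapply(c("H", "V"), function(comp) {
    data.frame(component = comp, frequency = params[[comp]][["frequency"]],
               amplitude = params[[comp]][["amplitude"]],
               velocity = params[[comp]][["velocity"]], stringsAsFactors = FALSE)
  }))
  list(trace = tr, truth = truth, params = pdf, end_pos = end_pos)
}

# invalid-sample mask; blink mode groups the invalid time into bursts
.dropout_mask <- function(n, config, dt) {
  p <- config$dropout_rate
  if (config$dropout_mode == "bernoulli") return(stats::runif(n) < p)
  mask <- rep(FALSE, n)
  mean_len <- max(1, round(0.25 / dt))
  n_blinks <- stats::rpois(1, p * n / mean_len)
  if (n_blinks > 0) {
    starts <- sample.int(n, n_blinks, replace = TRUE)
    lens <- pmax(1, stats::rpois(n_blinks, mean_len))
    for (b in seq_len(n_blinks)) {
      mask[starts[b]:min(n, starts[b] + lens[b] - 1L)] <- TRUE
    }
  }
  mask
}

#' Generate a mental-arithmetic problem list
#'
#' 18 multiplication problems, six per difficulty level, drawn from the
#' level-specific operand ranges (easy `[3-9] x [13-19]`, medium
#' `[6-14] x [13-27]`, difficult `[11-19] x [16-27]`), excluding items with
#' an operand that is a multiple of ten (their products are immediate,
#' e.g. 10 x 15) and items whose two operands are mutually confusable
#' under a 1/2 digit swap (auditorily ambiguous, e.g. 21 x 22 or 12 x 11).
#' The presentation order never repeats the same difficulty more than
#' three times in a row.
#'
#' @return A `data.frame` with columns `multiplicand`, `multiplier`,
#'   `difficulty` in presentation order.
#' @export
make_mat_problem_list <- function() {
  ranges <- list(easy = list(3:9, 13:19),
                 medium = list(6:14, 13:27),
                 difficult = list(11:19, 16:27))
  confusable <- function(a, b) {
    da <- strsplit(as.character(a), "")[[1]]
    db <- strsplit(as.character(b), "")[[1]]
    if (length(da) != length(db)) return(FALSE)
    all(da == db | (da %in% c("1", "2") & db %in% c("1", "2")))
  }
  pick <- lapply(names(ranges), function(lv) {
    cand <- expand.grid(multiplicand = ranges[[lv]][[1]],
                        multiplier = ranges[[lv]][[2]])
    ok <- cand$multiplicand %% 10 != 0 & cand$multiplier %% 10 != 0
    ok <- ok & !mapply(confusable, cand$multiplicand, cand$multiplier)
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[sample.int(nrow(cand), 6L), , drop = FALSE]
    cand$difficulty <- lv
    cand
  })
  probs <- do.call(rbind, pick)
  repeat {
    ord <- sample.int(18L)
    d <- probs$difficulty[ord]
    runs <- rle(d)$lengths
    if (max(runs) <= 3L) break
  }
  out <- probs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# session plan for one subject: segment table + event log + MAT windows
.plan_session <- function(config) {
  gap <- 2
  segs <- data.frame(period = "REST", start = 0,
                     end = config$rest_duration_s + gap)
  events <- data.frame(time = c(0, config$rest_duration_s),
                       label = c("rest_on", "rest_off"))
  t <- segs$end[1]
  order_tasks <- sample(c("MAT", "VFT"))
  for (task in order_tasks) {
    if (task == "VFT") {
      segs <- rbind(segs, data.frame(period = "VFT", start = t,
                                     end = t + config$vft_duration_s + gap))
      events <- rbind(events,
                      data.frame(time = c(t, t + config$vft_duration_s),
                                 label = c("vft_on", "vft_off")))
      t <- t + config$vft_duration_s + gap
    } else {
      probs <- make_mat_problem_list()
      med <- config$mat_median_s[probs$difficulty]
      calc <- stats::rlnorm(18L, meanlog = log(med), sdlog = config$mat_sdlog)
      onsets <- numeric(18L); clicks <- numeric(18L)
      tt <- t
      for (i in 1:18) {
        onsets[i] <- tt
        clicks[i] <- tt + calc[i]
        tt <- clicks[i] + config$answer_gap_s
      }
      segs <- rbind(segs, data.frame(period = "MAT", start = t, end = tt + gap - config$answer_gap_s))
      events <- rbind(events,
                      data.frame(time = c(rbind(onsets, clicks)),
                                 label = rep(c("mat_problem_on", "mat_click"), 18L)))
      t <- segs$end[nrow(segs)]
    }
  }
  events <- events[order(events$time), , drop = FALSE]
  list(segments = segs, events = event_log(events$time, events$label))
}

#' Simulate a full two-group cohort
#'
#' Generates `n_young + n_old` subjects, each with a complete session: a
#' rest block, and mental-arithmetic (18 problems) and verbal-fluency
#' (60 s) blocks in random order, as one continuous gaze trace per subject
#' with the matching event log and ground truth. Subject-level parameter
#' targets are drawn per period x component from the configured grid
#' (Gamma with the configured mean/SD), independently across periods.
#' Demographic covariates (age, sex, education, cognitive and task scores)
#' are drawn per group for the demographics report. Deterministic under
#' `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; falls back to `config$seed`.
#' @return list of class `sim_cohort` with elements `subjects` (list of
#'   per-subject lists: `trace`, `events`, `windows`, `truth`, `params`,
#'   `group`), `demographics` (data.frame), `param_draws` (data.frame of
#'   all target draws) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  groups <- c(rep("young", config$n_young), rep("old", config$n_old))
  ids <- sprintf("S%02d", seq_along(groups))
  subjects <- vector("list", length(groups))
  draws <- list()
  for (s in seq_along(groups)) {
    plan <- .plan_session(config)
    segs <- plan$segments
    # per-period parameter targets for this subject
    sub_par <- list()
    for (p in c("REST", "MAT", "VFT")) {
      sub_par[[p]] <- list()
      for (comp in c("H", "V")) {
        row <- config$grid[config$grid$group == groups[s] &
                             config$grid$period == p &
                             config$grid$component == comp, ]
        tri <- .draw_cell_triplet(1, row, config$main_sequence_rho)
        sub_par[[p]][[comp]] <- c(frequency = tri$frequency,
                                  amplitude = tri$amplitude,
                                  velocity = tri$velocity)
        draws[[length(draws) + 1L]] <- data.frame(
          subject_id = ids[s], group = groups[s], period = p, component = comp,
          frequency = sub_par[[p]][[comp]][["frequency"]],
          amplitude = sub_par[[p]][[comp]][["amplitude"]],
          velocity = sub_par[[p]][[comp]][["velocity"]],
          stringsAsFactors = FALSE)
      }
    }
    pieces <- vector("list", nrow(segs))
    truths <- vector("list", nrow(segs))
    pos <- c(0, 0)
    for (k in seq_len(nrow(segs))) {
      seg <- simulate_trace(config, groups[s], segs$period[k],
                            duration_s = segs$end[k] - segs$start[k],
                            subject_id = ids[s],
                            params = sub_par[[segs$period[k]]],
                            t0 = segs$start[k], start_pos = pos,
                            apply_noise = FALSE, apply_dropout = FALSE)
      pieces[[k]] <- seg; pos <- seg$end_pos
      truths[[k]] <- seg$truth
    }
    t_all <- unlist(lapply(pieces, function(z) z$trace$time))
    # recover degree positions piecewise, add noise once, convert once
    deg <- do.call(rbind, lapply(pieces, function(z) {
      ang <- pixels_to_degrees(z$trace, config$geometry)
      cbind(ang$x_deg, ang$y_deg)
    }))
    if (config$noise_sd_deg > 0) {
      deg <- deg + matrix(stats::rnorm(2 * length(t_all), 0, config$noise_sd_deg),
                          ncol = 2)
    }
    px <- degrees_to_pixels(deg[, 1], deg[, 2], config$geometry)
    valid <- rep(TRUE, length(t_all))
    if (config$dropout_rate > 0) {
      valid <- !.dropout_mask(length(t_all), config, 1 / config$rate_hz)
    }
    x <- px$x; y <- px$y
    x[!valid] <- NA_real_; y[!valid] <- NA_real_
    trace <- gaze_trace(t_all, x, y, valid, subject_id = ids[s],
                        rate_hz = config$rate_hz)
    truth <- do.call(rbind, truths)
    subjects[[s]] <- list(trace = trace, events = plan$events,
                          windows = windows_from_events(plan$events),
                          truth = truth, params = sub_par, group = groups[s])
  }
  structure(list(subjects = subjects,
                 demographics = .draw_demographics(ids, groups),
                 param_draws = do.call(rbind, draws),
                 config = config),
            class = "sim_cohort")
}

# demographic covariates per group (age, sex, education, cognition, task
# performance) matching the reference cohort's means/SDs
.draw_demographics <- function(ids, groups) {
  n <- length(groups)
  young <- groups == "young"
  rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    z <- stats::rnorm(n, mean, sd)
    pmin(pmax(z, lo), hi)
  }
  data.frame(
    subject_id = ids, group = groups,
    age = ifelse(young, rtrunc(n, 22.0, 1.6, 20, 29), rtrunc(n, 69.4, 5.9, 60, 95)),
    female = stats::runif(n) < ifelse(young, 0.607, 0.500),
    education_years = ifelse(young, rtrunc(n, 13.7, 1.0, 6, 22),
                             rtrunc(n, 12.4, 3.7, 0, 22)),
    cerad_ts = ifelse(young, rtrunc(n, 87.6, 4.3, 0, 100),
                      rtrunc(n, 71.3, 6.9, 0, 100)),
    mmse = ifelse(young, rtrunc(n, 29.8, 0.4, 24, 30), rtrunc(n, 27.7, 1.3, 24, 30)),
    mat_correct_pct = ifelse(young, rtrunc(n, 81.6, 12.2, 0, 100),
                             rtrunc(n, 41.9, 16.1, 0, 100)),
    vft_correct_n = round(ifelse(young, rtrunc(n, 19.4, 6.0, 0, 60),
                                 rtrunc(n, 13.1, 4.7, 0, 60))),
    stringsAsFactors = FALSE)
}
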