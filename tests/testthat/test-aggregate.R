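mk_trace <- function(dur = 10, rate = 120, valid = NULL) {
  n <- round(dur * rate)
  v <- if (is.null(valid)) rep(TRUE, n) else valid
  x <- ifelse(v, 512, NA)
  gaze_trace((seq_len(n) - 1) / rate, x, x, v, subject_id = "s1",
             rate_hz = rate)
}

mk_sacc <- function(onsets, component = "H", amp = 2, vel = 150) {
  k <- length(onsets)
  data.frame(component = rep(component, k), onset_idx = rep(1L, k),
             offset_idx = rep(2L, k), onset_t = onsets,
             offset_t = onsets + 0.025, amplitude_deg = rep(amp, k),
             mean_velocity = rep(vel, k), direction_sign = rep(1L, k),
             stringsAsFactors = FALSE)
}

mk_windows <- function(period = "REST", start = 0, end = 10) {
  structure(data.frame(period = period, start = start, end = end),
            class = c("period_windows", "data.frame"))
}

test_that("frequency is events per analysed second", {
  p <- aggregate_params(mk_sacc(c(1, 4, 8)), mk_windows(), mk_trace(),
                        group = "young")
  h <- p[p$component == "H", ]
  expect_equal(h$frequency, 0.3)
  expect_equal(h$n_events, 3L)
  expect_equal(h$analyzed_duration, 10)
  expect_equal(h$mean_amplitude, 2)
  expect_equal(h$mean_velocity, 150)
})

test_that("empty cells propagate as missing, never as zero parameters", {
  p <- aggregate_params(mk_sacc(numeric(0)), mk_windows(), mk_trace())
  v <- p[p$component == "V", ]
  expect_equal(v$frequency, 0)
  expect_true(is.na(v$mean_amplitude))
  expect_true(is.na(v$mean_velocity))
})

test_that("aggregation is invariant to partitioning a window", {
  s <- mk_sacc(c(1, 4, 8))
  one <- aggregate_params(s, mk_windows(), mk_trace())
  two <- aggregate_params(s, mk_windows(c("REST", "REST"), c(0, 6), c(6, 10)),
                          mk_trace())
  expect_equal(one$frequency, two$frequency)
  expect_equal(one$mean_amplitude, two$mean_amplitude)
  expect_equal(one$analyzed_duration, two$analyzed_duration)
})

test_that("frequency scales inversely with duration at fixed events", {
  s <- mk_sacc(c(1, 2))
  f10 <- aggregate_params(s, mk_windows(end = 10), mk_trace(10))$frequency[1]
  f20 <- aggregate_params(s, mk_windows(end = 20), mk_trace(20))$frequency[1]
  expect_equal(f10, 2 * f20)
})

test_that("invalid time is subtracted from the denominator (and can be kept)", {
  valid <- rep(TRUE, 1200); valid[1:240] <- FALSE  # 2 s of dropout
  tr <- mk_trace(10, valid = valid)
  s <- mk_sacc(c(4, 6, 8))
  p <- aggregate_params(s, mk_windows(), tr)
  expect_equal(p$frequency[p$component == "H"], 3 / 8)
  p_raw <- aggregate_params(s, mk_windows(), tr, use_valid_time = FALSE)
  expect_equal(p_raw$frequency[p_raw$component == "H"], 3 / 10)
})

test_that("events are assigned to periods by onset time", {
  w <- mk_windows(c("REST", "VFT"), c(0, 5), c(5, 10))
  s <- mk_sacc(c(4.99, 5.0))
  p <- aggregate_params(s, w, mk_trace())
  expect_equal(p$n_events[p$period == "REST" & p$component == "H"], 1L)
  expect_equal(p$n_events[p$period == "VFT" & p$component == "H"], 1L)
})

test_that("cohort summaries reproduce hand-computed means", {
  rows <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(subject_id = paste0("s", i), group = "young", period = "REST",
               component = "H", frequency = c(1, 2, 6)[i],
               mean_amplitude = c(2, 3, 4)[i], mean_velocity = c(100, 150, 200)[i],
               n_events = 5L, analyzed_duration = 10)
  }))
  ct <- cohort_table(rows)
  expect_equal(ct$summary$frequency_mean, 3)
  expect_equal(ct$summary$mean_amplitude_mean, 3)
  expect_equal(ct$summary$mean_velocity_sd, 50)
  # single subject: mean is the subject's value, SD reported as 0
  ct1 <- cohort_table(rows[1, ])
  expect_equal(ct1$summary$frequency_mean, 1)
  expect_equal(ct1$summary$frequency_sd, 0)
})
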