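test_that("sub-threshold traces yield no events", {
  vel <- speed_trace(c(0, 50, 99.9, 80, 0))
  expect_equal(nrow(detect_component(vel, "H")), 0L)
})

test_that("the independence rule merges close candidates and separates distant ones", {
  run <- c(150, 180, 150)
  # 3 sub-threshold samples (25 ms at 120 Hz): one merged event
  vx <- c(0, run, rep(20, 3), run, 0)
  ev <- detect_component(speed_trace(vx), "H")
  expect_equal(nrow(ev), 1L)
  # merged-gap samples belong to the event
  expect_equal(ev$offset_idx - ev$onset_idx, 9L)
  # 5 sub-threshold samples (41.7 ms): still merged
  vx <- c(0, run, rep(20, 5), run, 0)
  expect_equal(nrow(detect_component(speed_trace(vx), "H")), 1L)
  # 6 sub-threshold samples (exactly 50 ms): two independent saccades
  vx <- c(0, run, rep(20, 6), run, 0)
  expect_equal(nrow(detect_component(speed_trace(vx), "H")), 2L)
})

test_that("detection is idempotent under the merge rule and monotone in threshold", {
  set.seed(7)
  cfg <- detection_config()
  for (i in 1:30) {
    vx <- pmax(rnorm(240, 40, 60), 0)
    ev <- detect_component(speed_trace(vx), "H", cfg)
    if (nrow(ev) > 1) {
      # consecutive output events must already satisfy independence
      gap_samples <- ev$onset_idx[-1] - ev$offset_idx[-nrow(ev)]
      gap_time <- (ev$onset_t[-1] - ev$offset_t[-nrow(ev)])
      expect_true(all(gap_samples >= cfg$min_subthreshold_samples |
                        gap_time >= cfg$min_interval_s))
    }
    n_low <- nrow(ev)
    n_high <- nrow(detect_component(speed_trace(vx), "H",
                                    detection_config(velocity_threshold = 150)))
    expect_lte(n_high, n_low)
  }
})

test_that("events match the brute-force reference scanner on random traces", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(60:160, 1)
    vx <- pmax(rnorm(n, 50, 55), 0)
    valid <- runif(n) > 0.05
    vel <- speed_trace(vx, valid = valid)
    ev <- detect_component(vel, "H")
    bf <- brute_force_detect(vel$time, vel$speed_x, valid)
    expect_equal(nrow(ev), nrow(bf))
    if (nrow(ev)) {
      expect_equal(ev$onset_idx, unname(bf[, 1]))
      expect_equal(ev$offset_idx - 1L, unname(bf[, 2]))
    }
  }
})

test_that("invalid samples split candidate runs and are never bridged", {
  run <- c(150, 180, 150)
  vx <- c(0, run, 20, 20, run, 0)
  valid <- rep(TRUE, length(vx))
  valid[6] <- FALSE  # dropout inside the short gap
  ev <- detect_component(speed_trace(vx, valid = valid), "H")
  expect_equal(nrow(ev), 2L)
  # dropout inside a run splits it
  vx <- c(0, 150, 180, 170, 160, 150, 0)
  valid <- rep(TRUE, 7); valid[4] <- FALSE
  ev <- detect_component(speed_trace(vx, valid = valid), "H")
  expect_equal(nrow(ev), 2L)
})

test_that("event measurement gives displacement amplitude and mean speed", {
  # single-sample event moving 1 degree in one inter-sample interval
  vx <- c(0, 120, 0)
  pos <- positions_for(vx)
  ev <- detect_component(speed_trace(vx), "H", positions = pos)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$amplitude_deg, 1)
  expect_equal(ev$mean_velocity, 120)
  expect_equal(ev$direction_sign, 1L)
  # time reversal preserves amplitude and mean velocity, flips direction
  vx2 <- rev(-vx)
  ev2 <- detect_component(speed_trace(vx2), "H", positions = positions_for(vx2))
  expect_equal(ev2$amplitude_deg, ev$amplitude_deg)
  expect_equal(ev2$mean_velocity, ev$mean_velocity)
  expect_equal(ev2$direction_sign, -1L)
  # mean velocity averages all event samples including a merged gap
  vx <- c(0, 150, 150, 30, 30, 150, 150, 0)
  ev <- detect_component(speed_trace(vx), "H", positions = positions_for(vx))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mean_velocity, mean(c(150, 150, 30, 30, 150, 150)))
})

test_that("magnitude mode detects on 2D speed and measures both components", {
  n <- 9
  vx <- c(0, 80, 80, 80, 0, 0, 0, 0, 0)
  vy <- c(0, 80, 80, 80, 0, 0, 0, 0, 0)
  vel <- speed_trace(vx)
  vel$vy <- vy; vel$speed_y <- abs(vy)
  ang <- angular_trace((0:(n)) / 120, c(0, cumsum(vx / 120)),
                       c(0, cumsum(vy / 120)))
  # per-component: neither channel crosses 100
  expect_equal(nrow(detect_saccades(vel, ang, detection_config())), 0L)
  # magnitude: sqrt(80^2+80^2) = 113 crosses it, both components measured
  ev <- detect_saccades(vel, ang, detection_config(mode = "magnitude"))
  expect_equal(sort(unique(ev$component)), c("H", "V"))
  expect_equal(nrow(ev), 2L)
})
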