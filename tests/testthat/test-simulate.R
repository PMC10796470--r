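test_that("zero frequency gives a pure fixation trace with empty ground truth", {
  cfg <- tiny_sim_config()
  set.seed(1)
  st <- simulate_trace(cfg, "young", "REST", duration_s = 5, params = list(
    H = c(frequency = 0, amplitude = 3, velocity = 150),
    V = c(frequency = 0, amplitude = 3, velocity = 150)))
  expect_equal(nrow(st$truth), 0L)
  pp <- preprocess_trace(st$trace, cfg$geometry)
  expect_equal(nrow(detect_saccades(pp$velocity, pp$angular)), 0L)
})

test_that("an injected saccade reaches its requested speed and is recovered", {
  cfg <- tiny_sim_config(noise_sd_deg = 0.02, dropout_rate = 0)
  set.seed(2)
  st <- simulate_trace(cfg, "young", "REST", duration_s = 10, params = list(
    H = c(frequency = 0.4, amplitude = 3, velocity = 150),
    V = c(frequency = 0, amplitude = 3, velocity = 150)))
  expect_gt(nrow(st$truth), 0L)
  pp <- preprocess_trace(st$trace, cfg$geometry)
  # differentiating the generated positions shows the commanded speed
  expect_gte(max(pp$velocity$speed_x, na.rm = TRUE), 150 * 0.85)
  ev <- detect_saccades(pp$velocity, pp$angular)
  ev <- ev[ev$component == "H", ]
  expect_equal(nrow(ev), nrow(st$truth))
  # amplitudes recovered within a small tolerance of the targets
  expect_equal(sort(ev$amplitude_deg), sort(abs(st$truth$amplitude_deg)),
               tolerance = 0.2)
})

test_that("noiseless dropout-free cohorts recover ground-truth event counts exactly", {
  grid <- default_cohort_grid()
  grid$vel_mean <- 200; grid$vel_sd <- 5
  grid$amp_mean <- 3.5; grid$amp_sd <- 0.4
  cfg <- tiny_sim_config(noise_sd_deg = 0.02, dropout_rate = 0, grid = grid,
                         vel_jitter_sdlog = 0.03, amp_jitter_sdlog = 0.05)
  coh <- simulate_cohort(cfg, seed = 5)
  for (s in coh$subjects[1:2]) {
    pp <- preprocess_trace(s$trace, cfg$geometry)
    ev <- detect_saccades(pp$velocity, pp$angular)
    for (comp in c("H", "V")) {
      expect_equal(sum(ev$component == comp),
                   sum(s$truth$component == comp))
    }
  }
})

test_that("cohorts are bit-identical under the same seed", {
  cfg <- tiny_sim_config()
  c1 <- simulate_cohort(cfg, seed = 9)
  c2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(c1$param_draws, c2$param_draws)
  expect_identical(c1$subjects[[1]]$trace$x, c2$subjects[[1]]$trace$x)
  expect_identical(c1$subjects[[3]]$events, c2$subjects[[3]]$events)
  c3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(c1$subjects[[1]]$trace$x, c3$subjects[[1]]$trace$x))
})

test_that("cohort structure matches the study design", {
  cfg <- tiny_sim_config()
  coh <- simulate_cohort(cfg, seed = 3)
  expect_length(coh$subjects, 4L)
  s <- coh$subjects[[1]]
  expect_setequal(unique(s$windows$period), c("REST", "MAT", "VFT"))
  # 18 arithmetic problems, each with a click
  expect_equal(sum(s$events$label == "mat_problem_on"), 18L)
  expect_equal(sum(s$events$label == "mat_click"), 18L)
  # every ground-truth event lies inside the trace's span
  expect_true(all(s$truth$onset >= min(s$trace$time)))
  expect_true(all(s$truth$onset + 1.6 * s$truth$duration_s <= max(s$trace$time) + 1e-9))
})

test_that("subject parameter draws match the configured cell moments", {
  cfg <- tiny_sim_config(n_young = 28, n_old = 26)
  coh <- simulate_cohort(cfg, seed = 11)
  d <- coh$param_draws
  g <- default_cohort_grid()
  for (i in seq_len(nrow(g))) {
    n <- if (g$group[i] == "young") 28 else 26
    sel <- d$group == g$group[i] & d$period == g$period[i] &
      d$component == g$component[i]
    expect_lt(abs(mean(d$frequency[sel]) - g$freq_mean[i]),
              2 * g$freq_sd[i] / sqrt(n) + 1e-9)
    expect_lt(abs(mean(d$velocity[sel]) - g$vel_mean[i]),
              2 * g$vel_sd[i] / sqrt(n))
  }
  # draw SDs on the configured scale (pooled over cells, loose bound)
  rel <- abs(tapply(d$amplitude, paste(d$group, d$period, d$component),
                    sd)[paste(g$group, g$period, g$component)] - g$amp_sd) /
    g$amp_sd
  expect_lt(median(rel), 0.5)
})

test_that("dropout produces the configured invalid fraction in both modes", {
  for (mode in c("blink", "bernoulli")) {
    cfg <- tiny_sim_config(dropout_rate = 0.1, dropout_mode = mode)
    coh <- simulate_cohort(cfg, seed = 21)
    vf <- mean(sapply(coh$subjects, function(s) mean(s$trace$valid)))
    expect_equal(vf, 0.9, tolerance = 0.03)
  }
})

test_that("arithmetic problem lists respect construction rules", {
  set.seed(13)
  for (i in 1:200) {
    pl <- make_mat_problem_list()
    expect_equal(nrow(pl), 18L)
    expect_equal(unname(table(pl$difficulty)[c("easy", "medium", "difficult")]),
                 rep(6L, 3), ignore_attr = TRUE)
    ez <- pl[pl$difficulty == "easy", ]
    expect_true(all(ez$multiplicand %in% 3:9 & ez$multiplier %in% 13:19))
    md <- pl[pl$difficulty == "medium", ]
    expect_true(all(md$multiplicand %in% 6:14 & md$multiplier %in% 13:27))
    df <- pl[pl$difficulty == "difficult", ]
    expect_true(all(df$multiplicand %in% 11:19 & df$multiplier %in% 16:27))
    # no operand is a multiple of ten
    expect_true(all(pl$multiplicand %% 10 != 0 & pl$multiplier %% 10 != 0))
    # no same difficulty more than three times in a row
    expect_lte(max(rle(pl$difficulty)$lengths), 3L)
    # no 1/2-confusable operand pairs such as 21 x 22 or 12 x 11
    conf <- mapply(function(a, b) {
      da <- strsplit(as.character(a), "")[[1]]
      db <- strsplit(as.character(b), "")[[1]]
      length(da) == length(db) &&
        all(da == db | (da %in% c("1", "2") & db %in% c("1", "2")))
    }, pl$multiplicand, pl$multiplier)
    expect_false(any(conf))
  }
})

test_that("a sub-threshold configured velocity triggers a warning", {
  grid <- default_cohort_grid()
  grid$vel_mean[1] <- 80
  expect_warning(tiny_sim_config(grid = grid), "undetectable")
})
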