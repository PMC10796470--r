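# Shared fixtures and independent oracles for the test suite.

# Build a velocity_trace directly from a vector of horizontal speeds
# (deg/s, signed), sampled at `rate` Hz. Vertical channel is zero.
speed_trace <- function(vx, rate = 120, valid = rep(TRUE, length(vx))) {
  n <- length(vx)
  structure(list(subject_id = "fix", time = (seq_len(n) - 1) / rate,
                 vx = vx, vy = rep(0, n), speed_x = abs(vx),
                 speed_y = rep(0, n), valid = valid),
            class = "velocity_trace")
}

# Position trace whose forward differences are `vx` at `rate` Hz.
positions_for <- function(vx, rate = 120) {
  n <- length(vx)
  p <- c(0, cumsum(vx / rate))
  angular_trace(time = (seq_len(n + 1) - 1) / rate, x_deg = p,
                y_deg = rep(0, n + 1))
}

# Exhaustive reference saccade scanner: finds maximal supra-threshold
# runs by linear scan and applies the merge predicate pairwise until a
# fixed point. Independent of the package's rle-based implementation.
brute_force_detect <- function(time, speed, valid = rep(TRUE, length(speed)),
                               threshold = 100, min_interval = 0.05,
                               min_sub = 6) {
  n <- length(speed)
  runs <- list(); cur <- NULL
  for (i in seq_len(n)) {
    s <- !is.na(speed[i]) && valid[i] && speed[i] >= threshold
    if (s) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  repeat {
    merged <- FALSE
    out <- list(); j <- 1
    while (j <= length(runs)) {
      if (j < length(runs)) {
        a <- runs[[j]]; b <- runs[[j + 1]]
        gs <- a[2] + 1; ge <- b[1] - 1
        gap_ok <- (time[b[1]] - time[gs]) < min_interval &&
          (ge - gs + 1) < min_sub && all(valid[gs:ge])
        if (gap_ok) {
          runs[[j + 1]] <- c(a[1], b[2]); j <- j + 1; merged <- TRUE; next
        }
      }
      out[[length(out) + 1]] <- runs[[j]]; j <- j + 1
    }
    runs <- out
    if (!merged) break
  }
  if (!length(runs)) return(matrix(numeric(), ncol = 2))
  do.call(rbind, runs)
}

# Exact two-sided Wilcoxon-Mann-Whitney p by enumeration of all
# C(n1+n2, n1) labelings (midrank U statistic).
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n, n1)
  us <- apply(labelings, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Complete balanced-within fixture for the factorial analyses.
make_params_fixture <- function(n_young = 8, n_old = 6, seed = 1,
                                effect_period = c(0, 0, 0),
                                effect_group = 0, interaction = 0,
                                sd = 1) {
  set.seed(seed)
  groups <- c(rep("young", n_young), rep("old", n_old))
  ids <- sprintf("P%02d", seq_along(groups))
  rows <- list()
  for (s in seq_along(ids)) {
    for (k in 1:3) {
      p <- c("REST", "MAT", "VFT")[k]
      mu <- 10 + effect_period[k] +
        ifelse(groups[s] == "young", effect_group, 0) +
        ifelse(groups[s] == "young" && k > 1, interaction, 0)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ids[s], group = groups[s], period = p,
        component = "H", frequency = rnorm(1, mu, sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Small, fast simulation configuration for unit tests.
tiny_sim_config <- function(n_young = 2, n_old = 2, ...) {
  sim_config(n_young = n_young, n_old = n_old,
             rest_duration_s = 4, vft_duration_s = 5,
             mat_median_s = c(easy = 0.8, medium = 1, difficult = 1.2),
             answer_gap_s = 0.8, ...)
}

# As above, with event rates high enough that short test recordings have
# no empty cells (the factorial stage excludes incomplete subjects).
dense_sim_config <- function(n_young = 3, n_old = 3, ...) {
  grid <- default_cohort_grid()
  grid$freq_mean <- pmax(grid$freq_mean, 2.5)
  tiny_sim_config(n_young = n_young, n_old = n_old, grid = grid, ...)
}
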