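# Measurement model for simulated saccades.
#
# A simulated saccade is a raised-cosine primary movement, optionally
# followed by a post-saccadic oscillation (PSO): the recorded signal
# overshoots the landing position and returns, as pupil/corneal-reflection
# video trackers characteristically report. Writing A for the outgoing
# amplitude, o for the overshoot and T1 for the primary duration:
#   s(t) = A * P(t/T1),                      t in [0, T1]
#   s(t) = A - o * P((t - T1)/(0.6 T1)),     t in (T1, 1.6 T1]
# with P(u) = u - sin(2 pi u)/(2 pi) (raised-cosine velocity). The net
# displacement is A - o.
#
# The analysis pipeline measures mean velocity as the mean of sampled,
# 3-point-smoothed component speeds over the supra-threshold span of an
# event, and amplitude as the displacement across that span. Two hard
# facts shape the inversion the generator needs:
#   * measured amplitude == measured mean speed x span duration for any
#     motion without reversals, and
#   * MA3 smoothing smears a fast displacement D over >= 3 samples,
#     capping its measured speed near D/(3 dt).
# Together these make large measured mean velocities at small measured
# amplitudes unreachable for smooth one-way movements; the unsigned
# return path of the PSO breaks the identity and lets measured speed
# exceed net-displacement/time, exactly as in real video-tracker
# recordings. Because the generator's targets are on the measured scale,
# it solves per event for (A, T1, o) whose *expected* measurement is
# closest to the target.
#
# The forward model is dimensionless in u = T1/dt (samples per primary
# movement), r = threshold/mu (mu = A/T1) and q = o/A: measured velocity
# = mu W(u,r,q), measured amplitude = A C(u,r,q), detection probability
# D(u,r,q), all phase-averaged, tabulated once per session by simulating
# the sampling + smoothing + differencing + thresholding + merging chain.
# The inversion is a one-time nearest-achievable-point lookup: every
# table cell maps to an achievable (velocity, amplitude) pair at a given
# (threshold, dt); for a grid of targets the loss-minimising cell is
# stored, and per-event solutions are interpolated from that inverse
# table.

.sacc_profile <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# sampled recorded position of a unit-outgoing-amplitude event
.sacc_position <- function(t, Tn, q) {
  .sacc_profile(t / Tn) - q * .sacc_profile((t - Tn) / (0.6 * Tn))
}

.calib_env <- new.env(parent = emptyenv())

# Dimensionless forward tables W, C, D over (u, r, q).
.measurement_table <- function(n_phase = 16L) {
  if (!is.null(.calib_env$tab)) return(.calib_env$tab)
  log_u <- seq(log(0.25), log(30), length.out = 40L)
  r_grid <- seq(0.02, 2.2, length.out = 41L)
  q_grid <- c(0, 0.15, 0.3, 0.45, 0.6, 0.75)
  nu <- length(log_u); nr <- length(r_grid); nq <- length(q_grid)
  W <- C <- D <- array(NA_real_, c(nu, nr, nq))
  for (iq in seq_len(nq)) {
    q <- q_grid[iq]
    for (iu in seq_len(nu)) {
      Tn <- exp(log_u[iu])
      npost <- ceiling(1.6 * Tn) + 4L
      acc_w <- acc_c <- acc_d <- rep(0, nr)
      for (ph in seq_len(n_phase)) {
        t <- seq(-4L, npost) + (ph - 1) / n_phase
        p <- .sacc_position(t, Tn, q)
        n <- length(p)
        ps <- p
        ps[2:(n - 1L)] <- (p[1:(n - 2L)] + p[2:(n - 1L)] + p[3:n]) / 3
        w <- abs(diff(ps)) * Tn          # speed / mu (dt = 1, mu = 1/Tn)
        for (ir in seq_len(nr)) {
          supra <- which(w >= r_grid[ir])
          if (length(supra)) {
            # merge supra runs separated by < 6 sub-threshold samples, as
            # the detector does; measure the first merged event
            gaps <- which(diff(supra) > 1L)
            split_at <- gaps[supra[gaps + 1L] - supra[gaps] - 1L >= 6L]
            i2 <- if (length(split_at)) supra[split_at[1L]] else
              supra[length(supra)]
            i1 <- supra[1L]
            acc_w[ir] <- acc_w[ir] + mean(w[i1:i2])
            acc_c[ir] <- acc_c[ir] + abs(ps[i2 + 1L] - ps[i1])
            acc_d[ir] <- acc_d[ir] + 1
          }
        }
      }
      det <- acc_d > 0
      W[iu, det, iq] <- acc_w[det] / acc_d[det]
      C[iu, det, iq] <- acc_c[det] / acc_d[det]
      D[iu, , iq] <- acc_d / n_phase
    }
  }
  D[is.na(D)] <- 0
  .calib_env$tab <- list(log_u = log_u, r = r_grid, q = q_grid,
                         W = W, C = C, D = D)
  .calib_env$tab
}

# Linear interpolation with edge clamping over a strictly increasing x
# (lean replacement for stats::approx in the event-calibration hot path).
.lin_interp <- function(x, y, xout) {
  i <- findInterval(xout, x, all.inside = TRUE)
  f <- (xout - x[i]) / (x[i + 1L] - x[i])
  f <- pmin(pmax(f, 0), 1)
  y[i] * (1 - f) + y[i + 1L] * f
}

# Bilinear interpolation with edge clamping on an (xg, yg) grid.
.interp2 <- function(M, xg, yg, x, y) {
  x <- pmin(pmax(x, xg[1]), xg[length(xg)])
  y <- pmin(pmax(y, yg[1]), yg[length(yg)])
  i <- pmin(findInterval(x, xg), length(xg) - 1L)
  j <- pmin(findInterval(y, yg), length(yg) - 1L)
  fx <- (x - xg[i]) / (xg[i + 1L] - xg[i])
  fy <- (y - yg[j]) / (yg[j + 1L] - yg[j])
  M[cbind(i, j)] * (1 - fx) * (1 - fy) +
    M[cbind(i + 1L, j)] * fx * (1 - fy) +
    M[cbind(i, j + 1L)] * (1 - fx) * fy +
    M[cbind(i + 1L, j + 1L)] * fx * fy
}

# Inverse structure for a given (threshold, dt): one curve per (r, q)
# table slice, parameterised by u, carrying measured amplitude (monotone
# in u after cummax), measured velocity and log u. Only reliably detected
# points (D >= 0.9) participate, so calibrated events are effectively
# always detected. A dense (velocity, log amplitude) node grid snaps each
# target to its best curve (argmin over curves of |velocity error| plus
# penalties for amplitude clamping and overshoot); the amplitude equation
# is then re-solved exactly along the chosen curve.
.calib_inverse <- function(threshold, dt) {
  key <- sprintf("inv_%.6g_%.6g", threshold, dt)
  if (!is.null(.calib_env[[key]])) return(.calib_env[[key]])
  tab <- .measurement_table()
  curves <- list()
  for (iq in seq_along(tab$q)) {
    for (ir in seq_along(tab$r)) {
      W <- tab$W[, ir, iq]; C <- tab$C[, ir, iq]; D <- tab$D[, ir, iq]
      ok <- which(is.finite(W) & is.finite(C) & D >= 0.9)
      if (length(ok) < 2L) next
      mu <- threshold / tab$r[ir]
      amp <- mu * exp(tab$log_u[ok]) * dt * C[ok]
      keep <- !duplicated(cummax(amp))
      if (sum(keep) < 2L) next
      ca <- cummax(amp)[keep]
      curves[[length(curves) + 1L]] <-
        list(amp = ca, amp_min = ca[1L], amp_max = ca[length(ca)],
             vel = (mu * W[ok])[keep],
             log_u = tab$log_u[ok][keep], r = tab$r[ir], q = tab$q[iq])
    }
  }
  vq <- seq(threshold * 1.005, threshold * 3.2, by = threshold * 0.025)
  laq <- seq(log(0.25), log(15), length.out = 200L)
  nodes_a <- exp(laq)
  best_loss <- matrix(Inf, length(vq), length(laq))
  best_curve <- matrix(NA_integer_, length(vq), length(laq))
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    ampc <- pmin(pmax(nodes_a, cv$amp_min), cv$amp_max)
    velc <- .lin_interp(cv$amp, cv$vel, ampc)       # length laq
    amp_pen <- 40 * abs(log(ampc / nodes_a)) + 1.5 * cv$q
    loss <- abs(outer(vq, velc, `-`)) +
      matrix(amp_pen, length(vq), length(laq), byrow = TRUE)
    upd <- loss < best_loss
    best_loss[upd] <- loss[upd]
    best_curve[upd] <- ci
  }
  inv <- list(curves = curves, vq = vq, laq = laq, best_curve = best_curve)
  .calib_env[[key]] <- inv
  inv
}

# Joint solver: underlying (A, T1, o) per event for measured targets
# (m_t, a_t). Along every (r, q) curve the amplitude equation is solved
# exactly by interpolation in u; the curve whose velocity at that point
# is closest to the target wins (with a small preference for less
# overshoot). Events with target velocity at or below the threshold are
# left uncompensated: they are undetectable by design. Also returns the
# expected detection probability.
.calibrate_events <- function(m_t, a_t, dt, threshold) {
  k <- length(m_t)
  A <- a_t
  Td <- a_t / pmax(m_t, 1e-6)
  o <- numeric(k)
  pdet <- rep(0, k)
  doit <- which(m_t > threshold * 1.02)
  if (length(doit)) {
    inv <- .calib_inverse(threshold, dt)
    m <- m_t[doit]; a <- a_t[doit]
    iv <- pmin(pmax(round((m - inv$vq[1]) /
                            (inv$vq[2] - inv$vq[1])) + 1L, 1L), length(inv$vq))
    ja <- pmin(pmax(round((log(a) - inv$laq[1]) /
                            (inv$laq[2] - inv$laq[1])) + 1L, 1L), length(inv$laq))
    cid <- inv$best_curve[cbind(iv, ja)]
    lu <- r <- q <- numeric(length(m))
    for (ci in unique(cid)) {
      cv <- inv$curves[[ci]]
      sel <- cid == ci
      ac <- pmin(pmax(a[sel], cv$amp_min), cv$amp_max)
      lu[sel] <- .lin_interp(cv$amp, cv$log_u, ac)
      r[sel] <- cv$r
      q[sel] <- cv$q
    }
    mu <- threshold / r
    u <- exp(lu)
    A[doit] <- mu * u * dt
    Td[doit] <- u * dt
    o[doit] <- q * A[doit]
    pdet[doit] <- 1
  }
  miss <- setdiff(seq_len(k), doit)
  if (length(miss)) {
    tab <- .measurement_table()
    mu0 <- pmax(m_t[miss], 1e-6)
    pdet[miss] <- .interp2(tab$D[, , 1], tab$log_u, tab$r,
                           log(a_t[miss] / (mu0 * dt)), threshold / mu0)
  }
  # A is the outgoing amplitude; net displacement is A - o
  list(A = A, T = Td, o = o, pdet = pdet)
}
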