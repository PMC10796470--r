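# independent oracle: classical mixed ANOVA via aov with an Error stratum
aov_oracle <- function(d, response) {
  d$y <- d[[response]]
  d$subject_id <- factor(d$subject_id)
  d$group <- factor(d$group); d$period <- factor(d$period)
  fit <- summary(stats::aov(y ~ group * period + Error(subject_id), data = d))
  btw <- fit[["Error: subject_id"]][[1]]
  win <- fit[["Error: Within"]][[1]]
  list(F_group = btw["group", "F value"],
       F_period = win["period", "F value"],
       F_int = win["group:period", "F value"],
       ss_subj = btw["Residuals", "Sum Sq"],
       ss_werr = win["Residuals", "Sum Sq"])
}

test_that("mixed rmANOVA matches the aov oracle on balanced and unbalanced designs", {
  for (n_old in c(8, 6)) {  # balanced and unbalanced group sizes
    d <- make_params_fixture(8, n_old, seed = 41, effect_period = c(0, 1, 2),
                             effect_group = 0.8, interaction = 0.5)
    tab <- mixed_rmanova(d, "frequency")
    orc <- aov_oracle(d, "frequency")
    expect_equal(tab$F[tab$effect == "group"], orc$F_group, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "period"], orc$F_period, tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "group:period"], orc$F_int,
                 tolerance = 1e-8)
    expect_equal(tab$SS[tab$effect == "subjects_within_group"], orc$ss_subj,
                 tolerance = 1e-8)
    expect_equal(tab$SS[tab$effect == "period_x_subjects"], orc$ss_werr,
                 tolerance = 1e-8)
  }
})

test_that("mixed rmANOVA agrees with a hand-computed toy design", {
  # 2 groups x 2 subjects x 3 periods with simple integer responses
  d <- data.frame(
    subject_id = rep(c("a", "b", "c", "d"), each = 3),
    group = rep(c("young", "young", "old", "old"), each = 3),
    period = rep(c("REST", "MAT", "VFT"), 4),
    frequency = c(1, 2, 3,
                  2, 3, 4,
                  3, 4, 5,
                  5, 6, 7))
  tab <- mixed_rmanova(d, "frequency")
  # by hand: grand = 3.75; group means 2.5 / 5.0:
  # SS_group = 3 * [2 (2.5 - 3.75)^2 + 2 (5 - 3.75)^2] = 18.75
  expect_equal(tab$SS[tab$effect == "group"], 18.75)
  # period means (2.75, 3.75, 4.75): SS_period = 4 * (1 + 0 + 1) = 8
  expect_equal(tab$SS[tab$effect == "period"], 8)
  # periods are perfectly parallel: zero interaction and zero within error
  expect_equal(tab$SS[tab$effect == "group:period"], 0)
  expect_equal(tab$SS[tab$effect == "period_x_subjects"], 0)
  # subject means 2,3,4,6 about group means 2.5, 5:
  # SS_subj = 3 * (0.25 + 0.25 + 1 + 1) = 7.5
  expect_equal(tab$SS[tab$effect == "subjects_within_group"], 7.5)
  expect_equal(tab$df, c(1, 2, 2, 2, 4), ignore_attr = TRUE)
})

test_that("stratum sums of squares decompose additively on balanced fixtures", {
  d <- make_params_fixture(6, 6, seed = 43, effect_period = c(0, 2, 1),
                           effect_group = 1)
  tab <- mixed_rmanova(d, "frequency")
  y <- d$frequency
  subj_mean <- ave(y, d$subject_id)
  ss_between_total <- sum((subj_mean - mean(y))^2)
  ss_within_total <- sum((y - subj_mean)^2)
  expect_equal(tab$SS[tab$effect == "group"] +
                 tab$SS[tab$effect == "subjects_within_group"],
               ss_between_total, tolerance = 1e-8)
  expect_equal(tab$SS[tab$effect == "period"] +
                 tab$SS[tab$effect == "group:period"] +
                 tab$SS[tab$effect == "period_x_subjects"],
               ss_within_total, tolerance = 1e-8)
})

test_that("constant responses give zero F and zero reported effect size", {
  d <- make_params_fixture(4, 4, seed = 2, sd = 0)
  d$frequency <- 5
  tab <- mixed_rmanova(d, "frequency")
  expect_true(all(tab$F[!is.na(tab$F)] == 0 | is.nan(tab$F[!is.na(tab$F)])))
  expect_true(all(tab$partial_omega_sq[!is.na(tab$partial_omega_sq)] %in% c(0, NaN)))
})

test_that("partial omega squared is clipped at zero and monotone in effect SS", {
  d <- make_params_fixture(6, 6, seed = 3)  # null data: raw omega often < 0
  tab <- mixed_rmanova(d, "frequency")
  expect_true(all(tab$partial_omega_sq[!is.na(tab$partial_omega_sq)] >= 0))
  # growing the period effect grows omega
  oms <- sapply(c(0, 1, 2), function(e) {
    d <- make_params_fixture(6, 6, seed = 5, effect_period = c(0, e, 2 * e))
    tab <- mixed_rmanova(d, "frequency")
    tab$partial_omega_sq[tab$effect == "period"]
  })
  expect_true(all(diff(oms) > 0))
})

test_that("effect sizes reproduce the F-to-omega relation of the mixed design", {
  d <- make_params_fixture(14, 13, seed = 7, effect_period = c(0, 1.5, 1.2),
                           effect_group = 1)
  tab <- mixed_rmanova(d, "frequency")
  N <- 27
  f_g <- tab$F[tab$effect == "group"]
  om_g <- (f_g - 1) / (f_g - 1 + N)
  expect_equal(tab$partial_omega_sq_raw[tab$effect == "group"], om_g,
               tolerance = 1e-8)
  f_p <- tab$F[tab$effect == "period"]
  om_p <- 2 * (f_p - 1) / (2 * (f_p - 1) + 2 * N)
  expect_equal(tab$partial_omega_sq_raw[tab$effect == "period"], om_p,
               tolerance = 1e-8)
})

test_that("ART alignment has its defining algebraic properties", {
  set.seed(47)
  for (rep in 1:8) {
    d <- make_params_fixture(sample(4:9, 1), sample(4:9, 1), seed = rep,
                             effect_period = rnorm(3), effect_group = rnorm(1),
                             interaction = rnorm(1))
    art <- align_rank_transform(d, "frequency")
    scale <- sd(d$frequency)
    for (e in c("group", "period", "interaction")) {
      # each aligned column sums to zero
      expect_lt(abs(sum(art[[paste0("aligned_", e)]])), 1e-8 * scale * nrow(d))
      # rank columns are midranks of 1..N
      expect_equal(sort(art[[paste0("rank_", e)]]),
                   sort(rank(art[[paste0("aligned_", e)]])))
      # ANOVA of the aligned (unranked) response for e: all other effects
      # are annihilated
      d2 <- d; d2$frequency <- art[[paste0("aligned_", e)]]
      tab <- mixed_rmanova(d2, "frequency")
      others <- setdiff(c("group", "period", "group:period"),
                        c(group = "group", period = "period",
                          interaction = "group:period")[[e]])
      for (oth in others) {
        expect_lt(tab$SS[tab$effect == oth] / max(sum(d2$frequency^2), 1e-12),
                  1e-16)
      }
    }
  }
})

test_that("additive data leave the interaction-aligned cell means at zero", {
  d <- make_params_fixture(5, 4, seed = 8, effect_period = c(0, 2, 4),
                           effect_group = 3, interaction = 0, sd = 0)
  art <- align_rank_transform(d, "frequency")
  cm <- tapply(art$aligned_interaction, list(art$group, art$period), mean)
  expect_true(all(abs(cm) < 1e-10))
})

test_that("art_anova excludes incomplete subjects listwise and reports per effect", {
  d <- make_params_fixture(6, 6, seed = 9, effect_period = c(0, 2, 2))
  d$frequency[d$subject_id == "P01" & d$period == "MAT"] <- NA
  fit <- art_anova(d, "frequency")
  expect_equal(fit$n_excluded, 1L)
  expect_equal(fit$n_subjects, 11L)
  eff <- fit$table[fit$table$effect %in% c("group", "period", "group:period"), ]
  expect_equal(nrow(eff), 3L)
  expect_true(all(is.finite(eff$F)))
  # degrees of freedom follow the 2 x 3 mixed design after exclusion
  expect_equal(eff$df, c(1, 2, 2), ignore_attr = TRUE)
  werr <- fit$table[grepl("period_x_subjects", fit$table$effect), ]
  expect_true(all(werr$df == (11 - 2) * 2))
})

test_that("Tukey contrasts cover all period pairs and dominate unadjusted p", {
  set.seed(51)
  d <- make_params_fixture(10, 9, seed = 10, effect_period = c(0, 1.5, 3))
  art <- align_rank_transform(d, "frequency")
  ph <- tukey_posthoc(art)
  expect_equal(nrow(ph), 3L)
  expect_setequal(ph$contrast,
                  c("MAT - REST", "MAT - VFT", "REST - VFT"))
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))
  expect_true(all(ph$p_adjusted >= 0 & ph$p_adjusted <= 1))
  # equal period means: adjusted p near 1
  d0 <- make_params_fixture(8, 8, seed = 11, sd = 0.001)
  ph0 <- tukey_posthoc(align_rank_transform(d0, "frequency"))
  expect_true(all(ph0$p_adjusted > 0.5))
  # dominance on random fixtures
  for (rep in 1:10) {
    d <- make_params_fixture(5, 5, seed = 100 + rep,
                             effect_period = rnorm(3, 0, 0.5))
    ph <- tukey_posthoc(align_rank_transform(d, "frequency"))
    expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))
  }
})

test_that("Greenhouse-Geisser epsilon stays in its admissible range", {
  d <- make_params_fixture(8, 8, seed = 13, effect_period = c(0, 1, 2))
  eps <- nvsacc:::.gg_epsilon(d, "frequency")
  expect_gte(eps, 0.5)
  expect_lte(eps, 1)
  tab_gg <- mixed_rmanova(d, "frequency", gg = TRUE)
  tab <- mixed_rmanova(d, "frequency")
  expect_gte(tab_gg$p[tab_gg$effect == "period"],
             tab$p[tab$effect == "period"] - 1e-12)
})
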