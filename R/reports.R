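.fmt_pm <- function(m, s, digits = 1) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m, s)
}

#' Demographics comparison table
#'
#' Group comparison of participant characteristics: continuous variables
#' via [wilcoxon_mann_whitney()] (reported as Z), the sex proportion via
#' [chi_square_2x2()]. Layout mirrors a standard participant
#' characteristics table: one row per variable, mean +/- SD per group,
#' test statistic and p.
#'
#' @param demographics data.frame with columns `group` (`young`, `old`),
#'   `age`, `female` (logical), `education_years`, `cerad_ts`, `mmse`,
#'   `mat_correct_pct`, `vft_correct_n` (missing columns are skipped).
#' @return data.frame with columns `variable`, `young`, `old`,
#'   `statistic`, `p`.
#' @export
demographics_table <- function(demographics) {
  g <- demographics$group
  if (!all(c("young", "old") %in% g)) stop("need both groups", call. = FALSE)
  yg <- demographics[g == "young", , drop = FALSE]
  og <- demographics[g == "old", , drop = FALSE]
  cont_vars <- c(age = "Age (years)", education_years = "Education (years)",
                 cerad_ts = "CERAD-TS (points)", mmse = "MMSE (points)",
                 mat_correct_pct = "MAT (% correct)",
                 vft_correct_n = "VFT (n correct)")
  rows <- list()
  for (v in names(cont_vars)) {
    if (!v %in% names(demographics)) next
    w <- wilcoxon_mann_whitney(yg[[v]], og[[v]], exact = FALSE)
    rows[[v]] <- data.frame(
      variable = cont_vars[[v]],
      young = .fmt_pm(mean(yg[[v]]), stats::sd(yg[[v]])),
      old = .fmt_pm(mean(og[[v]]), stats::sd(og[[v]])),
      statistic = round(w$statistic, 2), p = w$p_value,
      stringsAsFactors = FALSE)
  }
  if ("female" %in% names(demographics)) {
    tab <- rbind(c(sum(yg$female), sum(!yg$female)),
                 c(sum(og$female), sum(!og$female)))
    cs <- chi_square_2x2(tab)
    rows$female <- data.frame(
      variable = "Sex (women, %)",
      young = sprintf("%.1f", 100 * mean(yg$female)),
      old = sprintf("%.1f", 100 * mean(og$female)),
      statistic = round(cs$statistic, 2), p = cs$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Saccade parameter summary table
#'
#' Mean +/- SD of each saccade parameter per group x period x component
#' (1-decimal report rounding), with a per-cell Wilcoxon-Mann-Whitney
#' young-vs-old comparison — the layout of a descriptive task-effects
#' table.
#'
#' @param params tidy parameter table (all subjects).
#' @return data.frame with one row per parameter x component x period:
#'   formatted `young`, `old` cells, `Z`, `p`.
#' @export
params_summary_table <- function(params) {
  if (length(intersect(c("young", "old"), unique(params$group))) < 2) {
    stop("need both groups to summarise", call. = FALSE)
  }
  vars <- c(frequency = "Frequency (n/s)", mean_amplitude = "Mean amplitude (deg)",
            mean_velocity = "Mean velocity (deg/s)")
  rows <- list()
  for (v in names(vars)) {
    for (comp in c("H", "V")) {
      for (p in c("REST", "MAT", "VFT")) {
        sel <- params$component == comp & params$period == p
        yv <- params[[v]][sel & params$group == "young"]
        ov <- params[[v]][sel & params$group == "old"]
        if (!length(yv) || !length(ov)) {
          stop("empty group cell: ", paste(v, comp, p), call. = FALSE)
        }
        w <- wilcoxon_mann_whitney(yv[!is.na(yv)], ov[!is.na(ov)], exact = FALSE)
        rows[[paste(v, comp, p)]] <- data.frame(
          parameter = vars[[v]], component = comp, period = p,
          young = .fmt_pm(mean(yv, na.rm = TRUE), stats::sd(yv, na.rm = TRUE)),
          old = .fmt_pm(mean(ov, na.rm = TRUE), stats::sd(ov, na.rm = TRUE)),
          Z = round(w$statistic, 2), p = w$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Factorial effects table across all saccade parameters
#'
#' Runs [art_anova()] for each of the six response x component analyses
#' (frequency, mean amplitude, mean velocity; horizontal and vertical) and
#' collects the age-group, task and interaction effects with F, p and
#' partial omega squared, plus a compact post hoc summary (which periods
#' differ at alpha). No correction is applied across the six analyses;
#' treat the family-wise error accordingly.
#'
#' @param params tidy parameter table.
#' @param alpha significance level for the post hoc summary column.
#' @return list with `table` (one row per response x component) and
#'   `posthoc` (all period contrasts, all analyses), and `fits` (the six
#'   [art_anova()] objects, named like `frequency_H`).
#' @export
saccade_effects_table <- function(params, alpha = 0.05) {
  rows <- list(); ph <- list(); fits <- list()
  for (v in c("frequency", "mean_amplitude", "mean_velocity")) {
    for (comp in c("H", "V")) {
      fit <- art_anova(params, v, component = comp)
      fits[[paste(v, comp, sep = "_")]] <- fit
      eff <- fit$table[fit$table$effect %in% c("group", "period", "group:period"), ]
      sig <- fit$posthoc[fit$posthoc$p_adjusted < alpha, , drop = FALSE]
      rows[[paste(v, comp)]] <- data.frame(
        response = v, component = comp,
        age_F = eff$F[eff$effect == "group"],
        age_p = eff$p[eff$effect == "group"],
        age_omega_sq = eff$partial_omega_sq[eff$effect == "group"],
        task_F = eff$F[eff$effect == "period"],
        task_p = eff$p[eff$effect == "period"],
        task_omega_sq = eff$partial_omega_sq[eff$effect == "period"],
        int_F = eff$F[eff$effect == "group:period"],
        int_p = eff$p[eff$effect == "group:period"],
        int_omega_sq = eff$partial_omega_sq[eff$effect == "group:period"],
        posthoc = if (nrow(sig)) paste(sig$contrast, collapse = "; ") else "-",
        n_subjects = fit$n_subjects,
        stringsAsFactors = FALSE)
      p2 <- fit$posthoc
      p2$response <- v; p2$component <- comp
      ph[[paste(v, comp)]] <- p2
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       posthoc = do.call(rbind, c(ph, list(make.row.names = FALSE))),
       fits = fits)
}
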