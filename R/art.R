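#' Aligned Rank Transform for a two-factor mixed design
#'
#' Prepares a response for nonparametric factorial ANOVA. For each fixed
#' effect (group, period, group x period) the response is *aligned* — every
#' estimated effect except the one of interest is subtracted — and the
#' aligned values are converted to midranks. The classical mixed-design
#' ANOVA is then run once per effect, on that effect's rank column, and
#' only that effect's test is read from each run.
#'
#' Effect estimates use observed-margin (weighted) cell means, which keeps
#' the decomposition orthogonal under the proportional cell frequencies of
#' a complete within-subject design with unequal group sizes, and gives the
#' defining ART properties: every aligned column sums to zero, and an ANOVA
#' of the aligned (unranked) response for effect `e` shows exactly zero
#' effect for every other factor.
#'
#' @param data data.frame with columns `subject_id`, `group`, `period`, and
#'   the response; one row per subject x period (complete cases only — use
#'   [art_anova()] for listwise handling).
#' @param response name of the response column.
#' @return A data.frame of class `art_dataset`: the input columns plus
#'   `aligned_group`, `rank_group`, `aligned_period`, `rank_period`,
#'   `aligned_interaction`, `rank_interaction`.
#' @export
align_rank_transform <- function(data, response) {
  need <- c("subject_id", "group", "period", response)
  stopifnot(all(need %in% names(data)))
  y <- data[[response]]
  if (anyNA(y)) stop("align_rank_transform requires complete responses",
                     call. = FALSE)
  tab <- table(data$subject_id, data$period)
  if (any(tab != 1L)) {
    stop("each subject must contribute exactly one observation per period",
         call. = FALSE)
  }
  grand <- mean(y)
  g_mean <- stats::ave(y, data$group)
  p_mean <- stats::ave(y, data$period)
  cell <- stats::ave(y, data$group, data$period)
  resid <- y - cell
  est <- list(group = g_mean - grand,
              period = p_mean - grand,
              interaction = cell - g_mean - p_mean + grand)
  out <- data
  for (e in names(est)) {
    aligned <- resid + est[[e]]
    out[[paste0("aligned_", e)]] <- aligned
    out[[paste0("rank_", e)]] <- rank(aligned)
  }
  class(out) <- c("art_dataset", "data.frame")
  out
}

#' Classical mixed-design repeated-measures ANOVA
#'
#' Two-way ANOVA with one between-subjects factor (group) and one
#' within-subjects factor (period), computed from cell and marginal means:
#' the group effect is tested against subjects-within-group variation, the
#' period and interaction effects against the period x subject-within-group
#' residual. No sphericity correction is applied by default (the classical
#' F with `(b-1, (N-a)(b-1))` degrees of freedom); Greenhouse-Geisser
#' correction of the within-subject p-values is available.
#'
#' Partial omega squared per effect is
#' `(SS_eff - df_eff * MS_err) / (SS_eff + (N_str - df_eff) * MS_err)`,
#' with `N_str` the number of observations in the effect's stratum (the N
#' subject means for the between stratum; the `N * (b - 1)` within-subject
#' contrasts for the within stratum). Negative values are clipped to 0 in
#' the `partial_omega_sq` column; `partial_omega_sq_raw` keeps the
#' unclipped estimate.
#'
#' @param data data.frame with `subject_id`, `group`, `period` and the
#'   response; complete, one observation per subject x period.
#' @param response response column name.
#' @param gg logical: apply Greenhouse-Geisser epsilon to within-subject
#'   p-values.
#' @return A data.frame of class `anova_table` with rows `group`,
#'   `subjects_within_group` (error), `period`, `group:period`,
#'   `period_x_subjects` (error) and columns `SS`, `df`, `MS`, `F`, `p`,
#'   `partial_omega_sq`, `partial_omega_sq_raw`.
#' @export
mixed_rmanova <- function(data, response, gg = FALSE) {
  need <- c("subject_id", "group", "period", response)
  stopifnot(all(need %in% names(data)))
  y <- data[[response]]
  if (anyNA(y)) stop("mixed_rmanova requires complete responses", call. = FALSE)
  subj <- as.character(data$subject_id)
  grp <- as.character(data$group)
  per <- as.character(data$period)
  if (any(table(subj, per) != 1L)) {
    stop("each subject must contribute exactly one observation per period",
         call. = FALSE)
  }
  a <- length(unique(grp)); b <- length(unique(per))
  subj_grp <- tapply(grp, subj, function(z) z[1L])
  N <- length(subj_grp)
  n_i <- table(subj_grp)
  if (any(n_i < 2)) stop("need at least 2 subjects per group", call. = FALSE)

  grand <- mean(y)
  subj_mean <- tapply(y, subj, mean)
  group_mean <- tapply(y, grp, mean)
  period_mean <- tapply(y, per, mean)
  cell_mean <- tapply(y, list(grp, per), mean)

  ss_group <- b * sum(n_i * (group_mean[names(n_i)] - grand)^2)
  ss_subj <- b * sum((subj_mean - group_mean[subj_grp])^2)
  ss_period <- N * sum((period_mean - grand)^2)
  int_dev <- sweep(sweep(cell_mean, 1, group_mean[rownames(cell_mean)]),
                   2, period_mean[colnames(cell_mean)]) + grand
  ss_int <- sum(as.numeric(n_i[rownames(cell_mean)]) * int_dev^2)
  fitted_w <- subj_mean[subj] + cell_mean[cbind(grp, per)] - group_mean[grp]
  ss_werr <- sum((y - fitted_w)^2)

  df <- c(group = a - 1, subj = N - a, period = b - 1,
          int = (a - 1) * (b - 1), werr = (N - a) * (b - 1))
  ms <- c(ss_group, ss_subj, ss_period, ss_int, ss_werr) / df
  names(ms) <- names(df)

  f_group <- ms[["group"]] / ms[["subj"]]
  f_period <- ms[["period"]] / ms[["werr"]]
  f_int <- ms[["int"]] / ms[["werr"]]
  eps <- 1
  if (gg && b > 2) eps <- .gg_epsilon(data, response)
  p_group <- stats::pf(f_group, df[["group"]], df[["subj"]], lower.tail = FALSE)
  p_period <- stats::pf(f_period, eps * df[["period"]], eps * df[["werr"]],
                        lower.tail = FALSE)
  p_int <- stats::pf(f_int, eps * df[["int"]], eps * df[["werr"]],
                     lower.tail = FALSE)

  omega <- function(ss_eff, df_eff, ms_err, n_str) {
    (ss_eff - df_eff * ms_err) / (ss_eff + (n_str - df_eff) * ms_err)
  }
  om <- c(omega(ss_group, df[["group"]], ms[["subj"]], N),
          omega(ss_period, df[["period"]], ms[["werr"]], N * (b - 1)),
          omega(ss_int, df[["int"]], ms[["werr"]], N * (b - 1)))

  out <- data.frame(
    effect = c("group", "subjects_within_group", "period", "group:period",
               "period_x_subjects"),
    SS = c(ss_group, ss_subj, ss_period, ss_int, ss_werr),
    df = df[c("group", "subj", "period", "int", "werr")],
    MS = ms[c("group", "subj", "period", "int", "werr")],
    F = c(f_group, NA, f_period, f_int, NA),
    p = c(p_group, NA, p_period, p_int, NA),
    partial_omega_sq_raw = c(om[1], NA, om[2], om[3], NA),
    stringsAsFactors = FALSE)
  out$partial_omega_sq <- pmax(out$partial_omega_sq_raw, 0)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
.gg_epsilon <- function(data, response) {
  wide <- stats::reshape(data[, c("subject_id", "period", response)],
                         idvar = "subject_id", timevar = "period",
                         direction = "wide")
  m <- as.matrix(wide[, -1])
  S <- stats::cov(m)
  k <- ncol(S)
  dbar <- mean(diag(S)); mbar <- mean(S)
  num <- (k * (dbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2)
  min(1, max(1 / (k - 1), num / den))
}

#' Nonparametric factorial analysis of one saccade parameter
#'
#' The full rank-based analysis for one response: listwise exclusion of
#' subjects with any missing cell, Aligned Rank Transform, one
#' mixed-design ANOVA per effect on that effect's rank column, and Tukey
#' post hoc contrasts between periods on the period rank column.
#'
#' @param params tidy parameter table (rows from [aggregate_params()], or
#'   any data.frame with `subject_id`, `group`, `period` and the response).
#' @param response response column name (e.g. `"frequency"`).
#' @param component optional: filter `params` to one component first.
#' @return list of class `art_anova` with `table` (the three effect rows
#'   with their error strata), `posthoc` (period contrasts), `art` (the
#'   [align_rank_transform()] dataset), `n_subjects`, `n_excluded`.
#' @export
art_anova <- function(params, response, component = NULL) {
  d <- params
  if (!is.null(component)) d <- d[d$component == component, , drop = FALSE]
  d <- d[, c("subject_id", "group", "period", response)]
  # listwise exclusion of subjects with any missing cell
  bad <- unique(d$subject_id[is.na(d[[response]])])
  n_excluded <- length(bad)
  d <- d[!(d$subject_id %in% bad), , drop = FALSE]
  art <- align_rank_transform(d, response)
  rows <- list(); err_rows <- list()
  for (e in c("group", "period", "interaction")) {
    rk <- paste0("rank_", e)
    tab <- mixed_rmanova(art, rk)
    eff_name <- c(group = "group", period = "period",
                  interaction = "group:period")[[e]]
    rows[[e]] <- tab[tab$effect == eff_name, ]
    err_name <- if (e == "group") "subjects_within_group" else "period_x_subjects"
    er <- tab[tab$effect == err_name, ]
    er$effect <- paste0(err_name, " [", eff_name, "]")
    err_rows[[e]] <- er
  }
  table <- do.call(rbind, c(rows, err_rows))
  rownames(table) <- NULL
  class(table) <- c("anova_table", "data.frame")
  period_tab <- mixed_rmanova(art, "rank_period")
  posthoc <- tukey_posthoc(art, period_tab)
  structure(list(table = table, posthoc = posthoc, art = art,
                 n_subjects = length(unique(d$subject_id)),
                 n_excluded = n_excluded, response = response,
                 component = component),
            class = "art_anova")
}

#' Tukey post hoc contrasts between periods
#'
#' All pairwise period comparisons on the rank scale of the period-aligned
#' column, using the studentized range distribution with the
#' within-subject error mean square and degrees of freedom.
#'
#' @param art an `art_dataset` from [align_rank_transform()].
#' @param period_tab the [mixed_rmanova()] table fitted on `rank_period`
#'   (refitted internally if omitted).
#' @return data.frame with one row per period pair: `contrast`, `estimate`
#'   (rank-scale difference), `p_unadjusted`, `p_adjusted`.
#' @export
tukey_posthoc <- function(art, period_tab = NULL) {
  stopifnot(inherits(art, "art_dataset"))
  if (is.null(period_tab)) period_tab <- mixed_rmanova(art, "rank_period")
  ms_err <- period_tab$MS[period_tab$effect == "period_x_subjects"]
  df_err <- period_tab$df[period_tab$effect == "period_x_subjects"]
  means <- tapply(art$rank_period, art$period, mean)
  periods <- names(means)
  N <- length(unique(art$subject_id))
  k <- length(periods)
  pairs <- utils::combn(periods, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    diff <- means[[p1]] - means[[p2]]
    se1 <- sqrt(ms_err / N)
    q <- abs(diff) / se1
    tstat <- abs(diff) / (se1 * sqrt(2))
    data.frame(contrast = paste(p1, "-", p2), estimate = diff,
               p_unadjusted = 2 * stats::pt(tstat, df_err, lower.tail = FALSE),
               p_adjusted = stats::ptukey(q, nmeans = k, df = df_err,
                                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.art_anova <- function(x, ...) {
  cat(sprintf("ART mixed ANOVA on %s%s (%d subjects, %d excluded)\n",
              x$response,
              if (!is.null(x$component)) paste0(" [", x$component, "]") else "",
              x$n_subjects, x$n_excluded))
  eff <- x$table[x$table$effect %in% c("group", "period", "group:period"), ]
  print(data.frame(effect = eff$effect, F = round(eff$F, 2),
                   df1 = eff$df,
                   p = signif(eff$p, 3),
                   omega_sq_p = round(eff$partial_omega_sq, 2)), row.names = FALSE)
  invisible(x)
}
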