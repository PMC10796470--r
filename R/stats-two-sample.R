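#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Rank-sum comparison of two independent samples, reported as a Z
#' statistic (normal approximation with midranks and tie-corrected
#' variance, no continuity correction — the convention used when such
#' comparisons are tabulated as "Z"). The p-value is exact (from the null
#' distribution of the Mann-Whitney U over all labelings) when the pooled
#' sample is free of ties and small; otherwise the normal approximation is
#' used.
#'
#' @param x,y numeric samples.
#' @param exact logical or `NULL` (auto: exact iff no ties and
#'   `length(x) + length(y) <= 50`).
#' @return list with `statistic_name = "Z"`, `statistic`, `p_value`, `U`,
#'   and `exact` (whether the exact p was used).
#' @export
wilcoxon_mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  N <- n1 + n2
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_sizes <- table(r)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic_name = "Z", statistic = 0, p_value = 1, U = U,
                exact = FALSE))
  }
  Z <- (U - mu) / sqrt(sigma2)
  has_ties <- tie_term > 0
  if (is.null(exact)) exact <- !has_ties && N <= 50
  exact <- exact && !has_ties
  if (exact) {
    lower <- stats::pwilcox(U, n1, n2)
    upper <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(statistic_name = "Z", statistic = Z, p_value = p, U = U, exact = exact)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's statistic without Yates continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic_name = "chi_square"`, `statistic`,
#'   `p_value`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: zero marginal", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic_name = "chi_square", statistic = unname(res$statistic),
       p_value = res$p.value, df = unname(res$parameter))
}

#' Normality diagnostics
#'
#' Shapiro-Wilk W and p, together with the adjusted Fisher-Pearson sample
#' skewness and excess kurtosis (the conventions of mainstream statistics
#' packages), used to judge whether a response needs the rank transform
#' before factorial analysis.
#'
#' @param values numeric vector, `n >= 3`, non-constant.
#' @return list with `shapiro_W`, `shapiro_p`, `skew`, `kurtosis` (excess).
#' @export
normality_report <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant sample", call. = FALSE)
  sw <- stats::shapiro.test(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  g1 <- m3 / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  kurt <- if (n > 3) {
    (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (m4 / m2^2 - 3) + 6)
  } else NA_real_
  list(shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
       skew = skew, kurtosis = kurt)
}
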