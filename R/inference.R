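# Welch tests, p-values, multiplicity adjustment and detection power on
# cell type-specific expression estimates.

#' Welch two-sample statistic on regression coefficients
#'
#' Compares two cell type-specific expression estimates using their
#' regression-based variance estimates (diagonal of `s2 (X'X)^{-1}`), which
#' are not assumed equal across groups. Degrees of freedom follow
#' Welch-Satterthwaite with per-group degrees of freedom `M_g - P`.
#'
#' Both variances zero is the noise-free limit: the statistic is reported as
#' `0` when the estimates agree and signed infinity when they differ (the
#' difference is then exact), with degrees of freedom `df1 + df2`.
#'
#' All arguments are vectorised.
#'
#' @param b1,b2 coefficient estimates (cases, controls).
#' @param var1,var2 their estimated variances (`>= 0`).
#' @param df1,df2 per-group residual degrees of freedom (`>= 1`).
#' @return A list with vectors `t` and `df`.
#' @export
welch_statistic <- function(b1, var1, df1, b2, var2, df2) {
  if (any(var1 < 0) || any(var2 < 0)) stop("variances must be non-negative")
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  v <- var1 + var2
  tt <- ifelse(v > 0, (b1 - b2) / sqrt(v),
               ifelse(b1 == b2, 0, Inf * sign(b1 - b2)))
  df <- ifelse(v > 0, v^2 / (var1^2 / df1 + var2^2 / df2), df1 + df2)
  list(t = tt, df = df)
}

#' Two-sided p-value of a t-statistic
#'
#' `p = 2 * P(T_df > |t|)` under the central t distribution.
#'
#' @param t t-statistic(s); infinite values give `p = 0`.
#' @param df degrees of freedom (`>= 1`).
#' @return p-values in `[0, 1]`.
#' @export
t_p_value <- function(t, df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  ifelse(is.infinite(t), 0, 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' t-statistic-based detection power
#'
#' Per-gene sensitivity of the Welch test, read off the observed statistic:
#' with `t_crit` the two-sided critical value at level `alpha`, a
#' non-significant statistic (`|t| < t_crit`) has power reported as the
#' floor `alpha`; a significant one has power equal to the upper tail
#' probability of the central t distribution beyond the critical value,
#' `P(T_df > t_crit - |t|)` — the probability mass of the estimate's
#' sampling distribution on the rejection side. At the boundary
#' `|t| = t_crit` the power is exactly 0.5.
#'
#' @param t observed t-statistic(s).
#' @param df degrees of freedom (`>= 1`).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power values in `[alpha, 1]`.
#' @export
detection_power <- function(t, df, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  t_crit <- stats::qt(1 - alpha / 2, df)
  ifelse(abs(t) < t_crit, alpha,
         stats::pt(t_crit - abs(t), df, lower.tail = FALSE))
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni adjustment over the full gene x cell table (`min(1, p * N)`),
#' or no adjustment.
#'
#' @param p vector of p-values.
#' @param method `"bonferroni"` or `"none"`.
#' @param n number of tests (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = c("bonferroni", "none"), n = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method, n = n)
}
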