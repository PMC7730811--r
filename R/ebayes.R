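# Shared empirical-Bayes variance shrinkage for the region-level
# methylation test and the expression moderated t-test.
#
# Per-feature residual variances s_g^2 with d_g degrees of freedom are
# modelled as draws from a scaled inverse chi-square prior with
# hyperparameters (d0, s0^2). The hyperparameters are estimated by the
# method of moments on log s_g^2: for s^2 ~ s0^2 * chisq(d)/d,
#   E[log s^2] = log s0^2 + digamma(d/2) - log(d/2)
#   Var[log s^2] = trigamma(d/2),
# so the excess variance of the centred log variances over trigamma(d/2)
# identifies d0 through trigamma(d0/2), and the mean identifies s0^2.
# The posterior variance is the precision-weighted blend
#   s~^2 = (d0 s0^2 + d s^2) / (d0 + d), with d0 + d total df.

# Newton solve of trigamma(y) = x (decreasing, convex in 1/y)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-10) break
  }
  y
}

#' Empirical-Bayes squeezing of per-feature variances
#'
#' @param s2 per-feature residual variances.
#' @param df residual degrees of freedom (scalar or per-feature).
#' @param covariate optional per-feature covariate (e.g. mean log
#'   expression); when given, the prior log-variance is a lowess trend in
#'   the covariate instead of a constant (mean-variance trend).
#' @param d0 optional forced prior df (0 = no shrinkage, Inf = full
#'   shrinkage to the prior); estimated when NULL.
#' @param s02 optional forced prior variance (scalar or per-feature);
#'   estimated when NULL.
#' @return list with `var_post`, `df_prior` (d0), `var_prior` (s0^2, per
#'   feature if trended), `df_total`.
#' @export
squeeze_variances <- function(s2, df, covariate = NULL, d0 = NULL,
                              s02 = NULL) {
  n <- length(s2)
  df <- rep_len(df, n)
  ok <- is.finite(s2) & s2 > 0 & df > 0

  if (is.null(d0) || is.null(s02)) {
    if (sum(ok) < 2L) {
      warning("fewer than 2 usable variances; no shrinkage applied (d0 = 0)")
      est_d0 <- 0
      est_s02 <- rep(mean(s2[ok]), n)
    } else {
      z <- log(s2[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      if (is.null(covariate)) {
        emean <- rep(mean(e), n)
      } else {
        lo <- lowess(covariate[ok], e, f = 0.5)
        emean_ok <- approx(lo$x, lo$y, xout = covariate[ok], rule = 2)$y
        emean <- rep(mean(e), n)
        emean[ok] <- emean_ok
      }
      resid_var <- sum((e - emean[ok])^2) / (sum(ok) - 1L) -
        mean(trigamma(df[ok] / 2))
      if (is.finite(resid_var) && resid_var > 0) {
        est_d0 <- 2 * trigamma_inverse(resid_var)
        est_s02 <- exp(emean + digamma(est_d0 / 2) - log(est_d0 / 2))
      } else {
        est_d0 <- Inf
        est_s02 <- exp(emean)
      }
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s02)) s02 <- est_s02
  }
  s02 <- rep_len(s02, n)

  var_post <- if (is.infinite(d0)) {
    s02
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(var_post = var_post, df_prior = d0, var_prior = s02,
       df_total = d0 + df)
}

#' Two-group empirical-Bayes moderated t-test per feature
#'
#' Fits the per-feature two-group linear model (difference of group means),
#' squeezes the residual variances with [squeeze_variances()], and reports
#' the moderated t statistic, total degrees of freedom and two-sided
#' p-value. Missing values are dropped per feature; features with fewer
#' than `min_per_group` non-missing values in either group, or with zero
#' residual variance and no shrinkage target, are reported untested.
#'
#' @param x numeric matrix, features x samples.
#' @param group logical vector, TRUE = NEC (test is NEC minus non-NEC).
#' @param trend logical; model the prior variance as a function of the
#'   per-feature mean of `x` (mean-variance trend).
#' @param d0,s02 optional forced hyperparameters (see
#'   [squeeze_variances()]); used for the limit identities d0 = 0
#'   (ordinary t) and d0 = Inf (fixed-variance z).
#' @param min_per_group minimum non-missing values per group (default 2).
#' @return data.table `feature_id`, `delta` (mean difference, NEC minus
#'   control), `mean_value` (grand mean of non-missing values), `s2`, `df`,
#'   `t`, `df_total`, `p_value`, `tested`, `reason`; attributes `df_prior`
#'   and `var_prior` carry the estimated hyperparameters.
#' @export
eb_moderated_test <- function(x, group, trend = FALSE, d0 = NULL,
                              s02 = NULL, min_per_group = 2L) {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  group <- as.logical(group)
  ok1 <- !is.na(x[, group, drop = FALSE])
  ok0 <- !is.na(x[, !group, drop = FALSE])
  n1 <- rowSums(ok1); n0 <- rowSums(ok0)

  sum_or_zero <- function(m) { m[is.na(m)] <- 0; m }
  x1 <- sum_or_zero(x[, group, drop = FALSE])
  x0 <- sum_or_zero(x[, !group, drop = FALSE])
  mean1 <- rowSums(x1) / n1
  mean0 <- rowSums(x0) / n0
  delta <- mean1 - mean0
  grand <- (rowSums(x1) + rowSums(x0)) / (n1 + n0)

  ss1 <- rowSums((x1 - mean1 * ok1)^2 * ok1)
  ss0 <- rowSums((x0 - mean0 * ok0)^2 * ok0)
  df <- n1 + n0 - 2
  s2 <- ifelse(df > 0, (ss1 + ss0) / df, NA_real_)

  tested <- n1 >= min_per_group & n0 >= min_per_group & df > 0
  reason <- rep(NA_character_, nrow(x))
  reason[!tested] <- "fewer than min_per_group non-missing values in a group"

  if (sum(tested) < 2L && is.null(d0)) {
    warning("fewer than 2 testable features; using ordinary t (d0 = 0)")
    d0 <- 0
    s02 <- 1
  }

  sq <- squeeze_variances(ifelse(tested, s2, NA_real_), df,
                          covariate = if (trend) grand else NULL,
                          d0 = d0, s02 = s02)

  se <- sqrt(sq$var_post * (1 / n1 + 1 / n0))
  tstat <- delta / se
  df_total <- sq$df_total
  p <- if (is.infinite(sq$df_prior)) {
    2 * pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = df_total)
  }
  zero_var <- tested & !is.na(se) & se == 0
  p[zero_var & delta == 0] <- 1
  tested[zero_var & delta != 0] <- FALSE
  reason[zero_var & delta != 0] <- "zero variance"
  p[!tested] <- NA_real_

  out <- data.table(
    feature_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                 else rownames(x),
    delta = delta, mean_value = grand, s2 = s2, df = df,
    t = ifelse(tested, tstat, NA_real_),
    df_total = ifelse(rep(is.infinite(sq$df_prior), nrow(x)), Inf, df_total),
    p_value = p, tested = tested, reason = reason
  )
  setattr(out, "df_prior", sq$df_prior)
  setattr(out, "var_prior", sq$var_prior)
  out[]
}
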