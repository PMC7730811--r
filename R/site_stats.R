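# Per-CpG differential methylation between NEC and non-NEC samples.
#
# The model is a binomial logistic regression of the methylation proportion
# on group with weights equal to coverage. With a single binary covariate
# the MLE has a closed form -- the fitted probability in each group is the
# coverage-weighted pooled rate -- so the whole table is fit vectorized.
# The group effect is tested by quasi-likelihood analysis of deviance in
# the McCullagh-Nelder style: the likelihood-ratio chi-square comparing
# the two-group fit against the pooled (null) fit is scaled by a
# dispersion estimate phi = Pearson X^2 / (n - 2), floored at 1, and
# referred to chi-square(1). The deviance is finite at boundary rates
# (groups with pooled rate exactly 0 or 1), so complete separation needs
# no special handling.

#' Differential methylation test for every CpG site
#'
#' @param ms a `meth_set`.
#' @param group optional logical/character vector marking the NEC samples;
#'   defaults to `ms$samples$condition == "NEC"`.
#' @param min_samples minimum samples with coverage > 0 required per group
#'   (default 2); sites below it are reported as untested with a reason.
#' @return data.table with one row per site: `cpg_id`, `chrom`, `pos`,
#'   `p_value`, `meth_diff` (percentage points, NEC minus non-NEC),
#'   `mean_nec`, `mean_ctrl` (coverage-weighted pooled rates),
#'   `n_samples_used`, `dispersion_estimate`, `tested`, `reason`.
#'   `q_value` is added by [call_dms()] / [adjust_pvalues()].
#' @export
dms_test <- function(ms, group = NULL, min_samples = 2L) {
  if (is.null(group)) group <- ms$samples$condition == "NEC"
  if (!is.logical(group)) group <- group == "NEC"
  stopifnot(length(group) == ncol(ms$meth))

  res <- .dms_core(ms$meth, ms$cov, group, min_samples)
  cbind(ms$sites[, .(cpg_id, chrom, pos)], res)
}

# m*log(m/(t*p)) + u*log(u/(t*(1-p))) with the 0*log0 = 0 convention
.xlogx_dev <- function(m, t, p) {
  u <- t - m
  out <- numeric(length(m))
  pos <- m > 0
  out[pos] <- m[pos] * log(m[pos] / (t[pos] * p[pos]))
  posu <- u > 0
  out[posu] <- out[posu] + u[posu] * log(u[posu] / (t[posu] * (1 - p[posu])))
  out
}

.dms_core <- function(meth, cov, group, min_samples = 2L) {
  has_cov <- cov > 0
  n1 <- rowSums(has_cov[, group, drop = FALSE])
  n0 <- rowSums(has_cov[, !group, drop = FALSE])
  n_used <- n1 + n0

  M1 <- rowSums(meth[, group, drop = FALSE])
  T1 <- rowSums(cov[, group, drop = FALSE])
  M0 <- rowSums(meth[, !group, drop = FALSE])
  T0 <- rowSums(cov[, !group, drop = FALSE])

  tested <- n1 >= min_samples & n0 >= min_samples
  reason <- rep(NA_character_, length(n1))
  reason[!tested] <- "fewer than min_samples covered samples in a group"

  p1 <- ifelse(T1 > 0, M1 / T1, NA_real_)
  p0 <- ifelse(T0 > 0, M0 / T0, NA_real_)
  pp <- ifelse(T1 + T0 > 0, (M1 + M0) / (T1 + T0), NA_real_)

  # likelihood-ratio chi-square: two-group fit vs pooled fit
  G2 <- 2 * (.xlogx_dev(M1, T1, pp) + .xlogx_dev(M0, T0, pp))

  # Pearson dispersion against the two-group fitted rates; samples in a
  # boundary group (fitted rate 0 or 1) have zero-variance fits and
  # contribute nothing
  pg <- matrix(NA_real_, nrow(meth), ncol(meth))
  pg[, group] <- p1
  pg[, !group] <- p0
  den <- cov * pg * (1 - pg)
  num <- (meth - cov * pg)^2
  term <- num / den
  term[!has_cov | den == 0 | is.na(den)] <- 0
  X2 <- rowSums(term)
  phi <- pmax(1, X2 / pmax(n_used - 2, 1))

  p_value <- pchisq(G2 / phi, df = 1, lower.tail = FALSE)
  p_value[tested & G2 == 0] <- 1
  p_value[!tested] <- NA_real_

  data.table(
    p_value = p_value,
    meth_diff = 100 * (p1 - p0),
    mean_nec = p1, mean_ctrl = p0,
    n_samples_used = as.integer(n_used),
    dispersion_estimate = ifelse(tested, phi, NA_real_),
    tested = tested, reason = reason
  )
}

#' Differential methylation test for a single CpG site
#'
#' Convenience wrapper around the same closed-form quasi-binomial machinery
#' as [dms_test()], for one site given per-sample counts.
#'
#' @param count_m methylated counts per sample.
#' @param count_u unmethylated counts per sample.
#' @param group logical vector, TRUE = NEC.
#' @return one-row data.table as in [dms_test()] (without coordinates).
#' @export
site_test <- function(count_m, count_u, group) {
  stopifnot(length(count_m) == length(count_u),
            length(count_m) == length(group))
  .dms_core(matrix(count_m, nrow = 1L),
            matrix(count_m + count_u, nrow = 1L),
            as.logical(group))
}

#' Benjamini-Hochberg adjustment with realized p-threshold
#'
#' Applies the BH step-up procedure (via [stats::p.adjust]), excluding
#' non-finite p-values, and reports the realized p-value threshold
#' corresponding to each requested FDR level: the largest raw p among
#' features with q <= alpha. This is the quantity that lets a q < 0.05 call
#' set be described by an equivalent raw-p cutoff.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA/NaN excluded).
#' @param method adjustment method passed to [stats::p.adjust].
#' @param alpha FDR level(s) for the realized threshold report.
#' @return list with `q` (same length as `p`, NA where p was not finite),
#'   `p_threshold` (named numeric per alpha; NA if nothing passes),
#'   `n_excluded`.
#' @export
adjust_pvalues <- function(p, method = "BH", alpha = 0.05) {
  ok <- is.finite(p)
  if (any(ok & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = method)
  thr <- vapply(alpha, function(a) {
    pass <- ok & q <= a
    if (any(pass)) max(p[pass]) else NA_real_
  }, numeric(1))
  names(thr) <- paste0("alpha_", alpha)
  list(q = q, p_threshold = thr, n_excluded = sum(!ok))
}

#' Call differentially methylated sites
#'
#' Filters a [dms_test()] table at an FDR threshold and a minimum absolute
#' methylation difference, sorted by q then p.
#'
#' @param results data.table from [dms_test()].
#' @param q_threshold FDR cutoff (default 0.05).
#' @param min_diff minimum |meth_diff| in percentage points (default 0).
#' @param method multiple-testing method (default BH).
#' @return data.table of called DMSs with a `q_value` column; attribute
#'   `p_threshold` carries the realized raw-p cutoff at `q_threshold`.
#' @export
call_dms <- function(results, q_threshold = 0.05, min_diff = 0,
                     method = "BH") {
  results <- as.data.table(results)
  if (nrow(results) == 0L) {
    out <- copy(results)
    out[, q_value := numeric(0)]
    return(out)
  }
  adj <- adjust_pvalues(results$p_value, method = method,
                        alpha = q_threshold)
  out <- copy(results)
  out[, q_value := adj$q]
  out <- out[!is.na(q_value) & q_value < q_threshold &
               abs(meth_diff) >= min_diff]
  setorder(out, q_value, p_value, na.last = TRUE)
  setattr(out, "p_threshold", adj$p_threshold)
  out[]
}
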