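# Methylation-expression integration: per-gene Pearson correlation between
# promoter (or gene-body) methylation and log2 normalized expression across
# samples, BH adjustment, the conjunctive gene-selection rule, hyper/hypo x
# up/down directionality tables, and the cross-tissue correlation of
# correlations.

#' Per-gene Pearson correlation between methylation and expression
#'
#' Row-wise Pearson correlation between paired per-sample methylation rates
#' and log2 normalized expression, with the t-test on n - 2 degrees of
#' freedom. Pairs with a missing value in either variable are dropped per
#' gene; genes with fewer than 3 complete pairs or zero variance in either
#' variable are excluded with a reason.
#'
#' @param meth gene x sample matrix of methylation rates.
#' @param expr gene x sample matrix of log2 normalized expression
#'   (matching rows and columns).
#' @return data.table `gene_id`, `r`, `t_stat`, `p_corr`, `n_pairs`,
#'   `tested`, `reason`.
#' @export
gene_correlations <- function(meth, expr) {
  stopifnot(all(dim(meth) == dim(expr)))
  n_genes <- nrow(meth)
  r <- t_stat <- p <- rep(NA_real_, n_genes)
  n_pairs <- integer(n_genes)
  reason <- rep(NA_character_, n_genes)
  for (i in seq_len(n_genes)) {
    ok <- !is.na(meth[i, ]) & !is.na(expr[i, ])
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] < 3L) { reason[i] <- "fewer than 3 paired samples"; next }
    x <- meth[i, ok]; y <- expr[i, ok]
    if (var(x) == 0 || var(y) == 0) { reason[i] <- "zero variance"; next }
    r[i] <- cor(x, y)
    if (abs(r[i]) < 1) {
      t_stat[i] <- r[i] * sqrt(n_pairs[i] - 2L) / sqrt(1 - r[i]^2)
      p[i] <- 2 * pt(-abs(t_stat[i]), df = n_pairs[i] - 2L)
    } else {
      t_stat[i] <- sign(r[i]) * Inf
      p[i] <- 0
    }
  }
  data.table(
    gene_id = if (is.null(rownames(meth))) as.character(seq_len(n_genes))
              else rownames(meth),
    r = r, t_stat = t_stat, p_corr = p, n_pairs = n_pairs,
    tested = !is.na(r), reason = reason
  )
}

#' Build per-gene integration records for one tissue
#'
#' Joins the region-level methylation statistics ([region_test()]) with the
#' per-gene methylation-expression correlations ([gene_correlations()]),
#' BH-adjusts the correlation p-values, and attaches methylation and
#' expression directions.
#'
#' @param region_res [region_test()] table (promoter or gene body).
#' @param corr [gene_correlations()] table for the same genes.
#' @param de optional [de_test()] table contributing `expr_direction`.
#' @param region_type label (`"promoter"` or `"gene_body"`).
#' @return data.table of integration records: `gene_id`, `region_type`,
#'   `r`, `t_stat`, `p_corr`, `p_corr_adj`, `delta_rate`, `delta_logit`,
#'   `p_meth`, `meth_direction` (`hyper`/`hypo`), `expr_direction`.
#' @export
integration_records <- function(region_res, corr, de = NULL,
                                region_type = "promoter") {
  rec <- merge(
    as.data.table(region_res)[, .(gene_id = region_id, delta_rate,
                                  delta_logit, p_meth = p_value)],
    as.data.table(corr)[, .(gene_id, r, t_stat, p_corr, n_pairs)],
    by = "gene_id"
  )
  rec[, p_corr_adj := adjust_pvalues(p_corr)$q]
  rec[, region_type := region_type]
  rec[, meth_direction := ifelse(delta_rate > 0, "hyper",
                                 ifelse(delta_rate < 0, "hypo",
                                        NA_character_))]
  if (!is.null(de)) {
    rec <- merge(rec,
                 as.data.table(de)[, .(gene_id, expr_direction = direction,
                                       de_significant = significant)],
                 by = "gene_id", all.x = TRUE)
  } else {
    rec[, `:=`(expr_direction = NA_character_, de_significant = NA)]
  }
  rec[]
}

#' Select genes whose expression tracks their methylation
#'
#' Conjunctive criteria on the integration records: (1) region-level
#' empirical-Bayes p `<= p_meth_max`; (2) absolute logit-scale methylation
#' difference `>= min_delta_logit`; (3) BH-adjusted correlation p
#' `<= p_corr_adj_max`. A stricter nested tier additionally requires the
#' adjusted correlation p `<= tier2_adj_max`.
#'
#' @param records [integration_records()] table.
#' @param p_meth_max criterion 1 threshold (default 0.05).
#' @param min_delta_logit criterion 2 threshold (default 1).
#' @param p_corr_adj_max criterion 3 threshold (default 0.1).
#' @param tier2_adj_max nested stricter tier (default 0.05).
#' @return the records with logical columns `selected` and
#'   `selected_strict` (`selected_strict` implies `selected`).
#' @export
select_genes <- function(records, p_meth_max = 0.05, min_delta_logit = 1,
                         p_corr_adj_max = 0.1, tier2_adj_max = 0.05) {
  rec <- as.data.table(records)
  rec[, selected := !is.na(p_meth) & p_meth <= p_meth_max &
        !is.na(delta_logit) & abs(delta_logit) >= min_delta_logit &
        !is.na(p_corr_adj) & p_corr_adj <= p_corr_adj_max]
  rec[, selected_strict := selected & p_corr_adj <= tier2_adj_max]
  rec[]
}

#' Directionality table of methylation versus expression changes
#'
#' Cross-tabulates methylation direction (hyper/hypo) against expression
#' direction (up/down) over genes carrying both, with row fractions and
#' the summary fractions used to describe promoter hypermethylation of
#' down-regulated genes.
#'
#' @param records table with `meth_direction` and `expr_direction`
#'   (typically [integration_records()] filtered to DE genes).
#' @return list: `table` (counts + row fractions by expression direction),
#'   `n_total`, `n_down`, `pct_down` (share of down-regulated genes),
#'   `pct_hyper_down`, `pct_hyper_up` (share hypermethylated within each).
#' @export
directionality_summary <- function(records) {
  rec <- as.data.table(records)[!is.na(meth_direction) &
                                  !is.na(expr_direction)]
  if (nrow(rec) == 0L) {
    return(list(table = data.table(), n_total = 0L, n_down = 0L,
                pct_down = NA_real_, pct_hyper_down = NA_real_,
                pct_hyper_up = NA_real_))
  }
  tab <- rec[, .N, by = .(expr_direction, meth_direction)]
  tab[, row_total := sum(N), by = expr_direction]
  tab[, row_fraction := N / row_total]
  n_total <- nrow(rec)
  n_down <- rec[expr_direction == "down", .N]
  n_up <- rec[expr_direction == "up", .N]
  hyper_down <- rec[expr_direction == "down" & meth_direction == "hyper", .N]
  hyper_up <- rec[expr_direction == "up" & meth_direction == "hyper", .N]
  list(table = tab[],
       n_total = n_total, n_down = n_down,
       pct_down = 100 * n_down / n_total,
       pct_hyper_down = if (n_down > 0) 100 * hyper_down / n_down else NA_real_,
       pct_hyper_up = if (n_up > 0) 100 * hyper_up / n_up else NA_real_)
}

#' Cross-tissue correlation of correlations
#'
#' Pearson correlation between the per-gene methylation-expression
#' correlation coefficients of two tissues (genes present and tested in
#' both), with the t-test p-value.
#'
#' @param records_x,records_y [integration_records()] (or
#'   [gene_correlations()]) tables for the two tissues.
#' @param region_type optional filter when records carry `region_type`.
#' @return list `r_cc`, `t_stat`, `p_value`, `n_genes`.
#' @export
correlation_of_correlations <- function(records_x, records_y,
                                        region_type = NULL) {
  fx <- as.data.table(records_x); fy <- as.data.table(records_y)
  if (!is.null(region_type)) {
    if ("region_type" %in% names(fx)) fx <- fx[fx$region_type == region_type]
    if ("region_type" %in% names(fy)) fy <- fy[fy$region_type == region_type]
  }
  m <- merge(fx[!is.na(r), .(gene_id, r_x = r)],
             fy[!is.na(r), .(gene_id, r_y = r)], by = "gene_id")
  if (nrow(m) < 3L) stop("fewer than 3 shared genes with correlations")
  r_cc <- cor(m$r_x, m$r_y)
  n <- nrow(m)
  t_stat <- r_cc * sqrt(n - 2) / sqrt(max(1 - r_cc^2, .Machine$double.eps))
  list(r_cc = r_cc, t_stat = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = n - 2), n_genes = n)
}

#' Correlation density stratified by methylation difference
#'
#' Splits the per-gene correlations into genes with a large methylation
#' difference (|delta_rate| > `delta_threshold`) and the rest, and returns
#' binned densities of r together with the mean correlation per stratum.
#'
#' @param records [integration_records()] table (needs `r`, `delta_rate`).
#' @param delta_threshold rate-difference split (default 0.2).
#' @param n_bins histogram bins over \[-1, 1\] (default 40).
#' @return list `density` (data.table `bin_mid`, `density_high`,
#'   `density_low`), `mean_r_high`, `mean_r_low`, `n_high`, `n_low`,
#'   `note` (set when a stratum is empty and its density omitted).
#' @export
correlation_density <- function(records, delta_threshold = 0.2,
                                n_bins = 40L) {
  rec <- as.data.table(records)[!is.na(r) & !is.na(delta_rate)]
  hi <- rec[abs(delta_rate) > delta_threshold, r]
  lo <- rec[abs(delta_rate) <= delta_threshold, r]
  brk <- seq(-1, 1, length.out = n_bins + 1L)
  dens <- function(x) {
    if (length(x) == 0L) return(rep(NA_real_, n_bins))
    cnt <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE),
                         n_bins), nbins = n_bins)
    cnt / length(x) / diff(brk)
  }
  note <- NA_character_
  if (length(hi) == 0L) note <- "high-delta stratum empty; density omitted"
  if (length(lo) == 0L) note <- "low-delta stratum empty; density omitted"
  list(density = data.table(bin_mid = (brk[-1] + brk[-length(brk)]) / 2,
                            density_high = dens(hi), density_low = dens(lo)),
       mean_r_high = if (length(hi)) mean(hi) else NA_real_,
       mean_r_low = if (length(lo)) mean(lo) else NA_real_,
       n_high = length(hi), n_low = length(lo), note = note)
}
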