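# RNA-seq normalization, gene filtering and differential expression.
# Counts-per-million feed the abundance filter and the moderated t-test
# (on log2 CPM with a pseudocount); median-of-ratios size factors are the
# normalization used for the methylation-expression integration.

#' Counts-per-million normalization
#'
#' `cpm_gj = counts_gj / libsize_j * 1e6` with `libsize_j` the column sum.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return CPM matrix (columns sum to 1e6 when the library is non-empty).
#' @export
cpm_normalize <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0]
    stop("zero library size for sample(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' Per-sample size factor `s_j = median_g (counts_gj / geomean_g)` over
#' reference genes (those with a strictly positive geometric mean across
#' samples, i.e. no zero count).
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of size factors.
#' @export
median_of_ratios <- function(counts) {
  logg <- rowMeans(log(counts))
  ref <- is.finite(logg)
  if (!any(ref))
    stop("no reference gene: every gene has a zero count in some sample")
  geomean <- exp(logg[ref])
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(cj) {
    median(cj / geomean)
  })
  setNames(sf, colnames(counts))
}

#' Normalize counts by median-of-ratios size factors
#' @param counts gene x sample count matrix.
#' @return list with `normalized` matrix and `size_factors`.
#' @export
mor_normalize <- function(counts) {
  sf <- median_of_ratios(counts)
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Abundance filter on normalized counts
#'
#' Drops genes with fewer than 10 total normalized reads (strictly fewer:
#' a total of exactly 10 is retained), or whose mean normalized count is
#' below 1 in every group (flag `group_mean_rule = "per_group"`, the
#' default) / overall (`"overall"`).
#'
#' @param normalized gene x sample matrix of normalized counts (CPM or
#'   size-factor scale).
#' @param group logical vector (TRUE = NEC) for the per-group means.
#' @param group_mean_rule how to read the "lowest average coverage of 1"
#'   rule; see above.
#' @return list `keep` (logical per gene), `n_total_rule`,
#'   `n_mean_rule`, `n_kept`.
#' @export
filter_genes <- function(normalized, group,
                         group_mean_rule = c("per_group", "overall")) {
  group_mean_rule <- match.arg(group_mean_rule)
  total <- rowSums(normalized)
  low_total <- total < 10
  if (group_mean_rule == "per_group") {
    m1 <- rowMeans(normalized[, group, drop = FALSE])
    m0 <- rowMeans(normalized[, !group, drop = FALSE])
    low_mean <- m1 < 1 & m0 < 1
  } else {
    low_mean <- rowMeans(normalized) < 1
  }
  keep <- !(low_total | low_mean)
  list(keep = keep,
       n_total_rule = sum(low_total),
       n_mean_rule = sum(low_mean),
       n_kept = sum(keep))
}

#' Differential expression by moderated t with a mean-variance trend
#'
#' Tests each gene's log2 normalized expression (pseudocount added) between
#' NEC and non-NEC samples using the shared empirical-Bayes machinery
#' ([eb_moderated_test()]) with the prior variance following a lowess trend
#' in the least-squares mean (`ls_mean`, the mean log2 normalized value
#' across samples). Genes pass at `p <= p_threshold` and
#' `ls_mean > ls_mean_min`.
#'
#' @param normalized gene x sample matrix of normalized counts (CPM).
#' @param group logical vector, TRUE = NEC.
#' @param pseudocount added before log2 (default 0.5).
#' @param p_threshold significance cutoff (default 0.05).
#' @param ls_mean_min abundance cutoff on ls_mean (default 1, strict).
#' @param trend fit the mean-variance trend (default TRUE).
#' @return data.table `gene_id`, `log2_fc`, `ls_mean`, `t_moderated`,
#'   `df_total`, `p_value`, `q_value` (BH), `direction` (`up`/`down`),
#'   `significant`, `tested`, `reason`.
#' @export
de_test <- function(normalized, group, pseudocount = 0.5,
                    p_threshold = 0.05, ls_mean_min = 1, trend = TRUE) {
  y <- log2(normalized + pseudocount)
  eb <- eb_moderated_test(y, group, trend = trend)
  q <- adjust_pvalues(eb$p_value)$q
  out <- data.table(
    gene_id = eb$feature_id,
    log2_fc = eb$delta,
    ls_mean = eb$mean_value,
    t_moderated = eb$t,
    df_total = eb$df_total,
    p_value = eb$p_value,
    q_value = q,
    direction = ifelse(eb$delta > 0, "up",
                       ifelse(eb$delta < 0, "down", NA_character_)),
    tested = eb$tested,
    reason = eb$reason
  )
  out[, significant := tested & !is.na(p_value) & p_value <= p_threshold &
        ls_mean > ls_mean_min]
  out[]
}

#' Up/down summary of differential expression
#'
#' Counts significant up- and down-regulated genes and their fractions of
#' the total. Accepts either a [de_test()] table (using its `significant`
#' flag) or explicit counts.
#'
#' @param de a [de_test()] table, or NULL when counts are given.
#' @param n_up,n_down explicit counts (used when `de` is NULL).
#' @return data.table `n_up`, `n_down`, `n_total`, `pct_up`, `pct_down`
#'   (percent; NA when no gene is called).
#' @export
de_summary <- function(de = NULL, n_up = NULL, n_down = NULL) {
  if (!is.null(de)) {
    de <- as.data.table(de)
    n_up <- de[significant == TRUE & direction == "up", .N]
    n_down <- de[significant == TRUE & direction == "down", .N]
  }
  n_total <- n_up + n_down
  data.table(n_up = n_up, n_down = n_down, n_total = n_total,
             pct_up = if (n_total > 0) 100 * n_up / n_total else NA_real_,
             pct_down = if (n_total > 0) 100 * n_down / n_total else NA_real_)
}
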