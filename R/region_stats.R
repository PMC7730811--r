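# Region-level differential methylation: promoter and gene-body
# aggregation of per-CpG rates, logit transform, empirical-Bayes moderated
# t-test on the logit scale, and DMR calling at the rate-difference and
# informative-CpG thresholds.

#' Aggregate per-CpG methylation over regions
#'
#' For each region and sample, averages (unweighted) the per-site
#' methylation rates of the CpGs located inside the region, counting only
#' informative sites (per-sample coverage >= `min_cov`). A region with no
#' informative site in a sample is missing for that sample; nothing is
#' imputed.
#'
#' @param ms a `meth_set`.
#' @param regions data.table `region_id`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @param min_cov minimum per-sample coverage for a CpG to be informative
#'   (default 5).
#' @return list of class `region_meth`: `rate` (regions x samples matrix of
#'   mean rates, NA where uninformative), `n_informative` (matching integer
#'   matrix), `regions`, `samples`.
#' @export
aggregate_region <- function(ms, regions, min_cov = 5L) {
  regions <- as.data.table(regions)
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)),
            min_cov >= 1L)
  q <- data.table(chrom = ms$sites$chrom, start = ms$sites$pos,
                  end = ms$sites$pos)
  s <- regions[, .(chrom, start, end)]
  setkey(s, chrom, start, end)
  hits <- foverlaps(q, s, type = "any", which = TRUE, nomatch = NULL)

  nr <- nrow(regions); ns <- nrow(ms$samples)
  rate <- matrix(NA_real_, nr, ns,
                 dimnames = list(regions$region_id, ms$samples$sample_id))
  n_inf <- matrix(0L, nr, ns, dimnames = dimnames(rate))

  if (nrow(hits) > 0L) {
    r <- ms$meth / ms$cov
    informative <- ms$cov >= min_cov
    r[!informative] <- NA_real_
    for (j in seq_len(ns)) {
      d <- data.table(reg = hits$yid, v = r[hits$xid, j])
      agg <- d[!is.na(v), .(mu = mean(v), n = .N), by = reg]
      rate[agg$reg, j] <- agg$mu
      n_inf[agg$reg, j] <- agg$n
    }
  }
  out <- list(rate = rate, n_informative = n_inf, regions = regions,
              samples = as.data.table(ms$samples))
  class(out) <- "region_meth"
  out
}

#' Promoter or gene-body methylation per gene
#'
#' Builds the region set from an annotation (promoters via
#' [build_promoters()]; gene bodies are the annotated gene intervals) and
#' aggregates with [aggregate_region()]. Region ids are the gene ids.
#'
#' @param ms a `meth_set`.
#' @param annotation an `annotation_set`.
#' @param region_type `"promoter"` or `"gene_body"`.
#' @param min_cov informative-CpG coverage threshold (default 5).
#' @param gene_ids optional subset of genes; an error names any id absent
#'   from the annotation.
#' @return a `region_meth` (see [aggregate_region()]).
#' @export
region_methylation <- function(ms, annotation,
                               region_type = c("promoter", "gene_body"),
                               min_cov = 5L, gene_ids = NULL) {
  region_type <- match.arg(region_type)
  genes <- annotation$genes
  if (!is.null(gene_ids)) {
    miss <- base::setdiff(gene_ids, genes$gene_id)
    if (length(miss))
      stop("region(s) absent from annotation: ",
           paste(head(miss, 5L), collapse = ", "))
    genes <- genes[gene_id %in% gene_ids]
  }
  regions <- if (region_type == "promoter") {
    p <- build_promoters(genes)
    data.table(region_id = p$feature_id, chrom = p$chrom,
               start = p$start, end = p$end)
  } else {
    data.table(region_id = genes$gene_id, chrom = genes$chrom,
               start = genes$gene_start, end = genes$gene_end)
  }
  aggregate_region(ms, regions, min_cov = min_cov)
}

#' Logit transform of methylation rates
#'
#' `log(r' / (1 - r'))` with rates clamped to `[eps, 1 - eps]` so that
#' boundary rates stay finite.
#'
#' @param rate numeric vector/matrix of rates in \[0, 1\].
#' @param eps clamp (default 0.01).
#' @return transformed values, same shape as input.
#' @export
logit_transform <- function(rate, eps = 0.01) {
  r <- pmin(pmax(rate, eps), 1 - eps)
  qlogis(r)
}

#' Region-level differential methylation test
#'
#' Logit-transforms the per-sample region rates and runs the two-group
#' empirical-Bayes moderated t-test ([eb_moderated_test()]), NEC minus
#' non-NEC. Also reports the rate-scale difference of group means and the
#' per-region minimum number of informative CpGs across samples.
#'
#' @param rm a `region_meth` from [aggregate_region()].
#' @param eps logit clamp (default 0.01).
#' @param ... passed to [eb_moderated_test()] (e.g. `d0`, `trend`).
#' @return data.table `region_id`, `delta_rate`, `delta_logit`,
#'   `t_moderated`, `df_total`, `p_value`, `q_value` (BH),
#'   `n_informative_min`, `tested`.
#' @export
region_test <- function(rm, eps = 0.01, ...) {
  group <- rm$samples$condition == "NEC"
  lg <- logit_transform(rm$rate, eps = eps)
  eb <- eb_moderated_test(lg, group, ...)

  nz <- rm$rate
  mean_or_na <- function(m, g) {
    k <- rowSums(!is.na(m[, g, drop = FALSE]))
    out <- rowMeans(m[, g, drop = FALSE], na.rm = TRUE)
    out[k == 0] <- NA_real_
    out
  }
  delta_rate <- mean_or_na(nz, group) - mean_or_na(nz, !group)
  n_inf_min <- apply(rm$n_informative, 1L, min)

  q <- adjust_pvalues(eb$p_value)$q
  data.table(region_id = rm$regions$region_id,
             delta_rate = delta_rate,
             delta_logit = eb$delta,
             t_moderated = eb$t,
             df_total = eb$df_total,
             p_value = eb$p_value,
             q_value = q,
             n_informative_min = as.integer(n_inf_min),
             tested = eb$tested)
}

#' Call differentially methylated regions
#'
#' Retains regions with an absolute rate difference of at least
#' `min_delta` (inclusive), more than `min_informative - 1` informative
#' CpGs in every sample, and p below the threshold.
#'
#' @param results a [region_test()] table.
#' @param min_delta minimum |delta_rate| (default 0.1, inclusive).
#' @param min_informative minimum per-sample informative CpGs (default 4,
#'   i.e. more than 3).
#' @param p_threshold p-value cutoff (default 0.05, unadjusted; the BH
#'   `q_value` stays in the output for stricter filtering).
#' @return filtered data.table sorted by p.
#' @export
call_dmrs <- function(results, min_delta = 0.1, min_informative = 4L,
                      p_threshold = 0.05) {
  out <- as.data.table(results)[
    tested & !is.na(delta_rate) &
      abs(delta_rate) >= min_delta &
      n_informative_min >= min_informative &
      p_value <= p_threshold
  ]
  setorder(out, p_value)
  out[]
}

#' DMRs shared between two tissues
#'
#' Inner join of two DMR tables on `region_id`, with per-tissue statistics
#' suffixed.
#'
#' @param colon,ileum [call_dmrs()] tables.
#' @return data.table of shared regions.
#' @export
shared_dmrs <- function(colon, ileum) {
  merge(as.data.table(colon), as.data.table(ileum), by = "region_id",
        suffixes = c("_colon", "_ileum"))
}
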