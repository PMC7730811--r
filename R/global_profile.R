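# Genome-wide methylome characterization: LM/IM/HM classification of pooled
# per-condition rates, element-stratified contingency tests, methylation
# density summaries, spatial (binned) chromosome profiles, and classical
# multidimensional scaling of samples.

#' Coverage-weighted pooled methylation rate per condition
#'
#' For each site and condition, the pooled rate is the sum of methylated
#' reads over the sum of coverage across that condition's samples.
#'
#' @param ms a `meth_set`.
#' @return list with numeric vectors `nec` and `ctrl` (NA where the pooled
#'   coverage is zero) and the matching pooled coverages `cov_nec`,
#'   `cov_ctrl`.
#' @export
pooled_rates <- function(ms) {
  g <- ms$samples$condition == "NEC"
  Tn <- rowSums(ms$cov[, g, drop = FALSE])
  Tc <- rowSums(ms$cov[, !g, drop = FALSE])
  nec <- ifelse(Tn > 0, rowSums(ms$meth[, g, drop = FALSE]) / Tn, NA_real_)
  ctrl <- ifelse(Tc > 0, rowSums(ms$meth[, !g, drop = FALSE]) / Tc, NA_real_)
  list(nec = nec, ctrl = ctrl, cov_nec = Tn, cov_ctrl = Tc)
}

#' Classify methylation rates as LM / IM / HM
#'
#' Low methylation is a rate below 20%, intermediate 20-80% (both ends
#' included), high above 80%: LM = \[0, 0.2), IM = \[0.2, 0.8\],
#' HM = (0.8, 1\]. Rates of NA (zero pooled coverage) are unclassified.
#'
#' @param rate numeric vector of methylation rates in \[0, 1\].
#' @return character vector of `"LM"`, `"IM"`, `"HM"` (NA for NA input).
#' @export
classify_sites <- function(rate) {
  out <- rep(NA_character_, length(rate))
  ok <- !is.na(rate)
  out[ok & rate < 0.2] <- "LM"
  out[ok & rate >= 0.2 & rate <= 0.8] <- "IM"
  out[ok & rate > 0.8] <- "HM"
  out
}

#' Pearson chi-square test on a condition-by-class contingency table
#'
#' Builds the 2 x 3 (condition x LM/IM/HM) table of site counts for one
#' element class and computes the Pearson chi-square statistic (no
#' continuity correction) with df = 2, plus per-condition percentages.
#' Accepts either class label vectors or pre-tabulated counts, so printed
#' summary tables can be re-tested directly.
#'
#' @param nec LM/IM/HM labels of NEC sites, or a named count triple
#'   `c(LM=, IM=, HM=)`.
#' @param ctrl same for non-NEC.
#' @param element_class optional label carried into the output.
#' @return one-row data.table with counts and percentages per condition and
#'   class, `chi_square`, `df`, `p_value`. When any row or column total is
#'   zero the statistic is undefined and reported as NA with a note.
#' @export
class_contingency_test <- function(nec, ctrl, element_class = NA_character_) {
  to_counts <- function(x) {
    if (is.numeric(x)) {
      stopifnot(length(x) == 3L)
      if (is.null(names(x))) names(x) <- c("LM", "IM", "HM")
      return(x[c("LM", "IM", "HM")])
    }
    c(LM = sum(x == "LM", na.rm = TRUE),
      IM = sum(x == "IM", na.rm = TRUE),
      HM = sum(x == "HM", na.rm = TRUE))
  }
  a <- to_counts(nec); b <- to_counts(ctrl)
  tab <- rbind(NEC = a, ctrl = b)

  note <- NA_character_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    chi <- NA_real_; df <- NA_integer_; p <- NA_real_
    note <- "chi-square undefined: zero row or column total"
  } else {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi <- sum((tab - E)^2 / E)
    df <- 2L
    p <- pchisq(chi, df, lower.tail = FALSE)
  }
  data.table(
    element_class = element_class,
    nec_LM = a[["LM"]], nec_IM = a[["IM"]], nec_HM = a[["HM"]],
    ctrl_LM = b[["LM"]], ctrl_IM = b[["IM"]], ctrl_HM = b[["HM"]],
    nec_pct_LM = 100 * a[["LM"]] / sum(a),
    nec_pct_IM = 100 * a[["IM"]] / sum(a),
    nec_pct_HM = 100 * a[["HM"]] / sum(a),
    ctrl_pct_LM = 100 * b[["LM"]] / sum(b),
    ctrl_pct_IM = 100 * b[["IM"]] / sum(b),
    ctrl_pct_HM = 100 * b[["HM"]] / sum(b),
    chi_square = chi, df = df, p_value = p, note = note
  )
}

#' Element-stratified LM/IM/HM table for a cohort
#'
#' Classifies the pooled per-condition rates and produces one
#' [class_contingency_test()] row per element class, including the
#' composite classes CGI + shore, exons + introns, and all sites.
#'
#' @param ms a `meth_set`.
#' @param site_annotation output of [annotate_sites()] for `ms$sites`.
#' @return data.table, one row per element class.
#' @export
methylation_class_table <- function(ms, site_annotation) {
  pr <- pooled_rates(ms)
  lab_nec <- classify_sites(pr$nec)
  lab_ctrl <- classify_sites(pr$ctrl)
  sa <- site_annotation
  strata <- list(
    promoter = sa$promoter, exonic = sa$exon, intronic = sa$intron,
    cpg_island = sa$cgi, cpg_shore = sa$shore, enhancer = sa$enhancer,
    intergenic = sa$intergenic,
    cgi_plus_shore = sa$cgi | sa$shore,
    exons_plus_introns = sa$exon | sa$intron,
    all = rep(TRUE, nrow(sa))
  )
  rbindlist(lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    class_contingency_test(lab_nec[idx], lab_ctrl[idx], element_class = nm)
  }))
}

#' Binned density of per-condition methylation rates
#'
#' Histogram density over \[0, 1\] for each condition (density integrates
#' to 1 over the binned support).
#'
#' @param nec,ctrl numeric rate vectors (NA dropped).
#' @param n_bins number of equal-width bins (default 50).
#' @return data.table `bin_mid`, `density_nec`, `density_ctrl`.
#' @export
density_profile <- function(nec, ctrl, n_bins = 50L) {
  brk <- seq(0, 1, length.out = n_bins + 1L)
  dens <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(rep(NA_real_, n_bins))
    cnt <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE),
                         n_bins), nbins = n_bins)
    cnt / length(x) / diff(brk)
  }
  data.table(bin_mid = (brk[-1] + brk[-length(brk)]) / 2,
             density_nec = dens(nec), density_ctrl = dens(ctrl))
}

#' Spatial (binned) methylation profile along chromosomes
#'
#' Tiles each chromosome with `bin_size` windows and reports the
#' coverage-weighted mean methylation rate per condition in every bin
#' (NA for empty bins).
#'
#' @param ms a `meth_set`.
#' @param bin_size bin width in bp (> 0).
#' @return data.table `chrom`, `bin_start`, `bin_end`, `mean_nec`,
#'   `mean_ctrl`, `n_sites`.
#' @export
spatial_profile <- function(ms, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  g <- ms$samples$condition == "NEC"
  d <- data.table(chrom = ms$sites$chrom, pos = ms$sites$pos,
                  m1 = rowSums(ms$meth[, g, drop = FALSE]),
                  t1 = rowSums(ms$cov[, g, drop = FALSE]),
                  m0 = rowSums(ms$meth[, !g, drop = FALSE]),
                  t0 = rowSums(ms$cov[, !g, drop = FALSE]))
  d[, bin := (pos - 1L) %/% as.integer(bin_size)]
  agg <- d[, .(mean_nec = ifelse(sum(t1) > 0, sum(m1) / sum(t1), NA_real_),
               mean_ctrl = ifelse(sum(t0) > 0, sum(m0) / sum(t0), NA_real_),
               n_sites = .N),
           by = .(chrom, bin)]
  # emit empty bins up to the last occupied bin per chromosome
  full <- agg[, .(bin = 0:max(bin)), by = chrom]
  out <- merge(full, agg, by = c("chrom", "bin"), all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[, `:=`(bin_start = bin * as.integer(bin_size) + 1L,
             bin_end = (bin + 1L) * as.integer(bin_size))]
  setorder(out, chrom, bin_start)
  out[, .(chrom, bin_start, bin_end, mean_nec, mean_ctrl, n_sites)]
}

#' Classical multidimensional scaling of samples
#'
#' Restricts to sites covered at `min_cov` or more reads in every sample,
#' computes Euclidean distances between the per-sample methylation-rate
#' vectors, and embeds the samples in 2-D by classical (Torgerson) MDS.
#' Output is centred at the origin; orientation is fixed so the first
#' coordinate of the first sample is non-negative (each axis independently).
#'
#' @param ms a `meth_set`.
#' @param min_cov minimum per-sample coverage for a site to enter (default 5).
#' @param k embedding dimension (default 2).
#' @return data.table `sample_id`, `tissue`, `condition`, `dim1`, `dim2`,
#'   with attribute `n_sites` = number of sites used.
#' @export
sample_mds <- function(ms, min_cov = 5L, k = 2L) {
  if (nrow(ms$samples) < 3L) stop("sample_mds needs at least 3 samples")
  keep <- rowSums(ms$cov >= min_cov) == ncol(ms$cov)
  if (sum(keep) < 3L)
    stop("fewer than 3 sites covered at min_cov in all samples")
  r <- ms$meth[keep, , drop = FALSE] / ms$cov[keep, , drop = FALSE]
  d <- dist(t(r))
  xy <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(xy) < k) xy <- cbind(xy, matrix(0, nrow(xy), k - ncol(xy)))
  xy <- sweep(xy, 2, colMeans(xy))
  for (j in seq_len(ncol(xy))) if (xy[1, j] < 0) xy[, j] <- -xy[, j]
  out <- data.table(sample_id = ms$samples$sample_id,
                    tissue = ms$samples$tissue,
                    condition = ms$samples$condition,
                    dim1 = xy[, 1], dim2 = xy[, 2])
  setattr(out, "n_sites", sum(keep))
  out[]
}
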