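#!/usr/bin/env Rscript
# Methylation-expression integration: per-gene Pearson correlation between
# promoter (and gene-body) methylation and log2 median-of-ratios
# normalized expression, the conjunctive selection rule (region p <= 0.05,
# |delta logit| >= 1, BH-adjusted correlation p <= 0.1, strict tier at
# 0.05), directionality tables for DE genes, the correlation density split
# at |delta rate| = 0.2, and the colon-ileum correlation of correlations.

suppressMessages({
  library(necmethylome)
  library(data.table)
})

dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)
records <- list()

for (tis in c("colon", "ileum")) {
  d <- file.path("results/data", tis)
  cfg <- read_sim_config(file.path(d, "config.yaml"))
  ms <- read_bismark_cov(d)
  ann <- read_annotation(file.path(d, "annotation"), cfg$genome_length)
  counts <- read_counts(file.path(d, "rna_counts.tsv"))
  g <- ms$samples$condition == "NEC"

  el2 <- log2(mor_normalize(counts)$normalized + 0.5)
  de <- de_test(cpm_normalize(counts)[
    filter_genes(cpm_normalize(counts), g)$keep, , drop = FALSE], g)

  for (rtype in c("promoter", "gene_body")) {
    rm1 <- region_methylation(ms, ann, rtype, min_cov = 5)
    rt <- region_test(rm1)
    corr <- gene_correlations(
      rm1$rate[match(rownames(el2), rownames(rm1$rate)), , drop = FALSE],
      el2)
    rec <- select_genes(integration_records(rt, corr, de = de,
                                            region_type = rtype))
    fwrite(rec, sprintf("results/integration/records_%s_%s.tsv",
                        tis, rtype), sep = "\t")
    records[[paste(tis, rtype, sep = "_")]] <- rec
    message(sprintf("%s %s: %d genes selected (tier 0.1), %d at the strict tier (0.05)",
                    tis, rtype, sum(rec$selected),
                    sum(rec$selected_strict)))
  }

  rec_p <- records[[paste(tis, "promoter", sep = "_")]]
  ds <- directionality_summary(rec_p[de_significant == TRUE])
  if (ds$n_total > 0) {
    message(sprintf(
      "%s: of %d DE genes with promoter methylation, %.1f%% are down; %.1f%% of down genes are promoter-hypermethylated",
      tis, ds$n_total, ds$pct_down, ds$pct_hyper_down))
  }
  cd <- correlation_density(rec_p, delta_threshold = 0.2)
  fwrite(cd$density, sprintf("results/integration/corr_density_%s.tsv", tis),
         sep = "\t")
  message(sprintf("%s: mean correlation, high-|delta| genes %.2f vs low-|delta| genes %.2f",
                  tis, cd$mean_r_high, cd$mean_r_low))
}

for (rtype in c("promoter", "gene_body")) {
  cc <- correlation_of_correlations(records[[paste0("colon_", rtype)]],
                                    records[[paste0("ileum_", rtype)]])
  message(sprintf("correlation of %s correlations colon vs ileum: r = %.3f (p = %.2e, n = %d)",
                  rtype, cc$r_cc, cc$p_value, cc$n_genes))
}
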