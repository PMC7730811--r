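#!/usr/bin/env Rscript
# Genome-wide methylome characterization per tissue: LM/IM/HM classification
# of pooled per-condition rates stratified by genomic element (with Pearson
# chi-square per element), methylation density profiles, binned spatial
# profiles along the chromosome, and classical MDS of samples.

suppressMessages({
  library(necmethylome)
  library(data.table)
})

dir.create("results/global_profile", showWarnings = FALSE, recursive = TRUE)

for (tis in c("colon", "ileum")) {
  d <- file.path("results/data", tis)
  cfg <- read_sim_config(file.path(d, "config.yaml"))
  ms <- read_bismark_cov(d)
  ann <- read_annotation(file.path(d, "annotation"), cfg$genome_length)
  sa <- annotate_sites(ms$sites, ann)

  mct <- methylation_class_table(ms, sa)
  fwrite(mct, sprintf("results/global_profile/class_table_%s.tsv", tis),
         sep = "\t")
  allrow <- mct[element_class == "all"]
  message(sprintf(
    "%s all-sites LM/IM/HM: NEC %.1f/%.1f/%.1f%% vs non-NEC %.1f/%.1f/%.1f%% (X2 = %.0f)",
    tis, allrow$nec_pct_LM, allrow$nec_pct_IM, allrow$nec_pct_HM,
    allrow$ctrl_pct_LM, allrow$ctrl_pct_IM, allrow$ctrl_pct_HM,
    allrow$chi_square))

  pr <- pooled_rates(ms)
  fwrite(density_profile(pr$nec, pr$ctrl),
         sprintf("results/global_profile/density_%s.tsv", tis), sep = "\t")
  fwrite(spatial_profile(ms, bin_size = 1e6),
         sprintf("results/global_profile/spatial_%s.tsv", tis), sep = "\t")

  xy <- sample_mds(ms, min_cov = 5)
  fwrite(xy, sprintf("results/global_profile/mds_%s.tsv", tis), sep = "\t")
  D <- as.matrix(dist(cbind(xy$dim1, xy$dim2)))
  g <- xy$condition == "NEC"
  sep <- mean(D[g, !g]) / mean(c(D[g, g][upper.tri(D[g, g])],
                                 D[!g, !g][upper.tri(D[!g, !g])]))
  message(sprintf("%s MDS inter/intra-group distance ratio: %.2f (n sites %d)",
                  tis, sep, attr(xy, "n_sites")))
}
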