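#!/usr/bin/env Rscript
# RNA-seq differential expression per tissue: counts-per-million
# normalization, the abundance filter (fewer than 10 total normalized
# reads, or below-1 group means, dropped), and the trended moderated-t
# test; genes pass at p <= 0.05 with LS mean > 1.

suppressMessages({
  library(necmethylome)
  library(data.table)
})

dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)

for (tis in c("colon", "ileum")) {
  d <- file.path("results/data", tis)
  counts <- read_counts(file.path(d, "rna_counts.tsv"))
  samples <- read_sample_sheet(file.path(d, "samples.csv"))
  g <- samples$condition == "NEC"

  cpm <- cpm_normalize(counts)
  fl <- filter_genes(cpm, g)
  message(sprintf("%s: %d of %d genes pass the abundance filter (%d below 10 total, %d below group means of 1)",
                  tis, fl$n_kept, nrow(counts), fl$n_total_rule,
                  fl$n_mean_rule))

  de <- de_test(cpm[fl$keep, , drop = FALSE], g)
  fwrite(de, sprintf("results/expression/de_%s.tsv", tis), sep = "\t")
  s <- de_summary(de)
  message(sprintf("%s: %d DE genes (p <= 0.05, LS mean > 1): %d up (%.1f%%), %d down (%.1f%%)",
                  tis, s$n_total, s$n_up, s$pct_up, s$n_down, s$pct_down))

  truth <- fread(file.path(d, "truth_expression.tsv"))
  sig <- de[significant == TRUE, gene_id]
  recall <- mean(truth[is_de == TRUE, gene_id] %in% sig)
  message(sprintf("%s: recall of truly DE genes %.2f", tis, recall))
}
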