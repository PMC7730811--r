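# Synthetic-cohort generator: config validation, annotation packing,
# methylation truth structure, determinism, and the generative model's
# marginal properties.

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(lmimhm_weights_control = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(sim_config(hyper_shift = -1), "hyper_shift")
  expect_error(sim_config(n_samples_per_group = 1), "n_samples_per_group")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  # YAML round trip
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  expect_equal(read_sim_config(f), cfg)
})

test_that("a gene-free genome is entirely intergenic", {
  cfg <- sim_config(n_genes = 0, genome_length = 1e5, n_cpg = 100)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(nrow(ann$elements$promoter), 0L)
  expect_equal(ann$elements$intergenic$start, 1L)
  expect_equal(ann$elements$intergenic$end, 100000L)
})

test_that("promoters are non-overlapping 2001-bp intervals by construction", {
  cfg <- sim_config(n_genes = 50, genome_length = 5e6, n_cpg = 1000, seed = 1)
  ann <- simulate_annotation(cfg)
  p <- ann$elements$promoter
  expect_equal(nrow(p), 50L)
  expect_equal(sum(p$end - p$start + 1L), 50L * 2001L)
  o <- order(p$start)
  expect_true(all(p$end[o][-50] < p$start[o][-1]))
  expect_true(all(p$start >= 1))
  expect_true(all(p$end <= 5e6))
})

test_that("infeasible gene packing fails with an explicit constraint", {
  cfg <- sim_config(n_genes = 1000, genome_length = 1e6, n_cpg = 100)
  expect_error(simulate_annotation(cfg), "infeasible packing")
})

test_that("all annotation intervals lie inside the genome and genes partition into exons+introns", {
  co <- tiny_cohort()
  ann <- co$annotation
  for (cl in names(ann$elements)) {
    el <- ann$elements[[cl]]
    if (nrow(el) == 0L) next
    expect_true(all(el$start >= 1), info = cl)
    expect_true(all(el$end <= ann$genome_length), info = cl)
    expect_true(all(el$start <= el$end), info = cl)
  }
  # exons + introns tile each gene body exactly
  g <- ann$genes
  ex <- rbind(ann$elements$exon, ann$elements$intron)
  bases <- ex[, sum(end - start + 1L), by = feature_id]
  glen <- g[, .(feature_id = gene_id, len = gene_end - gene_start + 1L)]
  m <- merge(bases, glen, by = "feature_id")
  expect_equal(m$V1, m$len)
})

test_that("methylated counts never exceed coverage and seeds give byte-identical output", {
  co <- tiny_cohort()
  expect_true(all(co$meth$meth <= co$meth$cov))
  expect_true(all(co$meth$meth >= 0))
  cfg <- tiny_config()
  ann <- simulate_annotation(cfg)
  m1 <- simulate_methylation(cfg, ann)
  m2 <- simulate_methylation(cfg, ann)
  expect_identical(m1, m2)
  e1 <- simulate_expression(cfg, m1, ann)
  e2 <- simulate_expression(cfg, m2, ann)
  expect_identical(e1, e2)
})

test_that("hyper_shift = 0 marks no shifted sites and group means agree", {
  cfg <- sim_config(n_samples_per_group = 4, n_cpg = 5000, n_genes = 50,
                    genome_length = 2e6, hyper_shift = 0, seed = 7)
  ms <- simulate_methylation(cfg, simulate_annotation(cfg))
  expect_equal(sum(ms$truth$sites$shifted), 0L)
  expect_equal(ms$truth$sites$m_control, ms$truth$sites$m_nec)
  pr <- pooled_rates(ms)
  expect_lt(abs(mean(pr$nec - pr$ctrl, na.rm = TRUE)), 0.01)
})

test_that("high precision and coverage concentrate observed rates at the site mean", {
  # kappa and coverage -> large: observed rate -> m for every sample
  cfg <- sim_config(n_samples_per_group = 3, n_cpg = 200, n_genes = 0,
                    genome_length = 1e5, coverage_mean = 5000,
                    coverage_dispersion = 1e5, site_noise_kappa = 1e6,
                    hyper_shift = 0, seed = 9)
  ms <- simulate_methylation(cfg, simulate_annotation(cfg))
  r <- meth_rates(ms)
  dev <- abs(r - ms$truth$sites$m_control)
  expect_lt(max(dev, na.rm = TRUE), 0.05)
  expect_lt(mean(dev, na.rm = TRUE), 0.01)
})

test_that("mean rate shift over shifted sites matches a Monte-Carlo oracle", {
  cfg <- sim_config(n_samples_per_group = 5, n_cpg = 10000, n_genes = 100,
                    genome_length = 1e7, hyper_shift = 1,
                    frac_shifted_sites = 0.5, seed = 7)
  ann <- simulate_annotation(cfg)
  ms <- simulate_methylation(cfg, ann)
  tr <- ms$truth$sites
  expect_equal(sum(tr$shifted), 5000L)
  pr <- pooled_rates(ms)
  obs <- mean(pr$nec[tr$shifted] - pr$ctrl[tr$shifted], na.rm = TRUE)

  # independent Monte-Carlo oracle: 1e6 site means drawn from the same
  # element-blended beta mixture, shifted analytically on the logit scale
  set.seed(4242)
  ew <- element_component_weights()
  cls <- table(tr$element_class[tr$shifted])
  betas <- rbind(c(0.5, 8), c(5, 5), c(8, 0.5))
  draw <- unlist(lapply(names(cls), function(cl) {
    w <- if (cl %in% ew$element_class) {
      as.numeric(ew[ew$element_class == cl, c("w_LM", "w_IM", "w_HM")])
    } else cfg$lmimhm_weights_control
    n <- round(1e6 * cls[[cl]] / sum(cls))
    u <- runif(n)
    k <- 1L + (u > w[1]) + (u > w[1] + w[2])
    rbeta(n, betas[k, 1], betas[k, 2])
  }))
  oracle <- mean(plogis(qlogis(draw) + 1) - draw)
  expect_lt(abs(obs - oracle), 0.01)
})

test_that("marginal LM/IM/HM mass matches the analytic mixture blend at 1e5 sites", {
  cfg <- sim_config(n_samples_per_group = 3, n_cpg = 100000, n_genes = 500,
                    genome_length = 3e7, hyper_shift = 0, seed = 5)
  ann <- simulate_annotation(cfg)
  ms <- simulate_methylation(cfg, ann)
  tr <- ms$truth$sites
  ew <- element_component_weights()
  cls <- table(tr$element_class)
  mass <- c(LM = 0, IM = 0, HM = 0)
  for (cl in names(cls)) {
    w <- if (cl %in% ew$element_class) {
      as.numeric(ew[ew$element_class == cl, c("w_LM", "w_IM", "w_HM")])
    } else cfg$lmimhm_weights_control
    mass <- mass + (cls[[cl]] / nrow(tr)) * mixture_class_mass(w)
  }
  pr <- pooled_rates(ms)
  lab <- classify_sites(pr$ctrl)
  obs <- table(factor(lab, c("LM", "IM", "HM"))) / sum(!is.na(lab))
  expect_lt(max(abs(as.numeric(obs) - as.numeric(mass))), 0.02)
})

test_that("DE truth counts are deterministic and coupling holds by construction", {
  cfg <- sim_config(n_samples_per_group = 3, n_cpg = 5000, n_genes = 2000,
                    genome_length = 3e7, de_frac = 0.2, coupling_frac = 1,
                    hyper_shift = 2, frac_shifted_sites = 0.3,
                    shift_unit = "promoter", seed = 31)
  co <- simulate_cohort(cfg)
  tru <- co$expr$truth
  expect_equal(sum(tru$is_de), 400L)
  # every coupled gene has a shifted (hypermethylated) promoter and a
  # negative true fold change
  coupled <- tru[coupled == TRUE]
  shifted <- co$meth$truth$promoters[shifted == TRUE, gene_id]
  expect_true(all(coupled$gene_id %in% shifted))
  expect_true(all(coupled$lfc_true < 0))
})

test_that("de_frac = 0 yields an empty expression truth", {
  cfg <- tiny_config(de_frac = 0)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$expr$truth$is_de), 0L)
  expect_equal(sum(co$expr$truth$coupled), 0L)
  expect_true(all(co$expr$truth$lfc_true == 0))
})

test_that("written cohort round-trips through the on-disk formats", {
  co <- tiny_cohort()
  d <- tempfile()
  write_bismark_cov(co$meth, d)
  ms2 <- read_bismark_cov(d)
  expect_equal(unname(ms2$meth), unname(co$meth$meth))
  expect_equal(unname(ms2$cov), unname(co$meth$cov))
  expect_equal(ms2$sites$pos, co$meth$sites$pos)
  expect_equal(ms2$samples$condition, co$meth$samples$condition)

  write_annotation(co$annotation, d)
  ann2 <- read_annotation(d, co$annotation$genome_length)
  expect_equal(ann2$elements$promoter$start,
               co$annotation$elements$promoter$start)
  expect_equal(ann2$elements$cgi$end, co$annotation$elements$cgi$end)

  f <- file.path(d, "counts.tsv")
  write_counts(co$expr$counts, f)
  expect_equal(read_counts(f), co$expr$counts)
})
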