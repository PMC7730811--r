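# Methylation-expression integration: correlation oracles, the selection
# rule, directionality arithmetic, and the cross-tissue correlation of
# correlations.

library(data.table)

test_that("per-gene Pearson correlation matches the closed-form oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 3, 2, 4)
  m <- rbind(g1 = x); e <- rbind(g1 = y)
  got <- gene_correlations(m, e)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-10)
  expect_equal(got$t_stat, r_hand * sqrt(3) / sqrt(1 - r_hand^2),
               tolerance = 1e-10)
  ct <- cor.test(x, y)
  expect_equal(got$p_corr, ct$p.value, tolerance = 1e-10)

  # exhaustive small fixtures against cor.test
  set.seed(6)
  for (n in 3:6) {
    for (k in 1:5) {
      xx <- rnorm(n); yy <- rnorm(n)
      g2 <- gene_correlations(rbind(a = xx), rbind(a = yy))
      expect_equal(g2$r, cor(xx, yy), tolerance = 1e-12)
      expect_equal(g2$p_corr, cor.test(xx, yy)$p.value, tolerance = 1e-10)
    }
  }
})

test_that("perfect linear relation gives |r| = 1 with p ~ 0; swap symmetry holds", {
  x <- 1:6
  up <- gene_correlations(rbind(g = x), rbind(g = 2 * x + 1))
  expect_equal(up$r, 1)
  expect_equal(up$p_corr, 0)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(gene_correlations(rbind(g = a), rbind(g = b))$r,
               gene_correlations(rbind(g = b), rbind(g = a))$r)
})

test_that("zero-variance and short inputs are excluded with reasons", {
  m <- rbind(flat = rep(0.5, 5), short = c(0.1, 0.2, NA, NA, NA))
  e <- rbind(flat = rnorm(5), short = rnorm(5))
  got <- gene_correlations(m, e)
  expect_false(got$tested[1])
  expect_match(got$reason[1], "variance")
  expect_false(got$tested[2])
  expect_match(got$reason[2], "paired")
})

test_that("the selection rule is conjunctive with a nested strict tier", {
  rec <- data.table(
    gene_id = c("a", "b", "c", "d"),
    p_meth = c(0.01, 0.01, 0.2, 0.01),
    delta_logit = c(2, 0.5, 2, -2),
    delta_rate = c(0.3, 0.1, 0.3, -0.3),
    r = -0.8, t_stat = -3, p_corr = 0.001,
    p_corr_adj = c(0.04, 0.04, 0.04, 0.08)
  )
  sel <- select_genes(rec)
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE, TRUE))   # b fails delta, c fails p_meth
  expect_equal(sel$selected_strict, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(sel$selected_strict <= sel$selected))
  # vacuous thresholds select everything
  sel2 <- select_genes(rec, p_meth_max = 1, min_delta_logit = 0,
                       p_corr_adj_max = 1, tier2_adj_max = 1)
  expect_true(all(sel2$selected))
})

test_that("directionality arithmetic reproduces the printed fractions", {
  rec <- data.table(
    meth_direction = c(rep("hyper", 428), rep("hypo", 77),
                       rep("hyper", 153), rep("hypo", 81)),
    expr_direction = c(rep("down", 505), rep("up", 234))
  )
  ds <- directionality_summary(rec)
  expect_equal(ds$n_total, 739L)
  expect_equal(ds$pct_down, 68.3, tolerance = 0.05)
  expect_equal(ds$pct_hyper_down, 84.8, tolerance = 0.05)
  expect_equal(ds$pct_hyper_up, 65.4, tolerance = 0.05)
  # row fractions sum to 1 within each expression direction
  expect_equal(ds$table[, sum(row_fraction), by = expr_direction]$V1,
               c(1, 1))
  expect_equal(sum(ds$table$N), ds$n_total)
  # empty join
  e <- directionality_summary(rec[0])
  expect_equal(e$n_total, 0L)
  expect_true(is.na(e$pct_down))
})

test_that("correlation of correlations: identity, shared coupling, independence", {
  rec <- data.table(gene_id = sprintf("g%03d", 1:100), r = runif(100, -1, 1))
  same <- correlation_of_correlations(rec, rec)
  expect_equal(same$r_cc, 1)

  expect_error(correlation_of_correlations(rec[1:2], rec[1:2]),
               "fewer than 3")
})

test_that("coupled simulations: selection recovers coupled genes, densities shift negative", {
  cfg <- sim_config(n_samples_per_group = 8, n_cpg = 30000, n_genes = 500,
                    genome_length = 1e7, hyper_shift = 3.5,
                    frac_shifted_sites = 0.2, shift_unit = "promoter",
                    coupling_frac = 0.5, de_frac = 0.2, seed = 17)
  co <- simulate_cohort(cfg)
  rmp <- region_methylation(co$meth, co$annotation, "promoter")
  rt <- region_test(rmp)
  el2 <- log2(mor_normalize(co$expr$counts)$normalized + 0.5)
  corr <- gene_correlations(rmp$rate[match(rownames(el2),
                                           rownames(rmp$rate)), ], el2)
  rec <- select_genes(integration_records(rt, corr))
  tru <- co$expr$truth
  sub <- rec[match(tru$gene_id[tru$coupled], rec$gene_id)]
  expect_gte(mean(sub$selected), 0.7)

  # high-delta stratum shows the negative-correlation shift
  cd <- correlation_density(rec)
  expect_lt(cd$mean_r_high, cd$mean_r_low)
  expect_lt(cd$mean_r_high, -0.2)
  bw <- 2 / 40
  expect_equal(sum(cd$density$density_high) * bw, 1, tolerance = 1e-6)
  expect_equal(sum(cd$density$density_low) * bw, 1, tolerance = 1e-6)

  # single stratum when all deltas are zero
  rec0 <- data.table(gene_id = "g", r = 0.5, delta_rate = 0)
  cd0 <- correlation_density(rec0)
  expect_equal(cd0$n_high, 0L)
  expect_match(cd0$note, "empty")
})

test_that("shared-truth tissues correlate, independent tissues do not", {
  cfg <- sim_config(n_samples_per_group = 8, n_cpg = 20000, n_genes = 400,
                    genome_length = 1e7, hyper_shift = 3.5,
                    frac_shifted_sites = 0.2, shift_unit = "promoter",
                    coupling_frac = 0.5, de_frac = 0.2, seed = 29)
  mk <- function(config, tissue, nseed) {
    ann <- simulate_annotation(config)
    ms <- simulate_methylation(config, ann, tissue = tissue,
                               noise_seed = nseed)
    ex <- simulate_expression(config, ms, ann, noise_seed = nseed + 1L)
    rmx <- region_methylation(ms, ann, "promoter")
    rt <- region_test(rmx)
    el2 <- log2(mor_normalize(ex$counts)$normalized + 0.5)
    corr <- gene_correlations(rmx$rate[match(rownames(el2),
                                             rownames(rmx$rate)), ], el2)
    integration_records(rt, corr)
  }
  colon <- mk(cfg, "colon", 101L)
  ileum <- mk(cfg, "ileum", 202L)   # same truth, independent noise
  cc <- correlation_of_correlations(colon, ileum)
  expect_gt(cc$r_cc, 0)
  expect_lt(cc$p_value, 0.05)

  cfg2 <- sim_config(n_samples_per_group = 8, n_cpg = 20000, n_genes = 400,
                     genome_length = 1e7, hyper_shift = 3.5,
                     frac_shifted_sites = 0.2, shift_unit = "promoter",
                     coupling_frac = 0.5, de_frac = 0.2, seed = 83)
  other <- mk(cfg2, "ileum", 303L)  # independent truth
  cc0 <- correlation_of_correlations(colon, other)
  # null: within +-3 standard errors of zero
  expect_lt(abs(cc0$r_cc), 3 / sqrt(cc0$n_genes - 3))
})
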