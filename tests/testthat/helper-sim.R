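# Shared fixtures, built in code. Small cohorts are cached per session so
# several test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

tiny_config <- function(...) {
  sim_config(n_samples_per_group = 3, n_cpg = 2000, n_genes = 40,
             genome_length = 1e6, seed = 101, ...)
}

tiny_cohort <- function() {
  cached("tiny_cohort", simulate_cohort(tiny_config()))
}

# small meth_set built by hand from explicit counts
manual_meth_set <- function(meth, cov, conditions, tissue = "colon") {
  n <- nrow(meth)
  sites <- data.table::data.table(
    cpg_id = sprintf("cpg%04d", seq_len(n)),
    chrom = "chr1", pos = as.integer(seq(1000, by = 1000, length.out = n)))
  samples <- data.table::data.table(
    sample_id = sprintf("s%02d", seq_along(conditions)),
    tissue = tissue, condition = conditions)
  dimnames(meth) <- dimnames(cov) <- list(sites$cpg_id, samples$sample_id)
  meth_set(meth, cov, sites, samples)
}

# brute-force interval membership oracle: is each point in any interval?
brute_overlap <- function(pos, start, end) {
  vapply(pos, function(p) any(p >= start & p <= end), logical(1))
}

# brute-force BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# printed LM/IM/HM count tables (ileum and colon) used as worked examples
ileum_counts <- list(
  promoter = list(nec = c(LM = 37570, IM = 67544, HM = 71628),
                  ctrl = c(LM = 37809, IM = 67963, HM = 70970),
                  chi = 5.12,
                  pct_nec = c(21.3, 38.2, 40.5), pct_ctrl = c(21.4, 38.5, 40.2)),
  cpg_island = list(nec = c(LM = 14248, IM = 6478, HM = 10611),
                    ctrl = c(LM = 14297, IM = 6496, HM = 10544),
                    chi = 0.32,
                    pct_nec = c(45.5, 20.7, 33.9), pct_ctrl = c(45.6, 20.7, 33.6)),
  exonic = list(nec = c(LM = 11252, IM = 105227, HM = 124986),
                ctrl = c(LM = 11276, IM = 108315, HM = 121874),
                chi = 83.9,
                pct_nec = c(4.7, 43.6, 51.8), pct_ctrl = c(4.7, 44.9, 50.5)),
  all = list(nec = c(LM = 205779, IM = 4378720, HM = 5074456),
             ctrl = c(LM = 208548, IM = 4618095, HM = 4832312),
             chi = 12306,
             pct_nec = c(2.1, 45.3, 52.5), pct_ctrl = c(2.2, 47.8, 50.0))
)

colon_counts <- list(
  enhancer = list(nec = c(LM = 913, IM = 5830, HM = 5006),
                  ctrl = c(LM = 1095, IM = 6339, HM = 4315),
                  chi = 89,
                  pct_nec = c(7.8, 49.6, 42.6), pct_ctrl = c(9.3, 54.0, 36.7)),
  all = list(nec = c(LM = 191444, IM = 4407199, HM = 5060312),
             ctrl = c(LM = 261637, IM = 5166249, HM = 4231069),
             chi = 145070,
             pct_nec = c(2.0, 45.6, 52.4), pct_ctrl = c(2.7, 53.5, 43.8))
)
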