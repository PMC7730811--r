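#' Simulation configuration for a synthetic WGBS + RNA-seq cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. Defaults describe
#' a colon-like contrast: two groups of epithelial samples whose CpG
#' methylation follows a trimodal beta mixture of low (LM), intermediate (IM)
#' and high (HM) methylation components, with NEC samples receiving a
#' logit-scale hypermethylation shift at a subset of sites, and RNA-seq
#' counts for a matching gene set with a fraction of genes differentially
#' expressed and a fraction of those coupled (anti-correlated) to promoter
#' hypermethylation.
#'
#' @param n_samples_per_group samples per condition (NEC and non-NEC); >= 2.
#' @param n_cpg number of CpG sites to simulate.
#' @param n_genes number of genes (0 allowed: purely intergenic genome).
#' @param genome_length genome size in bp (single synthetic chromosome).
#' @param coverage_mean mean per-CpG per-sample read depth (negative binomial).
#' @param coverage_dispersion negative-binomial size (shape) parameter of the
#'   coverage distribution; smaller = more dispersed.
#' @param lmimhm_weights_control probability triple over the (LM, IM, HM)
#'   mixture components used for sites outside the element classes that carry
#'   their own component weights (see [element_component_weights()]).
#' @param hyper_shift logit-scale increase in site mean methylation applied to
#'   NEC samples at shifted sites; >= 0.
#' @param frac_shifted_sites fraction of CpG sites (or of promoters when
#'   `shift_unit = "promoter"`) receiving the shift.
#' @param shift_unit `"site"`: shifted CpGs are a seeded random subset of all
#'   sites; `"promoter"`: a seeded random subset of promoters is shifted and
#'   every CpG inside those promoters receives the shift (regionally coherent
#'   truth for DMR benchmarking).
#' @param site_noise_kappa beta precision of per-sample methylation around the
#'   site mean (larger = less biological variation between samples).
#' @param de_frac fraction of genes with a true expression fold change.
#' @param de_lfc_mean mean absolute log2 fold change of DE genes.
#' @param coupling_frac fraction of DE genes whose expression is driven by
#'   (anti-correlated with) their promoter methylation.
#' @param seed RNG seed; every generator call is deterministic given the seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_annotation()], [simulate_methylation()],
#'   [simulate_expression()]
#' @export
sim_config <- function(n_samples_per_group = 10,
                       n_cpg = 20000,
                       n_genes = 500,
                       genome_length = 2e7,
                       coverage_mean = 15,
                       coverage_dispersion = 5,
                       lmimhm_weights_control = c(LM = 0.0138131359,
                                                  IM = 0.4623588073,
                                                  HM = 0.5238280568),
                       hyper_shift = 1.0,
                       frac_shifted_sites = 0.1,
                       shift_unit = c("site", "promoter"),
                       site_noise_kappa = 50,
                       de_frac = 0.1,
                       de_lfc_mean = 1.5,
                       coupling_frac = 0.5,
                       seed = 1L) {
  shift_unit <- match.arg(shift_unit)
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_cpg = as.integer(n_cpg),
    n_genes = as.integer(n_genes),
    genome_length = as.numeric(genome_length),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    lmimhm_weights_control = unname(lmimhm_weights_control),
    hyper_shift = hyper_shift,
    frac_shifted_sites = frac_shifted_sites,
    shift_unit = shift_unit,
    site_noise_kappa = site_noise_kappa,
    de_frac = de_frac,
    de_lfc_mean = de_lfc_mean,
    coupling_frac = coupling_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  w <- cfg$lmimhm_weights_control
  if (length(w) != 3L || any(w < 0) || any(w > 1))
    stop("lmimhm_weights_control must be three probabilities in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("lmimhm_weights_control must sum to 1 (within 1e-9); got ", sum(w))
  if (cfg$hyper_shift < 0) stop("hyper_shift must be >= 0")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (cfg$n_samples_per_group < 2L) stop("n_samples_per_group must be >= 2")
  if (cfg$n_cpg < 1L) stop("n_cpg must be >= 1")
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (cfg$genome_length < 1) stop("genome_length must be >= 1")
  if (cfg$frac_shifted_sites < 0 || cfg$frac_shifted_sites > 1)
    stop("frac_shifted_sites must be in [0, 1]")
  if (cfg$de_frac < 0 || cfg$de_frac > 1) stop("de_frac must be in [0, 1]")
  if (cfg$coupling_frac < 0 || cfg$coupling_frac > 1)
    stop("coupling_frac must be in [0, 1]")
  if (cfg$site_noise_kappa <= 0) stop("site_noise_kappa must be > 0")
  invisible(cfg)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}
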