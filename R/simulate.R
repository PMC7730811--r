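# Synthetic WGBS + RNA-seq cohort generator.
#
# The methylation model is a trimodal beta mixture: every CpG draws a
# component (LM, IM, HM), then a site mean m from that component's beta
# distribution; per-sample methylation varies around m with beta precision
# kappa; observed counts are Binomial(coverage, p) with negative-binomial
# coverage. NEC samples receive a logit-scale shift at a seeded subset of
# sites (or of whole promoters), which is the ground truth for differential
# methylation benchmarking.

# Beta parameters of the three mixture components (LM, IM, HM).
.component_betas <- list(
  LM = c(0.5, 8),
  IM = c(5, 5),
  HM = c(8, 0.5)
)

#' Per-element-class mixture component weights
#'
#' Component weights (over LM, IM, HM) used when a CpG falls in each genomic
#' element class. Values are calibrated so that the *realized* fraction of
#' sites below 20%, between 20 and 80%, and above 80% methylation matches the
#' class-specific proportions observed in non-NEC intestinal epithelium
#' (CpG islands and promoters strongly enriched for low methylation,
#' gene bodies and intergenic space dominated by intermediate/high):
#' the weights solve a 3x3 linear system against the class-leak matrix of
#' the three beta components.
#'
#' Sites in none of these classes (intergenic) use
#' `lmimhm_weights_control` from the configuration.
#'
#' @return A `data.table` with columns `element_class`, `w_LM`, `w_IM`, `w_HM`.
#' @export
element_component_weights <- function() {
  data.table(
    element_class = c("cgi", "shore", "promoter", "enhancer", "exon", "intron"),
    w_LM = c(0.4836677533, 0.1638941114, 0.2206170545, 0.0719857942,
             0.0411225416, 0.0115427543),
    w_IM = c(0.1608298774, 0.3265112869, 0.3583746397, 0.4907570672,
             0.4295677196, 0.4178186367),
    w_HM = c(0.3555023693, 0.5095946017, 0.4210083058, 0.4372571386,
             0.5293097388, 0.5706386090)
  )
}

#' Analytic LM/IM/HM class mass of a component-weight triple
#'
#' Given mixture component weights, returns the expected fraction of site
#' means falling below 0.2 (LM), in \[0.2, 0.8\] (IM), and above 0.8 (HM)
#' under the generator's beta components. Used as the exact reference for
#' the marginal-histogram invariant of the generator.
#'
#' @param w numeric triple of component weights (LM, IM, HM), summing to 1.
#' @return Named numeric triple `c(LM=, IM=, HM=)` of realized class masses.
#' @export
mixture_class_mass <- function(w) {
  stopifnot(length(w) == 3L, abs(sum(w) - 1) < 1e-6)
  M <- sapply(.component_betas, function(ab) {
    lm <- pbeta(0.2, ab[1], ab[2])
    hm <- 1 - pbeta(0.8, ab[1], ab[2])
    c(LM = lm, IM = 1 - lm - hm, HM = hm)
  })
  drop(M %*% as.numeric(w))
}

# Component weights per site given its priority element class.
.site_component_weights <- function(element_class, cfg) {
  ew <- element_component_weights()
  W <- matrix(rep(cfg$lmimhm_weights_control, each = length(element_class)),
              ncol = 3L)
  idx <- match(element_class, ew$element_class)
  hit <- !is.na(idx)
  W[hit, ] <- as.matrix(ew[idx[hit], .(w_LM, w_IM, w_HM)])
  W
}

# Gene packing geometry: each gene lives in its own slot with 2 kb flanks so
# promoters never overlap and never clip at the chromosome start.
.min_slot <- 12000
.max_gene_len <- 8000
.min_gene_len <- 2000

#' Simulate a genome annotation
#'
#' Places `n_genes` non-overlapping gene bodies (one synthetic chromosome,
#' one slot per gene with 2 kb flanks), partitions each into exons and
#' introns, derives strand-aware promoters (TSS-1500 to TSS+500), places CpG
#' islands at half of the promoters (601 bp centred on the TSS), builds 2 kb
#' CGI shores, drops 500 bp enhancers into a fraction of the intergenic
#' gaps, and labels the complement of genes and promoters intergenic.
#'
#' @param config a [sim_config()].
#' @return An `annotation_set`: list with `genes` (data.table `gene_id`,
#'   `chrom`, `strand`, `gene_start`, `gene_end`, `tss`), `elements` (named
#'   list of data.tables `chrom`, `start`, `end`, `strand`, `feature_id`
#'   for classes promoter, exon, intron, cgi, shore, enhancer, intergenic;
#'   1-based closed coordinates), `chrom`, and `genome_length`.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$genome_length
  chrom <- "chr1"

  empty_el <- data.table(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         feature_id = character())

  if (config$n_genes == 0L) {
    ann <- list(
      genes = data.table(gene_id = character(), chrom = character(),
                         strand = character(), gene_start = integer(),
                         gene_end = integer(), tss = integer()),
      elements = list(
        promoter = empty_el, exon = empty_el, intron = empty_el,
        cgi = empty_el, shore = empty_el, enhancer = empty_el,
        intergenic = data.table(chrom = chrom, start = 1L, end = as.integer(G),
                                strand = "*", feature_id = "intergenic_1")
      ),
      chrom = chrom, genome_length = G
    )
    class(ann) <- "annotation_set"
    return(ann)
  }

  slot <- floor(G / config$n_genes)
  if (slot < .min_slot) {
    stop("infeasible packing: genome_length/n_genes = ", slot,
         " bp per gene, but at least ", .min_slot,
         " bp are needed (gene body up to ", .max_gene_len,
         " bp plus 2 kb flanks for promoter and shore space)")
  }

  n <- config$n_genes
  slot_start <- (seq_len(n) - 1L) * slot + 1L
  glen <- sample(.min_gene_len:.max_gene_len, n, replace = TRUE)
  room <- slot - 4000L - glen
  gstart <- slot_start + 2000L + floor(runif(n) * (room + 1L))
  gend <- gstart + glen - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", gstart, gend)
  gene_id <- sprintf("gene%04d", seq_len(n))

  genes <- data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                      gene_start = as.integer(gstart),
                      gene_end = as.integer(gend), tss = as.integer(tss))

  promoters <- build_promoters(genes)

  # exon/intron partition: 1-4 exons per gene, alternating segments
  exon_list <- vector("list", n)
  intron_list <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(1:4, 1L)
    nseg <- 2L * k - 1L
    if (nseg == 1L || glen[i] <= nseg) {
      exon_list[[i]] <- data.table(start = gstart[i], end = gend[i],
                                   feature_id = gene_id[i])
      next
    }
    cuts <- sort(sample(seq_len(glen[i] - 1L), nseg - 1L))
    seg_start <- gstart[i] + c(0L, cuts)
    seg_end <- gstart[i] + c(cuts, glen[i]) - 1L
    is_exon <- seq_len(nseg) %% 2L == 1L
    exon_list[[i]] <- data.table(start = seg_start[is_exon],
                                 end = seg_end[is_exon],
                                 feature_id = gene_id[i])
    intron_list[[i]] <- data.table(start = seg_start[!is_exon],
                                   end = seg_end[!is_exon],
                                   feature_id = gene_id[i])
  }
  exons <- rbindlist(exon_list)
  introns <- rbindlist(intron_list)
  mk_el <- function(d, str) {
    if (is.null(d) || nrow(d) == 0L) return(empty_el)
    data.table(chrom = chrom, start = as.integer(d$start),
               end = as.integer(d$end), strand = str,
               feature_id = d$feature_id)
  }
  exon_el <- mk_el(exons, strand[match(exons$feature_id, gene_id)])
  intron_el <- if (nrow(introns)) {
    mk_el(introns, strand[match(introns$feature_id, gene_id)])
  } else empty_el

  # CGIs at half of the promoters, centred on the TSS
  has_cgi <- sample(c(TRUE, FALSE), n, replace = TRUE)
  cgi <- if (any(has_cgi)) {
    data.table(chrom = chrom,
               start = as.integer(tss[has_cgi] - 300L),
               end = as.integer(tss[has_cgi] + 300L),
               strand = "*",
               feature_id = sprintf("cgi_%s", gene_id[has_cgi]))
  } else empty_el
  shores <- build_shores(cgi, genome_length = G)

  # enhancers: 500 bp islands at the start of a random 30% of slots,
  # guaranteed clear of gene bodies and promoters by the 2 kb flank
  enh_slot <- which(runif(n) < 0.3)
  enhancer <- if (length(enh_slot)) {
    data.table(chrom = chrom,
               start = as.integer(slot_start[enh_slot]),
               end = as.integer(slot_start[enh_slot] + 499L),
               strand = "*",
               feature_id = sprintf("enh%04d", seq_along(enh_slot)))
  } else empty_el

  # intergenic = genome minus (gene bodies union promoters)
  occupied <- interval_reduce(rbind(
    data.table(start = genes$gene_start, end = genes$gene_end),
    data.table(start = promoters$start, end = promoters$end)
  ))
  inter <- interval_complement(occupied, G)
  intergenic <- if (nrow(inter)) {
    data.table(chrom = chrom, start = inter$start, end = inter$end,
               strand = "*",
               feature_id = sprintf("intergenic_%d", seq_len(nrow(inter))))
  } else empty_el

  ann <- list(
    genes = genes,
    elements = list(promoter = promoters, exon = exon_el, intron = intron_el,
                    cgi = cgi, shore = shores, enhancer = enhancer,
                    intergenic = intergenic),
    chrom = chrom, genome_length = G
  )
  class(ann) <- "annotation_set"
  ann
}

#' Simulate per-CpG methylation counts for a two-group cohort
#'
#' CpG positions are placed with promoter enrichment (a quarter of sites
#' inside promoters when promoters exist, mimicking CpG density at gene
#' starts), assigned an element class by priority
#' (CGI > shore > promoter > enhancer > exon > intron > intergenic), and
#' given a mixture component by the class-specific LM/IM/HM weights. The
#' NEC group receives `hyper_shift` on the logit scale at the shifted
#' subset (seeded shuffle of sites, or of promoters when
#' `shift_unit = "promoter"`).
#'
#' @param config a [sim_config()].
#' @param annotation an `annotation_set` from [simulate_annotation()].
#' @param tissue tissue label for the sample sheet (`"colon"` or `"ileum"`).
#' @param noise_seed seed of the observation layer (per-sample beta draws,
#'   coverage and read counts). Defaults to a value derived from
#'   `config$seed`, so a config is fully deterministic; passing a different
#'   `noise_seed` with the same config reuses the identical ground truth
#'   (components, site means, shifted set) under independent measurement
#'   noise -- the paired-tissue design.
#' @return A `meth_set` (see [meth_set()]) with an extra `truth` element:
#'   `truth$sites` (per-CpG `component`, `element_class`, `m_control`,
#'   `m_nec`, `shifted`, `true_diff`), `truth$promoters` (per-gene `shifted`,
#'   `n_cpg_promoter`, `delta_true`), and `truth$true_rates` (the latent
#'   per-sample methylation probabilities).
#' @export
simulate_methylation <- function(config, annotation, tissue = "colon",
                                 noise_seed = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(annotation, "annotation_set"))
  if (is.null(noise_seed)) noise_seed <- config$seed + 1L
  set.seed(config$seed + 1L)

  G <- annotation$genome_length
  n_cpg <- config$n_cpg
  prom <- annotation$elements$promoter

  # positions: ~25% in promoters (if any), rest uniform; unique, sorted
  pos <- integer(0)
  if (nrow(prom) > 0L) {
    n_prom_sites <- round(0.25 * n_cpg)
    plen <- prom$end - prom$start + 1L
    offsets <- sample.int(sum(plen), min(n_prom_sites, sum(plen)))
    cum <- cumsum(plen)
    pi_idx <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos <- prom$start[pi_idx] + (offsets - 1L - c(0L, cum)[pi_idx])
  }
  need <- n_cpg - length(pos)
  pos <- unique(c(pos, sample.int(G, min(need * 2L + 10L, G))))
  while (length(pos) < n_cpg) {
    pos <- unique(c(pos, sample.int(G, min(n_cpg, G))))
  }
  pos <- sort(pos[seq_len(n_cpg)])
  sites <- data.table(cpg_id = sprintf("cpg%07d", seq_len(n_cpg)),
                      chrom = annotation$chrom, pos = as.integer(pos))

  sa <- annotate_sites(sites, annotation)
  element_class <- priority_class(sa)

  # mixture component and site mean methylation
  W <- .site_component_weights(element_class, config)
  u <- runif(n_cpg)
  comp <- 1L + (u > W[, 1]) + (u > W[, 1] + W[, 2])
  comp_lab <- c("LM", "IM", "HM")[comp]
  ab <- do.call(rbind, .component_betas)[comp, , drop = FALSE]
  m <- rbeta(n_cpg, ab[, 1], ab[, 2])
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)

  # shifted subset
  shifted <- rep(FALSE, n_cpg)
  shifted_genes <- character(0)
  if (config$frac_shifted_sites > 0 && config$hyper_shift >= 0) {
    if (config$shift_unit == "site") {
      ord <- sample.int(n_cpg)
      k <- ceiling(config$frac_shifted_sites * n_cpg)
      shifted[ord[seq_len(k)]] <- TRUE
    } else {
      ng <- nrow(annotation$genes)
      if (ng > 0L) {
        # hypermethylation targets promoters that are not already
        # saturated (mean site methylation < 0.5): the observed NEC
        # pattern is low/intermediate sites moving toward high, and a
        # logit shift on an already-high promoter is invisible on the
        # rate scale. Eligible promoters are shuffled first; the count
        # ceiling(frac * n_genes) stays deterministic by topping up from
        # the remaining genes if too few are eligible.
        pm <- data.table(gene = sa$promoter_gene, m = m)[!is.na(gene)]
        pmean <- pm[, .(mu = mean(m)), by = gene]
        eligible <- pmean[mu < 0.5, gene]
        ord_all <- annotation$genes$gene_id[sample.int(ng)]
        ord <- c(ord_all[ord_all %in% eligible],
                 ord_all[!ord_all %in% eligible])
        k <- ceiling(config$frac_shifted_sites * ng)
        shifted_genes <- ord[seq_len(k)]
        shifted <- sa$promoter & sa$promoter_gene %in% shifted_genes
      }
    }
  }
  if (config$hyper_shift == 0) shifted[] <- FALSE
  m_nec <- ifelse(shifted, plogis(qlogis(m) + config$hyper_shift), m)

  # samples
  npg <- config$n_samples_per_group
  samples <- data.table(
    sample_id = c(sprintf("%s_ctrl_%02d", tissue, seq_len(npg)),
                  sprintf("%s_nec_%02d", tissue, seq_len(npg))),
    tissue = tissue,
    condition = rep(c("non-NEC", "NEC"), each = npg)
  )
  ns <- nrow(samples)
  is_nec <- samples$condition == "NEC"

  set.seed(noise_seed)
  kappa <- config$site_noise_kappa
  mu_mat <- matrix(m, n_cpg, ns)
  mu_mat[, is_nec] <- m_nec
  p <- matrix(rbeta(n_cpg * ns, kappa * mu_mat, kappa * (1 - mu_mat)),
              n_cpg, ns)
  cov <- matrix(rnbinom(n_cpg * ns, size = config$coverage_dispersion,
                        mu = config$coverage_mean), n_cpg, ns)
  meth <- matrix(rbinom(n_cpg * ns, cov, p), n_cpg, ns)
  dimnames(meth) <- dimnames(cov) <- list(sites$cpg_id, samples$sample_id)

  truth_sites <- data.table(
    cpg_id = sites$cpg_id, chrom = sites$chrom, pos = sites$pos,
    element_class = element_class, component = comp_lab,
    m_control = m, m_nec = m_nec, shifted = shifted,
    true_diff = m_nec - m
  )
  truth_prom <- if (nrow(annotation$genes) > 0L) {
    pg <- sa$promoter_gene
    dt <- data.table(gene_id = pg, true_diff = truth_sites$true_diff)[!is.na(pg)]
    agg <- dt[, .(n_cpg_promoter = .N, delta_true = mean(true_diff)),
              by = gene_id]
    out <- merge(annotation$genes[, .(gene_id)], agg, by = "gene_id",
                 all.x = TRUE)
    out[is.na(n_cpg_promoter), `:=`(n_cpg_promoter = 0L, delta_true = 0)]
    out[, shifted := gene_id %in% shifted_genes]
    if (config$shift_unit == "site") {
      out[, shifted := delta_true > 0]
    }
    out[]
  } else {
    data.table(gene_id = character(), n_cpg_promoter = integer(),
               delta_true = numeric(), shifted = logical())
  }

  ms <- meth_set(meth, cov, sites, samples)
  ms$truth <- list(sites = truth_sites, promoters = truth_prom,
                   true_rates = p)
  ms
}

#' Simulate RNA-seq counts coupled to promoter methylation
#'
#' Generates negative-binomial counts for the annotated genes. A seeded
#' shuffle marks the first `ceiling(de_frac * n_genes)` genes as truly
#' differentially expressed; of those, `ceiling(coupling_frac * n_de)` are
#' coupled genes drawn preferentially from genes with a shifted
#' (hypermethylated) promoter, whose per-sample log2 expression tracks the
#' latent promoter methylation with a negative slope (so hypermethylation
#' in NEC reduces expression). Remaining DE genes receive a plain group
#' fold change with random sign. Library sizes vary by a log-normal factor
#' (sdlog 0.3, i.e. typically within ~2-fold).
#'
#' @param config a [sim_config()].
#' @param meth a `meth_set` from [simulate_methylation()] (supplies the
#'   per-sample latent promoter methylation and the shifted-promoter truth).
#' @param annotation the `annotation_set` the methylation was simulated on.
#' @param noise_seed seed of the count-drawing layer (see
#'   [simulate_methylation()]); DE/coupled gene selection stays tied to
#'   `config$seed`.
#' @return List of class `expr_sim`: `counts` (gene x sample integer
#'   matrix), `samples` (the methylation sample sheet), and `truth`
#'   (data.table `gene_id`, `is_de`, `coupled`, `lfc_true`).
#' @export
simulate_expression <- function(config, meth, annotation,
                                noise_seed = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(annotation, "annotation_set"))
  if (nrow(annotation$genes) == 0L)
    stop("simulate_expression needs at least one gene in the annotation")
  if (is.null(noise_seed)) noise_seed <- config$seed + 2L
  set.seed(config$seed + 2L)

  genes <- annotation$genes$gene_id
  ng <- length(genes)
  samples <- meth$samples
  ns <- nrow(samples)
  is_nec <- samples$condition == "NEC"

  base <- rnorm(ng, mean = 5, sd = 1.5)
  n_de <- ceiling(config$de_frac * ng)
  ord <- sample.int(ng)

  # coupled genes are drawn from shifted-promoter genes (seeded shuffle
  # order), so coupling holds by construction; if the methylation truth has
  # fewer shifted promoters than requested, the coupled set is smaller and
  # the difference reverts to plain DE genes
  shifted_genes <- meth$truth$promoters[shifted == TRUE, gene_id]
  n_cp <- if (n_de > 0L) ceiling(config$coupling_frac * n_de) else 0L
  cand <- ord[genes[ord] %in% shifted_genes]
  coupled_idx <- head(cand, n_cp)
  plain_idx <- head(base::setdiff(ord, coupled_idx),
                    n_de - length(coupled_idx))
  de_idx <- c(coupled_idx, plain_idx)

  lfc <- numeric(ng)
  if (length(plain_idx)) {
    sgn <- sample(c(-1, 1), length(plain_idx), replace = TRUE)
    lfc[plain_idx] <- sgn * rgamma(length(plain_idx), shape = 4,
                                   rate = 4 / config$de_lfc_mean)
  }

  # log2 mean per gene/sample
  logmu <- matrix(base, ng, ns) +
    outer(lfc, as.numeric(is_nec))

  if (length(coupled_idx)) {
    pg_map <- promoter_site_index(meth, annotation)
    for (i in coupled_idx) {
      g <- genes[i]
      sidx <- pg_map[[g]]
      if (is.null(sidx) || length(sidx) == 0L) {
        lfc[i] <- -rgamma(1, shape = 4, rate = 4 / config$de_lfc_mean)
        logmu[i, ] <- base[i] + lfc[i] * as.numeric(is_nec)
        next
      }
      mbar <- colMeans(meth$truth$true_rates[sidx, , drop = FALSE])
      lz <- qlogis(pmin(pmax(mbar, 0.01), 0.99))
      sep <- mean(lz[is_nec]) - mean(lz[!is_nec])
      if (sep < 0.05) {
        # promoter not effectively hypermethylated in the latent rates
        # (e.g. saturated sites): keep the truth guarantee with a plain
        # negative fold change instead of methylation tracking
        lfc[i] <- -rgamma(1, shape = 4, rate = 4 / config$de_lfc_mean)
        logmu[i, ] <- base[i] + lfc[i] * as.numeric(is_nec)
        next
      }
      # slope calibrated per gene so the realized group log2 fold change
      # of a coupled gene is -de_lfc_mean (the gene tracks its promoter's
      # logit methylation sample by sample, scaled to that effect size)
      slope <- config$de_lfc_mean / max(sep, 0.25)
      logmu[i, ] <- base[i] - slope * (lz - mean(lz))
      lfc[i] <- mean(logmu[i, is_nec]) - mean(logmu[i, !is_nec])
    }
  }

  set.seed(noise_seed)
  sf <- rlnorm(ns, 0, 0.3)
  mu <- 2^logmu * rep(sf, each = ng)
  counts <- matrix(rnbinom(ng * ns, size = 20, mu = mu), ng, ns,
                   dimnames = list(genes, samples$sample_id))

  is_de <- seq_len(ng) %in% de_idx
  coupled <- seq_len(ng) %in% coupled_idx
  truth <- data.table(gene_id = genes, is_de = is_de, coupled = coupled,
                      lfc_true = ifelse(is_de, lfc, 0))

  out <- list(counts = counts, samples = samples, truth = truth)
  class(out) <- "expr_sim"
  out
}

# index of site rows per promoter gene
promoter_site_index <- function(meth, annotation) {
  sa <- annotate_sites(meth$sites, annotation)
  pg <- sa$promoter_gene
  split(which(!is.na(pg)), pg[!is.na(pg)])
}

#' Simulate a complete tissue cohort
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_methylation()] and [simulate_expression()] with one config.
#'
#' @param config a [sim_config()].
#' @param tissue tissue label.
#' @param noise_seed optional observation-layer seed (see
#'   [simulate_methylation()]).
#' @return List with `annotation`, `meth`, `expr`.
#' @export
simulate_cohort <- function(config, tissue = "colon", noise_seed = NULL) {
  ann <- simulate_annotation(config)
  meth <- simulate_methylation(config, ann, tissue = tissue,
                               noise_seed = noise_seed)
  expr <- simulate_expression(config, meth, ann,
                              noise_seed = if (is.null(noise_seed)) NULL
                                           else noise_seed + 1L)
  list(annotation = ann, meth = meth, expr = expr)
}
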