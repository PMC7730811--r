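# Genomic element annotation. All internal coordinates are 1-based, fully
# closed intervals (a single CpG has start == end); BED on disk is 0-based
# half-open and converted at the I/O boundary.

# ---- interval algebra (single chromosome), thin wrappers over IRanges ----

interval_reduce <- function(d) {
  if (nrow(d) == 0L) return(data.table(start = integer(), end = integer()))
  r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
  data.table(start = IRanges::start(r), end = IRanges::end(r))
}

interval_complement <- function(d, genome_length) {
  full <- IRanges::IRanges(1L, as.integer(genome_length))
  if (nrow(d) == 0L) {
    return(data.table(start = 1L, end = as.integer(genome_length)))
  }
  g <- IRanges::setdiff(full, IRanges::IRanges(d$start, d$end))
  data.table(start = IRanges::start(g), end = IRanges::end(g))
}

interval_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(data.table(start = integer(), end = integer()))
  if (nrow(b) == 0L) return(interval_reduce(a))
  r <- IRanges::setdiff(IRanges::IRanges(a$start, a$end),
                        IRanges::IRanges(b$start, b$end))
  data.table(start = IRanges::start(r), end = IRanges::end(r))
}

# ---- promoters ----

#' Build strand-aware promoter intervals
#'
#' The promoter of a gene spans 1500 bp upstream to 500 bp downstream of its
#' transcription start site: \[TSS-1500, TSS+500\] on the + strand and
#' \[TSS-500, TSS+1500\] on the - strand, clipped at position 1. Each
#' promoter covers 2001 bp (both endpoints included) unless clipped.
#'
#' @param genes data.table/data.frame with columns `gene_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `tss`.
#' @return data.table with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_id` (the gene id), one row per gene.
#' @export
build_promoters <- function(genes) {
  genes <- as.data.table(genes)
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")]
    stop("promoter undefined for gene(s) without strand: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  up <- ifelse(genes$strand == "+", genes$tss - 1500L, genes$tss - 500L)
  dn <- ifelse(genes$strand == "+", genes$tss + 500L, genes$tss + 1500L)
  data.table(chrom = genes$chrom,
             start = as.integer(pmax(up, 1L)),
             end = as.integer(dn),
             strand = genes$strand,
             feature_id = genes$gene_id)
}

#' Build CpG-island shores
#'
#' Shores are the 2 kb flanks on each side of a CpG island. Bases falling
#' inside any CGI are removed, shores from adjacent CGIs are merged, and
#' intervals are clipped at position 1 (and at `genome_length` if given).
#'
#' @param cgis data.table with columns `chrom`, `start`, `end` (one
#'   chromosome at a time or with a `chrom` column; processed per chromosome).
#' @param width shore width per flank in bp (default 2000).
#' @param genome_length optional upper clip.
#' @return data.table `chrom`, `start`, `end`, `strand` (`"*"`),
#'   `feature_id`.
#' @export
build_shores <- function(cgis, width = 2000L, genome_length = NULL) {
  cgis <- as.data.table(cgis)
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_id = character())
  if (nrow(cgis) == 0L) return(empty)
  out <- lapply(split(cgis, cgis$chrom), function(cc) {
    flanks <- rbind(
      data.table(start = cc$start - width, end = cc$start - 1L),
      data.table(start = cc$end + 1L, end = cc$end + width)
    )
    flanks[, start := pmax(start, 1L)]
    if (!is.null(genome_length)) flanks[, end := pmin(end, as.integer(genome_length))]
    flanks <- flanks[start <= end]
    sh <- interval_setdiff(flanks, cc[, .(start, end)])
    if (nrow(sh) == 0L) return(NULL)
    data.table(chrom = cc$chrom[1L], start = sh$start, end = sh$end,
               strand = "*", feature_id = NA_character_)
  })
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0L) return(empty)
  setorder(out, chrom, start)
  out[, feature_id := sprintf("shore_%d", seq_len(.N))]
  out[]
}

# ---- site annotation ----

.element_classes <- c("promoter", "exon", "intron", "cgi", "shore",
                      "enhancer", "intergenic")

#' Annotate CpG sites with genomic element membership
#'
#' Every site gets a logical membership flag per element class (a site may
#' belong to several classes, e.g. promoter and CGI), the identity of the
#' gene whose promoter contains it (lexicographically smallest gene id when
#' promoters overlap), and the nearest gene with a signed distance: 0 inside
#' the gene body, negative upstream of it on the gene's strand, positive
#' downstream. Sites on chromosomes absent from the annotation are flagged
#' intergenic with no nearest feature (a warning is issued).
#'
#' @param sites data.table with columns `cpg_id`, `chrom`, `pos`, sorted by
#'   (chrom, pos).
#' @param annotation an `annotation_set` (or a list with `elements` and
#'   `genes` in the same shape).
#' @return data.table with `cpg_id`, `chrom`, `pos`, one logical column per
#'   element class, `promoter_gene`, `nearest_feature_id`,
#'   `dist_to_feature`, `feature_strand`. The `intergenic` flag is TRUE iff
#'   promoter, exon and intron are all FALSE.
#' @export
annotate_sites <- function(sites, annotation) {
  sites <- as.data.table(sites)
  stopifnot(all(c("cpg_id", "chrom", "pos") %in% names(sites)))
  out <- sites[, .(cpg_id, chrom, pos)]

  flag_classes <- base::setdiff(.element_classes, "intergenic")
  for (cl in flag_classes) {
    el <- annotation$elements[[cl]]
    set(out, j = cl, value = overlaps_any(sites, el))
  }
  out[, intergenic := !(promoter | exon | intron)]

  out[, promoter_gene := overlap_feature(sites, annotation$elements$promoter)]

  # nearest gene and signed distance
  genes <- annotation$genes
  if (!is.null(genes) && nrow(genes) > 0L) {
    nf <- nearest_gene(sites, genes)
    out[, nearest_feature_id := nf$feature_id]
    out[, dist_to_feature := nf$dist]
    out[, feature_strand := nf$strand]
  } else {
    out[, nearest_feature_id := NA_character_]
    out[, dist_to_feature := NA_integer_]
    out[, feature_strand := NA_character_]
  }

  known <- unique(unlist(lapply(annotation$elements,
                                function(e) unique(e$chrom))))
  missing_chrom <- base::setdiff(unique(sites$chrom), known)
  if (length(missing_chrom)) {
    warning("sites on chromosome(s) absent from annotation flagged intergenic: ",
            paste(missing_chrom, collapse = ", "))
  }
  out[]
}

# TRUE for sites overlapping any interval of el
overlaps_any <- function(sites, el) {
  if (is.null(el) || nrow(el) == 0L) return(rep(FALSE, nrow(sites)))
  q <- data.table(chrom = sites$chrom, start = sites$pos, end = sites$pos)
  s <- data.table(chrom = el$chrom, start = el$start, end = el$end)
  setkey(s, chrom, start, end)
  hit <- foverlaps(q, s, type = "any", which = TRUE, nomatch = NULL)
  res <- rep(FALSE, nrow(sites))
  res[unique(hit$xid)] <- TRUE
  res
}

# feature_id of containing interval (lexicographically smallest on ties)
overlap_feature <- function(sites, el) {
  if (is.null(el) || nrow(el) == 0L) return(rep(NA_character_, nrow(sites)))
  q <- data.table(chrom = sites$chrom, start = sites$pos, end = sites$pos)
  s <- data.table(chrom = el$chrom, start = el$start, end = el$end,
                  feature_id = el$feature_id)
  setkey(s, chrom, start, end)
  hit <- foverlaps(q, s, type = "any", which = TRUE, nomatch = NULL)
  if (nrow(hit) == 0L) return(rep(NA_character_, nrow(sites)))
  hit[, fid := s$feature_id[yid]]
  best <- hit[order(xid, fid)][, .(fid = fid[1L]), by = xid]
  res <- rep(NA_character_, nrow(sites))
  res[best$xid] <- best$fid
  res
}

# nearest gene body with signed distance (0 inside; negative upstream on the
# gene's strand); ties on |distance| broken by lexicographic gene_id
nearest_gene <- function(sites, genes) {
  res <- data.table(feature_id = rep(NA_character_, nrow(sites)),
                    dist = rep(NA_integer_, nrow(sites)),
                    strand = rep(NA_character_, nrow(sites)))
  for (ch in unique(sites$chrom)) {
    gi <- genes[genes$chrom == ch, ]
    si <- which(sites$chrom == ch)
    if (nrow(gi) == 0L || length(si) == 0L) next
    gi <- gi[order(gi$gene_id), ]
    pos <- sites$pos[si]
    ord <- order(gi$gene_start)
    disjoint <- nrow(gi) == 1L ||
      all(gi$gene_end[ord][-nrow(gi)] < gi$gene_start[ord][-1L])
    if (disjoint) {
      # sorted non-overlapping genes: the nearest is either the last gene
      # starting at or before the site or the next one; ties on |distance|
      # go to the lexicographically smaller gene_id
      gs <- gi$gene_start[ord]; ge <- gi$gene_end[ord]
      k <- findInterval(pos, gs)
      cand1 <- ifelse(k >= 1L, ord[pmax(k, 1L)], NA_integer_)
      cand2 <- ifelse(k < nrow(gi), ord[pmin(k + 1L, nrow(gi))], NA_integer_)
      gap <- function(j) {
        out <- rep(Inf, length(pos))
        okj <- !is.na(j)
        out[okj] <- pmax(gi$gene_start[j[okj]] - pos[okj], 0L) +
          pmax(pos[okj] - gi$gene_end[j[okj]], 0L)
        out
      }
      d1 <- gap(cand1); d2 <- gap(cand2)
      id1 <- ifelse(is.na(cand1), NA, gi$gene_id[cand1])
      id2 <- ifelse(is.na(cand2), NA, gi$gene_id[cand2])
      take2 <- d2 < d1 | (d2 == d1 & !is.na(id2) & !is.na(id1) & id2 < id1)
      take2[is.na(take2)] <- FALSE
      best_j <- ifelse(take2, cand2, cand1)
      best_d <- ifelse(take2, d2, d1)
    } else {
      # general case: O(n_sites x n_genes) scan vectorized over genes
      best_d <- rep(Inf, length(pos)); best_j <- rep(NA_integer_, length(pos))
      for (j in seq_len(nrow(gi))) {
        d <- pmax(gi$gene_start[j] - pos, 0L) + pmax(pos - gi$gene_end[j], 0L)
        upd <- d < best_d
        best_d[upd] <- d[upd]; best_j[upd] <- j
      }
    }
    gs <- gi$gene_start[best_j]; ge <- gi$gene_end[best_j]
    st <- gi$strand[best_j]
    inside <- pos >= gs & pos <= ge
    sgn <- ifelse(inside, 0L,
                  ifelse(st == "+",
                         ifelse(pos < gs, pos - gs, pos - ge),
                         ifelse(pos > ge, ge - pos, gs - pos)))
    res$feature_id[si] <- gi$gene_id[best_j]
    res$dist[si] <- as.integer(sgn)
    res$strand[si] <- gi$strand[best_j]
  }
  res
}

#' Priority element class of annotated sites
#'
#' Collapses the multi-membership flags of [annotate_sites()] to a single
#' class per site with priority CGI > shore > promoter > enhancer > exon >
#' intron > intergenic (used by the generator to pick mixture weights and
#' by stratified summaries).
#'
#' @param site_annotation output of [annotate_sites()].
#' @return character vector of class labels.
#' @export
priority_class <- function(site_annotation) {
  sa <- site_annotation
  cl <- rep("intergenic", nrow(sa))
  cl[sa$intron] <- "intron"
  cl[sa$exon] <- "exon"
  cl[sa$enhancer] <- "enhancer"
  cl[sa$promoter] <- "promoter"
  cl[sa$shore] <- "shore"
  cl[sa$cgi] <- "cgi"
  cl
}
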