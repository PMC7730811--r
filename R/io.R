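# Containers and on-disk formats. Methylation travels as Bismark
# coverage-style TSVs (chrom, start, end, methylation%, count_methylated,
# count_unmethylated; 1-based, start == end for a CpG), annotations as BED6
# (0-based half-open on disk, 1-based closed in memory), expression as a
# gene-by-sample count TSV, sample metadata as a CSV.

#' Per-CpG methylation count container
#'
#' Holds methylated and total read-count matrices (sites x samples), the
#' site coordinates and the sample sheet. This is the atomic WGBS
#' observation unit consumed by every downstream stage.
#'
#' @param meth integer matrix of methylated read counts (sites x samples).
#' @param cov integer matrix of total coverage, same dim as `meth`.
#' @param sites data.table `cpg_id`, `chrom`, `pos` (1-based), sorted.
#' @param samples data.table `sample_id`, `tissue` (`colon`/`ileum`),
#'   `condition` (`NEC`/`non-NEC`), rows matching the matrix columns.
#' @return An object of class `meth_set`.
#' @export
meth_set <- function(meth, cov, sites, samples) {
  stopifnot(is.matrix(meth), is.matrix(cov),
            all(dim(meth) == dim(cov)),
            nrow(meth) == nrow(sites), ncol(meth) == nrow(samples))
  if (any(meth > cov)) stop("methylated count exceeds coverage")
  if (any(meth < 0) || any(cov < 0)) stop("negative counts")
  samples <- as.data.table(samples)
  stopifnot(all(samples$condition %in% c("NEC", "non-NEC")))
  x <- list(meth = meth, cov = cov, sites = as.data.table(sites),
            samples = samples)
  class(x) <- "meth_set"
  x
}

#' @export
print.meth_set <- function(x, ...) {
  cat("meth_set:", nrow(x$sites), "CpG sites x", nrow(x$samples),
      "samples (", sum(x$samples$condition == "NEC"), "NEC /",
      sum(x$samples$condition == "non-NEC"), "non-NEC )\n")
  invisible(x)
}

#' Per-site per-sample methylation rates
#'
#' @param ms a `meth_set`.
#' @return numeric matrix of `meth/cov`; `NA` where coverage is zero.
#' @export
meth_rates <- function(ms) {
  r <- ms$meth / ms$cov
  r[ms$cov == 0] <- NA_real_
  r
}

# ---- Bismark coverage files ----

#' Write / read Bismark coverage-style files
#'
#' One TSV per sample with columns chrom, start, end, methylation percent,
#' count methylated, count unmethylated (no header), plus a sample sheet
#' CSV. Zero-coverage sites are written with 0% methylation.
#'
#' @param ms a `meth_set`.
#' @param dir output directory (created if needed).
#' @return `write_bismark_cov` returns the directory invisibly;
#'   `read_bismark_cov` returns a `meth_set`. Sites absent from a sample's
#'   file get zero coverage.
#' @export
write_bismark_cov <- function(ms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(nrow(ms$samples))) {
    m <- ms$meth[, j]; cv <- ms$cov[, j]
    d <- data.table(chrom = ms$sites$chrom, start = ms$sites$pos,
                    end = ms$sites$pos,
                    pct = ifelse(cv > 0, 100 * m / cv, 0),
                    count_m = m, count_u = cv - m)
    fwrite(d, file.path(dir, paste0(ms$samples$sample_id[j], ".cov.tsv")),
           sep = "\t", col.names = FALSE)
  }
  write_sample_sheet(ms$samples, file.path(dir, "samples.csv"))
  invisible(dir)
}

#' @rdname write_bismark_cov
#' @export
read_bismark_cov <- function(dir) {
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  per <- lapply(samples$sample_id, function(sid) {
    f <- file.path(dir, paste0(sid, ".cov.tsv"))
    d <- fread(f, col.names = c("chrom", "start", "end", "pct",
                                "count_m", "count_u"))
    d[, .(chrom, pos = start, count_m, count_u)]
  })
  sites <- unique(rbindlist(per)[, .(chrom, pos)])
  setorder(sites, chrom, pos)
  sites[, cpg_id := sprintf("cpg%07d", seq_len(.N))]
  setcolorder(sites, c("cpg_id", "chrom", "pos"))
  n <- nrow(sites); ns <- nrow(samples)
  meth <- matrix(0L, n, ns); cov <- matrix(0L, n, ns)
  key <- paste(sites$chrom, sites$pos)
  for (j in seq_len(ns)) {
    d <- per[[j]]
    i <- match(paste(d$chrom, d$pos), key)
    meth[i, j] <- d$count_m
    cov[i, j] <- d$count_m + d$count_u
  }
  dimnames(meth) <- dimnames(cov) <- list(sites$cpg_id, samples$sample_id)
  meth_set(meth, cov, sites, samples)
}

# ---- sample sheet ----

#' Write / read the sample sheet (sample_id, tissue, condition)
#' @param samples data.table with `sample_id`, `tissue`, `condition`.
#' @param path CSV path.
#' @return the samples table (invisibly for the writer).
#' @export
write_sample_sheet <- function(samples, path) {
  fwrite(as.data.table(samples)[, .(sample_id, tissue, condition)], path)
  invisible(samples)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  d <- fread(path, colClasses = "character")
  stopifnot(all(c("sample_id", "tissue", "condition") %in% names(d)))
  d
}

# ---- BED6 ----

#' Write / read an element class as BED6
#'
#' On disk BED is 0-based half-open; in memory intervals are 1-based closed.
#' The conversion is `start_bed = start - 1`, `end_bed = end`.
#'
#' @param el data.table `chrom`, `start`, `end`, `strand`, `feature_id`.
#' @param path BED file path.
#' @return `read_bed6` returns the in-memory 1-based closed data.table.
#' @export
write_bed6 <- function(el, path) {
  d <- data.table(chrom = el$chrom, start = el$start - 1L, end = el$end,
                  name = el$feature_id, score = 0L,
                  strand = ifelse(el$strand %in% c("+", "-"), el$strand, "."))
  fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  d <- fread(path, header = FALSE,
             col.names = c("chrom", "start", "end", "name", "score", "strand"))
  data.table(chrom = as.character(d$chrom),
             start = as.integer(d$start + 1L),
             end = as.integer(d$end),
             strand = ifelse(d$strand %in% c("+", "-"), d$strand, "*"),
             feature_id = as.character(d$name))
}

#' Write a full annotation set (BED6 per class + gene table TSV)
#' @param ann an `annotation_set`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(ann$elements)) {
    write_bed6(ann$elements[[cl]], file.path(dir, paste0(cl, ".bed")))
  }
  fwrite(ann$genes, file.path(dir, "genes.tsv"), sep = "\t")
  invisible(dir)
}

#' Read an annotation set written by [write_annotation()]
#' @param dir directory containing `<class>.bed` files and `genes.tsv`.
#' @param genome_length genome size (needed for interval complements).
#' @return an `annotation_set`.
#' @export
read_annotation <- function(dir, genome_length) {
  beds <- list.files(dir, pattern = "\\.bed$")
  elements <- lapply(beds, function(f) read_bed6(file.path(dir, f)))
  names(elements) <- sub("\\.bed$", "", beds)
  genes <- fread(file.path(dir, "genes.tsv"))
  ann <- list(genes = genes, elements = elements,
              chrom = if (nrow(genes)) genes$chrom[1] else "chr1",
              genome_length = genome_length)
  class(ann) <- "annotation_set"
  ann
}

# ---- expression counts ----

#' Write / read a gene-by-sample count matrix as TSV
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path TSV path.
#' @return `read_counts` returns the matrix.
#' @export
write_counts <- function(counts, path) {
  d <- data.table(gene_id = rownames(counts))
  d <- cbind(d, as.data.table(counts))
  fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  d <- fread(path)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}
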