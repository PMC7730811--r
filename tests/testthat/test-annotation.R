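# Promoter construction, shore arithmetic, and site-to-element annotation
# against brute-force oracles.

library(data.table)

test_that("promoters follow the strand-aware TSS-1500/+500 definition", {
  genes <- data.table(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      strand = c("+", "-", "+"),
                      tss = c(100000L, 100000L, 800L))
  p <- build_promoters(genes)
  expect_equal(p$start, c(98500L, 99500L, 1L))
  expect_equal(p$end, c(100500L, 101500L, 1300L))
  # 2001 bp when unclipped
  expect_equal(p$end[1] - p$start[1] + 1L, 2001L)
  expect_error(build_promoters(data.table(gene_id = "gX", chrom = "chr1",
                                          strand = "*", tss = 500L)),
               "strand")
})

test_that("shores are trimmed 2 kb flanks, merged between nearby CGIs, clipped at 1", {
  # single CGI
  sh <- build_shores(data.table(chrom = "chr1", start = 10000L, end = 10500L))
  expect_equal(sh$start, c(8000L, 10501L))
  expect_equal(sh$end, c(9999L, 12500L))

  # two CGIs 1 kb apart: inter-CGI shore is one interval excluding both
  cgis <- data.table(chrom = "chr1", start = c(10000L, 11500L),
                     end = c(10500L, 12000L))
  sh2 <- build_shores(cgis)
  # brute-force oracle over base positions
  rng <- 6000:16000
  in_flank <- brute_overlap(rng, c(cgis$start - 2000L, cgis$end + 1L),
                            c(cgis$start - 1L, cgis$end + 2000L))
  in_cgi <- brute_overlap(rng, cgis$start, cgis$end)
  want <- rng[in_flank & !in_cgi]
  got <- unlist(Map(seq, sh2$start, sh2$end))
  expect_equal(sort(got), sort(want))
  expect_true(all(c(10501, 11499) %in% got))   # single inter-CGI block
  expect_false(any(got %in% unlist(Map(seq, cgis$start, cgis$end))))

  # CGI at chromosome start: left shore empty
  sh3 <- build_shores(data.table(chrom = "chr1", start = 1L, end = 300L))
  expect_equal(nrow(sh3), 1L)
  expect_equal(sh3$start, 301L)
  expect_equal(sh3$end, 2300L)
})

test_that("annotate_sites matches a brute-force overlap scan on random instances", {
  set.seed(3)
  n_sites <- 1000L
  n_int <- 50L
  pos <- sort(sample.int(100000L, n_sites))
  sites <- data.table(cpg_id = sprintf("c%04d", seq_len(n_sites)),
                      chrom = "chr1", pos = pos)
  mk <- function(n) {
    s <- sample.int(95000L, n)
    data.table(chrom = "chr1", start = s, end = s + sample.int(3000L, n),
               strand = "*", feature_id = sprintf("f%02d", seq_len(n)))
  }
  ann <- list(genes = data.table(), elements = list(
    promoter = mk(n_int), exon = mk(n_int), intron = mk(n_int),
    cgi = mk(10L), shore = mk(10L), enhancer = mk(5L),
    intergenic = data.table(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            feature_id = character())))
  sa <- annotate_sites(sites, ann)
  for (cl in c("promoter", "exon", "intron", "cgi", "shore", "enhancer")) {
    el <- ann$elements[[cl]]
    expect_equal(sa[[cl]], brute_overlap(pos, el$start, el$end), info = cl)
  }
  expect_equal(sa$intergenic, !(sa$promoter | sa$exon | sa$intron))
})

test_that("annotation flags are stable under input-order permutation", {
  co <- tiny_cohort()
  sa1 <- annotate_sites(co$meth$sites, co$annotation)
  perm <- sample(nrow(co$meth$sites))
  sa2 <- annotate_sites(co$meth$sites[perm], co$annotation)
  sa2 <- sa2[match(sa1$cpg_id, sa2$cpg_id)]
  for (cl in c("promoter", "exon", "intron", "cgi", "shore", "enhancer",
               "intergenic")) {
    expect_equal(sa2[[cl]], sa1[[cl]], info = cl)
  }
})

test_that("empty annotation marks all sites intergenic; unknown chromosomes warn", {
  sites <- data.table(cpg_id = c("a", "b"), chrom = "chr9",
                      pos = c(100L, 200L))
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_id = character())
  ann <- list(genes = data.table(),
              elements = setNames(rep(list(empty), 7),
                                  c("promoter", "exon", "intron", "cgi",
                                    "shore", "enhancer", "intergenic")))
  expect_warning(sa <- annotate_sites(sites, ann), "absent")
  expect_true(all(sa$intergenic))
  expect_true(all(is.na(sa$nearest_feature_id)))
})

test_that("nearest gene distance is 0 inside, negative upstream on the gene strand", {
  genes <- data.table(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"),
                      gene_start = c(1000L, 9000L), gene_end = c(2000L, 9500L),
                      tss = c(1000L, 9500L))
  ann <- list(genes = genes, elements = list(
    promoter = build_promoters(genes),
    exon = data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), feature_id = character()),
    intron = data.table(chrom = character(), start = integer(), end = integer(),
                        strand = character(), feature_id = character()),
    cgi = data.table(chrom = character(), start = integer(), end = integer(),
                     strand = character(), feature_id = character()),
    shore = data.table(chrom = character(), start = integer(), end = integer(),
                       strand = character(), feature_id = character()),
    enhancer = data.table(chrom = character(), start = integer(), end = integer(),
                          strand = character(), feature_id = character()),
    intergenic = data.table(chrom = character(), start = integer(), end = integer(),
                            strand = character(), feature_id = character())))
  sites <- data.table(cpg_id = c("s1", "s2", "s3", "s4"), chrom = "chr1",
                      pos = c(1500L, 900L, 2100L, 9800L))
  sa <- annotate_sites(sites, ann)
  expect_equal(sa$dist_to_feature[1], 0L)        # inside gA
  expect_equal(sa$dist_to_feature[2], -100L)     # 100 bp upstream of gA (+)
  expect_equal(sa$dist_to_feature[3], 100L)      # 100 bp downstream of gA (+)
  expect_equal(sa$nearest_feature_id[4], "gB")
  expect_equal(sa$dist_to_feature[4], -300L)     # upstream of gB on - strand
})

test_that("a site inside a promoter-embedded CGI carries both flags", {
  co <- tiny_cohort()
  sa <- annotate_sites(co$meth$sites, co$annotation)
  both <- sa$cgi & sa$promoter
  # the generator centres CGIs on TSSs, so CGI sites are promoter sites
  expect_true(any(both))
  expect_true(all(sa$promoter[sa$cgi]))
})

test_that("BED6 round trip preserves 1-based closed coordinates", {
  el <- data.table(chrom = "chr1", start = c(1L, 100L), end = c(50L, 100L),
                   strand = c("+", "*"), feature_id = c("x", "y"))
  f <- tempfile(fileext = ".bed")
  write_bed6(el, f)
  raw <- fread(f, header = FALSE)
  expect_equal(raw$V2, c(0L, 99L))   # 0-based starts on disk
  expect_equal(raw$V3, c(50L, 100L))
  back <- read_bed6(f)
  expect_equal(back$start, el$start)
  expect_equal(back$end, el$end)
  expect_equal(back$strand, c("+", "*"))
})
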