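gr <- function(starts, ends, chrom = "c1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

test_that("union merging handles overlap and bookended intervals", {
  # half-open [10,20) + [15,30) -> [10,30): closed 10..19 + 15..29
  u <- union_peaks(gr(c(10, 15), c(19, 29)))
  expect_equal(GenomicRanges::start(u), 10)
  expect_equal(GenomicRanges::end(u), 29)

  # bookended [10,20) + [20,30) -> [10,30): closed 10..19 + 20..29
  u2 <- union_peaks(gr(c(10, 20), c(19, 29)))
  expect_length(u2, 1L)
  expect_equal(GenomicRanges::end(u2), 29)

  # disjoint intervals stay apart
  u3 <- union_peaks(gr(c(10, 25), c(19, 29)))
  expect_length(u3, 2L)
})

test_that("union equals a sweep oracle, is order-invariant and idempotent", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 40
    starts <- sample.int(2000, n)
    ends <- starts + sample.int(80, n, replace = TRUE)
    peaks <- gr(starts, ends)
    shuffled <- peaks[sample(n)]
    u1 <- union_peaks(peaks)
    u2 <- union_peaks(shuffled)
    expect_equal(GenomicRanges::start(u1), GenomicRanges::start(u2))
    expect_equal(GenomicRanges::end(u1), GenomicRanges::end(u2))

    oracle <- oracle_sweep_merge(starts, ends)
    expect_equal(GenomicRanges::start(u1), unname(oracle[, "start"]))
    expect_equal(GenomicRanges::end(u1), unname(oracle[, "end"]))

    u_again <- union_peaks(u1)
    expect_equal(GenomicRanges::start(u_again), GenomicRanges::start(u1))
    expect_equal(GenomicRanges::end(u_again), GenomicRanges::end(u1))
    # disjoint and sorted
    expect_true(all(diff(GenomicRanges::start(u1)) > 0))
    expect_equal(sum(GenomicRanges::countOverlaps(u1, u1)), length(u1))
  }
})

test_that("BED I/O round-trips without coordinate shifts", {
  peaks <- gr(c(100, 300), c(199, 399))
  peaks$gene_id <- c("a", "b")
  f <- tempfile(fileext = ".bed")
  write_bed(peaks, f)
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2]), 99L)   # 0-based start on disk
  expect_equal(as.integer(fields[3]), 199L)  # half-open end on disk
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(peaks))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(peaks))
})

test_that("read counting assigns by the 5'-most base", {
  u <- union_peaks(gr(c(100, 300), c(199, 399)))
  # forward read fully inside the first peak
  inside <- GenomicRanges::GRanges("c1", IRanges::IRanges(150, 170))
  # forward read starting in peak 1 and ending in peak 2 (5' base in 1)
  spanning <- GenomicRanges::GRanges("c1", IRanges::IRanges(190, 310))
  # reverse read with the same span: 5' base (end) is in peak 2
  spanning_rev <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(190, 310), strand = "-")
  m <- count_in_union(list(lib = c(inside, spanning, spanning_rev)), u)
  expect_equal(unname(m[, "lib"]), c(2L, 1L))
  # total assigned reads never exceed the library size
  expect_lte(sum(m), 3L)
})

test_that("planted per-stage intensity fold changes are recovered", {
  cfg <- sim_config(seed = 31)
  pk <- gen_peak_sets(cfg)
  u <- union_peaks(pk$peak_calls)
  cm <- count_in_union(pk$reads, u)
  sf <- size_factors(cm + 1)
  norm <- sweep(cm, 2, sf, "/")
  tp <- sub("_[0-9]+$", "", colnames(norm))
  # map union peaks back to planted peaks (1:1 by construction: disjoint)
  hits <- GenomicRanges::findOverlaps(u, pk$peaks)
  truth <- pk$truth[S4Vectors::subjectHits(hits), ]
  for (stage in c("PA", "MA")) {
    rows <- which(truth$truth_stage == stage)
    hi_tp <- if (stage == "PA") "d-2" else "d7"
    lo_tp <- if (stage == "PA") "d7" else "d-2"
    fc_obs <- mean(rowMeans(norm[rows, tp == hi_tp, drop = FALSE])) /
      mean(rowMeans(norm[rows, tp == lo_tp, drop = FALSE]))
    fc_true <- 400 / 40
    expect_lt(abs(fc_obs / fc_true - 1), 0.10)
  }
})

test_that("differential regions flag steps and spare nulls", {
  set.seed(61)
  # a region with identical counts everywhere is never flagged
  flat <- matrix(50L, 1, 8,
                 dimnames = list("r1", paste0(rep(c("d-2", "d7"), each = 4),
                                              "_", 1:4)))
  d_flat <- differential_regions(flat, sf = rep(1, 8))
  expect_false(d_flat$flagged)

  # a 10x step at low dispersion is flagged
  step <- matrix(c(stats::rnbinom(6, mu = 20, size = 20),
                   stats::rnbinom(6, mu = 200, size = 20)), 1,
                 dimnames = list("r2", paste0(rep(c("d-2", "d7"),
                                                  each = 6), "_", 1:6)))
  d_step <- differential_regions(step, sf = rep(1, 12))
  expect_true(d_step$flagged)

  # single-replicate designs are refused
  expect_error(
    differential_regions(matrix(1:2, 1, dimnames = list(
      "r", c("d-2_1", "d7_1")))), "replicate")
})

test_that("annotation categories partition peaks with precedence", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "c1", strand = c("+", "-"),
    start = c(10000L, 40000L), end = c(20000L, 48000L))
  exons <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(10000, 15000, 47000), c(10500, 15400, 48000)),
    gene_id = c("gA", "gA", "gB"))
  models <- gene_models(genes, exons)
  mk_peak <- function(summit) {
    GenomicRanges::GRanges("c1", IRanges::IRanges(summit - 50,
                                                  summit + 50),
                           summit = 50L)
  }
  # 50 bp upstream of gA TSS -> promoter
  expect_equal(annotate_peaks(mk_peak(9950), models)$category,
               "promoter-TSS")
  # inside an exon far from any TSS -> exon (precedence over intron)
  expect_equal(annotate_peaks(mk_peak(15200), models)$category, "exon")
  # in the gene body but outside exons -> intron
  expect_equal(annotate_peaks(mk_peak(13000), models)$category, "intron")
  # 5 kb upstream, no feature overlap -> distant promoter
  expect_equal(annotate_peaks(mk_peak(5000), models)$category,
               "distant promoter")
  # minus-strand gene: upstream means higher coordinates
  expect_equal(annotate_peaks(mk_peak(48200), models)$category,
               "promoter-TSS")
  # far from everything -> intergenic
  expect_equal(annotate_peaks(mk_peak(80000), models)$category,
               "intergenic")

  # partition property: every peak gets exactly one known category
  set.seed(71)
  peaks <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(sample.int(90000, 200), width = 100),
    summit = 50L)
  ann <- annotate_peaks(peaks, models)
  expect_equal(nrow(ann), 200L)
  expect_true(all(ann$category %in%
                    c("promoter-TSS", "exon", "intron",
                      "distant promoter", "intergenic")))
  expect_false(any(is.na(ann$category)))
  # nearest gene ties break to the smaller gene id
  mid <- round((10000 + 40000) / 2)
  tie <- annotate_peaks(mk_peak(mid), models)
  expect_equal(tie$nearest_gene, "gA")
})

test_that("mean profiles have closed-form CPM for uniform coverage", {
  seqlen <- 20000L
  lib <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(seq_len(seqlen), width = 1L),
    seqlengths = c(c1 = seqlen))
  anchors <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(6000, 10000, 14000), width = 1L))
  pr <- mean_profile(list(lib = lib), anchors, window = 2000L, step = 10L)
  # every base covered once: CPM = 1e6 / N everywhere
  expect_true(all(abs(pr$profile[, "lib"] - 1e6 / seqlen) < 1e-9))

  # zero-read library gives an all-zero profile
  empty <- GenomicRanges::GRanges(seqlengths = c(c1 = seqlen))
  pr0 <- mean_profile(list(a = lib, z = empty), anchors, window = 2000L)
  expect_true(all(pr0$profile[, "z"] == 0))

  # anchors too close to the edge are skipped with a message
  edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100, 10000),
                                                        width = 1L))
  expect_message(pr1 <- mean_profile(list(lib = lib), edge,
                                     window = 2000L), "skipping")
  expect_equal(pr1$n_anchors, 1L)

  # a planted peak puts the profile maximum at the anchor
  set.seed(81)
  peak_reads <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(round(stats::rnorm(4000, 10000, 80)) - 25L,
                           width = 50L),
    seqlengths = c(c1 = seqlen))
  anchor <- GenomicRanges::GRanges("c1", IRanges::IRanges(10000,
                                                          width = 1L))
  pr2 <- mean_profile(list(lib = peak_reads), anchor, window = 2000L,
                      step = 10L)
  peak_pos <- pr2$position[which.max(pr2$profile[, "lib"])]
  expect_lte(abs(peak_pos), 10L) # within one step of the anchor
})
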