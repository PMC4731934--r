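test_that("BED12 block arithmetic expands to exon intervals", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t200\tsingle\t0\t+\t100\t200\t0\t1\t100\t0",
    "chr1\t1000\t1200\ttwo\t0\t-\t1000\t1200\t0\t2\t50,60\t0,140"),
    tmp)
  ann <- read_bed12(tmp)
  expect_equal(nrow(ann$transcripts), 2L)
  e1 <- ann$exons[transcript_id == "single"]
  expect_equal(c(e1$start, e1$end), c(100L, 200L))
  e2 <- ann$exons[transcript_id == "two"][order(start)]
  expect_equal(e2$start, c(1000L, 1140L))
  expect_equal(e2$end, c(1050L, 1200L))
})

test_that("BED12 write-read round-trip is identity on canonical records", {
  set.seed(11)
  ds <- plant_geometry(default_class_params("lncRNA", n_loci = 6L),
                       default_class_params("mRNA", n_loci = 4L),
                       seed = 11)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed12(ds$truth, tmp)
  back <- read_bed12(tmp)
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  write_bed12(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  # structural identity
  expect_setequal(back$transcripts$transcript_id,
                  ds$truth$transcripts$transcript_id)
  o <- order(back$exons$transcript_id, back$exons$start)
  oo <- order(ds$truth$exons$transcript_id, ds$truth$exons$start)
  expect_equal(back$exons$start[o], ds$truth$exons$start[oo])
  expect_equal(back$exons$end[o], ds$truth$exons$end[oo])
})

test_that("BED12 agrees with an independent reader (rtracklayer)", {
  skip_if_not_installed("rtracklayer")
  ann <- one_tx("t1", "chr2", "+", list(c(100L, 180L), c(300L, 420L),
                                        c(900L, 1000L)))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed12(ann, tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  blocks <- gr$blocks[[1]]
  expect_equal(BiocGenerics::start(blocks) - 1L + BiocGenerics::start(gr) - 1L,
               c(100L, 300L, 900L))
  expect_equal(BiocGenerics::width(blocks), c(80L, 120L, 100L))
})

test_that("malformed BED12 errors name the offending line", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t200\tok\t0\t+\t100\t200\t0\t1\t100\t0",
    "chr1\t100\t200\tbad\t0\t+"), tmp)
  expect_error(read_bed12(tmp), "line 2")
  writeLines(
    "chr1\t100\t400\tbad\t0\t+\t100\t400\t0\t2\t50\t0,100", tmp)
  expect_error(read_bed12(tmp), "blockCount")
})

test_that("GTF coordinates convert to 0-based half-open and duplicates drop", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "test", "exon", 101, 200, ".", "+", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t"),
    paste("chr1", "test", "exon", 301, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t"),
    paste("chr1", "test", "exon", 301, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t")), tmp)
  expect_warning(ann <- read_gtf(tmp), "duplicate")
  ex <- ann$exons[order(start)]
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$start, c(100L, 300L))
  expect_equal(ex$end, c(200L, 400L))
  # exon without transcript_id errors
  writeLines(paste("chr1", "test", "exon", 101, 200, ".", "+", ".",
                   'gene_id "g1";', sep = "\t"), tmp)
  expect_error(read_gtf(tmp), "transcript_id")
})

test_that("exonic_overlap_bp follows interval arithmetic", {
  a <- one_tx("a", "chr1", "+", list(c(0L, 100L)))
  b <- one_tx("b", "chr1", "+", list(c(50L, 150L)))
  expect_equal(exonic_overlap_bp(a$exons, b$exons), 50L)
  expect_equal(exonic_overlap_bp(b$exons, a$exons), 50L)
  # identical transcripts -> total exonic length
  m <- one_tx("m", "chr1", "-", list(c(10L, 60L), c(100L, 160L)))
  expect_equal(exonic_overlap_bp(m$exons, m$exons), 110L)
  # disjoint, different strand, different chrom -> 0
  c1 <- one_tx("c", "chr1", "+", list(c(500L, 600L)))
  expect_equal(exonic_overlap_bp(a$exons, c1$exons), 0L)
  d <- one_tx("d", "chr1", "-", list(c(0L, 100L)))
  expect_equal(exonic_overlap_bp(a$exons, d$exons), 0L)
  e <- one_tx("e", "chr9", "+", list(c(0L, 100L)))
  expect_equal(exonic_overlap_bp(a$exons, e$exons), 0L)
})

test_that("overlap is bounded by the shorter exonic length (property)", {
  set.seed(5)
  for (r in 1:25) {
    mk <- function(id) {
      n <- sample(1:3, 1)
      st <- sort(sample(0:500, n)) * 300L
      one_tx(id, "chr1", "+",
             lapply(seq_len(n), function(i) c(st[i], st[i] + sample(50:250, 1))))
    }
    a <- mk("a"); b <- mk("b")
    ov <- exonic_overlap_bp(a$exons, b$exons)
    expect_lte(ov, min(sum(exonic_lengths(a)), sum(exonic_lengths(b))))
    expect_gte(ov, 0L)
  }
})

test_that("build_loci groups by transitive same-strand exonic overlap", {
  # A overlaps B, B overlaps C, A disjoint from C -> one locus of three
  ann <- make_ann(list(
    A = list(chrom = "chr1", strand = "+", exons = list(c(0L, 100L))),
    B = list(chrom = "chr1", strand = "+", exons = list(c(50L, 250L))),
    C = list(chrom = "chr1", strand = "+", exons = list(c(200L, 300L)))))
  b <- build_loci(ann)
  expect_equal(nrow(b$loci), 1L)
  expect_equal(b$loci$n_transcripts, 3L)
  # same span, opposite strands -> two loci
  ann2 <- make_ann(list(
    P = list(chrom = "chr1", strand = "+", exons = list(c(0L, 100L))),
    M = list(chrom = "chr1", strand = "-", exons = list(c(0L, 100L)))))
  expect_equal(nrow(build_loci(ann2)$loci), 2L)
  # span overlap without exon overlap does not group
  ann3 <- make_ann(list(
    X = list(chrom = "chr1", strand = "+",
             exons = list(c(0L, 100L), c(5000L, 5100L))),
    Y = list(chrom = "chr1", strand = "+", exons = list(c(1000L, 1100L)))))
  expect_equal(nrow(build_loci(ann3)$loci), 2L)
})

test_that("build_loci matches the brute-force union-find oracle", {
  set.seed(42)
  for (r in 1:5) {
    n <- sample(30:80, 1)
    spec <- lapply(seq_len(n), function(i) {
      st <- sample(0:2000, 1) * 25L
      nexn <- sample(1:3, 1)
      exs <- lapply(seq_len(nexn), function(k)
        c(st + (k - 1L) * 400L, st + (k - 1L) * 400L + sample(100:350, 1)))
      list(chrom = sample(c("chr1", "chr2"), 1),
           strand = sample(c("+", "-"), 1), exons = exs)
    })
    names(spec) <- sprintf("t%03d", seq_len(n))
    ann <- make_ann(spec)
    expect_identical(built_partition(ann), oracle_loci(ann))
  }
})

test_that("build_loci is idempotent and partitions the input", {
  set.seed(7)
  geo <- plant_geometry(default_class_params("lncRNA", n_loci = 10L),
                        default_class_params("mRNA", n_loci = 5L), seed = 7)
  b <- build_loci(geo$truth)
  expect_false(anyNA(b$transcripts$locus_id))
  expect_equal(sum(b$loci$n_transcripts), n_transcripts(b))
  # recomputing loci on one locus's members reproduces a single locus
  lid <- b$loci$locus_id[1]
  sub <- annotation_subset(b, b$transcripts[locus_id == lid, transcript_id])
  b2 <- build_loci(sub)
  expect_equal(nrow(b2$loci), 1L)
  expect_equal(b2$loci$start, b$loci$start[1])
  expect_equal(b2$loci$end, b$loci$end[1])
})

test_that("unstranded transcripts never join stranded loci", {
  ann <- make_ann(list(
    S = list(chrom = "chr1", strand = "+", exons = list(c(0L, 100L))),
    U = list(chrom = "chr1", strand = ".", exons = list(c(0L, 100L)))))
  expect_equal(nrow(build_loci(ann)$loci), 2L)
})

test_that("merge_intervals merges overlapping same-strand intervals", {
  ex <- data.table::data.table(
    chrom = "chr1", start = c(0L, 50L, 300L), end = c(100L, 150L, 400L),
    strand = "+")
  m <- merge_intervals(ex)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(0L, 300L))
  expect_equal(m$end, c(150L, 400L))
})

test_that("annotation_set validates its invariants", {
  expect_error(one_tx("t", "chr1", "+", list(c(100L, 100L))), "start < end")
  expect_error(one_tx("t", "chr1", "x", list(c(0L, 10L))), "strand")
  # overlapping exons within one transcript
  expect_error(one_tx("t", "chr1", "+", list(c(0L, 100L), c(50L, 150L))),
               "overlap")
  # exon outside span
  tx <- data.table::data.table(transcript_id = "t", chrom = "chr1",
                               start = 0L, end = 50L, strand = "+")
  ex <- data.table::data.table(transcript_id = "t", start = 0L, end = 100L)
  expect_error(annotation_set(tx, ex), "span")
})
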