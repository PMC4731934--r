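cfg <- analysis_config()

test_that("positional rules force the three classes with precedence", {
  # coding gene on '-' spanning [0, 5000); its TSS = 5000
  pc <- one_tx("pc", "chr1", "-", list(c(0L, 300L), c(4700L, 5000L)))
  lnc <- make_ann(list(
    # TSS 800 bp from the coding TSS, opposite strand, no body overlap
    bidir = list(chrom = "chr1", strand = "+",
                 exons = list(c(5800L, 6000L), c(7000L, 7200L))),
    # nested inside the coding gene body, TSS far from the coding TSS
    anti = list(chrom = "chr1", strand = "+",
                exons = list(c(1000L, 1200L), c(2000L, 2200L))),
    # 50 kb away from everything
    inter = list(chrom = "chr1", strand = "+",
                 exons = list(c(55000L, 55200L), c(56000L, 56200L)))))
  cl <- positional_classify(lnc, pc, cfg)
  got <- stats::setNames(cl$class, cl$id)
  expect_equal(got[["bidir"]], "bidirectional")
  expect_equal(got[["anti"]], "antisense")
  expect_equal(got[["inter"]], "intergenic")
  # a promoter-sharing antisense lncRNA is bidirectional (precedence)
  both <- one_tx("both", "chr1", "+", list(c(4200L, 4400L), c(4800L, 6000L)))
  cl2 <- positional_classify(both, pc, cfg)
  expect_equal(cl2$class, "bidirectional")
})

test_that("unstranded lncRNAs are flagged, not classified", {
  pc <- one_tx("pc", "chr1", "+", list(c(0L, 1000L)))
  u <- one_tx("u", "chr1", ".", list(c(5000L, 5200L)))
  cl <- positional_classify(u, pc, cfg)
  expect_true(is.na(cl$class))
  expect_equal(cl$flag, "unstranded")
})

test_that("locus-level classification uses any member TSS", {
  pc <- one_tx("pc", "chr1", "-", list(c(0L, 300L), c(4700L, 5000L)))
  lnc <- make_ann(list(
    near = list(chrom = "chr1", strand = "+",
                exons = list(c(5800L, 6000L), c(7000L, 7200L))),
    far = list(chrom = "chr1", strand = "+",
               exons = list(c(5900L, 6000L), c(7000L, 7300L)))))
  lnc <- build_loci(lnc)
  expect_equal(nrow(lnc$loci), 1L)
  cl <- positional_classify(lnc, pc, cfg, level = "locus")
  expect_equal(cl$class, "bidirectional")
})

test_that("PA coverage classes follow per-exon covered counts", {
  pa <- make_ann(list(
    pa1 = list(chrom = "chr1", strand = "+",
               exons = list(c(0L, 200L), c(1000L, 1200L), c(2000L, 2200L)))))
  q <- make_ann(list(
    allcov = list(chrom = "chr1", strand = "+",
                  exons = list(c(50L, 150L), c(1100L, 1150L), c(2100L, 2300L))),
    partial = list(chrom = "chr1", strand = "+",
                   exons = list(c(50L, 150L), c(1100L, 1150L),
                                c(5000L, 5200L))),
    none = list(chrom = "chr1", strand = "+",
                exons = list(c(8000L, 8200L), c(9000L, 9200L))),
    anti = list(chrom = "chr1", strand = "-",
                exons = list(c(50L, 150L), c(1100L, 1150L)))))
  cl <- pa_coverage_classify(q, pa)
  got <- stats::setNames(cl$pa_class, cl$transcript_id)
  expect_equal(got[["allcov"]], "in_PA")
  expect_equal(got[["partial"]], "isoform_not_in_PA")
  expect_equal(got[["none"]], "not_in_PA")
  expect_equal(got[["anti"]], "not_in_PA")  # strand-aware
  # strict-junction mode needs exact coordinates
  cls <- pa_coverage_classify(q, pa, strict_junctions = TRUE)
  expect_equal(cls[transcript_id == "allcov", pa_class], "not_in_PA")
})

test_that("classification is a total partition of the input", {
  set.seed(21)
  ds <- generate_dataset(default_class_params("lncRNA", n_loci = 40L),
                         default_class_params("mRNA", n_loci = 10L),
                         seed = 21)
  lnc <- annotation_subset(ds$truth,
                           ds$truth_table[class == "lncRNA", transcript_id])
  cl <- positional_classify(lnc, ds$pc_ref, cfg)
  expect_equal(nrow(cl), n_transcripts(lnc))
  expect_true(all(cl$class %in% c("bidirectional", "antisense",
                                  "intergenic")))
  pcl <- pa_coverage_classify(lnc, ds$pa)
  expect_equal(nrow(pcl), n_transcripts(lnc))
  expect_true(all(pcl$pa_class %in% c("in_PA", "isoform_not_in_PA",
                                      "not_in_PA")))
})

test_that("planted positional and PA labels are recovered exactly", {
  set.seed(22)
  ds <- generate_dataset(default_class_params("lncRNA", n_loci = 60L),
                         default_class_params("mRNA", n_loci = 15L),
                         seed = 22)
  tt <- ds$truth_table
  lnc <- annotation_subset(ds$truth, tt[class == "lncRNA", transcript_id])
  cl <- positional_classify(lnc, ds$pc_ref, cfg)
  truth <- tt[class == "lncRNA",
              stats::setNames(positional_class, transcript_id)]
  expect_equal(unname(truth[cl$id]), cl$class)
  pcl <- pa_coverage_classify(lnc, ds$pa)
  truth_pa <- tt[class == "lncRNA", stats::setNames(pa_class, transcript_id)]
  expect_equal(unname(truth_pa[pcl$transcript_id]), pcl$pa_class)
  # locus novelty: new iff all members not_in_PA
  lnc <- build_loci(lnc)
  nv <- locus_novelty(lnc, ds$pa)
  mem <- merge(lnc$transcripts[, .(transcript_id, locus_id)],
               tt[, .(transcript_id, pa_class)], by = "transcript_id")
  want <- mem[, .(truth = if (all(pa_class == "not_in_PA")) "new"
                  else "known"), by = locus_id]
  cmp <- merge(nv, want, by = "locus_id")
  expect_equal(cmp$novelty_class, cmp$truth)
})

test_that("unique exon and region counting", {
  q <- make_ann(list(
    t1 = list(chrom = "chr1", strand = "+",
              exons = list(c(0L, 100L), c(1000L, 1100L))),
    t2 = list(chrom = "chr1", strand = "+",
              exons = list(c(0L, 100L), c(1050L, 1200L)))))
  # shared exon counts once; overlapping distinct exons merge to 1 region
  cn <- count_novel_exons(q, NULL)
  expect_equal(cn$unique_exons, 3L)
  expect_equal(cn$regions, 2L)
  # 1 bp overlap with a PA exon disqualifies novelty
  pa <- one_tx("pa", "chr1", "+", list(c(99L, 150L)))
  cn2 <- count_novel_exons(q, pa)
  expect_equal(cn2$novel_unique_exons, 2L)   # both 1000-based exons
  expect_equal(cn2$novel_regions, 1L)
})
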