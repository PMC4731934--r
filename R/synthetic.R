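# --- synthetic data generator ----------------------------------------------
#
# Emits a small "world" with the statistical structure the analysis
# modules assume: exon-structured transcripts grouped into loci with
# unambiguous positional geometry, a protein-coding reference, a partial
# public annotation, hierarchical lognormal expression (transcript
# baseline x donor effect x replicate noise), class-specific splicing
# efficiency with Poisson-noised coverage windows, polyA enrichment
# factors, and a tissue panel with planted specificity labels.

#' Per-class generative parameters
#'
#' Defaults encode the two transcript classes of the granulocyte world:
#' mRNAs are highly expressed (median 6.14 RPKM), tightly spliced
#' (median efficiency 99.02), polyA-enriched (median 2.62), rarely
#' tissue-specific (4 %), with low inter-donor variability (CV 0.15);
#' lncRNAs are lowly expressed (median 0.65), less efficiently spliced
#' (88.13), less polyA-enriched (1.56), often tissue-specific (32.5 %),
#' more variable (CV 0.29), and only partially covered by public
#' annotations.  Inter-donor log-SDs derive from the target CV via the
#' lognormal identity `sigma = sqrt(log(1 + CV^2))`.
#'
#' @param class `"mRNA"` or `"lncRNA"`.
#' @param n_loci number of loci to generate.
#' @param tx_per_locus_mean mean transcripts per locus (1 + Poisson).
#' @param median_rpkm class median of the transcript expression
#'   baseline.
#' @param baseline_log_sd log-scale SD of the baseline across
#'   transcripts.
#' @param target_cv target inter-individual coefficient of variation.
#' @param intra_donor_log_sd log-scale SD of replicate noise within a
#'   donor.
#' @param splice_s_median class median splicing efficiency (0-100).
#' @param splice_f_log_sd log-scale SD of the intronic fraction across
#'   transcripts.
#' @param polya_enrichment_median class median polyA+ enrichment factor.
#' @param polya_log_sd log-scale SD of the enrichment factor.
#' @param frac_tissue_specific fraction of transcripts planted as
#'   tissue-specific.
#' @param positional_mix named fractions (bidirectional, antisense,
#'   intergenic); NULL for mRNA.
#' @param frac_new_locus fraction of loci absent from the public
#'   annotation (all members not_in_PA).
#' @param p_in_pa_extra probability that a non-first member of a known
#'   locus is itself fully in the public annotation.
#' @return list of class `class_params`.
#' @export
class_params <- function(class = c("mRNA", "lncRNA"),
                         n_loci,
                         tx_per_locus_mean,
                         median_rpkm,
                         baseline_log_sd = 1.5,
                         target_cv,
                         intra_donor_log_sd = 0.1,
                         splice_s_median,
                         splice_f_log_sd = 0.8,
                         polya_enrichment_median,
                         polya_log_sd = 0.5,
                         frac_tissue_specific,
                         positional_mix = NULL,
                         frac_new_locus = 0,
                         p_in_pa_extra = 0.27) {
  class <- match.arg(class)
  if (!is.null(positional_mix)) {
    if (abs(sum(positional_mix) - 1) > 1e-6)
      stop("positional_mix must sum to 1")
    stopifnot(all(c("bidirectional", "antisense", "intergenic") %in%
                    names(positional_mix)))
  }
  stopifnot(frac_new_locus >= 0, frac_new_locus <= 1,
            frac_tissue_specific >= 0, frac_tissue_specific <= 1,
            target_cv > 0, splice_s_median > 0, splice_s_median <= 100)
  structure(list(
    class = class, n_loci = as.integer(n_loci),
    tx_per_locus_mean = tx_per_locus_mean,
    median_rpkm = median_rpkm, baseline_log_sd = baseline_log_sd,
    target_cv = target_cv,
    inter_donor_log_sd = sqrt(log(1 + target_cv^2)),
    intra_donor_log_sd = intra_donor_log_sd,
    splice_s_median = splice_s_median,
    splice_f_median = 1 - splice_s_median / 100,
    splice_f_log_sd = splice_f_log_sd,
    polya_enrichment_median = polya_enrichment_median,
    polya_log_sd = polya_log_sd,
    frac_tissue_specific = frac_tissue_specific,
    positional_mix = positional_mix,
    frac_new_locus = frac_new_locus,
    p_in_pa_extra = p_in_pa_extra), class = "class_params")
}

#' Default class parameter sets
#' @param class `"mRNA"` or `"lncRNA"`.
#' @param n_loci override the default locus count (mRNA 152, lncRNA 520;
#'   with the default transcripts-per-locus means both yield roughly
#'   2,000 transcripts per class).
#' @return a [class_params()] object.
#' @export
default_class_params <- function(class = c("mRNA", "lncRNA"),
                                 n_loci = NULL) {
  class <- match.arg(class)
  if (class == "mRNA") {
    class_params("mRNA", n_loci = if (is.null(n_loci)) 152L else n_loci,
                 tx_per_locus_mean = 13.2, median_rpkm = 6.14,
                 target_cv = 0.15, splice_s_median = 99.02,
                 polya_enrichment_median = 2.62,
                 frac_tissue_specific = 0.04)
  } else {
    class_params("lncRNA", n_loci = if (is.null(n_loci)) 520L else n_loci,
                 tx_per_locus_mean = 3.9, median_rpkm = 0.65,
                 target_cv = 0.29, splice_s_median = 88.13,
                 polya_enrichment_median = 1.56,
                 frac_tissue_specific = 0.325,
                 positional_mix = c(bidirectional = 0.25,
                                    antisense = 0.33, intergenic = 0.42),
                 frac_new_locus = 0.31)
  }
}

# ---- geometry --------------------------------------------------------------

# exon scaffold at a genomic offset; returns data.table(start, end)
.scaffold_exons <- function(at, n_exons, exon_lens, intron_lens) {
  starts <- at + c(0L, cumsum(exon_lens[-n_exons] + intron_lens))
  data.table::data.table(start = starts, end = starts + exon_lens)
}

# extra-exon slots inside scaffold introns; each slot is a 120 bp exon
# placed so slots never overlap each other, the scaffold, or the splice
# windows of the flanking junctions
.exon_slots <- function(scaffold) {
  n <- nrow(scaffold)
  if (n < 2L) return(data.table::data.table(start = integer(),
                                            end = integer()))
  slots <- list()
  for (i in seq_len(n - 1L)) {
    s <- scaffold$end[i]
    L <- scaffold$start[i + 1L] - s
    nd <- max(0L, (L - 420L) %/% 130L + 1L)
    if (nd > 0L) {
      off <- 150L + 130L * (seq_len(nd) - 1L)
      slots[[length(slots) + 1L]] <-
        data.table::data.table(start = s + off, end = s + off + 120L)
    }
  }
  if (!length(slots)) return(data.table::data.table(start = integer(),
                                                    end = integer()))
  data.table::rbindlist(slots)
}

# build the transcripts of one locus: every isoform carries the scaffold
# exons plus one unique extra exon, so isoforms always overlap exonically
# (one locus) while having distinct intron chains
.locus_transcripts <- function(tx_prefix, chrom, strand, scaffold,
                               n_tx) {
  slots <- .exon_slots(scaffold)
  n_tx <- max(1L, min(n_tx, nrow(slots)))
  ex <- lapply(seq_len(n_tx), function(j) {
    e <- rbind(scaffold, slots[j])
    e <- e[order(start)]
    data.table::data.table(
      transcript_id = sprintf("%s.%d", tx_prefix, j),
      chrom = chrom, start = e$start, end = e$end, strand = strand)
  })
  data.table::rbindlist(ex)
}

#' Plant annotation geometry with unambiguous class labels
#'
#' Lays loci along a virtual chromosome with 50 kb spacing so that each
#' planted positional label is forced: bidirectional lncRNAs start
#' within 1.5 kb of a coding partner's TSS on the opposite strand with
#' no body overlap; antisense lncRNAs sit inside the (intronic) body of
#' an opposite-strand coding gene with TSSs far apart; intergenic
#' lncRNAs are at least 10 kb from any gene.  Known lncRNA loci
#' contribute their fully-annotated members to the public annotation
#' (PA); new loci contribute nothing.
#'
#' @param params_lnc,params_mrna [class_params()] for the two classes.
#' @param seed integer seed.
#' @return list: `truth` (annotation_set, biotype = planted class),
#'   `pc_ref`, `pa` (annotation_sets), `labels` (data.table per
#'   transcript: transcript_id, class, locus_key, positional_class,
#'   pa_class).
#' @export
plant_geometry <- function(params_lnc = default_class_params("lncRNA"),
                           params_mrna = default_class_params("mRNA"),
                           seed = 1L) {
  set.seed(as.integer(seed))
  cursor <- 10000L
  chrom <- "chr1"
  tx_rows <- list(); pc_rows <- list(); pa_rows <- list(); lab_rows <- list()

  n_lnc <- params_lnc$n_loci
  mix <- params_lnc$positional_mix
  n_bid <- round(mix[["bidirectional"]] * n_lnc)
  n_as <- round(mix[["antisense"]] * n_lnc)
  pos_classes <- c(rep("bidirectional", n_bid), rep("antisense", n_as),
                   rep("intergenic", n_lnc - n_bid - n_as))
  pos_classes <- sample(pos_classes)
  new_locus <- stats::runif(n_lnc) < params_lnc$frac_new_locus

  for (i in seq_len(n_lnc)) {
    n_ex <- sample(2:4, 1L)
    scaffold <- .scaffold_exons(0L, n_ex,
                                exon_lens = sample(120:250, n_ex,
                                                   replace = TRUE),
                                intron_lens = sample(1200:2000,
                                                     max(n_ex - 1L, 1L),
                                                     replace = TRUE))
    span <- max(scaffold$end)
    pcls <- pos_classes[i]
    if (pcls == "bidirectional") {
      # partner gene on '-' occupying [cursor, cursor+pclen); its TSS is
      # the right end; lncRNA on '+' starts a short gap downstream
      pclen <- 4000L
      pc_sc <- .scaffold_exons(cursor, 2L, c(400L, 400L), 3200L - 800L + 800L)
      gap <- sample(300:1200, 1L)
      lnc_at <- cursor + pclen + gap
      pc_rows[[length(pc_rows) + 1L]] <- data.table::data.table(
        transcript_id = sprintf("PCpart%d", i), chrom = chrom,
        start = pc_sc$start, end = pc_sc$end, strand = "-")
      offset <- lnc_at
    } else if (pcls == "antisense") {
      # host gene on '+': two terminal exons and a giant intron in which
      # the '-' strand lncRNA nests; TSS distance is the 8 kb offset
      host_len <- span + 16000L
      pc_rows[[length(pc_rows) + 1L]] <- data.table::data.table(
        transcript_id = sprintf("PChost%d", i), chrom = chrom,
        start = c(cursor, cursor + host_len - 300L),
        end = c(cursor + 300L, cursor + host_len), strand = "+")
      offset <- cursor + 8000L
    } else {
      offset <- cursor
    }
    strand <- if (pcls == "bidirectional") "+"
              else if (pcls == "antisense") "-"
              else sample(c("+", "-"), 1L)
    sc <- data.table::copy(scaffold)[, `:=`(start = start + offset,
                                            end = end + offset)]
    n_tx <- 1L + stats::rpois(1L, params_lnc$tx_per_locus_mean - 1)
    ex <- .locus_transcripts(sprintf("lnc%d", i), chrom, strand, sc, n_tx)
    tx_ids <- unique(ex$transcript_id)
    tx_rows[[length(tx_rows) + 1L]] <- ex
    if (new_locus[i]) {
      pa_class <- rep("not_in_PA", length(tx_ids))
    } else {
      in_pa <- c(TRUE, stats::runif(length(tx_ids) - 1L) <
                   params_lnc$p_in_pa_extra)
      pa_class <- ifelse(in_pa, "in_PA", "isoform_not_in_PA")
      for (id in tx_ids[in_pa]) {
        cp <- ex[transcript_id == id]
        pa_rows[[length(pa_rows) + 1L]] <- data.table::data.table(
          transcript_id = paste0("PA_", id), chrom = chrom,
          start = cp$start, end = cp$end, strand = strand)
      }
    }
    lab_rows[[length(lab_rows) + 1L]] <- data.table::data.table(
      transcript_id = tx_ids, class = "lncRNA", locus_key = sprintf("L%d", i),
      positional_class = pcls, pa_class = pa_class)
    cursor <- cursor + span + 30000L + 50000L
  }

  for (i in seq_len(params_mrna$n_loci)) {
    n_ex <- sample(4:8, 1L)
    sc <- .scaffold_exons(cursor, n_ex,
                          exon_lens = sample(120:300, n_ex, replace = TRUE),
                          intron_lens = sample(1200:2000, n_ex - 1L,
                                               replace = TRUE))
    strand <- sample(c("+", "-"), 1L)
    n_tx <- 1L + stats::rpois(1L, params_mrna$tx_per_locus_mean - 1)
    ex <- .locus_transcripts(sprintf("mrna%d", i), chrom, strand, sc, n_tx)
    tx_ids <- unique(ex$transcript_id)
    tx_rows[[length(tx_rows) + 1L]] <- ex
    # the protein-coding reference carries the scaffold of each locus
    pc_rows[[length(pc_rows) + 1L]] <- data.table::data.table(
      transcript_id = sprintf("PCref%d", i), chrom = chrom,
      start = sc$start, end = sc$end, strand = strand)
    lab_rows[[length(lab_rows) + 1L]] <- data.table::data.table(
      transcript_id = tx_ids, class = "mRNA", locus_key = sprintf("M%d", i),
      positional_class = NA_character_, pa_class = NA_character_)
    cursor <- cursor + (max(sc$end) - cursor) + 50000L
  }

  .as_ann <- function(rows, biotype) {
    ex <- data.table::rbindlist(rows)
    tx <- ex[, .(chrom = chrom[1L], start = min(start), end = max(end),
                 strand = strand[1L]), by = transcript_id]
    tx[, `:=`(biotype = biotype, source = "synthetic")]
    annotation_set(tx, ex)
  }
  labels <- data.table::rbindlist(lab_rows)
  truth <- .as_ann(tx_rows, "candidate")
  truth$transcripts[, biotype := labels$class[
    match(transcript_id, labels$transcript_id)]]
  pa <- if (length(pa_rows)) .as_ann(pa_rows, "lncRNA") else NULL
  list(truth = truth, pc_ref = .as_ann(pc_rows, "mRNA"), pa = pa,
       labels = labels)
}

# ---- expression and coverage ----------------------------------------------

#' Generate a full synthetic dataset
#'
#' Expression model per transcript t, donor i, replicate j:
#' `x_tij = b_t * d_ti * e_tij` with `b_t ~ LogNormal(log median_class,
#' baseline_log_sd)`, `d_ti ~ LogNormal(0, inter_donor_log_sd)` and
#' `e_tij ~ LogNormal(0, intra_donor_log_sd)`.  The polyA matrix is the
#' ribo-depleted matrix scaled by a per-transcript lognormal enrichment
#' factor.  Splice-window counts are Poisson around the donor-pooled
#' expression, with the intronic mean scaled by the transcript's true
#' intronic fraction; window read counts use an effective length of
#' window + read length, mimicking overlap-based read counting on short
#' windows.
#'
#' @param params_lnc,params_mrna [class_params()] objects.
#' @param n_donors,n_replicates donor/replicate layout (7 x 3 default).
#' @param depth_per_replicate total mapped reads per replicate sample.
#' @param read_length_bp read length used for the effective window
#'   length of coverage counting.
#' @param n_tissues size of the specificity panel.
#' @param seed integer master seed (all stage seeds derive from it).
#' @return list of class `synthetic_dataset`: `truth`, `pc_ref`, `pa`,
#'   `scores`, `meta`, `expr` (list `ribo`, `polya`), `tissue` (list
#'   `target`, `panel`), `splice` (list `windows`, `exonic_counts`,
#'   `intronic_counts`, `total_reads`, `f_true`), `truth_table`,
#'   `params`.
#' @export
generate_dataset <- function(params_lnc = default_class_params("lncRNA"),
                             params_mrna = default_class_params("mRNA"),
                             n_donors = 7L, n_replicates = 3L,
                             depth_per_replicate = 5e7,
                             read_length_bp = 100L,
                             n_tissues = 33L,
                             seed = 1L) {
  seeds <- derive_seeds(seed, 6L)
  geo <- plant_geometry(params_lnc, params_mrna, seed = seeds[1L])
  labels <- geo$labels
  ids <- labels$transcript_id
  n <- length(ids)

  # --- hierarchical lognormal expression
  set.seed(seeds[2L])
  cls <- labels$class
  b <- stats::rlnorm(n,
    meanlog = log(ifelse(cls == "lncRNA", params_lnc$median_rpkm,
                         params_mrna$median_rpkm)),
    sdlog = ifelse(cls == "lncRNA", params_lnc$baseline_log_sd,
                   params_mrna$baseline_log_sd))
  sig_d <- ifelse(cls == "lncRNA", params_lnc$inter_donor_log_sd,
                  params_mrna$inter_donor_log_sd)
  sig_e <- ifelse(cls == "lncRNA", params_lnc$intra_donor_log_sd,
                  params_mrna$intra_donor_log_sd)
  donors <- sprintf("D%d", seq_len(n_donors))
  d_eff <- matrix(stats::rlnorm(n * n_donors, 0, rep(sig_d, n_donors)),
                  nrow = n, dimnames = list(ids, donors))
  samples <- as.vector(outer(donors, seq_len(n_replicates),
                             function(d, t) sprintf("%s_T%d", d, t)))
  expr_ribo <- matrix(0, nrow = n, ncol = length(samples),
                      dimnames = list(ids, samples))
  for (ti in seq_len(n_replicates)) {
    e <- matrix(stats::rlnorm(n * n_donors, 0, rep(sig_e, n_donors)),
                nrow = n)
    cols <- sprintf("%s_T%d", donors, ti)
    expr_ribo[, cols] <- b * d_eff * e
  }
  enr <- stats::rlnorm(n,
    meanlog = log(ifelse(cls == "lncRNA",
                         params_lnc$polya_enrichment_median,
                         params_mrna$polya_enrichment_median)),
    sdlog = ifelse(cls == "lncRNA", params_lnc$polya_log_sd,
                   params_mrna$polya_log_sd))
  expr_polya <- expr_ribo * enr

  meta <- sample_metadata(data.table::data.table(
    sample_id = c(samples, paste0(samples, "_pa")),
    donor_id = rep(rep(donors, n_replicates), 2L),
    time_point = rep(rep(seq_len(n_replicates), each = n_donors), 2L),
    sex = "F", population = "pop1",
    protocol = rep(c("ribo_depleted", "polyA_plus"),
                   each = length(samples)),
    stranded = TRUE,
    total_mapped_reads = depth_per_replicate,
    read_length_bp = read_length_bp))
  colnames(expr_polya) <- paste0(samples, "_pa")

  # --- tissue panel with planted specificity
  set.seed(seeds[3L])
  spec <- stats::runif(n) < ifelse(cls == "lncRNA",
                                   params_lnc$frac_tissue_specific,
                                   params_mrna$frac_tissue_specific)
  panel <- matrix(0, nrow = n, ncol = n_tissues,
                  dimnames = list(ids, sprintf("tissue%02d", seq_len(n_tissues))))
  fold <- 3
  for (j in seq_len(n_tissues))
    panel[, j] <- b / fold * stats::runif(n, 0.1, 0.8)
  hot <- sample.int(n_tissues, n, replace = TRUE)
  notspec <- which(!spec)
  panel[cbind(notspec, hot[notspec])] <-
    b[notspec] * stats::runif(length(notspec), 0.5, 1.5)

  # --- splicing truth and Poisson window counts
  set.seed(seeds[4L])
  windows <- site_windows(geo$truth)
  f_tx <- stats::rlnorm(n,
    meanlog = log(ifelse(cls == "lncRNA", params_lnc$splice_f_median,
                         params_mrna$splice_f_median)),
    sdlog = ifelse(cls == "lncRNA", params_lnc$splice_f_log_sd,
                   params_mrna$splice_f_log_sd))
  names(f_tx) <- ids
  wt <- data.table::copy(windows)
  wt[, best := site_id == site_id[1L], by = transcript_id]
  wt[, f_true := f_tx[transcript_id] *
       ifelse(best, 1, stats::runif(.N, 2, 5))]
  wt[, f_true := pmin(f_true, 1.2)]
  drp <- donor_mean(expr_ribo, meta, protocol = "ribo_depleted")
  pooled_depth <- depth_per_replicate * n_replicates
  we <- wt$exonic_end - wt$exonic_start
  wi <- wt$intronic_end - wt$intronic_start
  lam_e <- drp[wt$transcript_id, , drop = FALSE] *
    (we + read_length_bp) * pooled_depth / 1e9
  lam_i <- drp[wt$transcript_id, , drop = FALSE] *
    (wi + read_length_bp) * pooled_depth / 1e9 * wt$f_true
  exonic_counts <- matrix(stats::rpois(length(lam_e), lam_e),
                          nrow = nrow(wt),
                          dimnames = list(wt$site_id, donors))
  intronic_counts <- matrix(stats::rpois(length(lam_i), lam_i),
                            nrow = nrow(wt),
                            dimnames = list(wt$site_id, donors))
  s_true_site <- pmax(0, pmin(100, 100 * (1 - wt$f_true)))
  s_true_tx <- wt[, .(s_true = max(pmax(0, pmin(100, 100 * (1 - f_true))))),
                  by = transcript_id]

  # --- coding-potential scores: lncRNAs always pass, mRNAs always fail
  set.seed(seeds[5L])
  scores <- data.table::data.table(
    transcript_id = ids,
    rnacode = ifelse(cls == "lncRNA", stats::runif(n, -30, 15),
                     stats::runif(n, 25, 60)),
    cpc = ifelse(cls == "lncRNA", stats::runif(n, -3, 1.3),
                 stats::runif(n, 2, 5)))

  truth_table <- data.table::data.table(
    transcript_id = ids, class = cls, locus_key = labels$locus_key,
    positional_class = labels$positional_class,
    pa_class = labels$pa_class,
    baseline_rpkm = b, polya_enrichment = enr,
    tissue_specific = spec,
    s_true = s_true_tx$s_true[match(ids, s_true_tx$transcript_id)])

  structure(list(
    truth = geo$truth, pc_ref = geo$pc_ref, pa = geo$pa,
    scores = scores, meta = meta,
    expr = list(ribo = expr_ribo, polya = expr_polya),
    tissue = list(target = stats::setNames(b, ids), panel = panel),
    splice = list(windows = windows, exonic_counts = exonic_counts,
                  intronic_counts = intronic_counts,
                  total_reads = stats::setNames(rep(pooled_depth, n_donors),
                                                donors),
                  f_true = stats::setNames(wt$f_true, wt$site_id),
                  s_true_site = stats::setNames(s_true_site, wt$site_id)),
    truth_table = truth_table,
    params = list(lncRNA = params_lnc, mRNA = params_mrna,
                  n_donors = n_donors, n_replicates = n_replicates,
                  seed = seed)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d transcripts (%d lncRNA, %d mRNA), %d donors x %d replicates\n",
              nrow(x$truth_table), sum(x$truth_table$class == "lncRNA"),
              sum(x$truth_table$class == "mRNA"),
              x$params$n_donors, x$params$n_replicates))
  invisible(x)
}

#' Synthetic world for the donor-saturation analysis
#'
#' A larger donor panel (default 120 donors: 12 female + 12 male in each
#' of five populations) with single-sample expression per donor.  mRNAs
#' are expressed in every donor; lncRNA loci are expressed in a random
#' donor subset (locus on-probability drawn from a Beta distribution),
#' emulating the on/off detection patterns that drive lncRNA discovery
#' as donors are added, while inter-donor log-SDs use lymphoblastoid
#' cell line CV levels (0.56 lncRNA, 0.24 mRNA).
#'
#' @param n_lnc_loci,n_mrna_loci locus counts (scaled-down world).
#' @param n_donors total donors (multiple of 4 x populations).
#' @param n_populations donor populations.
#' @param on_alpha,on_beta Beta parameters of the per-locus donor
#'   on-probability for lncRNAs.
#' @param lnc_cv,mrna_cv inter-donor CV targets of the donor effects.
#' @param seed integer master seed.
#' @return list: `truth`, `pc_ref`, `pa`, `scores`, `donors`
#'   (data.table donor_id/sex/population), `donor_expr` (feature x donor
#'   RPKM matrix), `labels`.
#' @export
generate_saturation_world <- function(n_lnc_loci = 600L,
                                      n_mrna_loci = 800L,
                                      n_donors = 120L,
                                      n_populations = 5L,
                                      on_alpha = 0.08, on_beta = 4,
                                      lnc_cv = 0.56, mrna_cv = 0.24,
                                      seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  p_lnc <- default_class_params("lncRNA", n_loci = n_lnc_loci)
  p_mrna <- default_class_params("mRNA", n_loci = n_mrna_loci)
  geo <- plant_geometry(p_lnc, p_mrna, seed = seeds[1L])
  labels <- geo$labels
  ids <- labels$transcript_id
  n <- length(ids)
  per_pop <- n_donors / n_populations
  stopifnot(per_pop %% 4 == 0)
  donors <- data.table::data.table(
    donor_id = sprintf("G%03d", seq_len(n_donors)),
    sex = rep(rep(c("F", "M"), each = per_pop / 2), n_populations),
    population = rep(sprintf("pop%d", seq_len(n_populations)),
                     each = per_pop))

  set.seed(seeds[2L])
  cls <- labels$class
  b <- stats::rlnorm(n,
    meanlog = log(ifelse(cls == "lncRNA", p_lnc$median_rpkm,
                         p_mrna$median_rpkm)),
    sdlog = 1.5)
  sig_d <- ifelse(cls == "lncRNA", sqrt(log(1 + lnc_cv^2)),
                  sqrt(log(1 + mrna_cv^2)))
  d_eff <- matrix(stats::rlnorm(n * n_donors, 0, rep(sig_d, n_donors)),
                  nrow = n, dimnames = list(ids, donors$donor_id))
  # locus-level donor on/off for lncRNAs
  lnc_loci <- unique(labels[class == "lncRNA", locus_key])
  pi_locus <- stats::setNames(stats::rbeta(length(lnc_loci), on_alpha,
                                           on_beta), lnc_loci)
  on <- matrix(1, nrow = n, ncol = n_donors,
               dimnames = list(ids, donors$donor_id))
  lnc_rows <- which(cls == "lncRNA")
  pi_tx <- pi_locus[labels$locus_key[lnc_rows]]
  on[lnc_rows, ] <- matrix(
    stats::rbinom(length(lnc_rows) * n_donors, 1L, rep(pi_tx, n_donors)),
    nrow = length(lnc_rows))
  donor_expr <- b * d_eff * on

  set.seed(seeds[3L])
  scores <- data.table::data.table(
    transcript_id = ids,
    rnacode = ifelse(cls == "lncRNA", stats::runif(n, -30, 15),
                     stats::runif(n, 25, 60)),
    cpc = ifelse(cls == "lncRNA", stats::runif(n, -3, 1.3),
                 stats::runif(n, 2, 5)))
  list(truth = geo$truth, pc_ref = geo$pc_ref, pa = geo$pa,
       scores = scores, donors = donors, donor_expr = donor_expr,
       labels = labels)
}
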