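# --- positional and public-annotation coverage classifiers -----------------

#' Positional classification of lncRNAs
#'
#' Each lncRNA transcript (or locus) gets exactly one label relative to
#' protein-coding genes, with precedence
#' bidirectional > antisense > intergenic:
#' \itemize{
#'   \item \strong{bidirectional}: its TSS lies within the promoter
#'     (TSS +/- `cfg$promoter_halfwidth_bp`) of a protein-coding gene;
#'     for a locus, any member transcript's TSS qualifies.
#'   \item \strong{antisense}: its span overlaps a protein-coding gene
#'     span on the opposite strand by >= 1 bp.
#'   \item \strong{intergenic}: no overlap with a protein-coding gene.
#' }
#' Sense-overlapping lncRNAs are assumed to have been removed upstream
#' ([remove_sense_overlap()]).  Unstranded records cannot be classified
#' and are returned with `class = NA` and `flag = "unstranded"`.
#'
#' @param lnc lncRNA [annotation_set()].
#' @param pc protein-coding [annotation_set()] (de novo mRNAs combined
#'   with public references).
#' @param cfg an [analysis_config()].
#' @param level `"transcript"` or `"locus"` (requires loci built).
#' @return data.table (id, class, flag).
#' @export
positional_classify <- function(lnc, pc, cfg = analysis_config(),
                                level = c("transcript", "locus")) {
  level <- match.arg(level)
  pc_tss <- transcript_tss(pc)
  lnc_tss <- transcript_tss(lnc)
  hw <- cfg$promoter_halfwidth_bp

  # transcript TSS within hw of any coding TSS: nearest-neighbour search
  # per chromosome via findInterval on the sorted coding TSS positions
  bidir_tx <- rep(NA, nrow(lnc_tss))
  for (ch in unique(lnc_tss$chrom)) {
    qi <- which(lnc_tss$chrom == ch & !is.na(lnc_tss$tss))
    if (!length(qi)) next
    p <- sort(pc_tss[chrom == ch & !is.na(tss), tss])
    if (!length(p)) { bidir_tx[qi] <- FALSE; next }
    t <- lnc_tss$tss[qi]
    idx <- findInterval(t, p)
    d_lo <- ifelse(idx >= 1L, abs(t - p[pmax(idx, 1L)]), Inf)
    d_hi <- ifelse(idx < length(p), abs(p[pmin(idx + 1L, length(p))] - t), Inf)
    bidir_tx[qi] <- pmin(d_lo, d_hi) <= hw
  }

  # opposite-strand span overlap with a coding gene
  lspan <- lnc$transcripts[, .(transcript_id, chrom, start, end, strand)]
  flip <- data.table::copy(lspan)
  flip[, strand := data.table::fcase(strand == "+", "-",
                                     strand == "-", "+",
                                     default = ".")]
  pspan <- pc$transcripts[, .(transcript_id, chrom, start, end, strand)]
  as_ids <- unique(flip$transcript_id[
    .exon_overlap_pairs(flip, pspan, same_strand = TRUE)$q])

  res <- data.table::data.table(
    id = lnc_tss$transcript_id,
    class = data.table::fcase(
      is.na(bidir_tx), NA_character_,
      bidir_tx, "bidirectional",
      lnc_tss$transcript_id %in% as_ids, "antisense",
      default = "intergenic"),
    flag = ifelse(is.na(bidir_tx), "unstranded", ""))

  if (level == "transcript") return(res[])
  if (is.null(lnc$loci)) stop("locus-level classification requires build_loci()")
  mem <- lnc$transcripts[, .(transcript_id, locus_id)]
  res <- merge(res, mem, by.x = "id", by.y = "transcript_id")
  out <- res[, .(
    class = if (any(is.na(class))) NA_character_
            else if (any(class == "bidirectional")) "bidirectional"
            else if (any(class == "antisense")) "antisense"
            else "intergenic",
    flag = if (any(flag == "unstranded")) "unstranded" else ""),
    by = locus_id]
  data.table::setnames(out, "locus_id", "id")
  out[]
}

#' Public-annotation (PA) coverage classification
#'
#' Compares each transcript's exons to a merged public lncRNA annotation.
#' An exon is "covered" iff it has >= 1 bp same-strand overlap with any
#' PA exon.  Labels: `in_PA` (all exons covered), `isoform_not_in_PA`
#' (some but not all), `not_in_PA` (none).  With `strict_junctions =
#' TRUE` an exon only counts as covered when a PA exon with identical
#' coordinates exists.
#'
#' @param ann query [annotation_set()].
#' @param pa public-annotation [annotation_set()].
#' @param strict_junctions require exact exon coordinate identity.
#' @return data.table (transcript_id, n_exons, n_covered, pa_class).
#' @export
pa_coverage_classify <- function(ann, pa, strict_junctions = FALSE) {
  ex <- data.table::copy(ann$exons)
  if (strict_junctions) {
    key <- paste(pa$exons$chrom, pa$exons$start, pa$exons$end,
                 pa$exons$strand)
    ex[, covered := paste(chrom, start, end, strand) %in% key]
  } else {
    prs <- .exon_overlap_pairs(ex, pa$exons, same_strand = TRUE)
    ex[, covered := FALSE]
    ex[unique(prs$q), covered := TRUE]
  }
  out <- ex[, .(n_exons = .N, n_covered = sum(covered)), by = transcript_id]
  out[, pa_class := data.table::fcase(
    n_covered == n_exons, "in_PA",
    n_covered > 0L, "isoform_not_in_PA",
    default = "not_in_PA")]
  # keep input order
  out[match(ann$transcripts$transcript_id, transcript_id)][]
}

#' Locus novelty from PA coverage
#'
#' A locus is `new` iff every member transcript is `not_in_PA`,
#' otherwise `known`.
#'
#' @param ann [annotation_set()] with loci built.
#' @param pa public-annotation [annotation_set()].
#' @param strict_junctions see [pa_coverage_classify()].
#' @return data.table (locus_id, novelty_class).
#' @export
locus_novelty <- function(ann, pa, strict_junctions = FALSE) {
  if (is.null(ann$loci)) stop("locus novelty requires build_loci()")
  cl <- pa_coverage_classify(ann, pa, strict_junctions)
  cl <- merge(cl, ann$transcripts[, .(transcript_id, locus_id)],
              by = "transcript_id")
  out <- cl[, .(novelty_class = if (all(pa_class == "not_in_PA")) "new"
                else "known"), by = locus_id]
  out[]
}

#' Count unique exons and non-overlapping exonic regions
#'
#' Unique exons are distinct (chrom, start, end, strand) tuples; regions
#' are same-strand merged exonic intervals.  "Novel" subsets have zero
#' same-strand overlap with any PA exon.
#'
#' @param ann query [annotation_set()].
#' @param pa public-annotation [annotation_set()] (or NULL: novel counts
#'   equal the totals).
#' @return list with `unique_exons`, `regions`, `novel_unique_exons`,
#'   `novel_regions` (integer counts).
#' @export
count_novel_exons <- function(ann, pa = NULL) {
  uex <- unique(ann$exons[, .(chrom, start, end, strand)])
  reg <- merge_intervals(ann$exons)
  if (is.null(pa) || n_transcripts(pa) == 0L) {
    novel_ex <- uex; novel_reg <- reg
  } else {
    hit_ex <- .exon_overlap_pairs(uex, pa$exons, same_strand = TRUE)
    novel_ex <- uex[setdiff(seq_len(nrow(uex)), unique(hit_ex$q))]
    hit_reg <- .exon_overlap_pairs(reg, pa$exons, same_strand = TRUE)
    novel_reg <- reg[setdiff(seq_len(nrow(reg)), unique(hit_reg$q))]
  }
  list(unique_exons = nrow(uex), regions = nrow(reg),
       novel_unique_exons = nrow(novel_ex), novel_regions = nrow(novel_reg))
}
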