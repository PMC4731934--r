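# --- lncRNA identification cascade -----------------------------------------
# Stages, in pipeline order:
#   1. filter_structure        multi-exonic and > 200 bp exonic length
#   2. partition_by_coding_overlap   mRNA match / pseudogene discard
#   3. coding_potential_filter RNAcode < 18 & CPC < 1.6
#   4. remove_sense_overlap    span overlap with a coding gene, same strand

.report_row <- function(stage, n_input, kept_ids, removed_ids) {
  data.table::data.table(stage = stage, n_input = n_input,
                         n_kept = length(kept_ids),
                         n_removed = length(removed_ids),
                         removed_ids = list(removed_ids))
}

# per-query-transcript: does any exon overlap any subject exon (same strand)?
.tx_exonic_hit <- function(q_ann, s_ann) {
  prs <- .exon_overlap_pairs(q_ann$exons, s_ann$exons, same_strand = TRUE)
  unique(q_ann$exons$transcript_id[prs$q])
}

# span-level same-strand overlap (gene-body rule)
.tx_span_hit <- function(q_ann, s_ann) {
  qspan <- q_ann$transcripts[, .(transcript_id, chrom, start, end, strand)]
  sspan <- s_ann$transcripts[, .(transcript_id, chrom, start, end, strand)]
  prs <- .exon_overlap_pairs(qspan, sspan, same_strand = TRUE)
  unique(qspan$transcript_id[prs$q])
}

#' Structural filter: multi-exonic transcripts longer than 200 bp
#'
#' Keeps transcripts with at least `min_exons` exons and exonic length
#' strictly greater than `min_length_bp`.
#'
#' @param ann candidate [annotation_set()].
#' @param cfg an [analysis_config()].
#' @return list with `kept` (annotation_set) and `report` (one-row
#'   data.table: stage, n_input, n_kept, n_removed, removed_ids).
#' @export
filter_structure <- function(ann, cfg = analysis_config()) {
  nex <- ann$exons[, .N, by = transcript_id]
  len <- exonic_lengths(ann)
  ok_ids <- nex[N >= cfg$min_exons, transcript_id]
  ok_ids <- ok_ids[len[ok_ids] > cfg$min_length_bp]
  removed <- setdiff(ann$transcripts$transcript_id, ok_ids)
  list(kept = annotation_subset(ann, ok_ids),
       report = .report_row("structure", n_transcripts(ann), ok_ids, removed))
}

#' Partition candidates by overlap with coding and pseudogene references
#'
#' A candidate with >= 1 bp same-strand exonic overlap with a
#' protein-coding exon becomes an mRNA; otherwise, same-strand exonic
#' overlap with a pseudogene exon discards it; the remainder are lncRNA
#' candidates.  Precedence: mRNA > pseudogene.
#'
#' @param ann candidate [annotation_set()].
#' @param pc_ref protein-coding reference annotation.
#' @param pseudo_ref pseudogene reference annotation (may be empty set of
#'   transcripts only if explicitly constructed; `NULL` skips the stage).
#' @return list `mRNA`, `lnc_candidates` (annotation_sets),
#'   `pseudogene_ids` (character) and `report` (two rows).
#' @export
partition_by_coding_overlap <- function(ann, pc_ref, pseudo_ref = NULL) {
  if (is.null(pc_ref) || n_transcripts(pc_ref) == 0L)
    stop("empty protein-coding reference")
  ids <- ann$transcripts$transcript_id
  mrna_ids <- intersect(ids, .tx_exonic_hit(ann, pc_ref))
  rest <- setdiff(ids, mrna_ids)
  pseudo_ids <- character()
  if (!is.null(pseudo_ref) && n_transcripts(pseudo_ref) > 0L) {
    rest_ann <- annotation_subset(ann, rest)
    pseudo_ids <- intersect(rest, .tx_exonic_hit(rest_ann, pseudo_ref))
  }
  lnc_ids <- setdiff(rest, pseudo_ids)
  rep1 <- .report_row("coding_overlap", length(ids),
                      lnc_ids, mrna_ids)
  rep2 <- .report_row("pseudogene", length(rest), lnc_ids, pseudo_ids)
  mr <- annotation_subset(ann, mrna_ids)
  if (length(mrna_ids)) mr$transcripts[, biotype := "mRNA"]
  list(mRNA = mr,
       lnc_candidates = annotation_subset(ann, lnc_ids),
       pseudogene_ids = pseudo_ids,
       report = rbind(rep1, rep2))
}

#' Coding-potential filter
#'
#' A candidate is kept as lncRNA iff its RNAcode score is below
#' `cfg$rnacode_max` and its CPC score below `cfg$cpc_max`.  A missing
#' score means the coding-potential tool emitted nothing for that
#' transcript; under the default `missing_score_policy = "keep"` this is
#' treated as absence of coding evidence (kept, flagged), under
#' `"drop"` the transcript is removed.
#'
#' @param ann lncRNA candidate [annotation_set()].
#' @param scores data.frame with columns `transcript_id`, `rnacode`,
#'   `cpc` (NA = tool produced no score).
#' @param cfg an [analysis_config()].
#' @return list `kept` (annotation_set, biotype set to "lncRNA"),
#'   `flagged_missing` (ids kept on missing scores) and `report`.
#' @export
coding_potential_filter <- function(ann, scores, cfg = analysis_config()) {
  sc <- data.table::as.data.table(scores)
  ids <- ann$transcripts$transcript_id
  sc <- sc[match(ids, transcript_id)]
  partial_rna <- is.na(sc$rnacode)
  partial_cpc <- is.na(sc$cpc)
  below_rna <- partial_rna | sc$rnacode < cfg$rnacode_max
  below_cpc <- partial_cpc | sc$cpc < cfg$cpc_max
  keep <- below_rna & below_cpc
  flagged <- ids[keep & (partial_rna | partial_cpc)]
  if (cfg$missing_score_policy == "drop")
    keep <- keep & !(partial_rna | partial_cpc)
  kept_ids <- ids[keep]
  kept <- annotation_subset(ann, kept_ids)
  if (length(kept_ids)) kept$transcripts[, biotype := "lncRNA"]
  list(kept = kept,
       flagged_missing = if (cfg$missing_score_policy == "keep")
         flagged else character(),
       report = .report_row("coding_potential", length(ids), kept_ids,
                            setdiff(ids, kept_ids)))
}

#' Remove lncRNAs overlapping a protein-coding gene in sense direction
#'
#' Uses gene-span (not exon-only) overlap so that lncRNAs fully inside
#' an intron of a sense mRNA are removed too.
#'
#' @param ann lncRNA [annotation_set()].
#' @param pc_all combined protein-coding annotation (de novo mRNAs plus
#'   public coding references).
#' @return list `kept` and `report`.
#' @export
remove_sense_overlap <- function(ann, pc_all) {
  ids <- ann$transcripts$transcript_id
  hit <- .tx_span_hit(ann, pc_all)
  kept_ids <- setdiff(ids, hit)
  list(kept = annotation_subset(ann, kept_ids),
       report = .report_row("sense_overlap", length(ids), kept_ids, hit))
}

#' Run the full lncRNA identification cascade
#'
#' Composes [filter_structure()], [partition_by_coding_overlap()],
#' [coding_potential_filter()] and [remove_sense_overlap()] in pipeline
#' order and groups the surviving transcripts into loci.
#'
#' @param candidates assembled candidate [annotation_set()].
#' @param pc_ref protein-coding reference annotation.
#' @param scores coding-potential score table (see
#'   [coding_potential_filter()]).
#' @param pseudo_ref optional pseudogene reference.
#' @param cfg an [analysis_config()].
#' @return list `lncRNA` and `mRNA` annotation_sets (with loci built) and
#'   the telescoping `report` table.
#' @export
run_lnc_filter_cascade <- function(candidates, pc_ref, scores,
                                   pseudo_ref = NULL,
                                   cfg = analysis_config()) {
  st <- filter_structure(candidates, cfg)
  pt <- partition_by_coding_overlap(st$kept, pc_ref, pseudo_ref)
  cp <- coding_potential_filter(pt$lnc_candidates, scores, cfg)
  pc_all <- .bind_annotations(pt$mRNA, pc_ref)
  so <- remove_sense_overlap(cp$kept, pc_all)
  lnc <- build_loci(so$kept, prefix = paste0(cfg$locus_prefix, "_lnc"))
  mrna <- build_loci(pt$mRNA, prefix = paste0(cfg$locus_prefix, "_pc"))
  list(lncRNA = lnc, mRNA = mrna,
       report = rbind(st$report, pt$report, cp$report, so$report))
}

# concatenate two annotation sets (ids must not clash across sets; a
# suffix disambiguates if they do)
.bind_annotations <- function(a, b) {
  clash <- intersect(a$transcripts$transcript_id, b$transcripts$transcript_id)
  if (length(clash)) {
    b <- annotation_set(
      data.table::copy(b$transcripts)[, transcript_id :=
        ifelse(transcript_id %in% clash,
               paste0(transcript_id, ".b"), transcript_id)],
      data.table::copy(b$exons)[, transcript_id :=
        ifelse(transcript_id %in% clash,
               paste0(transcript_id, ".b"), transcript_id)])
  }
  annotation_set(rbind(a$transcripts, b$transcripts, fill = TRUE),
                 rbind(a$exons, b$exons))
}
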