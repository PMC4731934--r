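# --- RPKM expression summaries ---------------------------------------------

#' Sample metadata table
#'
#' Validates the per-sample metadata used throughout: donor identity,
#' time point, library protocol and sequencing depth.
#'
#' @param df data.frame with columns `sample_id`, `donor_id`,
#'   `time_point`, `protocol` (one of `polyA_plus`, `ribo_depleted`),
#'   `total_mapped_reads`, and optionally `sex`, `population`,
#'   `stranded`, `read_length_bp`.
#' @return validated data.table of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  m <- data.table::as.data.table(df)
  req <- c("sample_id", "donor_id", "time_point", "protocol",
           "total_mapped_reads")
  if (!all(req %in% names(m)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  if (!all(m$protocol %in% c("polyA_plus", "ribo_depleted")))
    stop("protocol must be 'polyA_plus' or 'ribo_depleted'")
  if (any(m$total_mapped_reads <= 0))
    stop("total_mapped_reads must be > 0")
  if (anyDuplicated(m[, .(donor_id, time_point, protocol)]))
    stop("(donor_id, time_point, protocol) must be unique")
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id")
  data.table::setattr(m, "class", c("sample_metadata", class(m)))
  m
}

#' Compute RPKM from read counts
#'
#' `rpkm = count * 1e9 / (length_bp * total_mapped_reads)`.  At the
#' transcript level `lengths` is the exonic length; at the locus level
#' the intron-inclusive span length (with reads counted over the whole
#' span) should be supplied.
#'
#' @param counts feature x sample matrix of read (fragment) counts with
#'   dimnames.
#' @param lengths named vector of feature lengths in bp.
#' @param meta [sample_metadata()] covering all count columns.
#' @return feature x sample RPKM matrix.
#' @export
compute_rpkm <- function(counts, lengths, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  lens <- lengths[rownames(counts)]
  if (anyNA(lens)) stop("missing length for some features")
  if (any(lens <= 0)) stop("feature lengths must be > 0")
  tot <- meta$total_mapped_reads[match(colnames(counts), meta$sample_id)]
  if (anyNA(tot)) stop("missing metadata for some samples")
  sweep(sweep(counts, 1L, lens, "/"), 2L, tot, "/") * 1e9
}

#' Donor-level expression: mean over a donor's replicate samples
#'
#' @param expr feature x sample RPKM matrix.
#' @param meta [sample_metadata()].
#' @param protocol restrict to one library protocol (default: all
#'   samples in `expr`); polyA and ribo-depleted data are never mixed
#'   within one statistic.
#' @return feature x donor matrix of arithmetic means.
#' @export
donor_mean <- function(expr, meta, protocol = NULL) {
  m <- meta[sample_id %in% colnames(expr)]
  if (!is.null(protocol)) {
    keep <- m$protocol == protocol
    m <- m[which(keep)]
  }
  if (nrow(m) == 0L) stop("no samples left after protocol filter")
  donors <- unique(m$donor_id)
  out <- vapply(donors, function(d) {
    cols <- m[donor_id == d, sample_id]
    if (length(cols) == 0L) stop("donor without samples: ", d)
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  matrix(out, nrow = nrow(expr),
         dimnames = list(rownames(expr), donors))
}

#' Assign features to expression bins
#'
#' The binning statistic is the maximum over donors of the donor-mean
#' RPKM.  With default edges the bins are (0.5,1], (1,2], (2,4], (4,8],
#' (8,Inf); values at or below the lowest edge are `unbinned` (0).
#'
#' @param dmean feature x donor matrix from [donor_mean()].
#' @param cfg an [analysis_config()].
#' @return data.table (feature_id, stat, bin); bin 0 = unbinned.
#' @export
assign_bin <- function(dmean, cfg = analysis_config()) {
  stat <- apply(dmean, 1L, max)
  edges <- cfg$expression_bins
  # bins are left-open: bin(x) = number of edges strictly below x, so a
  # value exactly on an edge falls into the lower bin and x <= min edge
  # is unbinned (bin 0)
  bin <- rowSums(outer(stat, edges, ">"))
  data.table::data.table(feature_id = rownames(dmean), stat = stat,
                         bin = as.integer(bin))
}

#' PolyA+ enrichment per feature
#'
#' Ratio of a feature's mean RPKM across polyA-selected samples to its
#' mean across ribosome-depleted samples.  Features whose ribo-depleted
#' mean is below the detection cutoff are excluded (ratio NA).
#'
#' @param expr_polya,expr_total feature x sample RPKM matrices sharing
#'   rownames.
#' @param cfg an [analysis_config()].
#' @return data.table (feature_id, polya_mean, total_mean, ratio,
#'   excluded).
#' @export
polya_enrichment <- function(expr_polya, expr_total,
                             cfg = analysis_config()) {
  feats <- intersect(rownames(expr_polya), rownames(expr_total))
  pm <- rowMeans(expr_polya[feats, , drop = FALSE])
  tm <- rowMeans(expr_total[feats, , drop = FALSE])
  excl <- tm < cfg$detection_rpkm
  ratio <- ifelse(excl, NA_real_, pm / tm)
  data.table::data.table(feature_id = feats, polya_mean = pm,
                         total_mean = tm, ratio = ratio, excluded = excl)
}

#' Tissue-specific expression call
#'
#' A feature is specific to the focal tissue iff its expression there is
#' at least `cfg$tissue_fold` times higher than in every other tissue
#' (inclusive >=).  When the panel maximum is zero the fold ratio is
#' undefined; the feature is then called specific iff it is detected in
#' the focal tissue (>= detection cutoff), and flagged.
#'
#' @param target named vector of focal-tissue RPKM per feature.
#' @param panel feature x tissue RPKM matrix (same feature order).
#' @param cfg an [analysis_config()].
#' @return data.table (feature_id, target, panel_max, specific, flag).
#' @export
tissue_specific <- function(target, panel, cfg = analysis_config()) {
  panel <- as.matrix(panel)
  if (length(target) != nrow(panel))
    stop("target and panel must cover the same features")
  if (ncol(panel) < 1L) stop("panel must contain at least one tissue")
  pmax_ <- apply(panel, 1L, max)
  zero <- pmax_ == 0
  spec <- ifelse(zero, target >= cfg$detection_rpkm,
                 target >= cfg$tissue_fold * pmax_)
  data.table::data.table(
    feature_id = if (is.null(names(target))) rownames(panel)
                 else names(target),
    target = as.numeric(target), panel_max = pmax_,
    specific = as.logical(spec),
    flag = ifelse(zero, "zero_panel", ""))
}
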