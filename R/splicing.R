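# --- splice-site splicing efficiency ---------------------------------------
#
# For every exon/intron junction of a multi-exonic transcript two
# coverage windows are laid out, an exonic and an intronic one, each up
# to 45 bp wide and separated by a 2 x 5 bp excluded zone straddling the
# junction (the exclusion absorbs imprecision in splice-site placement).
# The efficiency of the site in one donor is
#   S = 100 * (1 - RPKM_intronic / RPKM_exonic),  clamped to [0, 100],
# i.e. 100 when no intronic signal is present and 0 when intronic signal
# reaches or exceeds the exonic signal (full absence of splicing).

#' Splice-site coverage windows for a transcript
#'
#' Both ends of every intron are scored as separate sites: the `donor`
#' side at the upstream exon end and the `acceptor` side at the
#' downstream exon start (genomic orientation; labels follow transcript
#' orientation on the minus strand).  Windows are truncated when the
#' flanking exon or intron is short: the exonic window may use at most
#' `exon_length - offset` bp, the intronic window at most
#' `intron_length - 2 * offset` bp (the intron carries an excluded zone
#' at each of its ends).  A site whose truncated exonic or intronic
#' window would be narrower than `cfg$splice_min_window_bp` is skipped.
#'
#' @param ann [annotation_set()].
#' @param cfg an [analysis_config()].
#' @return data.table with one row per retained junction side:
#'   transcript_id, site_id, side ("donor"/"acceptor"), chrom, strand,
#'   exonic_start/exonic_end, intronic_start/intronic_end (0-based
#'   half-open windows).
#' @export
site_windows <- function(ann, cfg = analysis_config()) {
  w <- cfg$splice_window_bp; off <- cfg$splice_offset_bp
  minw <- cfg$splice_min_window_bp
  ex <- ann$exons[order(transcript_id, start)]
  nex <- ex[, .N, by = transcript_id]
  single <- nex[N < 2L, transcript_id]
  if (length(single))
    stop("single-exon transcript(s) have no splice sites: ",
         paste(head(single, 3), collapse = ", "))
  res <- ex[, {
    n <- .N
    up_end <- end[-n]          # upstream exon ends (intron starts)
    dn_start <- start[-1L]     # downstream exon starts (intron ends)
    exlen_up <- end[-n] - start[-n]
    exlen_dn <- end[-1L] - start[-1L]
    intlen <- dn_start - up_end
    # donor side: exonic [e - off - we, e - off), intronic [e + off, e + off + wi)
    we_d <- pmin(w, exlen_up - off)
    wi_d <- pmin(w, intlen - 2L * off)
    # acceptor side: intronic [s - off - wi, s - off), exonic [s + off, s + off + we)
    we_a <- pmin(w, exlen_dn - off)
    wi_a <- pmin(w, intlen - 2L * off)
    d <- data.table::data.table(
      junction = rep(seq_len(n - 1L), 2L),
      side = rep(c("donor", "acceptor"), each = n - 1L),
      exonic_start = c(up_end - off - we_d, dn_start + off),
      exonic_end = c(up_end - off, dn_start + off + we_a),
      intronic_start = c(up_end + off, dn_start - off - wi_a),
      intronic_end = c(up_end + off + wi_d, dn_start - off),
      we = c(we_d, we_a), wi = c(wi_d, wi_a),
      chrom = chrom[1L], strand = strand[1L])
    d[we >= minw & wi >= minw]
  }, by = transcript_id]
  if (nrow(res) == 0L) return(res)
  res[, site_id := paste0(transcript_id, ":", junction, ":", side)]
  res[, c("we", "wi") := NULL]
  data.table::setcolorder(res, c("transcript_id", "site_id", "junction",
                                 "side", "chrom", "strand"))
  res[]
}

#' Per-donor splicing efficiency of splice sites
#'
#' Takes per-donor window RPKMs and applies the clamped efficiency
#' formula.  A site is discarded entirely (all donors) when its exonic
#' RPKM falls below the detection cutoff in any donor.
#'
#' @param windows data.table from [site_windows()] (or any table with a
#'   `site_id` column).
#' @param exonic_rpkm,intronic_rpkm site x donor matrices of window
#'   RPKM, rownames = site_id, identical dimnames.
#' @param cfg an [analysis_config()].
#' @return list with `per_donor` (site x donor matrix of S, NA for
#'   discarded sites) and `site` data.table (site_id, transcript_id,
#'   mean_S, valid).
#' @export
site_efficiency <- function(windows, exonic_rpkm, intronic_rpkm,
                            cfg = analysis_config()) {
  stopifnot(identical(dimnames(exonic_rpkm), dimnames(intronic_rpkm)))
  S <- 100 * (1 - intronic_rpkm / exonic_rpkm)
  S[intronic_rpkm == 0] <- 100       # 0/0 -> site has no signal either way,
  S[exonic_rpkm == 0] <- NA_real_    # but zero exonic signal invalidates it
  S <- pmin(pmax(S, 0), 100)
  bad <- apply(exonic_rpkm < cfg$detection_rpkm, 1L, any)
  S[bad, ] <- NA_real_
  site <- data.table::data.table(
    site_id = rownames(S),
    mean_S = rowMeans(S),
    valid = !bad)
  site[!valid == TRUE, mean_S := NA_real_]
  wt <- data.table::as.data.table(windows)[, .(site_id, transcript_id)]
  site <- merge(site, wt, by = "site_id", sort = FALSE)
  data.table::setcolorder(site, c("site_id", "transcript_id"))
  list(per_donor = S, site = site[])
}

#' Aggregate splicing efficiency to transcripts and loci
#'
#' Transcript efficiency is the donor-mean S of its most efficiently
#' spliced valid site; locus efficiency is the maximum over member
#' transcripts.  Features with no valid site get NA.
#'
#' @param site data.table from [site_efficiency()] (`$site`).
#' @param ann [annotation_set()] (needed with loci built for
#'   `level = "locus"`).
#' @param level `"transcript"` or `"locus"`.
#' @return data.table (id, S).
#' @export
aggregate_efficiency <- function(site, ann = NULL,
                                 level = c("transcript", "locus")) {
  level <- match.arg(level)
  tr <- site[, .(S = if (all(is.na(mean_S))) NA_real_
                 else max(mean_S, na.rm = TRUE)), by = transcript_id]
  data.table::setnames(tr, "transcript_id", "id")
  if (level == "transcript") return(tr[])
  if (is.null(ann) || is.null(ann$loci))
    stop("locus-level aggregation requires an annotation with loci")
  mem <- ann$transcripts[, .(transcript_id, locus_id)]
  lv <- merge(tr, mem, by.x = "id", by.y = "transcript_id")
  out <- lv[, .(S = if (all(is.na(S))) NA_real_
                else max(S, na.rm = TRUE)), by = locus_id]
  data.table::setnames(out, "locus_id", "id")
  out[]
}

#' Window RPKM from per-window read counts
#'
#' Applies the standard RPKM formula with the window width as feature
#' length.
#'
#' @param counts site x donor matrix of window read counts.
#' @param widths named vector of window widths in bp (by site_id).
#' @param total_reads named vector of total mapped reads per donor
#'   (column order of `counts`).
#' @return site x donor RPKM matrix.
#' @export
window_rpkm <- function(counts, widths, total_reads) {
  counts <- as.matrix(counts)
  wd <- widths[rownames(counts)]
  tot <- total_reads[colnames(counts)]
  if (anyNA(wd) || anyNA(tot)) stop("missing window width or library size")
  sweep(sweep(counts, 1L, wd, "/"), 2L, tot, "/") * 1e9
}
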