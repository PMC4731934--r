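#' Transcript annotation set
#'
#' The central container of the package: a set of exon-structured
#' transcript models, optionally grouped into strand-aware loci.  All
#' coordinates are 0-based half-open (BED convention); GTF input is
#' converted on read.
#'
#' @param transcripts data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (one of `"+"`, `"-"`, `"."`), and
#'   optionally `biotype` (one of mRNA, lncRNA, candidate, pseudogene,
#'   other), `source` and `locus_id`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#'   `chrom`/`strand` are inherited from the transcript when absent.
#'   Exons of one transcript must be sorted, non-overlapping and lie
#'   within the transcript span.
#'
#' @return object of class `annotation_set`: a list with data.tables
#'   `transcripts`, `exons`, and (after [build_loci()]) `loci`.
#' @export
annotation_set <- function(transcripts, exons) {
  tx <- data.table::as.data.table(transcripts)
  ex <- data.table::as.data.table(exons)
  req <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(tx)))
    stop("transcripts must have columns: ", paste(req, collapse = ", "))
  if (!all(c("transcript_id", "start", "end") %in% names(ex)))
    stop("exons must have columns transcript_id, start, end")
  if (anyDuplicated(tx$transcript_id))
    stop("duplicate transcript_id in transcripts")
  if (!"biotype" %in% names(tx)) tx[, biotype := "candidate"]
  if (!"source" %in% names(tx)) tx[, source := "unknown"]
  if (!"locus_id" %in% names(tx)) tx[, locus_id := NA_character_]
  tx[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (!"chrom" %in% names(ex))
    ex <- merge(ex, tx[, .(transcript_id, chrom, strand)],
                by = "transcript_id", sort = FALSE)
  if (!"strand" %in% names(ex))
    ex <- merge(ex, tx[, .(transcript_id, strand)],
                by = "transcript_id", sort = FALSE)
  ex[, `:=`(start = as.integer(start), end = as.integer(end))]
  data.table::setkey(ex, transcript_id, start)
  data.table::setcolorder(
    ex, c("transcript_id", "chrom", "start", "end", "strand"))
  ann <- structure(list(transcripts = tx, exons = ex, loci = NULL),
                   class = "annotation_set")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  tx <- ann$transcripts; ex <- ann$exons
  if (any(tx$start < 0L) || any(tx$start >= tx$end))
    stop("invalid transcript span: need 0 <= start < end")
  if (!all(tx$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (any(ex$start < 0L) || any(ex$start >= ex$end))
    stop("invalid exon interval: need 0 <= start < end")
  missing_tx <- setdiff(ex$transcript_id, tx$transcript_id)
  if (length(missing_tx))
    stop("exons reference unknown transcripts: ",
         paste(head(missing_tx, 3), collapse = ", "))
  no_exon <- setdiff(tx$transcript_id, ex$transcript_id)
  if (length(no_exon))
    stop("transcripts without exons: ", paste(head(no_exon, 3), collapse = ", "))
  chk <- merge(ex, tx[, .(transcript_id, tchrom = chrom, tstrand = strand,
                          tstart = start, tend = end)],
               by = "transcript_id", sort = FALSE)
  if (any(chk$chrom != chk$tchrom) || any(chk$strand != chk$tstrand))
    stop("exon chrom/strand differs from transcript span")
  if (any(chk$start < chk$tstart) || any(chk$end > chk$tend))
    stop("exon outside transcript span")
  bad <- ex[, .(ok = .N <= 1L || all(start[-1L] >= end[-.N])),
            by = transcript_id][!ok == TRUE]
  if (nrow(bad))
    stop("overlapping or unsorted exons within transcript: ",
         paste(head(bad$transcript_id, 3), collapse = ", "))
  invisible(ann)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcripts, %d exons",
              nrow(x$transcripts), nrow(x$exons)))
  if (!is.null(x$loci)) cat(sprintf(", %d loci", nrow(x$loci)))
  cat("\n")
  if (nrow(x$transcripts)) {
    bt <- table(x$transcripts$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of transcripts in an annotation set
#' @param ann an `annotation_set`.
#' @return integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$transcripts)

#' Subset an annotation set by transcript id
#' @param ann an `annotation_set`.
#' @param ids transcript identifiers to keep.
#' @return a new `annotation_set` (loci are dropped; rebuild if needed).
#' @export
annotation_subset <- function(ann, ids) {
  annotation_set(ann$transcripts[transcript_id %in% ids],
                 ann$exons[transcript_id %in% ids])
}

#' Exonic length per transcript
#' @param ann an `annotation_set`.
#' @return named integer vector, sum of exon widths per transcript.
#' @export
exonic_lengths <- function(ann) {
  el <- ann$exons[, .(len = sum(end - start)), by = transcript_id]
  stats::setNames(el$len, el$transcript_id)
}

# exon table -> GRanges (1-based closed for IRanges machinery).
# Unstranded "." maps to "*" but strand equality is enforced separately
# where it matters, so "*" never silently joins "+"/"-" features.
.gr_exons <- function(ex) {
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand == ".", "*", ex$strand))
}

# all pairs of (query exon row, subject exon row) with >= 1 bp overlap,
# restricted to identical strand symbols when same_strand = TRUE
.exon_overlap_pairs <- function(qex, sex, same_strand = TRUE) {
  if (nrow(qex) == 0L || nrow(sex) == 0L)
    return(data.table::data.table(q = integer(), s = integer(),
                                  bp = integer()))
  hits <- GenomicRanges::findOverlaps(.gr_exons(qex), .gr_exons(sex),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- qex$chrom[q] == sex$chrom[s]
  if (same_strand) keep <- keep & qex$strand[q] == sex$strand[s]
  q <- q[keep]; s <- s[keep]
  bp <- pmin(qex$end[q], sex$end[s]) - pmax(qex$start[q], sex$start[s])
  data.table::data.table(q = q, s = s, bp = as.integer(bp))
}

#' Exonic overlap between two transcripts in base pairs
#'
#' Symmetric; returns 0 when the transcripts sit on different
#' chromosomes or strands (unstranded "." only matches ".").
#'
#' @param a,b exon tables (data.frames with `chrom`, `start`, `end`,
#'   `strand`) for a single transcript each, e.g. via
#'   `ann$exons[transcript_id == id]`.
#' @return integer base-pair count of exonic intersection.
#' @export
exonic_overlap_bp <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) return(0L)
  # merge each side first so shared regions are not double counted
  am <- merge_intervals(a); bm <- merge_intervals(b)
  prs <- .exon_overlap_pairs(am, bm, same_strand = TRUE)
  as.integer(sum(prs$bp))
}

#' Merge overlapping intervals within one chrom/strand group
#' @param ex data.frame with `chrom`, `start`, `end`, `strand`.
#' @return data.table of disjoint merged intervals, sorted.
#' @export
merge_intervals <- function(ex) {
  ex <- data.table::as.data.table(ex)[order(chrom, strand, start, end)]
  if (nrow(ex) <= 1L) return(ex[, .(chrom, start, end, strand)])
  ex[, grp := {
    newblk <- c(TRUE, start[-1L] > cummax(end[-.N]))
    cumsum(newblk)
  }, by = .(chrom, strand)]
  out <- ex[, .(start = min(start), end = max(end)),
            by = .(chrom, strand, grp)][, grp := NULL]
  out[order(chrom, strand, start), .(chrom, start, end, strand)]
}

#' Group transcripts into loci by same-strand exonic overlap
#'
#' Loci are the connected components of the graph whose edges join
#' transcripts on the same chromosome and strand that share at least one
#' exonic base pair (transitive closure).  Unstranded transcripts only
#' group with other unstranded transcripts.  Locus identifiers are
#' assigned deterministically in (chrom, start) order.
#'
#' @param ann an `annotation_set`.
#' @param prefix locus id prefix (default from `cfg`, "loc").
#' @return the `annotation_set` with `transcripts$locus_id` filled and a
#'   `loci` data.table (locus_id, chrom, start, end, strand, biotype,
#'   n_transcripts).
#' @export
build_loci <- function(ann, prefix = "loc") {
  tx <- data.table::copy(ann$transcripts)
  ex <- ann$exons
  txids <- tx$transcript_id
  prs <- .exon_overlap_pairs(ex, ex, same_strand = TRUE)
  eq <- data.table::data.table(a = ex$transcript_id[prs$q],
                               b = ex$transcript_id[prs$s])
  eq <- unique(eq[a != b])
  g <- igraph::graph_from_data_frame(
    eq, directed = FALSE,
    vertices = data.frame(name = txids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[txids]
  tx[, locus_id := paste0(".comp", comp)]
  loci <- merge(tx, ex[, .(exmin = min(start), exmax = max(end)),
                       by = transcript_id],
                by = "transcript_id")[
    , .(chrom = chrom[1L], start = min(exmin), end = max(exmax),
        strand = strand[1L],
        biotype = names(sort(table(biotype), decreasing = TRUE))[1L],
        n_transcripts = .N),
    by = locus_id]
  data.table::setorder(loci, chrom, start, end, strand)
  loci[, new_id := sprintf("%s%d", prefix, seq_len(.N))]
  remap <- stats::setNames(loci$new_id, loci$locus_id)
  tx[, locus_id := remap[locus_id]]
  loci[, locus_id := new_id][, new_id := NULL]
  loci[, `:=`(positional_class = NA_character_,
              novelty_class = NA_character_)]
  data.table::setcolorder(loci, c("locus_id", "chrom", "start", "end",
                                  "strand", "biotype", "n_transcripts"))
  out <- ann
  out$transcripts <- tx
  out$loci <- loci
  out
}

#' Strand-aware transcription start sites
#'
#' @param ann an `annotation_set`.
#' @return data.table (transcript_id, chrom, tss, strand); `tss` is the
#'   0-based position of the 5' end (span start on "+", span end on "-").
#'   Unstranded transcripts get NA.
#' @export
transcript_tss <- function(ann) {
  tx <- ann$transcripts
  tss <- ifelse(tx$strand == "+", tx$start,
                ifelse(tx$strand == "-", tx$end, NA_integer_))
  data.table::data.table(transcript_id = tx$transcript_id,
                         chrom = tx$chrom, tss = as.integer(tss),
                         strand = tx$strand)
}
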