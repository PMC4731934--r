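#' Read a BED12 file into an annotation set
#'
#' Standard 12-column BED: exon blocks are expanded into exon intervals
#' using `blockSizes`/`blockStarts`.  Coordinates stay 0-based half-open.
#'
#' @param path BED12 file path.
#' @param biotype biotype assigned to all records (default "candidate").
#' @param source source tag recorded per transcript.
#' @return an [annotation_set()].
#' @export
read_bed12 <- function(path, biotype = "candidate", source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L)
    return(annotation_set(
      data.table::data.table(transcript_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             strand = character()),
      data.table::data.table(transcript_id = character(), start = integer(),
                             end = integer())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("malformed BED12 at line ", which(nf < 12L)[1L],
         ": expected 12 tab-separated fields, found ", nf[nf < 12L][1L])
  tx_list <- vector("list", length(fields))
  ex_list <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    chrom <- f[1L]
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    name <- f[4L]
    strand <- f[6L]
    n_blocks <- suppressWarnings(as.integer(f[10L]))
    if (is.na(start) || is.na(end) || is.na(n_blocks))
      stop("malformed BED12 at line ", i, ": non-numeric coordinate field")
    sizes <- suppressWarnings(
      as.integer(strsplit(sub(",$", "", f[11L]), ",", fixed = TRUE)[[1L]]))
    offs <- suppressWarnings(
      as.integer(strsplit(sub(",$", "", f[12L]), ",", fixed = TRUE)[[1L]]))
    if (length(sizes) != n_blocks || length(offs) != n_blocks ||
        anyNA(sizes) || anyNA(offs))
      stop("BED12 blockCount mismatch at line ", i, ": blockCount=",
           n_blocks, " but ", length(sizes), " sizes / ", length(offs),
           " starts")
    es <- start + offs
    ee <- es + sizes
    if (es[1L] != start || ee[n_blocks] != end)
      stop("BED12 block arithmetic inconsistent with span at line ", i)
    tx_list[[i]] <- data.table::data.table(
      transcript_id = name, chrom = chrom, start = start, end = end,
      strand = strand)
    ex_list[[i]] <- data.table::data.table(
      transcript_id = name, chrom = chrom, start = es, end = ee,
      strand = strand)
  }
  tx <- data.table::rbindlist(tx_list)
  ex <- data.table::rbindlist(ex_list)
  tx[, `:=`(biotype = biotype, source = source)]
  annotation_set(tx, ex)
}

#' Write an annotation set as BED12
#'
#' One line per transcript in canonical form: score 0, thickStart/End
#' equal to the span, itemRgb 0, comma-separated block arrays without a
#' trailing comma.  `write_bed12(read_bed12(p))` reproduces the
#' canonicalised input byte for byte.
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(ann, path) {
  tx <- ann$transcripts[order(chrom, start, end, transcript_id)]
  ex <- merge(ann$exons, tx[, .(transcript_id, tstart = start)],
              by = "transcript_id", sort = FALSE)
  data.table::setorder(ex, transcript_id, start)
  blk <- ex[, .(n_blocks = .N,
                sizes = paste(end - start, collapse = ","),
                offs = paste(start - tstart, collapse = ",")),
            by = transcript_id]
  tx <- merge(tx, blk, by = "transcript_id", sort = FALSE)
  data.table::setorder(tx, chrom, start, end, transcript_id)
  lines <- paste(tx$chrom, tx$start, tx$end, tx$transcript_id, 0L,
                 tx$strand, tx$start, tx$end, 0L, tx$n_blocks, tx$sizes,
                 tx$offs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read exon features from a GTF file into an annotation set
#'
#' Only `exon` features are used; each must carry a `transcript_id`
#' attribute.  1-based inclusive GTF coordinates are converted to the
#' internal 0-based half-open convention.  Duplicate
#' (transcript_id, exon) records are dropped with a warning.
#'
#' @param path GTF file path.
#' @param biotype,source as in [read_bed12()].
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path, biotype = "candidate", source = basename(path)) {
  cols <- c("chrom", "src", "feature", "start", "end", "score", "strand",
            "frame", "attributes")
  g <- data.table::fread(path, sep = "\t", header = FALSE, col.names = cols,
                         quote = "", fill = TRUE)
  g <- g[feature == "exon"]
  if (nrow(g) == 0L) stop("no exon features in GTF: ", path)
  m <- regmatches(g$attributes,
                  regexpr('transcript_id "[^"]+"', g$attributes))
  has_id <- grepl('transcript_id "', g$attributes, fixed = TRUE)
  if (!all(has_id))
    stop("GTF exon without transcript_id attribute (record ",
         which(!has_id)[1L], ")")
  g[, transcript_id := sub('transcript_id "([^"]+)"', "\\1", m)]
  # GTF 1-based inclusive -> 0-based half-open
  g[, `:=`(start = as.integer(start) - 1L, end = as.integer(end))]
  ndup <- sum(duplicated(g[, .(transcript_id, chrom, start, end)]))
  if (ndup > 0L) {
    warning("dropping ", ndup, " duplicate exon record(s) in ", path)
    g <- unique(g, by = c("transcript_id", "chrom", "start", "end"))
  }
  ex <- g[, .(transcript_id, chrom, start, end, strand)]
  tx <- ex[, .(chrom = chrom[1L], start = min(start), end = max(end),
               strand = strand[1L]), by = transcript_id]
  tx[, `:=`(biotype = biotype, source = source)]
  annotation_set(tx, ex)
}
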