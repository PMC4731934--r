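# fixture builders shared across test files; everything is constructed
# in code, no binary fixtures

# quick annotation_set from a compact spec:
#   list(id = list(chrom, strand, exons = list(c(start, end), ...)))
make_ann <- function(spec) {
  tx <- data.table::rbindlist(lapply(names(spec), function(id) {
    s <- spec[[id]]
    ex <- do.call(rbind, s$exons)
    data.table::data.table(transcript_id = id, chrom = s$chrom,
                           start = min(ex[, 1]), end = max(ex[, 2]),
                           strand = s$strand)
  }))
  ex <- data.table::rbindlist(lapply(names(spec), function(id) {
    s <- spec[[id]]
    ex <- do.call(rbind, s$exons)
    data.table::data.table(transcript_id = id, chrom = s$chrom,
                           start = ex[, 1], end = ex[, 2],
                           strand = s$strand)
  }))
  annotation_set(tx, ex)
}

# single multi-exon transcript helper
one_tx <- function(id, chrom, strand, exons) {
  spec <- stats::setNames(list(list(chrom = chrom, strand = strand,
                                    exons = exons)), id)
  make_ann(spec)
}

# independent brute-force union-find oracle over same-strand exonic
# overlap; returns the partition as a sorted list of sorted id vectors
oracle_loci <- function(ann) {
  ids <- ann$transcripts$transcript_id
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  exs <- split(ann$exons, by = "transcript_id")
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      if (exonic_overlap_bp(exs[[ids[i]]], exs[[ids[j]]]) > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  comps <- unname(split(ids, roots))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# partition produced by build_loci in the same canonical form
built_partition <- function(ann) {
  b <- build_loci(ann)
  comps <- split(b$transcripts$transcript_id, b$transcripts$locus_id)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, character(1), 1L))])
}

# brute-force BH step-up from the definition: q_i = min over p_(j) >= p_i
# of p_(j) * m / rank(j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq(from = which(o == i), to = m), function(k)
      p[o[k]] * m / k, numeric(1))
    r[i] <- min(1, cand)
  }
  r
}

# 7 donors x 3 replicates metadata, ribo-depleted
make_meta21 <- function(depth = 5e7) {
  donors <- sprintf("D%d", 1:7)
  sample_metadata(data.table::data.table(
    sample_id = as.vector(outer(donors, 1:3,
                                function(d, t) sprintf("%s_T%d", d, t))),
    donor_id = rep(donors, 3),
    time_point = rep(1:3, each = 7),
    protocol = "ribo_depleted",
    total_mapped_reads = depth))
}
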