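# --- donor-saturation discovery curves -------------------------------------
#
# The discovery analysis asks how the number of annotated loci grows as
# assemblies from more donors are merged before the identification
# cascade.  Read-level assembly is emulated by a detection model: a
# transcript is found in a pool when its pooled expression (mean over
# the pool's member donors) reaches the assembly threshold, optionally
# softened to a logistic detection probability centred on the threshold.

#' Design donor pools for the saturation analysis
#'
#' Donors are grouped into pools of four (two female + two male, same
#' population), deterministically given a seed.
#'
#' @param donors data.frame with columns `donor_id`, `sex` ("F"/"M"),
#'   `population`.
#' @param reads_per_donor nominal reads sampled per donor (recorded
#'   only).
#' @param seed integer seed for the shuffling.
#' @return data.table (pool_id, donor_id, sex, population,
#'   reads_per_donor); every donor appears in exactly one pool.
#' @export
design_pools <- function(donors, reads_per_donor = 25e6, seed = 1L) {
  d <- data.table::as.data.table(donors)
  stopifnot(all(c("donor_id", "sex", "population") %in% names(d)))
  tab <- d[, .(nF = sum(sex == "F"), nM = sum(sex == "M")),
           by = population]
  bad <- tab[nF %% 2L != 0L | nM %% 2L != 0L | nF != nM]
  if (nrow(bad))
    stop("cannot form balanced 2F+2M pools; offending population(s): ",
         paste(sprintf("%s (F=%d, M=%d)", bad$population, bad$nF, bad$nM),
               collapse = ", "))
  set.seed(as.integer(seed))
  pools <- list(); pid <- 0L
  for (pop in sort(unique(d$population))) {
    f <- sample(d[population == pop & sex == "F", donor_id])
    m <- sample(d[population == pop & sex == "M", donor_id])
    for (i in seq_len(length(f) / 2L)) {
      pid <- pid + 1L
      pools[[pid]] <- data.table::data.table(
        pool_id = sprintf("pool%02d", pid),
        donor_id = c(f[2L * i - 1L], f[2L * i], m[2L * i - 1L], m[2L * i]))
    }
  }
  out <- data.table::rbindlist(pools)
  out <- merge(out, d[, .(donor_id, sex, population)], by = "donor_id",
               sort = FALSE)
  out[, reads_per_donor := reads_per_donor]
  data.table::setcolorder(out, c("pool_id", "donor_id", "sex",
                                 "population", "reads_per_donor"))
  out[order(pool_id, donor_id)][]
}

#' Emulate transcriptome assembly of one pool by a detection model
#'
#' A transcript is detected when its pooled expression (arithmetic mean
#' of the member donors' values) reaches `cfg$assembly_theta`; in
#' `"logistic"` mode detection is Bernoulli with probability
#' `plogis(slope * (log10(pooled) - log10(theta)))`, i.e. 0.5 exactly at
#' the threshold.
#'
#' @param pool character vector of member donor ids.
#' @param truth truth [annotation_set()].
#' @param donor_expr feature x donor RPKM matrix covering all truth
#'   transcripts.
#' @param cfg an [analysis_config()].
#' @param seed seed for the logistic mode (ignored in deterministic
#'   mode).
#' @return character vector of detected transcript ids (a subset of the
#'   truth set).
#' @export
emulate_assembly <- function(pool, truth, donor_expr,
                             cfg = analysis_config(), seed = 1L) {
  ids <- truth$transcripts$transcript_id
  missing <- setdiff(ids, rownames(donor_expr))
  if (length(missing))
    stop("donor_expr lacks truth transcripts: ",
         paste(head(missing, 3), collapse = ", "))
  pooled <- rowMeans(donor_expr[ids, pool, drop = FALSE])
  if (cfg$detection_mode == "deterministic") {
    det <- pooled >= cfg$assembly_theta
  } else {
    pr <- stats::plogis(cfg$logistic_slope *
                          (log10(pmax(pooled, 1e-12)) -
                             log10(cfg$assembly_theta)))
    set.seed(as.integer(seed))
    det <- stats::runif(length(pr)) < pr
  }
  ids[det]
}

# intron-chain identity key: chrom, strand and the ordered intron
# coordinates (exon boundaries excluding the outermost ends)
.intron_chain_key <- function(ann) {
  ex <- ann$exons[order(transcript_id, start)]
  ex[, {
    n <- .N
    ch <- if (n >= 2L)
      paste(c(rbind(end[-n], start[-1L])), collapse = ",")
    else sprintf("monoexonic:%d-%d", start, end)
    list(key = paste(chrom[1L], strand[1L], ch, sep = "|"))
  }, by = transcript_id]
}

#' Merge assemblies, de-duplicating by intron-chain identity
#'
#' Transcripts present in several assemblies are kept once; two
#' transcripts are the same iff they share chromosome, strand and the
#' exact ordered intron coordinates.
#'
#' @param assemblies list of character vectors of transcript ids (one
#'   per assembly).
#' @param truth truth [annotation_set()] the ids refer to.
#' @return merged [annotation_set()].
#' @export
merge_assemblies <- function(assemblies, truth) {
  if (length(assemblies) == 0L) stop("need at least one assembly")
  ids <- unique(unlist(assemblies))
  ann <- annotation_subset(truth, ids)
  ick <- .intron_chain_key(ann)
  keep <- ick$transcript_id[!duplicated(ick$key)]
  annotation_subset(ann, keep)
}

#' Donor-saturation curve
#'
#' For each k in `k_list`, picks k assemblies uniformly without
#' replacement (`reps` independent picks; a single pick when k equals
#' the number of available assemblies), merges them, runs the
#' identification cascade and counts lncRNA/mRNA loci and transcripts.
#'
#' @param assemblies list of detected-transcript id vectors (one per
#'   pool).
#' @param truth truth [annotation_set()].
#' @param pc_ref protein-coding reference for the cascade.
#' @param scores coding-potential score table.
#' @param pa optional public-annotation set; when given, known/new
#'   lncRNA locus counts are reported via [locus_novelty()].
#' @param cfg an [analysis_config()].
#' @param k_list numbers of assemblies to merge.
#' @param reps random picks per k.
#' @param seed integer seed.
#' @return data.table (k, n_donors, rep, lnc_loci, mrna_loci, lnc_tx,
#'   mrna_tx, known_lnc_loci, new_lnc_loci).
#' @export
saturation_curve <- function(assemblies, truth, pc_ref, scores, pa = NULL,
                             cfg = analysis_config(),
                             k_list = c(1, 2, 3, 4, 5, 6, 8, 10, 15, 20,
                                        25, 30),
                             reps = 3L, seed = 1L) {
  n_avail <- length(assemblies)
  if (any(k_list > n_avail))
    stop("k exceeds available assemblies (", n_avail, ")")
  seeds <- derive_seeds(seed, length(k_list) * reps)
  rows <- list(); ri <- 0L
  for (ki in seq_along(k_list)) {
    k <- k_list[ki]
    n_reps <- if (k == n_avail) 1L else reps
    for (r in seq_len(n_reps)) {
      set.seed(seeds[(ki - 1L) * reps + r])
      picked <- sample.int(n_avail, k)
      merged <- merge_assemblies(assemblies[picked], truth)
      res <- run_lnc_filter_cascade(merged, pc_ref, scores, cfg = cfg)
      known <- new <- NA_integer_
      if (!is.null(pa) && !is.null(res$lncRNA$loci) &&
          nrow(res$lncRNA$loci) > 0L) {
        nv <- locus_novelty(res$lncRNA, pa)
        known <- sum(nv$novelty_class == "known")
        new <- sum(nv$novelty_class == "new")
      }
      ri <- ri + 1L
      rows[[ri]] <- data.table::data.table(
        k = k, n_donors = 4L * k, rep = r,
        lnc_loci = if (is.null(res$lncRNA$loci)) 0L
                   else nrow(res$lncRNA$loci),
        mrna_loci = if (is.null(res$mRNA$loci)) 0L
                    else nrow(res$mRNA$loci),
        lnc_tx = n_transcripts(res$lncRNA),
        mrna_tx = n_transcripts(res$mRNA),
        known_lnc_loci = known, new_lnc_loci = new)
    }
  }
  data.table::rbindlist(rows)
}

#' Recovery of a reference annotation by a smaller annotation
#'
#' A reference locus counts as recovered when same-strand exonic overlap
#' with the query covers strictly more than `cfg$ref_locus_coverage` of
#' its exonic bases.
#'
#' @param ann_k query [annotation_set()].
#' @param reference reference [annotation_set()] with loci built.
#' @param cfg an [analysis_config()].
#' @return list: `fraction_recovered`, `median_coverage`, and
#'   `per_locus` data.table (locus_id, exonic_bp, covered_bp, coverage,
#'   recovered).
#' @export
reference_recovery <- function(ann_k, reference,
                               cfg = analysis_config()) {
  if (is.null(reference$loci)) stop("reference needs loci (build_loci)")
  ref_ex <- merge(reference$exons,
                  reference$transcripts[, .(transcript_id, locus_id)],
                  by = "transcript_id")
  # merge exons within each reference locus so bases count once
  loc_ex <- ref_ex[, merge_intervals(.SD), by = locus_id,
                   .SDcols = c("chrom", "start", "end", "strand")]
  tot <- loc_ex[, .(exonic_bp = sum(end - start)), by = locus_id]
  if (n_transcripts(ann_k) == 0L) {
    per <- tot[, .(locus_id, exonic_bp, covered_bp = 0L, coverage = 0,
                   recovered = FALSE)]
    return(list(fraction_recovered = 0, median_coverage = 0,
                per_locus = per[]))
  }
  q_ex <- merge_intervals(ann_k$exons)
  prs <- .exon_overlap_pairs(loc_ex, q_ex, same_strand = TRUE)
  cov <- data.table::data.table(locus_id = loc_ex$locus_id[prs$q],
                                bp = prs$bp)
  cov <- cov[, .(covered_bp = sum(bp)), by = locus_id]
  per <- merge(tot, cov, by = "locus_id", all.x = TRUE)
  per[is.na(covered_bp), covered_bp := 0L]
  per[, coverage := covered_bp / exonic_bp]
  per[, recovered := coverage > cfg$ref_locus_coverage]
  list(fraction_recovered = mean(per$recovered),
       median_coverage = stats::median(per$coverage),
       per_locus = per[])
}
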