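#' Analysis configuration
#'
#' Collects every numeric threshold used across the annotation and
#' expression-variability pipeline in one validated object.  Defaults are
#' the values used throughout the granulocyte workflow: an RPKM detection
#' cutoff of 0.2, multi-exonic transcripts strictly longer than 200 bp,
#' coding-potential cutoffs (RNAcode < 18, CPC < 1.6), promoters defined
#' as TSS +/- 1.5 kb, a three-fold tissue-specificity rule, 45 bp splice
#' windows with a 5 bp exclusion zone, and the significance criteria
#' (ANOVA p < 0.01, BH FDR < 0.05, fold change > 3).
#'
#' @param detection_rpkm RPKM below or at which a feature is "not
#'   detected" in a sample. Default 0.2.
#' @param robust_rpkm stricter cutoff for the well-expressed robust list.
#' @param min_length_bp minimal exonic length, exclusive ("longer than").
#' @param min_exons minimal exon count (inclusive).
#' @param rnacode_max transcripts with RNAcode score at or above this are
#'   considered protein-coding (kept as lncRNA iff score < cutoff).
#' @param cpc_max same rule for the CPC score.
#' @param promoter_halfwidth_bp promoter half-width around the TSS.
#' @param tissue_fold fold-ratio for tissue specificity (inclusive >=).
#' @param splice_window_bp width of the exonic/intronic splice windows.
#' @param splice_offset_bp excluded zone on each side of the junction.
#' @param splice_min_window_bp minimal usable window after truncation;
#'   sites with a shorter window are skipped.
#' @param anova_p_max,fdr_max,fold_change_min significance criteria.
#' @param expression_bins numeric vector of interior bin edges; bins are
#'   (e1,e2], ..., (ek,Inf) and values at or below e1 are unbinned.
#' @param ref_locus_coverage fraction of exonic bases of a reference
#'   locus that must be covered for it to count as recovered (exclusive).
#' @param excluded_chroms chromosomes dropped from variability analyses.
#' @param mwu_reps number of subsampling repeats for the equalized
#'   Mann-Whitney test.
#' @param assembly_theta pooled-RPKM threshold of the emulated assembly
#'   detection model.
#' @param detection_mode `"deterministic"` or `"logistic"` detection in
#'   the emulated assembly.
#' @param logistic_slope slope (per log10-RPKM unit) of the logistic
#'   detection model.
#' @param locus_prefix prefix for deterministic locus identifiers.
#' @param missing_score_policy `"keep"` (absent coding-potential score is
#'   treated as absence of coding evidence) or `"drop"`.
#' @param random_seed master seed recorded in the config.
#'
#' @return object of class `lncvar_config` (a validated named list).
#' @export
analysis_config <- function(detection_rpkm = 0.2,
                            robust_rpkm = 1.0,
                            min_length_bp = 200L,
                            min_exons = 2L,
                            rnacode_max = 18,
                            cpc_max = 1.6,
                            promoter_halfwidth_bp = 1500L,
                            tissue_fold = 3,
                            splice_window_bp = 45L,
                            splice_offset_bp = 5L,
                            splice_min_window_bp = 10L,
                            anova_p_max = 0.01,
                            fdr_max = 0.05,
                            fold_change_min = 3,
                            expression_bins = c(0.5, 1, 2, 4, 8),
                            ref_locus_coverage = 0.5,
                            excluded_chroms = c("chrX", "chrY"),
                            mwu_reps = 3L,
                            assembly_theta = 0.2,
                            detection_mode = c("deterministic", "logistic"),
                            logistic_slope = 8,
                            locus_prefix = "loc",
                            missing_score_policy = c("keep", "drop"),
                            random_seed = 1L) {
  detection_mode <- match.arg(detection_mode)
  missing_score_policy <- match.arg(missing_score_policy)
  cfg <- list(
    detection_rpkm = detection_rpkm, robust_rpkm = robust_rpkm,
    min_length_bp = as.integer(min_length_bp),
    min_exons = as.integer(min_exons),
    rnacode_max = rnacode_max, cpc_max = cpc_max,
    promoter_halfwidth_bp = as.integer(promoter_halfwidth_bp),
    tissue_fold = tissue_fold,
    splice_window_bp = as.integer(splice_window_bp),
    splice_offset_bp = as.integer(splice_offset_bp),
    splice_min_window_bp = as.integer(splice_min_window_bp),
    anova_p_max = anova_p_max, fdr_max = fdr_max,
    fold_change_min = fold_change_min,
    expression_bins = expression_bins,
    ref_locus_coverage = ref_locus_coverage,
    excluded_chroms = excluded_chroms,
    mwu_reps = as.integer(mwu_reps),
    assembly_theta = assembly_theta,
    detection_mode = detection_mode,
    logistic_slope = logistic_slope,
    locus_prefix = locus_prefix,
    missing_score_policy = missing_score_policy,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "lncvar_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- c("detection_rpkm", "robust_rpkm", "min_length_bp", "min_exons",
           "rnacode_max", "cpc_max", "promoter_halfwidth_bp", "tissue_fold",
           "splice_window_bp", "splice_offset_bp", "splice_min_window_bp",
           "anova_p_max", "fdr_max", "fold_change_min", "ref_locus_coverage",
           "mwu_reps", "assembly_theta")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number")
  }
  b <- cfg$expression_bins
  if (length(b) < 1L || is.unsorted(b, strictly = TRUE))
    stop("expression_bins must be strictly increasing")
  invisible(cfg)
}

#' Read / write an analysis configuration as JSON
#'
#' @param path file path.
#' @param cfg an `lncvar_config`.
#' @return `read_config` returns an `lncvar_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lncvar_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.lncvar_config <- function(x, ...) {
  cat("<lncvar_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-22s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}
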