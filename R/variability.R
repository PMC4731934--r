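# --- expression-variability statistics -------------------------------------

#' Coefficient of variation (normalized standard deviation)
#'
#' `sd(values) / mean(values)` with the sample (n-1) standard deviation.
#' Undefined (NA) when the mean is zero or fewer than two values are
#' given.
#'
#' @param values numeric vector of donor-level expression.
#' @return a single CV value.
#' @export
normalized_sd <- function(values) {
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

# row-wise CV for a feature x donor matrix
.row_cv <- function(x) {
  m <- rowMeans(x)
  n <- ncol(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1L))
  ifelse(m > 0, s / m, NA_real_)
}

#' Feature filter shared by all variability analyses
#'
#' Keeps features detected (donor-mean RPKM above the detection cutoff)
#' in at least one donor and not located on an excluded chromosome.
#'
#' @param dmean feature x donor matrix.
#' @param chroms named chromosome vector per feature (optional; no
#'   chromosome filter when NULL).
#' @param cfg an [analysis_config()].
#' @return character vector of retained feature ids.
#' @export
variability_filter <- function(dmean, chroms = NULL,
                               cfg = analysis_config()) {
  keep <- apply(dmean, 1L, function(v) any(v > cfg$detection_rpkm))
  ids <- rownames(dmean)[keep]
  if (!is.null(chroms))
    ids <- ids[!(chroms[ids] %in% cfg$excluded_chroms)]
  ids
}

#' Inter-individual expression variability
#'
#' CV of donor-mean expression across donors, computed for features
#' passing [variability_filter()].
#'
#' @param expr feature x sample RPKM matrix.
#' @param meta [sample_metadata()].
#' @param chroms optional named chromosome vector for the X/Y exclusion.
#' @param cfg an [analysis_config()].
#' @return data.table (feature_id, grand_mean, sd, cv).
#' @export
inter_individual <- function(expr, meta, chroms = NULL,
                             cfg = analysis_config()) {
  dm <- donor_mean(expr, meta)
  ids <- variability_filter(dm, chroms, cfg)
  dm <- dm[ids, , drop = FALSE]
  m <- rowMeans(dm)
  n <- ncol(dm)
  s <- sqrt(rowSums((dm - m)^2) / (n - 1L))
  data.table::data.table(feature_id = ids, grand_mean = m, sd = s,
                         cv = ifelse(m > 0, s / m, NA_real_))
}

#' Intra-individual expression variability
#'
#' CV across the replicate samples of each donor separately, for
#' features passing the same filter as [inter_individual()].
#'
#' @inheritParams inter_individual
#' @return data.table (feature_id, donor_id, cv).
#' @export
intra_individual <- function(expr, meta, chroms = NULL,
                             cfg = analysis_config()) {
  dm <- donor_mean(expr, meta)
  ids <- variability_filter(dm, chroms, cfg)
  m <- meta[sample_id %in% colnames(expr)]
  out <- lapply(unique(m$donor_id), function(d) {
    cols <- m[donor_id == d, sample_id]
    cv <- .row_cv(expr[ids, cols, drop = FALSE])
    data.table::data.table(feature_id = ids, donor_id = d, cv = cv)
  })
  data.table::rbindlist(out)
}

#' One-way ANOVA across donors, vectorised over features
#'
#' Fixed-effect one-way ANOVA with donor as the factor and the replicate
#' samples (time points) as within-group observations, computed in
#' closed form per feature.  Conventions for degenerate rows: zero
#' between- and within-group variance gives p = 1 (flagged); zero
#' within-group variance with non-zero between-group variance gives
#' p = 0.
#'
#' @param expr feature x sample RPKM matrix (e.g. 7 donors x 3 time
#'   points = 21 columns).
#' @param meta [sample_metadata()].
#' @return data.table (feature_id, f_stat, df1, df2, p, flag).
#' @export
anova_donor <- function(expr, meta) {
  m <- meta[sample_id %in% colnames(expr)]
  groups <- split(m$sample_id, m$donor_id)
  a <- length(groups)
  if (a < 2L) stop("ANOVA needs at least two donors")
  n_i <- lengths(groups)
  N <- sum(n_i)
  if (any(n_i < 2L))
    warning("unbalanced layout: donor(s) with a single replicate")
  gm_list <- lapply(groups, function(cols)
    rowMeans(expr[, cols, drop = FALSE]))
  gm <- do.call(cbind, gm_list)                 # feature x donor means
  grand <- as.vector(gm %*% n_i) / N
  ssb <- as.vector(((gm - grand)^2) %*% n_i)
  sst <- rowSums((expr[, m$sample_id, drop = FALSE] - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- a - 1L; df2 <- N - a
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  flag <- rep("", nrow(expr))
  zero_w <- ssw <= .Machine$double.eps * pmax(sst, 1)
  both0 <- zero_w & ssb <= .Machine$double.eps * pmax(sst, 1)
  p[zero_w & !both0] <- 0
  p[both0] <- 1
  flag[both0] <- "zero_variance"
  data.table::data.table(feature_id = rownames(expr), f_stat = f,
                         df1 = df1, df2 = df2, p = p, flag = flag)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' The standard step-up procedure: order the m p-values increasingly,
#' compute p_(i) * m / i, and enforce monotonicity by taking the running
#' minimum from the largest rank downwards.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed; NA
#'   propagates and does not count towards m).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m == 0L) return(q)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  q[ok[o]] <- adj
  q
}

#' Fold change between highest and lowest donor expression
#'
#' `max(donor means) / max(min(donor means), floor)` where the floor is
#' the detection cutoff, preventing division by (near) zero for donors
#' in which the feature is undetected.
#'
#' @param dmean feature x donor matrix.
#' @param cfg an [analysis_config()].
#' @return named numeric vector of fold changes (>= 1 whenever the
#'   maximum exceeds the floor).
#' @export
fold_change <- function(dmean, cfg = analysis_config()) {
  if (ncol(dmean) < 2L) stop("fold change needs >= 2 donors")
  hi <- apply(dmean, 1L, max)
  lo <- pmax(apply(dmean, 1L, min), cfg$detection_rpkm)
  fc <- hi / lo
  stats::setNames(pmax(fc, 1), rownames(dmean))
}

#' Call significantly variable features
#'
#' Significant iff ANOVA p < `anova_p_max`, BH q < `fdr_max`, fold
#' change > `fold_change_min`, and the feature is detected in at least
#' one donor.
#'
#' @param p,q,fc,detected equal-length vectors of ANOVA p, BH q, fold
#'   change, and detection (logical).
#' @param cfg an [analysis_config()].
#' @return logical vector.
#' @export
call_significant <- function(p, q, fc, detected, cfg = analysis_config()) {
  !is.na(p) & !is.na(q) & !is.na(fc) &
    p < cfg$anova_p_max & q < cfg$fdr_max & fc > cfg$fold_change_min &
    detected
}

#' Full per-feature variability table
#'
#' Combines CV, ANOVA, BH correction, fold change and the significance
#' call into one table for features passing [variability_filter()].
#'
#' @param expr feature x sample RPKM matrix (donors x replicates).
#' @param meta [sample_metadata()].
#' @param chroms optional named chromosome vector (X/Y exclusion).
#' @param cfg an [analysis_config()].
#' @return data.table (feature_id, grand_mean, sd, cv, anova_p, fdr_q,
#'   fold_change, significant).
#' @export
variability_table <- function(expr, meta, chroms = NULL,
                              cfg = analysis_config()) {
  dm <- donor_mean(expr, meta)
  ids <- variability_filter(dm, chroms, cfg)
  sub <- expr[ids, , drop = FALSE]
  dm <- dm[ids, , drop = FALSE]
  cv <- inter_individual(expr, meta, chroms, cfg)
  an <- anova_donor(sub, meta)
  fc <- fold_change(dm, cfg)
  q <- bh_fdr(an$p)
  detected <- apply(dm, 1L, function(v) any(v > cfg$detection_rpkm))
  out <- data.table::data.table(
    feature_id = ids,
    grand_mean = cv$grand_mean[match(ids, cv$feature_id)],
    sd = cv$sd[match(ids, cv$feature_id)],
    cv = cv$cv[match(ids, cv$feature_id)],
    anova_p = an$p, fdr_q = q, fold_change = fc,
    significant = call_significant(an$p, q, fc, detected, cfg))
  out[]
}

#' Intra- and inter-individual reproducibility by expression bin
#'
#' A feature is intra-reproducible iff in every donor its replicates are
#' either all detected (> cutoff) or all undetected; inter-reproducible
#' iff the donor mean exceeds the cutoff in every donor.  Fractions are
#' reported per expression bin (bins from [assign_bin()]).
#'
#' @param expr feature x sample RPKM matrix.
#' @param meta [sample_metadata()].
#' @param cfg an [analysis_config()].
#' @return list with `per_feature` (feature_id, bin, intra_reproducible,
#'   inter_reproducible, all_undetected) and `per_bin` (bin, n,
#'   frac_intra, frac_inter).
#' @export
reproducibility <- function(expr, meta, cfg = analysis_config()) {
  dm <- donor_mean(expr, meta)
  bins <- assign_bin(dm, cfg)
  m <- meta[sample_id %in% colnames(expr)]
  det <- expr > cfg$detection_rpkm
  donors <- unique(m$donor_id)
  intra_by_donor <- vapply(donors, function(d) {
    cols <- m[donor_id == d, sample_id]
    dd <- det[, cols, drop = FALSE]
    rowSums(dd) %in% c(0L, length(cols))
  }, logical(nrow(expr)))
  intra <- apply(matrix(intra_by_donor, nrow = nrow(expr)), 1L, all)
  inter <- apply(dm > cfg$detection_rpkm, 1L, all)
  all_undet <- apply(dm <= cfg$detection_rpkm, 1L, all)
  pf <- data.table::data.table(
    feature_id = rownames(expr), bin = bins$bin,
    intra_reproducible = intra, inter_reproducible = inter,
    all_undetected = all_undet)
  pb <- pf[bin > 0L, .(n = .N, frac_intra = mean(intra_reproducible),
                       frac_inter = mean(inter_reproducible)),
           by = bin][order(bin)]
  list(per_feature = pf[], per_bin = pb[])
}

#' Mann-Whitney U test on equalized population sizes
#'
#' The larger population is subsampled without replacement to the size
#' of the smaller, a two-sided Mann-Whitney U test (normal
#' approximation with tie correction) is applied, and the procedure is
#' repeated `cfg$mwu_reps` times with sub-seeds derived
#' deterministically from `seed`; the repeat p-values are averaged.
#'
#' @param a,b numeric value populations.
#' @param cfg an [analysis_config()].
#' @param seed integer seed for the subsampling.
#' @return list (class `equalized_mwu`): n_a, n_b, n_equalized,
#'   p_values (per repeat), mean_p.
#' @export
equalized_mwu <- function(a, b, cfg = analysis_config(),
                          seed = cfg$random_seed) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both populations need at least two values")
  n <- min(length(a), length(b))
  sub_seeds <- derive_seeds(seed, cfg$mwu_reps)
  ps <- vapply(seq_len(cfg$mwu_reps), function(r) {
    set.seed(sub_seeds[r])
    aa <- if (length(a) > n) sample(a, n) else a
    bb <- if (length(b) > n) sample(b, n) else b
    suppressWarnings(
      stats::wilcox.test(aa, bb, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1L))
  structure(list(n_a = length(a), n_b = length(b), n_equalized = n,
                 p_values = ps, mean_p = mean(ps)),
            class = "equalized_mwu")
}

#' @export
print.equalized_mwu <- function(x, ...) {
  cat(sprintf(
    "<equalized_mwu> n = %d vs %d (equalized %d), mean p = %.4g\n",
    x$n_a, x$n_b, x$n_equalized, x$mean_p))
  invisible(x)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return integer vector of `n` seeds, all below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Robust and variable transcript lists
#'
#' \itemize{
#'   \item robust: RPKM > detection cutoff in all samples;
#'   \item well-expressed robust: RPKM > `robust_rpkm` in all samples
#'     (a subset of robust);
#'   \item significantly variable: [variability_table()] significance.
#' }
#' Locus counts are loci containing at least one qualifying transcript.
#'
#' @param expr feature x sample RPKM matrix (transcript level).
#' @param ann [annotation_set()] with loci built (or NULL to skip locus
#'   counts).
#' @param meta [sample_metadata()].
#' @param chroms optional named chromosome vector (X/Y exclusion for the
#'   variable list).
#' @param cfg an [analysis_config()].
#' @return list with character vectors `robust`,
#'   `well_expressed_robust`, `variable`, and a `counts` data.table
#'   (list, n_transcripts, n_loci).
#' @export
build_lists <- function(expr, ann = NULL, meta, chroms = NULL,
                        cfg = analysis_config()) {
  robust <- rownames(expr)[apply(expr > cfg$detection_rpkm, 1L, all)]
  well <- rownames(expr)[apply(expr > cfg$robust_rpkm, 1L, all)]
  vt <- variability_table(expr, meta, chroms, cfg)
  variable <- vt[significant == TRUE, feature_id]
  n_loci <- function(ids) {
    if (is.null(ann) || is.null(ann$loci)) return(NA_integer_)
    length(unique(
      ann$transcripts[transcript_id %in% ids, locus_id]))
  }
  counts <- data.table::data.table(
    list = c("robust", "well_expressed_robust", "variable"),
    n_transcripts = c(length(robust), length(well), length(variable)),
    n_loci = c(n_loci(robust), n_loci(well), n_loci(variable)))
  list(robust = robust, well_expressed_robust = well,
       variable = variable, counts = counts)
}
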