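# --- orchestration ----------------------------------------------------------

.write_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  path
}

.write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  dt <- data.table::as.data.table(m, keep.rownames = id_col)
  data.table::fwrite(dt, path, sep = "\t")
  path
}

#' Read a feature x sample matrix from TSV
#' @param path TSV with a first id column and one column per sample.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Run a canned end-to-end workflow
#'
#' Workflows:
#' \describe{
#'   \item{simulate}{generate a synthetic dataset and write all of its
#'     files (BED12 annotations, expression TSVs, metadata, scores,
#'     splice-window counts, truth table) to `out_dir`.}
#'   \item{annotate}{run the lncRNA identification cascade on
#'     `inputs$candidates` (BED12) against `inputs$pc_ref` (BED12) and
#'     `inputs$scores` (TSV), classify positionally and write filtered
#'     BED12s, the filter report and the class table.}
#'   \item{variability}{compute the per-feature variability table and
#'     robust/variable lists from `inputs$expr` (TSV matrix) and
#'     `inputs$meta` (TSV).}
#' }
#' A JSON run manifest (config snapshot, input digests, seed, per-stage
#' counts, outputs) is written alongside the outputs; reruns with
#' identical inputs and seed produce identical outputs.
#'
#' @param workflow one of `"simulate"`, `"annotate"`, `"variability"`.
#' @param out_dir output directory (created if missing).
#' @param cfg an [analysis_config()].
#' @param inputs named list of input file paths (see workflows).
#' @param seed integer seed.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(workflow = c("simulate", "annotate", "variability"),
                         out_dir, cfg = analysis_config(),
                         inputs = list(), seed = cfg$random_seed) {
  workflow <- match.arg(workflow)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]]))
      stop("missing input '", nm, "': ", inputs[[nm]])
  }
  t0 <- Sys.time()
  outputs <- character()
  counts <- list()

  if (workflow == "simulate") {
    ds <- generate_dataset(seed = seed)
    outputs <- c(
      truth = write_bed12(ds$truth, file.path(out_dir, "truth.bed12")),
      pc_ref = write_bed12(ds$pc_ref, file.path(out_dir, "pc_ref.bed12")),
      pa = write_bed12(ds$pa, file.path(out_dir, "pa.bed12")),
      scores = .write_tsv(ds$scores, file.path(out_dir, "scores.tsv")),
      meta = .write_tsv(ds$meta, file.path(out_dir, "metadata.tsv")),
      expr_ribo = .write_matrix_tsv(ds$expr$ribo,
                                    file.path(out_dir, "expr_ribo.tsv")),
      expr_polya = .write_matrix_tsv(ds$expr$polya,
                                     file.path(out_dir, "expr_polya.tsv")),
      truth_table = .write_tsv(ds$truth_table,
                               file.path(out_dir, "truth_table.tsv")))
    counts$transcripts <- nrow(ds$truth_table)
  } else if (workflow == "annotate") {
    req <- c("candidates", "pc_ref", "scores")
    if (!all(req %in% names(inputs)))
      stop("annotate needs inputs: ", paste(req, collapse = ", "))
    cand <- read_bed12(inputs$candidates)
    pc <- read_bed12(inputs$pc_ref, biotype = "mRNA")
    sc <- data.table::fread(inputs$scores, sep = "\t")
    res <- run_lnc_filter_cascade(cand, pc, sc, cfg = cfg)
    pos <- positional_classify(res$lncRNA, pc, cfg)
    rep_flat <- data.table::copy(res$report)[, removed_ids := NULL]
    outputs <- c(
      lncRNA = write_bed12(res$lncRNA, file.path(out_dir, "lncRNA.bed12")),
      mRNA = write_bed12(res$mRNA, file.path(out_dir, "mRNA.bed12")),
      report = .write_tsv(rep_flat, file.path(out_dir, "filter_report.tsv")),
      classes = .write_tsv(pos, file.path(out_dir, "positional_class.tsv")))
    counts$lncRNA_transcripts <- n_transcripts(res$lncRNA)
    counts$lncRNA_loci <- nrow(res$lncRNA$loci)
    counts$mRNA_transcripts <- n_transcripts(res$mRNA)
    counts$mRNA_loci <- nrow(res$mRNA$loci)
  } else {
    req <- c("expr", "meta")
    if (!all(req %in% names(inputs)))
      stop("variability needs inputs: ", paste(req, collapse = ", "))
    expr <- read_matrix_tsv(inputs$expr)
    meta <- sample_metadata(data.table::fread(inputs$meta, sep = "\t"))
    vt <- variability_table(expr, meta, cfg = cfg)
    lists <- build_lists(expr, NULL, meta, cfg = cfg)
    outputs <- c(
      variability = .write_tsv(vt, file.path(out_dir, "variability.tsv")),
      lists = .write_tsv(lists$counts, file.path(out_dir, "list_counts.tsv")))
    counts$features <- nrow(vt)
    counts$significant <- sum(vt$significant)
  }

  manifest <- list(
    workflow = workflow,
    version = as.character(utils::packageVersion("lncvar")),
    seed = as.integer(seed),
    config = unclass(cfg),
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1L))),
    counts = counts,
    outputs = as.list(outputs),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches `lncvar <workflow> --out DIR [--config FILE] [--seed N]
#' [--candidates F] [--pc-ref F] [--scores F] [--expr F] [--meta F]`.
#' Intended for use from `Rscript -e 'lncvar::lncvar_cli()'` or the
#' wrapper script shipped in `inst/cli/`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0 on success (invisibly); errors propagate.
#' @export
lncvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: lncvar <simulate|annotate|variability> --out DIR ...")
  workflow <- args[[1L]]
  if (!workflow %in% c("simulate", "annotate", "variability"))
    stop("unknown workflow: ", workflow)
  opt <- list(out = NULL, config = NULL, seed = NULL,
              candidates = NULL, `pc-ref` = NULL, scores = NULL,
              expr = NULL, meta = NULL)
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (!key %in% names(opt)) stop("unknown option: ", rest[[i]])
    if (i + 1L > length(rest)) stop("option ", rest[[i]], " needs a value")
    opt[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  if (is.null(opt$out)) stop("--out is required")
  cfg <- if (is.null(opt$config)) analysis_config() else read_config(opt$config)
  seed <- if (is.null(opt$seed)) cfg$random_seed else as.integer(opt$seed)
  inputs <- list(candidates = opt$candidates, pc_ref = opt$`pc-ref`,
                 scores = opt$scores, expr = opt$expr, meta = opt$meta)
  inputs <- inputs[!vapply(inputs, is.null, logical(1L))]
  run_pipeline(workflow, out_dir = opt$out, cfg = cfg, inputs = inputs,
               seed = seed)
  invisible(0L)
}
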