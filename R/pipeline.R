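#' Read and write count matrices and sample metadata as TSV
#'
#' Count matrices are stored features-in-rows with a leading `feature_id`
#' column; metadata is a plain TSV whose first two columns are `sample_id`
#' and `group` (further clinical columns pass through untouched).
#'
#' @param counts Features x samples matrix.
#' @param path File path.
#' @return Readers return the matrix / data.frame; writers return `path`
#'   invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- as_count_matrix(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stopf("count matrix TSV must start with a feature_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  m
}

#' @rdname write_count_matrix
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(md)))
    stopf("metadata TSV needs columns sample_id and group")
  md
}

#' Run the full screening pipeline
#'
#' Executes the whole analysis end to end: quantification (from FASTQ files
#' and a reference, or from a precomputed count matrix), the univariate
#' screen for the three comparisons against the non-metastasized reference,
#' overlap statistics of the three candidate lists, the exhaustive
#' separating-pair search per comparison, and a descriptive cohort summary.
#' All tables are written as TSV plus a machine-readable `summary.json` and
#' a `manifest.yaml` recording parameters and package version; re-running
#' with the same manifest reproduces the bundle byte for byte.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `metadata` (path or data.frame; required), either `counts` (path or
#'   matrix) or `fastq_dir` + `reference` (path or data.frame); optional
#'   `out_dir` (default `"."`), `adapter`, `min_length`, `min_overlap`,
#'   `max_mismatch`, `end_tolerance`, `alpha`, `min_reads`, `min_fold`,
#'   `p_adjust`, `pool` (`"significant"` or `"filtered"` — which feature
#'   pool enters the pair search).
#' @return Invisibly, a list with `quant`, `cpm`, `screens`, `overlap`,
#'   `pairs`, `cohort` and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  for (req in "metadata")
    if (is.null(config[[req]])) stopf("config is missing input '%s'", req)
  if (is.null(config$counts) &&
      (is.null(config$fastq_dir) || is.null(config$reference)))
    stopf("config is missing input 'counts' (or 'fastq_dir' + 'reference')")

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  metadata <- if (is.character(config$metadata)) read_metadata(config$metadata)
              else config$metadata
  alpha <- config$alpha %||% 0.05
  min_reads <- config$min_reads %||% 50
  min_fold <- config$min_fold %||% 2
  pool <- config$pool %||% "significant"
  p_adjust <- config$p_adjust %||% "none"
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  quant <- NULL
  if (!is.null(config$counts)) {
    counts <- stage("counts",
      if (is.character(config$counts)) read_count_matrix(config$counts)
      else as_count_matrix(config$counts))
  } else {
    quant <- stage("process", {
      ref <- if (is.character(config$reference))
        read_reference_fasta(config$reference) else config$reference
      fq <- sort(list.files(config$fastq_dir, "\\.fastq(\\.gz)?$",
                            full.names = TRUE), method = "radix")
      if (!length(fq)) stopf("no FASTQ files in %s", config$fastq_dir)
      sample_ids <- sub("\\.fastq(\\.gz)?$", "", basename(fq))
      tagsets <- lapply(fq, trim_readset,
                        adapter = config$adapter %||% srna_adapter(),
                        min_overlap = config$min_overlap %||% 7L,
                        max_mismatch = config$max_mismatch %||% 1L,
                        min_length = config$min_length %||% 15L)
      names(tagsets) <- sample_ids
      build_count_matrix(tagsets, ref,
                         end_tolerance = config$end_tolerance %||% 2L)
    })
    counts <- quant$counts
    files["counts"] <- write_count_matrix(counts,
                                          file.path(out_dir, "counts.tsv"))
    write.table(quant$lib_stats, file.path(out_dir, "library_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files["library_stats"] <- file.path(out_dir, "library_stats.tsv")
  }

  comparisons <- c("combined", "lymphogen", "occult")
  screens <- stage("screen", lapply(setNames(comparisons, comparisons),
    function(tg) screen(counts, metadata, tg, alpha = alpha,
                        min_reads = min_reads, min_fold = min_fold,
                        p_adjust = p_adjust)))
  for (tg in comparisons) {
    fn <- file.path(out_dir, paste0("candidates_", tg, ".tsv"))
    write.table(as.data.frame(screens[[tg]]), fn, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[paste0("candidates_", tg)] <- fn
  }

  cand_lists <- lapply(screens, function(s) attr(s, "candidates"))
  overlap <- if (all(lengths(cand_lists) > 0)) {
    stage("overlap", overlap_stats(cand_lists))
  } else NULL
  if (!is.null(overlap)) {
    ov <- as.data.frame(as.table(overlap$percentages),
                        stringsAsFactors = FALSE)
    names(ov) <- c("list_a", "list_b", "pct_of_b_in_a")
    ov$intersection <- as.vector(overlap$intersections)
    fn <- file.path(out_dir, "overlap.tsv")
    write.table(ov, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    files["overlap"] <- fn
  }

  cpm <- normalize_cpm(counts)
  pairs <- stage("pairs", lapply(setNames(comparisons, comparisons),
    function(tg) {
      s <- screens[[tg]]
      ids <- if (pool == "filtered") s$feature_id[s$passed_filter]
             else attr(s, "candidates")
      if (length(ids) < 2) return(NULL)
      enumerate_separating_pairs(cpm, ids, metadata, tg)
    }))
  for (tg in comparisons) {
    if (is.null(pairs[[tg]])) next
    fn <- file.path(out_dir, paste0("pairs_", tg, ".tsv"))
    write.table(as.data.frame(pairs[[tg]]), fn, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[paste0("pairs_", tg)] <- fn
  }

  cohort <- stage("cohort", summarize_cohort(metadata))
  fn <- file.path(out_dir, "cohort_numeric.tsv")
  write.table(cohort$numeric, fn, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files["cohort"] <- fn

  summary <- list(
    n_samples = nrow(metadata),
    n_features = nrow(counts),
    candidates = lapply(cand_lists, as.list),
    n_significant = lapply(cand_lists, length),
    n_separating_pairs = lapply(pairs, function(p)
      if (is.null(p)) 0L else attr(p, "n_separating")),
    svm_disagreements = lapply(pairs, function(p)
      if (is.null(p)) 0L else attr(p, "svm_disagreements")),
    overlap_pct = if (is.null(overlap)) NULL else
      as.list(as.data.frame(overlap$percentages)))
  fn <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, fn, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files["summary"] <- fn

  manifest <- list(
    package = "seminomiR",
    version = as.character(packageVersion("seminomiR")),
    parameters = list(alpha = alpha, min_reads = min_reads,
                      min_fold = min_fold, pool = pool, p_adjust = p_adjust),
    inputs = list(
      counts = if (is.character(config$counts)) config$counts else
        if (!is.null(config$counts)) "in-memory" else NULL,
      fastq_dir = config$fastq_dir,
      reference = if (is.character(config$reference)) config$reference else NULL,
      metadata = if (is.character(config$metadata)) config$metadata else
        "in-memory"))
  fn <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, fn)
  files["manifest"] <- fn

  invisible(list(quant = quant, counts = counts, cpm = cpm,
                 screens = screens, overlap = overlap, pairs = pairs,
                 cohort = cohort, files = files))
}
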