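#' Annotate a tag against the reference library
#'
#' A tag matches a reference entry if it equals the entry's sequence, is a
#' prefix of it missing at most `end_tolerance` 3' bases, or extends it by
#' at most `end_tolerance` 3' bases (the extra bases are ignored) — the
#' usual allowance for 3'-end length heterogeneity of mature small RNAs.
#' miRNA entries take priority over ncRNA entries when both classes match.
#' The assignment is `"unique"` if exactly one entry of the winning class
#' matches, `"ambiguous"` if several do, and `"unannotated"` if none does.
#' With `end_tolerance = 0` the rule reduces to exact string equality.
#'
#' @param tag Tag sequence (a post-trimming insert).
#' @param reference Reference data.frame (see [generate_reference()]).
#' @param end_tolerance Maximum 3'-end length difference tolerated
#'   (default 2 nt).
#' @return A list with `status` (`"unique"`, `"ambiguous"`,
#'   `"unannotated"`) and `feature_id` (the assigned id iff unique).
#' @export
annotate_tag <- function(tag, reference, end_tolerance = 2L) {
  idx <- make_annotation_index(assert_reference(reference), end_tolerance)
  res <- annotate_with_index(tag, idx)
  list(status = res$status,
       feature_id = if (res$status == "unique") res$feature_id else NULL)
}

#' @rdname annotate_tag
#' @param tags Character vector of tags (vectorized annotation).
#' @return `annotate_tags()` returns a data.frame with columns `tag`,
#'   `status` and `feature_id` (`NA` unless unique).
#' @export
annotate_tags <- function(tags, reference, end_tolerance = 2L) {
  idx <- make_annotation_index(assert_reference(reference), end_tolerance)
  res <- annotate_with_index(tags, idx)
  data.frame(tag = tags, status = res$status, feature_id = res$feature_id,
             stringsAsFactors = FALSE)
}

# Hash index over the reference: `prefix` maps every sequence and its
# 3'-truncations (down to end_tolerance missing bases) to entry rows,
# so looking a tag up in `prefix` covers equality and tag-is-truncated
# cases; looking up the tag's own truncations in `exact` covers
# tag-extends-entry cases.
make_annotation_index <- function(reference, end_tolerance = 2L) {
  end_tolerance <- as.integer(end_tolerance)
  prefix <- new.env(hash = TRUE, parent = emptyenv())
  exact <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(reference))) {
    s <- reference$sequence[i]
    L <- nchar(s)
    assign(s, c(get0(s, exact), i), envir = exact)
    for (t in 0:min(end_tolerance, L - 1L)) {
      key <- substr(s, 1, L - t)
      assign(key, c(get0(key, prefix), i), envir = prefix)
    }
  }
  list(prefix = prefix, exact = exact, tol = end_tolerance,
       class = reference$class, feature_id = reference$feature_id)
}

annotate_with_index <- function(tags, idx) {
  status <- character(length(tags))
  fid <- rep(NA_character_, length(tags))
  for (j in seq_along(tags)) {
    tg <- tags[j]
    hits <- get0(tg, idx$prefix)
    if (idx$tol > 0) {
      L <- nchar(tg)
      for (t in seq_len(min(idx$tol, L - 1L)))
        hits <- c(hits, get0(substr(tg, 1, L - t), idx$exact))
    }
    hits <- unique(hits)
    if (!length(hits)) { status[j] <- "unannotated"; next }
    cls <- idx$class[hits]
    win <- if (any(cls == "mirna")) hits[cls == "mirna"] else hits
    if (length(win) == 1L) {
      status[j] <- "unique"
      fid[j] <- idx$feature_id[win]
    } else status[j] <- "ambiguous"
  }
  list(status = status, feature_id = fid)
}

#' Build an annotated count matrix from per-sample tag tables
#'
#' Rows are the reference feature ids; a cell is the summed read count of
#' all tags uniquely assigned to that feature in that sample.  Ambiguous
#' and unannotated tags contribute nothing to the matrix but are tallied in
#' the per-sample library statistics, which mirror the standard library
#' accounting columns: total reads, reads after trimming (abs, %),
#' annotated reads (abs, %), unique tags, annotated tags (abs, %).
#'
#' @param samples Named list of `"srna_tags"` objects from
#'   [trim_readset()]; names are the sample ids.
#' @param reference Reference data.frame.
#' @param end_tolerance 3'-end tolerance passed to the annotator.
#' @return A list of class `"srna_quant"`: `counts` (features x samples
#'   integer matrix) and `lib_stats` (one row per sample).
#' @export
build_count_matrix <- function(samples, reference, end_tolerance = 2L) {
  assert_reference(reference)
  if (length(samples) < 1) stopf("need at least one sample")
  ids <- names(samples)
  if (is.null(ids) || any(!nzchar(ids))) stopf("samples must be named")
  if (anyDuplicated(ids)) stopf("duplicate sample ids")
  idx <- make_annotation_index(reference, end_tolerance)

  counts <- matrix(0L, nrow(reference), length(samples),
                   dimnames = list(reference$feature_id, ids))
  stats <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    ts <- samples[[s]]
    stopifnot(inherits(ts, "srna_tags"))
    acc <- ts$accounting
    tags <- ts$tags
    ann <- annotate_with_index(names(tags), idx)
    uni <- ann$status == "unique"
    if (any(uni)) {
      agg <- tapply(as.integer(tags[uni]), ann$feature_id[uni], sum)
      counts[names(agg), s] <- as.integer(agg)
    }
    annotated_reads <- sum(tags[uni])
    stats[[s]] <- data.frame(
      sample_id = ids[s],
      total_reads = acc$total,
      reads_after_trim = acc$kept,
      pct_after_trim = 100 * acc$kept / max(acc$total, 1),
      annotated_reads = annotated_reads,
      pct_annotated = 100 * annotated_reads / max(acc$kept, 1),
      tags_total = length(tags),
      tags_annotated = sum(uni),
      pct_tags_annotated = 100 * sum(uni) / max(length(tags), 1),
      tags_ambiguous = sum(ann$status == "ambiguous"),
      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, lib_stats = do.call(rbind, stats)),
            class = "srna_quant")
}

#' Per-sample and per-group library accounting report
#'
#' Summarizes the library statistics of an [build_count_matrix()] result by
#' metastasis-status group: mean, between-sample standard deviation (n-1;
#' `NA` for single-sample groups), minimum and maximum of every accounting
#' column.
#'
#' @param quant An `"srna_quant"` object (or its `lib_stats` data.frame).
#' @param metadata Data.frame mapping `sample_id` to `group`.
#' @return A list with `per_sample` (the library stats joined with groups)
#'   and `per_group` (long-format group summary with columns `group`,
#'   `statistic`, one column per accounting metric).
#' @export
library_summary <- function(quant, metadata) {
  stats <- if (inherits(quant, "srna_quant")) quant$lib_stats else quant
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stopf("metadata needs columns sample_id and group")
  miss <- setdiff(stats$sample_id, metadata$sample_id)
  if (length(miss))
    stopf("samples missing from metadata: %s", paste(miss, collapse = ", "))
  per_sample <- merge(stats,
                      metadata[, c("sample_id", "group")], by = "sample_id",
                      sort = FALSE)
  metrics <- setdiff(names(stats), "sample_id")
  rows <- list()
  for (g in unique(per_sample$group)) {
    sub <- per_sample[per_sample$group == g, metrics, drop = FALSE]
    fns <- list(mean = function(v) mean(v),
                stdev = function(v) if (length(v) >= 2) sd(v) else NA_real_,
                min = function(v) min(v),
                max = function(v) max(v))
    for (st in names(fns)) {
      vals <- vapply(sub, function(v) fns[[st]](as.numeric(v)), numeric(1))
      rows[[length(rows) + 1]] <-
        cbind(data.frame(group = g, statistic = st, n = nrow(sub),
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(vals)))
    }
  }
  list(per_sample = per_sample, per_group = do.call(rbind, rows))
}
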