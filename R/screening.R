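#' Counts-per-million normalization
#'
#' Scales each sample column of a raw count matrix to a common library size
#' of one million annotated small-RNA reads.  Library sizes in blood
#' small-RNA data vary several-fold between samples, so all expression
#' comparisons in the screen are made on the CPM scale.
#'
#' @param counts Features x samples matrix of raw counts (an
#'   `"srna_quant"`/`"srna_sim"` object is also accepted).
#' @return Matrix of CPM values; every column sums to 1e6.
#' @export
#' @examples
#' m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(letters[1:3], "s1"))
#' normalize_cpm(m)
normalize_cpm <- function(counts) {
  counts <- as_count_matrix(counts)
  cs <- colSums(counts)
  if (any(cs == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2, cs, "/") * 1e6
}

as_count_matrix <- function(counts) {
  if (inherits(counts, "srna_quant") || inherits(counts, "srna_sim"))
    counts <- counts$counts
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stopf("counts must be non-negative")
  counts
}

# resolve a comparison into reference / target sample ids
comparison_samples <- function(metadata, target,
                               reference_group = "non_metastasized") {
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stopf("metadata needs columns sample_id and group")
  tg <- switch(target,
               lymphogen = "lymphogen", occult = "occult",
               combined = c("lymphogen", "occult"),
               stopf("unknown comparison target '%s'", target))
  bad <- setdiff(metadata$group, srna_groups())
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  list(ref = metadata$sample_id[metadata$group == reference_group],
       target = metadata$sample_id[metadata$group %in% tg])
}

#' Candidate filter: read depth and fold change
#'
#' Applies the screen's entry filter for one comparison against the
#' non-metastasized reference group: a small RNA is retained iff its mean
#' raw count is at least `min_reads` in at least one of the two compared
#' groups, and the ratio of CPM group means (target / reference, with a
#' pseudocount of 0.5 added to each mean) is at least `min_fold` or at most
#' `1/min_fold`.
#'
#' @param counts Raw count matrix (features x samples).
#' @param metadata Data.frame with `sample_id` and `group`.
#' @param target `"lymphogen"`, `"occult"` or `"combined"`.
#' @param min_reads Read-depth threshold on group-mean raw counts
#'   (default 50).
#' @param min_fold Fold-change threshold on CPM group means (default 2).
#' @return Data.frame with one row per feature: group means (raw and CPM),
#'   `fold_change` (target/reference CPM ratio) and `passed_filter`.
#' @export
candidate_filter <- function(counts, metadata, target, min_reads = 50,
                             min_fold = 2) {
  counts <- as_count_matrix(counts)
  cs <- comparison_samples(metadata, target)
  if (length(cs$ref) < 2 || length(cs$target) < 2)
    stopf("both compared groups need at least 2 samples")
  cpm <- normalize_cpm(counts)
  m_ref_raw <- rowMeans(counts[, cs$ref, drop = FALSE])
  m_tgt_raw <- rowMeans(counts[, cs$target, drop = FALSE])
  m_ref_cpm <- rowMeans(cpm[, cs$ref, drop = FALSE])
  m_tgt_cpm <- rowMeans(cpm[, cs$target, drop = FALSE])
  fc <- (m_tgt_cpm + 0.5) / (m_ref_cpm + 0.5)
  passed <- (pmax(m_ref_raw, m_tgt_raw) >= min_reads) &
    (fc >= min_fold | fc <= 1 / min_fold)
  data.frame(feature_id = rownames(counts),
             mean_ref_raw = m_ref_raw, mean_target_raw = m_tgt_raw,
             mean_ref_cpm = m_ref_cpm, mean_target_cpm = m_tgt_cpm,
             fold_change = fc, passed_filter = passed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate logistic screen for one comparison
#'
#' Runs [candidate_filter()], then fits [firth_logistic()] to every
#' filtered feature with predictor `log2(CPM + 1)` and response
#' reference = 0 / target = 1.  A feature is significant iff its p-value is
#' at most `alpha`; by default no multiple-testing adjustment is applied
#' (the screen is explorative), with an optional Benjamini-Hochberg toggle.
#' The expression fold change (ratio of CPM group means) and the logistic
#' odds ratio (per log2-CPM unit, with profile confidence interval) are
#' both reported and are distinct quantities.
#'
#' @inheritParams candidate_filter
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data.frame of class `"srna_screen"`, one row per feature with
#'   columns `feature_id`, `p_value`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `fold_change`, `mean_ref_cpm`, `mean_target_cpm`, `passed_filter`,
#'   `significant` (p/OR columns are `NA` for unfiltered features).
#'   Attribute `comparison` records the target; `candidates` the
#'   significant ids.
#' @export
screen <- function(counts, metadata, target, alpha = 0.05, min_reads = 50,
                   min_fold = 2, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  counts <- as_count_matrix(counts)
  filt <- candidate_filter(counts, metadata, target, min_reads, min_fold)
  cs <- comparison_samples(metadata, target)
  cpm <- normalize_cpm(counts)
  x_all <- log2(cpm[, c(cs$ref, cs$target), drop = FALSE] + 1)
  y <- rep(c(0, 1), c(length(cs$ref), length(cs$target)))

  n <- nrow(filt)
  p <- or <- lo <- hi <- rep(NA_real_, n)
  for (i in which(filt$passed_filter)) {
    fit <- firth_logistic(x_all[filt$feature_id[i], ], y)
    p[i] <- fit$p_value; or[i] <- fit$odds_ratio
    lo[i] <- fit$ci_low; hi[i] <- fit$ci_high
  }
  p_use <- p
  if (p_adjust == "BH") {
    sel <- which(filt$passed_filter)
    p_use[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  res <- data.frame(feature_id = filt$feature_id, p_value = p,
                    odds_ratio = or, ci_low = lo, ci_high = hi,
                    fold_change = filt$fold_change,
                    mean_ref_cpm = filt$mean_ref_cpm,
                    mean_target_cpm = filt$mean_target_cpm,
                    passed_filter = filt$passed_filter,
                    significant = filt$passed_filter & !is.na(p_use) &
                      p_use <= alpha,
                    stringsAsFactors = FALSE)
  structure(res, class = c("srna_screen", "data.frame"),
            comparison = target,
            candidates = res$feature_id[res$significant])
}

#' Overlap statistics between candidate lists
#'
#' Pairwise intersections and a three-way Venn partition of candidate id
#' lists.  The percentage reported for the ordered pair (A, B) is
#' `100 * |A intersect B| / |B|`, rounded half away from zero to the
#' nearest integer — the convention used when quoting how much of list B
#' is recovered in list A.
#'
#' @param lists Named list of character vectors of unique feature ids
#'   (three lists for the Venn partition; pairwise statistics work for any
#'   number of lists >= 2).
#' @return A list with `sizes`, `intersections` (matrix of
#'   `|A intersect B|`), `percentages` (matrix, `[A, B]` uses denominator
#'   `|B|`), and — for exactly three lists — `venn`, the 7 region counts
#'   named e.g. `"A_only"`, `"A_B"`, `"A_B_C"`.
#' @export
#' @examples
#' overlap_stats(list(a = c("x", "y"), b = c("y", "z"), c = c("y")))
overlap_stats <- function(lists) {
  if (length(lists) < 2 || is.null(names(lists)))
    stopf("lists must be a named list of length >= 2")
  for (nm in names(lists))
    if (anyDuplicated(lists[[nm]]))
      stopf("duplicate ids within list '%s'", nm)
  k <- length(lists)
  nms <- names(lists)
  inter <- pct <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (a in nms) for (b in nms) {
    inter[a, b] <- length(intersect(lists[[a]], lists[[b]]))
    pct[a, b] <- round_half_up(100 * inter[a, b] / length(lists[[b]]))
  }
  out <- list(sizes = vapply(lists, length, integer(1)),
              intersections = inter, percentages = pct)
  if (k == 3) {
    A <- lists[[1]]; B <- lists[[2]]; C <- lists[[3]]
    inAB <- intersect(A, B); inAC <- intersect(A, C); inBC <- intersect(B, C)
    core <- intersect(inAB, C)
    venn <- c(length(setdiff(A, union(B, C))),
              length(setdiff(B, union(A, C))),
              length(setdiff(C, union(A, B))),
              length(setdiff(inAB, core)),
              length(setdiff(inAC, core)),
              length(setdiff(inBC, core)),
              length(core))
    names(venn) <- c(paste0(nms, "_only"),
                     paste(nms[1], nms[2], sep = "_"),
                     paste(nms[1], nms[3], sep = "_"),
                     paste(nms[2], nms[3], sep = "_"),
                     paste(nms, collapse = "_"))
    out$venn <- venn
  }
  out
}
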