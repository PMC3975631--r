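#' Configuration for the synthetic blood small-RNA study
#'
#' Collects every tunable of the synthetic-data generator.  The defaults
#' encode the study design the pipeline targets: three groups
#' (non-metastasized reference, lymphogen and occult metastasized) with five
#' samples each, negative-binomial counts over a log-normal baseline, and a
#' read-class mixture whose trimming/annotation accounting lands in the
#' ranges typical of blood small-RNA libraries (roughly 73% of reads
#' surviving trimming and roughly 82% of trimmed reads annotated).
#'
#' @param n_per_group Samples per group (>= 2; study design uses 5).
#' @param groups The three group labels (first label = reference group).
#' @param n_features Number of reference features to simulate when a
#'   reference is generated from this config.
#' @param library_size_mean Expected annotated reads per sample, i.e. the
#'   expected column sum of the simulated count matrix.  The desk-scale
#'   default is 1e5; the study's absolute 1e7 depth is not emulated.
#' @param library_size_cv Coefficient of variation of library sizes across
#'   samples (gamma-distributed; 0 = all libraries equal).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean / sd of the
#'   log-normal per-feature baseline abundance (only relative values
#'   matter; abundances are renormalized per sample).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.  The default 0.4
#'   (biological CV ~ 0.63) reflects the large between-subject variability
#'   of circulating small RNAs in human cohorts.
#' @param truth_set `NULL`, or a data.frame with columns `feature_id`,
#'   `groups` (comma-separated affected group labels) and `fold_change`
#'   (> 0) giving the implanted discriminating features.  An optional
#'   `baseline_mean` column pins a truth feature's expected raw count in
#'   the unaffected groups (instead of drawing its baseline from the
#'   log-normal), so implanted biomarkers can be placed at a quantifiable
#'   depth the way real candidate small RNAs are moderately-to-highly
#'   expressed.
#' @param adapter 3' adapter appended to every real insert.
#' @param junk_read_fraction Proportion of reads carrying no adapter.
#' @param short_fragment_fraction Proportion of reads whose insert is
#'   shorter than 15 nt.
#' @param unannotated_tag_fraction Proportion of reads with a trimmable
#'   insert not drawn from the reference.
#' @param end_jitter Maximum 3'-end truncation/extension of real inserts,
#'   in nt (0, 1 or 2).
#' @param seed Integer RNG seed.
#' @return A list of class `"srna_sim_config"`.
#' @export
simulation_config <- function(n_per_group = 5L,
                              groups = srna_groups(),
                              n_features = 500L,
                              library_size_mean = 1e5,
                              library_size_cv = 0.3,
                              baseline_log_mean = 0,
                              baseline_log_sd = 1.5,
                              dispersion = 0.4,
                              truth_set = NULL,
                              adapter = srna_adapter(),
                              junk_read_fraction = 0.25,
                              short_fragment_fraction = 0.02,
                              unannotated_tag_fraction = 0.13,
                              end_jitter = 2L,
                              seed = 1L) {
  props <- c(junk_read_fraction, short_fragment_fraction,
             unannotated_tag_fraction)
  if (any(props < 0) || any(props > 1) || sum(props) >= 1)
    stopf("read-class fractions must lie in [0,1] and sum to < 1")
  if (n_per_group < 2) stopf("n_per_group must be >= 2")
  if (length(groups) != 3 || anyDuplicated(groups))
    stopf("groups must be three distinct labels")
  if (!end_jitter %in% 0:2) stopf("end_jitter must be 0, 1 or 2")
  if (library_size_mean <= 0 || library_size_cv < 0 || dispersion < 0)
    stopf("library_size_mean must be > 0; cv and dispersion must be >= 0")
  if (!is.null(truth_set)) {
    if (!is.data.frame(truth_set) ||
        !all(c("feature_id", "groups", "fold_change") %in% names(truth_set)))
      stopf("truth_set needs columns feature_id, groups, fold_change")
    if (any(truth_set$fold_change <= 0)) stopf("fold_change must be > 0")
    tg <- unlist(strsplit(truth_set$groups, ","))
    if (!all(trimws(tg) %in% groups))
      stopf("truth_set groups must be among: %s", paste(groups, collapse = ", "))
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 n_features = as.integer(n_features),
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion, truth_set = truth_set,
                 adapter = adapter,
                 junk_read_fraction = junk_read_fraction,
                 short_fragment_fraction = short_fragment_fraction,
                 unannotated_tag_fraction = unannotated_tag_fraction,
                 end_jitter = as.integer(end_jitter),
                 seed = as.integer(seed)),
            class = "srna_sim_config")
}

truth_folds <- function(truth_set, feature_ids, group) {
  fold <- rep(1, length(feature_ids))
  if (is.null(truth_set) || nrow(truth_set) == 0) return(fold)
  for (i in seq_len(nrow(truth_set))) {
    affected <- trimws(strsplit(truth_set$groups[i], ",")[[1]])
    if (group %in% affected) {
      j <- match(truth_set$feature_id[i], feature_ids)
      fold[j] <- truth_set$fold_change[i]
    }
  }
  fold
}

#' Simulate a group-structured small-RNA count matrix
#'
#' Draws raw counts per feature and sample from a negative binomial whose
#' mean is the sample's expected library size times the feature's relative
#' abundance.  Relative abundances come from a log-normal baseline shared by
#' all samples; features listed in the config's `truth_set` have their
#' baseline multiplied by `fold_change` in the affected groups (abundances
#' are renormalized per sample, so the expected column sum stays at the
#' library size).
#'
#' @param config An [simulation_config()] object.
#' @param reference Reference data.frame; its entries are the matrix rows.
#' @return A list of class `"srna_sim"` with elements `counts`
#'   (features x samples integer matrix), `metadata` (sample_id, group),
#'   `library_sizes`, and `truth` (the implanted effects plus
#'   `expected_pairs`, the unordered pairs of truth features sharing the
#'   same affected-group set, expected to be jointly separating when their
#'   fold changes are strong).
#' @export
#' @examples
#' ref <- generate_reference(30, 5, seed = 1)
#' cfg <- simulation_config(n_features = 35, seed = 2)
#' sim <- simulate_counts(cfg, ref)
#' dim(sim$counts)
simulate_counts <- function(config, reference) {
  stopifnot(inherits(config, "srna_sim_config"))
  assert_reference(reference)
  truth <- config$truth_set
  if (!is.null(truth) && !all(truth$feature_id %in% reference$feature_id))
    stopf("truth_set feature ids missing from the reference")
  if (config$n_per_group < 2) stopf("n_per_group must be >= 2")

  set.seed(config$seed)
  fids <- reference$feature_id
  nf <- length(fids)
  groups <- rep(config$groups, each = config$n_per_group)
  sample_ids <- paste(groups, sequence(rep(config$n_per_group, 3)), sep = "_")

  w <- rlnorm(nf, config$baseline_log_mean, config$baseline_log_sd)
  if (!is.null(truth) && !is.null(truth$baseline_mean)) {
    pin <- which(!is.na(truth$baseline_mean))
    if (length(pin)) {
      j <- match(truth$feature_id[pin], fids)
      prop <- truth$baseline_mean[pin] / config$library_size_mean
      if (sum(prop) >= 1) stopf("pinned baseline_means exceed the library size")
      w[j] <- prop * sum(w[-j]) / (1 - sum(prop))
    }
  }
  lib <- if (config$library_size_cv == 0) {
    rep(config$library_size_mean, length(sample_ids))
  } else {
    shape <- 1 / config$library_size_cv^2
    rgamma(length(sample_ids), shape = shape,
           rate = shape / config$library_size_mean)
  }

  counts <- matrix(0L, nf, length(sample_ids),
                   dimnames = list(fids, sample_ids))
  for (s in seq_along(sample_ids)) {
    f <- truth_folds(truth, fids, groups[s])
    mu <- lib[s] * (w * f) / sum(w * f)
    counts[, s] <- as.integer(
      if (config$dispersion == 0) rpois(nf, mu)
      else rnbinom(nf, mu = mu, size = 1 / config$dispersion))
  }

  expected_pairs <- NULL
  if (!is.null(truth) && nrow(truth) >= 2) {
    key <- vapply(truth$groups, function(g)
      paste(sort(trimws(strsplit(g, ",")[[1]])), collapse = ","), character(1))
    for (k in unique(key)) {
      ids <- sort(truth$feature_id[key == k])
      if (length(ids) >= 2) {
        prs <- t(combn(ids, 2))
        expected_pairs <- rbind(expected_pairs,
                                data.frame(id1 = prs[, 1], id2 = prs[, 2],
                                           stringsAsFactors = FALSE))
      }
    }
  }

  structure(list(counts = counts,
                 metadata = data.frame(sample_id = sample_ids, group = groups,
                                       stringsAsFactors = FALSE),
                 library_sizes = setNames(lib, sample_ids),
                 truth = list(features = truth,
                              expected_pairs = expected_pairs)),
            class = "srna_sim")
}
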