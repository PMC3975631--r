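test_that("CPM normalization rescales columns to one million", {
  m <- matrix(c(10, 30, 60), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(normalize_cpm(m)[, 1]), c(1e5, 3e5, 6e5))
  m2 <- cbind(m, s2 = c(5e5, 3e5, 2e5))
  expect_equal(normalize_cpm(m2)[, "s2"], m2[, "s2"])        # already 1e6
  m3 <- m2; m3[, 1] <- m3[, 1] * 2
  expect_equal(normalize_cpm(m3), normalize_cpm(m2))          # scale invariance
  m2[, 1] <- 0
  expect_error(normalize_cpm(m2), "all-zero")
})

toy_metadata <- function(n = 5) data.frame(
  sample_id = paste0("s", 1:(3 * n)),
  group = rep(srna_groups(), each = n), stringsAsFactors = FALSE)

# equal library sizes of 1e5 so CPM = raw x 10
toy_counts <- function(ref_vals, tgt_vals, extra = NULL) {
  md <- toy_metadata()
  m <- rbind(feat = c(rep(ref_vals, length.out = 5),
                      rep(tgt_vals, length.out = 10)))
  if (!is.null(extra)) m <- rbind(m, extra = rep(extra, 15))
  m <- rbind(m, filler = 1e5 - colSums(m))
  colnames(m) <- md$sample_id
  list(counts = m, md = md)
}

test_that("candidate filter applies depth and fold thresholds on CPM means", {
  t1 <- toy_counts(25, 60)   # CPM ratio (600.5/250.5) = 2.40 -> kept
  f1 <- candidate_filter(t1$counts, t1$md, "combined")
  expect_true(f1$passed_filter[f1$feature_id == "feat"])
  expect_equal(f1$fold_change[f1$feature_id == "feat"], 600.5 / 250.5)

  t2 <- toy_counts(40, 60)   # ratio 1.50 -> excluded
  f2 <- candidate_filter(t2$counts, t2$md, "combined")
  expect_false(f2$passed_filter[f2$feature_id == "feat"])

  t3 <- toy_counts(15, 40)   # ratio 2.66 but both means < 50 reads -> excluded
  f3 <- candidate_filter(t3$counts, t3$md, "combined")
  expect_false(f3$passed_filter[f3$feature_id == "feat"])

  zero <- toy_counts(0, 0, extra = 100)  # all-zero feature -> excluded
  fz <- candidate_filter(zero$counts, zero$md, "lymphogen")
  expect_false(fz$passed_filter[fz$feature_id == "feat"])
  expect_error(candidate_filter(t1$counts, transform(t1$md, group = "odd"),
                                "combined"), "unknown group")
})

test_that("tightening the filter never enlarges the filtered set", {
  ref <- tiny_reference()
  cfg <- simulation_config(n_features = 25, library_size_mean = 2e4, seed = 31)
  sim <- simulate_counts(cfg, ref)
  base <- candidate_filter(sim$counts, sim$metadata, "combined",
                           min_reads = 20, min_fold = 1.5)
  for (mr in c(50, 100)) for (mf in c(2, 4)) {
    tight <- candidate_filter(sim$counts, sim$metadata, "combined",
                              min_reads = mr, min_fold = mf)
    expect_true(all(tight$feature_id[tight$passed_filter] %in%
                      base$feature_id[base$passed_filter]))
  }
})

test_that("the screen flags implanted discriminating features", {
  ref <- tiny_reference()
  truth <- data.frame(feature_id = "mir-sim-4", groups = "lymphogen,occult",
                      fold_change = 6, baseline_mean = 150)
  cfg <- simulation_config(n_features = 25, library_size_mean = 3e4,
                           dispersion = 0.05, truth_set = truth, seed = 57)
  sim <- simulate_counts(cfg, ref)
  scr <- screen(sim$counts, sim$metadata, "combined")
  expect_true("mir-sim-4" %in% attr(scr, "candidates"))
  expect_false(anyNA(scr$significant))
  # significant implies filtered
  expect_true(all(scr$passed_filter[scr$significant]))
  # alpha = 0 empties the candidate list
  scr0 <- screen(sim$counts, sim$metadata, "combined", alpha = 0)
  expect_length(attr(scr0, "candidates"), 0)
  # nothing passing the filter gives an empty candidate list
  flat <- matrix(20L, 4, 15,
                 dimnames = list(paste0("f", 1:4), sim$metadata$sample_id))
  scrf <- screen(flat, sim$metadata, "combined")
  expect_length(attr(scrf, "candidates"), 0)
})

test_that("overlap statistics count intersections, percentages and Venn regions", {
  ids <- function(k) sprintf("id%02d", k)
  same <- list(a = ids(1:10), b = ids(1:10), c = ids(1:10))
  ov <- overlap_stats(same)
  expect_true(all(ov$percentages == 100))
  expect_equal(unname(ov$venn["a_b_c"]), 10)

  lists <- list(a = ids(1:10), b = ids(6:14), c = ids(c(1:3, 9:12)))
  ov2 <- overlap_stats(lists)
  expect_equal(ov2$intersections["a", "b"], 5)   # ids 6-10
  expect_equal(ov2$percentages["a", "b"], round_half_up(100 * 5 / 9))
  expect_equal(ov2$percentages["b", "a"], 50)
  expect_equal(sum(ov2$venn), length(unique(unlist(lists))))
  expect_equal(unname(ov2$venn["a_b_c"]), 2)     # ids 9, 10
  expect_error(overlap_stats(list(a = c("x", "x"), b = "y")), "duplicate")
})
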