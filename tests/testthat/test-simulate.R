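test_that("count simulation is deterministic and echoes the implanted truth", {
  ref <- tiny_reference()
  cfg <- simulation_config(n_features = 25, library_size_mean = 5e3, seed = 3)
  s1 <- simulate_counts(cfg, ref)
  s2 <- simulate_counts(cfg, ref)
  expect_identical(s1$counts, s2$counts)
  expect_equal(dim(s1$counts), c(25, 15))
  expect_null(s1$truth$features)
  expect_null(s1$truth$expected_pairs)

  truth <- data.frame(feature_id = c("mir-sim-1", "mir-sim-3"),
                      groups = "lymphogen,occult", fold_change = 4)
  cfg2 <- simulation_config(n_features = 25, library_size_mean = 5e3,
                            truth_set = truth, seed = 3)
  s3 <- simulate_counts(cfg2, ref)
  expect_equal(s3$truth$features$feature_id, truth$feature_id)
  expect_equal(s3$truth$expected_pairs,
               data.frame(id1 = "mir-sim-1", id2 = "mir-sim-3",
                          stringsAsFactors = FALSE))
})

test_that("invalid simulation inputs are rejected", {
  ref <- tiny_reference()
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  expect_error(simulation_config(junk_read_fraction = 1.2), "fractions")
  expect_error(
    simulation_config(truth_set = data.frame(feature_id = "x", groups = "lymphogen",
                                             fold_change = -1)),
    "fold_change")
  bad <- simulation_config(
    truth_set = data.frame(feature_id = "not-there", groups = "occult",
                           fold_change = 2))
  expect_error(simulate_counts(bad, ref), "missing from the reference")
})

test_that("implanted fold changes are recovered by empirical group-mean ratios", {
  # large-n law-of-large-numbers check: fold 4 in both metastasized groups,
  # baseline pinned at 200 reads, 50 samples per group
  ref <- tiny_reference()
  truth <- data.frame(feature_id = "mir-sim-5", groups = "lymphogen,occult",
                      fold_change = 4, baseline_mean = 200)
  cfg <- simulation_config(n_per_group = 50, n_features = 25,
                           library_size_mean = 2e4, dispersion = 0.3,
                           truth_set = truth, seed = 17)
  sim <- simulate_counts(cfg, ref)
  md <- sim$metadata
  m_ref <- mean(sim$counts["mir-sim-5", md$sample_id[md$group == "non_metastasized"]])
  m_met <- mean(sim$counts["mir-sim-5", md$sample_id[md$group != "non_metastasized"]])
  expect_gt(m_met / m_ref, 3.2)
  expect_lt(m_met / m_ref, 4.8)
})

test_that("simulated column sums concentrate around the configured library size", {
  # moderate abundance spread and overdispersion keep the negative-binomial
  # noise on the column sums well below the 10% band at 200 features
  ref <- generate_reference(160, 40, seed = 5)
  cfg <- simulation_config(n_features = 200, library_size_mean = 2e4,
                           library_size_cv = 0, baseline_log_sd = 1,
                           dispersion = 0.1, seed = 6)
  sim <- simulate_counts(cfg, ref)
  expect_true(all(abs(colSums(sim$counts) / 2e4 - 1) < 0.10))
})

test_that("read simulation writes the configured number of records per class", {
  ref <- tiny_reference()
  cfg <- simulation_config(n_features = 25, seed = 8,
                           junk_read_fraction = 0, short_fragment_fraction = 0,
                           unannotated_tag_fraction = 0, end_jitter = 0)
  counts <- matrix(0L, nrow(ref), 2,
                   dimnames = list(ref$feature_id, c("s1", "s2")))
  counts["mir-sim-2", ] <- c(10L, 4L)
  rd <- withr::local_tempdir()
  info <- simulate_reads(counts, ref, cfg, rd, gzip = FALSE)
  reads <- read_fastq(info$file[info$sample_id == "s1"])
  expect_length(reads, 10)
  # noise-free reads all carry the adapter and an annotatable insert
  ts <- trim_readset(info$file[1], srna_adapter())
  expect_equal(ts$accounting$kept, 10)
  ann <- annotate_tags(names(ts$tags), ref)
  expect_true(all(ann$status == "unique" & ann$feature_id == "mir-sim-2"))
})

test_that("read classes appear at their configured fractions", {
  ref <- tiny_reference()
  cfg <- simulation_config(n_features = 25, library_size_mean = 4e3,
                           dispersion = 0.1, seed = 21)
  sim <- simulate_counts(cfg, ref)
  rd <- withr::local_tempdir()
  info <- simulate_reads(sim$counts[, 1, drop = FALSE], ref, cfg, rd)
  ts <- trim_readset(info$file[1], srna_adapter())
  acc <- ts$accounting
  # exact class accounting is certified by the generator
  expect_equal(acc$kept + acc$no_adapter + acc$too_short, acc$total)
  expect_equal(acc$no_adapter, info$n_junk)
  expect_equal(acc$too_short, info$n_short)
  expect_equal(acc$kept, info$n_annotatable + info$n_unannotated)
})
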