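test_that("tag annotation applies the 3'-end tolerance rule", {
  ref <- manual_reference(
    c("mir-a", "mir-b", "ENST00000000001"),
    c("mirna", "mirna", "ncrna"),
    c("ACGTACGTACGTACGTAC",      # 18 nt
      "TTGGTTGGTTGGTTGGTTGG",    # 20 nt
      "CCAACCAACCAACCAACCAACCAACCAACC"))  # 30 nt
  expect_equal(annotate_tag(ref$sequence[1], ref)$feature_id, "mir-a")
  expect_equal(annotate_tag("GGGGGGGGGGGGGGGG", ref)$status, "unannotated")
  # missing up to 2 3' bases: unique; missing 3: unannotated
  expect_equal(annotate_tag(substr(ref$sequence[2], 1, 18), ref)$feature_id,
               "mir-b")
  expect_equal(annotate_tag(substr(ref$sequence[2], 1, 17), ref)$status,
               "unannotated")
  # extending by up to 2 ignored 3' bases: unique
  expect_equal(annotate_tag(paste0(ref$sequence[1], "GT"), ref)$feature_id,
               "mir-a")
  expect_equal(annotate_tag(paste0(ref$sequence[1], "GTT"), ref)$status,
               "unannotated")
  # zero tolerance is exact string equality
  expect_equal(annotate_tag(substr(ref$sequence[2], 1, 19), ref,
                            end_tolerance = 0)$status, "unannotated")
  expect_equal(annotate_tag(ref$sequence[2], ref, end_tolerance = 0)$feature_id,
               "mir-b")
})

test_that("shared prefixes give ambiguity and miRNA outranks ncRNA", {
  p <- "ACGTACGTACGTACGT"  # 16 nt common prefix
  ref <- manual_reference(c("mir-x", "mir-y"), c("mirna", "mirna"),
                          c(p, paste0(p, "GG")))
  # the prefix itself is within tolerance of both entries
  expect_equal(annotate_tag(paste0(p, "G"), ref)$status, "ambiguous")
  # same geometry, but the longer entry is ncRNA: the miRNA wins
  ref2 <- manual_reference(c("mir-x", "ENST00000000002"), c("mirna", "ncrna"),
                           c(p, paste0(p, "GG")))
  res <- annotate_tag(paste0(p, "G"), ref2)
  expect_equal(res$status, "unique")
  expect_equal(res$feature_id, "mir-x")
})

test_that("count matrix assembly matches a hand-computed table", {
  ref <- manual_reference(
    c("mir-a", "mir-b", "ENST00000000003"),
    c("mirna", "mirna", "ncrna"),
    c("ACGTACGTACGTACGTAC", "TTGGTTGGTTGGTTGGTTGG",
      "CCAACCAACCAACCAACCAACCAACCAACC"))
  p <- "GGTTGGTTGGTTGGTT"
  amb_ref <- rbind(ref, data.frame(feature_id = c("mir-c", "mir-d"),
                                   class = "mirna",
                                   sequence = c(p, paste0(p, "AA")),
                                   stringsAsFactors = FALSE))
  mk <- function(tags, counts, total = 100L) {
    structure(list(tags = setNames(as.integer(counts), tags),
                   accounting = list(total = total, kept = sum(counts),
                                     no_adapter = 0L, too_short = 0L)),
              class = "srna_tags")
  }
  samples <- list(
    s1 = mk(c(ref$sequence[1], ref$sequence[2], "AAAAAAAAAAAAAAAA",
              substr(ref$sequence[3], 1, 29), paste0(p, "A")),
            c(12L, 3L, 7L, 2L, 5L)),
    s2 = mk(c(ref$sequence[1], paste0(ref$sequence[1], "G"),
              ref$sequence[3], "CCCCCCCCCCCCCCCC", paste0(p, "A")),
            c(4L, 6L, 9L, 1L, 2L)),
    s3 = mk(c(ref$sequence[2], "GGGGGGGGGGGGGGGG", ref$sequence[1],
              substr(ref$sequence[2], 1, 18), paste0(p, "A")),
            c(8L, 2L, 1L, 5L, 3L)))
  q <- build_count_matrix(samples, amb_ref)
  # hand-enumerated: the 16 nt tag paste0(p, "A") is within tolerance of
  # mir-c and mir-d -> ambiguous everywhere, contributes nothing
  expected <- matrix(c(12L, 3L, 2L, 0L, 0L,
                       10L, 0L, 9L, 0L, 0L,
                       1L, 13L, 0L, 0L, 0L),
                     nrow = 5,
                     dimnames = list(amb_ref$feature_id, c("s1", "s2", "s3")))
  expect_identical(q$counts, expected)
  expect_equal(q$lib_stats$annotated_reads, c(17L, 19L, 14L))
  expect_equal(q$lib_stats$tags_ambiguous, c(1L, 1L, 1L))
  # annotated reads equal the matrix column sums
  expect_equal(unname(colSums(q$counts)), q$lib_stats$annotated_reads)
  expect_error(build_count_matrix(setNames(samples, c("s1", "s1", "s3")), ref),
               "duplicate sample ids")
})

test_that("library summary aggregates per group with n-1 stdev", {
  stats <- data.frame(sample_id = c("a", "b", "c", "d"),
                      total_reads = c(100L, 200L, 150L, 80L),
                      pct_after_trim = c(76, 72, 78, 70))
  md <- data.frame(sample_id = c("a", "b", "c", "d"),
                   group = c("non_metastasized", "non_metastasized",
                             "non_metastasized", "occult"))
  out <- library_summary(stats, md)
  pg <- out$per_group
  m <- pg[pg$group == "non_metastasized" & pg$statistic == "mean", ]
  expect_equal(m$pct_after_trim, mean(c(76, 72, 78)))
  expect_equal(round_half_up(m$pct_after_trim), 75)
  s <- pg[pg$group == "non_metastasized" & pg$statistic == "stdev", ]
  expect_equal(s$pct_after_trim, sd(c(76, 72, 78)))
  # single-sample group: mean equals the value, stdev not available
  o <- pg[pg$group == "occult", ]
  expect_equal(o$pct_after_trim[o$statistic == "mean"], 70)
  expect_true(is.na(o$pct_after_trim[o$statistic == "stdev"]))
  expect_error(library_summary(stats, md[1:2, ]), "missing from metadata")
})

test_that("quantifying noise-free simulated reads reproduces the count matrix", {
  ref <- tiny_reference()
  truth <- data.frame(feature_id = "mir-sim-1", groups = "lymphogen,occult",
                      fold_change = 5, baseline_mean = 40)
  cfg <- simulation_config(n_features = 25, library_size_mean = 2500,
                           dispersion = 0.2, truth_set = truth, seed = 19,
                           junk_read_fraction = 0, short_fragment_fraction = 0,
                           unannotated_tag_fraction = 0, end_jitter = 2)
  sim <- simulate_counts(cfg, ref)
  rd <- withr::local_tempdir()
  info <- simulate_reads(sim, ref, cfg, rd)
  ts <- lapply(setNames(info$file, info$sample_id), trim_readset,
               adapter = srna_adapter())
  q <- build_count_matrix(ts, ref, end_tolerance = 2)
  expect_identical(q$counts[rownames(sim$counts), colnames(sim$counts)],
                   sim$counts)
})
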