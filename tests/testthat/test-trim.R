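adapter <- srna_adapter()

test_that("single-read trimming honors the 15 nt insert boundary", {
  ins15 <- strrep("ACGTC", 3)
  ins14 <- substr(ins15, 1, 14)
  r <- trim_read(paste0(ins15, adapter), adapter)
  expect_equal(r$status, "kept")
  expect_equal(nchar(r$insert), 15)
  expect_equal(trim_read(paste0(ins14, adapter), adapter)$status, "too_short")
  expect_equal(trim_read(strrep("AC", 30), adapter)$status, "no_adapter")
})

test_that("adapter matching uses prefix overlap with mismatch tolerance", {
  ins <- "ACCGTTACCGGTTAACC"  # 17 nt
  # adapter truncated to its first 8 bases at the 3' end still matches
  expect_equal(trim_read(paste0(ins, substr(adapter, 1, 8)), adapter)$insert, ins)
  # 6 bases of adapter: below min_overlap, no hit
  expect_equal(trim_read(paste0(ins, substr(adapter, 1, 6)), adapter)$status,
               "no_adapter")
  # one mismatch inside a full-length adapter is tolerated, two are not
  mm1 <- adapter; substr(mm1, 3, 3) <- if (substr(mm1, 3, 3) == "A") "C" else "A"
  expect_equal(trim_read(paste0(ins, mm1), adapter)$insert, ins)
  mm2 <- mm1; substr(mm2, 12, 12) <- if (substr(mm2, 12, 12) == "A") "C" else "A"
  expect_equal(trim_read(paste0(ins, mm2), adapter, max_mismatch = 1)$status,
               "no_adapter")
  expect_error(trim_read("ACGT", ""), "adapter")
})

test_that("a hand-built 10-read set partitions exactly as enumerated", {
  ins <- c("ACGTACGTACGTACGTA",   # 17 nt - kept
           "TTTTACGTACGTACGTACG", # 19 nt - kept
           "ACCACCACCACCACC",     # 15 nt - kept
           "GTGTGTGTGTGTGTGTGTGT",# 20 nt - kept
           "CATCATCATCATCATCAT",  # 18 nt - kept
           "AAGGAAGGAAGGAAGG",    # 16 nt - kept
           "CCGGCCGGCCGGCCGGC")   # 17 nt - kept
  reads <- c(paste0(ins, adapter),
             "ACACACACACACACACACACACACAC",          # no adapter
             paste0("ACGTACGTAC", adapter),         # 10 nt insert
             paste0("ACGTACGTACGTAC", adapter))     # 14 nt insert
  ts <- trim_readset(reads, adapter)
  expect_equal(ts$accounting$total, 10)
  expect_equal(ts$accounting$kept, 7)
  expect_equal(ts$accounting$no_adapter, 1)
  expect_equal(ts$accounting$too_short, 2)
  expect_setequal(names(ts$tags), ins)
})

test_that("tag collapsing and conservation hold on FASTQ input", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  empty <- trim_readset(fq, adapter)
  expect_length(empty$tags, 0)
  expect_equal(unlist(empty$accounting), c(total = 0, kept = 0,
                                           no_adapter = 0, too_short = 0))

  ins <- "ACGTACGTACGTACGTA"
  write_fastq(rep(paste0(ins, adapter), 25), fq)
  ts <- trim_readset(fq, adapter)
  expect_equal(unname(ts$tags[ins]), 25)
  expect_length(ts$tags, 1)

  # conservation on arbitrary mixed input
  set.seed(42)
  mixed <- replicate(200, {
    n <- sample(10:40, 1)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  })
  mixed <- c(mixed, paste0(mixed, adapter))
  acc <- trim_readset(mixed, adapter)$accounting
  expect_equal(acc$kept + acc$no_adapter + acc$too_short, acc$total)
})

test_that("malformed FASTQ aborts with the offending record index", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(read_fastq(fq), "truncated record 2")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGTA", "+", "III"), fq)
  expect_error(read_fastq(fq), "length mismatch at record 2")
  writeLines(c("@r1", "ACGT", "x", "IIII"), fq)
  expect_error(read_fastq(fq), "record 1")
})

test_that("synthetic kept fraction matches the configured trimming survival", {
  # junk 25%, short 2% of total reads: expected survival 73%
  ref <- tiny_reference()
  cfg <- simulation_config(n_features = 25, library_size_mean = 1.2e4,
                           dispersion = 0.1, seed = 77)
  sim <- simulate_counts(cfg, ref)
  rd <- withr::local_tempdir()
  info <- simulate_reads(sim$counts[, 1, drop = FALSE], ref, cfg, rd)
  expect_gt(info$n_total, 15000)
  acc <- trim_readset(info$file[1], adapter)$accounting
  expect_lt(abs(100 * acc$kept / acc$total - 73), 1.5)
})
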