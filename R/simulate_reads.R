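#' Simulate per-sample FASTQ files from a count matrix
#'
#' Emits one FASTQ per sample containing, for every feature, `count` reads
#' made of the mature sequence (with optional 3'-end truncation/extension of
#' up to `end_jitter` nt) followed by the adapter, plus three noise classes
#' at the configured fractions of the total: junk reads carrying no adapter,
#' short-insert reads (insert < 15 nt), and reads whose insert is not drawn
#' from the reference.  Every emitted read is verified against the default
#' trimmer so that the read classes are exact: junk reads trim to
#' `no_adapter`, short reads to `too_short`, and every real insert survives
#' trimming intact (random components are redrawn on the rare spurious
#' adapter hit).  Output is deterministic for a fixed config seed.
#'
#' @param sim An `"srna_sim"` object from [simulate_counts()] (or a bare
#'   counts matrix with feature rownames and sample colnames).
#' @param reference Reference data.frame the counts refer to.
#' @param config The [simulation_config()] used for the simulation.
#' @param out_dir Directory for the FASTQ files (created if needed).
#' @param gzip Compress outputs (`<sample>.fastq.gz`)? Default `TRUE`.
#' @return Invisibly, a data.frame with per-sample file paths and the exact
#'   number of reads emitted per class (`n_total`, `n_annotatable`,
#'   `n_unannotated`, `n_junk`, `n_short`).
#' @export
simulate_reads <- function(sim, reference, config, out_dir, gzip = TRUE) {
  stopifnot(inherits(config, "srna_sim_config"))
  assert_reference(reference)
  counts <- if (inherits(sim, "srna_sim")) sim$counts else sim
  if (!all(rownames(counts) %in% reference$feature_id))
    stopf("counted feature ids missing from the reference")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)

  adapter <- config$adapter
  jf <- config$junk_read_fraction
  sf <- config$short_fragment_fraction
  uf <- config$unannotated_tag_fraction
  seqs <- setNames(reference$sequence, reference$feature_id)
  idx <- make_annotation_index(reference, end_tolerance = 2L)

  out <- lapply(colnames(counts), function(sid) {
    cnt <- counts[, sid]
    n_annot <- sum(cnt)
    n_total <- round(n_annot / (1 - jf - sf - uf))
    n_junk <- round(jf * n_total)
    n_short <- round(sf * n_total)
    n_unannot <- max(0L, n_total - n_annot - n_junk - n_short)
    n_total <- n_annot + n_junk + n_short + n_unannot

    real <- make_feature_reads(cnt, seqs, adapter, config$end_jitter)
    junk <- make_noise_reads(n_junk, adapter, idx, class = "junk")
    short <- make_noise_reads(n_short, adapter, idx, class = "short")
    unann <- make_noise_reads(n_unannot, adapter, idx, class = "unannotated")

    reads <- c(real, junk, short, unann)
    reads <- reads[sample.int(length(reads))]
    fn <- file.path(out_dir, paste0(sid, ".fastq", if (gzip) ".gz" else ""))
    write_fastq(reads, fn, ids = sprintf("%s:%d", sid, seq_along(reads)))
    data.frame(sample_id = sid, file = fn, n_total = n_total,
               n_annotatable = n_annot, n_unannotated = n_unannot,
               n_junk = n_junk, n_short = n_short,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, out))
}

make_feature_reads <- function(cnt, seqs, adapter, jitter) {
  active <- names(cnt)[cnt > 0]
  if (!length(active)) return(character(0))
  fid <- rep(active, cnt[active])
  ins <- seqs[fid]
  if (jitter > 0) {
    k <- sample(seq(-jitter, jitter), length(ins), replace = TRUE)
    L <- nchar(ins)
    trunc <- k < 0
    ins[trunc] <- substr(ins[trunc], 1, L[trunc] + k[trunc])
    ext <- which(k > 0)
    for (i in ext) ins[i] <- paste0(ins[i], random_seq(k[i]))
    # extensions carry random bases: redraw any whose junction with the
    # adapter creates a spurious adapter hit that would shorten the insert
    if (length(ext)) {
      for (tries in 1:50) {
        res <- trim_batch_cpp(paste0(ins[ext], adapter), adapter, 7L, 1L, 1L)
        bad <- which(res$status != 0L | is.na(res$insert) |
                       res$insert != ins[ext])
        if (!length(bad)) break
        if (tries == 50L) {  # give up on the extension, use the mature seq
          ins[ext[bad]] <- seqs[fid[ext[bad]]]
          break
        }
        for (i in ext[bad]) ins[i] <- paste0(seqs[fid[i]], random_seq(k[i]))
      }
    }
  }
  unname(paste0(ins, adapter))
}

# junk: no adapter anywhere; short: insert < 15 nt; unannotated: clean
# 18-25 nt insert absent from the reference.  Rejection-validated against
# the default trimmer (and annotator, for unannotated inserts).
make_noise_reads <- function(n, adapter, idx, class) {
  if (n <= 0) return(character(0))
  reads <- character(n)
  todo <- seq_len(n)
  for (tries in 1:100) {
    if (!length(todo)) break
    cand <- switch(class,
      junk = vapply(sample(30:60, length(todo), replace = TRUE),
                    random_seq, character(1)),
      short = paste0(vapply(sample(5:14, length(todo), replace = TRUE),
                            random_seq, character(1)), adapter),
      unannotated = paste0(vapply(sample(18:25, length(todo), replace = TRUE),
                                  random_seq, character(1)), adapter))
    res <- trim_batch_cpp(cand, adapter, 7L, 1L, 15L)
    ok <- switch(class,
      junk = res$status == 1L,
      short = res$status == 2L,
      unannotated = res$status == 0L &
        annotate_with_index(res$insert, idx)$status == "unannotated")
    ok[is.na(ok)] <- FALSE
    reads[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) stopf("could not generate valid %s reads", class)
  reads
}

#' Write a complete synthetic study bundle to disk
#'
#' Convenience wrapper tying the generator together: writes the reference
#' FASTA, per-sample FASTQ files, sample metadata TSV, the true (noise-free)
#' count matrix TSV, and a YAML file with the configuration and implanted
#' truth, so a full pipeline run needs no external data.
#'
#' @param config An [simulation_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param n_ncrna Number of ncRNA entries in the generated reference; the
#'   remaining `n_features - n_ncrna` entries are miRNAs.
#' @param write_reads Also simulate FASTQ files (slowest step)?
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(config, out_dir, n_ncrna = round(config$n_features * 0.2),
                           write_reads = TRUE) {
  stopifnot(inherits(config, "srna_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config$n_features - n_ncrna, n_ncrna,
                            seed = config$seed, adapter = config$adapter)
  sim <- simulate_counts(config, ref)
  paths <- list(reference = file.path(out_dir, "reference.fasta"),
                metadata = file.path(out_dir, "metadata.tsv"),
                counts = file.path(out_dir, "counts_true.tsv"),
                config = file.path(out_dir, "config.yaml"))
  write_reference_fasta(ref, paths$reference)
  write.table(sim$metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_matrix(sim$counts, paths$counts)
  cfg <- unclass(config)
  cfg$truth_set <- if (is.null(cfg$truth_set)) list() else
    lapply(seq_len(nrow(cfg$truth_set)), function(i) as.list(cfg$truth_set[i, ]))
  yaml::write_yaml(cfg, paths$config)
  reads <- NULL
  if (write_reads) {
    fq_dir <- file.path(out_dir, "fastq")
    reads <- simulate_reads(sim, ref, config, fq_dir)
    paths$fastq_dir <- fq_dir
  }
  invisible(list(reference = ref, sim = sim, reads = reads, paths = paths))
}
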