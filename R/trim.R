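#' Trim the 3' adapter from a single read
#'
#' Locates the leftmost position where a prefix of the adapter (length at
#' least `min_overlap`, with at most `max_mismatch` mismatches) matches the
#' read through its 3' end, or where the full adapter occurs internally
#' (bases beyond the adapter are ignored).  The insert is everything before
#' that position.  Reads with no adapter hit are discarded as
#' `"no_adapter"`; inserts shorter than `min_length` (default 15 nt, with
#' inserts of exactly 15 nt kept) as `"too_short"`.
#'
#' @param read Read sequence (nucleotide string).
#' @param adapter Adapter sequence; must be at least `min_overlap` long.
#' @param min_overlap Minimum adapter prefix length for a 3'-end match
#'   (default 7, a conventional small-RNA trimming setting).
#' @param max_mismatch Maximum mismatches tolerated in the match (default 1).
#' @param min_length Minimum insert length kept (default 15).
#' @return A list with `status` (`"kept"`, `"no_adapter"` or `"too_short"`)
#'   and `insert` (the trimmed insert, present iff kept).
#' @export
#' @examples
#' trim_read(paste0(strrep("ACGT", 5), srna_adapter()), srna_adapter())
trim_read <- function(read, adapter, min_overlap = 7L, max_mismatch = 1L,
                      min_length = 15L) {
  check_trim_params(adapter, min_overlap, max_mismatch, min_length)
  res <- trim_batch_cpp(read, adapter, as.integer(min_overlap),
                        as.integer(max_mismatch), as.integer(min_length))
  status <- c("kept", "no_adapter", "too_short")[res$status + 1L]
  list(status = status,
       insert = if (status == "kept") res$insert[[1]] else NULL)
}

check_trim_params <- function(adapter, min_overlap, max_mismatch, min_length) {
  if (!is.character(adapter) || length(adapter) != 1 || !nzchar(adapter))
    stopf("adapter must be a non-empty nucleotide string")
  if (min_overlap < 1 || nchar(adapter) < min_overlap)
    stopf("need adapter length >= min_overlap >= 1")
  if (max_mismatch < 0 || min_length < 1)
    stopf("max_mismatch must be >= 0 and min_length >= 1")
  invisible(TRUE)
}

#' Trim a whole read set and collapse inserts into tags
#'
#' Applies [trim_read()] to every record of a FASTQ file (or an in-memory
#' read vector), collapses the kept inserts into unique tags with read
#' counts, and returns the trimming accounting.  The three per-read
#' outcomes always partition the input:
#' `kept + no_adapter + too_short = total`.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped), or a character
#'   vector of read sequences.
#' @inheritParams trim_read
#' @return A list of class `"srna_tags"`: `tags` (named integer vector,
#'   tag sequence -> read count, decreasing), and `accounting` (list with
#'   `total`, `kept`, `no_adapter`, `too_short`).
#' @export
trim_readset <- function(fastq, adapter, min_overlap = 7L, max_mismatch = 1L,
                         min_length = 15L) {
  check_trim_params(adapter, min_overlap, max_mismatch, min_length)
  reads <- if (length(fastq) == 1 && file.exists(fastq)) read_fastq(fastq)
           else as.character(fastq)
  if (length(reads) == 0) {
    return(structure(list(tags = setNames(integer(0), character(0)),
                          accounting = list(total = 0L, kept = 0L,
                                            no_adapter = 0L, too_short = 0L)),
                     class = "srna_tags"))
  }
  res <- trim_batch_cpp(reads, adapter, as.integer(min_overlap),
                        as.integer(max_mismatch), as.integer(min_length))
  kept <- res$insert[res$status == 0L]
  tab <- table(kept)
  tags <- sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  structure(list(tags = tags,
                 accounting = list(total = length(reads),
                                   kept = sum(res$status == 0L),
                                   no_adapter = sum(res$status == 1L),
                                   too_short = sum(res$status == 2L))),
            class = "srna_tags")
}
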