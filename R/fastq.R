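#' Read and write FASTQ files
#'
#' Minimal strict FASTQ support for the trimmer: plain or gzip-compressed
#' 4-line records.  Qualities are read but not interpreted (no pipeline
#' stage consumes them); malformed records abort with the 1-based record
#' index, so a corrupt input is localizable.
#'
#' @param path File path; a `.gz` suffix selects gzip compression on write
#'   (reading auto-detects compression).
#' @return `read_fastq()` returns a character vector of read sequences,
#'   named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0)
    return(setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stopf("malformed FASTQ '%s': truncated record %d", path,
          length(lines) %/% 4 + 1)
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stopf("malformed FASTQ '%s': bad header/separator at record %d",
          path, bad[1])
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stopf("malformed FASTQ '%s': sequence/quality length mismatch at record %d",
          path, bad[1])
  setNames(seqs, sub("^@", "", hdr))
}

#' @rdname read_fastq
#' @param reads Character vector of read sequences (names used as read ids).
#' @param ids Optional read ids overriding `names(reads)`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% names(reads) %||% sprintf("read_%d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), reads, "+",
                           strrep("I", nchar(reads))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
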