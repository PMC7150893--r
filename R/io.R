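#' Read a FASTQ file into a read table
#'
#' Parses Phred+33 FASTQ into a data frame of reads. The parser is strict
#' about the 4-line block structure so that truncated or shuffled files are
#' reported with the offending line number rather than silently mis-paired.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @param keep_qualities Keep the quality strings (default `TRUE`). Dropping
#'   them halves memory for pipelines that only need the bases.
#' @return A data frame with columns `read_id`, `bases` and (optionally)
#'   `qualities`, one row per read, in file order.
#' @export
read_fastq <- function(path, keep_qualities = TRUE) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop_cryo(sprintf(
      "malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record near line %d)",
      path, n, 4L * (n %/% 4L) + 1L))
  }
  if (n == 0L) {
    out <- data.frame(read_id = character(), bases = character(),
                      stringsAsFactors = FALSE)
    if (keep_qualities) out$qualities <- character()
    return(out)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop_cryo(sprintf("malformed FASTQ '%s': line %d does not start with '@'",
                      path, 4L * (bad_hdr[1L] - 1L) + 1L))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop_cryo(sprintf("malformed FASTQ '%s': line %d does not start with '+'",
                      path, 4L * (bad_plus[1L] - 1L) + 3L))
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    stop_cryo(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at line %d",
      path, 4L * (bad_len[1L] - 1L) + 2L))
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", ids)
  out <- data.frame(read_id = ids, bases = seqs, stringsAsFactors = FALSE)
  if (keep_qualities) out$qualities <- qual
  out
}

#' Read a FASTA file into a read table
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A data frame with columns `read_id` and `bases`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(read_id = ids, bases = as.character(ss),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read table to FASTA
#'
#' @param reads Data frame with columns `read_id` and `bases`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- character(2L * nrow(reads))
  out[c(TRUE, FALSE)] <- paste0(">", reads$read_id)
  out[c(FALSE, TRUE)] <- reads$bases
  writeLines(out, path)
  invisible(path)
}

#' Write a read table to FASTQ (Phred+33)
#'
#' Reads without a `qualities` column get a constant quality string of `"I"`
#' (Q40) across their length.
#'
#' @param reads Data frame with `read_id`, `bases` and optionally `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  if (n == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  qual <- if ("qualities" %in% names(reads)) reads$qualities else
    vapply(nchar(reads$bases), function(k) strrep("I", k), character(1))
  out <- character(4L * n)
  out[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, 4L * n, by = 4L)] <- reads$bases
  out[seq(3L, 4L * n, by = 4L)] <- "+"
  out[seq(4L, 4L * n, by = 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Convert FASTQ records to FASTA records
#'
#' Identifiers and bases are preserved verbatim and in order; qualities are
#' discarded. Record count is conserved.
#'
#' @param x Either a path to a FASTQ file or a read table from [read_fastq()].
#' @param out Optional output FASTA path; when given, the FASTA is written.
#' @return The read table (columns `read_id`, `bases`), invisibly if `out`
#'   was written.
#' @export
convert_fastq_to_fasta <- function(x, out = NULL) {
  reads <- if (is.character(x) && length(x) == 1L) read_fastq(x) else x
  reads <- reads[, c("read_id", "bases")]
  if (!is.null(out)) {
    write_fasta(reads, out)
    return(invisible(reads))
  }
  reads
}
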