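#' Assign reads to samples by their MID
#'
#' Scans a 5' window of each read (default the first 45 bases, allowing the
#' platform adapter to precede the MID) for each manifest MID, tolerating up
#' to `max_mismatch` substitutions. A read is assigned to the sample whose
#' MID matches with strictly the fewest mismatches; if two or more MIDs
#' match equally well the read is left unassigned (ambiguity rule, which
#' avoids silent cross-sample bleed). Every input read lands in exactly one
#' bin or in `unassigned`.
#'
#' @param reads Read table (`read_id`, `bases`, ...).
#' @param manifest A [mid_manifest()].
#' @param max_mismatch Maximum substitutions tolerated in the MID match
#'   (default 0, exact).
#' @param search_window 5' window (bases) searched for the MID start.
#' @return A list with `bins` (named list of read tables, one per sample;
#'   each carries the matched MID end position in column `mid_end`) and
#'   `unassigned` (read table).
#' @export
assign_by_mid <- function(reads, manifest, max_mismatch = 0L,
                          search_window = 45L) {
  assert_that(inherits(manifest, "mid_manifest"), "manifest must be a mid_manifest")
  if (anyDuplicated(manifest$mid)) stop_cryo("duplicate MID in manifest")
  n <- nrow(reads)
  mids <- manifest$mid
  mid_len <- nchar(mids)
  if (n == 0L) {
    bins <- stats::setNames(rep(list(cbind(reads, mid_end = integer(0))),
                                length(mids)), manifest$sample_label)
    return(list(bins = bins, unassigned = reads))
  }
  # search space: 5' window plus room for the MID itself
  prefix <- substr(reads$bases, 1L, search_window + max(mid_len) - 1L)
  subject <- Biostrings::DNAStringSet(prefix)
  best_k <- rep(NA_integer_, n)      # fewest mismatches achieved
  best_mid <- rep(NA_integer_, n)    # manifest row achieving it
  best_pos <- rep(NA_integer_, n)    # MID start achieving it
  ambiguous <- rep(FALSE, n)
  for (k in 0:max_mismatch) {
    undecided <- is.na(best_k)
    if (!any(undecided)) break
    for (m in seq_along(mids)) {
      hits <- Biostrings::vmatchPattern(mids[m], subject, max.mismatch = k)
      starts <- Biostrings::startIndex(hits)
      found <- lengths(starts) > 0L
      # a MID start must fall inside the search window
      first <- rep(NA_integer_, n)
      first[found] <- vapply(starts[found], min, integer(1))
      found <- found & !is.na(first) & first <= search_window
      hit_new <- found & undecided & is.na(best_mid)
      hit_tie <- found & undecided & !is.na(best_mid) & best_mid != m
      best_mid[hit_new] <- m
      best_pos[hit_new] <- first[hit_new]
      ambiguous[hit_tie] <- TRUE
    }
    decided_now <- is.na(best_k) & (!is.na(best_mid) | ambiguous)
    best_k[decided_now] <- k
  }
  assigned <- !is.na(best_mid) & !ambiguous
  bins <- lapply(seq_along(mids), function(m) {
    sel <- which(assigned & best_mid == m)
    out <- reads[sel, , drop = FALSE]
    out$mid_end <- best_pos[sel] + mid_len[m] - 1L
    rownames(out) <- NULL
    out
  })
  names(bins) <- manifest$sample_label
  unassigned <- reads[!assigned, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(bins = bins, unassigned = unassigned)
}

#' Clip 5' decoration (and any 3' adapter) from assigned reads
#'
#' Removes everything from the read start through the end of the matched
#' MID, plus the linker when it immediately follows; if a 3' occurrence of
#' the linker or platform adapter (forward or reverse complement) remains in
#' the insert, the read is truncated before it. The retained bases are
#' always a contiguous substring of the input. Reads whose clip would leave
#' an empty sequence are routed to a discard list rather than erroring.
#'
#' @param bin Read table from one [assign_by_mid()] bin (with `mid_end`).
#' @param manifest_entry The matching manifest row (1-row data frame).
#' @return A list with `reads` (clipped read table) and `fully_clipped`
#'   (read table of reads clipped to nothing).
#' @export
clip_decoration <- function(bin, manifest_entry) {
  if (nrow(bin) == 0L) {
    return(list(reads = bin, fully_clipped = bin[0, , drop = FALSE]))
  }
  assert_that(!is.null(bin$mid_end), "bin lacks mid_end positions; run assign_by_mid first")
  linker <- manifest_entry$linker
  cut <- bin$mid_end
  # clip the linker when it directly follows the MID
  after <- substr(bin$bases, cut + 1L, cut + nchar(linker))
  has_linker <- after == linker
  cut[has_linker] <- cut[has_linker] + nchar(linker)
  clipped <- substr(bin$bases, cut + 1L, nchar(bin$bases))
  # 3' decoration: earliest occurrence of linker / P1 adapter, either strand
  three_prime <- c(linker, revcomp(linker),
                   manifest_entry$adapter_p1, revcomp(manifest_entry$adapter_p1))
  pos <- rep(Inf, length(clipped))
  for (pat in unique(three_prime)) {
    p <- regexpr(pat, clipped, fixed = TRUE)
    hit <- p > 0L
    pos[hit] <- pmin(pos[hit], p[hit])
  }
  trim <- is.finite(pos)
  clipped[trim] <- substr(clipped[trim], 1L, pos[trim] - 1L)
  out <- bin
  out$bases <- clipped
  if (!is.null(out$qualities)) {
    out$qualities <- substr(out$qualities, cut + 1L,
                            cut + nchar(clipped))
  }
  out$mid_end <- NULL
  empty <- nchar(out$bases) == 0L
  list(reads = out[!empty, , drop = FALSE],
       fully_clipped = out[empty, , drop = FALSE])
}

#' Drop reads shorter than a minimum length
#'
#' Retains reads with `nchar(bases) >= min_len` (the boundary length itself
#' is kept), preserving order.
#'
#' @param reads Read table.
#' @param min_len Minimum retained length in bp (default 50).
#' @return List with `reads` (retained) and `discarded` (count).
#' @export
filter_min_length <- function(reads, min_len = 50L) {
  keep <- nchar(reads$bases) >= min_len
  list(reads = reads[keep, , drop = FALSE], discarded = sum(!keep))
}

#' Demultiplex, clip and length-filter a multiplexed read set
#'
#' The pre-search curation stage in one call: FASTQ/FASTA (or an in-memory
#' read table) is split into per-sample bins by MID, decoration is clipped,
#' and short reads are dropped. Returns per-sample read tables plus a
#' bookkeeping report whose rows always satisfy
#' `assigned + unassigned = input` and
#' `assigned = retained + short + fully_clipped` per sample.
#'
#' @param x Path to a FASTQ/FASTA file or a read table.
#' @param manifest A [mid_manifest()].
#' @param min_len Minimum post-clip read length (default 50).
#' @param max_mismatch MID mismatch tolerance (default 0).
#' @param search_window 5' MID search window (default 45).
#' @return A list of class `demux_result`: `samples` (named list of clipped,
#'   filtered read tables), `unassigned`, `report` (data frame with columns
#'   `sample`, `assigned`, `retained`, `short`, `fully_clipped`).
#' @export
demultiplex <- function(x, manifest, min_len = 50L, max_mismatch = 0L,
                        search_window = 45L) {
  reads <- if (is.character(x) && length(x) == 1L) {
    first <- readLines(x, n = 1L)
    if (length(first) && startsWith(first, ">")) read_fasta(x) else read_fastq(x)
  } else x
  asg <- assign_by_mid(reads, manifest, max_mismatch = max_mismatch,
                       search_window = search_window)
  samples <- list()
  report <- list()
  for (s in names(asg$bins)) {
    entry <- manifest[manifest$sample_label == s, , drop = FALSE]
    cl <- clip_decoration(asg$bins[[s]], entry)
    fl <- filter_min_length(cl$reads, min_len)
    samples[[s]] <- fl$reads
    report[[s]] <- data.frame(
      sample = s, assigned = nrow(asg$bins[[s]]), retained = nrow(fl$reads),
      short = fl$discarded, fully_clipped = nrow(cl$fully_clipped),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  structure(list(samples = samples, unassigned = asg$unassigned,
                 report = report, n_input = nrow(reads)),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d reads in, %d unassigned\n",
              x$n_input, nrow(x$unassigned)))
  print(x$report, row.names = FALSE)
  invisible(x)
}
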