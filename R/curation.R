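hit_fields <- c("qseqid", "sacc", "sgi", "length", "sstart", "send",
                "pident", "evalue", "staxid", "sskingdom", "ssciname")
hit_numeric <- c("sgi", "length", "sstart", "send", "pident", "evalue", "staxid")

#' Parse an 11-field comma-separated homology-hit table
#'
#' The supported layout is headerless, comma-separated, one hit per row with
#' fields `qseqid sacc sgi length sstart send pident evalue staxid sskingdom
#' ssciname` (the tabular output dialect in which the subject scientific
#' name contains no embedded commas). Malformed rows are reported with their
#' row number; unparseable numeric fields name the field.
#'
#' @param path Path to the hit table (or a character vector of lines).
#' @return A data frame with one typed column per field, row order
#'   preserved.
#' @export
parse_hit_table <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_frame())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 11L)
  if (length(bad)) {
    stop_cryo(sprintf("hit table row %d has %d fields, expected 11",
                      bad[1L], nf[bad[1L]]))
  }
  mat <- matrix(unlist(parts), ncol = 11L, byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- hit_fields
  for (f in hit_numeric) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    nab <- which(is.na(v) & !is.na(out[[f]]))
    if (length(nab)) {
      stop_cryo(sprintf("hit table row %d: field '%s' value '%s' is not numeric",
                        nab[1L], f, out[[f]][nab[1L]]))
    }
    out[[f]] <- if (f %in% c("sgi", "length", "sstart", "send", "staxid"))
      as.integer(v) else v
  }
  out
}

#' Write a hit table in the 11-field comma-separated layout
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_fields], path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Apply identity and e-value cutoffs
#'
#' Retains hits with `pident >= min_pident` (inclusive, matching the
#' ">= 97%" convention) and `evalue < max_evalue` (strict).
#'
#' @param hits Hit data frame.
#' @param min_pident Minimum percent identity (default 97).
#' @param max_evalue Exclusive e-value ceiling (default 1e-6).
#' @return The retained hits.
#' @export
apply_thresholds <- function(hits, min_pident = 97.0, max_evalue = 1e-6) {
  out <- hits[hits$pident >= min_pident & hits$evalue < max_evalue, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove negative-control matches from a sample hit table
#'
#' Any sample hit whose subject GI also occurs in the negative control at
#' `pident >= min_pident` is removed; the sample-side identity is not
#' re-examined here (that is the threshold stage's job).
#'
#' @param sample_hits,control_hits Parsed hit data frames.
#' @param min_pident Control-side identity floor defining contamination.
#' @return A list: `hits` (decontaminated sample hits) and `removed` (data
#'   frame of removed GIs with the number of rows removed per GI).
#' @export
subtract_control <- function(sample_hits, control_hits, min_pident = 97.0) {
  contaminated <- unique(control_hits$sgi[control_hits$pident >= min_pident])
  drop <- sample_hits$sgi %in% contaminated
  removed_gis <- sort(unique(sample_hits$sgi[drop]))
  removed <- data.frame(
    sgi = removed_gis,
    n_rows = as.integer(table(factor(sample_hits$sgi[drop],
                                     levels = removed_gis))),
    stringsAsFactors = FALSE)
  out <- sample_hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(hits = out, removed = removed)
}

#' Enumerate read frequencies per accession (or GI, or species)
#'
#' Counts, for each subject key, the number of distinct query reads hitting
#' it; multiple HSP rows of the same read against the same subject count
#' once.
#'
#' @param hits Hit data frame (typically thresholded and decontaminated).
#' @param by Grouping key: `"sacc"` (accession, default), `"sgi"`, or
#'   `"ssciname"` (species-level aggregation).
#' @return A data frame with the key column and `read_count`, sorted by key.
#' @export
enumerate_reads <- function(hits, by = c("sacc", "sgi", "ssciname")) {
  by <- match.arg(by)
  pairs <- unique(hits[, c("qseqid", by)])
  tab <- table(pairs[[by]])
  out <- data.frame(key = names(tab), read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  names(out)[1L] <- by
  if (by == "sgi") out$sgi <- as.integer(out$sgi)
  out[order(out[[by]]), , drop = FALSE]
}

#' Collapse duplicate GIs to their best hit
#'
#' Keeps exactly one row per subject GI: the row with the lowest e-value,
#' ties broken by highest percent identity, then longest alignment, then
#' first-seen (stable). Idempotent.
#'
#' @param hits Hit data frame.
#' @return One row per unique `sgi`, in order of first appearance.
#' @export
dedupe_best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$sgi, hits$evalue, -hits$pident, -hits$length,
               seq_len(nrow(hits)))
  sorted <- hits[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$sgi), , drop = FALSE]
  # restore first-appearance order of GIs
  first_seen <- match(best$sgi, hits$sgi)
  out <- best[order(first_seen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign molecule classes to unique records
#'
#' @param records Unique-GI hit data frame (from [dedupe_best_hit()]).
#' @param reference_metadata Data frame mapping `sacc` to `molecule_class`
#'   (one of `rRNA`, `mRNA`, `other`); accessions absent from the map are
#'   classed `other` with a warning.
#' @return `records` with a `molecule_class` column appended.
#' @export
classify_molecule <- function(records, reference_metadata) {
  idx <- match(records$sacc, reference_metadata$sacc)
  cls <- reference_metadata$molecule_class[idx]
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sprintf("%d accession(s) absent from reference metadata; classed 'other'",
                    sum(missing)), call. = FALSE)
    cls[missing] <- "other"
  }
  records$molecule_class <- cls
  records
}

#' Curate one sample's hit table into a community profile
#'
#' Runs the fixed post-search curation pipeline: identity/e-value thresholds
#' -> negative-control subtraction -> read enumeration -> best-hit
#' deduplication (-> optional molecule classification). Returns a
#' `curated_profile`: one row per retained unique GI carrying its best hit,
#' its distinct-read count, and its molecule class, with the decontamination
#' report and the no-hit fraction as attributes.
#'
#' @param sample_hits Parsed hit table for the sample.
#' @param control_hits Parsed hit table for the negative control (default
#'   empty: no decontamination).
#' @param sample_label Sample name stored on the profile.
#' @param min_pident,max_evalue Curation thresholds (defaults 97, 1e-6).
#' @param reference_metadata Optional accession -> molecule class map.
#' @param n_reads_searched Optional number of reads submitted to the
#'   homology search; enables the no-hit fraction
#'   `1 - (reads with any hit) / (reads searched)` in the report.
#' @return A data frame of class `curated_profile` with columns `sgi`,
#'   `sacc`, `ssciname`, `staxid`, `sskingdom`, `pident`, `evalue`,
#'   `length`, `read_count`, `molecule_class`; attributes `sample_label`,
#'   `thresholds`, `removed` (decontamination report), `no_hit_fraction`.
#' @export
curate_profile <- function(sample_hits, control_hits = empty_hit_frame(),
                           sample_label = "sample",
                           min_pident = 97.0, max_evalue = 1e-6,
                           reference_metadata = NULL,
                           n_reads_searched = NULL) {
  thr <- apply_thresholds(sample_hits, min_pident, max_evalue)
  dec <- subtract_control(thr, control_hits, min_pident)
  counts <- enumerate_reads(dec$hits, by = "sgi")
  uniq <- dedupe_best_hit(dec$hits)
  uniq$read_count <- counts$read_count[match(uniq$sgi, counts$sgi)]
  if (!is.null(reference_metadata)) {
    uniq <- classify_molecule(uniq, reference_metadata)
  } else {
    uniq$molecule_class <- NA_character_
  }
  no_hit <- if (!is.null(n_reads_searched) && n_reads_searched > 0) {
    1 - length(unique(sample_hits$qseqid)) / n_reads_searched
  } else NA_real_
  out <- uniq[, c("sgi", "sacc", "ssciname", "staxid", "sskingdom",
                  "pident", "evalue", "length", "read_count",
                  "molecule_class")]
  rownames(out) <- NULL
  structure(out,
            class = c("curated_profile", "data.frame"),
            sample_label = sample_label,
            thresholds = c(min_pident = min_pident, max_evalue = max_evalue),
            removed = dec$removed,
            no_hit_fraction = no_hit)
}

#' @export
print.curated_profile <- function(x, ...) {
  thr <- attr(x, "thresholds")
  if (!is.null(thr)) {
    cat(sprintf("curated_profile '%s': %d unique taxa, %d reads (pident >= %g, evalue < %g)\n",
                attr(x, "sample_label") %||% "sample", nrow(x),
                sum(x$read_count), thr["min_pident"], thr["max_evalue"]))
  }
  removed <- attr(x, "removed")
  if (!is.null(removed) && nrow(removed)) {
    cat(sprintf("  %d contaminant GI(s) removed via negative control\n",
                nrow(removed)))
  }
  nh <- attr(x, "no_hit_fraction")
  if (!is.null(nh) && !is.na(nh)) cat(sprintf("  no-hit fraction: %.3f\n", nh))
  NextMethod()
}

#' Write a curated profile as TSV with a JSON provenance block
#'
#' @param profile A `curated_profile`.
#' @param path Output TSV path; provenance goes to `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_curated_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- list(sample_label = attr(profile, "sample_label"),
               thresholds = as.list(attr(profile, "thresholds")),
               removed_gis = attr(profile, "removed")$sgi,
               no_hit_fraction = attr(profile, "no_hit_fraction"))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
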