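split_set <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

#' Read / write a declarative trait table
#'
#' The trait table replaces a manual literature lookup with a declarative
#' TSV: one row per species (`ssciname` unique), with set-valued columns
#' (`sources`, `physiologies`, `processes`) comma-separated within the
#' cell, a `trophic` mode, free-text `evidence`, and an `ambiguous` flag.
#' Ambiguous entries must carry empty source and physiology sets — such
#' taxa stay in profiles but never contribute to category tallies.
#'
#' @param path TSV path with a header row.
#' @return A validated trait table data frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$ambiguous <- tolower(df$ambiguous %||% "false") %in% c("true", "1", "yes")
  validate_trait_table(df)
}

#' @rdname read_trait_table
#' @param traits A trait table data frame.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_trait_table <- function(traits) {
  need <- c("ssciname", "domain", "phylum", "sources", "physiologies",
            "trophic", "processes", "ambiguous")
  missing <- setdiff(need, names(traits))
  if (length(missing)) {
    stop_cryo(sprintf("trait table lacks columns: %s",
                      paste(missing, collapse = ", ")))
  }
  dup <- traits$ssciname[duplicated(traits$ssciname)]
  if (length(dup)) {
    stop_cryo(sprintf("duplicate ssciname rows in trait table: %s",
                      paste(unique(dup), collapse = ", ")))
  }
  bad_src <- setdiff(unique(unlist(split_set(traits$sources))), habitat_sources())
  if (length(bad_src)) {
    stop_cryo(sprintf("unknown source category: %s (vocabulary: %s)",
                      paste(bad_src, collapse = ", "),
                      paste(habitat_sources(), collapse = ", ")))
  }
  bad_phy <- setdiff(unique(unlist(split_set(traits$physiologies))),
                     physiology_categories())
  if (length(bad_phy)) {
    stop_cryo(sprintf("unknown physiology category: %s (vocabulary: %s)",
                      paste(bad_phy, collapse = ", "),
                      paste(physiology_categories(), collapse = ", ")))
  }
  bad_prc <- setdiff(unique(unlist(split_set(traits$processes))),
                     metabolic_processes())
  if (length(bad_prc)) {
    stop_cryo(sprintf("unknown metabolic process: %s (vocabulary: %s)",
                      paste(bad_prc, collapse = "; "),
                      paste(metabolic_processes(), collapse = "; ")))
  }
  amb <- traits$ambiguous
  amb_bad <- amb & (nzchar(traits$sources) | nzchar(traits$physiologies))
  if (any(amb_bad)) {
    stop_cryo(sprintf("ambiguous trait entries must carry empty sources/physiologies: %s",
                      paste(traits$ssciname[amb_bad], collapse = ", ")))
  }
  traits
}

#' Join trait annotations onto a curated profile
#'
#' Each curated taxon is joined to its trait entry by exact scientific name
#' (species/strain-level, no fuzzy genus fallback). The join is total: taxa
#' with no entry, or flagged ambiguous, remain in the profile but receive no
#' category labels (they still count toward domain/phylum tallies where
#' those fields are known). Annotation never drops or adds taxa.
#'
#' @param profile A [curate_profile()] result (or any data frame with
#'   `ssciname` and `sskingdom`).
#' @param traits A trait table (validated; see [read_trait_table()]).
#' @return The profile with columns `domain`, `phylum`, `sources`,
#'   `physiologies`, `trophic`, `processes`, `annotated` (logical) added;
#'   class `annotated_profile`.
#' @export
annotate_profile <- function(profile, traits) {
  traits <- validate_trait_table(traits)
  idx <- match(profile$ssciname, traits$ssciname)
  hit <- !is.na(idx)
  amb <- hit & traits$ambiguous[idx]
  usable <- hit & !amb
  out <- as.data.frame(profile)
  out$domain <- ifelse(hit, traits$domain[idx], out$sskingdom)
  out$phylum <- ifelse(hit, traits$phylum[idx], "")
  out$sources <- ifelse(usable, traits$sources[idx], "")
  out$physiologies <- ifelse(usable, traits$physiologies[idx], "")
  out$trophic <- ifelse(usable, traits$trophic[idx], "")
  out$processes <- ifelse(usable, traits$processes[idx], "")
  out$annotated <- usable
  structure(out, class = c("annotated_profile", "data.frame"),
            sample_label = attr(profile, "sample_label") %||% "sample")
}

#' Tally category memberships per sample
#'
#' Counts unique taxa per habitat-source category and per physiology
#' category. Categories are sets, not partitions: one taxon may increment
#' several categories. Ambiguous and unannotated taxa contribute to the
#' domain tally (when the domain is known) but to no source or physiology
#' category.
#'
#' @param profiles A single [annotate_profile()] result or a named list of
#'   them.
#' @return A data frame of class `category_summary`: one row per (sample,
#'   category type, category) with the unique-taxon `count`; all vocabulary
#'   categories are present, zero-filled.
#' @export
summarize_categories <- function(profiles) {
  if (inherits(profiles, "annotated_profile")) {
    profiles <- stats::setNames(list(profiles),
                                attr(profiles, "sample_label"))
  }
  rows <- lapply(names(profiles), function(s) {
    pr <- profiles[[s]]
    count_sets <- function(col, vocab) {
      sets <- split_set(pr[[col]])
      tab <- table(factor(unlist(sets), levels = vocab))
      data.frame(sample = s, type = col, category = vocab,
                 count = as.integer(tab), stringsAsFactors = FALSE)
    }
    doms <- table(factor(pr$domain, levels = taxonomic_domains()))
    rbind(
      count_sets("sources", habitat_sources()),
      count_sets("physiologies", physiology_categories()),
      data.frame(sample = s, type = "domain", category = taxonomic_domains(),
                 count = as.integer(doms), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("category_summary", "data.frame")
  out
}

#' Build the process-by-group metabolic capability matrix
#'
#' For each metabolic process and each sample group (e.g. basal ice vs
#' accretion ice), the cell holds the union of phylum codes of the taxa in
#' that group carrying that process; empty cells are rendered `"nd"` (not
#' detected). Phylum names are mapped to short codes via [phylum_codes()];
#' unknown phyla raise an error.
#'
#' @param profiles Named list of [annotate_profile()] results.
#' @param grouping Named character vector mapping sample label -> group.
#' @return A data frame: `process` column plus one character column per
#'   group, each cell a comma-joined sorted code set or `"nd"`.
#' @export
build_metabolic_matrix <- function(profiles, grouping) {
  missing <- setdiff(names(profiles), names(grouping))
  if (length(missing)) {
    stop_cryo(sprintf("no group assigned for sample(s): %s",
                      paste(missing, collapse = ", ")))
  }
  codes <- phylum_codes()
  groups <- unique(unname(grouping[names(profiles)]))
  procs <- metabolic_processes()
  cells <- matrix("nd", nrow = length(procs), ncol = length(groups),
                  dimnames = list(procs, groups))
  acc <- lapply(stats::setNames(groups, groups),
                function(g) lapply(stats::setNames(vector("list", length(procs)),
                                                   procs), identity))
  for (s in names(profiles)) {
    pr <- profiles[[s]]
    g <- grouping[[s]]
    sets <- split_set(pr$processes)
    for (i in seq_len(nrow(pr))) {
      if (!length(sets[[i]])) next
      phy <- pr$phylum[i]
      code <- if (pr$domain[i] == "Archaea") codes[["Archaea"]] else codes[phy]
      if (is.na(code)) {
        stop_cryo(sprintf("no phylum code for '%s' (taxon %s); vocabulary: %s",
                          phy, pr$ssciname[i],
                          paste(names(codes), collapse = ", ")))
      }
      for (p in sets[[i]]) acc[[g]][[p]] <- union(acc[[g]][[p]], code)
    }
  }
  for (g in groups) {
    for (p in procs) {
      got <- acc[[g]][[p]]
      if (length(got)) {
        cells[p, g] <- paste(sort_codes(got), collapse = ", ")
      }
    }
  }
  out <- data.frame(process = procs, stringsAsFactors = FALSE)
  for (g in groups) out[[g]] <- unname(cells[, g])
  out
}

# canonical code order: alphabetical by full phylum name (legend order),
# which is stable under the Greek-letter proteobacteria codes
sort_codes <- function(x) {
  codes <- phylum_codes()
  nm <- names(codes)[match(x, codes)]
  nm[is.na(nm)] <- x[is.na(nm)]
  x[order(nm)]
}
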