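#' The packaged metabolic-capability reference matrix
#'
#' The process-by-ice-group matrix of phylum codes describing which taxon
#' groups detected in Lake Vostok basal and accretion ice carry each
#' metabolic capability (nitrogen cycling, carbon fixation pathways, metal
#' and sulfur redox processes). Cells hold comma-separated phylum codes (see
#' [phylum_codes()]); `"nd"` marks a capability not detected in that group,
#' and the free-text markers `"many"` / `"other heterotrophs"` flag
#' capabilities spread across taxa beyond the code vocabulary.
#'
#' @return Data frame with columns `process`, `basal_ice`, `accretion_ice`.
#' @export
reference_metabolic_matrix <- function() {
  path <- system.file("extdata", "vostok_metabolic_matrix.tsv",
                      package = "cryocurate", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8")
}

#' Extract the phylum-code content of a capability cell
#'
#' Splits a matrix cell on commas and keeps the tokens that are phylum
#' codes; `"nd"` and free-text markers yield an empty set. Codes are
#' returned in canonical (full-phylum-name alphabetical) order.
#'
#' @param cell Character vector of cells.
#' @return List of character vectors of codes.
#' @export
cell_codes <- function(cell) {
  lapply(split_set(cell), function(tokens) {
    sort_codes(intersect(tokens, unname(phylum_codes())))
  })
}

#' Reconstruct a trait table and profiles from a capability matrix
#'
#' Inverts a process-by-group matrix into (a) one synthetic representative
#' taxon per (group, phylum code) carrying every process whose cell lists
#' that code, and (b) matching one-group profiles, so that
#' [build_metabolic_matrix()] applied to the result reproduces the matrix's
#' phylum-code content cell-for-cell. Used to validate the annotation layer
#' against the packaged reference.
#'
#' @param mat A matrix as returned by [reference_metabolic_matrix()] (first
#'   column `process`, one column per group).
#' @return List with `profiles` (named list of annotated-profile-shaped
#'   data frames, one per group), `traits` (trait table), `grouping`
#'   (sample -> group map).
#' @export
metabolic_traits_from_matrix <- function(mat = reference_metabolic_matrix()) {
  codes <- phylum_codes()
  groups <- setdiff(names(mat), "process")
  traits <- list()
  profiles <- list()
  gi <- 0L
  for (g in groups) {
    sets <- cell_codes(mat[[g]])
    present <- unique(unlist(sets))
    rows <- lapply(present, function(code) {
      phylum <- names(codes)[match(code, codes)]
      procs <- mat$process[vapply(sets, function(s) code %in% s, logical(1))]
      gi <<- gi + 1L
      sciname <- sprintf("%s representative (%s)", phylum, g)
      list(
        trait = data.frame(
          ssciname = sciname,
          domain = if (code == "Ar") "Archaea" else
            if (code %in% c("As", "Bd", "Ch")) "Eukarya" else "Bacteria",
          phylum = phylum, sources = "", physiologies = "",
          trophic = "heterotroph",
          processes = paste(procs, collapse = ","),
          evidence = "synthetic reconstruction from reference matrix",
          ambiguous = FALSE, stringsAsFactors = FALSE),
        profile = data.frame(
          sgi = 900000L + gi, sacc = paste0("SYN", gi), ssciname = sciname,
          staxid = 900000L + gi,
          sskingdom = if (code == "Ar") "Archaea" else
            if (code %in% c("As", "Bd", "Ch")) "Eukarya" else "Bacteria",
          pident = 99, evalue = 1e-30, length = 100L, read_count = 1L,
          molecule_class = "mRNA", stringsAsFactors = FALSE))
    })
    traits[[g]] <- do.call(rbind, lapply(rows, `[[`, "trait"))
    profiles[[g]] <- do.call(rbind, lapply(rows, `[[`, "profile"))
  }
  traits <- do.call(rbind, c(traits, list(make.row.names = FALSE)))
  profiles <- lapply(profiles, function(p) { rownames(p) <- NULL; p })
  list(profiles = profiles, traits = traits,
       grouping = stats::setNames(groups, groups))
}

#' Rebuild the capability matrix from its trait reconstruction
#'
#' Round-trips [reference_metabolic_matrix()] through
#' [metabolic_traits_from_matrix()], [annotate_profile()] and
#' [build_metabolic_matrix()].
#'
#' @param mat A capability matrix (default the packaged reference).
#' @return The rebuilt process-by-group matrix.
#' @export
rebuild_metabolic_matrix <- function(mat = reference_metabolic_matrix()) {
  rec <- metabolic_traits_from_matrix(mat)
  annotated <- lapply(rec$profiles, annotate_profile, traits = rec$traits)
  out <- build_metabolic_matrix(annotated, rec$grouping)
  out[match(mat$process, out$process), , drop = FALSE]
}
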