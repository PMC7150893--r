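#' Build a MID demultiplexing manifest
#'
#' A manifest assigns one distinct 10-mer multiplex identifier (MID) to each
#' sample and records the linker and platform adapter sequences that decorate
#' each read as `ADAPTER + MID + LINKER + insert`.
#'
#' @param sample_label Character vector of sample names.
#' @param mid Character vector of 10-mer DNA MIDs, one per sample, pairwise
#'   distinct.
#' @param linker Linker/adapter sequence ligated between the MID and the
#'   insert (recycled across samples).
#' @param adapter_a,adapter_p1 Platform adapter sequences (A and P1 ends).
#' @return A data frame of class `mid_manifest`.
#' @seealso [vostok_mid_manifest()] for the packaged default manifest.
#' @export
mid_manifest <- function(sample_label, mid,
                         linker = "AATTCGCGGCCGCGTCGAC",
                         adapter_a = "CCATCTCATCCCTGCGTGTCTCCGACTCAG",
                         adapter_p1 = "CCTCTCTATGGGCAGTCGGTGAT") {
  assert_that(length(sample_label) == length(mid),
              "one MID is required per sample")
  mid <- toupper(mid)
  assert_that(!anyDuplicated(sample_label),
              "duplicate sample labels in manifest")
  if (anyDuplicated(mid)) {
    stop_cryo(sprintf("duplicate MID in manifest: %s",
                      paste(unique(mid[duplicated(mid)]), collapse = ", ")))
  }
  bad <- which(nchar(mid) != 10L | !is_dna(mid))
  if (length(bad)) {
    stop_cryo(sprintf("MID for sample '%s' is not a 10-mer DNA sequence",
                      sample_label[bad[1L]]))
  }
  out <- data.frame(sample_label = as.character(sample_label), mid = mid,
                    linker = toupper(linker),
                    adapter_a = toupper(adapter_a),
                    adapter_p1 = toupper(adapter_p1),
                    stringsAsFactors = FALSE)
  class(out) <- c("mid_manifest", "data.frame")
  out
}

#' The packaged Lake Vostok ice-core MID manifest
#'
#' Five MIDs: four ice-core section samples (glacial 2149 m; basal
#' 3501+3520 m; western embayment 3540+3569 m; eastern embayment 3585 m) and
#' a sterile-water negative control, with the EcoRI/NotI linker and the Ion
#' Torrent A/P1 adapters.
#'
#' @return A `mid_manifest` with five rows; the control row is labelled
#'   `"control"`.
#' @export
vostok_mid_manifest <- function() {
  mid_manifest(
    sample_label = c("2149m", "3501_3520m", "3540_3569m", "3585m", "control"),
    mid = c("ACGCTCGACA",   # MID2A, glacial 2149 m
            "AGCACTGTAG",   # MID4A, basal 3501+3520 m
            "ATCAGACACG",   # MID5A, west embayment 3540+3569 m
            "ATATCGCGAG",   # MID6A, east embayment 3585 m
            "TCTCTATGCG"))  # MID10A, water control
}

#' Read / write a MID manifest as TSV
#'
#' @param path TSV path with columns `sample_label`, `mid`, `linker`,
#'   `adapter_a`, `adapter_p1` and a header row.
#' @return `read_mid_manifest()` returns a `mid_manifest`;
#'   `write_mid_manifest()` returns `path` invisibly.
#' @export
read_mid_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_label", "mid")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_cryo(sprintf("manifest '%s' lacks required columns: %s",
                      path, paste(missing, collapse = ", ")))
  }
  mid_manifest(df$sample_label, df$mid,
               linker = df$linker[1L] %||% "AATTCGCGGCCGCGTCGAC",
               adapter_a = df$adapter_a[1L] %||% "CCATCTCATCCCTGCGTGTCTCCGACTCAG",
               adapter_p1 = df$adapter_p1[1L] %||% "CCTCTCTATGGGCAGTCGGTGAT")
}

#' @rdname read_mid_manifest
#' @param manifest A `mid_manifest`.
#' @export
write_mid_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
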