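# small fixture builders shared across test files

tiny_taxa <- function(abundances, prefix = "Taxon") {
  n <- length(abundances)
  lapply(seq_len(n), function(i) {
    taxon_spec(sciname = sprintf("%s %02d", prefix, i),
               gi = 1000L + i, taxid = 2000L + i,
               domain = "Bacteria", phylum = "Betaproteobacteria",
               abundance = abundances[i],
               reference_length = 2000L)
  })
}

tiny_spec <- function(abundances = c(0.5, 0.3, 0.2), n_reads = 200L,
                      contaminants = character(), seed = 1L, error = 0,
                      insert_range = c(50L, 300L)) {
  community_spec(tiny_taxa(abundances), n_reads_per_sample = n_reads,
                 insert_length_range = insert_range,
                 per_base_error_rate = error,
                 contaminant_taxa = contaminants, seed = seed)
}

# one decorated read for a given manifest row
decorated_read <- function(entry, insert, id = "r1") {
  data.frame(read_id = id,
             bases = paste0(entry$adapter_a, entry$mid, entry$linker, insert),
             stringsAsFactors = FALSE)
}

random_hit_frame <- function(n, n_gi = 5L) {
  if (n == 0L) {
    out <- random_hit_frame(1L, n_gi)
    return(out[0L, , drop = FALSE])
  }
  gis <- sample.int(n_gi, n, replace = TRUE) + 100L
  data.frame(
    qseqid = paste0("q", sample.int(max(1L, n %/% 2L), n, replace = TRUE)),
    sacc = paste0("ACC", gis), sgi = gis,
    length = sample(30:500, n, replace = TRUE),
    sstart = 1L, send = 100L,
    pident = round(stats::runif(n, 90, 100), 2),
    evalue = 10^-stats::runif(n, 0, 40),
    staxid = gis + 10L, sskingdom = "Bacteria",
    ssciname = paste0("Species ", gis),
    stringsAsFactors = FALSE)
}

# brute-force best-hit selection: min evalue, then max pident, then max
# alignment length, then first seen
brute_force_dedupe <- function(hits) {
  rows <- lapply(unique(hits$sgi), function(g) {
    h <- hits[hits$sgi == g, , drop = FALSE]
    h <- h[h$evalue == min(h$evalue), , drop = FALSE]
    h <- h[h$pident == max(h$pident), , drop = FALSE]
    h <- h[h$length == max(h$length), , drop = FALSE]
    h[1L, , drop = FALSE]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(match(out$sgi, hits$sgi)), , drop = FALSE]
}
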