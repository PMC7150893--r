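#' Shannon-Weaver diversity and evenness
#'
#' With relative abundances `p_i = count_i / sum(counts)`,
#' `H = -sum(p_i * log(p_i))` and evenness `J = H / log(S)` where `S` is the
#' richness (number of taxa). The logarithm base is configurable (evenness
#' is base-invariant); the default is the natural log, so `H` is in nats and
#' lies in `[0, log(S)]`. A single-taxon community has `H = 0` and an
#' undefined evenness (reported as `NA`, flagged, rather than 0).
#'
#' @param counts Positive numeric vector of per-taxon read counts (an
#'   abundance vector), optionally named.
#' @param base Logarithm base (default `exp(1)`; 2 and 10 are common).
#' @return A list of class `shannon_weaver`: `H`, `evenness`, `S` (richness),
#'   `reads` (total count), `log_base`, `evenness_defined`.
#' @export
shannon_weaver <- function(counts, base = exp(1)) {
  counts <- counts[!is.na(counts)]
  assert_that(length(counts) >= 1, "at least one taxon is required")
  assert_that(all(counts > 0), "all counts must be positive")
  p <- counts / sum(counts)
  H <- -sum(p * log(p, base = base))
  S <- length(counts)
  defined <- S > 1L
  structure(list(H = H,
                 evenness = if (defined) H / log(S, base = base) else NA_real_,
                 S = S, reads = sum(counts), log_base = base,
                 evenness_defined = defined),
            class = "shannon_weaver")
}

#' @export
print.shannon_weaver <- function(x, ...) {
  cat(sprintf("Shannon-Weaver: H = %.4f (base %s), evenness = %s, S = %d, reads = %g\n",
              x$H,
              if (isTRUE(all.equal(x$log_base, exp(1)))) "e" else format(x$log_base),
              if (x$evenness_defined) sprintf("%.4f", x$evenness) else "undefined (S = 1)",
              x$S, x$reads))
  invisible(x)
}

#' Per-sample diversity table from curated profiles
#'
#' @param profiles Named list of curated (or annotated) profiles with a
#'   `read_count` column.
#' @param base Logarithm base passed to [shannon_weaver()].
#' @return Data frame: `sample`, `S`, `reads`, `H`, `evenness`, `log_base`.
#' @export
diversity_table <- function(profiles, base = exp(1)) {
  rows <- lapply(names(profiles), function(s) {
    sw <- shannon_weaver(profiles[[s]]$read_count, base = base)
    data.frame(sample = s, S = sw$S, reads = sw$reads, H = sw$H,
               evenness = sw$evenness, log_base = base,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Unique / shared taxon accounting across samples
#'
#' Computes, over unique taxon keys (post-deduplication, not reads): the
#' number of taxa exclusive to each sample, the pairwise intersection
#' sizes, and the exhaustive disjoint-region counts (taxa present in
#' exactly a given subset of samples — the regions of a Venn diagram).
#' Disjoint-region counts always sum to the union size.
#'
#' @param sets Named list (length >= 2, unique names) of character/integer
#'   vectors of taxon keys per sample.
#' @return A list of class `overlap_report`: `unique` (named counts of
#'   sample-exclusive taxa), `shared` (data frame `sample_a`, `sample_b`,
#'   `shared`), `regions` (data frame `members` (sample names joined with
#'   `+`), `count`), `union_size`.
#' @export
taxon_overlap <- function(sets) {
  assert_that(length(sets) >= 2, "at least two samples are required")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
    stop_cryo("sets must be uniquely named by sample")
  }
  sets <- lapply(sets, unique)
  labs <- names(sets)
  all_keys <- unique(unlist(lapply(sets, as.character)))
  member <- vapply(sets, function(s) all_keys %in% as.character(s),
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, labs))
  sig <- apply(member, 1L, function(r) paste(labs[r], collapse = "+"))
  region_tab <- table(sig)
  regions <- data.frame(members = names(region_tab),
                        count = as.integer(region_tab),
                        stringsAsFactors = FALSE)
  uniq <- vapply(labs, function(l) sum(sig == l), integer(1))
  pairs <- utils::combn(labs, 2L)
  shared <- data.frame(sample_a = pairs[1L, ], sample_b = pairs[2L, ],
                       shared = apply(pairs, 2L, function(p) {
                         length(intersect(as.character(sets[[p[1L]]]),
                                          as.character(sets[[p[2L]]])))
                       }),
                       stringsAsFactors = FALSE)
  structure(list(unique = uniq, shared = shared, regions = regions,
                 union_size = length(all_keys)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: union of %d taxa across %d samples\n",
              x$union_size, length(x$unique)))
  cat("sample-exclusive taxa:\n")
  print(x$unique)
  invisible(x)
}

#' Domain and phylum breakdown of an annotated profile
#'
#' @param profile An [annotate_profile()] result.
#' @return List with `domain` and `phylum` data frames (`category`, `count`,
#'   `fraction`); taxa with an empty phylum are tallied under `"+"` (other).
#'   Fractions sum to 1 for nonempty profiles.
#' @export
domain_phylum_breakdown <- function(profile) {
  n <- nrow(profile)
  mk <- function(v) {
    v[!nzchar(v) | is.na(v)] <- "+"
    tab <- sort(table(v), decreasing = TRUE)
    data.frame(category = names(tab), count = as.integer(tab),
               fraction = if (n) as.integer(tab) / n else numeric(0),
               stringsAsFactors = FALSE)
  }
  list(domain = mk(profile$domain), phylum = mk(profile$phylum))
}
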