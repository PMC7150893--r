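test_that("the 11-field hit table parses with typed columns and strict diagnostics", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(), tmp)
  expect_equal(nrow(parse_hit_table(tmp)), 0L)
  writeLines("r1,AB1,111,150,1,150,98.7,1e-40,562,Bacteria,Escherichia coli",
             tmp)
  h <- parse_hit_table(tmp)
  expect_equal(h$pident, 98.7)
  expect_equal(h$evalue, 1e-40)
  expect_identical(h$sgi, 111L)
  expect_identical(h$ssciname, "Escherichia coli")
  writeLines(c("r1,AB1,111,150,1,150,98.7,1e-40,562,Bacteria,Escherichia coli",
               "r2,AB1,111,150,1,150"), tmp)
  expect_error(parse_hit_table(tmp), "row 2 has 6 fields")
  writeLines("r1,AB1,xx,150,1,150,98.7,1e-40,562,Bacteria,Escherichia coli",
             tmp)
  expect_error(parse_hit_table(tmp), "'sgi'")
})

test_that("simulated hit tables round-trip through the parser with zero loss", {
  spec <- tiny_spec(n_reads = 150L, contaminants = "Taxon 02", seed = 2)
  sim <- simulate_reads(spec)
  ht <- simulate_hit_table(sim$truth, spec)
  tmp <- withr::local_tempfile(fileext = ".csv")
  for (h in c(ht$samples, list(ht$control))) {
    write_hit_table(h, tmp)
    back <- parse_hit_table(tmp)
    expect_equal(nrow(back), nrow(h))
    expect_equal(back$qseqid, h$qseqid)
    expect_equal(back$evalue, h$evalue)
    expect_equal(back$pident, h$pident)
    expect_equal(back$ssciname, h$ssciname)
  }
})

test_that("thresholding is inclusive on identity and strict on e-value", {
  h <- random_hit_frame(4)
  h$pident <- c(97.0, 96.9, 99.0, 99.0)
  h$evalue <- c(1e-7, 1e-30, 1e-6, 9.9e-7)
  kept <- apply_thresholds(h)
  expect_identical(which(h$pident >= 97 & h$evalue < 1e-6), c(1L, 4L))
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$pident >= 97 & kept$evalue < 1e-6))
})

test_that("control subtraction removes exactly the shared-GI hits", {
  sample_hits <- random_hit_frame(30, n_gi = 6L)
  expect_identical(subtract_control(sample_hits, empty_control <- sample_hits[0, ])$hits,
                   sample_hits)
  control <- sample_hits[1:2, ]
  control$pident <- c(99, 96)  # only the first defines contamination
  dec <- subtract_control(sample_hits, control)
  bad_gi <- control$sgi[1L]
  if (control$sgi[2L] != bad_gi) {
    expect_false(control$sgi[2L] %in% dec$removed$sgi)
  }
  expect_false(bad_gi %in% dec$hits$sgi)
  expect_equal(sort(unique(c(dec$hits$sgi, bad_gi))), sort(unique(sample_hits$sgi)))
  expect_equal(dec$removed$n_rows[dec$removed$sgi == bad_gi],
               sum(sample_hits$sgi == bad_gi))
})

test_that("read enumeration counts distinct reads per accession", {
  h <- data.frame(qseqid = c("r1", "r1", "r1", "r2", "r3", "r3"),
                  sacc = c("AB1", "AB1", "AB1", "AB1", "AB2", "AB1"),
                  sgi = c(1L, 1L, 1L, 1L, 2L, 1L),
                  length = 100L, sstart = 1L, send = 100L,
                  pident = 99, evalue = 1e-20, staxid = 9L,
                  sskingdom = "Bacteria", ssciname = c(rep("Sp one", 4), "Sp two", "Sp one"),
                  stringsAsFactors = FALSE)
  en <- enumerate_reads(h, by = "sacc")
  expect_equal(en$read_count[en$sacc == "AB1"], 3L)  # r1 counted once
  expect_equal(en$read_count[en$sacc == "AB2"], 1L)
  en2 <- enumerate_reads(h, by = "ssciname")
  expect_equal(en2$read_count[en2$ssciname == "Sp one"], 3L)
})

test_that("best-hit deduplication matches brute force and is idempotent", {
  h <- random_hit_frame(2)
  h$sgi <- c(111L, 111L)
  h$evalue <- c(1e-30, 1e-12)
  expect_equal(dedupe_best_hit(h)$evalue, 1e-30)
  h$evalue <- c(1e-12, 1e-12)
  h$pident <- c(98.0, 99.1)
  expect_equal(dedupe_best_hit(h)$pident, 99.1)
  withr::with_seed(99, {
    for (i in 1:25) {
      hits <- random_hit_frame(sample(1:40, 1))
      # force exact ties frequently
      hits$evalue <- sample(c(1e-10, 1e-20), nrow(hits), replace = TRUE)
      hits$pident <- sample(c(97.5, 99.0), nrow(hits), replace = TRUE)
      got <- dedupe_best_hit(hits)
      want <- brute_force_dedupe(hits)
      expect_equal(got, want, ignore_attr = TRUE)
      expect_equal(dedupe_best_hit(got), got)
    }
  })
})

test_that("molecule classification falls back to 'other' for unknown accessions", {
  meta <- data.frame(sacc = c("A1", "A2"),
                     molecule_class = c("rRNA", "mRNA"),
                     stringsAsFactors = FALSE)
  rec <- data.frame(sacc = c("A1", "A2", "A9"), stringsAsFactors = FALSE)
  expect_warning(out <- classify_molecule(rec, meta), "absent")
  expect_identical(out$molecule_class, c("rRNA", "mRNA", "other"))
})

test_that("curate_profile composes the stages and its invariants hold on random input", {
  withr::with_seed(4, {
    for (i in 1:20) {
      hits <- random_hit_frame(sample(5:80, 1), n_gi = 8L)
      control <- random_hit_frame(sample(0:10, 1), n_gi = 8L)
      pr <- curate_profile(hits, control, n_reads_searched = 60L)
      expect_false(anyDuplicated(pr$sgi) > 0)
      expect_true(all(pr$pident >= 97 & pr$evalue < 1e-6))
      expect_true(all(pr$read_count >= 1))
      contaminated <- unique(control$sgi[control$pident >= 97])
      expect_length(intersect(pr$sgi, contaminated), 0L)
      nh <- attr(pr, "no_hit_fraction")
      expect_true(nh >= 0 && nh <= 1)
    }
  })
})

test_that("curation recovers the true community from a planted synthetic run", {
  spec <- tiny_spec(abundances = c(0.4, 0.3, 0.2, 0.1), n_reads = 400L,
                    contaminants = "Taxon 04", seed = 31)
  sim <- simulate_reads(spec)
  ht <- simulate_hit_table(sim$truth, spec, no_hit_rate = 0.33)
  meta <- molecule_metadata(spec)
  truth <- sim$truth
  for (s in names(ht$samples)) {
    pr <- curate_profile(ht$samples[[s]], ht$control, sample_label = s,
                         reference_metadata = meta,
                         n_reads_searched = attr(ht, "searched")[[s]])
    # recovered GI set = true community GIs with >= 1 surviving read,
    # minus planted contaminants
    surviving <- unique(ht$samples[[s]]$sgi[ht$samples[[s]]$sgi < 9e6])
    want <- setdiff(surviving, 1004L)
    expect_setequal(pr$sgi, want)
    # read counts match the truth-map tally of hit-returning reads
    own <- ht$samples[[s]][ht$samples[[s]]$sgi < 9e6, ]
    tally <- table(truth$sciname[match(unique(own$qseqid), truth$read_id)])
    for (nm in pr$ssciname) {
      expect_equal(pr$read_count[pr$ssciname == nm], unname(tally[nm]),
                   ignore_attr = TRUE)
    }
    # no-hit fraction equals its definition
    expect_equal(attr(pr, "no_hit_fraction"),
                 1 - length(unique(ht$samples[[s]]$qseqid)) /
                   attr(ht, "searched")[[s]])
  }
})

test_that("molecule-class proportions track each taxon's class mix", {
  taxa <- list(
    taxon_spec("Mixy alpha", 1L, 11L, "Bacteria", "Betaproteobacteria", 0.5,
               molecule_class_mix = c(rRNA = 0.7, mRNA = 0.2, other = 0.1),
               reference_length = 3000L),
    taxon_spec("Mixy beta", 2L, 12L, "Bacteria", "Betaproteobacteria", 0.5,
               molecule_class_mix = c(rRNA = 0.1, mRNA = 0.8, other = 0.1),
               reference_length = 3000L))
  spec <- community_spec(taxa, n_reads_per_sample = 1500L, seed = 8)
  sim <- simulate_reads(spec)
  ht <- simulate_hit_table(sim$truth, spec, no_hit_rate = 0)
  h <- ht$samples[[1L]]
  en <- enumerate_reads(h[h$sgi < 9e6, ], by = "sacc")
  for (tx in taxa) {
    counts <- en$read_count[match(paste0("ACC", tx$gi, "_",
                                         c("rRNA", "mRNA", "other")),
                                  en$sacc)]
    counts[is.na(counts)] <- 0L
    n <- sum(counts)
    for (k in 1:3) {
      p <- tx$molecule_class_mix[k]
      expect_lt(abs(counts[k] - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
    }
  }
})
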