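test_that("community specification enforces its invariants", {
  expect_error(community_spec(tiny_taxa(c(0.5, 0.4))), "sum")
  expect_error(tiny_spec(insert_range = c(0L, 10L)), "insert_length_range")
  taxa <- tiny_taxa(c(0.5, 0.5))
  taxa[[2L]]$gi <- taxa[[1L]]$gi
  expect_error(community_spec(taxa), "unique")
  expect_error(tiny_spec(contaminants = "Nope"), "contaminant")
  expect_error(taxon_spec("X", 1, 1, "Bacteria", "P", 0.5,
                          molecule_class_mix = c(rRNA = 0.5, mRNA = 0.4,
                                                 other = 0.2)),
               "sums to")
})

test_that("a degenerate one-taxon community has share 1 and shares always normalize", {
  one <- community_spec(tiny_taxa(1.0), seed = 3)
  expect_equal(simulate_community(one)$share, 1.0)
  spec <- random_community(n_taxa = 10, seed = 11)
  shares <- simulate_community(spec)$share
  expect_equal(sum(shares), 1, tolerance = 1e-9)
  expect_identical(simulate_community(spec), simulate_community(spec))
})

test_that("simulated reads follow the decoration grammar and the truth map", {
  spec <- tiny_spec(n_reads = 300L, seed = 5)
  mani <- vostok_mid_manifest()
  sim <- simulate_reads(spec, mani)
  # conservation: truth rows = total simulated reads (no contaminants -> no control reads)
  expect_equal(nrow(sim$truth), 4L * 300L)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  # decoration: the glacial sample's reads start with A-adapter then its MID
  g <- sim$reads[sim$reads$sample_label == "2149m", ]
  expect_true(all(startsWith(g$bases,
                             paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG",
                                    "ACGCTCGACA"))))
  # zero-error: every insert is an exact substring of its taxon's reference
  refs <- taxon_references(spec)
  idx <- sample.int(nrow(sim$truth), 50L)
  hit <- mapply(grepl, sim$truth$insert[idx],
                refs[sim$truth$sciname[idx]], MoreArgs = list(fixed = TRUE))
  expect_true(all(hit))
  # seed determinism
  sim2 <- simulate_reads(spec, mani)
  expect_identical(sim, sim2)
})

test_that("per-sample taxon counts stay within 3 binomial SD of expectation", {
  spec <- tiny_spec(abundances = c(0.9, 0.1), n_reads = 1000L, seed = 9)
  sim <- simulate_reads(spec)
  for (s in unique(sim$truth$sample_label)) {
    n1 <- sum(sim$truth$sciname[sim$truth$sample_label == s] == "Taxon 01")
    sd1 <- sqrt(1000 * 0.9 * 0.1)
    expect_lt(abs(n1 - 900), 3 * sd1)
  }
})

test_that("hit tables plant true, duplicate and sub-threshold rows as promised", {
  spec <- tiny_spec(n_reads = 400L, contaminants = "Taxon 01", seed = 13)
  sim <- simulate_reads(spec)
  ht <- simulate_hit_table(sim$truth, spec, no_hit_rate = 0.3)
  all_rows <- do.call(rbind, c(ht$samples, list(make.row.names = FALSE)))
  expect_equal(ncol(all_rows), 11L)
  # every read's true-taxon best row passes the curation thresholds
  truth <- sim$truth
  for (s in names(ht$samples)) {
    h <- ht$samples[[s]]
    own <- h[h$sgi < 9e6, ]
    expect_true(all(own$pident >= 97))
    idx <- match(own$qseqid, truth$read_id)
    expect_equal(own$ssciname, truth$sciname[idx])
  }
  # sub-threshold decoys really are sub-threshold
  decoys <- all_rows[all_rows$sgi >= 9e6, ]
  expect_gt(nrow(decoys), 0)
  expect_true(all(decoys$pident < 97 | decoys$evalue >= 1e-6))
  # planted contaminant appears in the control at >= 97 identity
  expect_true(1001L %in% ht$control$sgi[ht$control$pident >= 97])
  # no contaminants -> empty control
  spec0 <- tiny_spec(seed = 13)
  sim0 <- simulate_reads(spec0)
  ht0 <- simulate_hit_table(sim0$truth, spec0)
  expect_equal(nrow(ht0$control), 0L)
  # max 20 rows per read
  expect_true(all(table(all_rows$qseqid) <= 20L))
})

test_that("duplicate-GI planting preserves the best-row ordering oracle", {
  spec <- tiny_spec(n_reads = 500L, seed = 21)
  sim <- simulate_reads(spec)
  ht <- simulate_hit_table(sim$truth, spec, no_hit_rate = 0, dup_gi_rate = 1)
  h <- ht$samples[[1L]]
  own <- h[h$sgi < 9e6, ]
  dup_reads <- names(which(table(own$qseqid) > 1L))
  expect_gt(length(dup_reads), 0)
  for (q in dup_reads[1:10]) {
    rows <- own[own$qseqid == q, ]
    best <- rows[which.min(rows$evalue), ]
    kept <- dedupe_best_hit(rows)
    expect_equal(kept$evalue, best$evalue)
  }
})

test_that("the association generator is seeded and matches NB moments", {
  d1 <- simulate_association_dataset(betas = c(NPOC = 0.5), seed = 42)
  d2 <- simulate_association_dataset(betas = c(NPOC = 0.5), seed = 42)
  expect_identical(d1, d2)
  expect_error(simulate_association_dataset(dispersion = 0), "dispersion")
  expect_error(simulate_association_dataset(betas = c(Unobtanium = 1)),
               "unknown covariate")
  # all betas zero, sigma_u zero: counts are iid NB(mu = exp(intercept))
  d <- simulate_association_dataset(betas = c(NPOC = 0), dispersion = 2,
                                    n_obs = 4000, sigma_u = 0,
                                    intercept = 2, seed = 7)
  mu <- exp(2); theta <- 2
  se <- sqrt((mu + mu^2 / theta) / 4000)
  expect_lt(abs(mean(d$species_count) - mu), 3 * se)
})
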