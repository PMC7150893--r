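make_profile <- function(scinames, domains = "Bacteria") {
  n <- length(scinames)
  structure(data.frame(
    sgi = seq_len(n), sacc = paste0("A", seq_len(n)), ssciname = scinames,
    staxid = seq_len(n), sskingdom = rep_len(domains, n),
    pident = 99, evalue = 1e-20, length = 100L, read_count = 1L,
    molecule_class = "mRNA", stringsAsFactors = FALSE),
    class = c("curated_profile", "data.frame"), sample_label = "s1")
}

trait_row <- function(ssciname, domain = "Bacteria",
                      phylum = "Betaproteobacteria", sources = "",
                      physiologies = "", processes = "", ambiguous = FALSE) {
  data.frame(ssciname = ssciname, domain = domain, phylum = phylum,
             sources = sources, physiologies = physiologies,
             trophic = "heterotroph", processes = processes,
             evidence = "", ambiguous = ambiguous, stringsAsFactors = FALSE)
}

test_that("trait tables are validated against the controlled vocabularies", {
  tr <- rbind(trait_row("A b"), trait_row("A b"))
  expect_error(annotate_profile(make_profile("A b"), tr), "duplicate")
  expect_error(annotate_profile(make_profile("A b"),
                                trait_row("A b", sources = "outer_space")),
               "unknown source")
  expect_error(annotate_profile(make_profile("A b"),
                                trait_row("A b", physiologies = "barophilic")),
               "unknown physiology")
  expect_error(annotate_profile(make_profile("A b"),
                                trait_row("A b", processes = "alchemy")),
               "unknown metabolic process")
  expect_error(annotate_profile(make_profile("A b"),
                                trait_row("A b", sources = "marine",
                                          ambiguous = TRUE)),
               "ambiguous")
})

test_that("annotation is total, non-destructive, and skips ambiguous taxa", {
  pr <- make_profile(c("Known sp", "Ambig sp", "Mystery sp"))
  traits <- rbind(
    trait_row("Known sp", sources = "marine,aquatic_freshwater",
              physiologies = "halophilic_halotolerant"),
    trait_row("Ambig sp", ambiguous = TRUE))
  ann <- annotate_profile(pr, traits)
  expect_equal(nrow(ann), 3L)  # no taxon dropped
  expect_identical(ann$annotated, c(TRUE, FALSE, FALSE))
  expect_equal(ann$sources[1L], "marine,aquatic_freshwater")
  expect_equal(ann$sources[2L], "")
  # empty traits table: full retention, zero labels
  ann0 <- annotate_profile(pr, trait_row("placeholder")[0L, ])
  expect_equal(nrow(ann0), 3L)
  expect_true(all(!ann0$annotated))
  summ0 <- summarize_categories(ann0)
  expect_true(all(summ0$count[summ0$type %in% c("sources", "physiologies")] == 0L))
  # unannotated taxa still count toward their domain
  expect_equal(summ0$count[summ0$type == "domain" & summ0$category == "Bacteria"],
               3L)
})

test_that("category tallies use set semantics over unique taxa", {
  pr <- make_profile(c("Both sp", "Marine sp"))
  traits <- rbind(
    trait_row("Both sp", sources = "marine,aquatic_freshwater"),
    trait_row("Marine sp", sources = "marine"))
  summ <- summarize_categories(annotate_profile(pr, traits))
  src <- summ[summ$type == "sources", ]
  expect_equal(src$count[src$category == "marine"], 2L)
  expect_equal(src$count[src$category == "aquatic_freshwater"], 1L)
  expect_equal(src$count[src$category == "soil_sediment"], 0L)
  # order invariance
  pr2 <- pr[2:1, ]
  summ2 <- summarize_categories(annotate_profile(pr2, traits))
  expect_equal(summ$count, summ2$count)
})

test_that("category tallies match a brute-force recount on a synthetic community", {
  spec <- random_community(n_taxa = 40, n_reads_per_sample = 200, seed = 23)
  traits <- simulate_trait_table(spec)
  scinames <- vapply(spec$taxa, `[[`, character(1), "sciname")
  pr <- make_profile(scinames)
  pr$sskingdom <- vapply(spec$taxa, `[[`, character(1), "domain")
  summ <- summarize_categories(annotate_profile(pr, traits))
  # brute force from the trait table itself
  for (cat in habitat_sources()) {
    want <- sum(vapply(strsplit(traits$sources, ","), function(s) cat %in% s,
                       logical(1)) & !traits$ambiguous)
    expect_equal(summ$count[summ$type == "sources" & summ$category == cat],
                 want)
  }
})

test_that("physiology prevalence tracks the generator's inclusion probability", {
  spec <- random_community(n_taxa = 300, seed = 41)
  traits <- simulate_trait_table(spec, physiology_probs = c(halophilic_halotolerant = 0.3),
                                 p_ambiguous = 0)
  halo <- grepl("halophilic_halotolerant", traits$physiologies)
  n <- nrow(traits)
  expect_lt(abs(sum(halo) - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("the metabolic matrix reduces to per-cell unions with nd for empties", {
  pr <- make_profile(c("Iron sp", "Fix sp"))
  traits <- rbind(
    trait_row("Iron sp", phylum = "Betaproteobacteria",
              processes = "Iron oxidation"),
    trait_row("Fix sp", phylum = "Cyanobacteria",
              processes = "Carbon fixation: reductive PP cycle,Iron oxidation"))
  ann <- annotate_profile(pr, traits)
  mm <- build_metabolic_matrix(list(basal = ann, accretion = ann),
                               c(basal = "basal", accretion = "accretion"))
  iron <- mm[mm$process == "Iron oxidation", ]
  expect_equal(iron$basal, "βP, Cy")
  expect_equal(iron$accretion, "βP, Cy")
  expect_equal(mm$basal[mm$process == "Manganese oxidation"], "nd")
})

test_that("the packaged capability matrix is rebuilt cell-for-cell from traits", {
  ref <- reference_metabolic_matrix()
  reb <- rebuild_metabolic_matrix(ref)
  expect_identical(reb$process, ref$process)
  for (g in c("basal_ice", "accretion_ice")) {
    want <- cell_codes(ref[[g]])
    got <- cell_codes(reb[[g]])
    for (i in seq_along(want)) {
      expect_identical(got[[i]], want[[i]])
    }
  }
  # spot checks against the printed capability sets
  expect_equal(reb$basal_ice[reb$process == "Iron oxidation"], "βP")
  expect_equal(reb$basal_ice[reb$process == "Manganese oxidation"], "nd")
  expect_equal(reb$accretion_ice[reb$process == "Uranium reduction"], "nd")
})
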