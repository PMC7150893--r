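#' Describe one taxon of a synthetic community
#'
#' @param sciname Scientific name (unique within a community).
#' @param gi Positive integer surrogate database identifier (unique within a
#'   community; purely synthetic, no claim of real database identity).
#' @param taxid Positive integer surrogate taxon identifier.
#' @param domain One of `"Archaea"`, `"Bacteria"`, `"Eukarya"`.
#' @param phylum Phylum (or major group) name; may be `""` when unknown.
#' @param abundance Relative abundance in `[0, 1]`.
#' @param molecule_class_mix Named fractions over `rRNA`, `mRNA`, `other`
#'   summing to 1; the mix from which each read's molecule class is drawn.
#' @param reference_length Length in bp of the taxon's synthetic reference
#'   sequence that inserts are excised from.
#' @param traits Optional single-row trait entry (see [simulate_trait_table()]);
#'   when supplied it overrides the randomly generated entry.
#' @return A list of class `taxon_spec`.
#' @export
taxon_spec <- function(sciname, gi, taxid, domain, phylum, abundance,
                       molecule_class_mix = c(rRNA = 0.5, mRNA = 0.4, other = 0.1),
                       reference_length = 5000L, traits = NULL) {
  assert_that(is.character(sciname) && nzchar(sciname), "sciname must be nonempty text")
  assert_that(gi >= 1, "gi must be a positive integer")
  assert_that(taxid >= 1, "taxid must be a positive integer")
  assert_that(domain %in% taxonomic_domains(),
              sprintf("domain must be one of %s", paste(taxonomic_domains(), collapse = ", ")))
  assert_that(abundance >= 0 && abundance <= 1, "abundance must lie in [0, 1]")
  mix <- molecule_class_mix[c("rRNA", "mRNA", "other")]
  assert_that(!anyNA(mix), "molecule_class_mix must name rRNA, mRNA and other")
  if (abs(sum(mix) - 1) > 1e-9) {
    stop_cryo(sprintf("molecule_class_mix sums to %.12g, not 1", sum(mix)))
  }
  assert_that(reference_length >= 1, "reference_length must be positive")
  structure(list(sciname = sciname, gi = as.integer(gi), taxid = as.integer(taxid),
                 domain = domain, phylum = phylum, abundance = abundance,
                 molecule_class_mix = mix,
                 reference_length = as.integer(reference_length),
                 traits = traits),
            class = "taxon_spec")
}

#' Specify a synthetic multi-sample community
#'
#' A `community_spec` is the ground truth behind a simulated sequencing run:
#' the taxa with their relative abundances and traits, the per-sample read
#' depth, the insert-length range, the substitution error rate, and the
#' subset of taxa planted as negative-control contaminants.
#'
#' @param taxa List of [taxon_spec()] objects; abundances must sum to 1
#'   (within 1e-9) and `gi` values must be unique.
#' @param n_reads_per_sample Reads simulated per (non-control) sample.
#' @param insert_length_range Integer pair `(min, max)` in bp; inserts are
#'   drawn uniformly on this range. The default deliberately starts at 50 bp
#'   so the post-clip length filter boundary is exercised.
#' @param per_base_error_rate Per-base substitution probability in `[0, 1]`.
#' @param contaminant_taxa Character vector of scinames (subset of `taxa`)
#'   planted as also present in the negative control.
#' @param seed Integer seed; all downstream simulation derives from it.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(taxa, n_reads_per_sample = 1000L,
                           insert_length_range = c(50L, 1000L),
                           per_base_error_rate = 0,
                           contaminant_taxa = character(),
                           seed = 1L) {
  assert_that(length(taxa) >= 1, "at least one taxon is required")
  assert_that(all(vapply(taxa, inherits, logical(1), "taxon_spec")),
              "taxa must be a list of taxon_spec objects")
  ab <- vapply(taxa, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-9) {
    stop_cryo(sprintf("taxon abundances sum to %.12g, not 1", sum(ab)))
  }
  gis <- vapply(taxa, `[[`, integer(1), "gi")
  assert_that(!anyDuplicated(gis), "taxon gi values must be unique")
  scinames <- vapply(taxa, `[[`, character(1), "sciname")
  assert_that(!anyDuplicated(scinames), "taxon scinames must be unique")
  assert_that(n_reads_per_sample >= 1, "n_reads_per_sample must be positive")
  assert_that(length(insert_length_range) == 2 &&
                insert_length_range[1] >= 1 &&
                insert_length_range[1] <= insert_length_range[2],
              "insert_length_range must be an increasing pair with min >= 1")
  assert_that(per_base_error_rate >= 0 && per_base_error_rate <= 1,
              "per_base_error_rate must lie in [0, 1]")
  unknown <- setdiff(contaminant_taxa, scinames)
  if (length(unknown)) {
    stop_cryo(sprintf("contaminant_taxa not in the community: %s",
                      paste(unknown, collapse = ", ")))
  }
  structure(list(taxa = taxa,
                 n_reads_per_sample = as.integer(n_reads_per_sample),
                 insert_length_range = as.integer(insert_length_range),
                 per_base_error_rate = per_base_error_rate,
                 contaminant_taxa = contaminant_taxa,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("community_spec: %d taxa, %d reads/sample, inserts %d-%d bp, error %.3g, %d contaminant(s), seed %d\n",
              length(x$taxa), x$n_reads_per_sample,
              x$insert_length_range[1], x$insert_length_range[2],
              x$per_base_error_rate, length(x$contaminant_taxa), x$seed))
  invisible(x)
}

spec_table <- function(spec) {
  data.frame(
    sciname = vapply(spec$taxa, `[[`, character(1), "sciname"),
    gi = vapply(spec$taxa, `[[`, integer(1), "gi"),
    taxid = vapply(spec$taxa, `[[`, integer(1), "taxid"),
    domain = vapply(spec$taxa, `[[`, character(1), "domain"),
    phylum = vapply(spec$taxa, `[[`, character(1), "phylum"),
    abundance = vapply(spec$taxa, `[[`, numeric(1), "abundance"),
    reference_length = vapply(spec$taxa, `[[`, integer(1), "reference_length"),
    stringsAsFactors = FALSE)
}

#' Realize the normalized community abundance table
#'
#' Normalizes the specified abundances and returns the expected read share of
#' every taxon; this is the multinomial parameter vector used by
#' [simulate_reads()]. Deterministic for a fixed spec.
#'
#' @param spec A [community_spec()].
#' @return A data frame with columns `sciname`, `gi`, `domain`, `phylum`,
#'   `share`; shares sum to 1.
#' @export
simulate_community <- function(spec) {
  assert_that(inherits(spec, "community_spec"), "spec must be a community_spec")
  tab <- spec_table(spec)
  tab$share <- tab$abundance / sum(tab$abundance)
  tab$abundance <- NULL
  tab$reference_length <- NULL
  tab
}

#' Synthetic reference sequences for a community
#'
#' Each taxon gets a reproducible random DNA reference (derived from the
#' spec's seed and the taxon's gi) from which read inserts are excised.
#'
#' @param spec A [community_spec()].
#' @return Named character vector of references, names = sciname.
#' @export
taxon_references <- function(spec) {
  refs <- vapply(spec$taxa, function(tx) {
    with_seed(derive_seed(spec$seed, tx$gi), {
      paste(sample(c("A", "C", "G", "T"), tx$reference_length, replace = TRUE),
            collapse = "")
    })
  }, character(1))
  names(refs) <- vapply(spec$taxa, `[[`, character(1), "sciname")
  refs
}

apply_substitutions <- function(bases, rate) {
  if (rate <= 0) return(bases)
  alphabet <- c("A", "C", "G", "T")
  vapply(bases, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in pos) {
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate decorated multiplexed reads with ground truth
#'
#' Every read is `adapter_a + MID + linker + insert`. Insert lengths are
#' uniform on the spec's range (capped at the reference length), the source
#' taxon is drawn multinomially by abundance, and substitution errors are
#' applied at the spec's per-base rate. The negative-control sample (if
#' present in the manifest) receives reads only from the planted contaminant
#' taxa — each contaminant at least once — emulating shared contamination
#' between control and samples.
#'
#' @param spec A [community_spec()].
#' @param manifest A [mid_manifest()]; one row per sample.
#' @param control_label Which manifest row is the negative control
#'   (default `"control"`); ignored if absent from the manifest.
#' @param n_reads_control Reads for the control sample (default one tenth of
#'   `n_reads_per_sample`); forced to 0 when there are no contaminants.
#' @return A list with `reads` (data frame: `read_id`, `sample_label`,
#'   `bases`, `qualities`) and `truth` (data frame: `read_id`,
#'   `sample_label`, `sciname`, `gi`, `insert_length`, `insert`,
#'   `molecule_class`). `truth$insert` is the post-error insert, i.e. exactly
#'   what demultiplexing + clipping should recover.
#' @export
simulate_reads <- function(spec, manifest = vostok_mid_manifest(),
                           control_label = "control",
                           n_reads_control = NULL) {
  assert_that(inherits(spec, "community_spec"), "spec must be a community_spec")
  assert_that(inherits(manifest, "mid_manifest"), "manifest must be a mid_manifest")
  if (anyDuplicated(manifest$mid)) stop_cryo("duplicate MID in manifest")
  shares <- simulate_community(spec)
  refs <- taxon_references(spec)
  is_control <- manifest$sample_label == control_label
  n_ctrl <- n_reads_control %||% max(1L, spec$n_reads_per_sample %/% 10L)
  if (!length(spec$contaminant_taxa)) n_ctrl <- 0L

  with_seed(derive_seed(spec$seed, 1L), {
    read_rows <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(manifest))) {
      smp <- manifest$sample_label[i]
      if (is_control[i]) {
        n <- n_ctrl
        if (n == 0L) next
        # guarantee every planted contaminant is present in the control
        pool <- spec$contaminant_taxa
        picks <- c(pool, sample(pool, max(0L, n - length(pool)), replace = TRUE))
        picks <- picks[seq_len(n)]
      } else {
        n <- spec$n_reads_per_sample
        picks <- sample(shares$sciname, n, replace = TRUE, prob = shares$share)
      }
      lens <- sample(seq(spec$insert_length_range[1], spec$insert_length_range[2]),
                     n, replace = TRUE)
      ref_len <- nchar(refs[picks])
      lens <- pmin(lens, ref_len)
      starts <- floor(stats::runif(n, 1, ref_len - lens + 1 + 1))
      inserts <- substr(refs[picks], starts, starts + lens - 1L)
      mix <- vapply(spec$taxa, function(tx) tx$molecule_class_mix,
                    numeric(3))  # 3 x ntaxa, rows rRNA/mRNA/other
      colnames(mix) <- names(refs)
      classes <- vapply(picks, function(tx) {
        sample(c("rRNA", "mRNA", "other"), 1L, prob = mix[, tx])
      }, character(1), USE.NAMES = FALSE)
      bases <- paste0(manifest$adapter_a[i], manifest$mid[i],
                      manifest$linker[i], inserts)
      bases <- apply_substitutions(bases, spec$per_base_error_rate)
      deco <- nchar(manifest$adapter_a[i]) + nchar(manifest$mid[i]) +
        nchar(manifest$linker[i])
      inserts_out <- substr(bases, deco + 1L, nchar(bases))
      ids <- sprintf("%s_r%06d", smp, seq_len(n))
      gi_map <- stats::setNames(shares$gi, shares$sciname)
      read_rows[[smp]] <- data.frame(
        read_id = ids, sample_label = smp, bases = bases,
        qualities = strrep("I", nchar(bases)), stringsAsFactors = FALSE)
      truth_rows[[smp]] <- data.frame(
        read_id = ids, sample_label = smp, sciname = picks,
        gi = unname(gi_map[picks]), insert_length = nchar(inserts_out),
        insert = inserts_out, molecule_class = classes,
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, c(read_rows, list(make.row.names = FALSE)))
    truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
    list(reads = reads, truth = truth)
  })
}

random_evalue <- function(n, lo = 8, hi = 40) 10^-stats::runif(n, lo, hi)

#' Simulate homology-hit tables from a truth map
#'
#' Emits per-sample tables in the 11-field tabular layout
#' (`qseqid sacc sgi length sstart send pident evalue staxid sskingdom
#' ssciname`), comma-separated and headerless when written. For each read
#' that returns hits, the true taxon's row passes the curation thresholds by
#' construction (`pident >= true_pident_floor`, `evalue <=
#' true_evalue_ceiling`); planted decoys comprise sub-threshold noise rows,
#' duplicate-GI rows with strictly worse e-values, and (for contaminant
#' taxa) rows whose GI also appears in the emitted control table. At most 20
#' rows are emitted per read.
#'
#' @param truth Truth map from [simulate_reads()].
#' @param spec The generating [community_spec()].
#' @param no_hit_rate Fraction of reads returning no hits at all
#'   (default 0.33, the rate observed in deep ice-core surveys).
#' @param true_pident_floor,true_evalue_ceiling Quality of the true row.
#' @param dup_gi_rate Probability a read also gets 1-2 duplicate rows for the
#'   true GI at worse e-value.
#' @param noise_rate Probability a read also gets 1-3 sub-threshold decoy
#'   rows (pident < 97 or evalue >= 1e-6).
#' @param control_label Sample label of the negative control in `truth`.
#' @param min_len Only reads whose insert is at least this long are treated
#'   as searched (default 50, mirroring the demultiplexer's length filter so
#'   per-sample searched counts line up with demux retained counts).
#' @return A list with `samples` (named list of hit data frames) and
#'   `control` (hit data frame); `attr(, "searched")` holds the per-sample
#'   number of reads searched.
#' @export
simulate_hit_table <- function(truth, spec, no_hit_rate = 0.33,
                               true_pident_floor = 97.5,
                               true_evalue_ceiling = 1e-8,
                               dup_gi_rate = 0.3, noise_rate = 0.4,
                               control_label = "control", min_len = 50L) {
  assert_that(nrow(truth) > 0, "truth map is empty")
  assert_that(no_hit_rate >= 0 && no_hit_rate < 1, "no_hit_rate must lie in [0, 1)")
  truth <- truth[truth$insert_length >= min_len, , drop = FALSE]
  assert_that(nrow(truth) > 0, "no reads pass the length filter")
  tab <- spec_table(spec)
  tax <- stats::setNames(split(tab, seq_len(nrow(tab))), tab$sciname)

  with_seed(derive_seed(spec$seed, 2L), {
    make_rows <- function(tr, is_control) {
      n <- nrow(tr)
      if (n == 0L) return(empty_hit_frame())
      drop <- if (is_control) rep(FALSE, n) else stats::runif(n) < no_hit_rate
      rows <- vector("list", n)
      for (j in seq_len(n)) {
        if (drop[j]) next
        tx <- tax[[tr$sciname[j]]]
        len <- tr$insert_length[j]
        # the subject accession encodes the molecule class so that the
        # accession -> class reference map (molecule_metadata) is consistent
        acc <- paste0("ACC", tx$gi, "_", tr$molecule_class[j])
        true_row <- data.frame(
          qseqid = tr$read_id[j], sacc = acc, sgi = tx$gi,
          length = len, sstart = 1L, send = len,
          pident = round(stats::runif(1, true_pident_floor, 100), 2),
          evalue = 10^-stats::runif(1, -log10(true_evalue_ceiling), 40),
          staxid = tx$taxid, sskingdom = tx$domain, ssciname = tx$sciname,
          stringsAsFactors = FALSE)
        extra <- list()
        if (stats::runif(1) < dup_gi_rate) {
          k <- sample(1:2, 1L)
          extra$dup <- data.frame(
            qseqid = tr$read_id[j], sacc = acc, sgi = tx$gi,
            length = pmax(30L, len - sample(0:20, k, replace = TRUE)),
            sstart = 1L, send = len,
            pident = round(pmin(true_row$pident,
                                stats::runif(k, 97, true_row$pident)), 2),
            evalue = true_row$evalue * 10^stats::runif(k, 1, 6),
            staxid = tx$taxid, sskingdom = tx$domain, ssciname = tx$sciname,
            stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < noise_rate) {
          k <- sample(1:3, 1L)
          sub_ident <- stats::runif(k) < 0.5
          extra$noise <- data.frame(
            qseqid = tr$read_id[j],
            sacc = paste0("DEC", 9e6 + sample.int(1e4, k)),
            sgi = as.integer(9e6 + sample.int(1e4, k)),
            length = pmax(30L, len - sample(0:30, k, replace = TRUE)),
            sstart = 1L, send = len,
            pident = round(ifelse(sub_ident, stats::runif(k, 80, 96.9),
                                  stats::runif(k, 97, 100)), 2),
            evalue = ifelse(sub_ident, random_evalue(k, 2, 20),
                            10^-stats::runif(k, 0, 5.9)),
            staxid = as.integer(8e6 + sample.int(1e4, k)),
            sskingdom = "Bacteria",
            ssciname = paste0("Decoy organism ", sample.int(1e4, k)),
            stringsAsFactors = FALSE)
        }
        rows[[j]] <- do.call(rbind, c(list(true_row), unname(extra),
                                      list(make.row.names = FALSE)))
        if (nrow(rows[[j]]) > 20L) rows[[j]] <- rows[[j]][1:20, ]
      }
      out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                              list(make.row.names = FALSE)))
      if (is.null(out)) empty_hit_frame() else out
    }

    labs <- unique(truth$sample_label)
    sample_labs <- setdiff(labs, control_label)
    samples <- lapply(sample_labs, function(s) {
      make_rows(truth[truth$sample_label == s, , drop = FALSE], FALSE)
    })
    names(samples) <- sample_labs
    ctrl_truth <- truth[truth$sample_label == control_label, , drop = FALSE]
    control <- make_rows(ctrl_truth, TRUE)
    searched <- vapply(labs, function(s) sum(truth$sample_label == s), integer(1))
    structure(list(samples = samples, control = control),
              searched = searched)
  })
}

#' Accession-to-molecule-class reference map for a synthetic community
#'
#' Synthetic subject accessions take the form `ACC<gi>_<class>`; this map
#' drives [classify_molecule()] for simulated runs (decoy accessions are
#' deliberately absent, exercising the `other` fallback).
#'
#' @param spec A [community_spec()].
#' @return Data frame with columns `sacc` and `molecule_class`.
#' @export
molecule_metadata <- function(spec) {
  gis <- vapply(spec$taxa, `[[`, integer(1), "gi")
  classes <- c("rRNA", "mRNA", "other")
  data.frame(sacc = paste0("ACC", rep(gis, each = 3L), "_", classes),
             molecule_class = rep(classes, length(gis)),
             stringsAsFactors = FALSE)
}

empty_hit_frame <- function() {
  data.frame(qseqid = character(), sacc = character(), sgi = integer(),
             length = integer(), sstart = integer(), send = integer(),
             pident = numeric(), evalue = numeric(), staxid = integer(),
             sskingdom = character(), ssciname = character(),
             stringsAsFactors = FALSE)
}

#' Generate a declarative trait table for a synthetic community
#'
#' Each taxon receives habitat sources, physiologies, a trophic mode and
#' metabolic processes, drawn independently with the given inclusion
#' probabilities; a taxon-spec-level `traits` entry overrides the draw.
#' Ambiguous entries (which downstream tallies must skip) carry empty source
#' and physiology sets.
#'
#' @param spec A [community_spec()].
#' @param source_probs Named inclusion probabilities over [habitat_sources()]
#'   (unnamed scalar = shared probability).
#' @param physiology_probs As above, over [physiology_categories()].
#' @param process_probs As above, over [metabolic_processes()].
#' @param p_ambiguous Probability a taxon's literature evidence is ambiguous.
#' @return A trait table data frame (see [read_trait_table()] for the schema).
#' @export
simulate_trait_table <- function(spec, source_probs = 0.3,
                                 physiology_probs = 0.25,
                                 process_probs = 0.08,
                                 p_ambiguous = 0.1) {
  expand_probs <- function(p, vocab) {
    if (is.null(names(p))) return(stats::setNames(rep(p[1], length(vocab)), vocab))
    out <- stats::setNames(rep(0, length(vocab)), vocab)
    out[names(p)] <- p
    out
  }
  sp <- expand_probs(source_probs, habitat_sources())
  pp <- expand_probs(physiology_probs, physiology_categories())
  prp <- expand_probs(process_probs, metabolic_processes())
  with_seed(derive_seed(spec$seed, 3L), {
    rows <- lapply(spec$taxa, function(tx) {
      if (!is.null(tx$traits)) return(tx$traits)
      amb <- stats::runif(1) < p_ambiguous
      src <- if (amb) character() else names(sp)[stats::runif(length(sp)) < sp]
      phy <- if (amb) character() else names(pp)[stats::runif(length(pp)) < pp]
      prc <- names(prp)[stats::runif(length(prp)) < prp]
      data.frame(ssciname = tx$sciname, domain = tx$domain, phylum = tx$phylum,
                 sources = paste(src, collapse = ","),
                 physiologies = paste(phy, collapse = ","),
                 trophic = sample(trophic_modes(), 1L),
                 processes = paste(prc, collapse = ","),
                 evidence = "synthetic", ambiguous = amb,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulate a count-geochemistry association dataset
#'
#' Draws species counts from a negative-binomial mixed model: covariates
#' uniform on the printed ice-core concentration ranges, habitat random
#' intercepts `u ~ N(0, sigma_u^2)`, and `log mu = intercept +
#' sum(beta_i * z_i) + u_habitat` where `z_i` are the z-scored covariates
#' (so the betas are effect sizes per covariate standard deviation). Counts
#' are NB2: `Var = mu + mu^2 / dispersion`.
#'
#' @param betas Named numeric vector of standardized fixed effects; names
#'   must be covariate names from [geochem_covariates()]. Unnamed covariates
#'   get beta 0.
#' @param dispersion NB2 dispersion `theta` (> 0).
#' @param n_habitats Number of habitat levels (2-6 uses the canonical names).
#' @param n_obs Number of rows (>= n_habitats).
#' @param sigma_u Random-intercept standard deviation (>= 0).
#' @param intercept Fixed intercept on the log scale.
#' @param seed Integer seed.
#' @return A data frame (`habitat`, `depth_label`, `species_count`, one
#'   column per covariate) with the true parameters in `attr(, "truth")`.
#' @export
simulate_association_dataset <- function(betas = c(NPOC = 0), dispersion = 2,
                                         n_habitats = 6, n_obs = 600,
                                         sigma_u = 0, intercept = 2,
                                         seed = 1L) {
  assert_that(dispersion > 0, "dispersion must be > 0")
  assert_that(n_habitats >= 2, "n_habitats must be >= 2")
  assert_that(n_obs >= n_habitats, "n_obs must be >= n_habitats")
  assert_that(sigma_u >= 0, "sigma_u must be >= 0")
  covs <- geochem_covariates()
  unknown <- setdiff(names(betas), names(covs))
  if (length(unknown)) {
    stop_cryo(sprintf("unknown covariate(s) in betas: %s",
                      paste(unknown, collapse = ", ")))
  }
  beta <- stats::setNames(rep(0, length(covs)), names(covs))
  beta[names(betas)] <- betas
  habitats <- c("soil", "freshwater", "marine", "ice",
                "animal_associated", "plant_associated")
  hab_levels <- if (n_habitats <= 6) habitats[seq_len(n_habitats)] else
    paste0("habitat_", seq_len(n_habitats))
  with_seed(seed, {
    hab <- rep_len(hab_levels, n_obs)
    x <- vapply(covs, function(rg) stats::runif(n_obs, rg[1], rg[2]),
                numeric(n_obs))
    colnames(x) <- names(covs)
    z <- scale(x)
    u <- stats::setNames(stats::rnorm(n_habitats, 0, sigma_u), hab_levels)
    eta <- intercept + drop(z %*% beta) + u[hab]
    y <- stats::rnbinom(n_obs, size = dispersion, mu = exp(eta))
    out <- data.frame(habitat = hab,
                      depth_label = sprintf("d%04d", seq_len(n_obs)),
                      species_count = y, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(x))
    attr(out, "truth") <- list(betas = beta, dispersion = dispersion,
                               sigma_u = sigma_u, intercept = intercept,
                               random_intercepts = u)
    out
  })
}

#' Default geochemical covariate ranges
#'
#' Uniform sampling ranges for the synthetic association dataset, spanning
#' the concentration ranges reported for Lake Vostok accretion ice: major
#' ions in µmol/L, NPOC (non-purgeable organic carbon) and total amino acids
#' in mol/L. K+ is nearly constant in the ice (~1 µmol/L) and is jittered so
#' it remains a usable covariate.
#'
#' @return Named list of `(min, max)` pairs.
#' @export
geochem_covariates <- function() {
  list(Na  = c(4, 40), K = c(0.5, 1.5), Ca = c(1, 32), Mg = c(3, 30),
       Cl  = c(2, 30), SO4 = c(1, 32),
       NPOC = c(9e-7, 2e-6), AA = c(1e-8, 3e-7))
}

#' Build a realistic random community specification
#'
#' Convenience constructor emulating the study design: a multi-domain
#' community with lognormal relative abundances, a handful of planted
#' negative-control contaminants, and the default decoration grammar.
#'
#' @param n_taxa Number of taxa.
#' @param n_reads_per_sample Reads per sample.
#' @param n_contaminants Taxa flagged as control contaminants.
#' @param per_base_error_rate Substitution rate.
#' @param insert_length_range Insert range in bp.
#' @param seed Integer seed.
#' @return A [community_spec()].
#' @export
random_community <- function(n_taxa = 30L, n_reads_per_sample = 1000L,
                             n_contaminants = 3L, per_base_error_rate = 0,
                             insert_length_range = c(50L, 1000L), seed = 1L) {
  assert_that(n_contaminants <= n_taxa, "more contaminants than taxa")
  phyla_by_domain <- list(
    Bacteria = c("Betaproteobacteria", "Gammaproteobacteria",
                 "Alphaproteobacteria", "Actinobacteria", "Bacteroidetes",
                 "Firmicutes", "Cyanobacteria", "Planctomycetes", "Chlorobi"),
    Eukarya = c("Ascomycota", "Basidiomycota", "Chlorophyta"),
    Archaea = c("Archaea"))
  with_seed(seed, {
    ab <- stats::rlnorm(n_taxa)
    ab <- ab / sum(ab)
    domains <- sample(c("Bacteria", "Eukarya", "Archaea"), n_taxa,
                      replace = TRUE, prob = c(0.75, 0.23, 0.02))
    taxa <- lapply(seq_len(n_taxa), function(i) {
      mix <- stats::runif(3)
      mix <- mix / sum(mix)
      taxon_spec(
        sciname = sprintf("Synthetica taxon%03d", i),
        gi = 100000L + i, taxid = 500000L + i,
        domain = domains[i],
        phylum = sample(phyla_by_domain[[domains[i]]], 1L),
        abundance = ab[i],
        molecule_class_mix = c(rRNA = mix[1], mRNA = mix[2], other = mix[3]),
        reference_length = 4000L)
    })
    # contaminants are the most abundant taxa: control contamination in real
    # surveys comes from dominant reagent/lab organisms, and a contaminant
    # that never reaches the samples would be unobservable by construction
    top <- order(ab, decreasing = TRUE)[seq_len(n_contaminants)]
    contam <- vapply(taxa[top], `[[`, character(1), "sciname")
    community_spec(taxa, n_reads_per_sample = n_reads_per_sample,
                   insert_length_range = insert_length_range,
                   per_base_error_rate = per_base_error_rate,
                   contaminant_taxa = contam, seed = seed)
  })
}
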