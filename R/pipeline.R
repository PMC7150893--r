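#' Write a complete synthetic run to disk
#'
#' Materializes every input the pipeline consumes — multiplexed FASTQ,
#' per-sample and control hit tables (11-field comma-separated), the MID
#' manifest, trait table, molecule-class metadata, truth map and a seeded
#' depth-indexed geochemistry table — for a given community specification.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [community_spec()].
#' @param manifest A [mid_manifest()].
#' @param control_label Negative-control sample label.
#' @param no_hit_rate Passed to [simulate_hit_table()].
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   truth map (`truth_map`) and `spec`.
#' @export
write_synthetic_run <- function(dir, spec = random_community(),
                                manifest = vostok_mid_manifest(),
                                control_label = "control",
                                no_hit_rate = 0.33) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_reads(spec, manifest, control_label = control_label)
  hits <- simulate_hit_table(sim$truth, spec, no_hit_rate = no_hit_rate,
                             control_label = control_label)
  paths <- list(reads = file.path(dir, "reads.fastq"),
                manifest = file.path(dir, "manifest.tsv"),
                control = file.path(dir, "control_hits.csv"),
                traits = file.path(dir, "traits.tsv"),
                molecule = file.path(dir, "molecule_classes.tsv"),
                truth = file.path(dir, "truth.tsv"),
                geochem = file.path(dir, "geochem.tsv"))
  write_fastq(sim$reads, paths$reads)
  write_mid_manifest(manifest, paths$manifest)
  paths$hits <- list()
  for (s in names(hits$samples)) {
    p <- file.path(dir, sprintf("hits_%s.csv", s))
    write_hit_table(hits$samples[[s]], p)
    paths$hits[[s]] <- p
  }
  write_hit_table(hits$control, paths$control)
  write_trait_table(simulate_trait_table(spec), paths$traits)
  utils::write.table(molecule_metadata(spec), paths$molecule, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  covs <- geochem_covariates()
  depths <- setdiff(manifest$sample_label, control_label)
  geo <- with_seed(derive_seed(spec$seed, 4L), {
    g <- data.frame(depth_label = depths, stringsAsFactors = FALSE)
    for (cv in names(covs)) {
      g[[cv]] <- stats::runif(length(depths), covs[[cv]][1], covs[[cv]][2])
    }
    g
  })
  utils::write.table(geo, paths$geochem, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(truth_map = sim$truth, spec = spec)))
}

default_pipeline_params <- function() {
  list(min_len = 50L, min_pident = 97.0, max_evalue = 1e-6,
       max_mismatch = 0L, search_window = 45L, log_base = "e",
       alpha = 0.05, control_label = "control",
       association_covariates = c("Na", "NPOC"))
}

#' Run the full curation pipeline from a config
#'
#' Executes demultiplexing -> hit curation -> trait annotation ->
#' diversity/overlap -> count association in order, writing per-stage
#' outputs and a machine-readable run manifest (parameters, input digests,
#' per-stage record counts) to the output directory. Identical config and
#' inputs produce byte-identical outputs: nothing time- or
#' environment-dependent is written.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   `out_dir`; `inputs` (paths: `reads`, `manifest`, `hits` (named list or
#'   vector per sample), `control`, `traits`, `molecule`, `geochem`);
#'   optional `params` overriding the curation defaults (`min_len` 50,
#'   `min_pident` 97, `max_evalue` 1e-6, `max_mismatch` 0, `log_base` `"e"`
#'   (or a number), `alpha` 0.05); optional `stages` logical toggles
#'   (`demux`, `curate`, `annotate`, `diversity`, `associate`).
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop_cryo("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  stages <- utils::modifyList(list(demux = TRUE, curate = TRUE,
                                   annotate = TRUE, diversity = TRUE,
                                   associate = TRUE),
                              config$stages %||% list())
  inputs <- config$inputs %||% list()
  manifest_run <- list(package_version = as.character(utils::packageVersion("cryocurate")),
                       parameters = params[order(names(params))],
                       stages = stages, counts = list(), inputs = list())
  for (nm in names(inputs)) {
    ps <- unlist(inputs[[nm]], use.names = TRUE)
    ex <- file.exists(ps)
    if (any(ex)) {
      manifest_run$inputs[[nm]] <- as.list(unname(tools::md5sum(ps[ex])))
    }
  }
  stage_failed <- function(stage, err) {
    stop_cryo(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                      stage, conditionMessage(err), out_dir))
  }

  demux_res <- NULL
  if (isTRUE(stages$demux)) {
    tryCatch({
      mani <- if (!is.null(inputs$manifest)) read_mid_manifest(inputs$manifest)
              else vostok_mid_manifest()
      demux_res <- demultiplex(inputs$reads, mani, min_len = params$min_len,
                               max_mismatch = params$max_mismatch,
                               search_window = params$search_window)
      for (s in names(demux_res$samples)) {
        write_fasta(demux_res$samples[[s]],
                    file.path(out_dir, sprintf("demux_%s.fasta", s)))
      }
      utils::write.table(demux_res$report,
                         file.path(out_dir, "demux_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest_run$counts$demux <- list(
        input = demux_res$n_input,
        unassigned = nrow(demux_res$unassigned),
        retained = sum(demux_res$report$retained))
    }, error = function(e) stage_failed("demux", e))
  }

  profiles <- NULL
  if (isTRUE(stages$curate)) {
    tryCatch({
      control <- if (!is.null(inputs$control)) parse_hit_table(inputs$control)
                 else empty_hit_frame()
      meta <- if (!is.null(inputs$molecule)) {
        utils::read.delim(inputs$molecule, stringsAsFactors = FALSE)
      } else NULL
      searched <- if (!is.null(demux_res)) {
        stats::setNames(demux_res$report$retained, demux_res$report$sample)
      } else NULL
      profiles <- list()
      for (s in names(inputs$hits)) {
        hits <- parse_hit_table(inputs$hits[[s]])
        profiles[[s]] <- curate_profile(
          hits, control, sample_label = s,
          min_pident = params$min_pident, max_evalue = params$max_evalue,
          reference_metadata = meta,
          n_reads_searched = if (!is.null(searched)) searched[[s]] else NULL)
        write_curated_profile(profiles[[s]],
                              file.path(out_dir, sprintf("profile_%s.tsv", s)))
      }
      manifest_run$counts$curate <- list(
        samples = length(profiles),
        unique_taxa = vapply(profiles, nrow, integer(1)),
        reads = vapply(profiles, function(p) sum(p$read_count), integer(1)),
        removed_gis = vapply(profiles, function(p) nrow(attr(p, "removed")),
                             integer(1)),
        no_hit_fraction = vapply(profiles,
                                 function(p) attr(p, "no_hit_fraction"),
                                 numeric(1)))
    }, error = function(e) stage_failed("curate", e))
  }

  annotated <- NULL
  summaries <- NULL
  if (isTRUE(stages$annotate) && !is.null(profiles)) {
    tryCatch({
      traits <- read_trait_table(inputs$traits)
      annotated <- lapply(profiles, annotate_profile, traits = traits)
      summaries <- summarize_categories(annotated)
      utils::write.table(summaries,
                         file.path(out_dir, "category_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest_run$counts$annotate <- list(
        annotated_taxa = vapply(annotated, function(p) sum(p$annotated),
                                integer(1)))
    }, error = function(e) stage_failed("annotate", e))
  }

  if (isTRUE(stages$diversity) && !is.null(profiles)) {
    tryCatch({
      nonempty <- profiles[vapply(profiles, nrow, integer(1)) > 0]
      base <- if (identical(params$log_base, "e")) exp(1) else
        as.numeric(params$log_base)
      div <- diversity_table(nonempty, base = base)
      utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(nonempty) >= 2L) {
        ov <- taxon_overlap(lapply(nonempty, `[[`, "sacc"))
        jsonlite::write_json(
          list(unique = as.list(ov$unique), regions = ov$regions,
               shared = ov$shared, union_size = ov$union_size),
          file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
      }
      manifest_run$counts$diversity <- list(samples = nrow(div))
    }, error = function(e) stage_failed("diversity", e))
  }

  if (isTRUE(stages$associate) && !is.null(summaries)) {
    tryCatch({
      geochem <- utils::read.delim(inputs$geochem, stringsAsFactors = FALSE)
      assoc_data <- prepare_association_table(summaries, geochem)
      fit <- fit_count_association(assoc_data,
                                   covariates = params$association_covariates,
                                   alpha = params$alpha)
      res <- if (fit$converged) {
        list(converged = TRUE, coefficients = fit$coefficients,
             dispersion = fit$dispersion, sigma_u = fit$sigma_u,
             n_obs = fit$n_obs)
      } else list(converged = FALSE, diagnostics = fit$diagnostics)
      jsonlite::write_json(res, file.path(out_dir, "association.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest_run$counts$associate <- list(rows = nrow(assoc_data),
                                            converged = fit$converged)
    }, error = function(e) stage_failed("associate", e))
  }

  jsonlite::write_json(manifest_run, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_run)
}
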