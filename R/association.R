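#' Fit the mixed-effects negative-binomial count-association model
#'
#' Models per-habitat species counts against geochemical covariates:
#' `count ~ NB2(mu, theta)` with `log mu = b0 + sum(b_i * z_i) + u_habitat`,
#' `u ~ N(0, sigma_u^2)`, where `z_i` are the z-scored covariates (ion
#' concentrations in µmol/L and organic measures in mol/L differ by orders
#' of magnitude, so standardization is applied internally and coefficients
#' are reported on both scales). The marginal likelihood is maximized by
#' Laplace approximation (via `glmmTMB`); Wald two-tailed p-values are
#' reported with a significance flag at `alpha`. Data with a single habitat
#' level fall back to a fixed-effects-only NB regression (`MASS::glm.nb`)
#' with a warning. Non-convergence is an explicit failure status, never
#' silent coefficients.
#'
#' @param data Data frame with columns `species_count`, `habitat` and the
#'   covariates (see [simulate_association_dataset()] /
#'   [prepare_association_table()]).
#' @param covariates Character vector of covariate column names (default:
#'   all of [geochem_covariates()] present in `data`).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return An object of class `cryo_nb_fit`: list with `coefficients` (data
#'   frame: `term`, `estimate` (standardized), `estimate_raw` (per original
#'   unit), `std_error`, `z`, `p_value`, `significant`), `intercept`,
#'   `dispersion` (NB2 theta), `sigma_u`, `n_obs`, `n_habitats`,
#'   `converged`, `mixed` (logical: random intercept used), `alpha`,
#'   `model` (the underlying fit).
#' @export
fit_count_association <- function(data, covariates = NULL, alpha = 0.05) {
  assert_that(all(c("species_count", "habitat") %in% names(data)),
              "data must have species_count and habitat columns")
  assert_that(all(data$species_count >= 0), "species counts must be nonnegative")
  covariates <- covariates %||%
    intersect(names(geochem_covariates()), names(data))
  assert_that(length(covariates) >= 1, "at least one covariate is required")
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    stop_cryo(sprintf("covariate(s) absent from data: %s",
                      paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[, covariates, drop = FALSE])
  assert_that(all(is.finite(x)), "covariates must be finite")
  sds <- apply(x, 2L, stats::sd)
  const <- covariates[sds == 0 | is.na(sds)]
  if (length(const)) {
    stop_cryo(sprintf("covariate(s) constant across all rows: %s",
                      paste(const, collapse = ", ")))
  }
  z <- scale(x)
  df <- data.frame(species_count = data$species_count,
                   habitat = factor(data$habitat))
  df <- cbind(df, as.data.frame(z))
  n_hab <- nlevels(df$habitat)
  rhs <- paste(covariates, collapse = " + ")
  mixed <- n_hab >= 2L
  if (!mixed) {
    warning("single habitat level: falling back to fixed-effects-only NB regression",
            call. = FALSE)
    fit <- MASS::glm.nb(stats::as.formula(paste("species_count ~", rhs)),
                        data = df)
    co <- summary(fit)$coefficients
    est <- co[covariates, "Estimate"]
    se <- co[covariates, "Std. Error"]
    pz <- co[covariates, "z value"]
    pv <- co[covariates, "Pr(>|z|)"]
    b0 <- co["(Intercept)", "Estimate"]
    theta <- fit$theta
    sigma_u <- 0
    converged <- isTRUE(fit$converged)
  } else {
    form <- stats::as.formula(paste("species_count ~", rhs, "+ (1 | habitat)"))
    diag_msgs <- character()
    fit <- withCallingHandlers(
      glmmTMB::glmmTMB(form, data = df, family = glmmTMB::nbinom2()),
      warning = function(w) {
        diag_msgs <<- c(diag_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    converged <- isTRUE(fit$sdr$pdHess) &&
      (is.null(fit$fit$convergence) || fit$fit$convergence == 0)
    if (!converged) {
      return(structure(list(coefficients = NULL, converged = FALSE,
                            mixed = TRUE, n_obs = nrow(df),
                            n_habitats = n_hab, alpha = alpha, model = fit,
                            diagnostics = paste(
                              c(fit$fit$message, diag_msgs), collapse = "; ")),
                       class = "cryo_nb_fit"))
    }
    co <- summary(fit)$coefficients$cond
    est <- co[covariates, "Estimate"]
    se <- co[covariates, "Std. Error"]
    pz <- co[covariates, "z value"]
    pv <- co[covariates, "Pr(>|z|)"]
    b0 <- co["(Intercept)", "Estimate"]
    theta <- glmmTMB::sigma(fit)
    vc <- glmmTMB::VarCorr(fit)$cond$habitat
    sigma_u <- sqrt(as.numeric(vc[1L, 1L]))
  }
  coefs <- data.frame(term = covariates,
                      estimate = unname(est),
                      estimate_raw = unname(est / sds[covariates]),
                      std_error = unname(se),
                      z = unname(pz),
                      p_value = unname(pv),
                      significant = unname(pv < alpha),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, intercept = unname(b0),
                 dispersion = theta, sigma_u = sigma_u,
                 n_obs = nrow(df), n_habitats = n_hab,
                 converged = converged, mixed = mixed, alpha = alpha,
                 model = fit),
            class = "cryo_nb_fit")
}

#' @export
print.cryo_nb_fit <- function(x, ...) {
  if (!x$converged) {
    cat("cryo_nb_fit: DID NOT CONVERGE\n")
    cat("  diagnostics:", x$diagnostics %||% "unknown", "\n")
    return(invisible(x))
  }
  cat(sprintf("%s negative-binomial count model: %d obs, %d habitat(s)\n",
              if (x$mixed) "Mixed-effects" else "Fixed-effects",
              x$n_obs, x$n_habitats))
  cat(sprintf("  dispersion (theta) = %.3f, sigma_u = %.4f, alpha = %g (2-tailed)\n",
              x$dispersion, x$sigma_u, x$alpha))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.cryo_nb_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.cryo_nb_fit <- function(object, standardized = TRUE, ...) {
  if (!object$converged) stop_cryo("model did not converge; no coefficients")
  stats::setNames(if (standardized) object$coefficients$estimate
                  else object$coefficients$estimate_raw,
                  object$coefficients$term)
}

#' Join category summaries with a depth-indexed geochemistry table
#'
#' Builds the association analysis table: one row per (habitat category x
#' depth), with `species_count` the unique-taxon tally of the habitat's
#' source category at that depth and the geochemical covariates joined by
#' `depth_label`. Depths present in only one of the two inputs are dropped
#' with a warning.
#'
#' @param summaries A [summarize_categories()] result whose `sample` labels
#'   are depth labels.
#' @param geochem Data frame with `depth_label` plus covariate columns.
#' @return A data frame ready for [fit_count_association()].
#' @export
prepare_association_table <- function(summaries, geochem) {
  assert_that(nrow(geochem) > 0, "geochemistry table is empty")
  assert_that("depth_label" %in% names(geochem),
              "geochemistry table needs a depth_label column")
  src <- summaries[summaries$type == "sources", , drop = FALSE]
  habitat_of <- c(soil_sediment = "soil", aquatic_freshwater = "freshwater",
                  marine = "marine", permafrost_ice = "ice",
                  animal = "animal_associated", plant = "plant_associated")
  depths <- intersect(unique(src$sample), geochem$depth_label)
  if (!length(depths)) stop_cryo("no overlapping depth labels between summaries and geochemistry")
  dropped <- setdiff(union(unique(src$sample), geochem$depth_label), depths)
  if (length(dropped)) {
    warning(sprintf("unmatched depth(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  src <- src[src$sample %in% depths, , drop = FALSE]
  out <- data.frame(habitat = unname(habitat_of[src$category]),
                    depth_label = src$sample,
                    species_count = src$count,
                    stringsAsFactors = FALSE)
  gidx <- match(out$depth_label, geochem$depth_label)
  covs <- setdiff(names(geochem), "depth_label")
  for (cv in covs) out[[cv]] <- geochem[[cv]][gidx]
  rownames(out) <- NULL
  out
}
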