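#' Fixed-effect design rows for prediction
#'
#' Builds the fixed model-matrix rows for new data on the scale the fit was
#' made, keeping only the columns the fit estimated (rank-deficient columns
#' the optimizer dropped are removed on both sides).
#'
#' @keywords internal
fixed_design_rows <- function(fit, newdata) {
  fixed <- if (length(fit$spec$fixed_terms) == 0) "1"
           else paste(fit$spec$fixed_terms, collapse = " + ")
  used <- unique(unlist(lapply(fit$spec$fixed_terms, term_vars)))
  xlev <- Filter(Negate(is.null), fit$xlevels[intersect(names(fit$xlevels), used)])
  for (v in names(xlev)) newdata[[v]] <- factor(newdata[[v]], levels = xlev[[v]])
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), newdata,
                           xlev = xlev)
  X[, fit$coefficients$term, drop = FALSE]
}

#' Land-use effects relative to primary forest
#'
#' For each taxonomic group and land use, the difference in the fixed
#' linear predictor (logit scale for occurrence, natural-log scale for
#' abundance) between that land use and primary forest, with the other
#' covariates at their reference (standardized zero) values.  The SE comes
#' from the coefficient covariance through the contrast vector,
#' `sqrt(c' Sigma c)`.
#'
#' @param fit a `hurdle_fit` whose spec includes `land_use` terms.
#' @param baseline reference land use (default `"primary forest"`).
#' @return data.frame: `group`, `land_use`, `delta`, `se` (0/0 for the
#'   baseline itself; `NA` when the contrast is inestimable).
#' @export
relative_effects <- function(fit, baseline = "primary forest") {
  if (!any(grepl("land_use", fit$spec$fixed_terms)))
    warning("fit retains no land_use terms; relative effects are all zero")
  groups <- fit$xlevels$group
  lus <- fit$xlevels$land_use
  grid <- expand.grid(group = groups, land_use = lus,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in c("hpd", "forest_cover", "indvi"))
    grid[[v]] <- 0
  if (!is.null(fit$xlevels$trait)) grid$trait <- fit$xlevels$trait[1]
  X <- fixed_design_rows(fit, grid)
  beta <- fit$coefficients$estimate
  out <- grid[, c("group", "land_use")]
  out$delta <- NA_real_
  out$se <- NA_real_
  for (g in groups) {
    ref <- which(out$group == g & out$land_use == baseline)
    for (l in lus) {
      row <- which(out$group == g & out$land_use == l)
      cvec <- X[row, ] - X[ref, ]
      out$delta[row] <- sum(cvec * beta)
      out$se[row] <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    }
  }
  out
}

#' Community-abundance index: occurrence x abundance relative to primary forest
#'
#' A crude measure of total community abundance: the product of the
#' relative probability of occurrence and the relative abundance of
#' persisting species,
#' `invlogit(b0 + delta_occ) / invlogit(b0) * exp(delta_abund)`, where `b0`
#' is the occurrence model's reference intercept (random effects at zero,
#' covariates at reference).  Equals 1 for primary forest by construction.
#'
#' @param rel_occ,rel_abund outputs of [relative_effects()] for the two
#'   stages.
#' @param ref_intercept the occurrence model's fixed intercept on the logit
#'   scale.
#' @return data.frame: `group`, `land_use`, `value`.
#' @export
community_index <- function(rel_occ, rel_abund, ref_intercept) {
  key_o <- paste(rel_occ$group, rel_occ$land_use, sep = "\r")
  key_a <- paste(rel_abund$group, rel_abund$land_use, sep = "\r")
  m <- match(key_o, key_a)
  if (anyNA(m)) {
    warning("dropping ", sum(is.na(m)), " group x land-use pairs missing from the abundance stage")
  }
  keep <- !is.na(m)
  out <- rel_occ[keep, c("group", "land_use")]
  d_occ <- rel_occ$delta[keep]
  d_ab <- rel_abund$delta[m[keep]]
  out$value <- stats::plogis(ref_intercept + d_occ) /
    stats::plogis(ref_intercept) * exp(d_ab)
  out
}

#' Predicted response over a pressure grid
#'
#' Inverse-link predictions (probability of occurrence, or abundance on
#' the natural scale) over a grid of one or two continuous pressures, with
#' the non-plotted covariates at their data medians and land use at primary
#' forest.  Grid values beyond the observed covariate range are refused
#' unless `force = TRUE`.
#'
#' @param fit a `hurdle_fit`.
#' @param grid data.frame over one or two of `hpd`, `forest_cover`,
#'   `indvi` (standardized scale).
#' @param group taxonomic group to predict for.
#' @param data the model data (for observed ranges and medians).
#' @param force allow extrapolation.
#' @return `grid` with a `predicted` column.
#' @export
prediction_surface <- function(fit, grid, group, data, force = FALSE) {
  covars <- c("hpd", "forest_cover", "indvi")
  on_grid <- intersect(names(grid), covars)
  if (length(on_grid) < 1) stop("grid must vary at least one pressure")
  for (v in on_grid) {
    r <- range(data[[v]])
    if (!force && (min(grid[[v]]) < r[1] || max(grid[[v]]) > r[2]))
      stop(sprintf("grid extrapolates beyond the observed range of %s; use force = TRUE", v))
  }
  nd <- grid
  nd$group <- group
  nd$land_use <- "primary forest"
  for (v in setdiff(covars, on_grid)) nd[[v]] <- stats::median(data[[v]])
  if (!is.null(fit$xlevels$trait)) nd$trait <- fit$xlevels$trait[1]
  X <- fixed_design_rows(fit, nd)
  eta <- drop(X %*% fit$coefficients$estimate)
  grid$predicted <- if (fit$spec$response == "occurrence")
    stats::plogis(eta) else exp(eta)
  grid
}

#' Random-intercept variance components in decreasing order
#'
#' @param fit a `hurdle_fit`.
#' @return data.frame: `component`, `variance`, `rank` (1 = largest).
#' @export
variance_ordering <- function(fit) {
  vc <- fit$varcomps[setdiff(names(fit$varcomps), "resid")]
  out <- data.frame(component = names(vc), variance = unname(vc))
  out$rank <- rank(-out$variance, ties.method = "min")
  out[order(out$rank), ]
}

#' Run the full synthetic-analysis pipeline
#'
#' Simulates a dataset, computes pressures from the contaminated NDVI
#' series, preprocesses records (effort correction, occurrence
#' derivation, range classification, specialist flags), fits and
#' backward-selects both hurdle stages, runs the residual diagnostics
#' (Pagel's lambda on per-taxon residuals; per-study Moran's I with the
#' binomial meta-test and the refit-without-flagged-studies check), and
#' writes the derived summaries.
#'
#' @param config a [generator_config()].
#' @param outdir optional directory; when given, all result tables and a
#'   JSON run manifest are written there.
#' @param alpha backward-selection retention threshold.
#' @param full_terms starting fixed-term set (default [full_term_set()]).
#' @param nAGQ occurrence-model integration (see [fit_occurrence()]).
#' @return (invisibly when writing) a list with the dataset, fits, traces,
#'   diagnostics and summary tables.
#' @export
run_pipeline <- function(config = generator_config(), outdir = NULL,
                         alpha = 0.05, full_terms = full_term_set(),
                         nAGQ = 1) {
  dataset <- generate_dataset(config)

  pressures <- site_pressures(dataset$sites, dataset$ndvi_long)
  corrected <- correct_effort(dataset$records)
  occ <- derive_occurrence(corrected)
  taxa <- classify_range(dataset$points, dataset$taxa)
  taxa <- flag_specialists(taxa, dataset$habitat_table)

  occ_data <- build_model_data(occ, dataset$sites, pressures, taxa)
  pos <- corrected[corrected$value > 0, ]
  ab_data <- build_model_data(pos, dataset$sites, pressures, taxa)

  sel_occ <- backward_select(occ_data,
                             model_spec("occurrence", full_terms),
                             alpha = alpha, nAGQ = nAGQ)
  sel_ab <- backward_select(ab_data,
                            model_spec("log_abundance", full_terms),
                            alpha = alpha)

  term_table <- rbind(cbind(response = "occurrence", sel_occ$trace),
                      cbind(response = "abundance", sel_ab$trace))

  r2 <- rbind(
    data.frame(response = "occurrence",
               as.data.frame(r2_glmm(sel_occ$fit))),
    data.frame(response = "abundance",
               as.data.frame(r2_glmm(sel_ab$fit))))

  phylo <- lapply(list(occurrence = list(sel_occ$fit, occ_data),
                       abundance = list(sel_ab$fit, ab_data)),
                  function(x) {
    vals <- residuals_by_taxon(x[[1]], x[[2]])
    pagel_lambda(dataset$tree, vals)
  })

  moran <- list(
    occurrence = moran_by_study(sel_occ$fit, occ_data, dataset$sites),
    abundance = moran_by_study(sel_ab$fit, ab_data, dataset$sites))
  meta <- lapply(moran, autocorr_meta, alpha = alpha)
  flagged_occ <- moran$occurrence$study_id[
    !is.na(moran$occurrence$p) & moran$occurrence$p < alpha]
  refit_occ <- refit_excluding(occ_data, flagged_occ, sel_occ$fit$spec)

  rel_occ <- relative_effects(sel_occ$fit)
  rel_ab <- relative_effects(sel_ab$fit)
  b0 <- sel_occ$fit$coefficients$estimate[
    sel_occ$fit$coefficients$term == "(Intercept)"]
  index <- community_index(rel_occ, rel_ab, b0)

  res <- list(config = config, dataset = dataset, pressures = pressures,
              taxa = taxa, occ_data = occ_data, ab_data = ab_data,
              sel_occ = sel_occ, sel_ab = sel_ab,
              term_table = term_table, r2 = r2, phylo = phylo,
              moran = moran, autocorr_meta = meta,
              refit_occ = refit_occ,
              relative_effects = list(occurrence = rel_occ,
                                      abundance = rel_ab),
              community_index = index,
              variance_ordering = list(
                occurrence = variance_ordering(sel_occ$fit),
                abundance = variance_ordering(sel_ab$fit)))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.csv(x, file.path(outdir, f),
                                         row.names = FALSE)
    w(term_table, "model_terms.csv")
    w(rbind(cbind(response = "occurrence", sel_occ$fit$coefficients),
            cbind(response = "abundance", sel_ab$fit$coefficients)),
      "coefficients.csv")
    w(rbind(cbind(response = "occurrence",
                  variance_ordering(sel_occ$fit)),
            cbind(response = "abundance", variance_ordering(sel_ab$fit))),
      "varcomps.csv")
    w(r2, "r2.csv")
    w(rbind(cbind(response = "occurrence", moran$occurrence),
            cbind(response = "abundance", moran$abundance)),
      "moran_by_study.csv")
    w(rel_occ, "relative_effects_occurrence.csv")
    w(rel_ab, "relative_effects_abundance.csv")
    w(index, "community_index.csv")
    w(pressures, "pressures.csv")
    jsonlite::write_json(
      list(seed = config$seed, alpha = alpha,
           n_studies = config$n_studies,
           n_sites = nrow(dataset$sites),
           n_records = nrow(dataset$records),
           phylo_signal = phylo, autocorr_meta = meta,
           r_version = as.character(getRversion())),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
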