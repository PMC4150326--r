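#' Model specification for one hurdle stage
#'
#' A fixed-effect term list plus the random-intercept structure shared by
#' both hurdle stages (study, site nested in study, taxon).  Terms are R
#' interaction labels over the variables `land_use`, `group`, `hpd`,
#' `forest_cover`, `indvi` (and optionally a trait factor); marginality is
#' enforced at construction: every lower-order term implied by an
#' interaction must be listed.
#'
#' @param response `"occurrence"` or `"log_abundance"`.
#' @param fixed_terms character vector of term labels (e.g.
#'   `"land_use:group"`, `"hpd:forest_cover"`).
#' @param random character vector of random intercepts; default
#'   `c("study", "site", "taxon")`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response = c("occurrence", "log_abundance"),
                       fixed_terms,
                       random = c("study", "site", "taxon")) {
  response <- match.arg(response)
  fixed_terms <- unique(fixed_terms)
  for (t in fixed_terms) {
    v <- term_vars(t)
    if (length(v) > 1) {
      missing_mains <- setdiff(v, fixed_terms)
      if (length(missing_mains) > 0)
        stop(sprintf("marginality violated: '%s' requires main effect(s) %s",
                     t, paste(sQuote(missing_mains), collapse = ", ")))
    }
  }
  structure(list(response = response, fixed_terms = fixed_terms,
                 random = random),
            class = "model_spec")
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# does term `a` strictly contain term `b` (b's variables a proper subset)?
term_contains <- function(a, b) {
  va <- term_vars(a); vb <- term_vars(b)
  length(va) > length(vb) && all(vb %in% va)
}

#' The full fixed-effect term set considered for selection
#'
#' Land use crossed with taxonomic group, the three continuous pressures,
#' all pairwise interactions among them, their two-way interactions with
#' group, and the three-way interactions of continuous pairs with group.
#'
#' @param continuous names of the continuous pressures.
#' @return character vector of term labels (marginality-complete).
#' @export
full_term_set <- function(continuous = c("hpd", "forest_cover", "indvi")) {
  pairs <- utils::combn(continuous, 2, paste, collapse = ":")
  c("land_use", "group", "land_use:group",
    continuous,
    pairs,
    paste0(continuous, ":group"),
    paste0(pairs, ":group"))
}

#' Assemble model-ready data for the hurdle stages
#'
#' Joins occurrence (or positive-abundance) rows with site pressures and
#' taxon attributes, sets factor baselines (primary forest; invertebrates),
#' builds the site-in-study grouping factor, and centres/scales the
#' continuous pressures to unit SD (human population density is
#' log(x + 1)-transformed first by default).
#'
#' @param rows occurrence table (`present`) or corrected positive records
#'   (`value`), with `study_id`, `site_id`, `taxon_id`.
#' @param sites site table (`site_id`, `land_use`).
#' @param pressures pressure table (`site_id`, `forest_cover`, `hpd`,
#'   `indvi`).
#' @param taxa taxon table (`taxon_id`, `group`, optionally `specialist`,
#'   `range_class`).
#' @param log_hpd log-transform human population density before scaling.
#' @return data.frame with standardized covariates (scaling constants in
#'   `attr(, "scaling")`).
#' @export
build_model_data <- function(rows, sites, pressures, taxa, log_hpd = TRUE) {
  d <- rows
  ms <- match(d$site_id, sites$site_id)
  if (anyNA(ms)) stop("records reference unknown sites")
  d$land_use <- factor(sites$land_use[ms], levels = land_use_levels())
  if (anyNA(d$land_use)) stop("unseen land-use level in site table")
  d$lon <- sites$lon[ms]
  d$lat <- sites$lat[ms]
  mp <- match(d$site_id, pressures$site_id)
  if (anyNA(mp)) stop("sites missing from pressure table")
  mt <- match(d$taxon_id, taxa$taxon_id)
  if (anyNA(mt)) stop("records reference unknown taxa")
  d$group <- factor(taxa$group[mt], levels = group_levels())
  if (anyNA(d$group)) stop("unseen taxonomic group")
  for (col in c("specialist", "range_class"))
    if (col %in% names(taxa)) d[[col]] <- taxa[[col]][mt]
  d$site_in_study <- paste(d$study_id, d$site_id, sep = "/")

  raw <- list(hpd = if (log_hpd) log1p(pressures$hpd[mp]) else pressures$hpd[mp],
              forest_cover = pressures$forest_cover[mp],
              indvi = pressures$indvi[mp])
  scaling <- list()
  for (v in names(raw)) {
    mu <- mean(raw[[v]]); sdv <- stats::sd(raw[[v]])
    if (!is.finite(sdv) || sdv == 0)
      stop(sprintf("covariate '%s' has zero variance", v))
    d[[v]] <- (raw[[v]] - mu) / sdv
    scaling[[v]] <- c(center = mu, scale = sdv)
  }
  d <- droplevels(d)
  attr(d, "scaling") <- scaling
  d
}

land_use_levels <- function() {
  c("primary forest", "secondary vegetation", "wood plantation",
    "cropland", "pasture", "urban")
}
group_levels <- function() {
  c("invertebrates", "herptiles", "mammals", "birds")
}

spec_formula <- function(spec, random = spec$random) {
  lhs <- if (spec$response == "occurrence") "present" else "log_value"
  fixed <- if (length(spec$fixed_terms) == 0) "1"
           else paste(spec$fixed_terms, collapse = " + ")
  if (length(random) == 0)
    return(stats::as.formula(paste(lhs, "~", fixed)))
  rand <- c(study = "(1 | study_id)", site = "(1 | site_in_study)",
            taxon = "(1 | taxon_id)")[random]
  stats::as.formula(paste(lhs, "~", fixed, "+", paste(rand, collapse = " + ")))
}

# optimizer settings shared by all mixed-model fits; tight tolerances so
# independent implementations agree to ~1e-3 on fixed effects
glmer_control <- function() {
  lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE,
                     optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10,
                                    maxeval = 100000))
}
lmer_control <- function() {
  lme4::lmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
}

# a fit that wandered off (huge variance ratio or non-finite likelihood)
# is retried with bobyqa; the better likelihood wins
diverged <- function(model) {
  !inherits(model, "merMod") ||
    !is.finite(as.numeric(stats::logLik(model))) ||
    any(lme4::getME(model, "theta") > 10)
}

# random terms whose grouping factor actually varies in the data; a term
# collapsed to a single level drops out of the model
active_random <- function(spec, data) {
  cols <- c(study = "study_id", site = "site_in_study", taxon = "taxon_id")
  keep <- vapply(spec$random, function(r)
    length(unique(data[[cols[[r]]]])) >= 2, logical(1))
  spec$random[keep]
}

#' Fixed-effect design matrix and grouping indices for a spec
#'
#' Treatment-coded design matrix for the spec's fixed terms, plus integer
#' grouping indices for the random intercepts.
#'
#' @param data output of [build_model_data()].
#' @param spec a [model_spec()].
#' @return list with `X` (design matrix), `study`, `site`, `taxon`
#'   (integer indices).
#' @export
build_design <- function(data, spec) {
  fixed <- if (length(spec$fixed_terms) == 0) "1"
           else paste(spec$fixed_terms, collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), data)
  list(X = X,
       study = as.integer(factor(data$study_id)),
       site = as.integer(factor(data$site_in_study)),
       taxon = as.integer(factor(data$taxon_id)))
}

new_hurdle_fit <- function(model, spec, data, messages = character(0),
                           notes = character(0)) {
  if (inherits(model, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomps <- stats::setNames(vc$vcov, vc$grp)
    names(varcomps)[names(varcomps) == "study_id"] <- "study"
    names(varcomps)[names(varcomps) == "site_in_study"] <- "site"
    names(varcomps)[names(varcomps) == "taxon_id"] <- "taxon"
    names(varcomps)[names(varcomps) == "Residual"] <- "resid"
    beta <- lme4::fixef(model)
  } else {
    # degenerate fit without random effects (glm / lm)
    varcomps <- if (spec$response == "log_abundance")
      c(resid = sum(stats::residuals(model)^2) / stats::nobs(model))
    else stats::setNames(numeric(0), character(0))
    beta <- stats::coef(model)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  ll <- as.numeric(stats::logLik(model))
  df <- attr(stats::logLik(model), "df")
  structure(list(
    model = model, spec = spec,
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se)),
    vcov = as.matrix(stats::vcov(model)),
    varcomps = varcomps,
    logLik = ll, df = df, AIC = -2 * ll + 2 * df,
    n_obs = stats::nobs(model),
    xlevels = list(land_use = levels(data$land_use),
                   group = levels(data$group),
                   trait = if (is.factor(data$trait)) levels(data$trait)),
    converged = length(messages) == 0,
    messages = messages, notes = notes
  ), class = "hurdle_fit")
}

collect_fit <- function(expr) {
  msgs <- character(0)
  notes <- character(0)   # e.g. rank-deficiency column drops: expected, not a failure
  model <- withCallingHandlers(
    expr,
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  list(model = model, messages = msgs, notes = notes)
}

#' Fit the occurrence stage (binomial-logit GLMM)
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects and variance components via [lme4::glmer()].  Non-convergence is
#' flagged on the returned object, never silent.
#'
#' @param data output of [build_model_data()] with a binary `present`
#'   column.
#' @param spec a [model_spec()] with `response = "occurrence"`.
#' @param nAGQ Laplace (1, default) or faster PIRLS-only (0) integration.
#' @return a `hurdle_fit`.
#' @export
fit_occurrence <- function(data, spec, nAGQ = 1) {
  stopifnot(spec$response == "occurrence")
  if (!all(data$present %in% 0:1)) stop("'present' must be binary")
  rand <- active_random(spec, data)
  got <- if (length(rand) == 0) {
    # every grouping factor collapsed: plain logistic regression (IRLS)
    collect_fit(stats::glm(spec_formula(spec, rand), data = data,
                           family = stats::binomial))
  } else {
    g <- collect_fit(
      lme4::glmer(spec_formula(spec, rand), data = data,
                  family = stats::binomial, nAGQ = nAGQ,
                  control = glmer_control()))
    if (diverged(g$model)) {
      g2 <- collect_fit(
        lme4::glmer(spec_formula(spec, rand), data = data,
                    family = stats::binomial, nAGQ = nAGQ,
                    control = lme4::glmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE)))
      if (stats::logLik(g2$model) > stats::logLik(g$model)) {
        g2$notes <- c(g2$notes, "primary optimizer diverged; bobyqa refit used")
        g <- g2
      }
    }
    g
  }
  new_hurdle_fit(got$model, spec, data, got$messages, got$notes)
}

#' Fit the abundance stage (Gaussian LMM on log abundance)
#'
#' Fits natural-log (effort-corrected) abundance, restricted to presences,
#' by maximum likelihood (ML, not REML) so that likelihood-ratio tests and
#' AICs are comparable across fixed-effect structures.
#'
#' @param data output of [build_model_data()] on positive records; a
#'   `log_value` column is derived from `value` when absent.
#' @param spec a [model_spec()] with `response = "log_abundance"`.
#' @return a `hurdle_fit`.
#' @export
fit_abundance <- function(data, spec) {
  stopifnot(spec$response == "log_abundance")
  if (!"log_value" %in% names(data)) {
    if (any(data$value <= 0))
      stop("abundance stage received non-positive values; filter to presences first")
    data$log_value <- log(data$value)
  }
  rand <- active_random(spec, data)
  got <- if (length(rand) == 0) {
    collect_fit(stats::lm(spec_formula(spec, rand), data = data))
  } else {
    g <- collect_fit(
      lme4::lmer(spec_formula(spec, rand), data = data, REML = FALSE,
                 control = lmer_control()))
    if (diverged(g$model)) {
      g2 <- collect_fit(
        lme4::lmer(spec_formula(spec, rand), data = data, REML = FALSE,
                   control = lme4::lmerControl(optimizer = "bobyqa")))
      if (stats::logLik(g2$model) > stats::logLik(g$model)) {
        g2$notes <- c(g2$notes, "primary optimizer diverged; bobyqa refit used")
        g <- g2
      }
    }
    g
  }
  new_hurdle_fit(got$model, spec, data, got$messages, got$notes)
}

# dispatch on the spec's response
fit_hurdle_stage <- function(data, spec, ...) {
  if (spec$response == "occurrence") fit_occurrence(data, spec, ...)
  else fit_abundance(data, spec)
}

#' Likelihood-ratio test between nested hurdle fits
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` (clipped at 0) on the
#' difference in parameter counts, compared to the upper chi-squared tail.
#' Both fits must be ML fits of nested specs on the same data.
#'
#' @param full,reduced `hurdle_fit` objects.
#' @return data.frame with `term` (the dropped terms), `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  dropped <- setdiff(full$spec$fixed_terms, reduced$spec$fixed_terms)
  if (!all(reduced$spec$fixed_terms %in% full$spec$fixed_terms))
    stop("models are not nested")
  if (full$n_obs != reduced$n_obs)
    stop("fits use different data (n differs)")
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$df - reduced$df
  if (df < 0) stop("'full' has fewer parameters than 'reduced'")
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  data.frame(term = paste(dropped, collapse = " + "), chisq = chisq,
             df = df, p = p)
}

#' Backward stepwise selection with marginality-respecting LRTs
#'
#' Repeatedly tests only the currently highest-order droppable terms --
#' those contained in no retained term -- with likelihood-ratio tests, and
#' drops the least significant term with `p >= alpha` (ties broken towards
#' the smaller chi-squared per df).  Main effects are therefore only tested
#' once every interaction containing them is gone.  Stops when every
#' droppable term is significant.
#'
#' @param data output of [build_model_data()].
#' @param full_spec the starting [model_spec()] (marginality-complete).
#' @param alpha retention threshold (default 0.05).
#' @param always_keep terms never dropped (e.g. `"land_use"` to keep the
#'   design's backbone); default none.
#' @param nAGQ passed to [fit_occurrence()].
#' @return list with `fit` (minimum adequate model), `trace` (one row per
#'   term of the full spec: `term`, `chisq`, `df`, `p`, `dropped`; terms
#'   never exposed to a test have `NA` statistics, the table's "n.a."), and
#'   `n_fits`.
#' @export
backward_select <- function(data, full_spec, alpha = 0.05,
                            always_keep = character(0), nAGQ = 1) {
  cache <- new.env(parent = emptyenv())
  fit_terms <- function(terms) {
    key <- paste0("k:", paste(sort(terms), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    sp <- model_spec(full_spec$response, terms, full_spec$random)
    f <- if (full_spec$response == "occurrence")
      fit_occurrence(data, sp, nAGQ = nAGQ) else fit_abundance(data, sp)
    cache[[key]] <- f
    f
  }
  terms <- full_spec$fixed_terms
  current <- fit_terms(terms)
  n_fits <- 1L
  last_test <- list()   # term -> c(chisq, df, p)
  dropped <- character(0)

  repeat {
    droppable <- terms[!vapply(terms, function(t)
      any(vapply(terms, term_contains, logical(1), b = t)), logical(1))]
    droppable <- setdiff(droppable, always_keep)
    if (length(droppable) == 0) break
    tests <- lapply(droppable, function(t) {
      red <- fit_terms(setdiff(terms, t))
      n_fits <<- n_fits + 1L
      tt <- lrt(current, red)
      last_test[[t]] <<- c(chisq = tt$chisq, df = tt$df, p = tt$p)
      tt
    })
    p <- vapply(tests, function(x) x$p, numeric(1))
    if (all(p < alpha)) break
    cand <- which(p >= alpha)
    worst <- cand[order(-p[cand],
                        vapply(tests[cand], function(x) x$chisq / x$df,
                               numeric(1)))][1]
    drop_term <- droppable[worst]
    terms <- setdiff(terms, drop_term)
    dropped <- c(dropped, drop_term)
    current <- fit_terms(terms)
  }

  trace <- do.call(rbind, lapply(full_spec$fixed_terms, function(t) {
    lt <- last_test[[t]]
    data.frame(term = t,
               chisq = if (is.null(lt)) NA_real_ else unname(lt["chisq"]),
               df = if (is.null(lt)) NA_real_ else unname(lt["df"]),
               p = if (is.null(lt)) NA_real_ else unname(lt["p"]),
               dropped = t %in% dropped)
  }))
  list(fit = current, trace = trace, n_fits = n_fits)
}

#' Marginal and conditional R-squared from variance components
#'
#' `marginal = s2_f / total`, `conditional = (s2_f + sum(s2_re)) / total`
#' with `total = s2_f + sum(s2_re) + s2_resid + s2_dist`; the
#' distribution-specific variance `s2_dist` is `pi^2 / 3` for a
#' binomial-logit model and 0 for a Gaussian one (where `s2_resid` plays
#' that role).
#'
#' @param sigma2_f variance of the fixed-effect linear predictor.
#' @param sigma2_re numeric vector of random-intercept variances.
#' @param sigma2_resid residual variance (0 for binomial).
#' @param distribution `"gaussian"` or `"binomial"`.
#' @return list with `marginal` and `conditional`.
#' @export
r2_components <- function(sigma2_f, sigma2_re, sigma2_resid = 0,
                          distribution = c("gaussian", "binomial")) {
  distribution <- match.arg(distribution)
  s2d <- if (distribution == "binomial") pi^2 / 3 else 0
  total <- sigma2_f + sum(sigma2_re) + sigma2_resid + s2d
  list(marginal = sigma2_f / total,
       conditional = (sigma2_f + sum(sigma2_re)) / total)
}

#' R-squared for a fitted hurdle stage
#'
#' The fixed-effect variance is the variance of the fixed linear predictor
#' over the model data; random-intercept variances come from the fit.
#'
#' @param fit a `hurdle_fit`.
#' @return list with `marginal` and `conditional` in \[0, 1\].
#' @export
r2_glmm <- function(fit) {
  if (inherits(fit$model, "merMod")) {
    X <- lme4::getME(fit$model, "X")
    eta_f <- as.numeric(X %*% lme4::fixef(fit$model))
  } else {
    eta_f <- as.numeric(stats::model.matrix(fit$model) %*%
                          stats::coef(fit$model))
  }
  s2f <- stats::var(eta_f)
  vc <- fit$varcomps
  resid <- if ("resid" %in% names(vc)) vc[["resid"]] else 0
  re <- vc[setdiff(names(vc), "resid")]
  dist <- if (fit$spec$response == "occurrence") "binomial" else "gaussian"
  r2_components(s2f, re, resid, dist)
}

#' Post-hoc trait-interaction AIC scan
#'
#' Refines the taxonomic grouping by a trait (habitat specialization --
#' birds and mammals split into specialists and generalists -- or range
#' class, all groups split), then adds the trait interaction to each term
#' of the minimum adequate model in turn and reports the AIC change.
#' Negative `delta_aic` is an improvement.  Taxa whose trait is unknown
#' stay unsplit (mapped to the trait reference level).
#'
#' @param data model data carrying the trait column.
#' @param min_spec the minimum adequate [model_spec()].
#' @param trait `"specialist"` or `"range_class"`.
#' @param nAGQ passed to the occurrence fitter.
#' @return data.frame: `term`, `delta_aic`, `df_added`.
#' @export
posthoc_trait_scan <- function(data, min_spec,
                               trait = c("specialist", "range_class"),
                               nAGQ = 1) {
  trait <- match.arg(trait)
  tv <- data[[trait]]
  if (is.null(tv)) stop("data lacks trait column '", trait, "'")
  known <- if (trait == "specialist") tv %in% c("specialist", "generalist")
           else tv %in% c("narrow", "wide")
  if (!any(known)) {
    warning("trait '", trait, "' unknown for all taxa; nothing to scan")
    return(data.frame(term = character(0), delta_aic = numeric(0),
                      df_added = numeric(0)))
  }
  data$trait <- factor(ifelse(known, tv, "unsplit"),
                       levels = c("unsplit",
                                  sort(unique(tv[known]))))
  base <- fit_hurdle_stage(data, min_spec, nAGQ = nAGQ)
  out <- lapply(min_spec$fixed_terms, function(t) {
    terms2 <- c(min_spec$fixed_terms, "trait", paste0(t, ":trait"))
    sp2 <- model_spec(min_spec$response, terms2, min_spec$random)
    f2 <- fit_hurdle_stage(data, sp2, nAGQ = nAGQ)
    data.frame(term = t, delta_aic = f2$AIC - base$AIC,
               df_added = f2$df - base$df)
  })
  do.call(rbind, out)
}

#' Single-group occurrence model with a cubic polynomial pressure
#'
#' Occurrence GLMM for one taxonomic group with an orthogonal cubic
#' polynomial of one continuous pressure as the only fixed effects and the
#' usual random intercepts; used to resolve curvature (e.g. a U-shaped
#' response of herptiles to human population density) that the main models
#' cannot express.
#'
#' @param data model data restricted to a single group.
#' @param covariate name of the continuous pressure (default `"hpd"`).
#' @param nAGQ passed to [lme4::glmer()].
#' @return a `hurdle_fit` whose coefficients are the polynomial terms.
#' @export
fit_cubic_submodel <- function(data, covariate = "hpd", nAGQ = 1) {
  x <- data[[covariate]]
  if (length(unique(x)) < 4)
    stop("cubic polynomial needs >= 4 distinct values of ", covariate)
  data$poly_x <- x
  f <- stats::as.formula(paste(
    "present ~ poly(poly_x, 3) + (1 | study_id) + (1 | site_in_study) +",
    "(1 | taxon_id)"))
  got <- collect_fit(
    lme4::glmer(f, data = data, family = stats::binomial, nAGQ = nAGQ,
                control = glmer_control()))
  sp <- model_spec("occurrence", c("poly_x"))
  new_hurdle_fit(got$model, sp, data, got$messages, got$notes)
}
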