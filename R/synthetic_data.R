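#' Configuration for the synthetic multi-study generator
#'
#' Defaults emulate the structure of a tropical-forest multi-study
#' abundance compilation: ~20 studies of 20-40 spatially clustered sites
#' each (~600 sites), four taxonomic groups in the observed proportions
#' (invertebrates dominating, then birds, herptiles, mammals), the
#' six-class land-use vocabulary with primary forest most frequent, an
#' overall non-zero record fraction of about 26%, study > taxon > site
#' ordering of the random-intercept SDs, and MODIS-like 16-day NDVI
#' composites with both flagged and unflagged cloud contamination.
#'
#' Land-use offsets are on the logit scale (occurrence) and natural-log
#' scale (abundance), relative to primary forest (whose offsets are exactly
#' 0); continuous-pressure slopes act on internally standardized pressure
#' scores.  When `occ_intercept` is `NULL` it is calibrated at generation
#' time so the realized mean presence probability equals `target_nonzero`.
#'
#' @param n_studies number of studies.
#' @param sites_per_study integer range (min, max) of sites per study.
#' @param taxa_per_study integer range of taxa sampled per study.
#' @param pool_size total number of taxa across groups.
#' @param group_shares named proportions over the four groups (sum 1).
#' @param land_use_probs named proportions over the six land uses (sum 1).
#' @param true_occ_coefs,true_abund_coefs 4 x 6 matrices (group x land use)
#'   of offsets; the primary-forest column must be 0.
#' @param slopes_occ,slopes_abund named slopes on the standardized
#'   continuous pressures (`hpd`, `forest_cover`, `indvi`).
#' @param occ_intercept logit intercept; `NULL` = calibrate to
#'   `target_nonzero`.
#' @param target_nonzero target overall presence probability.
#' @param abund_intercept log-abundance intercept.
#' @param sd_study_occ,sd_site_occ,sd_taxon_occ random-intercept SDs,
#'   occurrence (logit scale).
#' @param sd_study_abund,sd_site_abund,sd_taxon_abund random-intercept SDs,
#'   abundance (log scale).
#' @param sigma_resid residual SD of log abundance.
#' @param lambda_true Pagel's lambda applied to the taxon random effects on
#'   the taxonomy tree (0 = independent taxa, 1 = full Brownian).
#' @param effort_range positive range of per-site sampling effort.
#' @param measure_probs named probabilities of a study's measure type.
#' @param ndvi_params list: `baseline`, `amplitude`, `noise_sd`,
#'   `p_flagged`, `p_unflagged`, `spike_depth`.
#' @param pressure_means land-use-conditional pressure means (see
#'   [default_pressure_means()]); controls how strongly forest cover,
#'   population density and offtake are coupled to land use.
#' @param seed root seed; all stages derive their streams from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(
    n_studies = 20,
    sites_per_study = c(20, 40),
    taxa_per_study = c(8, 16),
    pool_size = 600,
    group_shares = c(invertebrates = 0.577, herptiles = 0.080,
                     mammals = 0.056, birds = 0.287),
    land_use_probs = c("primary forest" = 348, "secondary vegetation" = 94,
                       "wood plantation" = 319, "cropland" = 7,
                       "pasture" = 20, "urban" = 7) / 795,
    true_occ_coefs = default_occ_coefs(),
    true_abund_coefs = default_abund_coefs(),
    slopes_occ = c(hpd = -0.3, forest_cover = 0.2, indvi = -0.2),
    slopes_abund = c(hpd = -0.1, forest_cover = 0.1, indvi = -0.3),
    occ_intercept = NULL,
    target_nonzero = 0.26,
    abund_intercept = log(5),
    sd_study_occ = 1.2, sd_site_occ = 0.4, sd_taxon_occ = 0.8,
    sd_study_abund = 0.8, sd_site_abund = 0.3, sd_taxon_abund = 0.5,
    sigma_resid = 0.8,
    lambda_true = 0.1,
    effort_range = c(0.5, 2),
    measure_probs = c(abundance = 47624, relative_abundance = 3528,
                      group_abundance = 171, density = 96,
                      reporting_rate = 122) / 51541,
    ndvi_params = list(baseline = 0.75, amplitude = 0.05, noise_sd = 0.02,
                       p_flagged = 0.10, p_unflagged = 0.005,
                       spike_depth = 0.35),
    pressure_means = default_pressure_means(),
    seed = 1L) {
  cfg <- list(n_studies = n_studies, sites_per_study = sites_per_study,
              taxa_per_study = taxa_per_study, pool_size = pool_size,
              group_shares = group_shares, land_use_probs = land_use_probs,
              true_occ_coefs = true_occ_coefs,
              true_abund_coefs = true_abund_coefs,
              slopes_occ = slopes_occ, slopes_abund = slopes_abund,
              occ_intercept = occ_intercept,
              target_nonzero = target_nonzero,
              abund_intercept = abund_intercept,
              sd_study_occ = sd_study_occ, sd_site_occ = sd_site_occ,
              sd_taxon_occ = sd_taxon_occ,
              sd_study_abund = sd_study_abund,
              sd_site_abund = sd_site_abund,
              sd_taxon_abund = sd_taxon_abund,
              sigma_resid = sigma_resid, lambda_true = lambda_true,
              effort_range = effort_range, measure_probs = measure_probs,
              ndvi_params = ndvi_params, pressure_means = pressure_means,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
default_occ_coefs <- function() {
  m <- rbind(
    invertebrates = c(0, -0.3, -0.5, -0.8, -0.7, -1.0),
    herptiles     = c(0,  0.3, -0.4, -0.6, -0.5, -0.8),
    mammals       = c(0, -0.5, -0.8, -1.2, -1.0, -1.5),
    birds         = c(0, -0.4, -0.6, -1.0, -0.8, -1.8))
  colnames(m) <- land_use_levels()
  m
}

#' @rdname generator_config
#' @export
default_abund_coefs <- function() {
  m <- rbind(
    invertebrates = c(0, -0.2, -0.1, -0.3, -0.4, -0.6),
    herptiles     = c(0,  0.3,  0.2,  0.1, -0.2, -0.5),
    mammals       = c(0,  0.2,  0.3,  0.2, -0.1, -0.7),
    birds         = c(0,  0.2,  0.4,  0.2, -0.2, -0.9))
  colnames(m) <- land_use_levels()
  m
}

#' Land-use-conditional means of the continuous pressures
#'
#' Mean forest cover (percent), log human population density and seasonal
#' offtake multiplier per land-use class; setting a row constant across
#' classes decouples that pressure from land use.
#'
#' @return list of three named vectors over the six land-use classes.
#' @export
default_pressure_means <- function() {
  lu <- land_use_levels()
  list(forest_cover = stats::setNames(c(85, 65, 70, 25, 20, 15), lu),
       loghpd = stats::setNames(c(1.0, 2.5, 2.5, 3.5, 3.0, 5.0), lu),
       offtake = stats::setNames(c(0.6, 0.9, 1.1, 1.6, 1.4, 1.0), lu))
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$group_shares) - 1) > 1e-8)
    stop("group_shares must sum to 1")
  if (abs(sum(cfg$land_use_probs) - 1) > 1e-8)
    stop("land_use_probs must sum to 1")
  if (any(cfg$group_shares < 0) || any(cfg$land_use_probs < 0))
    stop("proportions must be non-negative")
  sds <- c(cfg$sd_study_occ, cfg$sd_site_occ, cfg$sd_taxon_occ,
           cfg$sd_study_abund, cfg$sd_site_abund, cfg$sd_taxon_abund)
  if (any(sds < 0)) stop("random-effect SDs must be non-negative")
  if (cfg$sigma_resid <= 0) stop("sigma_resid must be positive")
  if (any(cfg$effort_range <= 0)) stop("effort_range must be positive")
  if (cfg$lambda_true < 0 || cfg$lambda_true > 1)
    stop("lambda_true must lie in [0, 1]")
  for (m in list(cfg$true_occ_coefs, cfg$true_abund_coefs)) {
    if (!all(dim(m) == c(4, 6))) stop("coefficient maps must be 4 x 6")
    if (any(m[, "primary forest"] != 0))
      stop("primary-forest (baseline) offsets must be exactly 0")
  }
  invisible(cfg)
}

# All randomness descends from the root seed through fixed stage offsets,
# so the stages are individually reproducible.
stage_seed <- function(cfg, stage) {
  offs <- c(world = 1L, studies = 2L, observations = 3L)
  (cfg$seed %% 2000000000L) + offs[[stage]]
}

#' Generate the taxon pool, its taxonomy tree and range-point records
#'
#' Each taxon gets a taxonomic group (multinomial on `group_shares`), a
#' ranked hierarchy path (class/order/family/genus/species), a true habitat
#' specialization (birds and mammals only, with a matching habitat table
#' from which [flag_specialists()] can recover it), a true range width and
#' a set of point-occurrence records for range classification.  The tree is
#' built from the hierarchy and given Grafen branch lengths.
#'
#' @param config a [generator_config()].
#' @return list: `taxa` (data.frame), `tree` (`phylo`), `habitat_table`,
#'   `points` (taxon_id, lon, lat).
#' @export
generate_world <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config, "world"))
  n <- config$pool_size
  groups <- sample(names(config$group_shares), n, replace = TRUE,
                   prob = config$group_shares)
  taxon_id <- sprintf("t%04d", seq_len(n))

  class_of <- c(invertebrates = "Insecta", herptiles = "Herpetofauna",
                mammals = "Mammalia", birds = "Aves")
  hier <- data.frame(taxon_id = taxon_id, class = class_of[groups],
                     order = NA_character_, family = NA_character_,
                     genus = NA_character_, stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_ord <- max(2L, round(length(idx) / 40))
    ords <- sample(n_ord, length(idx), replace = TRUE)
    hier$order[idx] <- sprintf("%s_ord%02d", class_of[g], ords)
    for (o in unique(ords)) {
      oi <- idx[ords == o]
      n_fam <- sample(2:4, 1)
      fams <- sample(n_fam, length(oi), replace = TRUE)
      hier$family[oi] <- sprintf("%s_ord%02d_fam%d", class_of[g], o, fams)
      for (f in unique(fams)) {
        fi <- oi[fams == f]
        n_gen <- max(1L, ceiling(length(fi) / 3))
        gens <- sample(n_gen, length(fi), replace = TRUE)
        hier$genus[fi] <- sprintf("%s_ord%02d_fam%d_gen%d",
                                  class_of[g], o, f, gens)
      }
    }
  }

  specialist_true <- ifelse(groups %in% c("birds", "mammals"),
                            sample(c("specialist", "generalist"), n,
                                   replace = TRUE, prob = c(0.4, 0.6)),
                            "unknown")
  habitat_table <- data.frame(
    taxon_id = taxon_id,
    forest_importance = ifelse(
      groups == "birds",
      ifelse(specialist_true == "specialist", "major",
             sample(c("suitable", "marginal"), n, replace = TRUE)),
      NA_character_),
    habitat_breadth = ifelse(
      groups == "mammals",
      ifelse(specialist_true == "specialist", 1L,
             sample(2:4, n, replace = TRUE)),
      NA_integer_))

  range_width <- exp(stats::rnorm(n, mean = 1.2, sd = 1))  # degrees
  centre_lon <- stats::runif(n, -179, 179)
  centre_lat <- stats::runif(n, -35, 35)
  n_pts <- 1L + stats::rpois(n, 12)
  points <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(taxon_id = taxon_id[i],
               lon = centre_lon[i] +
                 stats::runif(n_pts[i], -range_width[i], range_width[i]),
               lat = pmin(40, pmax(-40, centre_lat[i] +
                 stats::runif(n_pts[i], -range_width[i], range_width[i]))))
  }))

  taxa <- data.frame(taxon_id = taxon_id, group = groups,
                     specialist_true = specialist_true,
                     range_width = range_width,
                     stringsAsFactors = FALSE)
  taxa <- cbind(taxa, hier[, c("class", "order", "family", "genus")])
  tree <- grafen_lengths(build_tree(hier))
  list(taxa = taxa, tree = tree, habitat_table = habitat_table,
       points = points)
}

#' Generate studies, sites, pressures and per-site NDVI series
#'
#' Studies get a centre within the sub-tropical belt and spatially
#' clustered sites (centre + small jitter); each site draws a land use,
#' land-use-correlated forest cover and human population density, and a
#' 3-year 16-day NDVI composite series whose seasonal dip amplitude (the
#' site's true offtake) drives the site's true iNDVI.  The true iNDVI is
#' integrated from the latent noise- and contamination-free series by the
#' same integrator the pressure module uses, so downstream recovery error
#' isolates contamination handling.
#'
#' @param config a [generator_config()].
#' @param taxa the taxon table from [generate_world()].
#' @return list: `sites` (with true pressures and `indvi_true`),
#'   `ndvi_long` (site_id, date, ndvi, qa), `study_table` (study_id, group,
#'   measure_type, sample years).
#' @export
generate_studies <- function(config, taxa) {
  validate_config(config)
  set.seed(stage_seed(config, "studies"))
  np <- config$ndvi_params
  lu_levels <- land_use_levels()
  # land-use-conditional pressure distributions (means on transformed scales)
  fc_mean <- config$pressure_means$forest_cover[lu_levels]
  loghpd_mean <- config$pressure_means$loghpd[lu_levels]
  offtake_mult <- config$pressure_means$offtake[lu_levels]

  studies <- sprintf("st%02d", seq_len(config$n_studies))
  study_group <- sample(names(config$group_shares), config$n_studies,
                        replace = TRUE, prob = config$group_shares)
  study_measure <- sample(names(config$measure_probs), config$n_studies,
                          replace = TRUE, prob = config$measure_probs)
  year_first <- sample(2003:2010, config$n_studies, replace = TRUE)
  duration <- ifelse(stats::runif(config$n_studies) < 0.2,
                     sample(1:2, config$n_studies, replace = TRUE), 0)
  year_last <- pmin(year_first + duration, 2012)
  centre_lon <- stats::runif(config$n_studies, -179, 179)
  centre_lat <- stats::runif(config$n_studies, -39, 39)
  n_sites <- sample(config$sites_per_study[1]:config$sites_per_study[2],
                    config$n_studies, replace = TRUE)

  sites_list <- vector("list", config$n_studies)
  ndvi_list <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    ns <- n_sites[s]
    lu <- sample(lu_levels, ns, replace = TRUE, prob = config$land_use_probs)
    fc <- pmin(100, pmax(0, stats::rnorm(ns, fc_mean[lu], 10)))
    hpd <- exp(stats::rnorm(ns, loghpd_mean[lu], 1))
    offt <- offtake_mult[lu] * exp(stats::rnorm(ns, 0, 0.25))
    amp <- np$amplitude * offt
    site_id <- sprintf("%s_s%03d", studies[s], seq_len(ns))
    lon <- centre_lon[s] + stats::rnorm(ns, 0, 0.2)
    lat <- pmin(40, pmax(-40, centre_lat[s] + stats::rnorm(ns, 0, 0.2)))

    wend <- window_for_study(year_first[s]:year_last[s])
    wstart <- seq(wend, length.out = 2, by = "-3 years")[2] + 1
    dates <- seq(wstart - 16, wend + 16, by = 16)
    tnum <- as.numeric(dates)
    indvi_true <- numeric(ns)
    nd <- vector("list", ns)
    for (i in seq_len(ns)) {
      latent <- np$baseline - amp[i] * (1 + sin(2 * pi * tnum / 365.25)) / 2
      indvi_true[i] <- compute_indvi(
        data.frame(date = dates, ndvi = latent), wend)
      obs <- latent + stats::rnorm(length(dates), 0, np$noise_sd)
      qa <- ifelse(stats::runif(length(dates)) < np$p_flagged, 1L, 0L)
      obs[qa == 1L] <- obs[qa == 1L] - stats::runif(sum(qa == 1L), 0.1, 0.5)
      cloud <- qa == 0L & stats::runif(length(dates)) < np$p_unflagged
      obs[cloud] <- obs[cloud] - np$spike_depth
      nd[[i]] <- data.frame(site_id = site_id[i], date = dates,
                            ndvi = pmax(-1, pmin(1, obs)), qa = qa)
    }
    sites_list[[s]] <- data.frame(
      study_id = studies[s], site_id = site_id, lon = lon, lat = lat,
      land_use = lu, forest_cover = fc, hpd = hpd,
      indvi_true = indvi_true,
      sample_year_first = year_first[s], sample_year_last = year_last[s],
      effort = stats::runif(ns, config$effort_range[1],
                            config$effort_range[2]))
    ndvi_list[[s]] <- do.call(rbind, nd)
  }
  list(sites = do.call(rbind, sites_list),
       ndvi_long = do.call(rbind, ndvi_list),
       study_table = data.frame(study_id = studies, group = study_group,
                                measure_type = study_measure,
                                sample_year_first = year_first,
                                sample_year_last = year_last))
}

# standardization constants tying the generator's truth to fixed pressure
# scores (independent of any one realized sample)
truth_scaling <- function() {
  list(hpd = c(center = 2.2, scale = 1.1),        # on log(hpd + 1)
       forest_cover = c(center = 73, scale = 18),
       indvi = c(center = 25, scale = 10))        # NDVI x days
}

#' Generate abundance records from the true hurdle model
#'
#' Every taxon sampled by a study yields one record at every site of that
#' study (so downstream absence inference is exact by construction).
#' Presence is Bernoulli through a logit link; abundance given presence is
#' log-normal; recorded value = abundance x effort for the effort-sensitive
#' measure types (`abundance`, `group_abundance`), abundance as-is
#' otherwise.  Taxon random intercepts are drawn on the taxonomy tree with
#' the Pagel transform at `lambda_true`.  When `occ_intercept` is `NULL`
#' it is solved so the realized mean presence probability equals
#' `target_nonzero` exactly.
#'
#' @param config a [generator_config()].
#' @param world output of [generate_world()].
#' @param studies output of [generate_studies()].
#' @return list: `records` (long-format AbundanceRecord table) and `truth`
#'   (intercepts, coefficient maps, slopes, all random-effect draws, and
#'   per-record linear predictors).
#' @export
generate_observations <- function(config, world, studies) {
  validate_config(config)
  set.seed(stage_seed(config, "observations"))
  taxa <- world$taxa
  sites <- studies$sites
  stab <- studies$study_table
  sc <- truth_scaling()
  z_hpd <- (log1p(sites$hpd) - sc$hpd["center"]) / sc$hpd["scale"]
  z_fc <- (sites$forest_cover - sc$forest_cover["center"]) /
    sc$forest_cover["scale"]
  z_iv <- (sites$indvi_true - sc$indvi["center"]) / sc$indvi["scale"]

  # taxon effects: correlated on the tree at lambda_true, unit marginal SD
  C <- ape::vcv(world$tree)
  V <- pagel_transform(C, config$lambda_true)
  L <- t(chol(V))
  u_taxon <- stats::setNames(as.numeric(L %*% stats::rnorm(nrow(V))),
                             rownames(V))[taxa$taxon_id] * config$sd_taxon_occ
  v_taxon <- stats::setNames(as.numeric(L %*% stats::rnorm(nrow(V))),
                             rownames(V))[taxa$taxon_id] * config$sd_taxon_abund
  u_study <- stats::setNames(stats::rnorm(nrow(stab), 0, config$sd_study_occ),
                             stab$study_id)
  v_study <- stats::setNames(stats::rnorm(nrow(stab), 0, config$sd_study_abund),
                             stab$study_id)
  u_site <- stats::setNames(stats::rnorm(nrow(sites), 0, config$sd_site_occ),
                            sites$site_id)
  v_site <- stats::setNames(stats::rnorm(nrow(sites), 0, config$sd_site_abund),
                            sites$site_id)

  # sample taxa per study from the study's group pool
  sampled <- lapply(seq_len(nrow(stab)), function(s) {
    pool <- taxa$taxon_id[taxa$group == stab$group[s]]
    k <- min(length(pool),
             sample(config$taxa_per_study[1]:config$taxa_per_study[2], 1))
    sort(sample(pool, k))
  })

  rec <- do.call(rbind, lapply(seq_len(nrow(stab)), function(s) {
    sid <- stab$study_id[s]
    ss <- which(sites$study_id == sid)
    tx <- sampled[[s]]
    expand.grid(site_row = ss, taxon_id = tx,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  i <- rec$site_row
  g <- taxa$group[match(rec$taxon_id, taxa$taxon_id)]
  lu <- sites$land_use[i]
  eta_occ0 <- config$true_occ_coefs[cbind(g, lu)] +
    config$slopes_occ["hpd"] * z_hpd[i] +
    config$slopes_occ["forest_cover"] * z_fc[i] +
    config$slopes_occ["indvi"] * z_iv[i] +
    u_study[sites$study_id[i]] + u_site[sites$site_id[i]] +
    u_taxon[rec$taxon_id]
  eta_occ0 <- as.numeric(eta_occ0)

  b0 <- config$occ_intercept
  if (is.null(b0)) {
    b0 <- stats::uniroot(function(b)
      mean(stats::plogis(b + eta_occ0)) - config$target_nonzero,
      interval = c(-15, 15), tol = 1e-10)$root
  }
  p_occ <- stats::plogis(b0 + eta_occ0)
  present <- stats::rbinom(length(p_occ), 1, p_occ)

  mu_ab <- config$abund_intercept +
    as.numeric(config$true_abund_coefs[cbind(g, lu)]) +
    config$slopes_abund["hpd"] * z_hpd[i] +
    config$slopes_abund["forest_cover"] * z_fc[i] +
    config$slopes_abund["indvi"] * z_iv[i] +
    as.numeric(v_study[sites$study_id[i]]) +
    as.numeric(v_site[sites$site_id[i]]) +
    as.numeric(v_taxon[rec$taxon_id])
  abund <- ifelse(present == 1,
                  exp(mu_ab + stats::rnorm(length(mu_ab), 0,
                                           config$sigma_resid)),
                  0)
  measure <- stab$measure_type[match(sites$study_id[i], stab$study_id)]
  effort <- sites$effort[i]
  sensitive <- measure %in% c("abundance", "group_abundance")
  value <- ifelse(sensitive, abund * effort, abund)

  records <- data.frame(study_id = sites$study_id[i],
                        site_id = sites$site_id[i],
                        taxon_id = rec$taxon_id,
                        measure_type = measure, effort = effort,
                        value = value)
  truth <- list(occ_intercept = b0, abund_intercept = config$abund_intercept,
                occ_coefs = config$true_occ_coefs,
                abund_coefs = config$true_abund_coefs,
                slopes_occ = config$slopes_occ,
                slopes_abund = config$slopes_abund,
                lambda_true = config$lambda_true,
                scaling = truth_scaling(),
                u_study = u_study, v_study = v_study,
                u_site = u_site, v_site = v_site,
                u_taxon = u_taxon, v_taxon = v_taxon,
                eta_occ = b0 + eta_occ0, p_occ = p_occ, mu_abund = mu_ab,
                sd = list(study_occ = config$sd_study_occ,
                          site_occ = config$sd_site_occ,
                          taxon_occ = config$sd_taxon_occ,
                          study_abund = config$sd_study_abund,
                          site_abund = config$sd_site_abund,
                          taxon_abund = config$sd_taxon_abund,
                          resid = config$sigma_resid))
  list(records = records, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_world()], [generate_studies()]
#' and [generate_observations()].
#'
#' @param config a [generator_config()].
#' @return list with `taxa`, `tree`, `habitat_table`, `points`, `sites`,
#'   `ndvi_long`, `study_table`, `records`, `truth`.
#' @export
generate_dataset <- function(config = generator_config()) {
  world <- generate_world(config)
  studies <- generate_studies(config, world$taxa)
  obs <- generate_observations(config, world, studies)
  c(world, studies, obs)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `sites.csv`, `records.csv`, `taxa.csv`, `ndvi_long.csv` (ISO
#' dates), `points.csv`, `habitat.csv`, `tree.nwk` and `truth.json`.
#'
#' @param dataset output of [generate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(outdir, f),
                                       row.names = FALSE)
  w(dataset$sites, "sites.csv")
  w(dataset$records, "records.csv")
  w(dataset$taxa, "taxa.csv")
  nd <- dataset$ndvi_long
  nd$date <- format(as.Date(nd$date, origin = "1970-01-01"), "%Y-%m-%d")
  w(nd, "ndvi_long.csv")
  w(dataset$points, "points.csv")
  w(dataset$habitat_table, "habitat.csv")
  ape::write.tree(dataset$tree, file.path(outdir, "tree.nwk"))
  truth <- dataset$truth
  truth$occ_coefs <- as.data.frame(truth$occ_coefs)
  truth$abund_coefs <- as.data.frame(truth$abund_coefs)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
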