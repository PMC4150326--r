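test_that("model specs enforce marginality at construction", {
  expect_error(model_spec("occurrence", c("hpd:forest_cover")),
               "marginality")
  expect_silent(model_spec("occurrence",
                           c("hpd", "forest_cover", "hpd:forest_cover")))
})

test_that("the full term set is the expected 15 marginality-complete terms", {
  ts <- full_term_set()
  expect_length(ts, 15)
  expect_true(all(c("land_use:group", "hpd:forest_cover:group") %in% ts))
  expect_silent(model_spec("occurrence", ts))
})

test_that("treatment coding gives 23 non-reference interaction columns", {
  d <- expand.grid(land_use = factor(foresthurdle:::land_use_levels(),
                                     foresthurdle:::land_use_levels()),
                   group = factor(foresthurdle:::group_levels(),
                                  foresthurdle:::group_levels()))
  d$study_id <- "s"; d$site_in_study <- paste0("x", seq_len(nrow(d)))
  d$taxon_id <- "t"
  des <- build_design(d, model_spec("occurrence",
                                    c("land_use", "group", "land_use:group")))
  expect_equal(ncol(des$X) - 1, 23)
  expect_equal(length(unique(des$site)), nrow(d))
})

test_that("zero-variance covariates are rejected when standardizing", {
  ds <- generate_dataset(small_config(seed = 1))
  pr <- site_pressures(ds$sites, ds$ndvi_long)
  pr$forest_cover <- 50
  occ <- derive_occurrence(correct_effort(ds$records))
  expect_error(build_model_data(occ, ds$sites, pr, ds$taxa),
               "forest_cover")
})

test_that("collapsed random factors reduce to the IRLS logistic oracle", {
  set.seed(3)
  n <- 400
  d <- data.frame(present = NA, hpd = rnorm(n), forest_cover = rnorm(n),
                  study_id = "s1", site_in_study = "s1/a", taxon_id = "t1")
  d$present <- rbinom(n, 1, plogis(-0.6 + 0.9 * d$hpd - 0.4 * d$forest_cover))
  f <- fit_occurrence(d, model_spec("occurrence", c("hpd", "forest_cover")))
  X <- cbind(1, d$hpd, d$forest_cover)
  want <- irls_logistic(X, d$present)
  expect_lt(max(abs(f$coefficients$estimate - want)), 1e-6)
})

test_that("a balanced intercept-only occurrence model sits at logit one half", {
  d <- data.frame(present = rep(c(0L, 1L), 100), study_id = "s",
                  site_in_study = "s/a", taxon_id = "t")
  f <- fit_occurrence(d, model_spec("occurrence", character(0)))
  expect_equal(f$coefficients$estimate, 0, tolerance = 1e-8)
})

test_that("the abundance stage without random effects matches normal equations", {
  set.seed(9)
  n <- 200
  d <- data.frame(x = rnorm(n), study_id = "s", site_in_study = "s/a",
                  taxon_id = "t")
  d$log_value <- 1 + 0.5 * d$x + rnorm(n)
  f <- fit_abundance(d, model_spec("log_abundance", "x"))
  X <- cbind(1, d$x)
  want <- drop(solve(crossprod(X), crossprod(X, d$log_value)))
  expect_equal(f$coefficients$estimate, want, tolerance = 1e-10)
})

test_that("rescaling abundance shifts the intercept, not slopes or logLik", {
  set.seed(12)
  d <- sim_lmm_data(6, 4, 8, 0.5, 0.3, 0.4, 1, beta_x = 0.7, intercept = 1)
  sp <- model_spec("log_abundance", "x")
  f1 <- fit_abundance(d, sp)
  d2 <- d; d2$log_value <- d$log_value + log(3)   # natural-scale value x 3
  f2 <- fit_abundance(d2, sp)
  i1 <- f1$coefficients$term == "(Intercept)"
  expect_equal(f2$coefficients$estimate[!i1], f1$coefficients$estimate[!i1],
               tolerance = 1e-5)
  expect_equal(f2$coefficients$estimate[i1] - f1$coefficients$estimate[i1],
               log(3), tolerance = 1e-5)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("abundance rejects non-positive values", {
  d <- data.frame(value = c(1, 0), study_id = "s", site_in_study = "s/a",
                  taxon_id = c("t1", "t2"))
  expect_error(fit_abundance(d, model_spec("log_abundance", character(0))),
               "non-positive")
})

test_that("likelihood-ratio tests compare nested ML fits", {
  set.seed(15)
  d <- sim_lmm_data(8, 4, 6, 0.5, 0.3, 0.4, 1, beta_x = 0.8)
  full <- fit_abundance(d, model_spec("log_abundance", "x"))
  red <- fit_abundance(d, model_spec("log_abundance", character(0)))
  tt <- lrt(full, red)
  expect_equal(tt$df, 1)
  expect_gt(tt$chisq, 0)
  expect_lt(tt$p, 0.01)
  # identical models: zero statistic, p = 1
  same <- lrt(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(red, full), "not nested")
})

test_that("a strong effect at large n is detected essentially always", {
  set.seed(16)
  rejections <- vapply(1:10, function(r) {
    d <- sim_lmm_data(10, 10, 20, 0.5, 0.3, 0.4, 1, beta_x = 1)
    full <- fit_abundance(d, model_spec("log_abundance", "x"))
    red <- fit_abundance(d, model_spec("log_abundance", character(0)))
    lrt(full, red)$p < 0.05
  }, logical(1))
  expect_true(all(rejections))
})

test_that("backward selection respects marginality in its trace", {
  set.seed(23)
  # strong x1:x2 interaction; x3 null
  g <- sim_lmm_data(10, 6, 8, 0.5, 0.3, 0.4, 1)
  g$x1 <- rnorm(nrow(g)); g$x2 <- rnorm(nrow(g)); g$x3 <- rnorm(nrow(g))
  g$log_value <- g$log_value + 0.8 * g$x1 * g$x2
  sp <- model_spec("log_abundance", c("x1", "x2", "x3", "x1:x2"))
  sel <- backward_select(g, sp)
  tr <- sel$trace
  expect_true("x1:x2" %in% sel$fit$spec$fixed_terms)
  # mains under the retained interaction are never tested (the n.a. cells)
  expect_true(is.na(tr$p[tr$term == "x1"]))
  expect_true(is.na(tr$p[tr$term == "x2"]))
  expect_true(tr$dropped[tr$term == "x3"])
  # dropping a term never increased the log-likelihood
  full <- fit_abundance(g, sp)
  expect_lte(sel$fit$logLik, full$logLik + 1e-9)
  expect_lte(sel$fit$AIC, full$AIC + 1e-9)
})

test_that("fit results are invariant to relabelling grouping ids", {
  set.seed(31)
  d <- sim_lmm_data(6, 4, 8, 0.6, 0.3, 0.4, 1, beta_x = 0.5)
  sp <- model_spec("log_abundance", "x")
  f1 <- fit_abundance(d, sp)
  d2 <- d
  d2$study_id <- chartr("0123456789", "9876543210", d$study_id)
  d2$taxon_id <- paste0("zz_", d$taxon_id)
  f2 <- fit_abundance(d2, sp)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("r2 components reproduce the closed-form examples", {
  g <- r2_components(1, c(1, 0.5, 0.5), 1, "gaussian")
  expect_identical(g$marginal, 0.25)
  expect_identical(g$conditional, 0.75)
  expect_identical(r2_components(0, c(1, 1), 1, "gaussian")$marginal, 0)
  b <- r2_components(pi^2 / 3, c(0, 0, 0), 0, "binomial")
  expect_identical(b$marginal, 0.5)
  expect_identical(b$conditional, 0.5)
})

test_that("r2_glmm uses the realized fixed-effect variance", {
  set.seed(41)
  d <- sim_lmm_data(8, 5, 10, 0.7, 0.3, 0.5, 1, beta_x = 1)
  f <- fit_abundance(d, model_spec("log_abundance", "x"))
  r2 <- r2_glmm(f)
  expect_gte(r2$conditional, r2$marginal)
  expect_gt(r2$marginal, 0.05)
  # oracle: recompute from the pieces
  X <- lme4::getME(f$model, "X")
  s2f <- var(as.numeric(X %*% lme4::fixef(f$model)))
  vc <- f$varcomps
  want <- s2f / (s2f + sum(vc))
  expect_equal(r2$marginal, want, tolerance = 1e-10)
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(52)
  for (r in 1:3) {
    d <- sim_lmm_data(6, 4, 8, 0.5, 0.3, 0.4, 0.9, beta_x = 0.6)
    f <- fit_abundance(d, model_spec("log_abundance", "x"))
    ref <- glmmTMB::glmmTMB(
      log_value ~ x + (1 | study_id) + (1 | site_in_study) + (1 | taxon_id),
      data = d, REML = FALSE)
    expect_equal(f$coefficients$estimate,
                 unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-3)
    expect_equal(f$logLik, as.numeric(logLik(ref)), tolerance = 0.1)
  }
  set.seed(53)
  d <- sim_lmm_data(8, 6, 10, 0.6, 0.3, 0.5, 1, beta_x = 0.8)
  d$present <- rbinom(nrow(d), 1, plogis(d$log_value - mean(d$log_value)))
  f <- fit_occurrence(d, model_spec("occurrence", "x"))
  ref <- glmmTMB::glmmTMB(
    present ~ x + (1 | study_id) + (1 | site_in_study) + (1 | taxon_id),
    data = d, family = stats::binomial)
  expect_equal(f$coefficients$estimate, unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-2)
  expect_equal(f$logLik, as.numeric(logLik(ref)), tolerance = 0.1)
})

test_that("a null trait interaction costs about two AIC per parameter", {
  set.seed(61)
  daic <- numeric(8)
  for (r in 1:8) {
    d <- sim_lmm_data(8, 5, 10, 0.5, 0.3, 0.4, 1, beta_x = 0.6)
    d$specialist <- sample(c("specialist", "generalist"), nrow(d), TRUE)
    sp <- model_spec("log_abundance", "x")
    scan <- posthoc_trait_scan(d, sp, "specialist")
    daic[r] <- scan$delta_aic[scan$term == "x"] / scan$df_added[scan$term == "x"]
  }
  expect_gt(mean(daic), 0)
  expect_lt(mean(daic), 4)
})

test_that("a real trait effect yields a strongly negative delta AIC", {
  set.seed(62)
  d <- sim_lmm_data(12, 8, 16, 0.4, 0.2, 0.3, 0.8, beta_x = 0)
  tr_tab <- unique(d["taxon_id"])
  tr_tab$specialist <- sample(c("specialist", "generalist"),
                              nrow(tr_tab), TRUE)
  d$specialist <- tr_tab$specialist[match(d$taxon_id, tr_tab$taxon_id)]
  d$log_value <- d$log_value +
    ifelse(d$specialist == "specialist", 1.2, 0) * d$x
  scan <- posthoc_trait_scan(d, model_spec("log_abundance", "x"),
                             "specialist")
  expect_lt(scan$delta_aic[scan$term == "x"], -10)
})

test_that("the cubic side-model recovers a U-shaped response", {
  set.seed(71)
  hits <- vapply(1:8, function(r) {
    d <- sim_lmm_data(10, 8, 6, 0.3, 0.2, 0.3, 1)
    d$hpd <- rnorm(nrow(d))
    d$present <- rbinom(nrow(d), 1, plogis(-0.5 + 0.9 * d$hpd^2))
    f <- fit_cubic_submodel(d, "hpd")
    grid <- data.frame(poly_x = seq(-1.5, 1.5, length.out = 61))
    # predict on the fixed scale by rebuilding the polynomial basis
    pb <- predict(f$model, newdata = cbind(grid,
      study_id = d$study_id[1], site_in_study = d$site_in_study[1],
      taxon_id = d$taxon_id[1]), re.form = NA)
    which.min(pb) > 10 && which.min(pb) < 50   # interior minimum
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("cubic side-models refuse constant covariates", {
  d <- data.frame(present = rbinom(40, 1, 0.5), hpd = 1,
                  study_id = "s", site_in_study = "s/a", taxon_id = "t")
  expect_error(fit_cubic_submodel(d, "hpd"), "distinct")
})
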