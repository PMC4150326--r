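test_that("taxonomy trees are built from ranked paths", {
  h <- data.frame(taxon_id = c("sp1", "sp2", "sp3"),
                  family = "F1", genus = c("G1", "G1", "G2"))
  tr <- build_tree(h)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, h$taxon_id)
  # root (family) + genus G1; G2 is a singleton chain collapsed onto sp3
  expect_equal(tr$Nnode, 2L)
})

test_that("partial paths attach at the deepest resolvable node", {
  h <- data.frame(taxon_id = c("a", "b", "c"),
                  family = c("F1", "F1", "F1"),
                  genus = c("G1", "G1", NA))
  tr <- build_tree(h)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # c hangs off the family node, a and b share the genus node
  g <- ape::getMRCA(tr, c("a", "b"))
  expect_false(g == ape::getMRCA(tr, c("a", "c")))
})

test_that("conflicting parentage for a named node is an error", {
  h <- data.frame(taxon_id = c("a", "b"),
                  family = c("F1", "F2"), genus = c("G1", "G1"))
  expect_error(build_tree(h), "conflicting parentage")
})

test_that("tree construction ignores input order", {
  set.seed(2)
  h <- data.frame(taxon_id = sprintf("s%02d", 1:12),
                  order = sample(c("O1", "O2"), 12, TRUE))
  h$family <- paste0(h$order, "_F", sample(1:2, 12, TRUE))
  h$genus <- paste0(h$family, "_G", sample(1:2, 12, TRUE))
  t1 <- grafen_lengths(build_tree(h))
  t2 <- grafen_lengths(build_tree(h[sample(nrow(h)), ]))
  expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE))
})

test_that("single-taxon hierarchies give a degenerate one-leaf tree", {
  h <- data.frame(taxon_id = "only", family = "F", genus = "G")
  tr <- build_tree(h)
  expect_equal(tr$tip.label, "only")
  vals <- c(only = 1)
  expect_error(pagel_lambda(grafen_lengths(build_tree(data.frame(
    taxon_id = c("a", "b"), genus = c("G", "H")))), c(a = 1, b = 2)),
    ">= 3")
})

test_that("Grafen heights match hand enumeration on ((A,B),C)", {
  tr <- ape::read.tree(text = "((A,B),C);")
  g <- grafen_lengths(tr)
  # root height 1, (A,B) node height (2-1)/(3-1) = 0.5
  d <- ape::node.depth.edgelength(g)
  expect_equal(unname(d[1:3]), c(1, 1, 1))             # leaves at depth 1
  lens <- sort(g$edge.length)
  expect_equal(lens, c(0.5, 0.5, 0.5, 1))
})

test_that("Grafen heights on a balanced four-leaf tree are 1 and 1/3", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  g <- grafen_lengths(tr)
  internal_len <- g$edge.length[g$edge[, 2] > 4]
  expect_equal(sort(unique(round(internal_len, 10))), round(1 - 1/3, 10))
  tip_len <- g$edge.length[g$edge[, 2] <= 4]
  expect_equal(unique(round(tip_len, 10)), round(1/3, 10))
})

test_that("Grafen trees are ultrametric and match the ape reference", {
  set.seed(8)
  for (r in 1:5) {
    tr <- ape::rtree(sample(5:40, 1))
    g <- grafen_lengths(tr)
    d <- ape::node.depth.edgelength(g)[seq_along(g$tip.label)]
    expect_lt(max(d) - min(d), 1e-12)
    ref <- ape::compute.brlen(tr, method = "Grafen", power = 1)
    expect_equal(g$edge.length, ref$edge.length, tolerance = 1e-10)
  }
})

test_that("profile likelihood matches a dense-matrix GLS oracle", {
  set.seed(21)
  for (r in 1:10) {
    tr <- random_grafen_tree(10)
    C <- ape::vcv(tr)
    y <- as.numeric(chol(pagel_transform(C, 0.6)) %*% rnorm(10))
    names(y) <- rownames(C)
    for (lam in c(0, 0.3, 0.7, 1)) {
      got <- foresthurdle:::profile_loglik_lambda(C[names(y), names(y)], y, lam)
      want <- brute_lambda_loglik(C[names(y), names(y)], y, lam)
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
})

test_that("lambda is recovered under Brownian and independent simulation", {
  set.seed(77)
  tr <- random_grafen_tree(200)
  C <- ape::vcv(tr)
  L1 <- chol(pagel_transform(C, 1))
  hat_bm <- hat_iid <- numeric(15)
  for (r in 1:15) {
    y_bm <- as.numeric(t(L1) %*% rnorm(200)); names(y_bm) <- rownames(C)
    y_iid <- rnorm(200); names(y_iid) <- rownames(C)
    hat_bm[r] <- pagel_lambda(tr, y_bm)$lambda_hat
    hat_iid[r] <- pagel_lambda(tr, y_iid)$lambda_hat
  }
  expect_gt(mean(hat_bm), 0.85)
  expect_lt(mean(hat_iid), 0.1)
})

test_that("lambda estimate agrees with phytools on one dataset", {
  skip_if_not_installed("phytools")
  set.seed(5)
  tr <- random_grafen_tree(80)
  C <- ape::vcv(tr)
  y <- as.numeric(t(chol(pagel_transform(C, 0.5))) %*% rnorm(80))
  names(y) <- rownames(C)
  got <- pagel_lambda(tr, y)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(got$lambda_hat, ref$lambda, tolerance = 1e-3)
  expect_equal(got$loglik_tree, ref$logL, tolerance = 1e-4)
})

test_that("the boundary LRT uses the chi-squared(1) upper tail", {
  expect_equal(lambda_lrt_p(0), 1)
  expect_equal(lambda_lrt_p(3.841), 0.05, tolerance = 1e-3)
  expect_equal(lambda_lrt_p(3.841, mixture = TRUE), 0.025, tolerance = 1e-3)
})

test_that("per-taxon residual averaging matches brute-force group means", {
  d <- sim_lmm_data(4, 3, 6, 0.5, 0.3, 0.5, 1, beta_x = 1)
  f <- fit_abundance(d, model_spec("log_abundance", "x"))
  got <- residuals_by_taxon(f, d)
  r <- residuals(f$model, type = "response")
  want <- tapply(r, d$taxon_id, mean)
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))
})

test_that("Moran's I matches a brute-force double sum and ape", {
  set.seed(10)
  for (r in 1:10) {
    n <- sample(4:20, 1)
    co <- data.frame(lon = runif(n, 0, 2), lat = runif(n, 0, 2))
    z <- rnorm(n)
    W <- spatial_weights(co)
    got <- morans_i(z, W = W)
    expect_equal(got$I, brute_moran(z, W), tolerance = 1e-12)
    expect_equal(got$expected, -1 / (n - 1))
    ref <- ape::Moran.I(z, W)
    expect_equal(got$I, ref$observed, tolerance = 1e-10)
  }
})

test_that("Moran's I on the unit square with paired signs is positive", {
  co <- data.frame(lon = c(0, 0.1, 10, 10.1), lat = c(0, 0, 0, 0))
  z <- c(1, 1, -1, -1)
  got <- morans_i(z, coords = co)
  expect_gt(got$I, 0.5)
})

test_that("analytic Moran p matches a permutation oracle", {
  set.seed(20)
  n <- 12
  co <- data.frame(lon = runif(n), lat = runif(n))
  W <- spatial_weights(co)
  z <- rnorm(n) + co$lon          # mild spatial signal
  got <- morans_i(z, W = W)
  perm <- replicate(2000, brute_moran(sample(z), W))
  p_perm <- 2 * min(mean(perm >= got$I), mean(perm <= got$I))
  expect_lt(abs(got$p - p_perm), 0.05)
})

test_that("Moran's I stays within the row-standardized bound", {
  set.seed(30)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    co <- data.frame(lon = runif(n, 0, 3), lat = runif(n, 0, 3))
    expect_lte(abs(morans_i(rnorm(n), coords = co)$I), 1.05)
  }
})

test_that("degenerate Moran inputs are rejected", {
  co <- data.frame(lon = c(0, 1), lat = c(0, 1))
  expect_error(morans_i(c(1, 2), coords = co), ">= 3")
  co3 <- data.frame(lon = c(0, 1, 2), lat = c(0, 1, 2))
  expect_error(morans_i(c(1, 1, 1), coords = co3), "constant")
})

test_that("the autocorrelation meta-test counts flagged studies", {
  res <- data.frame(p = rep(0.5, 20))
  m <- autocorr_meta(res)
  expect_equal(m$fraction, 0)
  expect_equal(m$binom_p, 1)

  # at the fraction reported for the occurrence model (17.3% of 52 studies),
  # the excess over the 5% chance level is itself significant
  k <- round(0.173 * 52)
  res2 <- data.frame(p = c(rep(0.01, k), rep(0.5, 52 - k)))
  m2 <- autocorr_meta(res2)
  expect_equal(m2$fraction, k / 52, tolerance = 1e-12)
  expect_lt(m2$binom_p, 0.05)
  expect_equal(m2$binom_p,
               binom.test(k, 52, 0.05, alternative = "greater")$p.value)
})

test_that("refitting without flagged studies behaves sanely", {
  set.seed(44)
  d <- sim_lmm_data(12, 6, 8, 0.6, 0.3, 0.5, 1, beta_x = 0.5)
  sp <- model_spec("log_abundance", "x")
  same <- refit_excluding(d, character(0), sp)
  f <- fit_abundance(d, sp)
  expect_equal(same$fit$coefficients$estimate, f$coefficients$estimate,
               tolerance = 1e-8)
  # dropping half the studies inflates every SE
  half <- refit_excluding(d, paste0("s", 1:6), sp)
  expect_true(all(half$comparison$se_reduced > half$comparison$se_all))
  # and with no spatial signal the estimates stay within 2 SE
  expect_true(all(abs(half$comparison$estimate_reduced -
                        half$comparison$estimate_all) <
                    2 * half$comparison$se_all + 1e-8))
})
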