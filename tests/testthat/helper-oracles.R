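# Independent oracles and small simulators used across the tests.

# logistic regression by hand-rolled IRLS (oracle for degenerate GLMM fits)
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# dense 1-day-step Riemann integral of (v - min v) over the window
brute_indvi <- function(series, window_start, window_end) {
  t0 <- as.numeric(as.Date(window_start))
  t1 <- as.numeric(as.Date(window_end))
  grid <- seq(t0, t1, by = 1)
  v <- approx(as.numeric(series$date), series$ndvi, xout = grid,
              method = "linear", rule = 2)$y
  dev <- v - min(v)
  # trapezoid at 1-day steps
  sum((dev[-1] + dev[-length(dev)]) / 2)
}

# Moran's I by explicit double loops
brute_moran <- function(z, W) {
  n <- length(z)
  z <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# profile Gaussian log-likelihood at lambda via dense inverse/determinant
brute_lambda_loglik <- function(C, y, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  n <- length(y)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(one %*% Vi %*% y) / drop(one %*% Vi %*% one)
  r <- y - mu
  s2 <- drop(r %*% Vi %*% r) / n
  -n / 2 * log(2 * pi * s2) - 0.5 * determinant(V)$modulus[1] - n / 2
}

# direct crossed-intercept Gaussian simulator (study x site-in-study x taxon)
sim_lmm_data <- function(n_study, n_site, n_taxon, sd_study, sd_site,
                         sd_taxon, sigma, beta_x = 0, intercept = 0) {
  g <- expand.grid(study = seq_len(n_study), site = seq_len(n_site),
                   taxon = seq_len(n_taxon))
  u_s <- rnorm(n_study, 0, sd_study)
  site_key <- paste(g$study, g$site)
  u_site <- rnorm(length(unique(site_key)), 0, sd_site)
  names(u_site) <- unique(site_key)
  u_t <- rnorm(n_taxon, 0, sd_taxon)
  x <- rnorm(nrow(g))
  y <- intercept + beta_x * x + u_s[g$study] + u_site[site_key] +
    u_t[g$taxon] + rnorm(nrow(g), 0, sigma)
  data.frame(study_id = paste0("s", g$study),
             site_in_study = site_key,
             site_id = site_key,
             taxon_id = paste0("t", g$taxon),
             x = x, log_value = y)
}

# a small random ultrametric tree with Grafen lengths
random_grafen_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- sprintf("t%03d", seq_len(n_tips))
  grafen_lengths(tr)
}

# reduced-size generator config for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_studies = 8, sites_per_study = c(8, 14),
                   taxa_per_study = c(5, 8), pool_size = 150, ...)
}
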