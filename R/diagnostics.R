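#' Build a taxonomy tree from ranked hierarchy paths
#'
#' Constructs a rooted tree with one internal node per distinct
#' (rank, name) pair and one leaf per taxon.  Partial paths (NA at deeper
#' ranks) attach the leaf at the deepest resolvable node.  Chains of
#' single-child nodes are collapsed so the result is a valid `phylo`
#' object (polytomies allowed, singletons not).
#'
#' @param hierarchies data.frame with a `taxon_id` column plus rank columns
#'   ordered from coarsest to finest (e.g. class, order, family, genus).
#' @return an [ape::read.tree()]-style `phylo` object without branch
#'   lengths; tip labels are the taxon ids.
#' @seealso [grafen_lengths()] to calibrate branch lengths.
#' @export
build_tree <- function(hierarchies) {
  stopifnot("taxon_id" %in% names(hierarchies))
  ranks <- setdiff(names(hierarchies), "taxon_id")
  if (length(ranks) < 1) stop("need at least one rank column")
  n_taxa <- nrow(hierarchies)
  if (anyDuplicated(hierarchies$taxon_id)) stop("duplicate taxon_id")

  # node keys are (rank, name); check each named node has a single parent
  parent_of <- list()   # key -> parent key ("" = root)
  children <- list()    # key -> character vector of child node keys
  leaves_at <- list()   # key -> taxon ids attached
  add_child <- function(p, ch) {
    if (!ch %in% children[[p]]) children[[p]] <<- c(children[[p]], ch)
  }
  children[[".root"]] <- character(0)
  for (i in seq_len(n_taxa)) {
    path <- as.character(unlist(hierarchies[i, ranks]))
    keep <- !is.na(path) & path != ""
    if (any(!keep)) keep[which(!keep)[1]:length(keep)] <- FALSE
    parent <- ".root"
    for (j in which(keep)) {
      key <- paste(ranks[j], path[j], sep = "\r")
      if (is.null(parent_of[[key]])) {
        parent_of[[key]] <- parent
        children[[key]] <- character(0)
        add_child(parent, key)
      } else if (parent_of[[key]] != parent) {
        stop(sprintf("conflicting parentage for node '%s' at rank '%s'",
                     path[j], ranks[j]))
      }
      parent <- key
    }
    leaves_at[[parent]] <- c(leaves_at[[parent]], hierarchies$taxon_id[i])
  }

  # recursively collapse single-child chains into a nested list structure
  prune <- function(key) {
    kids <- c(lapply(children[[key]], prune),
              as.list(if (is.null(leaves_at[[key]])) character(0)
                      else leaves_at[[key]]))
    if (length(kids) == 1) return(kids[[1]])
    kids
  }
  nested <- prune(".root")

  if (is.character(nested)) {  # single-leaf degenerate tree
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = nested,
               Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }

  # assemble the phylo edge matrix by preorder traversal
  tips <- character(0)
  edges <- list()
  n_tip <- sum(rapply(list(nested), function(x) 1L, how = "unlist"))
  next_internal <- n_tip + 1L
  walk <- function(node, parent_num) {
    if (is.character(node)) {
      tips <<- c(tips, node)
      edges[[length(edges) + 1L]] <<- c(parent_num, length(tips))
      return(invisible())
    }
    me <- next_internal
    next_internal <<- next_internal + 1L
    if (!is.na(parent_num)) edges[[length(edges) + 1L]] <<- c(parent_num, me)
    for (k in node) walk(k, me)
  }
  walk(nested, NA_integer_)
  tr <- list(edge = do.call(rbind, edges), tip.label = tips,
             Nnode = next_internal - n_tip - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Grafen branch lengths
#'
#' Sets each node's height to its number of descendant leaves minus one,
#' rescaled so the root has height 1, raised to the power `rho`; leaves sit
#' at height 0 and each branch length is the parent height minus the child
#' height.  The result is ultrametric with depth exactly 1.
#'
#' @param tree a rooted `phylo` with >= 2 leaves.
#' @param rho power applied to the normalized heights (default 1).
#' @return the tree with `edge.length` set.
#' @export
grafen_lengths <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2) stop("need >= 2 leaves")
  ndesc <- ape::node.depth(tree)  # number of descendant tips per node
  h <- ((ndesc - 1) / (n - 1))^rho
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  tree
}

#' Pagel lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal of the Brownian-motion covariance by
#' `lambda`, leaving the diagonal untouched.
#'
#' @param C Brownian covariance matrix (e.g. [ape::vcv()]).
#' @param lambda scalar in \[0, 1\].
#' @return the transformed covariance matrix.
#' @export
pagel_transform <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# Gaussian profile log-likelihood at a given lambda: the mean is the GLS
# estimate and the scale its ML estimate, both analytic.
profile_loglik_lambda <- function(C, y, lambda, ridge = 0) {
  n <- length(y)
  V <- pagel_transform(C, lambda)
  if (ridge > 0) diag(V) <- diag(V) + ridge
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  one <- rep(1, n)
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(L, forwardsolve(t(L), r))
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(2 * pi * s2) - sum(log(diag(L))) - n / 2
}

#' Maximum-likelihood Pagel's lambda for values on a tree
#'
#' Estimates the phylogenetic signal of a continuous trait (here, model
#' residuals averaged per taxon) as the multiplier `lambda` on the
#' off-diagonal of the Brownian-motion covariance implied by the tree.  The
#' mean and scale are profiled analytically (GLS mean, ML variance); the
#' 1-D profile likelihood is maximized over \[0, 1\] by bounded search.
#' The reference likelihood `loglik_star` is evaluated at `lambda = 0`,
#' i.e. on a collapsed tree where all species are equally related.
#'
#' @param tree `phylo` with branch lengths (see [grafen_lengths()]).
#' @param values named numeric vector; names must be tip labels (>= 3).
#' @param tol optimization tolerance on lambda (default 1e-6).
#' @return list with `lambda_hat`, `loglik_tree`, `loglik_star`,
#'   `lrt_stat` (= 2 * (loglik_tree - loglik_star), clipped at 0), `p`
#'   (upper chi-squared tail, 1 df) and `n`.
#' @export
pagel_lambda <- function(tree, values, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(values)))
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("lambda estimation needs >= 3 taxa with values")
  miss <- setdiff(names(values), tree$tip.label)
  if (length(miss) > 0)
    stop("values for tips absent from the tree: ", paste(utils::head(miss), collapse = ", "))
  sub <- ape::keep.tip(tree, names(values))
  C <- ape::vcv(sub)
  C <- C[names(values), names(values)]
  y <- as.numeric(values)

  ll <- function(lam) {
    out <- profile_loglik_lambda(C, y, lam)
    if (!is.finite(out)) {
      out <- profile_loglik_lambda(C, y, lam, ridge = 1e-10)
    }
    out
  }
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = tol)
  # the optimum can sit at a boundary; compare against both endpoints
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  best <- which.max(vals)
  lambda_hat <- cand[best]
  loglik_tree <- vals[best]
  loglik_star <- vals[2]
  lrt <- max(0, 2 * (loglik_tree - loglik_star))
  list(lambda_hat = lambda_hat, loglik_tree = loglik_tree,
       loglik_star = loglik_star, lrt_stat = lrt,
       p = lambda_lrt_p(lrt), n = length(y))
}

#' p-value for the lambda likelihood-ratio test
#'
#' Upper tail of the chi-squared distribution with 1 df at the LRT
#' statistic.  This is conservative at the `lambda = 0` boundary (the usual
#' 50:50 mixture halves the p-value); `mixture = TRUE` applies that
#' correction.
#'
#' @param lrt_stat non-negative LRT statistic.
#' @param mixture use the 50:50 point-mass/chi-squared boundary mixture.
#' @return p-value in \[0, 1\].
#' @export
lambda_lrt_p <- function(lrt_stat, mixture = FALSE) {
  p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- ifelse(lrt_stat == 0, 1, p / 2)
  p
}

#' Average model residuals per taxon
#'
#' Record-level residuals -- deviance residuals for the occurrence model,
#' response residuals for the log-abundance model -- averaged over all
#' records of each taxon.  Taxa with no records are absent from the result.
#'
#' @param fit a `hurdle_fit` (see [fit_occurrence()], [fit_abundance()]).
#' @param data the model data the fit was produced from (with `taxon_id`).
#' @return named numeric vector of per-taxon mean residuals.
#' @export
residuals_by_taxon <- function(fit, data) {
  type <- if (fit$spec$response == "occurrence") "deviance" else "response"
  r <- stats::residuals(fit$model, type = type)
  tapply(r, data$taxon_id[seq_along(r)], mean)
}

#' Spatial weights from site coordinates
#'
#' Inverse great-circle distance weights with zero diagonal, row
#' standardized; coincident sites get a 1 m distance floor.  `scheme =
#' "knn"` instead links each site to its `k` nearest neighbours with equal
#' weights.
#'
#' @param coords matrix/data.frame of `lon`, `lat` in decimal degrees.
#' @param scheme `"idw"` (default) or `"knn"`.
#' @param k neighbours for `"knn"`.
#' @return n x n row-standardized weight matrix.
#' @export
spatial_weights <- function(coords, scheme = c("idw", "knn"), k = 4) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords[, c("lon", "lat")])
  n <- nrow(coords)
  D <- geosphere::distm(coords)  # metres, great-circle
  D[D < 1] <- 1                  # floor for coincident sites
  diag(D) <- Inf
  if (scheme == "idw") {
    W <- 1 / D
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[seq_len(min(k, n - 1))]
      W[i, nb] <- 1
    }
  }
  diag(W) <- 0
  W / rowSums(W)
}

#' Moran's I with randomization variance
#'
#' `I = (n / S0) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)` with `z` the
#' centred residuals.  The expectation is `-1/(n-1)`; the variance is the
#' standard randomization-assumption formula (using S1, S2 and the sample
#' kurtosis), from which a two-sided normal p-value is computed.  The
#' variance formula requires `n >= 4`; for `n = 3` the statistic is
#' returned with `p = NA`.
#'
#' @param residuals numeric vector (length n >= 3, non-constant).
#' @param coords data.frame with `lon`, `lat` (site order matching
#'   `residuals`), ignored when `W` is supplied.
#' @param W optional pre-built weight matrix (see [spatial_weights()]).
#' @param ... passed to [spatial_weights()].
#' @return list with `n`, `I`, `expected`, `variance`, `p`.
#' @export
morans_i <- function(residuals, coords = NULL, W = NULL, ...) {
  n <- length(residuals)
  if (n < 3) stop("Moran's I needs >= 3 sites")
  if (stats::sd(residuals) == 0) stop("constant residuals")
  if (is.null(W)) W <- spatial_weights(coords, ...)
  stopifnot(nrow(W) == n, ncol(W) == n)
  z <- residuals - mean(residuals)
  S0 <- sum(W)
  I <- (n / S0) * sum(W * tcrossprod(z)) / sum(z^2)
  EI <- -1 / (n - 1)
  if (n >= 4) {
    S1 <- sum((W + t(W))^2) / 2
    S2 <- sum((rowSums(W) + colSums(W))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
    VI <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    p <- 2 * stats::pnorm(abs(I - EI) / sqrt(VI), lower.tail = FALSE)
  } else {
    VI <- NA_real_
    p <- NA_real_
  }
  list(n = n, I = I, expected = EI, variance = VI, p = p)
}

#' Per-study Moran's I on per-site residuals
#'
#' Averages record-level residuals per site within each study, then runs
#' [morans_i()] study by study.  Studies with fewer than 3 sites or
#' constant residuals are skipped with a recorded reason.
#'
#' @param fit a `hurdle_fit`.
#' @param data the model data (with `study_id`, `site_id`).
#' @param sites site table supplying `site_id`, `lon`, `lat`.
#' @param ... passed to [spatial_weights()].
#' @return data.frame with one row per study: `study_id`, `n_sites`, `I`,
#'   `expected`, `variance`, `p`, `skipped`.
#' @export
moran_by_study <- function(fit, data, sites, ...) {
  type <- if (fit$spec$response == "occurrence") "deviance" else "response"
  r <- stats::residuals(fit$model, type = type)
  df <- data.frame(study_id = data$study_id[seq_along(r)],
                   site_id = data$site_id[seq_along(r)], r = r)
  out <- lapply(split(df, df$study_id), function(st) {
    rs <- tapply(st$r, st$site_id, mean)
    co <- sites[match(names(rs), sites$site_id), c("lon", "lat")]
    res <- tryCatch(morans_i(as.numeric(rs), coords = co, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(study_id = st$study_id[1], n_sites = length(rs),
                 I = NA_real_, expected = NA_real_, variance = NA_real_,
                 p = NA_real_, skipped = res)
    } else {
      data.frame(study_id = st$study_id[1], n_sites = res$n, I = res$I,
                 expected = res$expected, variance = res$variance,
                 p = res$p, skipped = NA_character_)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Meta-test of per-study spatial autocorrelation
#'
#' Fraction of tested studies significant at `alpha`, with a one-sided
#' exact binomial test of whether more studies are flagged than expected by
#' chance.
#'
#' @param results output of [moran_by_study()] (needs a `p` column).
#' @param alpha per-study significance level.
#' @return list with `n_tested`, `n_significant`, `fraction`, `binom_p`.
#' @export
autocorr_meta <- function(results, alpha = 0.05) {
  p <- results$p[!is.na(results$p)]
  if (length(p) < 1) stop("no studies tested")
  k <- sum(p < alpha)
  bt <- stats::binom.test(k, length(p), p = alpha, alternative = "greater")
  list(n_tested = length(p), n_significant = k,
       fraction = k / length(p), binom_p = bt$p.value)
}

#' Refit a model excluding flagged studies
#'
#' Repeats a fit on the data minus the studies with significant residual
#' spatial autocorrelation, and tabulates coefficients side by side.  A
#' contrast undefined in the reduced data (lost factor level) is reported
#' as `NA`, not an error.
#'
#' @param data model data used for the original fit.
#' @param flagged_studies study ids to drop.
#' @param spec the model spec to refit (usually the minimum adequate one).
#' @return list with `fit` (the refit) and `comparison` (data.frame of
#'   term, estimate/SE before and after).
#' @export
refit_excluding <- function(data, flagged_studies, spec) {
  fit_full <- fit_hurdle_stage(data, spec)
  keep <- !(data$study_id %in% flagged_studies)
  reduced <- droplevels(data[keep, , drop = FALSE])
  fit_red <- fit_hurdle_stage(reduced, spec)
  cf <- fit_full$coefficients
  cr <- fit_red$coefficients
  m <- match(cf$term, cr$term)
  comparison <- data.frame(term = cf$term,
                           estimate_all = cf$estimate, se_all = cf$se,
                           estimate_reduced = cr$estimate[m],
                           se_reduced = cr$se[m])
  list(fit = fit_red, comparison = comparison,
       n_dropped_studies = length(unique(data$study_id[!keep])))
}
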