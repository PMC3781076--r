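#' Specification of a synthetic spatial network
#'
#' Ground-truth settings for the generative process of the radius models:
#' nodes placed uniformly in a rectangle, truncated-Gaussian latent radii,
#' a sampled per-node popularity covariate, optional planted communities with
#' a don't-care fraction, and Bernoulli edges from the logistic link model.
#'
#' The defaults emulate the scale of real spatial networks of a few hundred
#' nodes: a 7 x 7 region (dense enough that each node's radius is well
#' constrained by nearby potential partners), radii around 1,
#' moderate spatial and popularity scales (`alpha = 2`, `beta = 0.5`), a
#' community weight `gamma = 3` strong enough to plant detectable structure,
#' Poisson(8) popularity covariates and 30% of nodes in the don't-care group.
#' Communities are planted few and sizeable (4 by default, ~20 nodes each at
#' `n = 120`): the models claim only salient, strongly-integrated groups, so
#' a recovery study plants structure of that kind; the fitting capacity
#' (10% of nodes) deliberately exceeds the planted count, with the don't-care
#' group absorbing the surplus.
#'
#' @param n node count.
#' @param region rectangle side lengths `c(width, height)`.
#' @param alpha,beta,gamma true global parameters (`gamma = 0` together with
#'   `n_comms = 0` gives the Radius-only generator).
#' @param radius_mean,radius_sd truncated-Gaussian radius distribution.
#' @param degree_dist popularity covariate family: `"poisson"` or
#'   `"powerlaw"`.
#' @param degree_mean Poisson mean for `"poisson"`.
#' @param powerlaw_exponent,k_min discrete power-law settings for
#'   `"powerlaw"`.
#' @param n_comms number of planted communities; `NULL` means 4 when
#'   `gamma > 0`, else 0.
#' @param dont_care_fraction probability a node gets the don't-care label 0.
#' @param seed optional integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 120, region = c(7, 7),
                           alpha = 2, beta = 0.5, gamma = 3,
                           radius_mean = 1, radius_sd = 0.3,
                           degree_dist = c("poisson", "powerlaw"),
                           degree_mean = 8, powerlaw_exponent = 2.5,
                           k_min = 1, n_comms = NULL,
                           dont_care_fraction = 0.3, seed = NULL) {
  degree_dist <- match.arg(degree_dist)
  stopifnot(n >= 2, length(region) == 2, all(region > 0),
            alpha > 0, beta > 0, gamma >= 0,
            radius_mean > 0, radius_sd > 0,
            dont_care_fraction >= 0, dont_care_fraction <= 1)
  if (is.null(n_comms)) n_comms <- if (gamma > 0) 4L else 0L
  structure(list(n = as.integer(n), region = as.numeric(region),
                 alpha = alpha, beta = beta, gamma = gamma,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 degree_dist = degree_dist, degree_mean = degree_mean,
                 powerlaw_exponent = powerlaw_exponent, k_min = as.integer(k_min),
                 n_comms = as.integer(n_comms),
                 dont_care_fraction = dont_care_fraction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synthetic_spec")
}

sample_degree_covariate <- function(spec) {
  switch(spec$degree_dist,
    poisson = rpois(spec$n, spec$degree_mean),
    powerlaw = {
      ks <- spec$k_min:max(spec$k_min + 1L, spec$n - 1L)
      sample(ks, spec$n, replace = TRUE, prob = ks^(-spec$powerlaw_exponent))
    })
}

#' Generate a spatial network from the model's generative process
#'
#' Places nodes uniformly in the rectangle, draws latent radii, popularity
#' covariates and community labels, computes the popularity midpoint M from
#' the sampled covariates on a provisional median-probability adjacency, and
#' draws every edge independently as Bernoulli(link probability). The
#' popularity covariate is a sampled attribute: the realised degrees of the
#' generated network need not (and generally do not) reproduce it exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `net` (a [spatial_network()]), `truth`
#'   (a [model_params()] holding the generating parameters, with the
#'   covariate-based M), `covariate_degrees` (the sampled popularity
#'   covariates) and `spec`.
#' @export
generate_network <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  coords <- cbind(runif(n, 0, spec$region[1]), runif(n, 0, spec$region[2]))
  radii <- rtnorm(n, spec$radius_mean, spec$radius_sd)
  k <- sample_degree_covariate(spec)
  comms <- if (spec$n_comms > 0) {
    ifelse(runif(n) < spec$dont_care_fraction, 0L,
           sample.int(spec$n_comms, n, replace = TRUE))
  } else integer(n)
  D <- pairwise_distances(coords)
  up <- upper.tri(D)

  ci <- matrix(comms, n, n)
  logit0 <- spec$alpha * (outer(radii, radii, "+") - D) +
    spec$beta * outer(k, k, "+") +
    community_offset(ci, t(ci), spec$gamma)
  # M from the sampled covariates via the midpoint recipe, applied to a
  # provisional adjacency linking the upper-median-probability pairs
  p0 <- stats::plogis(logit0[up])
  a0 <- p0 > median(p0)
  ksum <- outer(k, k, "+")[up]
  m_const <- if (any(a0) && !all(a0)) {
    (mean(ksum[a0]) + mean(ksum[!a0])) / 2
  } else {
    mean(ksum) # saturated regime: both class averages coincide
  }

  p <- stats::plogis(logit0[up] - spec$beta * m_const)
  draws <- rbinom(length(p), 1L, p)
  adj <- matrix(0L, n, n)
  adj[up] <- draws
  adj <- adj + t(adj)

  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  net <- spatial_network(coords, edges)
  truth <- model_params(spec$alpha, spec$beta, radii, m_const,
                        gamma = spec$gamma, comms = comms)
  list(net = net, truth = truth, covariate_degrees = k, spec = spec)
}

#' Quadrat index of dispersion
#'
#' Variance-to-mean ratio of point counts over a `grid_g x grid_g` partition
#' of the coordinate bounding box: close to 1 under complete spatial
#' randomness, above 1 under spatial clustering.
#'
#' @param coords two-column coordinate matrix.
#' @param grid_g quadrat grid resolution per side (default 10).
#' @return a number.
#' @export
index_of_dispersion <- function(coords, grid_g = 10) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("no points")
  stopifnot(grid_g >= 1)
  cell_of <- function(v) {
    br <- seq(min(v), max(v), length.out = grid_g + 1)
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L), grid_g)
  }
  cx <- cell_of(coords[, 1]); cy <- cell_of(coords[, 2])
  counts <- tabulate((cy - 1L) * grid_g + cx, grid_g^2)
  mu <- mean(counts)
  if (mu == 0) stop("zero mean quadrat count")
  mean((counts - mu)^2) / mu
}

#' Exponential fit to linked distances with a KS diagnostic
#'
#' Maximum-likelihood exponential fit (rate = 1 / mean) to a sample of
#' linked-pair distances, with a one-sample Kolmogorov-Smirnov test against
#' the fitted distribution. The default p-value uses the asymptotic KS
#' distribution, which is optimistic when the rate is estimated from the same
#' data; a parametric-bootstrap p-value is available.
#'
#' @param linked_distances positive distances of linked pairs (length >= 2).
#' @param bootstrap use a parametric bootstrap for the p-value.
#' @param n_boot bootstrap replicates.
#' @return list with `rate`, `statistic`, `p_value`, `method`.
#' @export
exponential_fit_ks <- function(linked_distances, bootstrap = FALSE,
                               n_boot = 200) {
  x <- as.numeric(linked_distances)
  if (length(x) < 2) stop("need at least two distances")
  if (any(x <= 0) || any(!is.finite(x))) stop("distances must be positive and finite")
  rate <- 1 / mean(x)
  ks <- suppressWarnings(ks.test(x, "pexp", rate = rate))
  p <- unname(ks$p.value)
  method <- "asymptotic"
  if (bootstrap) {
    stat_b <- vapply(seq_len(n_boot), function(b) {
      xb <- stats::rexp(length(x), rate)
      suppressWarnings(ks.test(xb, "pexp", rate = 1 / mean(xb))$statistic)
    }, numeric(1))
    p <- (1 + sum(stat_b >= unname(ks$statistic))) / (n_boot + 1)
    method <- "parametric_bootstrap"
  }
  list(rate = rate, statistic = unname(ks$statistic), p_value = p,
       method = method)
}
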