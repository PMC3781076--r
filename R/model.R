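# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' Model parameter set
#'
#' One configuration of all unknowns of the radius models: the global
#' distance scale `alpha`, popularity scale `beta`, community weight `gamma`,
#' the per-node latent radii, the per-node community labels (0 = don't-care)
#' and the popularity midpoint constant `M` (see [compute_m()]).
#'
#' @param alpha,beta positive reals; scale of the spatial and popularity terms.
#' @param gamma nonnegative real community weight; 0 for the Radius model.
#' @param radii positive numeric vector, one latent radius per node.
#' @param comms integer labels in `0..n_comms`; defaults to all 0.
#' @param m_const the popularity midpoint M of the network the parameters
#'   refer to.
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha, beta, radii, m_const, gamma = 0, comms = NULL) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (any(radii <= 0)) stop("all radii must be positive")
  if (!is.finite(m_const)) stop("m_const must be finite")
  if (is.null(comms)) comms <- integer(length(radii))
  comms <- as.integer(comms)
  if (any(comms < 0)) stop("community labels must be nonnegative")
  if (length(comms) != length(radii)) stop("radii and comms length mismatch")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 radii = as.numeric(radii), comms = comms,
                 m_const = m_const),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> alpha=", signif(x$alpha, 4), " beta=", signif(x$beta, 4),
      " gamma=", signif(x$gamma, 4), " M=", signif(x$m_const, 4), "\n", sep = "")
  cat("  ", length(x$radii), " radii in [", signif(min(x$radii), 3), ", ",
      signif(max(x$radii), 3), "]; ",
      sum(x$comms > 0), " nodes in communities\n", sep = "")
  invisible(x)
}

#' Popularity midpoint M
#'
#' The constant that centres the popularity term of the link model: the
#' midpoint between the mean combined degree (`k_i + k_j`) of linked pairs and
#' that of unlinked pairs. Centred this way, the popularity term can both
#' raise and lower the odds of a link.
#'
#' @param net a [spatial_network()].
#' @return a single number.
#' @examples
#' net <- spatial_network(cbind(c(0, 1, 2), 0), rbind(c(1, 2)))
#' compute_m(net) # linked pairs average 2, unlinked 1 -> 1.5
#' @export
compute_m <- function(net) {
  up <- upper.tri(net$adj)
  ksum <- outer(net$deg, net$deg, "+")
  linked <- net$adj == 1L & up
  unlinked <- net$adj == 0L & up
  if (!any(linked) || !any(unlinked))
    stop("degenerate network: M needs at least one linked and one unlinked pair")
  (mean(ksum[linked]) + mean(ksum[unlinked])) / 2
}

#' Community term of the link model
#'
#' Additive logit offset contributed by a pair of community labels: `+gamma`
#' when both nodes share a non-zero label, `-gamma` when they carry different
#' non-zero labels, and 0 whenever either node is in the don't-care group
#' (label 0). Vectorised over labels.
#'
#' @param c_i,c_j nonnegative integer labels.
#' @param gamma nonnegative community weight.
#' @return numeric offset(s).
#' @export
community_offset <- function(c_i, c_j, gamma) {
  if (any(gamma < 0)) stop("gamma must be nonnegative")
  ifelse(c_i > 0 & c_j > 0, ifelse(c_i == c_j, gamma, -gamma), 0)
}

# full n x n logit matrix (diagonal meaningless, set to 0)
logit_matrix <- function(net, params) {
  r <- params$radii
  spatial <- outer(r, r, "+") - net$dist
  popular <- outer(net$deg, net$deg, "+") - params$m_const
  l <- params$alpha * spatial + params$beta * popular
  if (params$gamma > 0 && any(params$comms > 0)) {
    ci <- matrix(params$comms, length(r), length(r))
    l <- l + community_offset(ci, t(ci), params$gamma)
  }
  diag(l) <- 0
  l
}

#' Link logit and probability
#'
#' `link_logit()` evaluates the linear predictor of the link model for a node
#' pair: `alpha * (r_i + r_j - d_ij) + beta * (k_i + k_j - M) +
#' s(c_i, c_j; gamma)`, with `s` the community offset. `link_probability()`
#' is its logistic transform, the model's probability of an edge.
#'
#' @param net a [spatial_network()].
#' @param params a [model_params()].
#' @param i,j distinct node indices (1-based).
#' @return a single number; `link_probability` lies strictly in (0, 1).
#' @export
link_logit <- function(net, params, i, j) {
  if (i == j) stop("self-pairs are excluded from the model")
  d <- net$dist[i, j]
  r <- params$radii
  params$alpha * (r[i] + r[j] - d) +
    params$beta * (net$deg[i] + net$deg[j] - params$m_const) +
    community_offset(params$comms[i], params$comms[j], params$gamma)
}

#' @rdname link_logit
#' @export
link_probability <- function(net, params, i, j) {
  stats::plogis(link_logit(net, params, i, j))
}

#' Link probability matrix
#'
#' All pairwise link probabilities under one parameter configuration
#' (diagonal set to zero; self-pairs are not modelled).
#'
#' @inheritParams link_logit
#' @return symmetric `n x n` numeric matrix.
#' @export
link_probability_matrix <- function(net, params) {
  p <- stats::plogis(logit_matrix(net, params))
  diag(p) <- 0
  p
}

#' Bernoulli log-likelihood of a network under the link model
#'
#' Sum over unordered node pairs of the Bernoulli log-mass
#' `A_ij log p_ij + (1 - A_ij) log(1 - p_ij)` with `p_ij` from
#' [link_probability()].
#'
#' @inheritParams link_logit
#' @return a finite number (probabilities are strictly interior).
#' @export
log_likelihood <- function(net, params) {
  l <- logit_matrix(net, params)
  up <- upper.tri(l)
  sum(net$adj[up] * l[up] - log1pexp(l[up]))
}

## truncated-Gaussian (at zero) helpers ------------------------------------

# log density of N(mean, sd) truncated to (0, Inf)
dtnorm_log <- function(x, mean, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  out <- dnorm(x, mean, sd, log = TRUE) -
    pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out[x <= 0] <- -Inf
  out
}

#' Draw from a zero-truncated Gaussian
#'
#' Samples from `N(mean, sd)` restricted to the positive reals, by inverse-CDF
#' transform. This is the prior (and proposal support) used for every
#' continuous model parameter.
#'
#' @param n number of draws.
#' @param mean,sd Gaussian location and scale before truncation; `sd > 0`.
#' @return numeric vector of positive draws.
#' @export
rtnorm <- function(n, mean, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  p0 <- pnorm(0, mean, sd)
  u <- runif(n, p0, 1)
  pmax(qnorm(u, mean, sd), .Machine$double.xmin)
}

#' Prior specification for the radius models
#'
#' Truncated-Gaussian prior mean and standard deviation for each variable
#' group. Usually built from network statistics via [default_priors()].
#'
#' @param radius,alpha,beta,gamma length-2 numeric vectors `c(mean, sd)`.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(radius, alpha, beta, gamma = c(1, 100)) {
  grp <- function(v, nm) {
    v <- as.numeric(v)
    if (length(v) != 2L || v[2] <= 0 || v[1] < 0)
      stop("prior for ", nm, " must be c(mean >= 0, sd > 0)")
    list(mean = v[1], sd = v[2])
  }
  structure(list(radius = grp(radius, "radius"), alpha = grp(alpha, "alpha"),
                 beta = grp(beta, "beta"), gamma = grp(gamma, "gamma")),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-7s ~ TruncNorm(mean = %.4g, sd = %.4g)\n",
                nm, x[[nm]]$mean, x[[nm]]$sd))
  invisible(x)
}

#' Log posterior density (up to an additive constant)
#'
#' Log-likelihood plus truncated-Gaussian log prior densities of the
#' continuous parameters. With `n_comms > 0` (the Radius+Comms model) the
#' gamma prior and the uniform categorical log-mass over community labels are
#' included; with `n_comms = 0` (the Radius model) gamma and labels carry no
#' prior mass.
#'
#' @inheritParams link_logit
#' @param priors a [prior_spec()].
#' @param n_comms number of non-don't-care community labels available
#'   (0 for the Radius model).
#' @return a number; `-Inf` only for out-of-support parameters.
#' @export
log_posterior <- function(net, params, priors, n_comms = 0L) {
  if (params$alpha <= 0 || params$beta <= 0 || any(params$radii <= 0))
    stop("continuous parameters must be positive")
  lp <- log_likelihood(net, params) +
    dtnorm_log(params$alpha, priors$alpha$mean, priors$alpha$sd) +
    dtnorm_log(params$beta, priors$beta$mean, priors$beta$sd) +
    sum(dtnorm_log(params$radii, priors$radius$mean, priors$radius$sd))
  if (n_comms > 0L) {
    if (params$gamma <= 0) stop("gamma must be positive in the Radius+Comms model")
    lp <- lp + dtnorm_log(params$gamma, priors$gamma$mean, priors$gamma$sd) -
      length(params$comms) * log(n_comms + 1)
  }
  lp
}
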