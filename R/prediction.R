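#' Posterior-predictive link probability
#'
#' The probability of a link between two nodes integrated over the posterior:
#' the mean of [link_probability()] across the retained draws of a trace.
#' Degrees are taken from the observed (training) network, which is not
#' constrained to match the degrees implied by predicted links.
#'
#' @param trace a [run_mcmc()] result (nonempty).
#' @param net the network whose degrees/distances serve as covariates.
#' @param i,j distinct node indices.
#' @return a number in (0, 1).
#' @export
predictive_link_prob <- function(trace, net, i, j) {
  s <- length(trace$log_posterior)
  if (s == 0) stop("empty trace")
  if (i == j) stop("self-pairs are excluded from the model")
  probs <- vapply(seq_len(s), function(k) {
    p <- model_params(trace$alpha[k], trace$beta[k], trace$radii[k, ],
                      trace$m_const, gamma = trace$gamma[k],
                      comms = trace$comms[k, ])
    link_probability(net, p, i, j)
  }, numeric(1))
  mean(probs)
}

#' MAP link probability
#'
#' Link probability with one plugged-in parameter configuration (typically
#' [map_estimate()]).
#'
#' @param params a [model_params()].
#' @inheritParams predictive_link_prob
#' @return a number in (0, 1).
#' @export
map_link_prob <- function(params, net, i, j) {
  link_probability(net, params, i, j)
}

new_score_matrix <- function(scores, method) {
  diag(scores) <- 0
  structure(list(scores = scores, method = method), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  up <- upper.tri(x$scores)
  cat("<score_matrix> method=", x$method, ", ", nrow(x$scores), " nodes, ",
      "scores in [", signif(min(x$scores[up]), 3), ", ",
      signif(max(x$scores[up]), 3), "]\n", sep = "")
  invisible(x)
}

#' Model-based score matrices
#'
#' All pairwise link scores from a fitted model: `"predictive"` averages the
#' probability matrix over the retained posterior draws, `"map"` plugs in the
#' MAP configuration.
#'
#' @param trace a [run_mcmc()] result.
#' @param net network providing the covariates (training degrees, distances).
#' @param type `"predictive"` or `"map"`.
#' @return a `score_matrix` (symmetric probabilities, zero diagonal).
#' @export
model_scores <- function(trace, net, type = c("predictive", "map")) {
  type <- match.arg(type)
  if (length(trace$log_posterior) == 0) stop("empty trace")
  if (type == "map") {
    p <- link_probability_matrix(net, map_estimate(trace))
    return(new_score_matrix(p, "map"))
  }
  s <- length(trace$log_posterior)
  acc <- matrix(0, net$n, net$n)
  for (k in seq_len(s)) {
    pk <- model_params(trace$alpha[k], trace$beta[k], trace$radii[k, ],
                       trace$m_const, gamma = trace$gamma[k],
                       comms = trace$comms[k, ])
    acc <- acc + link_probability_matrix(net, pk)
  }
  new_score_matrix(acc / s, "posterior_predictive")
}

# equal-count distance bins over all unordered pairs; returns per-pair bin id
# and the per-bin empirical link fraction. Bins with no pairs are merged with
# their left neighbour (first bin with the right one).
empirical_distance_profile <- function(net, n_bins) {
  up <- upper.tri(net$dist)
  d <- net$dist[up]
  a <- net$adj[up]
  qs <- quantile(d, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  qs <- unique(qs) # tied distances can collapse quantile breaks
  # merge any remaining empty bin with a neighbour
  repeat {
    nb <- length(qs) - 1
    bin <- findInterval(d, qs, rightmost.closed = TRUE, left.open = TRUE)
    counts <- tabulate(bin, nb)
    if (all(counts > 0) || nb == 1) break
    e <- which(counts == 0)[1]
    qs <- if (e == nb) qs[-e] else qs[-(e + 1)]
  }
  f <- vapply(seq_len(nb), function(b) mean(a[bin == b]), numeric(1))
  list(breaks = qs, f = f)
}

#' Baseline link-score matrices
#'
#' Spatial and degree null models used as link-prediction baselines, each an
#' expected-edge matrix normalised to the observed edge count and clipped to
#' probabilities:
#' \describe{
#'   \item{pa}{configuration model, `E_ij = k_i k_j / (2m)`.}
#'   \item{expdist}{exponential distance decay,
#'     `E_ij` proportional to `k_i k_j exp(-d_ij / lambda)` with `lambda` the
#'     mean linked-pair distance, scaled so the unordered-pair sum equals `m`.}
#'   \item{empdist}{empirical distance decay (deterrence function):
#'     `E_ij` proportional to `k_i k_j f(bin(d_ij))` with `f` the linked
#'     fraction in equal-count distance bins, scaled the same way.}
#' }
#' Expectations above 1 are thresholded to 1 (after normalisation).
#'
#' @param net a [spatial_network()] with at least one edge.
#' @param method one of `"pa"`, `"expdist"`, `"empdist"`.
#' @param n_bins number of equal-count distance bins for `empdist`.
#' @param use_degrees include the degree product in the distance baselines
#'   (the distance-only variants are obtained with `FALSE`).
#' @param clip threshold entries at 1 (set `FALSE` to obtain the raw
#'   normalised expectations, e.g. as a modularity null matrix).
#' @return a `score_matrix`.
#' @export
baseline_scores <- function(net, method = c("pa", "expdist", "empdist"),
                            n_bins = 10, use_degrees = TRUE, clip = TRUE) {
  method <- match.arg(method)
  if (net$m == 0) stop("baselines need at least one edge")
  k <- net$deg
  if (all(outer(k, k) == 0)) warning("all degree products are zero; degenerate scores")
  up <- upper.tri(net$dist)
  raw <- switch(method,
    pa = outer(k, k) / (2 * net$m),
    expdist = {
      lambda <- mean(net$dist[up & net$adj == 1L])
      base <- exp(-net$dist / lambda)
      if (use_degrees) base <- outer(k, k) * base
      base
    },
    empdist = {
      prof <- empirical_distance_profile(net, n_bins)
      bin <- findInterval(net$dist, prof$breaks, rightmost.closed = TRUE,
                          left.open = TRUE)
      base <- matrix(prof$f[bin], net$n, net$n)
      if (use_degrees) base <- outer(k, k) * base
      base
    })
  diag(raw) <- 0
  if (method != "pa") {
    tot <- sum(raw[up])
    if (tot <= 0) stop("degenerate ", method, " expectations (zero total)")
    raw <- raw * net$m / tot
  }
  if (clip) raw <- pmin(raw, 1)
  new_score_matrix(raw, method)
}

#' Export a score matrix as an edge-score table
#'
#' @param sm a `score_matrix`.
#' @param net the network giving node ids.
#' @param path output file (tab-separated, header `node_i`, `node_j`, `score`).
#' @param pairs optional 2-column index matrix of the pairs to write;
#'   defaults to all unordered pairs.
#' @return invisibly, the data frame written.
#' @export
write_scores <- function(sm, net, path, pairs = NULL) {
  if (is.null(pairs)) pairs <- which(upper.tri(sm$scores), arr.ind = TRUE)
  df <- data.frame(node_i = net$ids[pairs[, 1]], node_j = net$ids[pairs[, 2]],
                   score = sm$scores[pairs])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
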