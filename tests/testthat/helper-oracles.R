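# Small fixture networks and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (per-pair loops, full enumeration) so
# they stay independent of the vectorised implementation paths.

toy3 <- function() {
  # 3 nodes on a line, single edge 1-2
  spatial_network(cbind(c(0, 1, 2), 0), rbind(c(1, 2)))
}

path4 <- function() {
  spatial_network(cbind(0:3, 0), rbind(c(1, 2), c(2, 3), c(3, 4)))
}

two_cliques <- function(k = 4, gap = 10) {
  n <- 2 * k
  coords <- rbind(cbind(runif(k), runif(k)),
                  cbind(runif(k) + gap, runif(k)))
  e <- rbind(t(combn(1:k, 2)), t(combn((k + 1):n, 2)))
  spatial_network(coords, e)
}

random_net <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, 5), runif(n, 0, 5))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  spatial_network(coords, pairs[keep, , drop = FALSE])
}

random_params <- function(net, gamma = 0, n_comms = 0, seed = 1) {
  set.seed(seed)
  model_params(alpha = runif(1, 0.5, 3), beta = runif(1, 0.05, 0.5),
               radii = runif(net$n, 0.2, 2), m_const = 1.234,
               gamma = gamma,
               comms = if (n_comms > 0) sample(0:n_comms, net$n, TRUE)
                       else integer(net$n))
}

# per-pair Bernoulli log-mass sum, scalar loop
loglik_oracle <- function(net, params) {
  s <- 0
  for (i in seq_len(net$n - 1)) {
    for (j in (i + 1):net$n) {
      p <- link_probability(net, params, i, j)
      s <- s + if (net$adj[i, j] == 1L) log(p) else log(1 - p)
    }
  }
  s
}

# midpoint-of-combined-degree constant by scalar enumeration
compute_m_oracle <- function(net) {
  lk <- c(); ul <- c()
  for (i in seq_len(net$n - 1)) {
    for (j in (i + 1):net$n) {
      s <- net$deg[i] + net$deg[j]
      if (net$adj[i, j] == 1L) lk <- c(lk, s) else ul <- c(ul, s)
    }
  }
  (mean(lk) + mean(ul)) / 2
}

# modularity by double loop over ordered pairs
modularity_oracle <- function(net, partition, P) {
  q <- 0
  for (i in seq_len(net$n)) {
    for (j in seq_len(net$n)) {
      if (i != j && partition[i] == partition[j])
        q <- q + net$adj[i, j] - P[i, j]
    }
  }
  q / (2 * net$m)
}

# all set partitions of n elements as restricted-growth label vectors
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (l in seq_len(mx + 1)) rec(c(labels, l), max(mx, l))
  }
  rec(1L, 1L)
  out
}

# exact posterior marginals of the radii on a regular grid, alpha/beta fixed
grid_radius_marginals <- function(net, alpha, beta, grid_g, upper,
                                  r_mean, r_sd) {
  edges <- seq(0, upper, length.out = grid_g + 1)
  mid <- (edges[-1] + edges[-(grid_g + 1)]) / 2
  m_const <- compute_m(net)
  grid <- as.matrix(do.call(expand.grid, rep(list(mid), net$n)))
  lp <- apply(grid, 1, function(r) {
    p <- model_params(alpha, beta, r, m_const)
    log_likelihood(net, p) +
      sum(dnorm(r, r_mean, r_sd, log = TRUE) -
            pnorm(0, r_mean, r_sd, lower.tail = FALSE, log.p = TRUE))
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  marg <- lapply(seq_len(net$n), function(i)
    as.numeric(tapply(w, factor(grid[, i], levels = mid), sum)))
  list(edges = edges, mid = mid, marginals = marg)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# pinned-scalar priors: near-degenerate alpha/beta so only radii move
pinned_priors <- function(alpha, beta, r_mean, r_sd) {
  prior_spec(radius = c(r_mean, r_sd), alpha = c(alpha, 1e-9),
             beta = c(beta, 1e-9))
}
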