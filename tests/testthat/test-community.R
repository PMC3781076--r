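fake_comms_trace <- function(lp, label_rows, n_comms = 5) {
  s <- length(lp)
  n <- ncol(label_rows)
  structure(list(alpha = rep(1, s), beta = rep(0.1, s), gamma = rep(2, s),
                 log_posterior = lp, radii = matrix(1, s, n),
                 comms = label_rows, m_const = 1,
                 config = mcmc_config(n_comms = n_comms), n_nodes = n),
            class = "posterior_trace")
}

test_that("MAP community extraction relabels canonically and validates input", {
  tr <- fake_comms_trace(c(-4, -1, -7),
                         rbind(c(0L, 2L, 2L, 1L), c(0L, 7L, 7L, 4L),
                               c(1L, 1L, 1L, 1L)))
  part <- extract_map_communities(tr)
  expect_equal(as.integer(part), c(0L, 1L, 1L, 2L)) # from the argmax row
  # idempotent canonical relabelling
  tr2 <- fake_comms_trace(-1, matrix(as.integer(part), 1))
  expect_equal(as.integer(extract_map_communities(tr2)), as.integer(part))
  all0 <- fake_comms_trace(-1, matrix(0L, 1, 4))
  expect_equal(as.integer(extract_map_communities(all0)), rep(0L, 4))
  radius_only <- fake_comms_trace(-1, matrix(0L, 1, 4), n_comms = 0)
  expect_error(extract_map_communities(radius_only), "Radius model")
})

test_that("null expectation matrices follow their definitions", {
  net <- random_net(10, 0.4, seed = 21)
  P <- null_expectation_matrix(net, "pa")
  ref <- outer(net$deg, net$deg) / (2 * net$m); diag(ref) <- 0
  expect_equal(P, ref)
  fitted <- random_params(net, seed = 2)
  Pm <- null_expectation_matrix(net, "radius_map", fitted = fitted)
  expect_equal(Pm, link_probability_matrix(net, fitted))
  up <- upper.tri(Pm)
  expect_true(all(Pm[up] > 0 & Pm[up] < 1))
  for (m in c("pa", "expdist", "empdist"))
    expect_equal(null_expectation_matrix(net, m),
                 t(null_expectation_matrix(net, m)))
  expect_error(null_expectation_matrix(net, "radius_map"), "fitted")
})

test_that("modularity matches the brute-force oracle and rejects label 0", {
  net3 <- path4()
  P <- null_expectation_matrix(net3, "pa")
  one <- rep(1L, 4)
  expect_equal(modularity_score(net3, one, P),
               modularity_oracle(net3, one, P))
  # two disconnected triangles under the pa null, true split
  tri2 <- spatial_network(rbind(c(0, 0), c(1, 0), c(0.5, 1),
                                c(5, 0), c(6, 0), c(5.5, 1)),
                          rbind(c(1, 2), c(1, 3), c(2, 3),
                                c(4, 5), c(4, 6), c(5, 6)))
  Pt <- null_expectation_matrix(tri2, "pa")
  split <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(modularity_score(tri2, split, Pt),
               modularity_oracle(tri2, split, Pt))
  # singletons score zero: no within-community ordered pairs remain
  expect_equal(modularity_score(tri2, 1:6, Pt), 0)
  expect_error(modularity_score(tri2, c(0L, split[-1]), Pt), "don't-care")
})

test_that("pa-null modularity relates to the textbook convention (igraph)", {
  skip_if_not_installed("igraph")
  for (s in 1:4) {
    net <- random_net(10, 0.35, seed = 100 + s)
    if (net$m < 3) next
    P <- null_expectation_matrix(net, "pa")
    g <- igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
    part <- sample(1:3, 10, replace = TRUE)
    # textbook modularity includes the i = j null diagonal; ours excludes
    # self-pairs, differing by exactly sum(k^2) / (4 m^2)
    expect_equal(modularity_score(net, part, P),
                 igraph::modularity(g, part) +
                   sum(net$deg^2) / (4 * net$m^2))
  }
})

test_that("greedy optimisation recovers planted cliques and never trails singletons", {
  set.seed(14)
  net <- two_cliques(4)
  P <- null_expectation_matrix(net, "pa")
  part <- optimize_modularity_greedy(net, P, seed = 4)
  expect_equal(as.integer(part), rep(c(1L, 2L), each = 4))
  # exhaustive search over all partitions of the 8 nodes confirms optimality
  best <- max(vapply(enumerate_partitions(8),
                     function(l) modularity_score(net, l, P), numeric(1)))
  expect_equal(modularity_score(net, part, P), best)
  # improvement guarantee over singletons, any network
  net2 <- random_net(12, 0.3, seed = 33)
  P2 <- null_expectation_matrix(net2, "expdist")
  p2 <- optimize_modularity_greedy(net2, P2, seed = 5)
  expect_gte(modularity_score(net2, p2, P2),
             modularity_score(net2, 1:12, P2))
  expect_identical(as.integer(optimize_modularity_greedy(net2, P2, seed = 5)),
                   as.integer(p2))
})

test_that("NMI follows the arithmetic-mean normalisation with its conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1) # label permutation
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0) # independent
  expect_equal(nmi(c(1, 1, 1, 1), c(1, 2, 1, 2)), 0) # zero entropy
  set.seed(6)
  a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_equal(nmi(a, b), nmi(b, a))
  # restricted variant drops nodes outside the subset first
  expect_equal(nmi(a, b, restrict_to = 1:10), nmi(a[1:10], b[1:10]))
  expect_error(nmi(a, b, restrict_to = integer(0)), "empty")
  expect_error(nmi(a, b[1:10]), "same nodes")
})

test_that("NMI agrees with igraph's implementation on proper partitions", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (r in 1:4) {
    a <- sample(1:4, 40, TRUE); b <- sample(1:4, 40, TRUE)
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"))
  }
})

test_that("planted communities are recovered from Radius+Comms fits", {
  hits <- 0
  for (s in 1:5) {
    sim <- generate_network(synthetic_spec(n = 100, seed = 300 + s))
    cfg <- mcmc_config(n_iter = 2500, n_comms = 10, init_chain_iter = 300,
                       seed = 400 + s)
    tr <- run_mcmc(sim$net, cfg, degrees = sim$covariate_degrees,
                   m_const = sim$truth$m_const)
    part <- extract_map_communities(tr)
    sub <- which(part > 0 & sim$truth$comms > 0)
    if (length(sub) > 10 && nmi(part, sim$truth$comms, sub) >= 0.8)
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})
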