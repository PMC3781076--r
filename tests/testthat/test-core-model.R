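test_that("pairwise distances are euclidean, symmetric and validated", {
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(pairwise_distances(rbind(c(1, 1), c(1, 1)))[1, 2], 0)
  set.seed(2)
  d <- pairwise_distances(matrix(rnorm(20), 10, 2))
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 10))
  expect_true(all(d >= 0))
  expect_error(pairwise_distances(rbind(c(0, NA), c(1, 1))), "non-finite")
  expect_error(pairwise_distances(rbind(c(0, 1))), "two nodes")
})

test_that("haversine distances match geosphere on lon/lat coordinates", {
  ll <- rbind(c(0, 0), c(0, 1), c(10, 45))
  d <- pairwise_distances(ll, "haversine")
  expect_equal(d[1, 2], geosphere::distHaversine(ll[1, ], ll[2, ]) / 1000)
  expect_equal(d, t(d))
})

test_that("popularity midpoint M matches hand and brute-force enumeration", {
  expect_equal(compute_m(toy3()), 1.5) # linked mean 2, unlinked mean 1
  expect_equal(compute_m(path4()), compute_m_oracle(path4()))
  for (s in 1:5) {
    net <- random_net(7, 0.5, seed = s)
    if (net$m >= 1 && net$m < choose(7, 2))
      expect_equal(compute_m(net), compute_m_oracle(net))
  }
  # regular graph: every pair has combined degree 2k, both averages equal
  ring <- spatial_network(cbind(cos(2 * pi * (0:4) / 5),
                                sin(2 * pi * (0:4) / 5)),
                          rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)))
  expect_equal(compute_m(ring), 4)
})

test_that("degenerate networks for M raise an error", {
  empty <- spatial_network(cbind(0:2, 0), NULL)
  full <- spatial_network(cbind(0:2, 0), rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_error(compute_m(empty), "degenerate")
  expect_error(compute_m(full), "degenerate")
})

test_that("community offset follows same/different/don't-care semantics", {
  expect_equal(community_offset(3, 3, 2), 2)
  expect_equal(community_offset(2, 3, 2), -2)
  expect_equal(community_offset(0, 5, 2), 0)
  expect_equal(community_offset(5, 0, 2), 0)
  expect_equal(community_offset(0, 0, 2), 0)
  expect_equal(community_offset(c(1, 1, 0), c(1, 2, 9), 1.5), c(1.5, -1.5, 0))
  expect_error(community_offset(1, 1, -1), "nonnegative")
})

test_that("link logit composes spatial, popularity and community terms", {
  net <- toy3() # distances 1, 1, 2; degrees 1, 1, 0; M = 1.5
  p <- model_params(alpha = 1, beta = 1e-12, radii = c(0.5, 0.5, 0.5),
                    m_const = compute_m(net))
  # r_i + r_j = d_ij = 1, beta 0 -> logit 0, probability one half
  expect_equal(link_logit(net, p, 1, 2), 0)
  expect_equal(link_probability(net, p, 1, 2), 0.5)
  # alpha 1, radii 1, d = 4, no popularity/communities -> logit -2
  net2 <- spatial_network(rbind(c(0, 0), c(4, 0), c(1, 0)),
                          rbind(c(1, 3)))
  p2 <- model_params(1, 1e-12, radii = c(1, 1, 1), m_const = compute_m(net2))
  expect_equal(link_logit(net2, p2, 1, 2), -2, tolerance = 1e-6)
  expect_equal(link_probability(net2, p2, 1, 2), 1 / (1 + exp(2)),
               tolerance = 1e-6)
  expect_error(link_logit(net, p, 2, 2), "self")
})

test_that("link probabilities are symmetric, interior and monotone", {
  net <- random_net(8, 0.4, seed = 3)
  pr <- random_params(net, gamma = 1.2, n_comms = 3, seed = 4)
  P <- link_probability_matrix(net, pr)
  expect_equal(P, t(P))
  up <- upper.tri(P)
  expect_true(all(P[up] > 0 & P[up] < 1))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(link_logit(net, pr, i, j), link_logit(net, pr, j, i))
  # increasing r_i never decreases any probability involving i
  pr2 <- pr; pr2$radii[1] <- pr$radii[1] + 0.7
  P2 <- link_probability_matrix(net, pr2)
  expect_true(all(P2[1, -1] > P[1, -1]))
  expect_true(all(P2[-1, -1][upper.tri(P2[-1, -1])] ==
                    P[-1, -1][upper.tri(P[-1, -1])]))
  # strictly decreasing in distance: farther pair scores lower, params equal
  base <- pr$alpha * (2 - c(1, 3))
  expect_true(plogis(base[2]) < plogis(base[1]))
})

test_that("log-likelihood equals the independent-pair oracle exhaustively", {
  # single-pair sanity: one edge at logit zero
  net <- spatial_network(rbind(c(0, 0), c(1, 0)), rbind(c(1, 2)))
  p <- model_params(1, 1e-12, radii = c(0.5, 0.5), m_const = 0)
  expect_equal(log_likelihood(net, p), log(0.5), tolerance = 1e-6)
  for (n in 3:6) for (s in 1:3) {
    net <- random_net(n, 0.5, seed = 10 * n + s)
    pr <- random_params(net, gamma = 0.8, n_comms = 2, seed = s)
    expect_equal(log_likelihood(net, pr), loglik_oracle(net, pr))
  }
})

test_that("log-posterior adds prior terms and matches hand enumeration", {
  net <- toy3()
  priors <- prior_spec(radius = c(1, 0.5), alpha = c(1, 1), beta = c(1, 1),
                       gamma = c(1, 2))
  for (a in c(0.5, 2)) {
    p <- model_params(a, 0.3, radii = c(0.8, 1.1, 0.9),
                      m_const = compute_m(net), gamma = 1, comms = c(1, 1, 0))
    hand <- loglik_oracle(net, p) +
      sum(dnorm(c(a, 0.3, 1, p$radii), c(1, 1, 1, 1, 1, 1),
                c(1, 1, 2, 0.5, 0.5, 0.5), log = TRUE) -
            pnorm(0, c(1, 1, 1, 1, 1, 1), c(1, 1, 2, 0.5, 0.5, 0.5),
                  lower.tail = FALSE, log.p = TRUE)) -
      3 * log(3) # uniform categorical over {0, 1, 2}
    expect_equal(log_posterior(net, p, priors, n_comms = 2), hand)
  }
  # posterior differences with flat priors approach likelihood differences
  flat <- prior_spec(radius = c(0, 1e8), alpha = c(0, 1e8), beta = c(0, 1e8))
  p1 <- random_params(net, seed = 1); p2 <- random_params(net, seed = 2)
  expect_equal(log_posterior(net, p1, flat) - log_posterior(net, p2, flat),
               log_likelihood(net, p1) - log_likelihood(net, p2),
               tolerance = 1e-6)
})

test_that("gamma = 0 or all-don't-care labels reproduce the Radius model exactly", {
  for (s in 1:5) {
    net <- random_net(9, 0.4, seed = s)
    base <- random_params(net, seed = s)
    with_labels <- base
    with_labels$comms <- sample(0:3, net$n, replace = TRUE)
    with_labels$gamma <- 0
    expect_identical(link_probability_matrix(net, with_labels),
                     link_probability_matrix(net, base))
    zero_labels <- base
    zero_labels$gamma <- 2.5
    zero_labels$comms <- integer(net$n)
    expect_identical(link_probability_matrix(net, zero_labels),
                     link_probability_matrix(net, base))
  }
})
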