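# spatialreach

Bayesian node-centric models of spatial networks. Instead of assuming one
global link-cost function over distance, every node $i$ carries a latent
positive **spatial reach** $r_i$; an edge between nodes $i$ and $j$ is a
Bernoulli draw with

$$
\Pr(A_{ij}=1) = \sigma\big(\alpha\,(r_i + r_j - d_{ij}) +
\beta\,(k_i + k_j - M) + s(c_i, c_j;\gamma)\big),
$$

where $d_{ij}$ is the pairwise distance, $k_i$ the observed degree, $M$ the
midpoint between the mean combined degrees of linked and unlinked pairs, and
$s$ an optional community term: $+\gamma$ for a shared non-zero label,
$-\gamma$ for differing non-zero labels, and $0$ whenever either node is in
the *don't-care* group (label 0). With the community term switched off this
is the **Radius** model; with it, **Radius+Comms**, which claims only
community structure that distance and popularity cannot explain. All
continuous parameters get zero-truncated Gaussian priors built from network
statistics, and the posterior is sampled by Metropolis-within-Gibbs (C++
core): random-walk updates for the scalars and radii, exact Gibbs for the
labels.

The package is for anyone analysing networks embedded in space — neuronal
wiring, transportation, infrastructure, geo-located social ties — who wants
node-level spatial effects, link prediction, or community detection with
spatially-aware null models. It provides:

* `spatial_network()` / `read_network()` — the data container (coordinates,
  adjacency, distances, degrees; euclidean or haversine metrics);
* `run_mcmc()`, `map_estimate()` — posterior inference for both models;
* `model_scores()`, `baseline_scores()` — posterior-predictive / MAP link
  scores and the PA (configuration model), ExpDist and EmpDist
  (deterrence-function) baselines;
* `evaluate_link_prediction()` — 10-fold cross-validated AUC with
  quantile-resolved reports by distance and combined degree;
* `extract_map_communities()`, `optimize_modularity_greedy()`,
  `modularity_score()`, `nmi()` — community extraction and comparison under
  pluggable null matrices;
* `synthetic_spec()` / `generate_network()` — the model's generative
  process, for parameter-recovery studies;
* `index_of_dispersion()`, `exponential_fit_ks()` — spatial diagnostics.

A thin command-line surface over these functions ships in
`inst/cli/spatialreach.R` (subcommands `fit`, `predict`, `evaluate`,
`communities`, `simulate`, `eda`).

## Worked example

Generate a network from the model's own generative process, fit
Radius+Comms, and inspect what was recovered:

```r
library(spatialreach)

sim <- generate_network(synthetic_spec(n = 100, seed = 42))
sim$net
#> <spatial_network> 100 nodes, 952 edges (euclidean distances)
#>   mean degree 19.04; mean linked distance 2.041

fit <- run_mcmc(sim$net,
                mcmc_config(n_iter = 3000, n_comms = 10, seed = 1),
                degrees = sim$covariate_degrees,
                m_const = sim$truth$m_const)
fit
#> <posterior_trace> 300 retained draws, Radius+Comms model
#>   log-posterior [-1329.1, -1277.74]
#>   acceptance: global 0.308, radius 0.297

round(c(alpha = mean(fit$alpha), beta = mean(fit$beta),
        gamma = mean(fit$gamma)), 2)
#> alpha  beta gamma
#>  1.90  0.55  2.86
```

The posterior means sit close to the generating values
(`alpha = 2, beta = 0.5, gamma = 3`). The MAP labels recover the planted
communities on the nodes both place into communities:

```r
part <- extract_map_communities(fit)
sub <- which(part > 0 & sim$truth$comms > 0)
round(nmi(part, sim$truth$comms, restrict_to = sub), 2)
#> [1] 0.98
```

Link prediction against the spatial null models (here 4 folds to keep the
example quick; the full protocol uses 10):

```r
ev <- evaluate_link_prediction(
  sim$net, methods = c("radius", "pa", "expdist", "empdist"),
  n_folds = 4, config = mcmc_config(n_iter = 1500, n_comms = 0,
                                    init_chain_iter = 200),
  seed = 7)
aggregate(auc ~ method, ev$overall, mean)
#>    method       auc
#> 1 empdist 0.8925321
#> 2 expdist 0.8918072
#> 3      pa 0.7411493
#> 4  radius 0.9138540
```

The latent-radius model outperforms the distance-decay baselines, and the
configuration model (`pa`) — which ignores space — trails far behind. The
quantile report (`ev$quantiles`) shows the gap is widest for low-degree
pairs, where degree-driven models have nothing to go on.

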