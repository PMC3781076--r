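---
title: "Latent-radius models for spatial networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-radius models for spatial networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialreach)
```

## The model

A spatial network is an undirected simple graph whose nodes carry 2-D
coordinates. The defining empirical fact about such networks — neuronal
wiring, airline routes, geo-located social ties — is that link probability
decays with distance, but not through any single global cost function: the
same distance is cheap for one node and prohibitive for another, depending on
its local surroundings. The models in this package make that heterogeneity
explicit by attaching to every node $i$ a latent positive scalar $r_i$, its
*spatial reach*: how far node $i$'s connections tend to extend.

The **Radius** model states that an edge between $i$ and $j$ is a Bernoulli
draw with

$$
\Pr(A_{ij} = 1) \;=\;
\sigma\!\bigl(\alpha\,(r_i + r_j - d_{ij}) \;+\;
\beta\,(k_i + k_j - M)\bigr),
$$

where $\sigma$ is the logistic function, $d_{ij}$ the Euclidean distance,
$k_i$ the observed degree (treated as a conditioned-upon covariate, never
constrained to match the degrees implied by predictions), $\alpha, \beta > 0$
global scales, and $M$ the *popularity midpoint*: the midpoint between the
mean combined degree $k_i + k_j$ of linked pairs and that of unlinked pairs.
Centring at $M$ lets the popularity term push probabilities both up and down.
The quantity $r_i + r_j - d_{ij}$ is the *radius-corrected distance*: if the
two reaches jointly cover the gap, the spatial term favours the link.

The **Radius+Comms** model adds a discrete label $c_i \in \{0, 1, \dots, K\}$
per node and a positive weight $\gamma$, contributing
$s(c_i, c_j) = +\gamma$ when $c_i = c_j \neq 0$, $-\gamma$ when
$0 \neq c_i \neq c_j \neq 0$, and $0$ whenever either label is $0$. Label 0
is the *don't-care* group: its members' links follow the spatial/popularity
terms alone. This reward/penalty symmetry and the don't-care escape hatch
mean the model claims only communities that the spatial and popularity terms
cannot explain — salient, strongly integrated groups — rather than forcing a
full partition. The label capacity is set generously to
$K = \lceil 0.1\,n \rceil$; surplus capacity is harmless because unused
labels simply stay empty.

Setting $\gamma = 0$ (or all labels to 0) reproduces the Radius model
exactly; the package treats the Radius model as the $K = 0$ special case of
one implementation.

## Priors and inference

All continuous parameters are positive, so every prior is a Gaussian
truncated at zero. The prior recipe adapts to the distance units of the
data:

| parameter | mean | sd |
|---|---|---|
| $r_i$ | $d_{\mathrm{med}}/2$ | $d_{\mathrm{med}}$ |
| $\alpha$ | $10/d_{\mathrm{max}}$ | $100/d_{\mathrm{max}}$ |
| $\beta$ | $10/d_{\mathrm{max}}$ | $100/d_{\mathrm{max}}$ |
| $\gamma$ | $1$ | $100$ |

with $d_{\mathrm{med}}$ and $d_{\mathrm{max}}$ the median and maximum
distance over *linked* pairs. The radius prior is kept deliberately modest so
reaches are not overestimated a priori; the scale priors are weak, letting
the data dominate. The $\gamma$ prior is unit-free because the community
offset already lives on the logit scale. Labels carry a uniform categorical
prior over $\{0, \dots, K\}$.

Posterior computation is Metropolis-within-Gibbs (C++ core). One sweep:

1. each global scalar ($\alpha$, $\beta$, and $\gamma$ when $K > 0$) takes a
   Metropolis step with a zero-reflected Gaussian random walk ($x' = |x +
   \varepsilon|$, symmetric, so no Hastings correction);
2. each radius $r_i$ takes the same kind of reflected step, with a
   per-group shared step size;
3. each label $c_i$ is resampled exactly from its full conditional over
   $\{0,\dots,K\}$ (Gibbs; computable in $O(n)$ per node because only the
   three offset values $0, \pm\gamma$ occur).

We update each global scalar separately rather than as a joint block: a
joint proposal tuned to a sensible overall acceptance rate moves each
coordinate too slowly, and the per-scalar updates reach a stable posterior
in a few thousand sweeps.

Step sizes start at a tenth of each prior sd and are adapted every 25 sweeps
of the burn-in toward ~30% acceptance (multiplicative factor
$e^{2(\text{rate} - 0.3)}$, clamped to $[0.5, 2]$), then frozen, keeping the
post-burn-in chain a valid Markov chain. Defaults: 5,000 sweeps, 50%
burn-in, thinning 5. Chains are initialised by a short 500-sweep pilot chain
whose best-scoring state restarts the main chain. The pilot itself starts
from *data-driven* values — the default-prior recipe evaluated on the
network, clamped into the central region of whatever prior was actually
supplied, with $\gamma$ additionally capped at 1 — plus prior-recipe draws
for the radii and uniform draws for the labels. Starting instead from draws
or means of a weak prior (sd ~100) is a trap with two failure modes we
observed directly: a large initial $\gamma$ instantly collapses the labels
into tiny all-linked cliques (a logistic-separation configuration that
scores far below the data-supported mode but that a random walk cannot
leave), and huge initial radii force $\alpha$ onto the zero boundary. The
priors enter the accept ratios untouched; only the starting point is
data-driven. The recorded log-posterior of every retained state is computed
in the C++ core and verified in the tests against the R-side model
definition.

One mixing caveat: the label configuration reorganises on a slow timescale
(coordinated relabellings are single-site moves), so $\gamma$'s chain-level
mean wanders between runs by about its posterior sd at 5,000 sweeps.
Analyses that compare posterior means across settings (the prior-robustness
study) therefore pool several chains per setting rather than lengthening a
single chain.

The maximum a-posteriori (MAP) configuration — the retained state with the
highest log-posterior, earliest on ties — is used for point prediction,
community extraction and chain initialisation.

## Link prediction and evaluation

Two model-based scores are available for a candidate pair: the
posterior-predictive probability (the mean of the link probability across
retained draws) and the MAP plug-in probability. Both use the degrees of the
observed (training) network as covariates. Three baselines mirror the null
models common in spatial network analysis: the configuration model
(`pa`, $k_i k_j / 2m$), exponential distance decay (`expdist`,
$\propto k_i k_j e^{-d_{ij}/\lambda}$ with $\lambda$ the mean linked-pair
distance), and the empirical deterrence function (`empdist`,
$\propto k_i k_j f(\text{bin}(d_{ij}))$ with $f$ the linked fraction in
equal-count distance bins, 10 by default; empty bins merge with a
neighbour). The two distance baselines are normalised so their unordered-pair
sum equals the observed edge count, making them expectations; all
expectations above 1 are thresholded to 1. A flag drops the degree product
for the distance-only variants.

Evaluation is 10-fold cross-validation over edges: each fold's training
network is the original minus the held-out 10% of edges (degrees
recomputed), the positives are the held-out edges, and the negatives are all
unlinked pairs of the full network (at these sizes full enumeration is
cheap; nothing is subsampled). AUC is the Mann–Whitney statistic with ties
counted one half. Quantile-resolved reports split the evaluated pairs into
five bins whose boundaries divide the *positives* evenly — by pairwise
distance or by combined training degree — and report the AUC inside each
bin; single-class bins are flagged undefined rather than dropped silently.

## Community extraction and comparison

A Radius+Comms fit yields a partition directly: the MAP state's labels,
canonically renumbered (a per-node posterior-mode rule is exposed as an
alternative; the MAP rule is the default because it corresponds to one
coherent joint configuration). For comparison, modularity
$\tfrac{1}{2m}\sum_{i \neq j} (A_{ij} - P_{ij})\,[c_i = c_j]$ accepts any
expected-edge null matrix $P$: the unclipped `pa`/`expdist`/`empdist`
expectations or the MAP link probabilities of a fitted Radius model. Note
the sum excludes self-pairs; the textbook convention includes the $i = j$
null term, so values differ from e.g. igraph's by exactly
$\sum_i k_i^2 / 4m^2$ under the `pa` null (the test suite pins this
relation). A seeded greedy optimiser (single-node best moves interleaved
with whole-community merges, to local optimality) produces modularity
partitions under any of these nulls; on small graphs the tests verify it
against exhaustive partition search. Partitions are compared by NMI,
normalised by the arithmetic mean of the label entropies (the max-entropy
variant is an option), with zero-entropy partitions scoring 0 by convention;
a restricted variant first drops nodes outside a given subset, e.g. the
nodes the model actually placed into communities.

## The synthetic generator and the validation study

`generate_network()` draws from the model's own generative process: uniform
node placement in a rectangle, truncated-Gaussian radii, a sampled per-node
popularity covariate, planted labels, Bernoulli edges. Two conventions
resolve gaps the model description leaves open:

* **Popularity covariates are sampled attributes, not realised degrees.**
  The model conditions on degree but never constrains realised degree to
  match it, so a self-consistent generator cannot exist; we sample the
  covariate (Poisson(8) by default) and accept that realised degrees are a
  noisy image of it. Consequently, recovery studies must condition the fit
  on the generator's covariate and its midpoint (`run_mcmc(degrees =,
  m_const =)`): fitting against realised degrees estimates a different
  (rescaled) popularity coefficient by construction.
* **M needs an adjacency before one exists.** The generator computes the
  midpoint constant from the sampled covariates on a provisional adjacency
  linking the upper-median-probability pairs (or the overall mean combined
  degree in saturated regimes where that split degenerates).

Default study conditions (chosen once, for identifiability and realism, and
used by the acceptance suite): $n = 120$ nodes in a $7 \times 7$ region,
$\alpha = 2$, $\beta = 0.5$, $\gamma = 3$, radii from TN$(1, 0.3)$, four
planted communities with 30% of nodes don't-care. The density (mean degree
≈ 20) is the regime in which each node has enough potential partners near
its reach boundary to pin its radius; the planted communities are few and
sizeable because the model claims only salient groups. What the generator
does **not** emulate: the spatial clustering of real node placements
(quadrat index of dispersion ≈ 1 here versus 7–23 in real biological and
infrastructure networks), heavy-tailed degree structure, or any geometry of
real distance distributions — so passing recovery tests demonstrates
correctness of the machinery under the model's own assumptions, not fidelity
to any real network.

Validation layers, smallest to largest (sizes chosen to keep the default
suite in minutes):

* brute-force oracles for every summary statistic (M, AUC, NMI, modularity,
  index of dispersion) on hand-enumerable cases;
* exact-posterior agreement: on a 4-node network with $\alpha, \beta$ held
  fixed, MCMC radius marginals match a fully enumerated 15-point grid
  posterior within total-variation distance 0.05; an analogous 3-node label
  enumeration checks the Gibbs stage;
* parameter recovery: ten seeded networks at the default conditions,
  5,000-sweep chains; 90% central intervals are compared against the
  generating $\alpha, \beta, \gamma$;
* prior robustness: shifting all prior means from 10 to 50 (sd 80) moves
  the pooled posterior means (three chains per setting) by well under one
  posterior sd;
* link-prediction ordering: over five seeded networks ($n = 100$,
  1,500-sweep fits inside 10-fold CV), mean AUC orders Radius+Comms ≥
  Radius > {EmpDist, ExpDist, PA}, with the Radius-over-PA gain
  concentrated in the lowest combined-degree quantile.

## Numerical choices and known limitations

* Logistic masses are computed via a stable `log1p(exp(·))`; probabilities
  are strictly interior, so the log-likelihood is always finite.
* Truncated-Gaussian draws use the inverse-CDF transform; densities are
  renormalised by the positive-tail mass.
* The sampler resynchronises its running log-likelihood against a full
  evaluation every sweep, so incremental updates cannot drift.
* Equal-count distance bins collapse under heavily tied distances; collapsed
  or empty bins merge with a neighbour.
* Quadrat counts use the population variance (the variance-to-mean ratio of
  the counts as a finite set), and the bounding box comes from the data
  extent.
* The exponential-fit KS p-value uses the asymptotic distribution even
  though the rate is estimated (optimistic; a parametric bootstrap is
  available).
* **Marginal-posterior attenuation.** Integrating over 120 latent radii and
  labels shifts the marginal posteriors of $\alpha$ and especially $\gamma$
  a few percent below the generating values even when chains are run from
  the truth — a genuine property of the posterior (likelihood profiles at
  the true latents peak exactly at truth), of the errors-in-latent-covariates
  kind. It shrinks with node density and sample size, but at the default
  study conditions the 90% interval for $\gamma$ covers the generating value
  only about half the time (roughly two thirds for $\alpha$; $\beta$ is
  essentially unbiased). Strict interval-coverage checks for $\gamma$ and,
  marginally, $\alpha$ are therefore expected to fail at these sizes, and
  posterior point estimates for them should be read as mildly conservative.
* Directed, weighted or time-evolving networks and coordinates beyond 2-D
  are out of scope.
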