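# renumber non-zero labels by first appearance; 0 (don't-care) preserved
canonical_labels <- function(labels) {
  labels <- as.integer(labels)
  nz <- labels[labels > 0L]
  map <- setNames(seq_along(unique(nz)), unique(nz))
  out <- labels
  out[labels > 0L] <- map[as.character(nz)]
  names(out) <- names(labels)
  as.integer(out)
}

#' Extract the MAP community partition from a Radius+Comms trace
#'
#' Labels of the maximum a-posteriori state, canonically renumbered (label 0,
#' the don't-care group, is preserved; other labels are renumbered by first
#' appearance). An alternative per-node posterior mode is available.
#'
#' @param trace a [run_mcmc()] result fitted with `n_comms > 0`.
#' @param rule `"map"` (labels of the single best state, default) or
#'   `"posterior_mode"` (most frequent label per node across retained draws).
#' @return integer label vector of class `community_partition` with a
#'   `source` attribute.
#' @export
extract_map_communities <- function(trace, rule = c("map", "posterior_mode")) {
  rule <- match.arg(rule)
  if (trace$config$n_comms == 0)
    stop("trace was fitted with the Radius model; no community labels to extract")
  labels <- if (rule == "map") {
    trace$comms[which.max(trace$log_posterior), ]
  } else {
    apply(trace$comms, 2, function(x) as.integer(names(which.max(table(x)))))
  }
  structure(canonical_labels(labels), class = "community_partition",
            source = "radius_comms")
}

#' Null expectation matrix for modularity
#'
#' Pairwise expected-edge matrices to plug into [modularity_score()]:
#' the unclipped baseline expectations (`pa`, `expdist`, `empdist`) or the
#' link probabilities of a fitted Radius model at its MAP configuration
#' (`radius_map`).
#'
#' @param net a [spatial_network()].
#' @param model one of `"pa"`, `"expdist"`, `"empdist"`, `"radius_map"`.
#' @param fitted a [model_params()] (required for `radius_map`).
#' @param n_bins bins for `empdist`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
null_expectation_matrix <- function(net, model = c("pa", "expdist", "empdist",
                                                   "radius_map"),
                                    fitted = NULL, n_bins = 10) {
  model <- match.arg(model)
  if (model == "radius_map") {
    if (is.null(fitted)) stop("radius_map null needs fitted MAP parameters")
    return(link_probability_matrix(net, fitted))
  }
  baseline_scores(net, model, n_bins = n_bins, clip = FALSE)$scores
}

#' Modularity under a pluggable null matrix
#'
#' `(1 / 2m) * sum over ordered pairs i != j of (A_ij - P_ij) [c_i == c_j]`,
#' where `P` is any expected-edge null matrix. Every node must carry a proper
#' community label (no don't-care 0: modularity forces a full assignment).
#'
#' @param net a [spatial_network()].
#' @param partition positive integer label per node.
#' @param null_matrix symmetric expectation matrix `P`.
#' @return a number.
#' @export
modularity_score <- function(net, partition, null_matrix) {
  partition <- as.integer(partition)
  if (any(partition == 0L))
    stop("modularity requires every node assigned (no don't-care label 0)")
  if (length(partition) != net$n) stop("partition length mismatch")
  same <- outer(partition, partition, "==")
  diag(same) <- FALSE
  sum((net$adj - null_matrix)[same]) / (2 * net$m)
}

#' Greedy modularity optimisation with a dense null matrix
#'
#' Local-move heuristic: starting from singletons, repeatedly sweeps nodes in
#' a seeded random order, moving each to the community that maximally
#' improves modularity, interleaved with greedy community merges, until no
#' single-node move or merge improves the score.
#'
#' @param net a [spatial_network()].
#' @param null_matrix expectation matrix from [null_expectation_matrix()].
#' @param seed optional integer seed (node sweep order).
#' @return integer label vector (1-based, no label 0) of class
#'   `community_partition`.
#' @export
optimize_modularity_greedy <- function(net, null_matrix, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  W <- net$adj - null_matrix
  diag(W) <- 0
  labels <- seq_len(n)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    # single-node moves
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        gsum <- rowsum(W[, i], labels) # sum of W[i, j] by community of j
        own <- gsum[rownames(gsum) == as.character(labels[i])]
        best <- which.max(gsum[, 1])
        if (gsum[best, 1] > own + 1e-12) {
          labels[i] <- as.integer(rownames(gsum)[best])
          moved <- TRUE; improved <- TRUE
        }
      }
      if (!moved) break
    }
    # greedy merges of whole communities
    repeat {
      groups <- sort(unique(labels))
      if (length(groups) < 2) break
      B <- rowsum(t(rowsum(W, labels)), labels) # community-by-community W sums
      diag(B) <- -Inf
      best <- arrayInd(which.max(B), dim(B))
      if (B[best] <= 1e-12) break
      a <- groups[best[1]]; b <- groups[best[2]]
      labels[labels == b] <- a
      improved <- TRUE
    }
  }
  structure(canonical_labels(labels), class = "community_partition",
            source = "modularity")
}

#' Normalised mutual information between partitions
#'
#' Mutual information of the label co-occurrence table normalised by the
#' arithmetic mean of the two label entropies (the max-entropy variant is
#' available). Optionally restricted to a node subset first (e.g. the nodes a
#' Radius+Comms fit placed into proper communities).
#'
#' @param p1,p2 integer label vectors over the same node universe.
#' @param restrict_to optional index vector of nodes to compare on.
#' @param normalization `"arithmetic"` (default) or `"max"`.
#' @return a number in `[0, 1]`; 0 when either partition carries no
#'   information (zero entropy).
#' @export
nmi <- function(p1, p2, restrict_to = NULL,
                normalization = c("arithmetic", "max")) {
  normalization <- match.arg(normalization)
  if (length(p1) != length(p2)) stop("partitions must cover the same nodes")
  if (!is.null(restrict_to)) {
    if (length(restrict_to) == 0) stop("empty node subset")
    p1 <- p1[restrict_to]; p2 <- p2[restrict_to]
  }
  n <- length(p1)
  if (n == 0) stop("empty effective node set")
  tab <- table(p1, p2) / n
  px <- rowSums(tab); py <- colSums(tab)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  denom <- if (normalization == "arithmetic") (hx + hy) / 2 else max(hx, hy)
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}
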