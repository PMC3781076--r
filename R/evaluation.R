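#' Cross-validation splits over edges
#'
#' Randomly partitions the edge set into near-equal folds. Each fold yields a
#' training network (the original minus the held-out edges, degrees
#' recomputed) and the held-out edges as positives; the candidate negatives
#' are all unlinked pairs of the full network.
#'
#' @param net a [spatial_network()].
#' @param n_folds number of folds (default 10, i.e. a 90/10 split).
#' @param seed optional integer seed.
#' @return a list of `cv_split` objects with elements `fold`, `train`
#'   (network), `heldout` (2-column index matrix), `negatives`
#'   (2-column index matrix).
#' @export
cv_edge_splits <- function(net, n_folds = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- edge_index(net)
  m <- nrow(edges)
  if (m < n_folds) stop("fewer edges (", m, ") than folds (", n_folds, ")")
  fold <- sample(rep(seq_len(n_folds), length.out = m))
  negatives <- which(upper.tri(net$adj) & net$adj == 0L, arr.ind = TRUE)
  lapply(seq_len(n_folds), function(f) {
    held <- edges[fold == f, , drop = FALSE]
    structure(list(fold = f,
                   train = subset_edges(net, edges[fold != f, , drop = FALSE]),
                   heldout = held, negatives = negatives),
              class = "cv_split")
  })
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, at least one of each class.
#' @return a number in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Quantile-resolved AUC
#'
#' Splits evaluated pairs into bins of a stratifying covariate (pairwise
#' distance or combined degree) whose boundaries divide the *positives*
#' evenly, assigns negatives to bins by covariate value (right-closed
#' boundaries), and reports the AUC inside each bin. Bins containing a single
#' class get `NA` with a flag.
#'
#' @param scores,labels as in [auc_score()].
#' @param covariate numeric stratifier per evaluated pair.
#' @param n_quantiles number of bins (default 5).
#' @return data frame with one row per bin: `bin`, `lower`, `upper`, `n_pos`,
#'   `n_neg`, `auc`, `defined`.
#' @export
quantile_auc_report <- function(scores, labels, covariate, n_quantiles = 5) {
  labels <- as.integer(labels)
  pos <- covariate[labels == 1L]
  if (length(pos) == 0) stop("no positives to set quantile boundaries")
  qs <- quantile(pos, probs = seq(0, 1, length.out = n_quantiles + 1),
                 names = FALSE)
  qs[1] <- -Inf; qs[n_quantiles + 1] <- Inf
  bin <- findInterval(covariate, qs, rightmost.closed = TRUE, left.open = TRUE)
  out <- lapply(seq_len(n_quantiles), function(b) {
    sel <- bin == b
    np <- sum(labels[sel] == 1L); nn <- sum(labels[sel] == 0L)
    ok <- np > 0L && nn > 0L
    data.frame(bin = b, lower = qs[b], upper = qs[b + 1],
               n_pos = np, n_neg = nn,
               auc = if (ok) auc_score(scores[sel], labels[sel]) else NA_real_,
               defined = ok)
  })
  do.call(rbind, out)
}

# score one fold with one method; returns a full score matrix
fold_scores <- function(split, method, config, priors = NULL) {
  train <- split$train
  if (method %in% c("radius", "radius_comms")) {
    cfg <- config
    cfg$n_comms <- if (method == "radius") 0L else config$n_comms
    if (is.null(priors)) priors <- default_priors(train)
    trace <- run_mcmc(train, cfg, priors)
    model_scores(trace, train, "predictive")
  } else {
    baseline_scores(train, method)
  }
}

#' Cross-validated link-prediction evaluation
#'
#' The full evaluation protocol: for each fold, fit the requested models on
#' the training network, score every candidate pair (held-out positives plus
#' all unlinked pairs), and report overall and quantile-resolved AUCs
#' stratified by pairwise distance and by combined (training) degree.
#'
#' @param net a [spatial_network()].
#' @param methods subset of `"radius"`, `"radius_comms"`, `"pa"`,
#'   `"expdist"`, `"empdist"`.
#' @param n_folds,n_quantiles evaluation resolution (defaults 10 and 5).
#' @param config [mcmc_config()] used for the model fits; its `n_comms`
#'   applies to `radius_comms` (`NULL` resolves to 10% of nodes).
#' @param seed integer seed controlling the splits and the fits.
#' @return list with `overall` (data frame: fold, method, auc) and
#'   `quantiles` (data frame: fold, method, stratifier, bin, auc, ...).
#' @export
evaluate_link_prediction <- function(net,
                                     methods = c("radius", "radius_comms",
                                                 "pa", "expdist", "empdist"),
                                     n_folds = 10, n_quantiles = 5,
                                     config = mcmc_config(), seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  splits <- cv_edge_splits(net, n_folds)
  if (is.null(config$n_comms)) config$n_comms <- as.integer(ceiling(0.1 * net$n))
  overall <- list(); quant <- list()
  for (split in splits) {
    pairs <- rbind(split$heldout, split$negatives)
    labels <- rep(c(1L, 0L), c(nrow(split$heldout), nrow(split$negatives)))
    dcov <- net$dist[pairs]
    ktr <- split$train$deg
    kcov <- ktr[pairs[, 1]] + ktr[pairs[, 2]]
    for (method in methods) {
      sm <- fold_scores(split, method, config)
      sc <- sm$scores[pairs]
      overall[[length(overall) + 1]] <-
        data.frame(fold = split$fold, method = method,
                   auc = auc_score(sc, labels))
      for (strat in c("distance", "combined_degree")) {
        cov <- if (strat == "distance") dcov else kcov
        qr <- quantile_auc_report(sc, labels, cov, n_quantiles)
        qr$fold <- split$fold; qr$method <- method; qr$stratifier <- strat
        quant[[length(quant) + 1]] <- qr
      }
    }
  }
  list(overall = do.call(rbind, overall), quantiles = do.call(rbind, quant))
}
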