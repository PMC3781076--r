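#' Pairwise distances between node coordinates
#'
#' Computes the symmetric matrix of pairwise node distances used throughout
#' the radius models. Coordinates are taken at face value: euclidean distances
#' are in the units of the input, haversine distances expect
#' (longitude, latitude) in degrees and return kilometres.
#'
#' @param coords numeric matrix or data frame with one row per node and two
#'   columns of coordinates.
#' @param metric `"euclidean"` (default) or `"haversine"`.
#' @return an `n x n` symmetric numeric matrix with zero diagonal.
#' @examples
#' pairwise_distances(rbind(c(0, 0), c(3, 4)))
#' @export
pairwise_distances <- function(coords, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least two nodes")
  if (ncol(coords) != 2L) stop("coordinates must have exactly two columns")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(coords)),
    haversine = geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  )
  dimnames(d) <- NULL
  diag(d) <- 0
  d
}

#' Construct a spatial network
#'
#' Bundles node coordinates and an undirected edge list into the container all
#' model functions consume: symmetric binary adjacency, pairwise distance
#' matrix and degree vector. Edges are symmetrised and de-duplicated;
#' self-loops are dropped with a warning.
#'
#' @param coords numeric matrix/data frame, one row per node, two columns.
#' @param edges two-column matrix/data frame of edge endpoints, referring to
#'   `ids` (or to row indices when `ids` is `NULL`). May be empty.
#' @param ids optional vector of unique node identifiers; defaults to
#'   `1..n` (or rownames of `coords` if present).
#' @param metric distance metric passed to [pairwise_distances()].
#' @return an object of class `spatial_network` with elements `ids`, `coords`,
#'   `adj`, `dist`, `deg`, `n` (nodes), `m` (edges), `metric`.
#' @export
spatial_network <- function(coords, edges, ids = NULL, metric = "euclidean") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(coords))) rownames(coords) else as.character(seq_len(n))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate node id: ", ids[duplicated(ids)][1])
  if (length(ids) != n) stop("length of ids must match number of coordinate rows")
  d <- pairwise_distances(coords, metric)
  adj <- matrix(0L, n, n)
  if (!is.null(edges) && NROW(edges) > 0) {
    e <- as.matrix(edges)[, 1:2, drop = FALSE]
    ii <- match(as.character(e[, 1]), ids)
    jj <- match(as.character(e[, 2]), ids)
    bad <- is.na(ii) | is.na(jj)
    if (any(bad)) {
      miss <- c(e[, 1][is.na(ii)], e[, 2][is.na(jj)])
      stop("unknown edge endpoint: ", miss[1])
    }
    self <- ii == jj
    if (any(self)) {
      warning(sum(self), " self-loop(s) dropped")
      ii <- ii[!self]; jj <- jj[!self]
    }
    adj[cbind(ii, jj)] <- 1L
    adj[cbind(jj, ii)] <- 1L
  }
  deg <- as.integer(rowSums(adj))
  structure(
    list(ids = ids, coords = coords, adj = adj, dist = d, deg = deg,
         n = n, m = sum(adj) %/% 2L, metric = metric),
    class = "spatial_network"
  )
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("<spatial_network> ", x$n, " nodes, ", x$m, " edges (",
      x$metric, " distances)\n", sep = "")
  cat("  mean degree ", round(mean(x$deg), 2),
      "; mean linked distance ",
      if (x$m > 0) signif(mean(x$dist[upper.tri(x$dist) & x$adj == 1L]), 4) else NA,
      "\n", sep = "")
  invisible(x)
}

# edge list of a network as a two-column integer matrix with i < j
edge_index <- function(net) {
  which(upper.tri(net$adj) & net$adj == 1L, arr.ind = TRUE)
}

# rebuild a network with a subset of its edges (coords and ids kept)
subset_edges <- function(net, keep_edges) {
  adj <- matrix(0L, net$n, net$n)
  if (NROW(keep_edges) > 0) {
    adj[keep_edges] <- 1L
    adj[keep_edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  out <- net
  out$adj <- adj
  out$deg <- as.integer(rowSums(adj))
  out$m <- sum(adj) %/% 2L
  out
}
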