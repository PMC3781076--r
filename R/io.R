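# read a delimited table with a mandatory header; sep inferred from extension
read_delim_checked <- function(path, required_cols) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read a spatial network from node and edge tables
#'
#' The node table must carry columns `id`, `x`, `y`; the edge list columns
#' `source`, `target`. Tab-separated by default, comma-separated for `.csv`.
#' Edges are symmetrised and de-duplicated; self-loops are dropped with a
#' warning; unknown endpoints are an error.
#'
#' @param node_path,edge_path input file paths.
#' @param metric `"euclidean"` or `"haversine"` (for lon/lat coordinates).
#' @return a [spatial_network()].
#' @export
read_network <- function(node_path, edge_path, metric = "euclidean") {
  nodes <- read_delim_checked(node_path, c("id", "x", "y"))
  edges <- read_delim_checked(edge_path, c("source", "target"))
  spatial_network(cbind(nodes$x, nodes$y), edges[, c("source", "target")],
                  ids = nodes$id, metric = metric)
}

#' Write a spatial network to node and edge tables
#'
#' @param net a [spatial_network()].
#' @param node_path,edge_path output file paths (tab-separated).
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, node_path, edge_path) {
  write.table(data.frame(id = net$ids, x = net$coords[, 1], y = net$coords[, 2]),
              node_path, sep = "\t", row.names = FALSE, quote = FALSE)
  e <- edge_index(net)
  write.table(data.frame(source = net$ids[e[, 1]], target = net$ids[e[, 2]]),
              edge_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Serialise and restore a posterior trace
#'
#' `write_trace()` stores the retained draws as a tab-separated table (one
#' row per draw: `iteration`, `alpha`, `beta`, `gamma`, `log_posterior`,
#' radii `r_1..r_n`, labels `c_1..c_n`) plus a small JSON run summary
#' (acceptance rates, configuration, priors). `read_trace()` restores a
#' `posterior_trace` usable by all downstream functions.
#'
#' @param trace a [run_mcmc()] result.
#' @param path table file path; the summary goes to `<path>.summary.json`.
#' @return `write_trace` invisibly returns `path`; `read_trace` a
#'   `posterior_trace`.
#' @export
write_trace <- function(trace, path) {
  n <- trace$n_nodes
  df <- data.frame(iteration = seq_along(trace$log_posterior),
                   alpha = trace$alpha, beta = trace$beta, gamma = trace$gamma,
                   log_posterior = trace$log_posterior)
  r <- as.data.frame(trace$radii); names(r) <- paste0("r_", seq_len(n))
  cc <- as.data.frame(trace$comms); names(cc) <- paste0("c_", seq_len(n))
  write.table(cbind(df, r, cc), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  summ <- list(acceptance = trace$acceptance, m_const = trace$m_const,
               n_nodes = n,
               config = trace$config[c("n_iter", "burn_in_fraction", "thin",
                                       "n_comms", "init_chain_iter", "seed")],
               priors = lapply(unclass(trace$priors), unlist))
  jsonlite::write_json(summ, paste0(path, ".summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read_delim_checked(path, c("iteration", "alpha", "beta", "gamma",
                                   "log_posterior"))
  summ <- jsonlite::read_json(paste0(path, ".summary.json"),
                              simplifyVector = TRUE)
  n <- summ$n_nodes
  cfg <- do.call(mcmc_config, summ$config[!vapply(summ$config, is.null,
                                                  logical(1))])
  pr <- summ$priors
  structure(list(alpha = df$alpha, beta = df$beta, gamma = df$gamma,
                 log_posterior = df$log_posterior,
                 radii = as.matrix(df[paste0("r_", seq_len(n))]),
                 comms = as.matrix(df[paste0("c_", seq_len(n))]),
                 acceptance = summ$acceptance, steps_final = NULL,
                 m_const = summ$m_const,
                 priors = prior_spec(pr$radius, pr$alpha, pr$beta, pr$gamma),
                 config = cfg, n_nodes = n),
            class = "posterior_trace")
}

#' Write a community partition table
#'
#' @param partition integer labels (0 = don't-care).
#' @param net the network giving node ids.
#' @param path output file (tab-separated, columns `id`, `label`).
#' @return invisibly, `path`.
#' @export
write_partition <- function(partition, net, path) {
  write.table(data.frame(id = net$ids, label = as.integer(partition)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of run outputs and return a manifest
#'
#' Writes whichever components are supplied (posterior trace, score
#' matrices, partitions, evaluation reports) into `out_dir` together with a
#' JSON run summary, and returns the list of files written.
#'
#' @param out_dir output directory (created if needed).
#' @param net the [spatial_network()] the outputs refer to.
#' @param trace optional [run_mcmc()] result.
#' @param scores optional named list of `score_matrix` objects.
#' @param partitions optional named list of label vectors.
#' @param reports optional named list of data frames.
#' @param seed optional integer recorded in the run summary.
#' @return character vector of files written (the manifest), invisibly also
#'   saved as `manifest.json`.
#' @export
write_outputs <- function(out_dir, net, trace = NULL, scores = NULL,
                          partitions = NULL, reports = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)
  if (!is.null(trace)) {
    write_trace(trace, file.path(out_dir, "trace.tsv"))
    add(file.path(out_dir, "trace.tsv"))
    add(file.path(out_dir, "trace.tsv.summary.json"))
  }
  for (nm in names(scores)) {
    f <- file.path(out_dir, paste0("scores_", nm, ".tsv"))
    write_scores(scores[[nm]], net, f); add(f)
  }
  for (nm in names(partitions)) {
    f <- file.path(out_dir, paste0("partition_", nm, ".tsv"))
    write_partition(partitions[[nm]], net, f); add(f)
  }
  for (nm in names(reports)) {
    f <- file.path(out_dir, paste0("report_", nm, ".tsv"))
    write.table(reports[[nm]], f, sep = "\t", row.names = FALSE, quote = FALSE)
    add(f)
  }
  summ <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(seed = seed, n_nodes = net$n, n_edges = net$m,
         package_version = as.character(utils::packageVersion("spatialreach")),
         files = basename(files)),
    summ, auto_unbox = TRUE, null = "null")
  add(summ)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(basename(files), manifest)
  invisible(c(files, manifest))
}
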