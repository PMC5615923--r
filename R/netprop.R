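#' Load a PPI network from an edge list
#'
#' Filters edges at a confidence level, drops self-loops, collapses parallel
#' edges (keeping the maximum confidence) and returns a simple undirected
#' igraph graph.
#'
#' @param edges data frame with columns `node_a`, `node_b`, `confidence`.
#' @param min_confidence retain edges with confidence at or above this level
#'   (default 0.4, the 40% high-confidence filter).
#' @param nodes optional full node universe to include (isolated nodes kept).
#' @return An igraph object with edge attribute `confidence`.
#' @export
ppi_network <- function(edges, min_confidence = 0.4, nodes = NULL) {
  edges <- as_tibble(edges)
  req <- c("node_a", "node_b", "confidence")
  if (!all(req %in% names(edges))) {
    abort("`edges` needs columns node_a, node_b, confidence.")
  }
  edges <- edges |>
    dplyr::filter(.data$confidence >= min_confidence,
                  .data$node_a != .data$node_b) |>
    dplyr::mutate(lo = pmin(.data$node_a, .data$node_b),
                  hi = pmax(.data$node_a, .data$node_b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$lo, to = edges$hi, confidence = edges$confidence),
    directed = FALSE,
    vertices = if (is.null(nodes)) NULL else unique(c(nodes, edges$lo, edges$hi))
  )
  g
}

#' Read an edge-list TSV (or SIF) into a network
#'
#' @param path TSV with header `node_a`, `node_b`, `confidence`, or a SIF
#'   file (`node relation node`, confidence set to 1).
#' @inheritParams ppi_network
#' @return An igraph object.
#' @export
read_network_tsv <- function(path, min_confidence = 0.4, nodes = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("node_a", first)) {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    sif <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    edges <- tibble(node_a = sif[[1]], node_b = sif[[3]], confidence = 1)
  }
  ppi_network(edges, min_confidence = min_confidence, nodes = nodes)
}

#' Symmetric degree normalization of the adjacency matrix
#'
#' Returns `W = D^(-1/2) A D^(-1/2)` on the binary (default) or
#' confidence-weighted adjacency: the degree-symmetric normalization whose
#' spectrum lies in `[-1, 1]`, so that diffusion with spreading coefficient
#' `alpha < 1` is a contraction. Isolated nodes get zero rows and columns.
#'
#' @param network an igraph object from [ppi_network()].
#' @param weighted use edge confidences as weights (default `FALSE`).
#' @return A sparse symmetric matrix with dimnames = node names.
#' @export
normalize_adjacency <- function(network, weighted = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0) abort("Empty graph.")
  A <- igraph::as_adjacency_matrix(
    network, sparse = TRUE,
    attr = if (weighted) "confidence" else NULL
  )
  A <- methods::as(A, "generalMatrix")
  deg <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Dhalf <- Matrix::Diagonal(n, inv_sqrt)
  W <- Dhalf %*% A %*% Dhalf
  dimnames(W) <- list(igraph::V(network)$name, igraph::V(network)$name)
  W
}

#' Map p-values onto the network as propagation input scores
#'
#' Proteins in `subset` contribute `-log2(p)`; every other node carries 0
#' (equivalently, its p-value is set to 1 and excluded from the signal).
#'
#' @param pvalues named numeric vector of p-values in `(0, 1]`.
#' @param node_universe character vector of all network node names.
#' @param subset node names whose p-values are used; defaults to all names
#'   of `pvalues`.
#' @return Named nonnegative numeric vector over `node_universe`.
#' @export
build_score_vector <- function(pvalues, node_universe, subset = names(pvalues)) {
  p <- pvalues[names(pvalues) %in% subset]
  if (any(p <= 0)) {
    warn("p-values of 0 clipped to the smallest positive representable value.")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) abort("p-values must not exceed 1.")
  y <- setNames(rep(0, length(node_universe)), node_universe)
  common <- intersect(names(p), node_universe)
  y[common] <- -log2(p[common])
  y
}

#' Diffuse scores over the network
#'
#' Iterates `F <- alpha * W %*% F + (1 - alpha) * Y` from `F0 = Y` until the
#' maximum absolute change falls below `tol` — the random-walk-with-restart
#' smoothing in which `alpha` is the fraction of each node's score shared
#' with its neighbours per step. Convergence is guaranteed for `alpha < 1`
#' because the spectral radius of `alpha * W` is below 1.
#'
#' @param y named score vector over the nodes of `W` (order must match).
#' @param W normalized adjacency from [normalize_adjacency()].
#' @param alpha spreading coefficient in `[0, 1)` (default 0.8).
#' @param tol convergence threshold on the max absolute change (default 1e-9).
#' @param max_iter iteration cap (default 10000).
#' @return Named numeric vector of smoothed scores, with attributes
#'   `iterations` and `residual`.
#' @export
propagate_scores <- function(y, W, alpha = 0.8, tol = 1e-9, max_iter = 10000) {
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1).")
  if (tol <= 0) abort("`tol` must be positive.")
  if (length(y) != nrow(W)) abort("Score vector and W dimensions differ.")
  if (!is.null(names(y)) && !is.null(rownames(W)) &&
      !identical(names(y), rownames(W))) {
    abort("Score vector names must match W's node order.")
  }
  f <- y
  base <- (1 - alpha) * y
  for (i in seq_len(max_iter)) {
    f_new <- as.numeric(alpha * (W %*% f)) + base
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      return(structure(setNames(f, names(y)), iterations = i, residual = delta))
    }
  }
  abort(sprintf("Propagation did not converge in %d iterations (residual %.3g).",
                max_iter, delta))
}

#' Topology bias of the network under diffusion
#'
#' Propagates a uniform unit score from every node: the smoothed profile that
#' topology alone produces (hubs and dense regions accumulate score even
#' without signal). It is subtracted from signal-propagated scores to correct
#' for this bias. On k-regular graphs the bias is exactly 1 everywhere.
#'
#' @inheritParams propagate_scores
#' @return Named numeric vector of bias scores.
#' @export
topology_bias <- function(W, alpha = 0.8, tol = 1e-9, max_iter = 10000) {
  ones <- setNames(rep(1, nrow(W)), rownames(W))
  propagate_scores(ones, W, alpha = alpha, tol = tol, max_iter = max_iter)
}

#' Propagate a protein set's significance profile with bias correction
#'
#' Builds the `-log2(p)` score vector for the given protein subset, smooths
#' it over the network, and subtracts the topology bias.
#'
#' @param pvalues named p-values (typically the raw C vs A p-values).
#' @param subset protein names forming the profile (e.g. the foxo-dependent
#'   set); other nodes' p-values are treated as 1.
#' @param W normalized adjacency.
#' @inheritParams propagate_scores
#' @param bias optional precomputed [topology_bias()] vector (recycled across
#'   profiles for speed).
#' @return A tibble: `node`, `raw` (Y), `smoothed` (F), `bias`, `corrected`.
#' @export
propagate_profile <- function(pvalues, subset, W, alpha = 0.8, tol = 1e-9,
                              max_iter = 10000, bias = NULL) {
  y <- build_score_vector(pvalues, rownames(W), subset)
  f <- propagate_scores(y, W, alpha = alpha, tol = tol, max_iter = max_iter)
  if (is.null(bias)) bias <- topology_bias(W, alpha = alpha, tol = tol,
                                           max_iter = max_iter)
  tibble(
    node = rownames(W),
    raw = unname(y),
    smoothed = as.numeric(f),
    bias = as.numeric(bias),
    corrected = as.numeric(f) - as.numeric(bias)
  )
}

#' Combined dependent-minus-independent profile
#'
#' Subtracts the two bias-corrected smoothed profiles node by node, yielding
#' the signed score used to display dependent and independent signal on one
#' map: positive where foxo-dependent signal dominates.
#'
#' @param dep,indep profile tibbles from [propagate_profile()] over the same
#'   node universe.
#' @return A tibble `node`, `corrected_dep`, `corrected_indep`, `combined`.
#' @export
combined_profile <- function(dep, indep) {
  if (!identical(dep$node, indep$node)) abort("Profiles are over different node sets.")
  tibble(
    node = dep$node,
    corrected_dep = dep$corrected,
    corrected_indep = indep$corrected,
    combined = dep$corrected - indep$corrected
  )
}

#' Cluster smoothed score profiles
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance, via [stats::hclust()]) of the per-node profile rows, cut into
#' `n_clusters` groups. Deterministic for a given input order; nodes with
#' identical profiles always land in the same cluster.
#'
#' @param profiles data frame with a `node` column and one or more numeric
#'   score columns (e.g. the output of [combined_profile()]).
#' @param n_clusters number of clusters to cut the tree into.
#' @param method linkage method (default `"complete"`).
#' @return The input tibble with an integer `cluster` column; the `hclust`
#'   tree is attached as attribute `tree`.
#' @export
cluster_scores <- function(profiles, n_clusters, method = "complete") {
  score_cols <- setdiff(names(profiles), "node")
  mat <- as.matrix(profiles[, score_cols, drop = FALSE])
  if (n_clusters > nrow(mat)) abort("More clusters requested than nodes.")
  rownames(mat) <- profiles$node
  tree <- hclust(dist(mat, method = "euclidean"), method = method)
  cl <- cutree(tree, k = n_clusters)
  out <- dplyr::mutate(as_tibble(profiles), cluster = unname(cl[profiles$node]))
  attr(out, "tree") <- tree
  out
}

#' Export a dendrogram in Newick text for audit
#'
#' @param tree an `hclust` object (e.g. `attr(clustered, "tree")`).
#' @param path output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_dendrogram_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  build <- function(i) {
    # hclust merge: negative = leaf index, positive = earlier merge row
    node <- function(j, h) {
      if (j < 0) sprintf("%s:%.6g", tree$labels[-j], h)
      else sprintf("%s:%.6g", build(j), h - tree$height[j])
    }
    h <- tree$height[i]
    sprintf("(%s,%s)", node(tree$merge[i, 1], h), node(tree$merge[i, 2], h))
  }
  nwk <- paste0(build(nrow(tree$merge)), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Heatmap-style plot of clustered propagation profiles
#'
#' @param clustered tibble from [cluster_scores()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_propagation <- function(clustered, ...) {
  long <- clustered |>
    tidyr::pivot_longer(-c("node", "cluster"), names_to = "profile",
                        values_to = "score") |>
    dplyr::arrange(.data$cluster)
  long$node <- factor(long$node, levels = unique(long$node))
  ggplot2::ggplot(long, ggplot2::aes(.data$profile, .data$node,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score")
  }
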