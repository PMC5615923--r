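#' Build an ontology with true-path closure
#'
#' Takes the term-parent DAG and the direct term-gene annotations, checks
#' acyclicity, and propagates annotations upward so that a gene annotated to
#' a term is annotated to all of that term's ancestors (the true-path rule).
#' The root term (named `"root"` by convention, or any term without a listed
#' parent) sits at depth 0.
#'
#' @param term_parent data frame with columns `term`, `parent`; a term may
#'   have several parent rows.
#' @param term_gene data frame with columns `term`, `gene` (direct
#'   annotations).
#' @return A list of class `ontology`: `terms`, `parents` (named list),
#'   `ancestors` (named list), `depth` (named integer, longest path from the
#'   root), `genes` (named list of closed gene sets).
#' @export
build_ontology <- function(term_parent, term_gene) {
  term_parent <- as_tibble(term_parent)
  term_gene <- as_tibble(term_gene)
  terms <- sort(unique(c(term_parent$term, term_gene$term)))
  roots <- setdiff(unique(term_parent$parent), terms)
  parents <- split(term_parent$parent, term_parent$term)
  g <- igraph::graph_from_data_frame(
    term_parent[, c("term", "parent")], directed = TRUE,
    vertices = unique(c(terms, term_parent$parent))
  )
  if (!igraph::is_dag(g)) abort("Cyclic parent specification in the ontology.")
  # depth = longest child->...->root path; topological order guarantees
  # parents are finished before children
  all_nodes <- igraph::V(g)$name
  topo <- igraph::topo_sort(g, mode = "in")$name  # roots first
  depth <- setNames(rep(0L, length(all_nodes)), all_nodes)
  for (tm in topo) {
    pr <- parents[[tm]]
    if (length(pr)) depth[tm] <- max(depth[pr]) + 1L
  }
  direct <- lapply(split(term_gene$gene, term_gene$term), unique)
  closed <- direct
  anc <- setNames(vector("list", length(all_nodes)), all_nodes)
  for (tm in topo) {
    pr <- parents[[tm]]
    anc[[tm]] <- unique(c(pr, unlist(anc[pr], use.names = FALSE)))
  }
  # push genes up from deepest terms
  for (tm in all_nodes[order(-depth[all_nodes])]) {
    gset <- closed[[tm]]
    if (is.null(gset)) next
    for (p in parents[[tm]]) {
      closed[[p]] <- unique(c(closed[[p]], gset))
    }
  }
  structure(
    list(terms = terms, parents = parents, ancestors = anc,
         depth = depth, genes = closed),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, max depth %d, %d annotated genes\n",
              length(x$terms), max(x$depth),
              length(unique(unlist(x$genes, use.names = FALSE)))))
  invisible(x)
}

#' One-sided hypergeometric overlap test
#'
#' Probability of drawing at least `k` marked items when `n` items are drawn
#' without replacement from a universe of `N` containing `K` marked ones —
#' the one-sided Fisher test used for gene-set overrepresentation.
#'
#' @param k observed overlap.
#' @param K marked items in the universe (e.g. term size).
#' @param n items drawn (e.g. significant-set size).
#' @param N universe size.
#' @return One-sided p-value, `P(X >= k)`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k > pmin(K, n)) || any(K > N) || any(n > N) || any(c(k, K, n, N) < 0)) {
    abort("Inconsistent counts: need k <= min(K, n) and K, n <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Ontology enrichment with the elim Fisher procedure
#'
#' Tests each term's gene set for overrepresentation of `significant` genes
#' against `background` with a one-sided hypergeometric (Fisher) test, both
#' classically and with the elim refinement: terms are processed bottom-up by
#' DAG depth (equal-depth ties in lexical order), and whenever a term's elim
#' p-value reaches `alpha` its genes are removed from all ancestor terms
#' before those are tested, so parents are credited only with signal their
#' significant descendants do not explain. The enrichment score of a term is
#' `log2(observed / expected)` with
#' `expected = |term genes in background| * |significant| / |background|`.
#'
#' @param ontology an [build_ontology()] object.
#' @param significant character vector of significant genes (subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param alpha elimination threshold on the elim p-value (default 0.05).
#' @param min_sig reporting filter: minimum significant genes in the term
#'   (default 5) behind the `min_sig_ok` flag.
#' @return A tibble with one row per term: `term`, `depth`, `n_term`,
#'   `observed`, `expected`, `score`, `p_classic`, `p_elim`,
#'   `elim_significant`, `min_sig_ok`, ordered by `p_elim`. Terms with empty
#'   background intersection are skipped (flagged in attribute `skipped`).
#' @export
elim_fisher <- function(ontology, significant, background, alpha = 0.05,
                        min_sig = 5) {
  stopifnot(inherits(ontology, "ontology"))
  significant <- unique(significant)
  background <- unique(background)
  if (!all(significant %in% background)) {
    abort("`significant` must be a subset of `background`.")
  }
  N <- length(background)
  n_sig <- length(significant)
  term_ids <- names(ontology$genes)
  term_bg <- lapply(ontology$genes, intersect, background)
  skipped <- term_ids[lengths(term_bg) == 0]
  term_ids <- setdiff(term_ids, skipped)
  # bottom-up: deepest first, lexical within a level
  ord <- term_ids[order(-ontology$depth[term_ids], term_ids)]
  eliminated <- setNames(vector("list", length(term_ids)), term_ids)
  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    tm <- ord[i]
    genes_all <- term_bg[[tm]]
    K <- length(genes_all)
    k <- length(intersect(genes_all, significant))
    p_classic <- hypergeom_test(k, K, n_sig, N)
    genes_kept <- setdiff(genes_all, eliminated[[tm]])
    K_e <- length(genes_kept)
    k_e <- length(intersect(genes_kept, significant))
    p_elim <- hypergeom_test(k_e, K_e, n_sig, N)
    if (p_elim <= alpha) {
      for (a in intersect(ontology$ancestors[[tm]], term_ids)) {
        eliminated[[a]] <- unique(c(eliminated[[a]], genes_all))
      }
    }
    expected <- K * n_sig / N
    rows[[i]] <- tibble(
      term = tm,
      depth = unname(ontology$depth[tm]),
      n_term = K,
      observed = k,
      expected = expected,
      score = if (expected > 0 && k > 0) log2(k / expected) else
        if (expected > 0) -Inf else NA_real_,
      p_classic = p_classic,
      p_elim = p_elim,
      elim_significant = p_elim <= alpha,
      min_sig_ok = k >= min_sig
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$p_elim, .data$term)
  attr(out, "skipped") <- skipped
  out
}

#' PCA contribution tails of proteins
#'
#' Centers the protein-by-sample matrix, runs SVD-based PCA with proteins as
#' observations, and returns the proteins in the upper and lower `q`
#' quantiles of their signed contribution to the requested dimension
#' (squared-coordinate share, signed by the coordinate). The component sign
#' is fixed so the protein with the largest absolute coordinate is positive.
#' Boundary ties go to the lower set, so `q = 0.5` partitions the proteins.
#'
#' @param mat numeric matrix, proteins in rows (rownames = ids).
#' @param dimension principal dimension (1-based).
#' @param q tail fraction (default 0.05).
#' @return A list with `top`, `bottom` (character vectors) and
#'   `contributions` (tibble `protein`, `coordinate`, `contribution`).
#' @export
pca_contribution_sets <- function(mat, dimension = 1, q = 0.05) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  centered <- scale(mat, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  if (dimension > r) abort("`dimension` exceeds the matrix rank.")
  coord <- sv$u[, dimension] * sv$d[dimension]
  if (coord[which.max(abs(coord))] < 0) coord <- -coord
  contrib <- sign(coord) * coord^2 / sum(coord^2)
  lo <- quantile(contrib, q, type = 1, names = FALSE)
  hi <- quantile(contrib, 1 - q, type = 1, names = FALSE)
  tibble_out <- tibble(protein = rownames(mat), coordinate = coord,
                       contribution = contrib)
  list(
    top = rownames(mat)[contrib > hi],
    bottom = rownames(mat)[contrib <= lo],
    contributions = tibble_out
  )
}

#' Overlap of motif-bearing genes with a regulated set
#'
#' Hypergeometric test of whether genes whose promoters carry a motif hit
#' are overrepresented in a regulated protein set, with selection and
#' background limited to the measured-protein universe. Also reports the
#' fraction of regulated genes carrying a motif.
#'
#' @param genes_with_hits genes with at least one promoter motif hit.
#' @param regulated the regulated gene set (e.g. foxo-dependent proteins).
#' @param background the measured-gene universe.
#' @return A tibble: `overlap`, `n_regulated`, `n_hits`, `n_background`,
#'   `fraction_with_motif`, `p`.
#' @export
motif_overlap_test <- function(genes_with_hits, regulated, background) {
  background <- unique(background)
  regulated <- intersect(unique(regulated), background)
  hits <- intersect(unique(genes_with_hits), background)
  if (length(regulated) == 0) abort("The regulated set is empty.")
  k <- length(intersect(hits, regulated))
  tibble(
    overlap = k,
    n_regulated = length(regulated),
    n_hits = length(hits),
    n_background = length(background),
    fraction_with_motif = k / length(regulated),
    p = hypergeom_test(k, length(hits), length(regulated), length(background))
  )
}

#' Directional one-sample t-test on a set's fold changes
#'
#' Tests whether the mean log2 fold change of a named protein set differs
#' from zero (two-sided), the test used to call a coordinated directional
#' shift of a functional group. A zero-variance input is resolved by
#' convention (p = 0 for a nonzero mean, 1 otherwise) and flagged.
#'
#' @param values numeric vector of per-protein log2 fold changes (length
#'   at least 2).
#' @return A tibble: `mean`, `t`, `df`, `p`, `degenerate`.
#' @export
direction_test <- function(values) {
  if (length(values) < 2) abort("Need at least 2 values.")
  m <- mean(values)
  s <- sd(values)
  n <- length(values)
  if (s == 0) {
    return(tibble(mean = m, t = if (m == 0) 0 else Inf * sign(m),
                  df = n - 1, p = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  tstat <- m / (s / sqrt(n))
  tibble(mean = m, t = tstat, df = n - 1,
         p = 2 * pt(-abs(tstat), df = n - 1), degenerate = FALSE)
}

#' Bar plot of top enriched terms
#'
#' @param enrichment tibble from [elim_fisher()].
#' @param n_terms how many terms to show (by elim p).
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, n_terms = 10, ...) {
  top <- enrichment |>
    dplyr::filter(is.finite(.data$score)) |>
    dplyr::slice_min(.data$p_elim, n = n_terms, with_ties = FALSE)
  ggplot2::ggplot(top, ggplot2::aes(.data$score,
                                    stats::reorder(.data$term, .data$score),
                                    fill = -log10(.data$p_elim))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "enrichment score log2(observed/expected)", y = NULL,
                  fill = "-log10 elim p") +
    ggplot2::theme_minimal()
}
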