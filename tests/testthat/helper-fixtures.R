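# Shared fixtures: small in-code datasets and independent oracles.

# lfq_data with explicit per-genotype values; vals is a list of per-genotype
# matrices (proteins x replicates) or a single matrix reused for all four.
make_lfq <- function(vals, proteins = NULL, tissue = "gut") {
  if (is.matrix(vals)) vals <- list(A = vals, B = vals, C = vals, D = vals)
  reps <- vapply(vals, ncol, integer(1))
  m <- do.call(cbind, vals)
  if (is.null(proteins)) proteins <- sprintf("P%03d", seq_len(nrow(m)))
  rownames(m) <- proteins
  samples <- tibble::tibble(
    sample = unlist(lapply(names(vals), function(g) {
      paste0(g, seq_len(ncol(vals[[g]])))
    })),
    genotype = rep(names(vals), reps),
    tissue = tissue,
    replicate = unlist(lapply(reps, seq_len))
  )
  colnames(m) <- samples$sample
  lfq_data(m, samples)
}

# contrast-result tibble built from explicit fields (defaults: nonsignificant)
make_contrast <- function(protein, estimate, significant = FALSE,
                          se = 0.1, df = 20, ci_low = NULL, ci_high = NULL) {
  n <- length(protein)
  estimate <- rep_len(estimate, n)
  significant <- rep_len(significant, n)
  se <- rep_len(se, n)
  if (is.null(ci_low)) ci_low <- estimate - 2 * se
  if (is.null(ci_high)) ci_high <- estimate + 2 * se
  p <- ifelse(significant, 0.001, 0.5)
  tibble::tibble(
    protein = protein, estimate = estimate, se = se, t = estimate / se,
    df = df, p = p, adj_p = p, ci_low = ci_low, ci_high = ci_high,
    significant = significant, se_zero = FALSE
  )
}

# brute-force step-up BH from the definition: independent oracle
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  adj
}

# igraph ring/star/complete helpers returning confidence-1 edge tibbles
graph_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  tibble::tibble(node_a = el[, 1], node_b = el[, 2], confidence = 1)
}

named_ring <- function(n) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# hypergeometric upper tail straight from the counting definition
hyper_tail_brute <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# enumerate all width-w words, score with independently rounded per-column
# integer scores, and accumulate exact background probabilities
pwm_enum_tail <- function(motif, bin = 1e-3) {
  w <- motif$width
  bases <- rownames(motif$pwm)
  si <- round(log2(motif$pwm / motif$background) / bin)
  grid <- expand.grid(rep(list(seq_len(4)), w))
  scores <- apply(grid, 1, function(idx) sum(si[cbind(idx, seq_len(w))]))
  probs <- apply(grid, 1, function(idx) prod(motif$background[idx]))
  agg <- tapply(probs, scores, sum)
  s <- as.numeric(names(agg))
  o <- order(s)
  s <- s[o]
  tail <- rev(cumsum(rev(as.numeric(agg)[o])))
  list(scores = s, tail = tail)
}

# flat ontology: every term a child of the root
flat_ontology <- function(n_terms, genes, seed = 1) {
  set.seed(seed)
  tp <- tibble::tibble(term = sprintf("T%02d", 1:n_terms), parent = "root")
  tg <- purrr::map_dfr(tp$term, function(tm) {
    tibble::tibble(term = tm, gene = sample(genes, sample(4:12, 1)))
  })
  build_ontology(tp, tg)
}

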