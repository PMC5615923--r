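test_that("score mapping is -log2(p) on the subset and 0 elsewhere", {
  y <- build_score_vector(c(a = 0.25, b = 1, c = 0.5), c("a", "b", "c", "d"),
                          subset = c("a", "b"))
  expect_equal(unname(y), c(2, 0, 0, 0))
  expect_equal(unname(build_score_vector(c(a = 0.1), c("a", "b"),
                                         subset = character(0))), c(0, 0))
  expect_warning(build_score_vector(c(a = 0), "a"), "clipped")
})

test_that("degree-symmetric normalization matches closed forms", {
  # single edge: both entries 1
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b"), directed = FALSE)
  W2 <- normalize_adjacency(g2)
  expect_equal(W2["a", "b"], 1)
  expect_equal(W2["b", "a"], 1)
  # star with k leaves: center-leaf entries 1/sqrt(k)
  k <- 6
  star <- igraph::make_star(k + 1, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:k))
  Ws <- normalize_adjacency(star)
  expect_equal(unname(Ws["hub", "leaf1"]), 1 / sqrt(k), tolerance = 1e-12)
  # regular graph: rows sum to 1
  ring <- named_ring(8)
  Wr <- normalize_adjacency(ring)
  expect_equal(unname(Matrix::rowSums(Wr)), rep(1, 8), tolerance = 1e-12)
})

test_that("propagation matches the dense linear-system solution", {
  set.seed(31)
  g <- igraph::sample_gnp(200, 0.04)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(200, 0.04)
  igraph::V(g)$name <- sprintf("n%03d", 1:200)
  W <- normalize_adjacency(g)
  y <- setNames(rexp(200), rownames(W))
  f <- propagate_scores(y, W, alpha = 0.8, tol = 1e-12)
  # oracle: F solves (I - alpha W) F = (1 - alpha) Y
  f_direct <- solve(diag(200) - 0.8 * as.matrix(W), 0.2 * y)
  expect_lt(max(abs(f - f_direct)), 1e-6)
})

test_that("propagation limits: no spreading and zero input", {
  W <- normalize_adjacency(named_ring(10))
  y <- setNames(runif(10), rownames(W))
  expect_equal(as.numeric(propagate_scores(y, W, alpha = 0)), unname(y))
  expect_equal(as.numeric(propagate_scores(setNames(rep(0, 10), rownames(W)), W)),
               rep(0, 10))
})

test_that("propagation is linear in its input", {
  set.seed(37)
  W <- normalize_adjacency(named_ring(30))
  y1 <- setNames(runif(30), rownames(W))
  y2 <- setNames(runif(30), rownames(W))
  f12 <- propagate_scores(2 * y1 + 3 * y2, W, tol = 1e-12)
  f1 <- propagate_scores(y1, W, tol = 1e-12)
  f2 <- propagate_scores(y2, W, tol = 1e-12)
  expect_equal(as.numeric(f12), as.numeric(2 * f1 + 3 * f2), tolerance = 1e-8)
})

test_that("topology bias is exactly 1 on regular graphs", {
  cyc <- named_ring(12)
  comp <- igraph::make_full_graph(7)
  igraph::V(comp)$name <- paste0("c", 1:7)
  hyper <- igraph::make_lattice(c(2, 2, 2))  # the 3-cube, 3-regular
  igraph::V(hyper)$name <- paste0("h", 1:8)
  for (g in list(cyc, comp, hyper)) {
    b <- topology_bias(normalize_adjacency(g), tol = 1e-12)
    expect_lt(max(abs(b - 1)), 1e-9)
  }
  # alpha = 0 trivially returns the unit start vector
  expect_equal(as.numeric(topology_bias(normalize_adjacency(cyc), alpha = 0)),
               rep(1, 12))
})

test_that("star-graph bias accumulates at the hub and matches the solve", {
  k <- 8
  star <- igraph::make_star(k + 1, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:k))
  W <- normalize_adjacency(star)
  b <- topology_bias(W, alpha = 0.8, tol = 1e-12)
  b_direct <- solve(diag(k + 1) - 0.8 * as.matrix(W), rep(0.2, k + 1))
  expect_lt(max(abs(b - b_direct)), 1e-8)
  expect_gt(b["hub"], b["leaf1"])
})

test_that("bias correction preserves rankings on vertex-transitive graphs", {
  W <- normalize_adjacency(named_ring(20))
  set.seed(41)
  y <- setNames(rexp(20), rownames(W))
  prof <- propagate_profile(setNames(2^(-y), names(y)), names(y), W)
  expect_equal(order(prof$corrected), order(prof$smoothed))
})

test_that("iteration residuals contract monotonically", {
  set.seed(43)
  g <- igraph::sample_gnp(60, 0.1)
  igraph::V(g)$name <- paste0("v", 1:60)
  W <- normalize_adjacency(g)
  y <- setNames(runif(60), rownames(W))
  f <- y
  base <- 0.2 * y
  deltas <- numeric(40)
  for (i in 1:40) {
    f_new <- as.numeric(0.8 * (W %*% f)) + base
    deltas[i] <- max(abs(f_new - f))
    f <- f_new
  }
  expect_true(all(diff(deltas) <= 1e-12))
})

test_that("combined profiles subtract and identical inputs cancel", {
  W <- normalize_adjacency(named_ring(10))
  p <- setNames(runif(10, 0.01, 1), rownames(W))
  prof <- propagate_profile(p, names(p), W)
  comb <- combined_profile(prof, prof)
  expect_equal(comb$combined, rep(0, 10))
  expect_equal(comb$corrected_dep, prof$corrected)
})

test_that("clustering recovers two well-separated planted modules", {
  nodes <- c(paste0("m1_", 1:10), paste0("m2_", 1:10))
  profiles <- tibble::tibble(
    node = nodes,
    s1 = c(rnorm(10, 10, 0.1), rnorm(10, 0, 0.1)),
    s2 = c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  )
  cl <- cluster_scores(profiles, n_clusters = 2)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[11])
})

test_that("duplicated profiles never split across clusters", {
  set.seed(47)
  profiles <- tibble::tibble(node = paste0("n", 1:12), s = c(rnorm(11), NA))
  profiles$s[12] <- profiles$s[1]
  for (k in 2:6) {
    cl <- cluster_scores(profiles, n_clusters = k)
    expect_equal(cl$cluster[1], cl$cluster[12])
  }
})

test_that("the dendrogram exports as parseable Newick", {
  profiles <- tibble::tibble(node = paste0("n", 1:6), s = c(1, 1.1, 5, 5.2, 9, 9.3))
  cl <- cluster_scores(profiles, n_clusters = 3)
  nwk <- write_dendrogram_newick(attr(cl, "tree"))
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(profiles$node))
})

test_that("network loading collapses duplicates and keeps max confidence", {
  edges <- tibble::tibble(
    node_a = c("a", "b", "a", "c"),
    node_b = c("b", "a", "a", "d"),
    confidence = c(0.5, 0.9, 1.0, 0.2)
  )
  g <- ppi_network(edges, min_confidence = 0.4)
  expect_equal(igraph::ecount(g), 1)  # self-loop dropped, low confidence filtered
  expect_equal(igraph::E(g)$confidence, 0.9)
})
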