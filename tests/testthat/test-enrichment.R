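test_that("hypergeometric tail matches the counting definition", {
  expect_equal(hypergeom_test(0, 5, 10, 20), 1)
  expect_equal(hypergeom_test(5, 5, 5, 5), 1)
  expect_equal(hypergeom_test(5, 5, 10, 20),
               choose(15, 5) / choose(20, 10), tolerance = 1e-12)
  # exhaustive check over all consistent configurations up to N = 20
  for (N in c(5, 11, 20)) {
    for (K in seq(0, N, by = 3)) {
      for (n in seq(0, N, by = 4)) {
        for (k in seq(0, min(K, n))) {
          expect_equal(hypergeom_test(k, K, n, N), hyper_tail_brute(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
  expect_error(hypergeom_test(6, 5, 10, 20), "Inconsistent")
})

test_that("elim equals classic on flat ontologies", {
  genes <- sprintf("g%03d", 1:60)
  ont <- flat_ontology(12, genes, seed = 2)
  sig <- sample(genes, 15)
  res <- elim_fisher(ont, sig, genes)
  expect_equal(res$p_elim, res$p_classic, tolerance = 1e-15)
})

test_that("a significant child strips its genes from the parent's elim test", {
  # child: 5 genes, all significant; parent adds 5 never-significant genes.
  # After elimination the parent is tested on its residual 5 genes: overlap 0,
  # so p_elim = P(X >= 0) = 1, while classic keeps the child's signal.
  child_genes <- paste0("c", 1:5)
  extra <- paste0("e", 1:5)
  rest <- paste0("r", 1:40)
  tp <- tibble::tibble(term = c("parent", "child"), parent = c("root", "parent"))
  tg <- tibble::tibble(
    term = c(rep("child", 5), rep("parent", 5)),
    gene = c(child_genes, extra)
  )
  ont <- build_ontology(tp, tg)
  bg <- c(child_genes, extra, rest)
  res <- elim_fisher(ont, child_genes, bg, alpha = 0.05)
  child <- res[res$term == "child", ]
  parent <- res[res$term == "parent", ]
  expect_lte(child$p_elim, 0.05)
  expect_equal(parent$p_elim, 1)
  # classic p for the parent from the untouched 2x2 table
  expect_equal(parent$p_classic, hyper_tail_brute(5, 10, 5, 50), tolerance = 1e-12)
  expect_equal(parent$expected, 10 * 5 / 50)
  expect_equal(child$score, log2(5 / (5 * 5 / 50)))
})

test_that("alpha = 0 disables elimination entirely", {
  genes <- sprintf("g%03d", 1:50)
  set.seed(3)
  tp <- tibble::tibble(term = c("a", "b", "c"), parent = c("root", "a", "b"))
  tg <- purrr::map_dfr(c("a", "b", "c"), function(tm) {
    tibble::tibble(term = tm, gene = sample(genes, 10))
  })
  ont <- build_ontology(tp, tg)
  res <- elim_fisher(ont, sample(genes, 12), genes, alpha = 0)
  expect_equal(res$p_elim, res$p_classic, tolerance = 1e-15)
})

test_that("cyclic ontologies are rejected", {
  tp <- tibble::tibble(term = c("a", "b"), parent = c("b", "a"))
  tg <- tibble::tibble(term = c("a", "b"), gene = c("g1", "g2"))
  expect_error(build_ontology(tp, tg), "Cyclic")
})

test_that("true-path closure propagates genes to ancestors", {
  tp <- tibble::tibble(term = c("mid", "leaf"), parent = c("root", "mid"))
  tg <- tibble::tibble(term = c("leaf", "mid"), gene = c("g1", "g2"))
  ont <- build_ontology(tp, tg)
  expect_setequal(ont$genes[["leaf"]], "g1")
  expect_setequal(ont$genes[["mid"]], c("g1", "g2"))
  expect_setequal(ont$genes[["root"]], c("g1", "g2"))
  expect_true(all(ont$genes[["leaf"]] %in% ont$genes[["mid"]]))
})

test_that("random significant sets give near-zero mean enrichment score", {
  genes <- sprintf("g%03d", 1:200)
  ont <- flat_ontology(1, genes, seed = 5)
  tm_genes <- ont$genes[[setdiff(names(ont$genes), "root")[1]]]
  set.seed(6)
  scores <- replicate(200, {
    sig <- sample(genes, 50)
    k <- length(intersect(tm_genes, sig))
    expected <- length(tm_genes) * 50 / 200
    log2(max(k, 0.5) / expected)  # continuity-floor k=0 draws
  })
  expect_lt(abs(mean(scores)), 0.25)
})

test_that("PCA contribution tails follow a constructed rank-1 loading", {
  # rank-1 matrix: X = u d v'; protein coordinates are proportional to u
  u <- seq(-1, 1, length.out = 20)
  v <- c(1, 2, -1, 0.5)
  X <- outer(u, v) * 5
  rownames(X) <- sprintf("P%02d", 1:20)
  res <- pca_contribution_sets(X, dimension = 1, q = 0.1)
  o <- order(res$contributions$contribution)
  expect_setequal(res$bottom, res$contributions$protein[o][1:2])
  expect_setequal(res$top, res$contributions$protein[o][19:20])
  # tails are the extremes of the known loading order
  expect_setequal(c(res$top, res$bottom), c("P01", "P02", "P19", "P20"))
})

test_that("median split partitions proteins with ties to the lower set", {
  set.seed(8)
  X <- matrix(rnorm(14 * 5), 14, 5, dimnames = list(sprintf("P%02d", 1:14), NULL))
  res <- pca_contribution_sets(X, dimension = 1, q = 0.5)
  expect_equal(sort(c(res$top, res$bottom)), sort(rownames(X)))
  expect_length(intersect(res$top, res$bottom), 0)
})

test_that("duplicated proteins land in the same contribution tail", {
  set.seed(9)
  X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(sprintf("P%02d", 1:10), NULL))
  X[10, ] <- X[1, ]
  res <- pca_contribution_sets(X, dimension = 1, q = 0.3)
  expect_equal("P01" %in% res$top, "P10" %in% res$top)
  expect_equal("P01" %in% res$bottom, "P10" %in% res$bottom)
})

test_that("directional t-test matches hand computation and flags degeneracy", {
  sym <- direction_test(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  flat <- direction_test(c(1, 1, 1, 1))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 0)
  vals <- c(0.2, 0.4, 0.6, 0.8)
  res <- direction_test(vals)
  ref <- t.test(vals)  # independent oracle
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$t, mean(vals) / (sd(vals) / 2), tolerance = 1e-12)
  expect_equal(res$df, 3)
})

test_that("motif overlap statistics cover the degenerate cases", {
  bg <- sprintf("g%02d", 1:30)
  reg <- bg[1:10]
  no <- motif_overlap_test(bg[21:30], reg, bg)
  expect_equal(no$fraction_with_motif, 0)
  expect_equal(no$p, 1)
  sat <- motif_overlap_test(bg, reg, bg)
  expect_equal(sat$fraction_with_motif, 1)
  expect_equal(sat$p, 1)
  expect_error(motif_overlap_test(bg[1:5], character(0), bg), "empty")
})

test_that("planted motif enrichment is recovered from a synthetic bundle", {
  b <- simulate_bundle(sim_config(n_proteins = 150, seed = 91),
                       promoter_args = list(plant_fraction = 0.5,
                                            background_fraction = 0.05))
  hits <- scan_promoters(b$promoters, b$motif)
  dep <- b$truth$protein[b$truth$class == "foxo_dependent"]
  res <- motif_overlap_test(hits$gene[hits$has_hit], dep, b$truth$protein)
  # oracle: planted fraction 0.5 among dependents, binomial 95% band
  n_dep <- length(dep)
  band <- qbinom(c(0.005, 0.995), n_dep, 0.5) / n_dep
  expect_gte(res$fraction_with_motif, band[1])
  # background planting can only add hits beyond the planted 50%
  expect_lt(res$p, 0.01)
})
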