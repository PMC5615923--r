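test_that("all-null simulation has equal generating group means", {
  cfg <- sim_config(n_proteins = 50, residual_sd = 0,
                    class_fractions = c(null = 1, foxo_dependent = 0,
                                        foxo_independent = 0, exaggerated = 0),
                    seed = 3)
  sim <- simulate_intensities(cfg)
  fit <- fit_group_means(sim$data)
  expect_true(all(abs(fit$means - fit$means[, 1]) < 1e-12))
  expect_true(all(sim$truth$class == "null"))
})

test_that("zero-noise independent effects reproduce the planted contrast exactly", {
  cfg <- sim_config(n_proteins = 20, residual_sd = 0,
                    class_fractions = c(null = 0, foxo_dependent = 0,
                                        foxo_independent = 1, exaggerated = 0),
                    effect_size = function(n) rep(1, n), seed = 5)
  sim <- simulate_intensities(cfg)
  fit <- fit_group_means(sim$data)
  d_ca <- fit$means[, "C"] - fit$means[, "A"]
  d_db <- fit$means[, "D"] - fit$means[, "B"]
  expect_equal(unname(d_ca), sim$truth$effect_CA, tolerance = 1e-12)
  expect_equal(unname(d_db), sim$truth$effect_DB, tolerance = 1e-12)
  expect_true(all(abs(abs(sim$truth$effect_CA) - 1) < 1e-12))
})

test_that("pooled residual variance matches the generating model", {
  # oracle: the generating model has i.i.d. N(0, sd^2) residuals, so the
  # pooled within-group variance estimates sd^2 directly
  cfg <- sim_config(n_proteins = 2000, seed = 11)
  sim <- simulate_intensities(cfg)
  fit <- fit_group_means(sim$data)
  expect_lt(abs(mean(fit$s2) - cfg$residual_sd^2), 0.05 * cfg$residual_sd^2)
})

test_that("ground-truth class constraints hold across seeds", {
  for (seed in c(1, 17, 301)) {
    truth <- simulate_intensities(sim_config(n_proteins = 300, seed = seed))$truth
    null <- truth[truth$class == "null", ]
    expect_true(all(null$effect_CA == 0 & null$effect_DB == 0))
    ind <- truth[truth$class == "foxo_independent", ]
    expect_true(all(ind$effect_CA == ind$effect_DB & ind$effect_CA != 0))
    dep <- truth[truth$class == "foxo_dependent", ]
    expect_true(all(abs(dep$effect_CA) > abs(dep$effect_DB)))
    expect_true(all(dep$effect_DB == 0 |
                      sign(dep$effect_DB) == sign(dep$effect_CA)))
    ex <- truth[truth$class == "exaggerated", ]
    expect_true(all(abs(ex$effect_DB) > abs(ex$effect_CA)))
    expect_true(all(sign(ex$effect_DB) == sign(ex$effect_CA)))
  }
})

test_that("flat logistic censoring removes about half of all cells", {
  cfg <- sim_config(n_proteins = 500, mnar_steepness = 0, seed = 2)
  sim <- simulate_intensities(cfg)
  cen <- apply_missingness(sim$data, cfg)
  expect_lt(abs(mean(cen$mask) - 0.5), 0.02)
})

test_that("censoring vanishes in the low-midpoint limit", {
  cfg <- sim_config(n_proteins = 100, mnar_midpoint = -1e9, seed = 2)
  sim <- simulate_intensities(cfg)
  cen <- apply_missingness(sim$data, cfg)
  expect_equal(sum(cen$mask), 0)
})

test_that("missingness is left-censoring: rate falls across intensity deciles", {
  cfg <- sim_config(n_proteins = 2000, seed = 8)
  sim <- simulate_intensities(cfg)
  cen <- apply_missingness(sim$data, cfg)
  vals <- as.vector(sim$data$values)
  miss <- as.vector(cen$mask)
  dec <- cut(vals, quantile(vals, seq(0, 1, 0.1)), include.lowest = TRUE)
  rate <- tapply(miss, dec, mean)
  # oracle: logistic expectation per decile is monotone decreasing in value
  expected <- tapply(plogis((cfg$mnar_midpoint - vals) * cfg$mnar_steepness),
                     dec, mean)
  expect_true(all(diff(expected) <= 0))
  expect_true(all(diff(rate[1:4]) <= 0))
  expect_lt(suppressWarnings(cor(vals, miss, method = "spearman")), 0)
  expect_lt(max(abs(rate - expected)), 0.05)
})

test_that("planted modules are cliques at within-module probability 1", {
  truth <- simulate_intensities(sim_config(n_proteins = 100, seed = 4))$truth
  net <- simulate_network(truth, n_modules = 3, module_size = 5,
                          within_module_prob = 1, seed = 4)
  filt <- net$edges[net$edges$confidence >= 0.4, ]
  key <- paste(filt$node_a, filt$node_b)
  for (m in 1:3) {
    members <- sort(net$truth$protein[!is.na(net$truth$module_id) &
                                        net$truth$module_id == m])
    pairs <- utils::combn(members, 2)
    expect_true(all(paste(pairs[1, ], pairs[2, ]) %in% key),
                label = sprintf("module %d is a clique after filtering", m))
  }
  # planted edges always survive the 40% confidence filter
  expect_true(all(net$edges$confidence[net$edges$planted] >= 0.4))
})

test_that("an unplanted network is a plain heavy-tailed backbone", {
  truth <- simulate_intensities(sim_config(n_proteins = 200, seed = 9))$truth
  net <- simulate_network(truth, n_modules = 0, seed = 9)
  expect_true(all(is.na(net$truth$module_id)))
  g <- ppi_network(net$edges, min_confidence = 0)
  deg <- igraph::degree(g)
  expect_gt(max(deg), 5 * median(deg))
})

test_that("impossible module sizes are a configuration error", {
  truth <- simulate_intensities(sim_config(n_proteins = 30, seed = 1))$truth
  expect_error(simulate_network(truth, n_nodes = 30, n_modules = 10,
                                module_size = 5, seed = 1), "node count")
})

test_that("depth-1 ontologies are flat and module terms annotate module genes", {
  truth <- simulate_intensities(sim_config(n_proteins = 100, seed = 6))$truth
  net <- simulate_network(truth, n_modules = 2, module_size = 6, seed = 6)
  ont <- simulate_ontology(net$truth, n_terms = 10, dag_depth = 1, seed = 6)
  plain <- ont$term_parent[!grepl("^TMOD", ont$term_parent$term), ]
  expect_true(all(plain$parent == "root"))
  built <- build_ontology(ont$term_parent, ont$term_gene)
  expect_s3_class(built, "ontology")
  mod1 <- net$truth$protein[!is.na(net$truth$module_id) & net$truth$module_id == 1]
  expect_setequal(built$genes[["TMOD01"]], mod1)
})

test_that("planted promoters contain the exact consensus", {
  truth <- simulate_intensities(sim_config(n_proteins = 60, seed = 12))$truth
  prom <- simulate_promoters(truth, plant_fraction = 1, background_fraction = 0,
                             seed = 12)
  dep <- prom$truth$protein[prom$truth$class == "foxo_dependent"]
  expect_true(all(prom$truth$motif_planted[match(dep, prom$truth$protein)]))
  consensus <- foxo_motif()$consensus
  expect_true(all(vapply(prom$sequences[dep], grepl, logical(1),
                         pattern = consensus, fixed = TRUE)))
  nondep <- setdiff(prom$truth$protein, dep)
  expect_true(all(!prom$truth$motif_planted[match(nondep, prom$truth$protein)]))
})

test_that("a fixed seed reproduces the whole bundle bit-identically", {
  b1 <- simulate_bundle(sim_config(n_proteins = 80, seed = 21))
  b2 <- simulate_bundle(sim_config(n_proteins = 80, seed = 21))
  expect_identical(b1$data$values, b2$data$values)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$network, b2$network)
  expect_identical(b1$promoters, b2$promoters)
  expect_identical(b1$ontology, b2$ontology)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_fractions = c(null = 0.5, foxo_dependent = 0.2,
                                              foxo_independent = 0.2,
                                              exaggerated = 0.2)), "sum to 1")
  expect_error(sim_config(n_replicates = 1), "at least 2")
})

test_that("bundle files round-trip through the TSV/FASTA/MEME dialects", {
  b <- simulate_bundle(sim_config(n_proteins = 40, seed = 33))
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  dat <- read_lfq_tsv(paths["intensities"], paths["metadata"])
  expect_equal(dat$values, b$data$values, tolerance = 1e-10)
  expect_identical(dat$mask, b$data$mask)
  motif <- read_meme(paths["motif"])
  expect_equal(motif$pwm, b$motif$pwm, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(motif$consensus, b$motif$consensus)
  seqs <- read_fasta(paths["promoters"])
  expect_identical(unname(seqs[b$truth$protein]), unname(b$promoters))
})
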