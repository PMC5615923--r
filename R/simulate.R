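#' Configuration for the synthetic LFQ proteome generator
#'
#' Defines the four-genotype, one-tissue study design emulated by the
#' simulator: A = wild type, B = foxo-null, C = mNSC-ablated,
#' D = ablated foxo-null, with `n_replicates` biological replicates per
#' genotype. Effects are planted on the two ablation contrasts: C vs A in the
#' wild-type background and D vs B in the foxo-null background.
#'
#' @param n_proteins number of proteins.
#' @param n_replicates replicates per genotype (the study design uses 6).
#' @param baseline_mean_range interval to which per-protein baseline log2
#'   intensities are truncated.
#' @param baseline_mean,baseline_sd location and spread of the (truncated)
#'   normal distribution of per-protein baselines, emulating the bell-shaped
#'   log2 LFQ intensity histograms of real proteomes.
#' @param residual_sd residual standard deviation in log2 units.
#' @param class_fractions named proportions over the four planted classes
#'   `null`, `foxo_dependent`, `foxo_independent`, `exaggerated`; must sum
#'   to 1.
#' @param effect_size function(n) returning n positive effect magnitudes
#'   (|delta log2|) for non-null proteins. Default: constant 1.0.
#' @param exaggeration_factor multiplier giving the D-vs-B response of
#'   `exaggerated` proteins relative to their C-vs-A response (> 1).
#' @param mnar_midpoint,mnar_steepness logistic left-censoring parameters:
#'   a cell of intensity x is missing with probability
#'   `plogis((mnar_midpoint - x) * mnar_steepness)`.
#' @param dropped_samples optional character vector of sample ids to drop,
#'   emulating replicate imbalance from failed runs.
#' @param tissue tissue label attached to the sample metadata.
#' @param seed integer seed; a fixed seed makes the whole bundle bit-identical.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1500,
                       n_replicates = 6,
                       baseline_mean_range = c(22, 38),
                       baseline_mean = 30,
                       baseline_sd = 3,
                       residual_sd = 0.3,
                       class_fractions = c(null = 0.70, foxo_dependent = 0.15,
                                           foxo_independent = 0.10, exaggerated = 0.05),
                       effect_size = function(n) rep(1.0, n),
                       exaggeration_factor = 1.5,
                       mnar_midpoint = 22.5,
                       mnar_steepness = 1.0,
                       dropped_samples = NULL,
                       tissue = "gut",
                       seed = 1L) {
  classes <- c("null", "foxo_dependent", "foxo_independent", "exaggerated")
  if (!setequal(names(class_fractions), classes)) {
    abort("`class_fractions` must be named null, foxo_dependent, foxo_independent, exaggerated.")
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0)) {
    abort("`class_fractions` must be nonnegative and sum to 1.")
  }
  if (n_replicates < 2) abort("`n_replicates` must be at least 2.")
  if (residual_sd <= 0 && residual_sd != 0) abort("`residual_sd` must be nonnegative.")
  if (residual_sd < 0) abort("`residual_sd` must be nonnegative.")
  if (exaggeration_factor <= 1) abort("`exaggeration_factor` must exceed 1.")
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_replicates = as.integer(n_replicates),
      genotypes = c("A", "B", "C", "D"),
      baseline_mean_range = baseline_mean_range,
      baseline_mean = baseline_mean,
      baseline_sd = baseline_sd,
      residual_sd = residual_sd,
      class_fractions = class_fractions,
      effect_size = effect_size,
      exaggeration_factor = exaggeration_factor,
      mnar_midpoint = mnar_midpoint,
      mnar_steepness = mnar_steepness,
      dropped_samples = dropped_samples,
      tissue = tissue,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))

# Planted class labels and per-contrast effects; class semantics:
#   null:             no response in either background
#   foxo_dependent:   response to ablation abrogated by loss of foxo
#   foxo_independent: identical response in both backgrounds
#   exaggerated:      stronger same-direction response without foxo
sim_truth <- function(config) {
  n <- config$n_proteins
  counts <- round(config$class_fractions * n)
  counts[1] <- n - sum(counts[-1])
  class <- rep(names(counts), counts)[seq_len(n)]
  class <- sample(class)
  magnitude <- config$effect_size(n)
  stopifnot(all(magnitude >= 0))
  sign <- sample(c(-1, 1), n, replace = TRUE)
  delta <- magnitude * sign
  effect_ca <- dplyr::case_when(
    class == "null" ~ 0,
    TRUE ~ delta
  )
  effect_db <- dplyr::case_when(
    class == "null" ~ 0,
    class == "foxo_dependent" ~ 0,
    class == "foxo_independent" ~ delta,
    class == "exaggerated" ~ delta * config$exaggeration_factor
  )
  tibble(
    protein = protein_ids(n),
    class = class,
    effect_CA = effect_ca,
    effect_DB = effect_db
  )
}

#' Simulate a complete (no-missing) log2 LFQ intensity matrix
#'
#' Draws per-protein baselines, plants class-specific effects on genotypes C
#' and D, and adds i.i.d. normal residual noise. Genotype group means are
#' baseline (A, B), baseline + effect_CA (C) and baseline + effect_DB (D).
#'
#' @param config a [sim_config()].
#' @return A list with `data` (complete [lfq_data()]) and `truth` (tibble with
#'   `protein`, `class`, `effect_CA`, `effect_DB`).
#' @export
simulate_intensities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- sim_truth(config)
  n <- config$n_proteins
  r <- config$n_replicates
  # truncated-normal baselines: log2 LFQ intensities are bell-shaped with a
  # thin tail near the detection limit, the regime down-shifted imputation
  # presumes
  lo <- stats::pnorm(config$baseline_mean_range[1], config$baseline_mean, config$baseline_sd)
  hi <- stats::pnorm(config$baseline_mean_range[2], config$baseline_mean, config$baseline_sd)
  baseline <- stats::qnorm(runif(n, lo, hi), config$baseline_mean, config$baseline_sd)
  group_means <- cbind(
    A = baseline, B = baseline,
    C = baseline + truth$effect_CA,
    D = baseline + truth$effect_DB
  )
  samples <- tibble(
    genotype = rep(config$genotypes, each = r),
    replicate = rep(seq_len(r), times = 4),
    tissue = config$tissue
  ) |>
    dplyr::mutate(sample = paste0(.data$genotype, .data$replicate)) |>
    dplyr::select("sample", "genotype", "tissue", "replicate")
  mu <- group_means[, rep(config$genotypes, each = r), drop = FALSE]
  values <- mu + rnorm(n * 4L * r, sd = config$residual_sd)
  dimnames(values) <- list(truth$protein, samples$sample)
  dat <- lfq_data(values, samples)
  if (!is.null(config$dropped_samples)) {
    keep <- setdiff(samples$sample, config$dropped_samples)
    dat <- lfq_subset(dat, samples = keep)
  }
  list(data = dat, truth = truth)
}

#' Censor low-abundance intensities (MNAR missingness)
#'
#' Each cell is independently set missing with probability
#' `plogis((mnar_midpoint - value) * mnar_steepness)`: a logistic
#' left-censoring model in which low-abundance values are preferentially
#' lost, the regime the down-shifted imputation of [impute_downshift()]
#' assumes.
#'
#' @param x a complete [lfq_data()] object.
#' @param config a [sim_config()] (supplies midpoint, steepness and seed).
#' @return An [lfq_data()] object with `NA` cells and updated mask.
#' @export
apply_missingness <- function(x, config) {
  stopifnot(inherits(x, "lfq_data"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p_miss <- plogis((config$mnar_midpoint - x$values) * config$mnar_steepness)
  miss <- matrix(runif(length(p_miss)) < p_miss, nrow(p_miss), ncol(p_miss))
  vals <- x$values
  vals[miss] <- NA_real_
  lfq_data(vals, x$samples)
}

#' Simulate a scale-free protein-protein interaction network with planted
#' modules
#'
#' A preferential-attachment backbone (heavy-tailed degree sequence, in the
#' spirit of curated PPI resources) is overlaid with `n_modules` dense
#' modules whose members are drawn preferentially from planted
#' foxo-dependent proteins. Every edge carries a confidence score in `[0, 1]`;
#' planted module edges score at least 0.4 so the default confidence filter
#' keeps them.
#'
#' @param truth ground-truth tibble from [simulate_intensities()].
#' @param n_nodes total nodes (must be >= number of proteins; extra nodes are
#'   unmeasured interactors).
#' @param n_modules,module_size number and size of planted modules.
#' @param attachment_edges edges added per node in the preferential-attachment
#'   backbone.
#' @param within_module_prob probability of each within-module edge.
#' @param dependent_member_fraction fraction of each module drawn from planted
#'   foxo-dependent proteins (when enough are available).
#' @param seed integer seed.
#' @return A list with `edges` (tibble `node_a`, `node_b`, `confidence`),
#'   `nodes`, and `truth` augmented with a `module_id` column (`NA` = none).
#' @export
simulate_network <- function(truth, n_nodes = NULL, n_modules = 4,
                             module_size = 15, attachment_edges = 3,
                             within_module_prob = 0.9,
                             dependent_member_fraction = 0.8,
                             seed = 1L) {
  n_prot <- nrow(truth)
  if (is.null(n_nodes)) n_nodes <- n_prot + max(50L, round(0.1 * n_prot))
  if (n_nodes < n_prot) abort("`n_nodes` must cover all proteins.")
  if (n_modules * module_size > n_nodes) abort("Modules cannot exceed the node count.")
  set.seed(seed)
  nodes <- c(truth$protein, if (n_nodes > n_prot) sprintf("X%04d", seq_len(n_nodes - n_prot)))
  g <- igraph::sample_pa(n_nodes, m = attachment_edges, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # scramble PA vertex order so early (high-degree) vertices are not all proteins
  perm <- sample(n_nodes)
  backbone <- tibble(
    node_a = nodes[perm[el[, 1]]],
    node_b = nodes[perm[el[, 2]]],
    confidence = runif(nrow(el)),
    planted = FALSE
  )
  truth$module_id <- NA_integer_
  module_edges <- list()
  dep <- truth$protein[truth$class == "foxo_dependent"]
  pool_other <- setdiff(nodes, dep)
  for (m in seq_len(n_modules)) {
    n_dep <- min(length(dep), round(dependent_member_fraction * module_size))
    members <- sample(dep, n_dep)
    dep <- setdiff(dep, members)
    fillers <- sample(pool_other, module_size - n_dep)
    pool_other <- setdiff(pool_other, fillers)
    members <- c(members, fillers)
    truth$module_id[match(members, truth$protein)] <- m
    pairs <- utils::combn(sort(members), 2)
    keep <- runif(ncol(pairs)) < within_module_prob
    if (any(keep)) {
      module_edges[[m]] <- tibble(
        node_a = pairs[1, keep], node_b = pairs[2, keep],
        confidence = runif(sum(keep), 0.4, 1), planted = TRUE
      )
    }
  }
  edges <- dplyr::bind_rows(backbone, module_edges) |>
    dplyr::filter(.data$node_a != .data$node_b) |>
    dplyr::mutate(
      lo = pmin(.data$node_a, .data$node_b),
      hi = pmax(.data$node_a, .data$node_b)
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(confidence = max(.data$confidence),
                     planted = any(.data$planted), .groups = "drop") |>
    dplyr::transmute(node_a = .data$lo, node_b = .data$hi,
                     confidence = .data$confidence, planted = .data$planted)
  list(edges = edges, nodes = nodes, truth = truth)
}

#' Simulate a small ontology DAG over the simulated genes
#'
#' Builds an acyclic term hierarchy of depth `dag_depth` rooted at `"root"`.
#' Each planted network module gets a dedicated term annotated with exactly
#' the module's genes (so enrichment of recovered clusters is checkable
#' against ground truth); remaining terms receive random gene sets with sizes
#' drawn from `size_range`. Gene sets given here are the direct annotations;
#' the true-path closure is built by [build_ontology()].
#'
#' @param truth ground-truth tibble (after [simulate_network()], so that
#'   `module_id` is available; proteins without modules are still annotated).
#' @param n_terms number of random (non-module) terms.
#' @param size_range integer range of random term sizes.
#' @param dag_depth depth of the hierarchy below the root; `1` gives a flat
#'   ontology where every term's parent is the root.
#' @param seed integer seed.
#' @return A list with `term_parent` (tibble `term`, `parent`) and
#'   `term_gene` (tibble `term`, `gene`).
#' @export
simulate_ontology <- function(truth, n_terms = 30, size_range = c(5, 40),
                              dag_depth = 3, seed = 1L) {
  if (dag_depth < 1) abort("`dag_depth` must be at least 1.")
  set.seed(seed)
  genes <- truth$protein
  rand_terms <- sprintf("T%03d", seq_len(n_terms))
  depth <- if (dag_depth == 1) rep(1L, n_terms) else
    sample(seq_len(dag_depth), n_terms, replace = TRUE)
  parent <- character(n_terms)
  for (i in seq_len(n_terms)) {
    cand <- rand_terms[seq_len(i - 1)][depth[seq_len(i - 1)] < depth[i]]
    parent[i] <- if (depth[i] == 1 || !length(cand)) "root" else sample(cand, 1)
  }
  term_parent <- tibble(term = rand_terms, parent = parent)
  term_gene <- purrr::map2_dfr(rand_terms, seq_len(n_terms), function(tm, i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    tibble(term = tm, gene = sample(genes, min(sz, length(genes))))
  })
  mods <- sort(unique(truth$module_id[!is.na(truth$module_id)]))
  if (length(mods)) {
    mod_terms <- sprintf("TMOD%02d", mods)
    term_parent <- dplyr::bind_rows(
      term_parent,
      tibble(term = mod_terms, parent = "root")
    )
    term_gene <- dplyr::bind_rows(
      term_gene,
      purrr::map_dfr(seq_along(mods), function(i) {
        tibble(term = mod_terms[i],
               gene = truth$protein[!is.na(truth$module_id) & truth$module_id == mods[i]])
      })
    )
  }
  list(term_parent = term_parent, term_gene = dplyr::distinct(term_gene))
}

#' A peaked FoxO-like motif model
#'
#' A position weight matrix over the 8-bp FoxO consensus `TTGTTTAC` with a
#' dominant base probability of `peak` per column, plus background base
#' frequencies.
#'
#' @param peak probability of the consensus base in each column.
#' @param background named base frequencies (A, C, G, T).
#' @return A `motif_model` list: `pwm` (4 x width probability matrix),
#'   `background`, `width`, `consensus`.
#' @export
foxo_motif <- function(peak = 0.85,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  consensus <- strsplit("TTGTTTAC", "")[[1]]
  motif_model(consensus, peak = peak, background = background)
}

#' @rdname foxo_motif
#' @param consensus character vector of consensus bases defining the motif.
#' @export
motif_model <- function(consensus, peak = 0.85,
                        background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  bases <- c("A", "C", "G", "T")
  stopifnot(all(consensus %in% bases), abs(sum(background) - 1) < 1e-8)
  w <- length(consensus)
  if (w < 4) abort("Motif width must be at least 4.")
  pwm <- matrix((1 - peak) / 3, 4, w, dimnames = list(bases, NULL))
  for (j in seq_len(w)) pwm[consensus[j], j] <- peak
  structure(
    list(pwm = pwm, background = background[bases], width = w,
         consensus = paste(consensus, collapse = "")),
    class = "motif_model"
  )
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' One promoter of `length` bp per gene, i.i.d. background nucleotides. An
#' exact consensus copy of the motif is inserted at a random position for
#' `plant_fraction` of planted foxo-dependent genes and for
#' `background_fraction` of all other genes.
#'
#' @param truth ground-truth tibble.
#' @param motif a `motif_model` (default [foxo_motif()]).
#' @param plant_fraction fraction of foxo-dependent genes receiving a planted
#'   consensus.
#' @param background_fraction planting rate for all other genes.
#' @param length promoter length in bp (the analysis window is the 1,000 bp
#'   upstream of the TSS).
#' @param seed integer seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   augmented with a logical `motif_planted` column.
#' @export
simulate_promoters <- function(truth, motif = foxo_motif(), plant_fraction = 0.5,
                               background_fraction = 0.05, length = 1000,
                               seed = 1L) {
  if (motif$width >= length) abort("Motif width must be smaller than promoter length.")
  set.seed(seed)
  bases <- names(motif$background)
  n <- nrow(truth)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(bases, length, replace = TRUE, prob = motif$background), collapse = "")
  }, character(1))
  names(seqs) <- truth$protein
  is_dep <- truth$class == "foxo_dependent"
  plant <- (is_dep & runif(n) < plant_fraction) |
    (!is_dep & runif(n) < background_fraction)
  pos <- sample.int(length - motif$width + 1, n, replace = TRUE)
  for (i in which(plant)) {
    substr(seqs[i], pos[i], pos[i] + motif$width - 1) <- motif$consensus
  }
  truth$motif_planted <- plant
  list(sequences = seqs, truth = truth)
}

#' Simulate a complete input bundle with ground truth
#'
#' Runs every generator in sequence — intensities, MNAR censoring, PPI
#' network, ontology, promoters — on seeds derived from `config$seed`, so a
#' fixed seed yields a bit-identical bundle.
#'
#' @param config a [sim_config()].
#' @param network_args,ontology_args,promoter_args named lists of overrides
#'   passed to [simulate_network()], [simulate_ontology()] and
#'   [simulate_promoters()].
#' @return A list of class `synthetic_bundle` with elements `complete`
#'   (pre-censoring [lfq_data()]), `data` (with missing values), `truth`,
#'   `network`, `ontology`, `promoters`, `motif`, `config`.
#' @export
simulate_bundle <- function(config = sim_config(), network_args = list(),
                            ontology_args = list(), promoter_args = list()) {
  sim <- simulate_intensities(config)
  censored <- apply_missingness(sim$data, config)
  net <- do.call(simulate_network,
                 c(list(truth = sim$truth, seed = config$seed + 2L), network_args))
  ont <- do.call(simulate_ontology,
                 c(list(truth = net$truth, seed = config$seed + 3L), ontology_args))
  motif <- promoter_args$motif %||% foxo_motif()
  promoter_args$motif <- NULL
  prom <- do.call(simulate_promoters,
                  c(list(truth = net$truth, motif = motif, seed = config$seed + 4L),
                    promoter_args))
  structure(
    list(
      complete = sim$data,
      data = censored,
      truth = prom$truth,
      network = net$edges,
      nodes = net$nodes,
      ontology = ont,
      promoters = prom$sequences,
      motif = motif,
      config = config
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d proteins, %d network nodes, %d edges, %d terms, seed %d\n",
    nrow(x$truth), length(x$nodes), nrow(x$network),
    dplyr::n_distinct(x$ontology$term_gene$term), x$config$seed
  ))
  print(dplyr::count(x$truth, .data$class))
  invisible(x)
}

write_fasta <- function(sequences, path, width = 70) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path, width = width)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(sequences)) {
      writeLines(paste0(">", nm), con)
      s <- sequences[[nm]]
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    id <- cumsum(idx)
    nm <- sub("^>\\s*", "", lines[idx])
    seqs <- vapply(split(lines[!idx], id[!idx]), paste, character(1), collapse = "")
    setNames(unname(seqs), nm)
  }
}

#' Write a motif in MEME minimal format / read it back
#'
#' @param motif a `motif_model`.
#' @param path file path.
#' @export
write_meme <- function(motif, path) {
  bg <- motif$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    sprintf("MOTIF %s", motif$consensus),
    sprintf("letter-probability matrix: alength= 4 w= %d", motif$width),
    apply(motif$pwm, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                              col["A"], col["C"], col["G"], col["T"]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])
  }
  m_i <- grep("^letter-probability matrix", lines)
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[m_i]))
  rows <- lines[(m_i + 1):(m_i + w)]
  pwm <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
  pwm <- t(pwm)
  rownames(pwm) <- c("A", "C", "G", "T")
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  structure(list(pwm = pwm, background = bg[c("A", "C", "G", "T")], width = w,
                 consensus = consensus),
            class = "motif_model")
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits the TSV/FASTA/MEME dialects consumed by the pipeline: intensity and
#' metadata TSVs, ground-truth TSV, edge-list TSV, term-gene and term-parent
#' TSVs, promoters FASTA, motif in MEME minimal format, and the configuration
#' as YAML.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    metadata = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    edges = file.path(dir, "network_edges.tsv"),
    term_gene = file.path(dir, "term_gene.tsv"),
    term_parent = file.path(dir, "term_parent.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    motif = file.path(dir, "motif.meme"),
    config = file.path(dir, "config.yaml")
  )
  write_lfq_tsv(bundle$data, paths["intensities"], paths["metadata"])
  readr::write_tsv(bundle$truth, paths["truth"], progress = FALSE)
  readr::write_tsv(dplyr::select(bundle$network, "node_a", "node_b", "confidence"),
                   paths["edges"], progress = FALSE)
  readr::write_tsv(bundle$ontology$term_gene, paths["term_gene"], progress = FALSE)
  readr::write_tsv(bundle$ontology$term_parent, paths["term_parent"], progress = FALSE)
  write_fasta(bundle$promoters, paths["promoters"])
  write_meme(bundle$motif, paths["motif"])
  cfg <- bundle$config
  cfg$effect_size <- NULL  # closures do not serialize; record magnitudes' mean instead
  cfg$effect_size_mean <- mean(abs(bundle$truth$effect_CA[bundle$truth$class != "null"]))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], paths["config"])
  invisible(paths)
}
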