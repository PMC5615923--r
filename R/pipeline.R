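#' Pipeline configuration
#'
#' Collects every stage's parameters, per-stage seeds derived from a master
#' seed, and the output directory. The configuration round-trips through
#' YAML (generator closures are summarized, not serialized).
#'
#' @param out_dir output directory for all stage files.
#' @param seed master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @param sim a [sim_config()] for the simulate stage (its seed is set from
#'   `seed`).
#' @param fdr FDR level for significance (default 0.1).
#' @param alpha elim-Fisher elimination threshold (default 0.05).
#' @param min_valid,width,downshift preprocessing parameters.
#' @param spread propagation spreading coefficient (default 0.8).
#' @param tol propagation convergence threshold.
#' @param min_confidence network confidence filter (default 0.4).
#' @param n_clusters clusters to cut the combined-profile tree into.
#' @param p_threshold motif-scan score p-value threshold (default 1e-4).
#' @param t_override optional manual equivalence margin, used when no
#'   protein is significant in the interaction term.
#' @param network_args,ontology_args,promoter_args overrides forwarded to
#'   the bundle generators.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL, fdr = 0.1,
                            alpha = 0.05, min_valid = 4, width = 0.3,
                            downshift = 1.8, spread = 0.8, tol = 1e-9,
                            min_confidence = 0.4, n_clusters = 4,
                            p_threshold = 1e-4, t_override = NULL,
                            network_args = list(), ontology_args = list(),
                            promoter_args = list()) {
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- seed
  structure(
    list(out_dir = out_dir, seed = seed,
         seeds = list(simulate = seed, impute = seed + 10L),
         sim = sim, fdr = fdr, alpha = alpha, min_valid = min_valid,
         width = width, downshift = downshift, spread = spread, tol = tol,
         min_confidence = min_confidence, n_clusters = n_clusters,
         p_threshold = p_threshold, t_override = t_override,
         network_args = network_args, ontology_args = ontology_args,
         promoter_args = promoter_args),
    class = "pipeline_config"
  )
}

pipeline_paths <- function(config) {
  d <- config$out_dir
  inp <- file.path(d, "input")
  c(
    input_dir = inp,
    intensities = file.path(inp, "intensities.tsv"),
    metadata = file.path(inp, "samples.tsv"),
    truth = file.path(inp, "ground_truth.tsv"),
    edges = file.path(inp, "network_edges.tsv"),
    term_gene = file.path(inp, "term_gene.tsv"),
    term_parent = file.path(inp, "term_parent.tsv"),
    promoters = file.path(inp, "promoters.fasta"),
    motif = file.path(inp, "motif.meme"),
    processed = file.path(d, "processed_intensities.tsv"),
    processed_meta = file.path(d, "processed_samples.tsv"),
    contrast_CvsA = file.path(d, "contrast_CvsA.tsv"),
    contrast_DvsB = file.path(d, "contrast_DvsB.tsv"),
    contrast_interaction = file.path(d, "contrast_interaction.tsv"),
    moderation = file.path(d, "moderation.tsv"),
    classification = file.path(d, "classification.tsv"),
    threshold = file.path(d, "equivalence_threshold.tsv"),
    propagation = file.path(d, "propagation.tsv"),
    dendrogram = file.path(d, "dendrogram.newick"),
    enrich_dependent = file.path(d, "enrichment_dependent.tsv"),
    enrich_independent = file.path(d, "enrichment_independent.tsv"),
    enrich_cluster = file.path(d, "enrichment_dependent_cluster.tsv"),
    motif_genes = file.path(d, "motif_gene_hits.tsv"),
    motif_overlap = file.path(d, "motif_overlap.tsv"),
    manifest = file.path(d, "manifest.json"),
    summary = file.path(d, "summary.tsv")
  )
}

read_contrast_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

stage_simulate <- function(config, paths) {
  bundle <- simulate_bundle(config$sim,
                            network_args = config$network_args,
                            ontology_args = config$ontology_args,
                            promoter_args = config$promoter_args)
  write_bundle(bundle, paths["input_dir"])
  invisible(bundle)
}

stage_preprocess <- function(config, paths) {
  dat <- read_lfq_tsv(paths["intensities"], paths["metadata"])
  proc <- preprocess_lfq(dat, min_valid = config$min_valid,
                         width = config$width, downshift = config$downshift,
                         seed = config$seeds$impute)
  write_lfq_tsv(proc, paths["processed"], paths["processed_meta"])
  invisible(proc)
}

stage_de <- function(config, paths) {
  proc <- read_lfq_tsv(paths["processed"], paths["processed_meta"])
  de <- run_diffexp(proc, fdr = config$fdr)
  for (nm in names(de$contrasts)) {
    readr::write_tsv(de$contrasts[[nm]], paths[paste0("contrast_", nm)],
                     progress = FALSE)
  }
  readr::write_tsv(glance(de$moderation), paths["moderation"], progress = FALSE)
  invisible(de)
}

stage_classify <- function(config, paths) {
  cva <- read_contrast_tsv(paths["contrast_CvsA"])
  dvb <- read_contrast_tsv(paths["contrast_DvsB"])
  inter <- read_contrast_tsv(paths["contrast_interaction"])
  t <- if (!is.null(config$t_override)) config$t_override else
    equivalence_threshold(inter, tissue = config$sim$tissue)
  calls <- classify_dependency(cva, dvb, inter, t = t)
  readr::write_tsv(calls, paths["classification"], progress = FALSE)
  t_val <- if (inherits(t, "dependency_threshold")) t$t else t
  n_prov <- if (inherits(t, "dependency_threshold")) nrow(t$provenance) else NA_integer_
  readr::write_tsv(tibble(tissue = config$sim$tissue, t = t_val,
                          n_interaction_significant = n_prov),
                   paths["threshold"], progress = FALSE)
  invisible(calls)
}

stage_propagate <- function(config, paths) {
  calls <- readr::read_tsv(paths["classification"], show_col_types = FALSE,
                           progress = FALSE)
  cva <- read_contrast_tsv(paths["contrast_CvsA"])
  edges <- readr::read_tsv(paths["edges"], show_col_types = FALSE,
                           progress = FALSE)
  net <- ppi_network(edges, min_confidence = config$min_confidence,
                     nodes = union(unique(c(edges$node_a, edges$node_b)),
                                   calls$protein))
  W <- normalize_adjacency(net)
  pvals <- setNames(cva$p, cva$protein)
  bias <- topology_bias(W, alpha = config$spread, tol = config$tol)
  dep <- propagate_profile(pvals, calls$protein[calls$label == "foxo_dependent"],
                           W, alpha = config$spread, tol = config$tol, bias = bias)
  indep <- propagate_profile(pvals, calls$protein[calls$label == "foxo_independent"],
                             W, alpha = config$spread, tol = config$tol, bias = bias)
  combined <- combined_profile(dep, indep)
  clustered <- cluster_scores(combined, n_clusters = config$n_clusters)
  out <- tibble(
    node = dep$node,
    raw_dep = dep$raw, smoothed_dep = dep$smoothed, bias = dep$bias,
    corrected_dep = dep$corrected,
    raw_indep = indep$raw, smoothed_indep = indep$smoothed,
    corrected_indep = indep$corrected,
    combined = clustered$combined, cluster = clustered$cluster
  )
  readr::write_tsv(out, paths["propagation"], progress = FALSE)
  write_dendrogram_newick(attr(clustered, "tree"), paths["dendrogram"])
  invisible(out)
}

stage_enrich <- function(config, paths) {
  calls <- readr::read_tsv(paths["classification"], show_col_types = FALSE,
                           progress = FALSE)
  ont <- build_ontology(
    readr::read_tsv(paths["term_parent"], show_col_types = FALSE, progress = FALSE),
    readr::read_tsv(paths["term_gene"], show_col_types = FALSE, progress = FALSE)
  )
  background <- calls$protein
  dep_set <- calls$protein[calls$label == "foxo_dependent"]
  indep_set <- calls$protein[calls$label == "foxo_independent"]
  if (length(dep_set)) {
    readr::write_tsv(elim_fisher(ont, dep_set, background, alpha = config$alpha),
                     paths["enrich_dependent"], progress = FALSE)
  }
  if (length(indep_set)) {
    readr::write_tsv(elim_fisher(ont, indep_set, background, alpha = config$alpha),
                     paths["enrich_independent"], progress = FALSE)
  }
  # cluster enrichment: the dependent cluster is the one with the highest
  # mean dependent-minus-independent score; background = network proteins
  if (file.exists(paths["propagation"])) {
    prop <- readr::read_tsv(paths["propagation"], show_col_types = FALSE,
                            progress = FALSE)
    prop_meas <- dplyr::filter(prop, .data$node %in% background)
    dep_cluster <- prop_meas |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(m = mean(.data$combined), .groups = "drop") |>
      dplyr::slice_max(.data$m, n = 1, with_ties = FALSE) |>
      dplyr::pull("cluster")
    cluster_genes <- prop_meas$node[prop_meas$cluster == dep_cluster]
    net_background <- prop$node[prop$node %in% background]
    readr::write_tsv(
      elim_fisher(ont, cluster_genes, net_background, alpha = config$alpha),
      paths["enrich_cluster"], progress = FALSE)
  }
  # promoter scan + overlap of motif-bearing genes with the dependent set
  if (file.exists(paths["promoters"]) && length(dep_set)) {
    motif <- read_meme(paths["motif"])
    seqs <- read_fasta(paths["promoters"])
    gene_hits <- scan_promoters(seqs, motif, p_threshold = config$p_threshold)
    readr::write_tsv(gene_hits, paths["motif_genes"], progress = FALSE)
    overlap <- motif_overlap_test(gene_hits$gene[gene_hits$has_hit],
                                  dep_set, background)
    readr::write_tsv(overlap, paths["motif_overlap"], progress = FALSE)
  }
  invisible(NULL)
}

count_tsv_rows <- function(path) {
  if (!file.exists(path)) return(NA_integer_)
  length(readr::read_lines(path, progress = FALSE)) - 1L
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — simulate, preprocess, de,
#' classify, propagate, enrich — with each stage reading its inputs from the
#' files the previous stage wrote under `config$out_dir`, so later stages
#' can be re-run against precomputed files. Writes a JSON manifest (seeds,
#' parameters, per-file row counts) and a summary table.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run, in pipeline order.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess", "de", "classify",
                                    "propagate", "enrich")) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "preprocess", "de", "classify", "propagate", "enrich")
  bad <- setdiff(stages, order_all)
  if (length(bad)) abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- order_all[order_all %in% stages]
  paths <- pipeline_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  runner <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 de = stage_de, classify = stage_classify,
                 propagate = stage_propagate, enrich = stage_enrich)
  for (st in stages) {
    message(sprintf("[foxomics] stage %s", st))
    tryCatch(runner[[st]](config, paths),
             error = function(e) {
               abort(sprintf("Stage '%s' failed: %s", st, conditionMessage(e)))
             })
  }
  manifest <- list(
    package = "foxomics",
    version = as.character(utils::packageVersion("foxomics")),
    seed = config$seed,
    seeds = config$seeds,
    parameters = list(fdr = config$fdr, alpha = config$alpha,
                      min_valid = config$min_valid, width = config$width,
                      downshift = config$downshift, spread = config$spread,
                      min_confidence = config$min_confidence,
                      n_clusters = config$n_clusters,
                      p_threshold = config$p_threshold),
    stages = stages,
    row_counts = lapply(as.list(paths[setdiff(names(paths), "input_dir")]),
                        count_tsv_rows)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  summary_tbl <- pipeline_summary(config)
  if (!is.null(summary_tbl)) {
    readr::write_tsv(summary_tbl, paths["summary"], progress = FALSE)
  }
  invisible(manifest)
}

# Counts of significant proteins per contrast, dependency labels, cluster
# sizes and top enriched terms, collected from the stage output files.
pipeline_summary <- function(config) {
  paths <- pipeline_paths(config)
  rows <- list()
  for (nm in c("CvsA", "DvsB", "interaction")) {
    p <- paths[paste0("contrast_", nm)]
    if (file.exists(p)) {
      tab <- read_contrast_tsv(p)
      rows[[length(rows) + 1]] <- tibble(
        section = "diffexp", item = paste0("significant_", nm),
        value = as.character(sum(tab$significant)))
    }
  }
  if (file.exists(paths["classification"])) {
    calls <- readr::read_tsv(paths["classification"], show_col_types = FALSE,
                             progress = FALSE)
    cnt <- table(calls$label)
    for (lbl in names(cnt)) {
      rows[[length(rows) + 1]] <- tibble(section = "dependency", item = lbl,
                                         value = as.character(cnt[[lbl]]))
    }
  }
  if (file.exists(paths["propagation"])) {
    prop <- readr::read_tsv(paths["propagation"], show_col_types = FALSE,
                            progress = FALSE)
    cs <- table(prop$cluster)
    for (cl in names(cs)) {
      rows[[length(rows) + 1]] <- tibble(section = "clusters",
                                         item = paste0("cluster_", cl),
                                         value = as.character(cs[[cl]]))
    }
  }
  if (file.exists(paths["enrich_dependent"])) {
    enr <- readr::read_tsv(paths["enrich_dependent"], show_col_types = FALSE,
                           progress = FALSE)
    top <- head(enr$term, 3)
    rows[[length(rows) + 1]] <- tibble(section = "enrichment",
                                       item = "top_terms_dependent",
                                       value = paste(top, collapse = ","))
  }
  if (!length(rows)) return(NULL)
  dplyr::bind_rows(rows)
}

#' Validate pipeline input files
#'
#' Checks the TSV schemas, identifier cross-references and FASTA/motif
#' well-formedness of a pipeline input directory.
#'
#' @param dir directory holding the input files written by [write_bundle()].
#' @return A tibble of issues (`file`, `problem`); zero rows means the
#'   inputs are valid.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, problem) {
    issues[[length(issues) + 1]] <<- tibble(file = file, problem = problem)
  }
  ip <- file.path(dir, "intensities.tsv")
  mp <- file.path(dir, "samples.tsv")
  prot <- NULL
  if (!file.exists(ip)) note("intensities.tsv", "missing file")
  if (!file.exists(mp)) note("samples.tsv", "missing file")
  if (file.exists(ip) && file.exists(mp)) {
    tab <- readr::read_tsv(ip, show_col_types = FALSE, progress = FALSE)
    meta <- readr::read_tsv(mp, show_col_types = FALSE, progress = FALSE)
    if (names(tab)[1] != "protein") {
      note("intensities.tsv", "first column must be `protein`")
    } else {
      prot <- tab$protein
      dup <- unique(prot[duplicated(prot)])
      for (d in dup) note("intensities.tsv", paste0("duplicate protein row: ", d))
    }
    miss_cols <- setdiff(c("sample", "genotype", "tissue", "replicate"), names(meta))
    for (mc in miss_cols) note("samples.tsv", paste0("missing column: ", mc))
    if ("sample" %in% names(meta)) {
      absent <- setdiff(meta$sample, names(tab)[-1])
      for (s in absent) {
        note("samples.tsv", paste0("sample missing from intensity header: ", s))
      }
      extra <- setdiff(names(tab)[-1], meta$sample)
      for (s in extra) {
        note("intensities.tsv", paste0("sample column without metadata: ", s))
      }
    }
    if ("genotype" %in% names(meta)) {
      bad <- setdiff(unique(meta$genotype), c("A", "B", "C", "D"))
      for (b in bad) note("samples.tsv", paste0("unknown genotype: ", b))
    }
  }
  ep <- file.path(dir, "network_edges.tsv")
  if (file.exists(ep)) {
    edges <- readr::read_tsv(ep, show_col_types = FALSE, progress = FALSE)
    mc <- setdiff(c("node_a", "node_b", "confidence"), names(edges))
    for (m in mc) note("network_edges.tsv", paste0("missing column: ", m))
    if ("confidence" %in% names(edges) &&
        any(edges$confidence < 0 | edges$confidence > 1)) {
      note("network_edges.tsv", "confidence outside [0, 1]")
    }
  }
  tgp <- file.path(dir, "term_gene.tsv")
  tpp <- file.path(dir, "term_parent.tsv")
  if (file.exists(tgp) && file.exists(tpp)) {
    tg <- readr::read_tsv(tgp, show_col_types = FALSE, progress = FALSE)
    tp <- readr::read_tsv(tpp, show_col_types = FALSE, progress = FALSE)
    ok <- tryCatch({ build_ontology(tp, tg); TRUE }, error = function(e) FALSE)
    if (!ok) note("term_parent.tsv", "cyclic or malformed term DAG")
  }
  fp <- file.path(dir, "promoters.fasta")
  if (file.exists(fp)) {
    first <- readLines(fp, n = 1)
    if (!startsWith(first, ">")) note("promoters.fasta", "not a FASTA file")
    seqs <- tryCatch(read_fasta(fp), error = function(e) NULL)
    if (!is.null(seqs) && !is.null(prot)) {
      absent <- setdiff(prot, names(seqs))
      if (length(absent)) {
        note("promoters.fasta",
             sprintf("%d measured protein(s) without a promoter", length(absent)))
      }
    }
  }
  mm <- file.path(dir, "motif.meme")
  if (file.exists(mm)) {
    m <- tryCatch(read_meme(mm), error = function(e) NULL)
    if (is.null(m)) {
      note("motif.meme", "cannot parse MEME minimal format")
    } else if (any(abs(colSums(m$pwm) - 1) > 1e-3)) {
      note("motif.meme", "PWM columns do not sum to 1")
    }
  }
  if (!length(issues)) {
    return(tibble(file = character(), problem = character()))
  }
  dplyr::bind_rows(issues)
}
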