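#' LFQ intensity data container
#'
#' Bundles a protein-by-sample matrix of log2 LFQ intensities with its
#' missingness mask and per-sample metadata. Missing cells are `NA` in
#' `values` and `TRUE` in `mask`; an `imputed` mask records cells filled in by
#' [impute_downshift()] so downstream steps can audit them.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing.
#' @param samples data frame with one row per column of `values`; must contain
#'   columns `sample`, `genotype` (one of `"A"`, `"B"`, `"C"`, `"D"`),
#'   `tissue` and `replicate`.
#' @param imputed optional logical matrix flagging imputed cells.
#'
#' @details Genotype codes follow the four-group design: A = wild type,
#'   B = foxo-null, C = mNSC-ablated, D = ablated foxo-null. Analyses are run
#'   separately per tissue, so a single `lfq_data` object carries one tissue.
#'
#' @return An object of class `lfq_data`.
#' @export
lfq_data <- function(values, samples, imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (proteins x samples).")
  }
  if (is.null(rownames(values))) {
    abort("`values` must have protein identifiers as rownames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate protein identifiers in `values` rownames.")
  }
  samples <- as_tibble(samples)
  req <- c("sample", "genotype", "tissue", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    abort(paste0("`samples` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(samples) != ncol(values)) {
    abort("`samples` must have one row per column of `values`.")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!identical(colnames(values), as.character(samples$sample))) {
    abort("Column names of `values` must match `samples$sample` in order.")
  }
  bad <- setdiff(unique(samples$genotype), c("A", "B", "C", "D"))
  if (length(bad)) {
    abort(paste0("Unknown genotype label(s): ", paste(bad, collapse = ", ")))
  }
  mask <- is.na(values)
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  structure(
    list(values = values, mask = mask, samples = samples, imputed = imputed),
    class = "lfq_data"
  )
}

#' @export
print.lfq_data <- function(x, ...) {
  cat(sprintf(
    "<lfq_data> %d proteins x %d samples (%s), %.1f%% missing, %.1f%% imputed\n",
    nrow(x$values), ncol(x$values),
    paste(unique(x$samples$tissue), collapse = ","),
    100 * mean(x$mask), 100 * mean(x$imputed)
  ))
  print(dplyr::count(x$samples, .data$genotype))
  invisible(x)
}

#' @export
dim.lfq_data <- function(x) dim(x$values)

#' Tidy an lfq_data object into a long tibble
#'
#' @param x an [lfq_data()] object.
#' @param ... unused.
#' @return A tibble with columns `protein`, `sample`, `genotype`, `tissue`,
#'   `replicate`, `intensity`, `missing`, `imputed`.
#' @method tidy lfq_data
#' @export
tidy.lfq_data <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample", values_to = "intensity")
  mask <- as_tibble(x$mask, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample", values_to = "missing")
  imp <- as_tibble(x$imputed, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "sample", values_to = "imputed")
  long$missing <- mask$missing
  long$imputed <- imp$imputed
  dplyr::left_join(long, x$samples, by = "sample") |>
    dplyr::select("protein", "sample", "genotype", "tissue", "replicate",
                  "intensity", "missing", "imputed")
}

#' @rdname tidy.lfq_data
#' @method glance lfq_data
#' @export
glance.lfq_data <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$values),
    n_samples = ncol(x$values),
    n_genotypes = dplyr::n_distinct(x$samples$genotype),
    missing_rate = mean(x$mask),
    imputed_rate = mean(x$imputed)
  )
}

#' Read / write the intensity TSV dialect
#'
#' The on-disk dialect is two TSV files: an intensity table with a `protein`
#' column followed by one column per sample (empty cell = missing), and a
#' sample-metadata table with columns `sample`, `genotype`, `tissue`,
#' `replicate`.
#'
#' @param intensity_file,metadata_file paths to the two TSVs.
#' @return [read_lfq_tsv()] returns an [lfq_data()] object.
#' @export
read_lfq_tsv <- function(intensity_file, metadata_file) {
  tab <- readr::read_tsv(intensity_file, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "protein") abort("First column of the intensity TSV must be `protein`.")
  meta <- readr::read_tsv(metadata_file, show_col_types = FALSE, progress = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  mode(vals) <- "double"
  rownames(vals) <- tab$protein
  lfq_data(vals, meta)
}

#' @rdname read_lfq_tsv
#' @param x an [lfq_data()] object.
#' @export
write_lfq_tsv <- function(x, intensity_file, metadata_file) {
  tab <- as_tibble(x$values, rownames = "protein")
  readr::write_tsv(tab, intensity_file, na = "", progress = FALSE)
  readr::write_tsv(x$samples, metadata_file, progress = FALSE)
  invisible(c(intensity_file, metadata_file))
}

#' Restrict an lfq_data object to a subset of proteins or samples
#'
#' @param x an [lfq_data()] object.
#' @param proteins,samples character vectors of identifiers to keep (in the
#'   stored order); `NULL` keeps all.
#' @return An [lfq_data()] object.
#' @export
lfq_subset <- function(x, proteins = NULL, samples = NULL) {
  ri <- if (is.null(proteins)) seq_len(nrow(x$values)) else {
    stopifnot(all(proteins %in% rownames(x$values)))
    which(rownames(x$values) %in% proteins)
  }
  ci <- if (is.null(samples)) seq_len(ncol(x$values)) else {
    stopifnot(all(samples %in% colnames(x$values)))
    which(colnames(x$values) %in% samples)
  }
  lfq_data(
    x$values[ri, ci, drop = FALSE],
    x$samples[ci, , drop = FALSE],
    imputed = x$imputed[ri, ci, drop = FALSE]
  )
}
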