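#' Filter proteins on valid values per genotype category
#'
#' Keeps exactly the proteins with at least `min_valid` non-missing values in
#' at least one genotype category, the Perseus-style "minimum of four valid
#' values in at least one category" filter (category = genotype; tissues are
#' analysed in separate runs). Row order is preserved and the filter is
#' idempotent. A category with fewer samples than `min_valid` is allowed — it
#' simply cannot qualify a protein.
#'
#' @param x an [lfq_data()] object.
#' @param min_valid minimum count of observed values required in some
#'   genotype (default 4).
#' @return The filtered [lfq_data()] object.
#' @export
filter_min_valid <- function(x, min_valid = 4) {
  stopifnot(inherits(x, "lfq_data"))
  if (min_valid < 0) abort("`min_valid` must be nonnegative.")
  geno <- x$samples$genotype
  valid <- !x$mask
  counts <- vapply(unique(geno), function(g) {
    rowSums(valid[, geno == g, drop = FALSE])
  }, numeric(nrow(valid)))
  keep <- apply(counts >= min_valid, 1, any) | min_valid == 0
  if (!any(keep)) warn("No protein passes the valid-value filter; result is empty.")
  lfq_subset(x, proteins = rownames(x$values)[keep])
}

#' Impute missing values from a down-shifted normal, per sample column
#'
#' For each sample column with observed mean `m` and observed standard
#' deviation `s`, every missing cell is replaced by an independent draw from
#' `Normal(m - downshift * s, (width * s)^2)` — the Perseus imputation that
#' places imputed values in the low-abundance tail where MNAR censoring
#' occurs. Observed cells are never altered; imputed cells are flagged in the
#' `imputed` mask for audit.
#'
#' @param x an [lfq_data()] object.
#' @param width spread of the imputation distribution as a fraction of the
#'   observed column sd (default 0.3).
#' @param downshift location shift below the observed column mean in column
#'   sd units (default 1.8).
#' @param seed integer seed; a fixed seed makes imputation bit-identical.
#' @return A complete [lfq_data()] object with the `imputed` mask set.
#' @export
impute_downshift <- function(x, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(x, "lfq_data"))
  if (width < 0) abort("`width` must be nonnegative.")
  if (downshift < 0) abort("`downshift` must be nonnegative.")
  vals <- x$values
  n_obs <- colSums(!x$mask)
  if (any(n_obs < 2)) {
    abort(paste0("Column(s) with fewer than 2 observed values: ",
                 paste(colnames(vals)[n_obs < 2], collapse = ", ")))
  }
  set.seed(seed)
  imputed <- x$imputed
  for (j in seq_len(ncol(vals))) {
    miss <- x$mask[, j]
    if (!any(miss)) next
    obs <- vals[!miss, j]
    m <- mean(obs)
    s <- sd(obs)
    vals[miss, j] <- rnorm(sum(miss), mean = m - downshift * s, sd = width * s)
    imputed[miss, j] <- TRUE
  }
  lfq_data(vals, x$samples, imputed = imputed)
}

#' Run filtering and imputation in one step
#'
#' @param x an [lfq_data()] object.
#' @inheritParams filter_min_valid
#' @inheritParams impute_downshift
#' @return A complete [lfq_data()] object.
#' @export
preprocess_lfq <- function(x, min_valid = 4, width = 0.3, downshift = 1.8,
                           seed = 1L) {
  x |>
    filter_min_valid(min_valid = min_valid) |>
    impute_downshift(width = width, downshift = downshift, seed = seed)
}
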