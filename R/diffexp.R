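#' Standard contrasts of the four-genotype design
#'
#' C vs A is the ablation response in the wild-type background, D vs B the
#' response in the foxo-null background, and the interaction contrast
#' (C - A) - (D - B) tests whether the response depends on foxo. Every
#' contrast vector sums to zero.
#'
#' @return A named list of contrast vectors over groups A, B, C, D.
#' @export
standard_contrasts <- function() {
  list(
    CvsA = c(A = -1, B = 0, C = 1, D = 0),
    DvsB = c(A = 0, B = -1, C = 0, D = 1),
    interaction = c(A = -1, B = 1, C = 1, D = -1)
  )
}

#' Fit per-protein group means on the one-way four-genotype layout
#'
#' Ordinary least squares on the group-means parameterization: per protein,
#' the fitted values are genotype means; the residual variance is the pooled
#' within-group variance on `n - G` degrees of freedom (G = number of groups
#' present). Vectorized over proteins.
#'
#' @param x a complete [lfq_data()] object (no missing values).
#' @return A list of class `group_fit`: `means` (protein x group matrix),
#'   `s2` (residual variance), `df` (residual df, common to all proteins),
#'   `n_per_group`, `proteins`, `groups`.
#' @export
fit_group_means <- function(x) {
  stopifnot(inherits(x, "lfq_data"))
  if (any(x$mask)) abort("Matrix contains missing values; impute first.")
  geno <- x$samples$genotype
  groups <- intersect(c("A", "B", "C", "D"), unique(geno))
  n_per_group <- vapply(groups, function(g) sum(geno == g), integer(1))
  if (any(n_per_group < 1)) abort("Every genotype group needs at least one sample.")
  vals <- x$values
  means <- vapply(groups, function(g) {
    rowMeans(vals[, geno == g, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) means <- matrix(means, nrow = 1, dimnames = list(rownames(vals), groups))
  fitted <- means[, match(geno, groups), drop = FALSE]
  rss <- rowSums((vals - fitted)^2)
  df <- ncol(vals) - length(groups)
  if (df < 1) abort("No residual degrees of freedom; need more replicates.")
  structure(
    list(means = means, s2 = rss / df, df = df, n_per_group = n_per_group,
         proteins = rownames(vals), groups = groups),
    class = "group_fit"
  )
}

# Newton inversion of the trigamma function (for moment-matching the
# log-variance spread to a scaled-F prior). Monotone decreasing on (0, Inf).
trigamma_inverse <- function(y) {
  vapply(y, function(v) {
    if (!is.finite(v)) return(NA_real_)
    if (v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    if (v < 1e-6) return(1 / v)
    x <- 0.5 + 1 / v
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / v) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Models the per-protein sample variances as draws from a scaled-F
#' distribution around a prior variance `s0^2` with prior degrees of freedom
#' `d0`, and estimates `(d0, s0^2)` by matching the mean and spread of
#' `log s^2` through digamma/trigamma moment equations (the trigamma inverse
#' is solved by Newton iteration). The posterior (moderated) variance is the
#' degrees-of-freedom-weighted combination
#' `(d0 * s0^2 + df * s2) / (d0 + df)`. If the observed log-variance spread
#' does not exceed the sampling floor `trigamma(df/2)`, the prior is taken as
#' infinitely informative: `d0 = Inf` and every posterior variance equals the
#' common mean variance.
#'
#' @param s2 numeric vector of per-protein residual variances.
#' @param df residual degrees of freedom (scalar or per-protein vector).
#' @return A list of class `moderation_fit`: `prior_df` (d0), `prior_var`
#'   (s0^2), `post_var` (per-protein posterior variances), `df` (residual df).
#' @export
moderate_variances <- function(s2, df) {
  if (all(s2 == 0)) abort("All variances are zero; variance moderation is undefined.")
  if (length(df) == 1) df <- rep(df, length(s2))
  ok <- s2 > 0 & is.finite(s2)
  if (!all(ok)) {
    warn(sprintf("%d zero/non-finite variance(s) excluded from prior estimation.",
                 sum(!ok)))
  }
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1)
  # subtract the sampling variance of log s^2 | sigma^2; remainder is trigamma(d0/2)
  resid_spread <- evar - mean(trigamma(dfo / 2))
  if (is.na(resid_spread) || resid_spread <= 0) {
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  } else {
    d0 <- 2 * trigamma_inverse(resid_spread)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  structure(
    list(prior_df = d0, prior_var = s0_sq, post_var = post, df = df),
    class = "moderation_fit"
  )
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("<moderation_fit> d0 = %.3g, s0^2 = %.4g, %d proteins\n",
              x$prior_df, x$prior_var, length(x$post_var)))
  invisible(x)
}

#' @method tidy moderation_fit
#' @export
tidy.moderation_fit <- function(x, ...) {
  tibble(post_var = x$post_var, df = x$df)
}

#' @method glance moderation_fit
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble(prior_df = x$prior_df, prior_var = x$prior_var,
         n_proteins = length(x$post_var))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' delegating to [stats::p.adjust()]. `NaN` inputs propagate with a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(is.nan(p))) warn("NaN p-values propagated through BH adjustment.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Moderated test of one contrast
#'
#' The contrast estimate is the linear combination of group means; its
#' standard error uses the moderated variance and the group sizes; the
#' moderated t is referred to a t distribution on `d0 + df` degrees of
#' freedom. The 95% CI is `estimate +/- t_{0.975, d0+df} * SE`. Zero standard
#' errors are resolved by convention (p = 0 for a nonzero estimate, else 1)
#' and flagged in `se_zero`.
#'
#' @param fit a `group_fit` from [fit_group_means()].
#' @param moderation a `moderation_fit` from [moderate_variances()].
#' @param contrast named numeric vector over the fitted groups, summing to 0.
#' @param conf_level confidence level for the CI (default 0.95).
#' @param fdr FDR level used for the `significant` flag (default 0.1).
#' @return A tibble with one row per protein: `protein`, `estimate`, `se`,
#'   `t`, `df`, `p`, `adj_p`, `ci_low`, `ci_high`, `significant`, `se_zero`.
#' @export
contrast_test <- function(fit, moderation, contrast, conf_level = 0.95,
                          fdr = 0.1) {
  stopifnot(inherits(fit, "group_fit"), inherits(moderation, "moderation_fit"))
  if (!all(names(contrast) %in% fit$groups)) {
    abort("Contrast names must match fitted groups.")
  }
  cvec <- setNames(rep(0, length(fit$groups)), fit$groups)
  cvec[names(contrast)] <- contrast
  if (abs(sum(cvec)) > 1e-8) abort("Contrast vector must sum to zero.")
  est <- unname(drop(fit$means[, fit$groups, drop = FALSE] %*% cvec))
  unscaled <- sum(cvec^2 / fit$n_per_group[fit$groups])
  se <- unname(sqrt(moderation$post_var * unscaled))
  total_df <- moderation$prior_df + moderation$df
  tstat <- ifelse(se > 0, est / se, ifelse(est != 0, Inf * sign(est), 0))
  p <- ifelse(se > 0, 2 * pt(-abs(tstat), df = total_df),
              ifelse(est != 0, 0, 1))
  tcrit <- qt(1 - (1 - conf_level) / 2, df = total_df)
  adj <- adjust_bh(p)
  tibble(
    protein = fit$proteins,
    estimate = est,
    se = se,
    t = tstat,
    df = total_df,
    p = p,
    adj_p = adj,
    ci_low = est - tcrit * se,
    ci_high = est + tcrit * se,
    significant = adj <= fdr,
    se_zero = se == 0
  )
}

#' Fit the moderated four-group model and test the three study contrasts
#'
#' Convenience wrapper: [fit_group_means()], [moderate_variances()], then
#' [contrast_test()] for C vs A, D vs B and the interaction, with BH
#' adjustment within each contrast.
#'
#' @param x a complete [lfq_data()] object.
#' @param fdr FDR level for significance flags (default 0.1, the study's
#'   adjusted-p cut-off).
#' @param conf_level CI level (default 0.95).
#' @return A list of class `diffexp_fit` with `fit`, `moderation` and
#'   `contrasts` (named list of tibbles from [contrast_test()]).
#' @export
run_diffexp <- function(x, fdr = 0.1, conf_level = 0.95) {
  fit <- fit_group_means(x)
  moderation <- moderate_variances(fit$s2, fit$df)
  contrasts <- purrr::map(standard_contrasts(), contrast_test,
                          fit = fit, moderation = moderation,
                          conf_level = conf_level, fdr = fdr)
  structure(list(fit = fit, moderation = moderation, contrasts = contrasts,
                 fdr = fdr),
            class = "diffexp_fit")
}

#' @export
print.diffexp_fit <- function(x, ...) {
  cat(sprintf("<diffexp_fit> %d proteins, d0 = %.3g, FDR = %g\n",
              length(x$fit$proteins), x$moderation$prior_df, x$fdr))
  for (nm in names(x$contrasts)) {
    cat(sprintf("  %-12s %4d significant\n", nm, sum(x$contrasts[[nm]]$significant)))
  }
  invisible(x)
}

#' @method tidy diffexp_fit
#' @export
tidy.diffexp_fit <- function(x, ...) {
  dplyr::bind_rows(x$contrasts, .id = "contrast")
}

#' @method glance diffexp_fit
#' @export
glance.diffexp_fit <- function(x, ...) {
  tibble(
    n_proteins = length(x$fit$proteins),
    prior_df = x$moderation$prior_df,
    prior_var = x$moderation$prior_var,
    fdr = x$fdr,
    sig_CvsA = sum(x$contrasts$CvsA$significant),
    sig_DvsB = sum(x$contrasts$DvsB$significant),
    sig_interaction = sum(x$contrasts$interaction$significant)
  )
}

#' Volcano plot for a contrast table
#'
#' @param object a tibble from [contrast_test()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot contrast_result
#' @export
autoplot.contrast_result <- function(object, ...) {
  plot_volcano(object)
}

#' @rdname autoplot.contrast_result
#' @param contrast_tbl a tibble from [contrast_test()].
#' @export
plot_volcano <- function(contrast_tbl, ...) {
  ggplot2::ggplot(contrast_tbl,
                  ggplot2::aes(.data$estimate, -log10(.data$p),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "FDR sig.") +
    ggplot2::theme_minimal()
}
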