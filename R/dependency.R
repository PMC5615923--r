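#' Data-derived equivalence margin for a tissue
#'
#' The margin `t` of the equivalence interval `[-t, t]` is the minimum
#' absolute log2 fold change among proteins significant in the interaction
#' contrast — the smallest interaction effect the tissue's data could detect.
#' (On the study's real tissues this procedure gave brain 0.072, fat body
#' 0.177, gut 0.155, thorax 0.216.)
#'
#' @param interaction a contrast tibble from [contrast_test()] for the
#'   interaction contrast.
#' @param tissue optional tissue label recorded in the result.
#' @return A list of class `dependency_threshold`: `t`, `tissue`,
#'   `provenance` (tibble of the significant interaction proteins).
#' @export
equivalence_threshold <- function(interaction, tissue = NA_character_) {
  sig <- dplyr::filter(interaction, .data$significant)
  if (nrow(sig) == 0) {
    abort(paste0(
      "No protein is significant in the interaction term, so the equivalence ",
      "margin cannot be derived from the data; supply `t` manually ",
      "(classify_dependency(..., t = <value>))."
    ))
  }
  structure(
    list(
      t = min(abs(sig$estimate)),
      tissue = tissue,
      provenance = dplyr::select(sig, "protein", "estimate", "adj_p")
    ),
    class = "dependency_threshold"
  )
}

#' @export
print.dependency_threshold <- function(x, ...) {
  cat(sprintf("<dependency_threshold> t = %.4g (%s; min |log2FC| over %d interaction-significant proteins)\n",
              x$t, x$tissue %||% "unspecified tissue", nrow(x$provenance)))
  invisible(x)
}

#' Equivalence of a confidence interval within the margin
#'
#' A protein's interaction effect is equivalent to zero when the 95% CI of
#' its log2 fold change lies entirely within the closed interval `[-t, t]`.
#'
#' @param ci_low,ci_high CI bounds (vectorized).
#' @param t equivalence margin (> 0), a scalar or a `dependency_threshold`.
#' @return Logical vector.
#' @export
is_equivalent <- function(ci_low, ci_high, t) {
  if (inherits(t, "dependency_threshold")) t <- t$t
  if (t <= 0) abort("Equivalence margin `t` must be positive.")
  (-t <= ci_low) & (ci_high <= t)
}

#' Classify ablation-responsive proteins as foxo-dependent or -independent
#'
#' Implements the study's decision procedure on the three contrast tables.
#' Only proteins significant in C vs A (the ablation response in the
#' wild-type background) are ever labelled. Rules, in precedence order:
#'
#' * **dependent_interaction** (i): significant interaction; when the D vs B
#'   response is significant and shares the sign of C vs A, the C vs A
#'   response must additionally be the stronger (`|CvsA| > |DvsB|`) —
#'   otherwise the protein falls through to the exaggeration rule below.
#' * **dependent_abrogated** (ii, off by default): no significant
#'   interaction, but significant same-direction responses in both
#'   backgrounds with the C vs A response stronger. The published definition
#'   treats the "stronger response" proviso as a condition *within* the
#'   interaction-significant rule, not a separate pattern, so this rule is
#'   enabled only with `abrogation_rule = TRUE`; left on, it relabels noisy
#'   equivalence failures among truly background-independent responders.
#' * **independent_equivalent** (iii): the interaction CI lies within the
#'   closed equivalence interval `[-t, t]`.
#' * **independent_exaggerated** (iv): a stronger same-direction significant
#'   response in the foxo-null background (`|DvsB| > |CvsA|`, D vs B
#'   significant), regardless of interaction significance.
#'
#' Conflicts between rules are decided by the interaction-significance
#' branch: a significant interaction commits the protein to rules (i)/(iv);
#' without one, the explicit equivalence criterion (iii) outranks the
#' abrogation heuristic (ii). Proteins satisfying both a dependent and an
#' independent rule are flagged in `rule_conflict`.
#'
#' @param cva,dvb,inter contrast tibbles from [contrast_test()] for C vs A,
#'   D vs B and the interaction, aligned on the same proteins.
#' @param t equivalence margin: a `dependency_threshold`, a positive scalar,
#'   or `NULL` to derive it from `inter` via [equivalence_threshold()].
#' @param abrogation_rule enable rule (ii) (default `FALSE`; see above).
#' @return A tibble with one row per protein: `protein`, `label` (factor
#'   `foxo_dependent` / `foxo_independent` / `unclassified`), `rule`,
#'   estimates and significance flags for the three contrasts, `equivalent`,
#'   `rule_conflict`.
#' @export
classify_dependency <- function(cva, dvb, inter, t = NULL,
                                abrogation_rule = FALSE) {
  if (!identical(cva$protein, dvb$protein) ||
      !identical(cva$protein, inter$protein)) {
    abort("The three contrast tables must be aligned on the same proteins.")
  }
  if (is.null(t)) t <- equivalence_threshold(inter)
  t_val <- if (inherits(t, "dependency_threshold")) t$t else t
  if (t_val <= 0) abort("Equivalence margin `t` must be positive.")

  same_sign <- sign(cva$estimate) == sign(dvb$estimate) & cva$estimate != 0
  stronger_ca <- abs(cva$estimate) > abs(dvb$estimate)
  equivalent <- is_equivalent(inter$ci_low, inter$ci_high, t_val)

  # (i) interaction-significant dependence; exaggerated responses excluded
  rule_i <- inter$significant &
    !(same_sign & dvb$significant & !stronger_ca)
  # (ii) optional: abrogation pattern without interaction significance
  rule_ii <- if (abrogation_rule) {
    !inter$significant & dvb$significant & same_sign & stronger_ca
  } else {
    rep(FALSE, nrow(cva))
  }
  # (iii) interaction equivalent to zero
  rule_iii <- equivalent
  # (iv) exaggerated: stronger same-direction significant response in the
  # foxo-null background, regardless of interaction significance
  rule_iv <- dvb$significant & same_sign & !stronger_ca

  label <- rep("unclassified", nrow(cva))
  rule <- rep(NA_character_, nrow(cva))
  # precedence: the branch set by interaction significance decides. With a
  # significant interaction, rules (i)/(iv) rule; without one, the explicit
  # equivalence criterion (iii) outranks the abrogation heuristic (ii).
  label[rule_ii] <- "foxo_dependent"
  rule[rule_ii] <- "dependent_abrogated"
  label[rule_iii] <- "foxo_independent"
  rule[rule_iii] <- "independent_equivalent"
  label[rule_iv] <- "foxo_independent"
  rule[rule_iv] <- "independent_exaggerated"
  label[rule_i] <- "foxo_dependent"
  rule[rule_i] <- "dependent_interaction"
  conflict <- (rule_i | rule_ii) & (rule_iii | rule_iv)

  eligible <- cva$significant
  label[!eligible] <- "unclassified"
  rule[!eligible] <- NA_character_
  conflict[!eligible] <- FALSE

  tibble(
    protein = cva$protein,
    label = factor(label, levels = c("foxo_dependent", "foxo_independent",
                                     "unclassified")),
    rule = rule,
    estimate_CvsA = cva$estimate,
    estimate_DvsB = dvb$estimate,
    estimate_interaction = inter$estimate,
    sig_CvsA = cva$significant,
    sig_DvsB = dvb$significant,
    sig_interaction = inter$significant,
    ci_low_interaction = inter$ci_low,
    ci_high_interaction = inter$ci_high,
    equivalent = equivalent,
    rule_conflict = conflict
  )
}

#' Classify directly from a diffexp fit
#'
#' @param de a `diffexp_fit` from [run_diffexp()].
#' @inheritParams classify_dependency
#' @return See [classify_dependency()].
#' @export
classify_from_fit <- function(de, t = NULL, abrogation_rule = FALSE) {
  stopifnot(inherits(de, "diffexp_fit"))
  classify_dependency(de$contrasts$CvsA, de$contrasts$DvsB,
                      de$contrasts$interaction, t = t,
                      abrogation_rule = abrogation_rule)
}

#' Plot the classification against the two background responses
#'
#' @param calls tibble from [classify_dependency()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_dependency <- function(calls, ...) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(.data$estimate_CvsA, .data$estimate_DvsB,
                               colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7, size = 0.9) +
    ggplot2::labs(x = "log2 FC, C vs A (wild-type background)",
                  y = "log2 FC, D vs B (foxo-null background)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
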