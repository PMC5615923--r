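---
title: "Methods: classifying FoxO-dependent proteomic responses to reduced IIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying FoxO-dependent proteomic responses to reduced IIS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxomics)
```

## The scientific question and the design

Reduced insulin/IGF-like signalling (IIS) extends lifespan across taxa; in
*Drosophila*, ablating the insulin-producing median neurosecretory cells
(mNSCs) lowers circulating insulin-like peptides, and the transcription
factor dFOXO mediates part of the downstream response. The four-genotype
design separates dFOXO-dependent from dFOXO-independent proteome changes:

| code | genotype                      | role                         |
|------|-------------------------------|------------------------------|
| A    | wild type                     | baseline                     |
| B    | *foxo*-null                   | baseline without dFOXO       |
| C    | mNSC-ablated                  | reduced IIS                  |
| D    | mNSC-ablated, *foxo*-null     | reduced IIS without dFOXO    |

The contrasts of interest are the ablation response in the wild-type
background (C − A), the response without dFOXO (D − B), and their
interaction (C − A) − (D − B). Tissues behave differently under reduced
IIS, so each tissue is analysed as an independent run.

## Preprocessing

LFQ intensities are analysed on the log2 scale. Two Perseus-style steps:

* **Valid-value filter.** A protein is kept when it has at least
  `min_valid = 4` observed values in at least one genotype. A genotype with
  fewer samples than `min_valid` simply cannot qualify a protein; the filter
  is idempotent and order-preserving.
* **Down-shifted imputation.** Separately for each sample column with
  observed mean $m$ and standard deviation $s$, missing cells are drawn
  independently from $N(m - 1.8\,s,\ (0.3\,s)^2)$. This places imputed
  values in the low-abundance tail, which is where intensities go missing
  (left-censoring at the detection limit). Column statistics use the
  observed cells only, and mean/sd rather than median-based statistics —
  the standard Perseus behaviour. Imputed cells are flagged in an audit
  mask but treated as ordinary values downstream.

The `width = 0.3` and `downshift = 1.8` defaults are the conventional
Perseus parameters (fractions/multiples of the observed column sd).

## Moderated linear models

Each protein is fit by ordinary least squares on the one-way four-genotype
layout; the residual variance $s_g^2$ is pooled within groups on
$d_g = n - G$ degrees of freedom. Because $d_g$ is small, per-protein
variances are noisy; they are moderated by an empirical-Bayes scaled-F
model: $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g$ with a
scaled-inverse-chi-square prior $\sigma_g^2 \sim d_0 s_0^2 / \chi^2_{d_0}$.
The hyperparameters are estimated by moment matching on
$z_g = \log s_g^2$ using the digamma/trigamma identities
$\mathrm{E}[z] = \log s_0^2 + \psi(d_g/2) - \log(d_g/2) + \log(d_0/2) -
\psi(d_0/2)$ and $\mathrm{Var}[z] = \psi'(d_g/2) + \psi'(d_0/2)$; the
trigamma inverse is solved by Newton iteration. When the observed
log-variance spread does not exceed the sampling floor $\psi'(d_g/2)$ the
prior is taken as infinitely informative ($d_0 = \infty$, posterior variance
= mean variance). The posterior variance is the precision-weighted
combination $(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$.

Contrasts are tested with moderated $t$ statistics on $d_0 + d_g$ degrees
of freedom; 95% CIs use the same df (the df convention for CIs is our
choice; with moderation the posterior df is the natural scale). P-values
are Benjamini–Hochberg adjusted within each contrast and significance is
called at adjusted $p \le 0.1$, the FDR level of the original analysis.
Plain moderation is used — no intensity-dependent variance trend and no
robustness against variance outliers.

## Dependency classification

Only proteins significant in C − A are ever labelled. Rules, in the
precedence set by the interaction-significance branch:

1. **dependent (interaction)** — significant interaction; if the D − B
   response is significant and same-direction, C − A must be the stronger
   response (otherwise the protein is an exaggeration candidate, below).
2. **independent (equivalence)** — the interaction 95% CI lies inside the
   closed interval $[-t, t]$, where $t$ is the minimum $|\log_2 FC|$ among
   interaction-significant proteins of the tissue. The margin is
   data-derived: it is the smallest interaction effect the tissue's data
   could actually detect. If no protein is interaction-significant the
   margin cannot be derived and must be supplied explicitly.
3. **independent (exaggerated)** — a stronger same-direction significant
   response in the foxo-null background, regardless of interaction
   significance.

An optional **abrogation** rule (significant same-direction responses in
both backgrounds, C − A stronger, no significant interaction) can be
enabled with `abrogation_rule = TRUE`. It is off by default: the published
definition reads the "stronger response" clause as a proviso within the
interaction rule rather than a standalone pattern, and on synthetic data
the standalone reading relabels roughly half of the truly independent
proteins whose interaction CI misses the equivalence margin by noise.
The equivalence test is applied to the interaction contrast (the Methods
formulation), not to a separate responsiveness-difference statistic, and
interval membership is closed at the boundaries.

## Network propagation

Raw (unadjusted) C − A p-values of the dependent set (respectively the
independent set) are mapped to the PPI network as $Y_i = -\log_2 p_i$, with
excluded proteins set to $p = 1$, i.e. $Y_i = 0$. The network is filtered
at 40% edge confidence, self-loops dropped and parallel edges collapsed to
their maximum confidence. The adjacency is normalized symmetrically,
$W = D^{-1/2} A D^{-1/2}$ — the degree-symmetric reading of a "Laplacian"
normalization, chosen because diffusing with $I - W$ itself does not spread
scores. Scores are smoothed by

$$F \leftarrow \alpha W F + (1 - \alpha) Y, \qquad \alpha = 0.8,$$

iterated from $F_0 = Y$ until the maximum absolute change drops below
`tol = 1e-9` (the spectral radius of $\alpha W$ is below 1, so this
contraction always converges; the closed form is
$(I - \alpha W)F = (1-\alpha)Y$). Binary adjacency is the default;
confidence-weighted adjacency is a flag. Hubs accumulate score regardless
of signal, so a topology bias — the same diffusion started from the unit
vector — is subtracted from every smoothed profile. On $k$-regular graphs
the bias is exactly 1 and the correction is rank-preserving.

The dependent-minus-independent corrected profile is clustered with
complete-linkage hierarchical clustering on Euclidean distances
(`stats::hclust`); the cluster count is a parameter (default 4) because the
original tree-cut level is not recorded, and the "dependent cluster" used
for enrichment is the cluster with the highest mean combined score.

## Enrichment

* **elim Fisher.** Terms are tested bottom-up by DAG depth (lexical order
  within a level) with one-sided hypergeometric tests; when a term's elim
  p-value reaches $\alpha = 0.05$, its annotated genes are removed from all
  ancestors before those are tested. Classic p-values are reported
  alongside. The enrichment score is $\log_2(\text{observed}/\text{expected})$
  and a reporting flag marks terms with at least 5 significant genes.
  The one-sided Fisher test is computed as a hypergeometric tail — they are
  identical.
* **PCA tails.** Proteins are observations; the signed contribution of a
  protein to a dimension is its squared coordinate share, signed by the
  coordinate, with the component sign fixed so the largest-|coordinate|
  protein is positive. The upper/lower `q = 0.05` quantile tails feed the
  enrichment test; boundary ties go to the lower set so `q = 0.5`
  partitions.
* **PWM scanning.** Promoter windows are the 1,000 bp upstream of the TSS.
  Windows are scored on both strands by summed $\log_2(\mathrm{pwm}/\mathrm{bg})$
  odds; the score p-value is computed exactly by dynamic programming over
  the discretized score distribution (bins of 1e-3 on the log-odds scale;
  scanner and DP share one integer grid, so the p-value is exact for the
  discretized score). Hits are reported at $p \le 10^{-4}$. `N` bases
  contribute zero log-odds. The reverse strand reuses the forward score
  distribution, which is exact because complementing the background maps
  word probabilities bijectively.
* **Motif overlap.** Genes with promoter hits are intersected with a
  regulated set under a hypergeometric test, with selection and background
  limited to measured proteins; the fraction of regulated genes carrying a
  motif is reported alongside.
* **Directional shift.** A named set's log2 fold changes are tested against
  zero with a two-sided one-sample $t$ test; zero-variance inputs are
  flagged and resolved by convention.

## The synthetic-data generator

The generator emulates the statistical structure of a tissue-specific LFQ
experiment with known ground truth; it is the package's test bed, not a
model of any particular dataset.

* **Design**: 4 genotypes × 6 replicates, one tissue per bundle (tissues
  are independent runs); an optional drop list emulates excluded samples.
* **Baselines**: per-protein log2 baselines from $N(30, 3^2)$ truncated to
  [22, 38] — bell-shaped like real LFQ intensity histograms, with a thin
  tail near the detection limit.
* **Effect classes**: `null` (70%), `foxo_dependent` (15%; C − A effect,
  D − B zero), `foxo_independent` (10%; identical effects), `exaggerated`
  (5%; D − B response 1.5× the C − A response). Effect magnitude defaults
  to a constant 1.0 log2 unit with random sign; residual noise is
  i.i.d. $N(0, 0.3^2)$.
* **Missingness**: each cell is censored with probability
  $\mathrm{logistic}((22.5 - x) \times 1.0)$ — left-censoring confined to
  the low-abundance tail, giving ~5% missing cells overall, comparable to
  filtered MaxQuant output.
* **Network**: a preferential-attachment backbone (heavy-tailed degrees)
  plus dense planted modules recruited preferentially (80%) from
  foxo-dependent proteins; planted edges carry confidence ≥ 0.4 so the
  default filter retains them.
* **Ontology**: a random acyclic term hierarchy plus one term per planted
  module annotated with exactly the module's genes, so cluster enrichment
  is checkable against truth.
* **Promoters**: 1,000 bp i.i.d. background sequence; an exact FoxO-like
  consensus (`TTGTTTAC`) is inserted for 50% of foxo-dependent genes and 5%
  of others.

What the generator does **not** emulate: peptide-level structure, retention
time, between-tissue correlation, intensity-dependent variance trends,
correlated (batch) noise, or annotation incompleteness. Passing tests
demonstrate that the pipeline's inference machinery is correct and
well-calibrated under its own assumptions; they do not certify performance
on real proteomes, where those unmodelled features matter.

## Numerical choices and degenerate inputs

* Propagation convergence: max-absolute-change < 1e-9, cap 10,000
  iterations, error on non-convergence with the residual reported.
* Zero p-values are clipped to the smallest positive double before
  $-\log_2$; zero standard errors resolve to $p \in \{0, 1\}$ by the sign
  of the estimate, flagged.
* All-equal variances give $d_0 = \infty$ without error; all-zero
  variances are an error (degenerate simulation).
* hclust merge order and `cutree` give deterministic clusters for a fixed
  input order; duplicated profiles are at distance zero and can never be
  split.
* Every stochastic step takes an explicit seed; a fixed seed makes the
  bundle, the imputation and the whole pipeline run bit-identical.

## Problem sizes used in the validation suite

The test-bed sizes were chosen to make Monte-Carlo checks stable at
interactive runtimes: 50 random graphs up to 500 nodes for the propagation
oracle; 10,000 imputed cells for the imputation moments; 5,000 proteins ×
20 replicate draws for moderation recovery; 100 global-null datasets of
1,000 proteins for the FDR property; and the default 1,500-protein bundle
for classifier recovery and the end-to-end run.

## Known limitations

* The equivalence margin needs at least one interaction-significant
  protein; sparse tissues require a manual margin.
* The moderated-CI df convention and the raw-p propagation choice are
  package decisions where the original description is silent; both are
  configurable.
* elim traversal order beyond "deepest level first" is resolved lexically;
  other traversals can differ on ties.
* The PWM p-value is exact only with respect to the discretized score; the
  1e-3 bin makes the discretization error negligible at the 1e-4 threshold.
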