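# foxomics

Lowered insulin/IGF-like signalling (IIS) extends lifespan in *Drosophila*,
and much of that response is routed through the transcription factor dFOXO.
A proteomic way to ask *which* downstream changes need dFOXO is to profile
four genotypes per tissue — wild type (A), *foxo*-null (B), insulin-producing
mNSC-ablated (C), and ablated *foxo*-null (D) — and test, protein by protein,
whether the ablation response in the wild-type background (C − A) survives
the loss of *foxo* (D − B).

`foxomics` implements that analysis as a reusable, fully testable R pipeline
for label-free quantification (LFQ) proteomes:

* **Preprocessing** — Perseus-style filtering (≥ `min_valid` observed values
  in at least one genotype) and missing-value imputation from a down-shifted
  normal: per sample column with observed mean *m* and sd *s*, missing cells
  are drawn from *N*(*m* − 1.8 *s*, (0.3 *s*)²).
* **Moderated linear models** — per-protein one-way fits over the four
  genotypes with empirical-Bayes variance moderation: sample variances are
  shrunk toward a prior (*d*₀, *s*₀²) estimated by log-variance moment
  matching, and the contrasts C − A, D − B and the interaction
  (C − A) − (D − B) are tested with moderated *t* statistics,
  Benjamini–Hochberg corrected at FDR 0.1.
* **Dependency classification** — a protein significant in C − A is
  *foxo-dependent* when the interaction term is significant (with a
  stronger same-direction response in C − A), and *foxo-independent* when
  its interaction 95% CI falls inside the equivalence interval [−*t*, *t*]
  (with *t* the minimum |log2FC| among interaction-significant proteins of
  that tissue) or when the foxo-null response is the stronger one.
* **Network propagation** — −log2 *p* scores diffused over a
  confidence-filtered PPI network by F ← αWF + (1 − α)Y with
  W = D^(−1/2) A D^(−1/2) and α = 0.8, corrected for topology bias
  (the same diffusion started from a unit vector) and clustered by
  Euclidean-distance complete-linkage on the dependent-minus-independent
  profile.
* **Enrichment** — hand-implemented elim-Fisher ontology enrichment with the
  score log2(observed/expected), PCA contribution tails, PWM promoter
  scanning with exact DP score p-values (threshold 1e−4), hypergeometric
  motif-overlap tests, and directional one-sample *t* tests.
* **Synthetic data** — a generator that emulates the whole study design with
  planted ground truth (effect classes, network modules, ontology terms,
  promoter motifs), so every stage can be validated without any downloads.

## Worked example

```r
library(foxomics)

# a synthetic tissue: 1,500 proteins, 4 genotypes x 6 replicates,
# planted |log2FC| = 1 effects, MNAR censoring near the detection limit
bundle <- simulate_bundle(sim_config(seed = 1))
proc   <- preprocess_lfq(bundle$data)      # filter >=4 valid, impute
de     <- run_diffexp(proc, fdr = 0.1)     # moderated contrasts
glance(de)
#>   n_proteins prior_df prior_var   fdr sig_CvsA sig_DvsB sig_interaction
#> 1       1498     8.70    0.0938   0.1      455      234             244

calls <- classify_from_fit(de)
table(calls$label)
#>   foxo_dependent foxo_independent     unclassified
#>              209              140             1149

equivalence_threshold(de$contrasts$interaction, tissue = "gut")
#> <dependency_threshold> t = 0.5123 (gut; min |log2FC| over 244
#>   interaction-significant proteins)
```

Of the 1,498 proteins passing the valid-value filter, 455 respond to mNSC
ablation in the wild-type background; 209 of those need dFOXO for their
response (90% of the planted foxo-dependent class is recovered, with a 3%
false-labelling rate against the generator's ground truth), while 140 respond
identically without it. The equivalence margin *t* is derived from the data
as the smallest interaction effect the tissue could detect. Downstream,
`propagate_profile()` + `cluster_scores()` smooth the two significance
profiles over the PPI network, and `elim_fisher()` names the functional
modules each cluster represents; `plot_volcano()`, `plot_dependency()`,
`plot_propagation()` and `plot_enrichment()` draw each stage.

A full run with all intermediate TSVs is one call (or
`inst/scripts/foxomics run-all --seed 1 --out run1` from a shell):

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

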