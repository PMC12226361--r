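# plmatch

Differential-enrichment analysis for TurboID proximity-labeling (PL)
proteomics, built around one observation: **the background control must
express TurboID at the same level as the bait fusion.** Streptavidin
enrichment carries a large background that scales with TurboID expression,
so a control expressing less TurboID than the bait makes background
proteins look enriched (false positives), a control expressing more drowns
weakly labeled interactors (false negatives), and intensity normalization
repairs neither — with an over-expressing control it instead promotes
endogenously biotinylated proteins (ACACA-like carboxylases) into the
apparent interactome.

`plmatch` provides:

* **Quantification** from DIA-NN-style long-format precursor reports:
  unique-peptide filtering, per-sample total-intensity normalization (each
  sample rescaled to a summed intensity of 10<sup>7</sup>), protein
  aggregation by precursor sum, Top1, or a MaxLFQ-style pairwise-ratio
  solver, 1%-quantile imputation, log2 transform.
* **Testing**: an empirical-Bayes moderated t-test (variance shrinkage via
  moment matching of log variances to a scaled-F prior,
  s²ₚₒₛₜ = (d₀s₀² + d_g s_g²)/(d₀ + d_g)), Benjamini–Hochberg FDR,
  enrichment calls at fold change > 2 and adjusted p < 0.05, and the
  signed significance score π = −log₁₀(p) · sign(log₂FC).
* **Evaluation**: cross-control occurrence-frequency consensus, ROC/AUROC
  against known interactors, abundance-quartile relative-intensity
  analysis, per-protein linear fits of intensity vs TurboID expression
  (R²), and a control-matching report that recommends the control
  minimizing |log₂(E_control/E_bait)|.
* **A seeded simulator** of PL experiments reproducing the structure of
  real streptavidin data: abundance- and pI-biased bead background,
  labeling proportional to TurboID expression with per-protein response
  heterogeneity, endogenously biotinylated background, and detection-limit
  dropout, with per-protein ground truth for FP/FN accounting.

## Worked example

Simulate a bait (relative TurboID expression 1) with candidate controls at
0.25x, 1x and 4x, run the non-normalized pipeline, and compare the
controls:

```r
library(plmatch)

sim <- simulate_experiment(sim_config(seed = 1))
tab <- filter_min_unique_peptides(sim$report, 2)
mat <- log2_transform(impute_quantile(aggregate_proteins(tab, "sum")))

controls <- c("ctrl_low", "ctrl_matched", "ctrl_high")
diffs <- lapply(controls, function(ctl)
  classify_calls(fit_moderated(mat, sim$design, "bait", ctl)$result))
names(diffs) <- controls

mr <- matching_report(diffs, sim$design, "bait", truth = sim$truth)
mr$report
#>        control expression_mismatch n_enriched n_de_enriched true_positives
#> 1     ctrl_low                  -2       1582             0            197
#> 2 ctrl_matched                   0        192             0            191
#> 3    ctrl_high                   2         48          1611             48
#>   false_positives false_negatives
#> 1            1385              15
#> 2               1              21
#> 3               0             164
mr$recommended_control
#> [1] "ctrl_matched"
```

The under-expressing control calls 1,385 background proteins enriched; the
over-expressing control misses 164 of the 212 true interactors; the matched
control yields 191 true positives against a single false positive. Ranking
by π-value against the simulated truth:

```r
pos <- sim$truth$protein_group[sim$truth$is_interactor]
roc_analysis(diffs$ctrl_matched, pos)$auroc
#> [1] 0.9950328
```

The same run is available as one call with side-by-side normalized and
non-normalized branches:

```r
run_pipeline(list(simulation = list(seed = 1),
                  quantify = list(normalize = c("total", "none"))),
             out_dir = "pl_run")
```

or from a shell via the thin front-end
`Rscript inst/scripts/plmatch.R run --config pipeline.yaml --out DIR`
(subcommands: `simulate`, `quantify`, `diffexp`, `consensus`, `evaluate`,
`run`).

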