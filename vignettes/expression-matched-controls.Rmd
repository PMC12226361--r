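---
title: "Expression-matched controls for TurboID proximity-labeling proteomics"
author: "plmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-matched controls for TurboID proximity-labeling proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmatch)
```

## The problem

TurboID proximity labeling identifies the neighborhood of a bait protein by
fusing it to a promiscuous biotin ligase and enriching biotinylated proteins
on streptavidin beads. The enrichment step is statistically treacherous for
two reasons:

1. **Background is large and structured.** Streptavidin beads pull down a
   substantial background even without any TurboID expression, biased toward
   abundant proteins (most of the background comes from the top abundance
   quartile) and toward basic (high-pI) proteins. On top of that, a small
   set of endogenously biotinylated carboxylases (ACACA-like) binds the
   beads regardless of labeling.
2. **Labeling scales with ligase expression.** Per protein, the captured
   signal is close to proportional to how much TurboID the cell expresses.
   The number of identified proteins and the total ion signal both climb
   with expression, and — because detection has a lower limit — extra
   expression disproportionately lifts low-abundance proteins into the
   detected set.

A bait fusion is therefore only comparable to a control fusion (typically
TurboID-eGFP) when the two express TurboID at a similar level. A control
that expresses *less* than the bait makes every background protein look
bait-enriched (false positives); a control that expresses *more* drowns
weakly labeled true interactors (false negatives). Intensity normalization
narrows but does not remove the distortion, and with a strongly
over-expressing control it actively promotes endogenously biotinylated
background into the apparent interactome. `plmatch` implements the
quantification and testing pipeline around this observation, plus a
generative simulator that reproduces the structure above so the claims can
be exercised end to end.

## The pipeline

Starting from a DIA-NN-style long-format precursor report and a study
design (sample, group, role, replicate, relative TurboID expression from
whole-cell proteomics), the stages are:

1. **Unique-peptide filter** (`filter_min_unique_peptides`, default 2):
   proteins identified by a single unique peptide are excluded. Peptides
   are counted as distinct modified sequences with the charge stripped.
2. **Total-intensity normalization** (`normalize_total_intensity`,
   optional): each precursor intensity is scaled by
   `1e7 / (sample total)`, so every sample sums to 10,000,000. Applied at
   the precursor level, before aggregation. The pipeline can run the
   normalized and non-normalized branches side by side, because comparing
   the two is itself diagnostic.
3. **Aggregation** (`aggregate_proteins`): `sum` of present precursor
   intensities (the primary method), `top1` (the single precursor with the
   largest cross-sample total, chosen once so response factors stay
   comparable across samples; ties broken by lexicographic id), or
   `maxlfq` (median pairwise log-ratios solved by least squares over the
   sample graph, per connected component, each component rescaled to its
   sum-aggregate total; single-sample components keep their sum intensity).
   The delayed-normalization stage of full MaxLFQ is out of scope.
4. **Imputation** (`impute_quantile`): missing cells replaced by the 1%
   quantile of the sample's present values, with the linear-interpolation
   order-statistic convention `h = (n-1)q + 1`. The per-sample variant is
   the default; a global-matrix variant is available (`global = TRUE`)
   because the convention is not uniquely determined by common practice.
5. **log2 transform**, then the **moderated t-test** (`fit_moderated`):
   per-protein pooled two-group variances are shrunk toward a scaled-F
   prior estimated by matching the first two moments of `log(s^2)`
   (digamma/trigamma identities, Newton inversion of the trigamma). The
   posterior variance is the convex combination
   `(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`; the statistic has `d0 + d_g`
   degrees of freedom. When the log-variance dispersion does not exceed
   chi-square sampling noise the prior df is infinite and all variances
   collapse to the prior. Plain moderation only — no trend or robust
   variants. `prior_df = 0` recovers the classical pooled t-test exactly.
6. **Calls and scores**: Benjamini–Hochberg adjustment (`bh_adjust`);
   enriched means fold change > 2 *and* adjusted p < 0.05 (`classify_calls`);
   ranking uses the pi-value `-log10(p) * sign(log2FC)` (`pi_value`).
7. **Evaluation** (`occurrence_frequency`, `roc_analysis`,
   `abundance_quartiles`, `relative_intensity`, `expression_response_fit`,
   `matching_report`): cross-control consensus (a protein called enriched
   against 3 or more of 6 independent controls is high-confidence), AUROC
   against a known-interactor list by the rank formula with tie averaging,
   rank-based abundance quartiles with stable tie-breaks, relative
   intensities against the lowest-expression baseline group (arithmetic
   mean of per-protein ratios, not ratio of means), per-protein OLS of
   group-mean intensity on group TurboID expression (proteins quantified in
   at least 3 groups; zero-variance responses get R² = 0), and a
   control-matching report that recommends the control minimizing
   `|log2(E_control / E_bait)|`.

All stages carry provenance flags (`normalized`, `imputed`, `log2`) and
refuse to run out of order.

## The simulator

`simulate_experiment()` draws, per protein *i*: whole-cell abundance
`A_i ~ lognormal(log 1e4, 2)` (about four decades of dynamic range), an
isoelectric point `pI_i ~ N(7, 1.5)`, a precursor count `1 + Poisson(4)`
with Dirichlet(1) response fractions fixed across samples, and membership
flags (10% true interactors; 2% endogenously biotinylated proteins sampled
with 10:1 weight toward the top abundance decile, since carboxylases are
abundant). For a sample in group *g* with relative TurboID expression
`E_g`, the expected captured signal is

$$S_{ig} = B_i + A_i \, P_{ig} \, E_g^{\,1+\eta_i} + D\,[\mathrm{endog}_i]$$

with bead background `B_i = beta0 * A_i^gamma * exp(delta (pI_i - 7))`
(defaults `beta0 = 5e-5`, `gamma = 1.6`, `delta = 0.25`), proximity factor
`P_ig` equal to a per-interactor boost in bait groups (log-normal around 5,
sd 0.5 on the log scale, truncated at 1) and 1 otherwise, endogenous level
`D = 2e5`, and a per-protein response exponent `eta_i ~ N(0, 0.2^2)`.
Observed precursor intensities are `S * fraction * exp(eps)` with
`eps ~ N(0, 0.3^2)` per cell; cells below the detection limit (400) are
missing. A logistic dropout width can replace the hard threshold. The
default group layout is a bait at relative expression 1 with candidate
controls at 0.25x, 1x and 4x — the control-titration design — and three
biological replicates per group, the standard for cell-culture label-free
experiments.

Parameter choices worth explaining:

* **Bead background (`gamma = 1.6`, `beta0 = 5e-5`, LOD 400).** These were
  fixed together so that, with no TurboID expression, the detected
  background is dominated by the top abundance quartile (roughly 75–80% of
  detections; real bead background exceeds 50%) while a group at
  expression 1 still detects about half the proteome. The `gamma > 1`
  exponent is what makes background occupy proportionally more of the
  signal for abundant proteins, which in turn produces the observed
  pattern that low-abundance proteins gain several-fold more relative
  intensity from rising expression than the most abundant proteins do.
* **Response heterogeneity (`response_sdlog = 0.2`).** Real per-protein
  intensities track TurboID expression well but not perfectly: in titration
  data most, but not all, proteins fit a line with R² > 0.5. The exponent
  form `E^(1+eta_i)` reproduces that imperfect proportionality and encodes
  the central mechanism of this package: the deviation cancels exactly when
  bait and control expression are equal, and surfaces as protein-level
  fold-change scatter (invisible to replicate variance) when they are not.
  With `eta` suppressed, a mismatched comparison ranks interactors
  essentially as well as a matched one and the matching benefit cannot be
  observed in the ROC.
* **Interactor heterogeneity (`interactor_boost_sdlog = 0.5`).** Proximity
  labeling rates vary with distance and residence time; a uniform boost
  makes every interactor equally easy. The log-normal spread creates the
  weak interactors that an over-expressed control buries — the
  false-negative arm of the matching argument.
* **One global labeling scale.** Only relative expression matters; the
  scale constant is absorbed into the intensity units. Labeling time is
  deliberately folded into `E` as well.
* **Not modeled:** retention time and ion mobility, charge-state effects,
  interference/chimeric spectra, batch effects, additive electronic noise
  (the detection limit subsumes it). Simulated whole-cell abundances are
  noise-free, so abundance-quartile assignments are exact rather than
  estimated. Passing tests therefore demonstrate the pipeline's behavior
  under multiplicative noise with dropout, not robustness to run-order or
  acquisition artifacts.

## Numerical and design choices

* **Zero intensity in input reports is missing.** DIA-NN writes 0 or blank
  interchangeably for non-quantified precursors; treating 0 as detected
  would poison log transforms and dropout semantics.
* **Quantile convention** is the linear-interpolation order-statistic rule
  (the default of the major statistical environments), stated explicitly
  because "1% quantile" alone does not pin it down.
* **Variance floor.** Constant imputation can produce zero residual
  variance; such variances are floored at 1e-12 before prior estimation,
  which leaves ranks intact while avoiding infinite statistics. A fit in
  which *every* protein has zero residual variance is refused as
  degenerate.
* **Complete-shrinkage estimate.** With zero dispersion of log variances
  the moment estimator returns the prior `exp(mean(log s^2) - digamma(d/2)
  + log(d/2))`; the digamma term is the chi-square log-bias correction, so
  the prior is *not* numerically equal to the common variance. This matches
  the established empirical-Bayes implementations.
* **Error calibration is assessed on the non-normalized matched branch.**
  Total-intensity normalization is compositional: when true enrichment is
  present, the bait's interactor signal inflates its totals and every null
  protein is pushed slightly negative, yielding many small but genuinely
  significant fold changes. That is a property of the normalization (and
  one of the phenomena this package exists to expose), not of the test;
  on non-normalized matched data the realized false-discovery proportion
  at BH 0.05 sits near the nominal level.
* **FP/FN accounting uses the enriched arm only.** Interactome analysis
  treats enrichment as the discovery direction; de-enriched calls are
  reported but not counted as discoveries.
* **Ties.** Quartile ties break by protein id after the abundance sort;
  Top1 ties break by lexicographic precursor id; AUROC averages tied
  ranks. All outputs are deterministic given a config and seed.

## Problem sizes used in the checks

The test suite and the acceptance script run the simulator at 2,000
proteins with 3 replicates per group — large enough for stable quartile and
calibration estimates, small enough to iterate over tens of seeds. Error
calibration uses 100 seeds in the test suite (20 in the reporting script);
directional properties (detection monotonicity, quartile gains) use 50
seeds; the control-matching benchmark uses 20. Real experiments quantify
3–8k proteins; the simulated scale reproduces the structure, not the
absolute counts, of the deposited datasets.

## Known limitations

* Two-group contrasts only; no multi-factor or paired designs.
* Protein groups are opaque identifiers: no shared-peptide resolution, no
  gene-symbol normalization.
* The MaxLFQ solver implements the pairwise-ratio core only.
* The simulator's expression heterogeneity is a single log-normal exponent
  per protein; real deviations from proportionality are likely structured
  (compartment, solubility, labeling radius).
* Imputation at a constant low quantile understates uncertainty for
  proteins missing in a whole group; the moderated test partially absorbs
  this, but calls driven mostly by imputed cells deserve skepticism — one
  reason the cross-control occurrence frequency is the recommended final
  filter.
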