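---
title: "Quantifying chaperone-mediated autophagy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chaperone-mediated autophagy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaflux)
```

Chaperone-mediated autophagy (CMA) degrades individual cytosolic proteins in
lysosomes: substrates carrying KFERQ-like motifs are delivered by the Hsc70
chaperone to the LAMP2A receptor, which is rate-limiting for the pathway.
CMA activity is frequently elevated in cancer, and its transcriptional
program (activating components such as the receptor and chaperones, and
repressing components such as inhibitory signalling genes) can be summarised
into a single per-sample activity score.  `cmaflux` implements that score
together with the downstream quantitative workflows used around it:
qPCR-derived expression, cohort statistics, high-content screen hit calling,
and a lysosomal-flux proteomics classifier.  This vignette documents the
models, the parameters that matter, and the design choices made where more
than one reasonable convention exists.

## The transcriptional CMA score

For sample $s$ the score is the weighted, directed average

$$S_s = \frac{\sum_i w_i\, d_i\, v_{i,s}}{\sum_i w_i},$$

over the genes of a configurable CMA network, where $w_i > 0$ is the
component weight, $d_i \in \{+1,-1\}$ its direction (+1 for components that
promote CMA activity, −1 for repressors), and $v_{i,s}$ a transformed
expression value.  By convention LAMP2A carries weight 2 — it is the
rate-limiting step — and all other components weight 1.

**What $v$ is.**  Averaging raw expression would let a single highly
expressed gene dominate the score, and displayed score analyses are
z-scale comparisons across samples.  The default is therefore
`log2(x + 1)` followed by per-gene z-standardisation (sample SD, $n-1$
denominator; constant genes map to 0).  Both steps can be switched off
(`transform = "none"`, `standardize = "none"`), which is also how the
package's exactness tests pin the arithmetic.  Because standardisation is
computed *within the matrix passed in*, the score is a comparison within
that cohort: to compare across cohorts (e.g. across cancer types), score
the pooled matrix, never per-cohort matrices.

**Missing network genes.**  Public matrices rarely contain every network
gene.  The default (`missing_genes = "renormalize"`) renormalises the
weights over the genes present and emits a warning; `"error"` is available
for strict workflows.  Gene symbols are matched case-insensitively (human
and mouse symbol case differ).

**The network is configuration, not code.**  The package ships
`inst/extdata/cma_network_example.tsv`, an *illustrative, synthetic*
network (LAMP2A at weight 2 plus plausible activator and repressor
symbols).  It demonstrates the file format and exercises the pipeline; it
is not a curated gene list, and real analyses should supply their own
network file.

## qPCR-derived expression

`relative_expression_from_ct()` converts Ct tables to relative expression
against a single housekeeping gene, $2^{-\Delta Ct}$.  The
$\Delta\Delta Ct$ step (referencing a control group) is deliberately left
to the score's z-standardisation, which subsumes it: subtracting a
reference-group mean is an affine shift that per-gene standardisation
removes anyway.  The housekeeping row equals 1 everywhere by construction,
and a missing housekeeping value in any sample is an error naming that
sample.

## The lysosomal-flux proteomics classifier

The classifier starts from a protein × sample intensity matrix with
missing values and a design crossing genotype (WT / LAMP2A-knockdown),
treatment (vehicle / drug) and lysosomal inhibition (none / N-L, i.e.
ammonium chloride + leupeptin).  The steps, in order:

1. **Preprocess** — log2 transform, then normalisation by the average of
   each sample: the mean of the sample's observed log2 values is
   subtracted (equivalently, raw intensities are divided by their
   geometric mean).  Missingness is untouched.
2. **Impute** — each missing cell in sample $s$ is drawn from
   $N(\mu_s - k\sigma_s, (w\sigma_s)^2)$ with downshift $k = 2$ and width
   $w = 0.3$, where $\mu_s,\sigma_s$ are the sample's observed mean and
   SD.  The downshift models the missing-not-at-random (MNAR) character
   of proteomics data — values are absent mostly because they fall below
   the detection limit.  The 0.3 width is the conventional
   Perseus-style spread, a convention rather than a derived quantity;
   both are configurable in `flux_params()`.  Imputation is seeded and
   bit-reproducible.
3. **Differential abundance** — per-protein linear fold change
   $2^{\bar{A}-\bar{B}}$ and a two-tailed Welch (heteroscedastic) t-test
   with Welch–Satterthwaite degrees of freedom.  One shared
   implementation (`welch_test()`) serves both this module and the cohort
   statistics.
4. **Degradation call** — a protein is degraded in lysosomes in a given
   background if its N/L-vs-none fold change is at least `fc_flux`
   (default 1.2, inclusive) with p < `alpha` (default 0.05, raw).
5. **Set logic** — CMA substrates are proteins degraded in WT but not in
   the LAMP2A-knockdown background; drug-sensitive substrates are
   degraded under vehicle but not under drug.  Both sets are by
   construction subsets of the WT/vehicle degraded set.

**Thresholds are parameters.**  Closely related analyses use different
level-change cutoffs (1.5/0.8-fold for protein levels, 1.5/0.5-fold for
RNA-seq, with a 1.2/0.8 variant also in circulation for protein-level
displays).  Rather than adjudicating, `flux_params()` and `de_filter()`
expose them with per-analysis defaults (proteome 1.5/0.8; RNA-seq
1.5/0.5) — change them explicitly when a different convention is needed.

**Raw p-values by default.**  The historical pipeline applies an
unadjusted p < 0.05; `multiple_testing = "BH"` enables
Benjamini–Hochberg adjustment for more conservative use.

**Small-sample behaviour of Welch's test.**  With 3 replicates per group
and equal variances, the Welch–Satterthwaite approximation is mildly
conservative (empirical type-I error ≈ 0.036 at nominal 0.05; the
behaviour is identical in `stats::t.test`).  The calibration suite
therefore checks the nominal level at 10 replicates per group, where the
approximation is accurate, and treats the small-$n$ conservatism as a
property of the test, not a defect of the implementation.

## Cohort statistics

* `zscore_hits()` — screen readouts (puncta per cell of a fluorescent CMA
  reporter) are averaged over replicates per compound and z-standardised
  across the compounds of a batch; hits are `z < -1` (strict).  Z-scores
  are computed across all compounds passed in (one batch); the
  alternative — per imaging plate — is achieved by calling the function
  per plate.  Z-scores are affine-invariant, so units of the raw readout
  do not matter.
* `correlate_ratio_score()` — ordinary least squares of CMA score on the
  NCoR1/RARA expression ratio across cohort units (e.g. cancer types),
  with Pearson r and the two-tailed slope p-value.
* `stratify_by_mutation()` — WT-vs-mutant comparison (default TP53) of
  per-sample scores or ratios, using the shared Welch test; reports
  per-stratum mean ± SEM and the direction of the difference.

## Synthetic data and what passing tests mean

Every analysis stage has a seeded generator producing data with exactly
the structure the stage assumes, plus a `synthetic_truth` object recording
what was planted, so recovery is measurable:

* `simulate_expression_cohort()` — i.i.d. log-normal baseline expression;
  in designated groups each network gene's log2 mean shifts by
  `direction × score_shift` (default 1 log2 unit, noise SD 0.5, 20 per
  group) — a coherent, direction-consistent shift, the pattern the score
  detects.
* `simulate_ct_table()` — housekeeping Ct ≈ 20 cycles plus planted
  per-gene ΔCt and 0.1-cycle measurement noise.
* `simulate_proteome()` — full 2×2×2 design, 3 replicates per cell,
  baseline log2 intensities N(25, 2²); 15% of proteins are lysosomal
  substrates accumulating 1.5-fold under N/L; 40% of those lose the
  effect in the knockdown (CMA substrates) and 37% under drug
  (drug-sensitive, drawn from the CMA substrates, as a CMA-selective
  compound only blocks CMA-dependent degradation — the planted fractions
  echo, at small scale, the observed roughly-one-third drug-sensitive
  share).  Replicate noise is 0.1 log2 units.  Missingness (5% of cells)
  is MNAR: a logistic function of intensity with slope 10 per SD of log2
  intensity, i.e. a 10–90% dropout transition of roughly one log2 unit,
  mimicking detection-limit censoring; the intercept is calibrated so the
  overall rate is exact.
* `simulate_screen()` — 94 compounds, 3 replicates; planted inhibitors
  (default 16) have mean puncta reduced by `inhibition_depth` (default
  80%); at depth 0 the z-scores are a standard-normal sample, so the
  expected `z < -1` hit rate is the Gaussian tail (~16%).

**Expected recovery, honestly stated.**  Under the default proteome
conditions the classifier's expected sensitivity is about 0.92 per call,
not 1: the per-sample normalisation absorbs a small part of the planted
effect (15% of the proteome shifts under N/L, so centring removes
~0.09 log2 units), and the substrates that fall below the MNAR detection
limit are unrecoverable after imputation — information that censoring has
destroyed.  Specificity is ≈ 0.995+.  With ~55–150 planted positives per
call these sensitivities carry a binomial SD of 0.02–0.035 across seeds.

**What the generators do not emulate.**  Real proteomes have correlated
proteins (complexes, shared regulation), peptide-level quantification
artefacts, batch effects and heavier-tailed noise; real cohorts have
library-size and composition effects, and mutation status correlates with
lineage.  Passing recovery tests therefore demonstrates that the
implementation computes the intended procedure and that the procedure
works under its own assumptions — not that those assumptions hold in any
particular real dataset.

## Numerical conventions and degenerate inputs

* Welch test with zero variance in both groups: t = 0 and p = 1 when the
  means agree; p = 0 when they differ (a difference observed without
  noise).  This makes noiseless synthetic recovery exact.
* The degradation threshold is inclusive (fold change ≥ `fc_flux`); a
  fold change of 1.19 with p = 10⁻⁶ is *not* called at the default 1.2.
* The screen hit cutoff is strict (`z < -1`); a plate with zero spread
  yields a warning and no hits, not an error.
* Constant gene rows standardise to 0; fractions are computed as exact
  ratios with the whole-percent reported by integer truncation
  (316/833 → 37.93…%, "~37%").
* All generators and the imputer restore the caller's RNG state; the
  same seed reproduces outputs bit-for-bit, and pipeline runs via the
  `run_*()` functions write timestamp-free run records so reruns are
  byte-identical.

## Problem sizes used by the test suite

The suite exercises the score oracle on 100 random instances, the
flux-recovery check on a 1000-protein proteome, the Welch calibration on
10,000 null contrasts at 10 replicates per group, the imputer calibration
on >10,000 imputed cells, and the screen null-rate check on 40 simulated
plates — sizes chosen to make Monte-Carlo error small relative to the
tolerances being asserted while keeping the default test run fast.

## Known limitations

* The shipped network file is an illustrative fixture; scientific use
  requires a curated network.
* The classifier starts from protein intensities: search-engine output,
  peptide-to-protein inference and FDR control are upstream and out of
  scope, as are image segmentation for the screen readout and dose-response
  (IC50) fitting.
* With n = 3 replicates, Welch's test is conservative and single-protein
  calls near the thresholds are fragile; the pipeline reports exact fold
  changes and p-values so downstream users can apply stricter criteria.
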