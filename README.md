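# cmaflux

Quantitative workflows for studying **chaperone-mediated autophagy (CMA)**
— the selective lysosomal degradation pathway in which Hsc70 delivers
KFERQ-motif proteins to the rate-limiting receptor LAMP2A.  CMA is commonly
upregulated in cancer, and `cmaflux` packages the analyses used to measure
it from omics data:

* **Transcriptional CMA score.** For each sample $s$,
  $S_s = \sum_i w_i d_i v_{i,s} / \sum_i w_i$ over a configurable gene
  network, where $w_i > 0$ is the component weight (LAMP2A carries 2, all
  other components 1), $d_i \in \{+1,-1\}$ the direction (activating vs.
  repressing), and $v_{i,s}$ the log2, per-gene z-standardised expression.
  qPCR input is supported via $2^{-\Delta Ct}$ relative expression.
* **Lysosomal-flux proteomics classifier.** From a protein × sample
  intensity matrix with missing values: log2 transform, per-sample-mean
  normalisation, downshifted-normal imputation (2 SD below the sample
  mean, 0.3 SD spread), Welch differential abundance, then set logic —
  a protein is *degraded in lysosomes* if it accumulates ≥ 1.2-fold
  (p < 0.05) under protease inhibition (NH₄Cl + leupeptin), a *CMA
  substrate* if that degradation disappears on LAMP2A knockdown, and
  *drug-sensitive* if it disappears under compound treatment.
* **Cohort statistics.** NCoR1/RARα expression-ratio vs. score regression
  across cancer types, TP53 WT-vs-mutant stratification (Welch test),
  fold-change/p filtering for differential expression, and z-score hit
  calling for high-content screens (hits at z < −1).
* **Seeded synthetic-data generators** for each input type, with planted
  ground truth, so every stage is testable end-to-end without downloads.

## Worked example

```r
library(cmaflux)

net <- read_cma_network(system.file("extdata", "cma_network_example.tsv",
                                    package = "cmaflux"))
net
#> CMA network 'cma_network_example.tsv': 7 genes (5 activating, 2 repressing), total weight 8
#>    gene weight direction
#>  LAMP2A      2         1
#>   HSPA8      1         1
#>   ...

# a cohort in which the "shifted" group has coherently activated CMA genes
sim <- simulate_expression_cohort(n_genes = 500, n_per_group = 10,
                                  net = net, score_shift = 1, seed = 42)
scores <- cma_score(sim$expr, net)
head(scores, 4)
#>  sample_id      score
#>  control_1 -0.3945806
#>  control_2 -0.1592831
#>  control_3 -1.0222298
#>  control_4 -1.1692413

by <- split(scores$score, sim$annotations$group)
welch_test(by$shifted, by$control)
#> shifted - control score difference: 1.52 (Welch p = 1e-09)
```

The score is dimensionless (a weighted mean of z-values): positive values
mean the sample's CMA network is coherently shifted toward activity
relative to the cohort; the planted one-log2-unit shift is recovered as a
~1.5 score-unit difference.  The shipped network file is an
**illustrative fixture** (it shows the format and drives examples); real
analyses should supply a curated network TSV/YAML.

The proteomics classifier, end to end:

```r
prot <- simulate_proteome(n_proteins = 1000, seed = 42)   # planted truth inside
calls <- call_flux(prot$dataset, seed = 43)
calls
#> flux_call_table: 1000 proteins
#>   degraded in lysosomes (WT/vehicle): 141
#>   CMA substrates (lost in L2AKD):     61
#>   drug-sensitive substrates:          55 (39% of degraded, ~39%)
```

141 of 1000 proteins accumulate significantly under lysosomal protease
inhibition (the planted rate is 15%); 61 lose that degradation in
LAMP2A-knockdown cells and are therefore called CMA substrates; for 55 the
compound blocks degradation.  `summarize_fraction()` turns such counts
into the reported percentage, e.g. `summarize_fraction(316, 833)` →
37.94%, whole percent 37.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/cmaflux`, with subcommands `score`, `flux-call`,
`screen-hits`, `axis-corr` and `simulate {expression,ct,proteome,screen}`;
every run writes a timestamp-free `run_record.json`, so identical
config + seed reruns are byte-identical.

See `vignettes/cmaflux-methods.Rmd` for the models, parameter
conventions, and the design decisions behind the defaults.

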