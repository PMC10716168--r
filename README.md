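# connectodev

Analysis toolkit for the longitudinal development of weighted white-matter
structural connectomes, and for asking what shapes its spatial pattern:
regional gene expression, cell-type composition, and cortical
cytoarchitecture. It is written for imaging researchers who have per-scan
connectivity matrices (e.g. FA×FN-weighted from diffusion tractography), a
longitudinal cohort manifest, and region-level annotation tables — and for
methodologists who want every estimator in that pipeline exercised against
synthetic data with planted ground truth.

## What it computes

**Network properties.** For a symmetric nonnegative weighted adjacency
matrix $W$ with edge lengths $1/w_{ij}$: global/local/nodal efficiency,
characteristic path length, strength, Onnela weighted clustering, and
betweenness normalised by $1/((n-1)(n-2))$. Small-world ratios
$\gamma = C_p/\langle C_p^{rand}\rangle$,
$\lambda = L_p/\langle L_p^{rand}\rangle$, $\sigma = \gamma/\lambda$ are
taken against matched random networks (degree-preserving double-edge swaps
plus weight permutation). A group-average network keeps edges present in
≥75% of scans; hubs (degree strength or betweenness above mean + sd) induce
the rich-club/feeder/local edge taxonomy, alongside within/between-module
and long/short edge classes.

**Developmental trajectories.** Linear, quadratic and age×sex mixed-effect
models

$$y_{ij} = \beta_0 + b_i + (\beta_{age} + b_{age,i})\,age_{ij}
 + \beta_{sex} sex_i + \beta_{tbv} tbv_{ij} + \beta_{centre} centre_i + \varepsilon_{ij}$$

fitted by ML with AIC model selection, Wald and parametric-bootstrap
intervals for $\beta_{age}$, Bonferroni-corrected standardised per-region
slope maps, and spatial gradient contrasts.

**Imaging transcriptomics.** Univariate-response PLS of the slope map
against a region×gene expression matrix; permutation inference corrected
for spatial autocorrelation with variogram-matched surrogate maps;
bootstrap gene-weight z-scores with Bonferroni-1% positive/negative gene
selection; cell-type overlap enrichment against resampled gene sets; and
category enrichment whose null refits the PLS against every surrogate (so
it respects gene co-expression and spatial autocorrelation), with BH-FDR.

**Cytoarchitecture.** Spearman and partial (laminar-specific) rank
correlations of the slope map with myelin, L1–L6 laminar thickness and
cortical thickness maps, all with surrogate-based p-values.

**Synthetic study.** `make_regions()`, `simulate_cohort()`,
`simulate_expression()`, `simulate_annotations()` and
`simulate_cortical_maps()` generate every input with known ground truth —
planted slope fields, a planted expression component, a planted enriched
cell class, planted map correlations — so each estimator can be tested for
recovery and each permutation test for calibration.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
cohort (150 subjects, ≤3 yearly waves, 90 regions) and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_network_metrics.R
Rscript analysis/03_trajectories.R
Rscript analysis/04_transcriptomics.R
Rscript analysis/05_enrichment_cytoarchitecture.R
```

Output from a run of scripts 02–05:

```
group network: E_glob 4.008, E_loc 7.337, L_p 0.3121, C_p 0.418
small-world: gamma 3.22, lambda 1.47, sigma 2.19 (sigma > 1)
edge taxonomy: 149 rich-club / 234 feeder / 218 local edges; 26 hub regions
planted-slope recovery (degree strength, raw scale): r = 0.999
PLS component 1: r = 0.68, explained = 46.5%, SAC p = 0.022
selected genes at Bonferroni 1%: 33 positive, 41 negative
planted class 'excitatory': overlap 18, p = 9.999e-05 (smallest class p: excitatory)
```

Reading this: the distance-dependent synthetic network is strongly
small-world ($\sigma = 2.19 > 1$); the per-region age slopes estimated by
the mixed model reproduce the planted slope field almost exactly
(r = 0.999); the first PLS component of expression correlates r = 0.68 with
the estimated slope map and survives the spatial-autocorrelation-corrected
permutation test (p = 0.022 with 500 surrogates); the selected genes are
dominated by the planted true-support set, and the planted cell class is
the one flagged by the overlap permutation test at its near-minimal
attainable p.

A minimal programmatic session:

```r
library(connectodev)
regions <- make_regions(90, seed = 1)
sim <- simulate_cohort(regions, n_subjects = 150, seed = 2)
group <- group_average_network(sim$cohort)          # 75% prevalence rule
sm <- fit_slope_map(sim$cohort, "n_eglob")          # standardised slopes
head(sm[sm$significant, ])
```

`run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` runs every stage
end to end with logged sub-seeds; two runs with the same master seed write
byte-identical tables.

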