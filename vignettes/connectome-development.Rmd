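---
title: "Modelling the development of weighted white-matter connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of weighted white-matter connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`connectodev` implements a longitudinal analysis of weighted white-matter
structural connectomes: graph-theoretical network properties, mixed-effect
developmental trajectories, a connectome–transcriptome association via
partial least squares with spatially constrained permutation inference,
cell-type and gene-category enrichment, and correlations with
cytoarchitectural cortical maps. This vignette explains the models, the
defaults, and the design decisions; the numbers quoted are recomputed by the
test suite and by `scripts/acceptance.R`, not asserted here.

## Network model and metrics

A connectome is a symmetric nonnegative weighted adjacency matrix $W$ over
$R$ brain regions (for instance FA$\times$FN weights: mean fractional
anisotropy times streamline count), zero on the diagonal. Edge length for
path computations is $1/w_{ij}$, so stronger connections are shorter, and
$d_{ij}$ is the Dijkstra shortest-path distance.

* Global efficiency $E_{glob} = \frac{1}{R}\sum_i \frac{\sum_{j \ne i}
  d_{ij}^{-1}}{R-1}$ (disconnected pairs contribute zero); nodal efficiency
  is the inner average, so `mean(nodal_efficiency(x))` equals
  `global_efficiency(x)` exactly — a tested identity.
* Local efficiency of node $i$ is the global efficiency of the subgraph
  induced by $i$'s neighbours with $i$ removed and original weights kept;
  nodes with fewer than two neighbours contribute zero (the standard
  Latora–Marchiori convention; the choice is invisible for the dense group
  networks this is used on).
* Characteristic path length averages $d_{ij}$ over connected ordered
  pairs; if any pair is disconnected the value carries a `disconnected`
  attribute rather than becoming infinite, since empirical group-average
  networks are connected and the flag marks a data problem.
* Clustering uses the Onnela form: weights scaled by the network maximum,
  triangle geometric means, binary degree in the denominator; isolated and
  degree-one nodes get zero.
* Betweenness follows the ordered-pair normalisation $1/((n-1)(n-2))$ with
  shortest-path multiplicities splitting credit; ties in path length are
  resolved by igraph's exact multiplicity counting, and the brute-force test
  oracle uses a $10^{-12}$ tolerance.

Small-world ratios $\gamma$, $\lambda$, $\sigma = \gamma/\lambda$ are
normalised against matched random networks: Maslov–Sneppen double-edge swaps
(ten attempted swaps per edge) on the binary topology preserve the degree
sequence exactly, after which the observed weight multiset is permuted onto
the rewired edges. This preserves nodes, edges, degree distribution and the
weight distribution but deliberately not weight–degree coupling; preserving
that coupling as well is a stricter null that the package does not
implement, and the choice is recorded here because the two nulls can give
different $\gamma$ on weight-stratified networks. The default ensemble size
is 5000; tests and the analysis scripts use 100, which is ample for the
mean-only normalisation.

The group-average network keeps an edge only if it is nonzero in at least
75% of scans (false-positive suppression). Kept-edge weights are the mean
over *all* scans, zeros included: the prevalence rule already guards against
sparsely observed edges, and including zeros makes group weights comparable
across edges with different prevalence. Hubs are regions whose degree
strength *or* betweenness exceeds the across-region mean plus one sample
standard deviation (the upper tail is the only meaningful branch of a
"mean ± sd" rule for hub detection); edges are then rich-club (hub–hub),
feeder (hub–nonhub) or local, within- or between-module by the eight
functional subnetwork labels, and long or short around the mean
streamline length with ties assigned to short.

## Developmental trajectory models

For any per-scan response $y_{ij}$ (subject $i$, occasion $j$) the linear
model is

$$y_{ij} = \beta_0 + b_i + (\beta_{age} + b_{age,i})\,age_{ij}
  + \beta_{sex} sex_i + \beta_{tbv} tbv_{ij} + \beta_{centre} centre_i
  + \varepsilon_{ij},$$

with subject random intercepts and age slopes; the quadratic model adds an
$age^2$ fixed effect and random slope, and the interaction model an
age-by-sex term. Fits are maximum likelihood (not REML) so AIC is comparable
across fixed-effect structures; exact AIC ties go to the simpler model. Age
is mean-centred internally for conditioning and the slope reported on the
original per-year scale (back-transformed for the quadratic model); total
brain volume is standardised, which leaves $\beta_{age}$ unchanged. Boundary
("singular") fits are accepted as valid ML optima — degrading the
random-effect structure only on singularity would silently compare models on
different random structures and biases AIC selection; the structure is
simplified (correlated → uncorrelated → intercept-only → fixed-effects-only)
only on genuine non-convergence, with a warning. p-values use Satterthwaite
degrees of freedom; the per-region slope-map loop refits the same model
structure via `lme4::refit` and uses a normal approximation for $t$, which
at several hundred scans agrees with Satterthwaite to the third decimal and
makes 200-replicate family-wise-error simulations tractable.

Confidence intervals for $\beta_{age}$ are Wald intervals by default;
`ci_age()` provides a parametric-bootstrap percentile interval (simulate
from the fitted model, refit). Such intervals are sometimes obtained by
MCMC instead; the parametric bootstrap has the identical interpretation and
is the package's documented choice.

Slope maps z-score each region's metric across all scans (not within wave —
the standardisation exists to put regions on one effect scale), fit the
linear model per region, and Bonferroni-correct ($p_{bonf} = \min(1, pR)$)
across regions. Spatial gradients are tested by splitting region centroids
at the median coordinate along the posterior–anterior, inferior–superior or
(per-hemisphere) medial–lateral axis and comparing slopes with a two-sample
t-test; the original voxel-slice construction is replaced by centroid
medians because the package operates on region-level data only.

## Connectome–transcriptome association

The standardised slope map over cortical regions is linked to a
region×gene expression matrix by univariate-response PLS: component weights
proportional to $X^\top y$ with score deflation. With a univariate response
this makes "PLS correlation" and "PLS regression" coincide at the first
component up to scaling, which is why a single implementation serves both
names. Components are sign-flipped so scores correlate nonnegatively with
the response; explained fractions are additive shares of the response sum of
squares.

Inference on the component-1 score–map correlation uses variogram-matched
surrogate maps: permute the map, smooth with exponential and Gaussian
distance kernels over 20 log-spaced bandwidths, select the bandwidth and a
nonnegative affine rescaling (plus white noise for the nugget) minimising
the weighted squared error to the empirical binned variogram (25 bins up to
the 70th distance percentile), then affinely standardise each surrogate to
the source mean and sd. Two numerical choices matter and are deliberate:

* the variogram fit is weighted by inverse semivariance (floored at 5% of
  the mean) so that the near-zero short-range variance of smooth maps is
  matched as carefully as the sill;
* a smoothed candidate replaces the raw permutation only when it explains
  at least 75% of the variogram's weighted deviation from flatness. Without
  this parsimony rule the two free affine parameters let smoothed candidates
  win on any map by fitting bin noise, and surrogates of spatially
  *unstructured* maps would be mildly smoothed instead of reducing to the
  exchangeable permutation null.

Surrogate distances are Euclidean between region centroids — the package
has no cortical surface, and geodesic distances would be the natural
refinement for surface data. All permutation p-values are add-one,
$p = (1 + \#\{|r_{null}| \ge |r_{obs}|\})/(n+1)$, so the minimum attainable
p is $1/(n+1)$ and p depends only on the rank of the observed statistic.

Gene z-scores divide each component-1 weight by its bootstrap standard
deviation. The bootstrap resamples *regions* (the observation unit of the
spatial regression) with replacement and realigns each replicate's sign to
the full-data component, preventing z-deflation from reflection ambiguity.
Genes pass at a Bonferroni family level of 1% ($pG < 0.01$, strict), split
into positive and negative lists by weight sign.

## Enrichment and cytoarchitecture

Cell-type enrichment counts the overlap of selected genes with seven
canonical classes (astrocytes, endothelial, excitatory, inhibitory,
microglia, oligodendrocytes, OPC) against size-matched random gene sets
drawn from the PLS universe (one-sided add-one p); constraining the
resampling within each class is a conceivable alternative null, but the
unconstrained universe draw is the standard overlap permutation and is the
default. Category enrichment scores each category by its mean component-1
gene weight and recomputes those means from PLS weights refit against every
surrogate of the slope map, so the null carries both gene co-expression and
spatial autocorrelation; p-values are two-sided and Benjamini–Hochberg
adjusted across categories.

Cortical maps (myelin, laminar thicknesses L1–L6, cortical thickness) are
compared to the slope map by Spearman correlation with surrogate-based p
(surrogates of the slope map only — the documented asymmetry of the test),
and laminar specificity by partial Spearman: rank-transform everything,
residualise slope and target lamina on the other five by least squares,
correlate residuals, and push every surrogate through the identical
residualisation. A condition-number guard (>1e8) rejects collinear control
sets.

## The synthetic study and what it can show

The generator plants every effect the pipeline is supposed to find.
Defaults, chosen once as plausible desk-scale analogues of a developmental
cohort: 90 regions mirrored across hemispheres in a 140×170×120 mm box with
8 spatial-k-means modules and 10% subcortical; 150–200 subjects entering at
ages 6–11 (uniform) with yearly waves and 30% per-wave dropout; baseline
edge weights $15\,e^{-d/70\text{mm}}$ thresholded to 15% density; a planted
nodal slope field that is a Gaussian-process draw (length-scale 20 mm, mean
0.35, sd 0.15) entering edges as the endpoint average; subject random
intercept sd 0.5, random slope sd 0.05, residual sd 0.3; weights truncated
at zero with the truncation rate kept below 1%. Expression couples a latent
component to the slope field at an exact target correlation (0.5 by
default), gives 50 of 500 genes unit ±loadings on it, and models the rest of
the variance with ten shared spatially autocorrelated co-expression factors
plus 10% white noise — regional transcriptomes are dominated by a few
shared gradients, and this low effective rank is what keeps the first PLS
component from overfitting 81 cortical regions with 500 genes. Annotations
concentrate 80% of the positive support genes in one class; categories are
the sign-coherent halves of the support plus random decoys; cortical maps
are built with exact planted Pearson correlations (a strong, |ρ| = 0.6,
conditionally dependent lamina is planted for the partial-correlation
check).

What the passing tests show: the estimators recover what this generator
plants at realistic noise, and the permutation tests are calibrated under
its nulls. What they cannot show: robustness to tractography artefacts,
prevalence-threshold sensitivity on real streamline data, donor structure
and probe noise of real expression atlases, or geodesic-versus-Euclidean
distance effects — none of which the generator emulates.

Problem sizes in the tests were picked to keep the suite reproducible on a
laptop: 200 oracle graphs with at most 7 nodes, 200 trajectory replicates of
200 subjects, 50+50 replicates with 500 surrogates for the
spatial-autocorrelation calibration, 500 replicates with 100 surrogates for
the Spearman size check, and ensembles of 100 matched random networks.
Production defaults (5000 networks, 10,000 surrogates and resamples, 1000
bootstrap draws) remain the function defaults.

## Known limitations

* Bonferroni selection on bootstrap gene z-scores does not control the
  false-discovery rate with respect to *causal* support when decoy genes
  share co-expression gradients: a shared spatial factor that happens to
  correlate with the particular slope map makes whole groups of decoys
  genuinely, stably map-correlated (bootstrap z of 4–6), and region
  resampling cannot tell them from planted genes. On the default synthetic
  study the empirical decoy FDR is about 10%, not 5%. This is a property of
  the selection rule under realistic co-expression, not an implementation
  artefact — gene lists from this kind of analysis capture co-expression
  gradients aligned with the map, not causal genes.
* The surrogate generator matches binned variograms, not the full spatial
  covariance; very irregular region geometries may need more bins.
* The quadratic model's per-subject saturation (three waves, three
  random effects) makes AIC mildly generous to it; this is inherent to the
  model pair being compared.
* Partial Spearman p-values inherit the granularity of the surrogate count.
* Region-level analysis throughout; no voxel or vertex data structures.
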