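---
title: "Multi-scale regional homogeneity and its transcriptomic correlates: methods"
author: "rehomics"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Multi-scale regional homogeneity methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`rehomics` implements a two-armed analysis of resting-state brain
activity in a case-control design:

1. **Classification arm.** Regional homogeneity (ReHo) — the local rank
   concordance of a voxel's BOLD time series with its neighbours — is
   computed at four spatial scales: the voxel level and three nested
   regional parcellations linked by merge maps. At each scale, a
   support-vector machine classifies patients from controls under
   subject-level cross-validation, with F-score feature selection, a
   hyperparameter grid search confined to the training subjects, and a
   label-permutation null for inference.

2. **Association arm.** Case-control difference profiles (covariate-
   adjusted t statistics) are spatially correlated with module
   eigengenes from a signed weighted gene co-expression network built on
   Allen-atlas-style microarray expression, after probe-level quality
   filtering. A local hypergeometric over-representation test summarises
   the gene content of associated modules.

Because the patient scans such a study rests on are not public, the
package ships a seeded synthetic-data generator that reproduces the
*statistical structure* each stage assumes, with planted ground truth,
so every stage can be tested by parameter recovery.

# The ReHo statistic

For a voxel with time series $x_0$ and neighbours $x_1,\dots,x_{K-1}$
(26-connectivity by default, so $K = 27$ in the interior), each series
is rank-transformed over the $n$ timepoints and Kendall's coefficient of
concordance is

$$W = \frac{12\sum_{i=1}^{n}(R_i - \bar R)^2}{K^2(n^3 - n)},$$

where $R_i$ is the sum of the $K$ ranks at timepoint $i$. $W = 1$ means
identical rank orderings (perfect local synchrony); under independence
$E[W] = 1/K$. Design choices:

* **No tie correction.** BOLD residuals are continuous; ties arise only
  in degenerate synthetic inputs and are handled by average ranks. An
  all-constant neighbourhood returns $W = 0$ with a warning.
* **Mask borders.** Voxels use whatever in-mask neighbours exist
  (variable $K$, recorded per voxel). Voxels with fewer than
  `minNeighbours` neighbours (7 for the 26/18-neighbour schemes, 6 for
  6-connectivity, where 7 would be unattainable) are flagged invalid and
  excluded from standardisation and regional averages.
* **Standardisation.** Maps are z-scored over the valid in-mask voxels
  using the population SD (divide by $N$); this convention is recorded
  so regression tests are exact. Standardisation precedes regional
  averaging.

# Residual preprocessing

The package assumes spatially aligned input (slice-timing, realignment
and normalisation happen upstream) and performs the residual chain, in
the fixed order **nuisance regression, then band-pass**:

* The design contains an intercept, a linear drift term, the Friston-24
  motion expansion ($p$, $p^2$, the one-volume backshift $p_{t-1}$ and
  its square), white-matter and CSF signals, optionally the global mean
  signal, and one spike-indicator column per volume whose framewise
  displacement exceeds 0.5 mm.
* FD uses the Power formulation: the sum of absolute backward
  differences of the six rigid-body parameters, rotations converted to
  arc length on a 50 mm sphere; the analysis can be run with and without
  global-signal regression for comparison.
* **Spike regression, not censoring.** Flagged volumes are modelled out
  as indicator regressors rather than deleted, because Kendall's W needs
  an intact time-series grid. This is a documented interpretation the
  user should be aware of; censoring would change the statistic's
  support.
* The band-pass (0.01–0.08 Hz default) is an ideal frequency-domain
  filter: DFT components outside the band, including DC, are zeroed.
  Pass-band amplitude is preserved exactly on the DFT grid and stop-band
  leakage is nil, which makes the Parseval-based tests sharp.

# The MVPA stage

Features are the (z-scored) voxel or regional ReHo values. The contract
is that **nothing derived from held-out subjects influences training**:
per cross-validation fold, F scores (two-group ANOVA $F$ per feature),
the top-fraction feature selection, and the hyperparameter grid search
(inner cross-validation on training subjects) are all computed on the
training side only; the suite verifies this by recomputing selections
from the training rows and by corrupting held-out features.

The canonical grid is 20 values of $C$ (1 to 100, step 5) for C-SVC and
6 values of $\nu$ (0.2 to 0.7, step 0.1) for nu-SVC, each crossed with
linear, polynomial and RBF kernels — $(20 + 6)\times 3$ combinations.
Ties in the grid search go to the first combination in the documented
enumeration order (linear < polynomial < RBF, C-SVC before nu-SVC,
smaller penalty first), making results deterministic. The feature-
fraction series defaults to ten thresholds (10%…100%); the published
description of that series is internally inconsistent (1%-steps would
give 100 sets, not 10), so ten equal steps are used and the setting is
configurable. Accuracy is reported as the mean over folds at the best
fraction; the pooled-prediction accuracy is recorded alongside.

Permutation inference reruns the *entire* pipeline — selection, grid
search, cross-validation — on label-shuffled data and uses the add-one
estimator $p = (1 + \#\{A_{null} \ge A_{obs}\})/(B + 1)$, bounded below
by $1/(B+1)$. The reference design uses $B = 5000$; the shipped tests
use $B = 199$ (planted effect) and $B = 39$ (null calibration), sizes
chosen so the whole recovery suite runs on a laptop-class budget while
keeping the add-one p-value resolution well below the 0.05 decision
threshold.

Consensus feature weights (the top 20% by mean absolute primal weight
among features selected in every fold) are defined only for the linear
kernel; with a non-linear kernel in any fold the function refuses
explicitly rather than falling back, mirroring the restriction of
weight-based interpretation to linear models.

# Expression processing

The probe-level pipeline runs in a fixed order: table-driven
probe-to-gene assignment, background filter (a probe must be called
present in **strictly more** than 50% of samples), removal of genes
without RNA-seq measurements, RNA-seq concordance filter (Spearman
$\rho < 0.2$ excluded, computed only when at least 4 shared samples
exist), and representative-probe collapse (argmax $\rho$ per gene, ties
to the lowest probe id). The order matters — a test documents that
reordering the background and concordance filters changes the result.
Only left-hemisphere samples are retained, matching the hemispheric
coverage of the donor data the design emulates.

Differential stability (DS) is the mean over donor pairs of the Pearson
correlation between two donors' regional-mean expression profiles over
shared regions; the top half (ceiling) of genes by DS is retained.
Donor pairs with fewer than 3 common regions are skipped. An optional
per-donor z-normalisation flag exists (off by default, recorded in the
output metadata).

Sample-to-region assignment is nearest labelled voxel centre in world
millimetres, with a distance cap of twice the voxel size (unassigned
beyond it, logged) and ties resolved to the lowest region id.

# Co-expression modules

The network is **signed**: $A_{ij} = ((1 + r_{ij})/2)^\beta$, so
anti-correlated genes get near-zero adjacency instead of being folded
in. $\beta$ is the smallest candidate (1–20) whose scale-free topology
fit reaches $R^2 \ge 0.8$ (sign-corrected regression of log-frequency
on log-connectivity over 10 bins), falling back to 12 with a warning.
Fewer than 15 units is refused outright — a co-expression network on a
handful of spatial units is statistically meaningless, which is why the
coarsest (9-unit) scale never enters this analysis.

Clustering uses average linkage on $1 - \mathrm{TOM}$, where TOM is the
topological overlap matrix. The tree is cut **statically at 99% of the
top merge height** rather than at a fixed absolute height. The reason
is numerical: TOM dissimilarities concentrate just below the
between-module merge level, and that level moves with $\beta$ (about
0.97 for strong blocks at $\beta = 6$, above 0.99 for weak-loading
modules at $\beta \ge 8$), so no single absolute cut separates modules
in both regimes. The relative cut tracks the between-module level by
construction; an absolute `cutHeight` can still be supplied. Clusters
below `minModuleSize` (30) become the unassigned "grey" module 0;
modules are renumbered by decreasing size. Dynamic tree cutting is
deliberately not implemented — the static cut suffices for the
structures this package models and keeps the procedure transparent.

Each module's eigengene is the first principal component of its
standardised gene-by-unit submatrix, scaled to unit variance, with the
sign chosen so the mean correlation with member genes is non-negative;
variance explained is recorded. The grey module never enters eigengene
output unless requested.

# Difference maps and spatial association

Regional case-control differences come from the linear model
`y ~ group + age + sex`; the group coefficient's t statistic (df
$= n - \mathrm{rank}$) reduces exactly to the pooled two-sample t when
covariates are orthogonal. Normality is checked with a Monte-Carlo
Lilliefors test: the KS statistic against a normal with estimated
parameters, calibrated by a seeded null of 2000 standardised normal
samples (the naive KS null is wrong when parameters are estimated).
Bonferroni thresholds are $\alpha/m$ with $m$ the number of regional
units.

At the sample level, the t value attached to a tissue sample is the
mean over in-mask voxels whose centres lie within a 6 mm world-space
sphere (no partial-volume weighting). Eigengene-difference correlations
are computed separately for cortical and subcortical units — expression
profiles differ too sharply between the compartments to pool — with
Benjamini-Hochberg adjustment within compartment across modules and raw
p reported alongside (the original analysis does not state a
correction; reporting both keeps the user aware). Compartments with
fewer than 3 units are omitted.

Over-representation analysis is a local hypergeometric upper-tail test
against any GMT collection with BH-FDR control; it stands in for
web-service GO enrichment, whose database snapshots are not
reproducible. The default universe is the post-filtering retained gene
list — the genes actually eligible for selection — rather than a whole
genome, a selection-consistent background.

# The synthetic-data generator

The generator is the package's definition of its study conditions, not
a tuning knob. Cohort defaults: a $16^3$ grid of 3 mm voxels, 150
volumes at TR 2 s, 30 patients and 30 controls, and a hierarchical
16 → 4 → 2 region atlas (an arbitrary-count mode, e.g. 272 → 53 → 17,
exists for bookkeeping checks). Hemispheres are encoded by the sign of
world x around the grid midplane; within each hemisphere the quarter of
regions whose centroids lie nearest the grid centre are labelled
subcortical — a shell rule that needs only the atlas, no anatomy.

The planted group effect is **shared-signal mixing**: inside each
effect region, a patient's voxel series becomes
$(1 - w)\,\varepsilon + w\,\ell_r$ (re-standardised), with $\ell_r$ a
region-shared latent series and $w = 0.8\,e_i$ clipped to $[0, 1]$,
where $e_i \sim N(1, 0.25)$ is the subject's latent effect strength.
This is the smallest model that moves Kendall's W, because W responds
directly to rank concordance of neighbouring series. PANSS-like symptom
scores are linear transforms of $e_i$ plus noise, mixed by the
closed-form rule $z = r\,z_e + \sqrt{1 - r^2}\,z_\varepsilon$ to hit a
target correlation (default: negative score at $r = 0.4$); score means
and SDs follow the published cohort table. Motion traces are smooth
random walks with occasional 0.7 mm one-volume spikes that exceed the
scrubbing threshold. Four pseudo-donors are used, matching the
left-hemisphere donor majority of the atlas data the generator
emulates.

The expression bundle plants `nModules` latent profiles over
`nSamples` (default 200) left-hemisphere samples; gene loadings are
drawn as $0.25 + 0.75\,U^3$ — right-skewed, few hubs and many weak
genes — so the signed network's degree distribution admits a
scale-free fit, as real co-expression networks do. The planted module's
latent is an affine mixture of the local effect-map value achieving a
target correlation (default 0.7) in expectation. The probe layer adds
per-gene probes of increasing noise, a configurable fraction of
secondary probes with below-background detection calls, and an RNA-seq
twin equal to an exponential (monotone) transform of the gene signal
plus noise, so that at `noiseSd = 0` the entire processing pipeline
round-trips the generating matrix exactly.

What the generator does **not** model: anatomy, scanner artefacts,
spatial autocorrelation of noise, donor batch effects, negative gene
loadings (a signed network would split an anti-correlated module in
two, which is a different test than the one intended). Passing recovery
tests therefore demonstrates the correctness of the estimators under
the stated generative model, not performance on real scanner data.

# Test-scale study conditions

Recovery simulations are sized to run in minutes on one CPU; the sizes
below are the package's fixed, documented conditions:

* Planted-effect classification: the default cohort (30+30, $16^3$,
  150 volumes, synchrony 0.8), regional features at the 16-region
  scale, a linear C-SVC with a reduced C grid (1, 26, 51, 76), 3-fold
  inner tuning, $B = 199$ permutations.
* Null calibration: 50 seeds of an $8^3$, 60-volume, 6+6 null cohort,
  $B = 39$; the permutation p-values are checked for approximate
  uniformity by a KS test.
* Module recovery: 10 seeds of a 300-gene, 3×100-module, 100-sample
  bundle; mean adjusted Rand index against the planted labels.
* Association recovery: 20 seeds of the default 200-sample bundle; the
  processing for this loop omits the DS top-half filter, which with
  these module sizes can leave a planted module below the minimum
  module size — DS is tested separately, and the loop is meant to
  isolate the eigengene-association chain.

# Known limitations

* The static relative tree cut assumes modules merge near the top of
  the dendrogram; deeply nested module hierarchies would need dynamic
  cutting.
* Eigengene extraction is deterministic given input ordering, but SVD
  sign conventions are only fixed through the mean-correlation rule; a
  module whose genes correlate near zero with their own eigengene
  (pathological) would have an ill-defined sign.
* The permutation test's cost scales linearly in $B$ times the full
  cross-validation cost; the reference $B = 5000$ is supported but
  intended for batch use.
* Spike regression assumes flagged volumes are sparse; a run where most
  volumes exceed the FD threshold is rejected rather than cleaned.
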