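---
title: "Connectome gradients, transcriptomic association, and outcome prediction with gradix"
author: "gradix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradients, transcriptomic association, and outcome prediction with gradix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradix)
```

# The analysis in one paragraph

`gradix` implements a complete case–control connectome-gradient study as a
tested, reusable pipeline. From per-subject node × time series it builds
functional connectivity (FC) matrices, sparsifies each row to its strongest
connections, converts cosine similarity of the sparsified profiles into a
normalized-angle affinity, and embeds that affinity with diffusion maps to
obtain per-subject *gradients* — low-dimensional axes of connectivity
similarity whose first component typically runs from primary sensory to
transmodal cortex. Subject gradients are harmonized by iterative Procrustes
rotation, compared between groups with a covariate-adjusted GLM (FDR and
permutation cluster-extent correction), related to small-world network
topology, decoded against term-map collections, linked to regional gene
expression by PLS regression with spin-test significance and bootstrap
gene-weight *Z* ranking, screened for gene-set enrichment (permutation
overlap tests and preranked GSEA), and finally used as baseline features in
a leave-one-out SVR predicting post-treatment symptom change. Every stage
can be exercised end-to-end on a synthetic cohort whose gradient,
transcriptomic and outcome effects are planted and therefore known.

# Models and procedures

## Gradient construction

For a node × time matrix the FC matrix is pairwise Pearson correlation with
the diagonal excluded. `affinityMatrix()` keeps, per row, the top
`density` fraction of connections (rank-based; default 10%, ties at the
cutoff all kept so the realized density can slightly exceed the nominal
value), computes cosine similarity between the sparsified row profiles, and
maps it through the normalized angle \(1 - \arccos(c)/\pi\) so affinities
live in \([0, 1]\).

`diffusionEmbedding()` forms the anisotropic kernel
\(W = D^{-\alpha} A D^{-\alpha}\) (\(\alpha = 0.5\), approximating the
Laplace–Beltrami operator) and the transition matrix
\(P = D_W^{-1} W\). Components are the nontrivial right eigenvectors of
\(P\), computed through the conjugate symmetric operator for stability and
scaled by \(\lambda/(1-\lambda)\) (automatic diffusion time; a fixed time
\(t\) uses \(\lambda^t\)). The explained ratio of component *i* is
\(\lambda_i\) over the sum of the positive nontrivial eigenvalues. A
disconnected affinity graph is an error, never silently regularized,
because any patching changes the spectrum; the advice is to raise the
density. The diagonal is excluded from the sparsified profiles — with the
diagonal already zero in FC this is the natural convention, and it is
applied consistently.

Subjects are aligned with `procrustesAlign()`: each subject is rotated
(orthogonal transform, no scaling) to a template initialized as the
component-wise mean, the template is recomputed, and the loop repeats until
the total squared disparity changes by less than `1e-8` (at most `nIter`
rounds). The update is monotone — each step can only reduce the total
disparity — which the test suite asserts on random inputs. The grand-mean
template (rather than a leave-one-out reference) is used; a fixed external
reference can be supplied. After alignment `orientGradient()` flips
gradient 1, if needed, so its template mean over DMN-labeled nodes is
positive: the conventional primary-to-transmodal orientation.

Global metrics of a component are its score `range` (max − min),
population `variance`, and `explainedRatio`. Ten components are retained by
default; only gradient 1 propagates downstream.

## Group statistics

`glmCompare()` fits, per node, ordinary least squares of the aligned
gradient scores on intercept, group, age and sex, reporting the group
coefficient's *t*, its two-sided *p*, the signed normal quantile *z* (the
"case–control z map" consumed by decoding and PLS), and Cohen's
\(d = t\sqrt{1/n_1 + 1/n_2}\). Computing *d* from the GLM *t* keeps the
effect size covariate-adjusted; this is one standard choice among several.
Responses fit exactly (zero residual variance) return \(t = 0\) rather than
an indeterminate ratio. A sex-by-group interaction variant is provided.

Cluster-level inference (`clusterCorrect()`) thresholds the node map at a
cluster-forming *p*, takes connected components of same-sign nodes on a
supplied adjacency, and compares each cluster's extent with the null
distribution of the maximum extent under group-label permutation. This
permutation max-statistic scheme is exact under exchangeability; it
replaces random-field cluster correction, which requires volumetric
smoothness estimation that has no analogue for matrix-level data. This is a
deliberate, documented divergence from volumetric practice.

Missing clinical scores are handled by listwise deletion per analysis
(`clinicalCorr()`); paired pre/post comparisons use the classical paired
*t* with \(d = \bar{\Delta}/s_\Delta\). `networkShare()` reports, per
effect sign, the proportion of significant nodes in each of the seven
canonical networks.

## Network topology

Graphs are binarized at each sparsity in a 0.05–0.50 window (step 0.05) —
the conventional window for binarized brain graphs; the construction
details live in supplementary conventions across the field, so the window
is exposed as configuration. Gamma is mean local clustering over the mean
of `nRand` degree-preserving (Maslov–Sneppen) null graphs, lambda the
analogous path-length ratio (computed on the largest component when a
sparse graph disconnects, with a flag), sigma their ratio — held to
`gamma/lambda` within 1e-10 by the class validity itself. AUCs are
trapezoid integrals over the window. Twenty null graphs with
\(10\,|E|\) swap attempts each balance variance against runtime; both are
configurable.

## Spin permutations

Spatial maps are compared under a null that preserves spatial
autocorrelation: parcel centroids on a sphere are randomly rotated (QR of a
Gaussian matrix, sign-fixed, determinant +1; the rotation is mirrored for
right-hemisphere parcels) and each rotated parcel takes the value of its
nearest original centroid within its hemisphere. Nearest-neighbour
reassignment may map two parcels to one source; duplicates are counted and
accepted, as in the rotate-parcellation lineage. The spin *p* uses the
add-one formulation \((1 + \#\{|r_0| \ge |r_{obs}|\})/(1 + n)\), so it can
never be zero, and is two-sided by default (the one-sided variant is a
flag). One `SpinPermutationSet` is shared by all spatial tests in a run, so
every comparison sees the same nulls. `decodeMaps()` ranks a term-map
collection by spin-corrected correlation with a target map, optionally
splitting a z map at zero into increase/decrease maps first; term maps are
an input, never a bundled download.

## Imaging transcriptomics

`plsFit()` is NIPALS partial least squares with the region × gene
expression matrix (columns z-scored by default, as is standard for
expression-atlas work) as predictors and the case–control z map as the
univariate response. Components are sorted by explained y-variance, and
the first component's sign is fixed so its scores correlate positively
with the response. Significance of the explained variance is assessed by
refitting on spun responses. Gene stability uses bootstrap resampling of
regions: each resample's first-component weights are sign-aligned to the
original by dot product — PLS components are sign-indeterminate and
without alignment the bootstrap SEs are badly inflated — then
\(Z = w/\mathrm{SE}\), two-sided normal *p*, BH-FDR, and membership in
PLS1+/PLS1−/none by sign and significance. The selection boundary in *Z*
is therefore re-derived from the data on every run rather than fixed at
any particular numeric cutoff. Ranking is by descending *Z* with
lexicographic tie-breaks.

## Enrichment

`overlapPermTest()` scores the mean PLS-*Z* of the genes shared between a
PLS gene list and a target set. The null redraws gene subsets of the same
size as the *observed overlap* from the background: a target-set-sized
draw can produce an empty overlap whose mean is undefined, while
overlap-sized draws are always defined and match the statistic exactly.
Draws come from the full background, not expression-matched bins.
`markerOverlapTest()` uses the overlap count with equal-size resampled
gene lists, FDR across the marker sets. `gseaTest()` is preranked GSEA: a
weighted Kolmogorov–Smirnov running sum (hit increments
\(\propto |s|^{p}\), uniform miss decrements), ES the maximum signed
deviation, gene-label permutation nulls (the input is a single ranked
list, so phenotype permutation is unavailable), and
\(\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}_0|}\) over
same-sign nulls. Gene identifiers are harmonized by case-insensitive exact
match only; alias resolution is out of scope.

## Outcome prediction

`svrLoocv()` is linear-kernel \(\varepsilon\)-SVR (C = 1,
\(\varepsilon = 0.1\); kernel, cost and tube width are assumptions, stated
as such, since standard choices are rarely reported). The linear kernel is
deliberate: the primal weight vector is directly interpretable, which the
per-network attribution \( \mathrm{share}_k = \sum_{i \in k} |w_i| /
\sum_i |w_i|\) requires. Per fold, features are standardized on the
training subjects only; the held-out subject influences its own prediction
only through the prediction step — the test suite asserts this exactly by
corrupting a held-out subject and checking the fold's scaler and weights
are unchanged. Attribution weights come from the all-subject fit.
`permutationValidate()` shuffles outcomes and reruns the entire
cross-validation loop per permutation, reporting add-one p-values for the
correlation (greater) and MSE (less).

# The synthetic cohort: what it emulates and what it does not

`genCohort()` gives each node a latent axis position \(g \in [-1, 1]\),
split into seven contiguous blocks carrying the canonical network labels
(VN at one pole through DMN at the other). A subject's time series is a sum
of shared latent signals whose loadings decay with distance along the axis
(Gaussian kernel, width 0.35), a weak per-network block signal (weight
0.1), and white noise (SD 0.5). Expected node–node correlation therefore
decays with \(|g_i - g_j|\), and the principal gradient of the embedded
affinity recovers the axis (group-mean recovery \(|r| > 0.9\) at 200
nodes × 500 timepoints is a tested invariant). The block signal is kept
weak on purpose: a strong block structure competes with the smooth axis
for the leading eigenvector and makes component order unstable.

For cases, the axis is rescaled by `compression` on the affected nodes
(the extremes, \(|g| > 0.6\)), collapsing the gradient's extremes inward;
`compression = 1` plants no effect and the groups are exchangeable, which
is what all the calibration tests rely on. The planted contraction is a
*group-connectome* property: the gradient of the case group's mean FC has
a reliably narrower range than the control group's (the tested direction,
≥95% of cohorts at compression 0.6). Per-subject spectral metrics can move
the other way — diffusion components have fixed norm, so locally densified
extremes raise the leading eigenvalue and with it each subject's own range
— and the group comparison of per-subject global metrics should be read
with that in mind. This is a known, documented property of planting
effects through a generative connectivity model rather than directly in
gradient space.

Cases can be made heterogeneous: with `severitySd > 0` each case carries a
latent severity factor \(s_i \sim N(1, \text{severitySd})\) that scales
its compression depth (\(c_i = 1 - s_i(1 - \text{compression})\)) and
shifts its baseline PANSS positive and negative scores. Severity is then
partially encoded in the connectome, as it is in clinical cohorts — this
is what makes baseline gradient maps informative about treatment outcome
at realistic cohort sizes. With a homogeneous case group
(`severitySd = 0`, the default and the setting all direction/calibration
guarantees are stated for) the planted outcome signal lives only in scan
noise and is essentially unpredictable from 100+ features at a few dozen
subjects. The demo pipeline opts into `severitySd = 0.4`, chosen once so
its prediction stage can show the planted effect; it is a free parameter
of the generator, not calibrated to any empirical cohort. Even so, the
leave-one-out correlation is itself a high-variance statistic when the
feature count far exceeds the subject count: across simulation seeds it
ranges from near zero to about 0.7 at the demo sizes, which mirrors the
fragility of small-cohort prediction studies and is worth remembering
when reading any single run.
Heterogeneous compression also blurs the group-mean range contraction, so
the two planted effects trade off and are controlled by separate knobs.
The default planted outcome weight (5 PANSS points per unit gradient
score, uniform over DMN nodes) keeps the mean planted improvement well
inside the instrument range so floor clipping stays rare.

Demographics are drawn from the same distributions in both groups (ages
about 7–30 years centered near 17, balanced sexes, log-normal framewise
displacement), so groups are covariate-balanced by construction. Cases
carry integer PANSS scores with the instrument floor of 7 on the positive
and negative subscales and an onset age within a year of study age.
`genExpression()` plants a chosen number of genes as
`coupling · standardize(zmap) + noise` among spatially autocorrelated
background genes, columns z-scored. `genGeneSets()` draws a controlled
fraction of each set from the planted genes and the remainder from the
non-planted background, so `overlapFrac = 0` means exactly zero planted
overlap. `genOutcomes()` sets week-8 PANSS positive to baseline minus a
linear function of baseline gradient features plus noise, rounded and
clipped to the valid range. `genSphere()` places parcels on a Fibonacci
lattice rotated at random.

What the generator does *not* emulate: hemodynamics or neural-mass
dynamics, volumetric geometry, motion artifacts beyond an FD column,
probe-level expression preprocessing, or realistic gene–gene correlation
structure. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under a known generative model — not
that any particular empirical effect in real cohorts will reproduce.

# Numerical choices and degenerate inputs

- Full determinism: every generator and every randomized operation takes
  an explicit seed, consumes a private RNG stream, and restores the
  caller's RNG state. The pipeline derives per-stage sub-seeds (kept below
  \(2^{31}\)) from one master seed; two runs with the same configuration
  produce byte-identical manifests.
- Sparsification keeps values, not a binarized skeleton, and keeps every
  tie at the cutoff, so results do not depend on storage order.
- Affinities are clipped into \([-1, 1]\) before `acos`; eigen-ratios are
  computed over the positive nontrivial spectrum and defined as zero when
  that spectrum is empty.
- Permutation p-values are add-one throughout and can never be zero.
- Degenerate cases error early with named checks: constant time series,
  disconnected affinity graphs, rank-deficient designs, constant response
  maps, zero-variance maps, all-zero weight vectors, empty backgrounds.
  The one deliberate soft case is an empty enrichment overlap, which
  returns a flagged `p = 1` row because a downstream FDR across sets still
  needs the entry.
- Problem sizes in the shipped tests and the acceptance script are scaled
  to the package's own defaults (e.g., 200-rep calibrations, 1000-spin
  nulls, 1000-bootstrap gene tables, 60-subject demo cohorts); all sizes
  are parameters, and larger runs only tighten the Monte-Carlo error.

# Known limitations

- The compression effect's per-subject spectral signature is opposite to
  its group-mean signature, as discussed above.
- Nearest-neighbour spin reassignment is not a strict permutation;
  duplicate assignments are counted but retained.
- Cluster inference assumes group exchangeability under the null; strong
  covariate imbalance would require a residual-permutation scheme that is
  not implemented.
- GSEA NES normalizes by same-sign null ES; with very few same-sign nulls
  the NES is noisy (the p-value remains valid via the add-one rule).
- Gene harmonization is exact-match only; marker lists using aliases will
  silently shrink at construction (the collection reports its sizes).
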