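---
title: "Connectome-based two-group classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based two-group classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkconnectome)
```

## The analysis in one paragraph

Resting-state fMRI studies of early cognitive decline often summarise each
subject as a functional brain network: regional time series are correlated
pairwise (Pearson), negative correlations are discarded, and the weighted
matrix is binarised at a grid of proportional sparsity thresholds.  Graph
metrics computed at every threshold are aggregated into threshold-free
"area under the sparsity curve" (AUC) features.  Three feature families —
selected functional connections, 7 global graph metrics, and 90 × 6 nodal
graph metrics — are then combined by a multi-kernel support vector machine
(MK-SVM) under nested leave-one-out cross-validation (LOOCV), and the gain
from combining modalities is assessed by DeLong tests on the correlated
ROC curves.  This package implements that pipeline end to end, with a
synthetic cohort generator that plants known group differences so every
stage can be validated against ground truth.

## Network construction

`compute_connectivity()` forms Pearson correlations between all ROI pairs,
zeroes negative values (their physiological interpretation is ambiguous,
and the pipeline analyses positive-weight networks only), and zeroes the
diagonal.  `threshold_series()` binarises at each sparsity level `s` in
the default grid 0.02–0.50, step 0.01 (49 thresholds): exactly
`k = round(s · N(N−1)/2)` strongest edges are retained.

Numerical choices the data format forces us to make explicit:

* **Rounding.** `k` uses half-up rounding; base R's banker's rounding
  would make edge counts non-monotone in ties.
* **Ties.** Equal weights at the cut are broken by lexicographic
  `(i, j)` pair order, so degenerate inputs (and exact synthetic
  duplicates) binarise deterministically, and edge sets are nested
  across the grid by construction.
* **Negative-edge handling precedes thresholding**, so the retained
  edge count can fall short of `k` on weakly correlated data; this
  raises a warning rather than an error and the graph simply keeps all
  positive edges.

An optional `preprocess_timeseries()` offers per-column detrending and a
zero-phase frequency-domain band-pass with a fourth-order Butterworth
magnitude response (defaults off; the synthetic data need neither, and
full image preprocessing is out of scope).

## Graph metrics

Seven global metrics (clustering coefficient C~p~, characteristic path
length L~p~, normalised γ and λ, small-worldness σ = γ/λ, global
efficiency, modularity Q) and six nodal metrics (betweenness, degree,
clustering, efficiency, local efficiency, nodal shortest path) are
computed per threshold and summed over the grid into AUC features
(`metric_auc()` is a plain 49-value sum, no step-width weighting).

Disconnected graphs are inevitable at the sparse end of the grid (90
nodes at s = 0.02 keep ~80 edges), so:

* path-length averages (L~p~, nodal shortest path) run over *reachable*
  pairs only; an isolated node's nodal shortest path is 0 by convention;
* efficiency metrics use 1/∞ = 0 and need no special-casing;
* an edgeless graph has no defined L~p~ or Q (sentinel/error).

γ and λ normalise by a Maslov–Sneppen degree-preserving null ensemble
(default 100 rewired graphs per threshold, 10·|E| attempted double-edge
swaps each, seeded per threshold).  On very sparse graphs both the
observed and the null clustering can be exactly zero; we define the 0/0
ratio as 1 (the observation equals the null prediction), while a positive
observed value over a zero null mean remains an NA sentinel.  The null
ensembles are rebuilt per threshold rather than shared per subject — the
degree sequence changes with the threshold, so a single shared null would
mismatch most of the grid.

Modularity uses the partition-quality form
Q = Σ~i~ [l~i~/L − (d~i~/2L)²], evaluated by this package's own
implementation on the partition found by greedy agglomerative merging
(each node starts as its own module; the merge with the largest ΔQ is
applied until no merge improves Q).  The fast-greedy engine comes from
igraph; exhaustive partition enumeration on small graphs bounds its
optimality in the tests.  Hubs are the top ⌈5%⌉ of nodes by group-mean
degree AUC, ties broken by node index.

## Feature selection

**Edges.**  Pooled-variance two-sample Student t-tests per edge on the
training rows of each cross-validation fold, selecting p < 0.05
(two-sided, uncorrected — deliberately liberal, as the classifier, not
the test, is the arbiter).  The *consensus* connections, the set
intersection of all folds' selections, are the reported biomarker-style
output; classification itself uses each fold's own selection, so no fold
ever sees information from its held-out subject.  A flag enables a
Fisher r-to-z transform of the edge weights before testing (off by
default; the raw-r choice is conservative and the t-test is nearly
invariant to the monotone transform at these effect sizes).

**Nodal metrics.**  The 6 metrics of an ROI form a natural group, so
selection uses group-LASSO logistic regression: summed logistic loss
plus λ Σ~j~ ‖w~j·~‖₂ with unpenalised intercept, λ = 1 by default.
Features are z-scored on training rows first ("normalisation to avoid
scale imbalance"; metric AUCs are not correlations, so an r-to-z map
would be inapplicable — standardisation is the faithful reading).  The
solver is accelerated proximal gradient (FISTA) with block
soft-thresholding, backtracking line search from the analytic Lipschitz
bound ‖X‖²/4, a monotone restart, and convergence at relative objective
change < 10⁻⁸ (cap 10,000 iterations).  Zero groups are *exactly* zero —
that is what makes the fit a selector.  `group_lasso_lambda_max()` gives
the analytic smallest penalty with an all-zero solution, a useful scale
for tuning grids.  The group penalty is the standard Euclidean group
norm √(Σ w²) (some descriptions omit the square root typographically;
without it the penalty would not induce group sparsity).

## Multi-kernel SVM and evaluation

Each modality gets a linear kernel on training-standardised features,
trace-normalised to n (linear is the minimal kernel consistent with the
model's formulation and these sample sizes; an RBF variant would add a
bandwidth hyperparameter with no support at n ≈ 40).  Kernels combine
convexly, k = Σ β~m~ k~m~ with β on the probability simplex, and the
combined kernel feeds a soft-margin C-SVM dual solved by
maximal-violating-pair SMO (C++; KKT tolerance 10⁻⁶; bias averaged over
margin support vectors, or the KKT interval midpoint if none are free).

`mkl_nested_loocv()` is the evaluation backbone: the outer LOOCV leaves
one subject out; *all* selection and standardisation re-runs on the
remaining subjects; an inner LOOCV grid search over C ∈ {2⁻⁵, …, 2⁵}
(11 values) × the β simplex grid (step 0.1 → 66 points for three
modalities) picks the hyperparameters by inner accuracy, with
deterministic ties (smaller C, then β closest to uniform).  The decision
threshold is fixed at 0; no post-hoc tuning.  Accuracy, sensitivity and
specificity come from the pooled confusion counts; AUC is the
Mann–Whitney statistic on pooled decision values, and modality
combinations are compared pairwise with DeLong's placement-value test
(identical score vectors return z = 0, p = 1 by convention).

The positive class is an explicit configuration field
(`run_config(positive_class = ...)`): published sensitivity/specificity
pairs are sometimes inconsistent with the stated group sizes, so the
package never hard-codes which group counts as "positive".

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` describes a stationary multivariate-Gaussian world:
block-structured population correlation (within-module weight 0.4,
between-module 0.05 — typical resting-state within/between-network
levels), six near-equal modules over 90 ROIs, 230 time points, 22 + 20
subjects, observation noise with σ = 0.5 (signal variance 1), and an
optional AR(1) temporal smoothing flag (default off).  Pearson
correlation is completely determined by the covariance, so richer
hemodynamics would add realism the pipeline cannot see.  Group effects
are planted as a signed correlation change on designated edges; the
positive-definiteness repair (add (|λ~min~| + 10⁻⁶)·I, rescale to unit
diagonal) slightly shrinks all entries, so the ground truth records the
*post-repair* covariances and the differential edge set is defined as
"where the two covariances disagree".  Per-subject seeds derive
deterministically from the master seed, so cohorts are byte-reproducible
and single subjects regenerable.

A green test on this cohort establishes that the pipeline recovers
planted covariance and topology differences without leaking test
information — it does not establish robustness to head motion,
physiological confounds, scanner effects, or non-Gaussian BOLD dynamics,
none of which are modelled.

Two scale notes for the validation experiments:

* Edge-recovery experiments use 20-ROI cohorts.  With 90 ROIs the 4005
  edge tests at α = 0.05 admit ~200 false positives by design, which
  swamps any 20-edge planted set in a Jaccard score; at 190 edges the
  criterion measures recovery rather than the arithmetic of α.
* Topology-difference experiments plant a within-module correlation
  increase in the positive group on a baseline with deliberately weak
  module contrast (within 0.25, between 0.10), so the *binarised*
  networks differ in modularity, not merely in edge weight.

## Runtime choices

The permutation-null and end-to-end checks reduce the null-model
ensemble (15–20 graphs per threshold instead of 100) and coarsen the β
grid (step 0.5 or vertices only) so the full 42-subject pipeline runs in
minutes on one CPU.  These are sampling reductions, not threshold
changes: every statistical criterion is evaluated at its stated level.

## Known limitations

* Greedy modularity is a heuristic; its Q is bounded by, and on small
  graphs usually close to, the exhaustive maximum (tested), but the
  "modified" variants of agglomerative merging in the literature differ
  in tie-breaking and can return different partitions of equal Q.
* LOOCV accuracy on ~40 subjects has high variance and a known
  pessimistic bias at the null; the permutation check therefore tests a
  3-standard-error band around chance rather than a point value.
* With λ = 1 on summed (not averaged) logistic loss, the group-LASSO's
  effective shrinkage depends on n; cross-validated tuning on a
  λ_max-scaled grid is available and used in the support-recovery tests.
* The DeLong normal approximation is anti-conservative below ~15
  subjects per class; the calibration test runs at n = 40.
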