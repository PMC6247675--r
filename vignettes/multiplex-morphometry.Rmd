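---
title: "Multiplex patch-correlation morphometry: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex patch-correlation morphometry: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

mplexmorph characterizes structural brain MRI through an inter-subject
*multiplex network*. Every co-registered, intensity-normalized volume is
tiled into the same set of rectangular patches (default
$l_1 \times l_2 \times l_3 = 10 \times 15 \times 20$ voxels,
$D = 3000$), split at the midsagittal fissure so each patch belongs to one
hemisphere, and keeping only patches whose overlap with the brain mask
reaches 10%. The $N$ retained patches are the shared node set. One subject
contributes one *layer*: an undirected weighted network whose edge between
patches $i$ and $j$ is the Pearson correlation $r_{ij}$ of their voxel
intensity sequences (fixed raster order, voxel positions associated
pairwise), thresholded at moderate correlation,

$$w_{ij} = \begin{cases} 0 & |r_{ij}| \le \tau \\ r_{ij} & \text{otherwise}
\end{cases} \qquad \tau = 0.3 .$$

In the default mode surviving edges carry $|r_{ij}|$; a signed mode keeps
$r_{ij}$. The absolute-value default is deliberate: patch correlations are
used as an undirected similarity (sign flips arise from, e.g., left–right
tissue inversions and would lateralize the model), and absolute weights
keep node strengths nonnegative so the inverse participation ratio stays
in $[1/k, 1]$. With signed weights, strengths can cancel near zero and the
normalized quantities below become ill-conditioned; both modes are
provided.

Per node $i$ and layer $\alpha$, four single-layer features:

* strength $s_i^\alpha = \sum_j w_{ij}^\alpha$;
* inverse participation ratio
  $Y_i^\alpha = \sum_j (w_{ij}^\alpha / s_i^\alpha)^2$
  (1/k for k equal weights, 1 for a single edge, 0 for an isolated node);
* the degree-conditional means $s(k)^\alpha$ and $Y(k)^\alpha$: the mean
  strength (resp. IPR) over the $N_k$ nodes of degree $k$, assigned to
  each node at its own degree.

The multiplex context enters through the aggregate adjacency
$a^{multi}_{ij} = 1$ iff any layer carries a nonzero weight between $i$
and $j$ (we take $|w| > 0$ so signed-mode negative edges count; a support
union that dropped negative edges would contradict the undirected
modeling argument). Its row sums are the aggregate degrees $k^{multi}_i$.
Four multiplex features mirror the single-layer ones: $s$ and $Y$
weighted by the normalized aggregate degree $k^{multi}_i/(N-1)$, and the
conditional means recomputed grouping nodes by $k^{multi}$ instead of the
layer degree. The functional form of the aggregate-degree "weighting" is
a design choice: multiplication by the normalized aggregate degree is the
simplest reading that keeps features comparable across grids, and it is
isolated in a single function (`multiplex_node_features()`) so it can be
replaced. A cohort of $M$ subjects therefore yields an $M \times 8N$
feature matrix, built blind to diagnosis.

Held-out subjects never enter the training features: a test subject's
single-layer features come from its own layer, while its multiplex
features use the aggregate adjacency recomputed over the $M+1$ layers,
leaving training rows untouched. The perturbation of the aggregate by one
layer is small, which is what makes test rows comparable.

## Feature selection and the occurrence test

Selection is a repeated cross-validated random-forest wrapper
(`select_features()`). Each of `n_rounds` (default 1000) rounds draws
stratified `k_folds` = 5 folds; per fold the multiplex is rebuilt from the
training-fold layers only, a 500-tree forest is grown, and features whose
mean decrease in Gini impurity exceeds the fold's mean importance are
kept; fold selections are unioned into the round's set (one count per
round). A second forest on the kept features predicts the validation fold,
giving the round's accuracy. Per-feature occurrence counts are tested
against an empirical binomial null: the null rate is the pooled selection
mass $\hat p_0 = \sum_j c_j / (n_{trials} f)$ — the rate expected if
rounds picked features exchangeably — with the one-sided exact tail
$P(X \ge c_j)$ and no multiple-testing correction; features with
$p < \alpha = 0.01$ are selected.

Design choices left open by the problem and decided here:

* *Per-round rule* (importance above the round mean): scale-free and
  parameter-free; exposed in the config.
* *mtry*: the default is $\sqrt f$ candidate features per split, standard
  forest practice; `mtry = "all"` (pure bagging) is available.
* *Stratified folds*: with small classes, plain folds occasionally go
  single-class; stratification avoids refitting pathologies.
* *Counting unit*: one count per round (union over folds), not per fold.

**Known limitation.** The binomial null treats rounds as independent
trials, but rounds resample the *same* subjects: a noise feature that
happens to correlate with labels in this dataset is selected stably in
every round. The test is therefore anti-conservative as `n_rounds` grows
— on a lesion-free phantom we observe 0 selected features at 10–20
rounds but hundreds at 30+ rounds, all at $\alpha = 0.01$. Interpret the
selected set as "stably important in this training set", not as
familywise-controlled discoveries. The null-calibration experiment in the
test suite runs 20 replicate selections of 10 rounds each on fresh
lesion-free cohorts for exactly this reason.

## Evaluation and robustness experiments

`train_final()` grows a 500-tree forest on the selected columns;
`evaluate_test()` scores held-out layers with accuracy, sensitivity
(disease class; the positive class is configurable) and specificity,
averaged over 100 bootstrap resamples of the test set with bootstrap
standard errors (one-class test sets report the undefined metric as
missing, never as 0). Robustness experiments replicate the full protocol:

* `label_permutation_test()` permutes labels before selection and
  training, yielding the null accuracy distribution (empirical and
  normal-fit tails for the observed accuracy);
* `voxel_shuffle_experiment()` permutes a growing number of voxel
  positions within each patch — independently per patch, per subject and
  per replicate, the harshest variant — destroying voxel correspondence
  while keeping the decomposition fixed;
* `threshold_sweep()` rebuilds layers across $\tau \in [0, 0.8]$
  (correlations computed once) and tracks the empty-network fraction;
* `patch_size_sweep()` reruns the pipeline across patch volumes;
* `hemisphere_experiments()` either restricts feature columns to one
  hemisphere (`feature_subset`) or rebuilds layers from one hemisphere's
  nodes only (`half_multiplex`).

## Anatomical back-mapping

Direct features (strength, IPR and their multiplex-weighted versions)
attach to a single patch; a node's p is the minimum over its selected
direct features. Conditional-mean features summarize every node sharing
the conditioning degree, so their support is recovered per subject: the
nodes whose (layer or aggregate, per feature type) degree equals the
conditioning degree, with occurrence counts over subjects tested against
an empirical binomial null (null rate = mean fraction of nodes per subject
in the degree class — the problem statement leaves this null open, and the
empirical rate is the least-assumption choice; it is config-exposed).
Patches map to atlas regions by voxel overlap (one voxel qualifies), each
region reported once at its minimum p.

*Ordering ties.* With a strong signal, occurrence counts saturate at
`n_rounds` and p-values tie at their floor $\hat p_0^{\,n}$ for every
saturated feature, so whole regions tie. Ties are broken by the strength
of the *directly localized* evidence — the region's minimum
direct-feature p, then the number of direct features at that minimum —
because a direct feature names one patch while a conditional feature
localizes only through the occurrence heuristic; overlap voxels break any
remainder. On the phantom this ranks the lesioned octants above their
mirror-image counterparts, which carry genuine but indirect signal
(lesioned nodes lose correlations *to* them).

## The phantom

`generate_cohort()` produces a fully seeded synthetic cohort so every
stage is testable without clinical data. The template is a
nested-ellipsoid tissue model — CSF rim and ventricle at 0.2, gray-matter
shell at 0.5, white-matter core at 0.8 (arbitrary units; only the
relative order matters, Pearson correlation being scale invariant) — with
a faint smooth symmetric texture, mirror-symmetric about the midsagittal
plane; an octant atlas partitions the mask into 8 contiguous regions.
Each subject is the template times a smooth separable-cosine bias field
(amplitude 0.05, mimicking residual inhomogeneity after normalization)
plus Gaussian noise (sd 0.05, small against the 0.3 tier gap). Atrophy is
an intensity mechanism: inside designated boxes an `effect_size` fraction
of gray-matter-tier voxels (pre-noise band ±0.1 around the tier, so
lesioning is independent of the noise draw) is set to the CSF intensity —
CSF expanding at the expense of gray matter. Lesioned voxels are redrawn
per subject, modeling inter-subject variability.

What the phantom does *not* emulate: geometric (deformation) atrophy,
misregistration, scanner/site effects, or realistic anatomy. Passing
recovery tests therefore shows that the pipeline detects localized
intensity-pattern atrophy on co-registered data — not that it matches any
clinical effect size. One consequence: the small-patch side of the
patch-size sweep does not degrade on the phantom (degradation there
requires registration noise), so only the large-patch side of the
scale-recovery plateau is informative at phantom scale.

## Numerical conventions and degenerate inputs

* Thresholding discards the boundary ($|r| \le \tau$), so $r = \tau$
  yields no edge.
* Zero-variance patches correlate 0 by default (`zero_variance = "zero"`);
  an error mode exists.
* Isolated nodes: $Y = 0$; degree-0 (or aggregate-degree-0) nodes get 0
  for all conditional and multiplex features, guaranteeing a complete
  feature matrix.
* Empty layers are legal and flagged, mirroring high-threshold sweeps
  where networks empty out.
* Odd x-extents exclude the central sagittal plane from both hemispheres
  (the fissure belongs to neither); x-tiling anchors at the fissure and
  grows outward, y/z-tilings are centered, partial boxes are discarded.
  All three anchorings are config-exposed because the retained count is
  convention-sensitive: on the MNI152 1 mm grid (197×233×189) the default
  convention with 10×15×20 patches at 10% overlap retains 792 patches,
  and plausible alternative anchorings span roughly 680–820.
* Seeds: every stochastic step derives its seed from a master seed by
  counter; identical seeds give bit-identical cohorts, folds, forests and
  reports.

## Problem sizes used by the test suite

The suite exercises the full pipeline at a desk scale chosen to keep a
complete run comfortable on one CPU: a 64×72×60 phantom with 8×9×10
patches (N ≈ 200, f = 1600), 30 subjects per class for training, 15 per
class held out, five lesioned left-hemisphere boxes at effect size 0.6,
100 selection rounds for recovery experiments and 10-round replicates for
null calibration; smaller 32×36×30 cohorts back the unit tests. The
reference defaults (1000 rounds, 500 trees, 100 bootstraps, τ = 0.3,
10×15×20 patches) remain the documented configuration for real use.

## Command-line entry point

`inst/cli/mplexmorph.R` wraps the package for shell use with subcommands
`phantom`, `parcellate`, `validate` and `run` (end-to-end, writing every
stage artifact plus a manifest). Individual stages — layers, features,
selection, training, evaluation, anatomy, and the robustness experiments
— are exported R functions; `run` composes them, so no separate
per-stage subcommand is provided.
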