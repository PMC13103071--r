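---
title: "How maskqc scores brain masks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How maskqc scores brain masks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skull-stripping algorithms (BET, HD-BET, BrainMaGe and their fusions)
produce binary brain masks that occasionally fail: over-eroded brains,
leftover skull or neck, holes, truncated slabs, spurious extracranial
blobs. Screening thousands of masks by eye does not scale, and
supervised failure classifiers need labelled failures that rarely exist
for a new cohort. `maskqc` implements a training-free alternative: learn
what *normal* masks look like from a trusted ground-truth cohort, then
flag any candidate whose shape statistics are improbable under that
baseline.

Only the masks themselves are needed — never the underlying MRI. That
makes the screen cheap, privacy-preserving, and applicable to any cohort
that ships segmentation labels.

## The model

**Features.** Each mask is reduced to 23 morphological descriptors:
voxel count, physical volume, voxel-face surface area, border-contact
measures, elongation, flatness, roundness, equivalent-sphere radius and
surface, the three equivalent-ellipsoid diameters, the maximum caliper
(Feret) diameter, the three principal second central moments, the
centroid offset from the volume centre, and the bounding-box extents.
All physical quantities use the NIfTI voxel spacing (mm). The catalogue
actually holds 24 descriptors; the default list omits the
border-surface ratio because it is exactly the quotient of two other
entries. Users can substitute any 23-name subset (for example a
site-specific list) through the config — the scoring machinery is
list-agnostic.

The second central moment matrix is assembled with per-axis variances on
the diagonal and negated mixed products off the diagonal (the
product-of-inertia sign convention); its eigenvalues, sorted descending
as $\lambda_1 \ge \lambda_2 \ge \lambda_3$, drive elongation
$\sqrt{\lambda_1/\lambda_2}$ and flatness $\sqrt{\lambda_2/\lambda_3}$
(both $\ge 1$ — two conventions circulate, so this one is stated
explicitly), and the ellipsoid diameters via the gamma-function unit-ball
volume $\pi^{3/2}/\Gamma(5/2)$.

**Baseline.** Features of the ground-truth cohort $B$ are z-scored
(population standard deviation, so the fitted set has exactly unit
variance; constant features map to zero) and clustered with k-means.
The cluster count $k \in \{2,\dots,10\}$ is chosen by stability: for
each $k$, 500 restarts are run from seeded k-means++ initializations
and the mean pairwise Rand index over a seeded subsample of run pairs
is recorded; the $k$ with the highest mean index wins, ties going to
the smaller $k$. The final clustering is the restart with the lowest
within-cluster sum of squares. Each cluster stores its mean and a
shrinkage-regularized covariance (Ledoit–Wolf-style shrinkage toward a
scaled identity, floor $10^{-6}$), because clusters routinely have
fewer members than the 23 features and the plain covariance would be
singular; a pseudo-inverse is the fallback if inversion still fails.

**Scoring.** A candidate vector $v$ (normalized with the *baseline's*
scaler) gets a Mahalanobis distance to every cluster
$d(v, C_i) = \sqrt{(v-\bar{C_i})^\top S_i^{-1} (v-\bar{C_i})}$, from
which two statistics are formed: the minimum $d_{\min}(v)$ (local
similarity — closeness to *some* kind of normal mask) and the
aggregate $\bar{d}(v) = \sum_i d(v, C_i)/|C_i|$ (global similarity).
The thresholds $t_{\min}$ and $t_\mu$ are the 90th percentiles (linear
interpolation) of the baseline's own $d_{\min}$ and $\bar{d}$
distributions. The similarity score is

$$ r = \tfrac{2}{\pi}\arctan\!\Big(\gamma\,\tfrac{d_{\min}}{t_{\min}}
       + (1-\gamma)\,\tfrac{\bar{d}}{t_\mu}\Big), $$

bounded in $[0, 1)$, and a mask passes QC iff $r \le r_{\max}$.

Two deliberate readings are worth flagging. First, the $2/\pi$
constant: with it, a mask sitting exactly at both thresholds scores
exactly $0.5$ for every $\gamma$, which is what makes the default
cutoff $r_{\max} = 0.5$ a meaningful boundary between strong and weak
similarity; a literal $\pi/2$ constant (range $[0, \pi^2/4)$) is
available as `arctan_constant = "literal"` for anyone who wants that
variant. Second, $\bar{d}$ as defined divides each distance by the
cluster size, so small clusters dominate the sum; this is implemented
as the default, with the conventional size-weighted mean
($\sum_i |C_i| d_i / \sum_i |C_i|$) and a median-distance variant
available through `d_bar_mode`, since either may match a user's intent
better.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.75 | weight on the local ($d_{\min}$) term; $>0.5$ favours resemblance to *any* baseline cluster over conformance to the global trend |
| `percentile` | 90 | percentile of the baseline distance distributions used for $t_{\min}, t_\mu$; lower it for stricter screening |
| `r_max` | 0.5 | pass cutoff on $r$; the boundary value passes |
| `k_min:k_max` | 2:10 | k-means search range |
| `runs` | 500 | restarts per candidate $k$ in the stability selection |
| `d_bar_mode` | `as_printed` | aggregation for $\bar{d}$ (see above) |
| `arctan_constant` | `normalized` | $2/\pi$ vs literal $\pi/2$ |
| `min_baseline` | 30 | smallest cohort for which per-cluster covariances are considered estimable |

By construction roughly $100 - n$ percent of the *baseline itself*
exceeds each threshold, so the method can never certify 100% of clean
data; that is the price of an unsupervised percentile rule.

## The synthetic cohort generator

Real multi-institutional ground-truth cohorts are not redistributable,
so the package ships a deterministic generator used by every test.
Clean masks are jittered ellipsoids (brain-like semi-axes 70/55/50 mm,
±5% per-axis jitter, ±2 mm centre offset) whose implicit surface is
perturbed by a smooth sum of six random cosine modes (≈2 mm amplitude,
40 mm wavelength), thresholded on a 96³ grid at 2 mm isotropic spacing.
Cohorts are drawn from a three-recipe *site family* whose overall scale
differs between sites by more than the within-site jitter
(`site_recipes()`), emulating the between-institution structure of
pooled clinical cohorts — this matters, because the baseline clustering
step is only meaningful when the baseline actually has structure; on a
deliberately unimodal cohort the unadjusted Rand index drifts toward
the upper end of the k range and per-cluster covariances overfit.

Corruptions mirror characteristic skull-stripping failures:
over-erosion, over-inclusion (dilation), interior holes, spurious
distant blobs, axial truncation, and misalignment (translation).
Magnitudes are not fixed: they are solved by bisection so each corrupt
mask's Dice against its clean source lands in a target band
(0.85–0.93, safely below the 0.95 sanity threshold); the blob radius is
instead grown until HD95 exceeds 15 mm, since a distant blob barely
moves Dice — that corruption is sanity-positive through the Hausdorff
route. Every corrupt mask is therefore a *known* failure by
construction, giving labelled positives without human annotation.

What the generator does **not** emulate: cortical folding,
modality-dependent mask differences, mask smoothness/pixelation
artifacts, or intensity information of any kind. Passing the synthetic
screen shows the machinery separates shape-level failures from
shape-level normality under realistic size/position variation; it does
not certify performance on any particular clinical cohort, where the
feature distributions, failure modes, and the adequacy of the 23
descriptors must be judged anew.

## Evaluation harness

Dice is $2|A \cap B|/(|A|+|B|)$, with two empty masks defined as
agreement 1 and one empty mask as 0. HD95 extracts surfaces as
foreground voxels with a face-adjacent background neighbour
(6-connectivity; outside the grid counts as background), computes exact
nearest-surface distances in both directions (a small compiled kernel
does the all-pairs scan), takes each direction's 95th percentile with
linear interpolation, and reports the maximum of the two — the common
neuro-oncology benchmark convention; the 15 mm threshold is read in
physical units. A candidate is sanity-positive (expected to fail QC)
iff Dice < 0.95 **or** HD95 > 15 mm, both strict. Verdicts against
sanity labels populate the usual confusion matrix; ratios with empty
denominators are reported as `NA`, never 0.

## Numerical choices and degenerate inputs

* Percentiles everywhere use linear interpolation between order
  statistics (R's `quantile` type 7), so the worked case
  $D_{\min} = \{1,\dots,10\}$, $n = 90$ gives $t_{\min} = 9.1$.
* Tiny negative values under the Mahalanobis square root (possible
  after shrinkage + floating point) are clipped to zero.
* A single-voxel mask has a zero moment matrix; elongation and flatness
  ratios with zero denominators are defined as 1.
* Empty masks raise a classed error in feature extraction; in batch
  scoring the error is captured per mask into the `error` column and
  the batch completes.
* Any cluster left with a single member after the final k-means fit
  triggers a refit at $k-1$, down to $k=2$; a baseline of numerically
  identical points raises a degenerate-clustering error rather than
  silently producing zero thresholds.
* The Feret diameter is the maximum pairwise distance among directional
  extreme points of the surface over a fixed 321-direction Fibonacci
  sphere — deterministic, and exact for convex shapes up to that
  angular resolution.
* All randomness (generator, k-means restarts, pair subsampling) flows
  from explicit integer seeds through a save/restore RNG helper, so
  identical config + seed reproduces results bit for bit.

## Problem sizes in the shipped tests

The test suite and the acceptance script exercise the full pipeline at
a baseline of 60 clean masks and a test set of 40 clean + 40 calibrated
corrupt masks on 96³ grids — large enough that the feature
distributions, threshold calibration, and confusion rates are
meaningful, and small enough to run comfortably on a laptop. Unit
tests use 48³ grids and oracle checks use ≤32³ masks, where brute-force
triple loops and all-pairs surface scans are feasible.

## Known limitations

* The screen sees only what the 23 descriptors see: a failure that
  preserves gross shape statistics (a small misplaced hole, subtle
  boundary raggedness) can pass, and shape-irrelevant nuisance
  variation (mask smoothness conventions between tools) can fail
  otherwise fine masks.
* With the default 90th-percentile rule, ~10% of masks drawn from the
  baseline distribution itself are expected to score above threshold —
  sensitivity is bought with a floor on false positives.
* The as-printed $\bar{d}$ lets small clusters dominate the global
  term; with very unbalanced baselines consider
  `d_bar_mode = "size_weighted"`.
* Per-cluster covariances with few members lean heavily on shrinkage;
  distances within such clusters are closer to scaled Euclidean than
  truly covariance-aware.
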