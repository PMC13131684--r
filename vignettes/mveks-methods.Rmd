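---
title: "Multi-view ensemble Kalman smoothing: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view ensemble Kalman smoothing: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Multi-camera animal pose estimation yields, per frame and body part, one 2D
prediction per camera view — and several per view when an ensemble of
networks is used. These predictions jitter, fail under occlusion, and need
not agree on any single 3D location. `mveks` post-processes them with a
state-space model that exploits two independent sources of structure:
temporal continuity (animals move smoothly at typical frame rates) and
epipolar geometry (all views observe one 3D point). This vignette documents
the models, every tunable parameter, the numerical choices, and the limits
of what the synthetic validation shows.

# The state-space model

For a single body part, stack the per-view coordinates at frame $t$ into
$x_t = (x_1, y_1, \dots, x_V, y_V) \in \mathbb{R}^{2V}$. The model is

$$z_t \mid z_{t-1} \sim \mathcal{N}(z_{t-1},\, s E), \qquad
  x_t \mid z_t \sim \mathcal{N}(h(z_t),\, D_t),$$

where $z_t$ is a 3-dimensional latent state, $E$ a fixed process
covariance, $s > 0$ a per-keypoint smoothing scalar, and $D_t$ a diagonal
observation covariance taken from the ensemble variance (so observation
trust varies frame by frame). Two observation maps $h$ are provided:

* **Linear** (`mode = "linear"`): $h(z) = W z + \mu_x$ with $W$ and
  $\mu_x$ estimated by PCA. No camera calibration is needed; this relies on
  the empirical low dimensionality of stacked multi-view observations
  (three principal components suffice in narrow-field/near-affine regimes —
  the property the acceptance script measures).
* **Nonlinear** (`mode = "nonlinear"`): $h_j(z) = f_j(z)$ per view, the
  calibrated camera model (extrinsics, perspective division, five-parameter
  radial/tangential distortion, intrinsics). An extended Kalman filter
  linearizes $f_j$ at each predicted state with the analytic Jacobian
  (validated against central differences in the tests); smoothing is a
  Rauch–Tung–Striebel pass over the stored linearizations.

Both modes run a forward Kalman filter accumulating the marginal
log-likelihood from the innovations, then the RTS backward pass. Invalid
observations (missing predictions, fewer than two finite ensemble members)
are given a variance of $10^{12}\,\text{px}^2$ rather than resized out of
the recursion, keeping every step shape-stable.

## Parameter initialization (linear mode)

Frames whose maximum ensemble variance across views and coordinates falls
below the 50th percentile (`low_var_quantile = 0.5`) are used for the PCA
fit: $\mu_x$ is their mean; $W$ holds the top-$d$ principal directions
scaled by the singular values, so latent coordinates are approximately
unit-variance; $d = 3$ by default (a 3D latent). $E$ is the covariance of
the first differences of the PCA projections (computed between temporally
adjacent frames only). The observation rank must be at least $d$ after
filtering, otherwise initialization aborts naming the keypoint.

$E$ is held time-invariant. It is estimated once, from data; a per-frame
process covariance would not be identifiable from a single trajectory
without further structure.

## Choosing the smoothing scalar

$s$ trades smoothness against fidelity: too large undersmooths, too small
oversmooths. It is chosen per keypoint by maximizing the filter marginal
log-likelihood over $\log s$ with plain gradient ascent: learning rate
0.25, central-difference gradient ($h = 10^{-3}$), a step cap of 1 in log
space, step rejection with halving whenever the proposed likelihood is
non-finite or lower, at most 100 iterations, convergence when the accepted
step falls below $10^{-4}$. The optimizer never returns a likelihood below
its starting point. The starting value is the mean over latent dimensions
of the standard deviations of the projected first differences.

Two caveats worth knowing. First, because $E$ is itself estimated from the
same first differences, the likelihood-optimal $s$ on clean data sits near
1 in those units; the optimizer's job is to correct for noise
contamination of the difference covariance and for keypoints whose motion
departs from the initialization window. Second, recovering a *generating*
$s_{\text{true}}$ within a factor of two (which the acceptance suite
verifies over 20 simulations at $T = 1000$) is only an identifiable task
when the generating $W$, $\mu_x$, $E$ are used for the fit — re-running PCA
rescales the latent space and absorbs $s$ into $E$. The recovery tests
therefore fix the generating model and optimize $s$ alone, and also verify
that the likelihood over a 50-point log-spaced grid in $s$ has a single
interior maximum.

The initial state prior is the generalized-least-squares latent estimate
from the first fully observed frame with covariance $10E$ (linear), or the
triangulation of the first frame with at least two valid views (nonlinear).

# Cross-view inconsistency and variance inflation

Ensemble variance fails as an uncertainty signal precisely when all members
agree on a wrong prediction. Geometry provides an independent check: model
a single frame's stacked observation with the factor-analysis model
$x \sim \mathcal{N}(W z + \mu_x, D)$ under an uninformative latent prior,
giving posterior matrix $B = (W^\top D^{-1} W)^{-1}$. For each view $v$,
condition on the *remaining* views only and form the leave-one-out
posterior predictive mean $x'_v$ and covariance
$Q_v = D_v + W_v B W_v^\top$ (with $B$ from the remaining views). The
inconsistency score is the Mahalanobis distance

$$d_v = \sqrt{(x_v - x'_v)^\top Q_v^{-1} (x_v - x'_v)},$$

a multivariate z-score. The square-root scale is used so that the default
threshold of 5 reads as "five standard deviations".

Computing $B$ from the remaining views (rather than all views) has two
consequences we rely on: the prediction $x'_v$ is independent of view $v$'s
own variance, and inflating $D_v$ grows $Q_v$ in the PSD order while
leaving $x'_v$ fixed — so $d_v$ decreases monotonically under inflation and
the procedure terminates.

**Inflation procedure.** Per frame and keypoint: compute $d_v$ for all
views; while any view is at or above the threshold (default 5), multiply
the *most inconsistent* view's two variance entries by the factor (default
10) and recompute; stop when all views are below threshold or a view
reaches the round cap (default 25, i.e. variance scaled by $10^{25}$ —
effectively removing the observation; capped entries are reported as
unresolved, never raised as errors). Targeting the worst view first matters:
a confidently wrong view contaminates *every* leave-one-out prediction, so
naively inflating all flagged views penalizes clean ones; resolving the
largest distance first usually collapses the others' distances without
touching them. With exactly two views the outlier is unidentifiable, so
both views are inflated together. The two-view case also bounds the usable
latent dimension: the leave-one-out system needs $d \le 2(V-1)$; when it is
rank-deficient the view's distance is reported as 0 and skipped.

What inflation can and cannot do: when the inconsistent view is *less*
confident than the others, down-weighting it lets the posterior recover the
true position. When the wrong view is the *most* confident one, inflation
cannot always override it — but it reliably inflates the posterior
predictive variance of the affected frames, flagging them as unreliable.
Both behaviors are exercised in the acceptance suite (20 corrupted scenes:
inflated error never exceeds uninflated error on corrupted segments, and
the reported variance strictly increases).

In nonlinear mode the same machinery runs with $W$ taken as the per-frame
Jacobian of the camera projections at the triangulated estimate, and
$\mu_x$ the matching affine offset.

# Geometry

Coordinates are `x` = column, `y` = row, origin top-left, subpixel values
at pixel centers. The camera model is the standard five-coefficient
Brown–Conrady model, coefficients ordered `k1 k2 p1 p2 k3` (the calibration
file convention, documented in `read_calibration()`). Undistortion inverts
the distortion map by fixed-point iteration (20 iterations, tolerance
$10^{-8}$ in normalized units; non-convergent points are flagged invalid);
round trips are exact to well under $10^{-6}$ px for moderate distortion
($|k_1| \le 0.3$). Triangulation solves the homogeneous DLT system built
from undistorted normalized rays (identity intrinsics — distortion breaks
the linear DLT model) via the smallest right singular vector; degenerate
geometry (coincident/parallel rays, near-zero homogeneous scale) yields an
invalid entry. Multi-view triangulation is the unweighted mean over all
valid unordered view pairs — no RANSAC, no reprojection weighting — and
requires at least two valid views.

# Training-side operators

**Heatmaps.** `gaussian_heatmap()` renders isotropic bumps (peak 1,
$\sigma$ = 1.25 heatmap px by default) on a grid carrying an explicit
affine grid-to-image transform (default quarter resolution:
`image = 4 * heatmap + 1.5`). Off-grid keypoints render as all-near-zero
maps and are flagged missing.

**Soft argmax.** Two input conventions are supported, and this is a
deliberate design decision. For *density-scale* maps (the package's native
convention; anything produced by `gaussian_heatmap()`), the map is
renormalized to a distribution directly and the spatial expectation taken —
this is the exact subpixel inverse of the Gaussian renderer for interior
points (discretization error below $10^{-10}$ px at $\sigma = 1.25$), which
is what makes consistent-scene reprojection losses vanish to numerical
precision. For *logit-scale* maps (raw network outputs; `logits = TRUE`), a
spatial softmax with temperature $\tau$ (default 1000) is applied first; a
high temperature suppresses non-global maxima but quantizes the expectation
toward the discrete argmax, so exp-sharpening is *not* applied to
density maps, where it would destroy subpixel accuracy (a peak-1 Gaussian
under $\exp(1000\,v)$ collapses to the nearest pixel, a ~0.3 px error).
Confidence is the normalized mass within `radius` (default 3) heatmap
pixels of the estimate.

**Reprojection loss.** Soft-argmax each predicted map, map to image pixels,
triangulate across all pairs, reproject to every view, re-render Gaussian
heatmaps, and score mean squared error against the ground-truth maps scaled
by $h \times w$, averaged over valid keypoints and views. Missing keypoints
and keypoints with fewer than two valid views are excluded.

**Patch-mask curriculum.** Zero before iteration 700, then linear from 10%
to 50% at iteration 5000, constant after. Masks are unions of random
rectangles (1–4 patches per side) accumulated until the target fraction is
reached, so the realized fraction overshoots by at most one block.

**3D augmentation.** Triangulate the labels; scale about the per-axis
median by one draw from $U(0.8, 1.2)$; translate each axis by a draw from
$U(-0.25, 0.25)$ times that axis' bounding-box width; reproject everywhere.
A 4-DOF similarity (scale-rotation + translation) is fit per view by linear
least squares between original and augmented labels — this is the transform
a caller would apply to the images. Untriangulable keypoints pass through
unchanged and are flagged.

# Pseudo-label selection

Stage 1 ranks frames by $\sigma^2_{\max}$, the maximum predictive variance
across keypoints, views and coordinates, and keeps the lowest
`keep_fraction` (default 0.6), ties broken by frame index. The default
quality signal is the factor-model predictive variance $Q$ (diagonal of
$D + W B W^\top$) computed from the possibly-inflated ensemble variances;
the Kalman posterior predictive variance is available as an alternative
(`frame_quality_posterior()`). Stage 2 builds a pose vector per kept frame
— concatenated triangulated 3D keypoints, or per-keypoint PCA scores
without calibration (untriangulable keypoints imputed by the frame's valid
centroid and flagged) — clusters with k-means (default $k = 3000$,
k-means++-style seeding via 10 restarts, fixed seed, $k$ lowered to the
pool size when larger), and keeps the frame nearest each centroid. Export
writes per-view label CSVs in the training dialect with the smoothed
posterior means as coordinates.

# The synthetic scene generator

`simulate_scene()` draws a latent 3D center as the random walk
$z_t = z_{t-1} + \mathcal{N}(0, s_{\text{true}} E_{\text{true}})$ (defaults
$s_{\text{true}} = 1$, $E_{\text{true}} = \mathrm{diag}(2\times10^{-5})$
world units$^2$ — millimetre-scale steps at metre scale), attaches a fixed
random rigid constellation of keypoint offsets (sd 0.08 world units),
projects exactly through a circular rig (`make_rig()`: cameras evenly
spaced on a circle of radius 3 looking at the origin, focal 1200 px,
400×400 images — a narrow-field, near-affine regime; `arc_deg` spreads
cameras over a partial arc where an opposed two-camera pair would make
triangulation degenerate on the baseline), and adds i.i.d. Gaussian pixel
noise per ensemble member (default 2 px). Occlusion segments overwrite
listed (view, keypoint, frame) entries: *member-correlated* corruption
gives all members a common displaced value with 0.01 px spread — the
confidently wrong failure mode that motivates inflation — while
uncorrelated corruption uses independent 10 px-spread draws.

What this emulates: the generative assumptions of the smoother, ensemble
heteroscedasticity, and the cross-view-inconsistency failure modes. What it
does not: articulated skeletons (keypoints are a rigid constellation),
realistic network error distributions (heavy tails, systematic left/right
swaps), rolling shutter, calibration error, or appearance. Passing tests
therefore demonstrate correctness of the estimators under their stated
model, not performance on any real recording.

Problem sizes used by the test and acceptance suites (chosen to exercise
the asymptotics the claims rely on while staying desk-scale): dense-oracle
checks at $T \le 6$; parameter recovery at $T = 1000$ over 20 simulations;
inflation efficacy and median-vs-smoother comparisons over 20 scenes of
100–250 frames; the PCA dimensionality measurement at $T = 2000$.

# Degenerate inputs and numerical safeguards

* Points at or behind a camera plane: flagged invalid on projection;
  dropped per frame during EKF linearization (logged in `dropped_views`).
* Non-PSD intermediate covariances: symmetrized, with a jitter of
  $10^{-8}$ times the diagonal scale added before Cholesky retry (counted
  in `jitter_events`).
* Ensemble variances are floored at $10^{-12}$ px$^2$ before entering any
  precision computation.
* Leave-one-out systems with reciprocal condition number below $10^{-12}$
  are treated as rank-deficient (distance 0, view skipped).
* Even-sized ensembles use the midpoint of the two central order statistics
  as the median; the variance denominator (`ddof`, default 1 = unbiased) is
  exposed because the convention is a modeling choice, not a fact.

# Known limitations

* The linear mode presumes the 2V-dimensional observations are well
  approximated by a 3-dimensional affine subspace; strong lens distortion
  or very wide fields break this (use nonlinear mode with calibration).
* Inflation identifies inconsistency, not truth: with two views, or when
  the wrong view dominates in confidence, the estimate may remain wrong —
  the uncertainty is what becomes honest.
* $E$ is time-invariant and per-keypoint; no joint estimation of $E$ with
  $s$, no switching dynamics, no imputation of missing views beyond the
  infinite-variance mechanism.
* The smoothing-parameter search is a 1-D ascent on a smooth unimodal
  objective; it is not a global optimizer, and on multimodal likelihoods
  (not observed in simulation) it would return the local optimum reachable
  from the initialization.
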