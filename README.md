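# mveks

Multi-view Ensemble Kalman smoothing for animal pose estimation.

Markerless pose estimation from multiple synchronized cameras produces, for
every frame and body part, one 2D prediction per view — and, when an
ensemble of networks is run, several predictions per view. Individual
predictions jitter, fail under occlusion, and are not guaranteed to agree on
a single 3D location across views. `mveks` implements the probabilistic
post-processing layer that repairs this: it treats the stacked per-view
coordinates as noisy observations of a 3D latent trajectory, smooths them
with a Kalman filter-smoother, detects views that are geometrically
inconsistent with the rest of the rig (even when the ensemble is confidently
wrong), and turns the resulting posterior uncertainty into an automatic
pseudo-label frame selector. A synthetic multi-camera scene generator makes
the whole pipeline testable end to end without any recordings.

## The model

For one body part, let `x_t ∈ R^(2V)` stack the `(x, y)` predictions of all
`V` views at frame `t` (ensemble median), and let the diagonal matrix `D_t`
hold the per-coordinate ensemble variances. The state-space model is

    z_t | z_(t-1) ~ N(z_(t-1), s E)          latent random walk
    x_t | z_t     ~ N(W z_t + mu_x, D_t)     linear observation model

with a 3-dimensional latent `z_t`. In **linear** mode, `W` and `mu_x` are
estimated by PCA from low-ensemble-variance frames (no calibration needed);
in **nonlinear** mode the observation map is the calibrated camera
projection `f_j(z_t)` per view (full radial/tangential distortion model) and
an extended Kalman filter linearizes it per frame. The scalar `s` trades
temporal smoothness against observation fidelity and is chosen per keypoint
by maximizing the filter's marginal likelihood.

When all ensemble members agree on a *wrong* prediction, `D_t` is small and
the smoother trusts the bad view. Cross-view geometry exposes this: for each
view `v`, the package computes the leave-one-out posterior predictive
`x'_v` (from the remaining views, factor-analysis model with uninformative
prior, `B = (W' D^-1 W)^-1`) and the Mahalanobis distance

    d_v = sqrt( (x_v - x'_v)' Q_v^-1 (x_v - x'_v) ),   Q_v = D_v + W_v B W_v'

a multivariate z-score of cross-view consistency. Any view with `d_v >= 5`
has its observation variance multiplied by 10 (worst view first,
recomputing after each round) until every view is consistent; with two views
the outlier cannot be identified, so both are inflated together.

Training-side operators (Gaussian heatmaps, soft argmax with confidence, the
2D→3D→2D reprojection loss, the patch-mask curriculum, geometry-consistent
3D augmentation) and uncertainty-guided pseudo-label selection (quality
filter on the posterior predictive variance, then k-means diversity
selection in 3D pose space) round out the toolkit.

## Worked example

```r
library(mveks)

# a 3-camera scene, 2 keypoints, 5-network ensemble, 2 px member noise
spec <- scene_spec(V = 3, K = 2, T_ = 200, M = 5, sigma_obs = 2, seed = 1)
scene <- simulate_scene(spec)
obs <- aggregate_ensemble(scene$ensemble)   # median + variance over members
fit <- smooth_all_keypoints(obs, mode = "nonlinear", rig = scene$rig)
evaluate_predictions(obs$coords, scene)$mean_pixel_error   # raw median
#> [1] 1.353247
evaluate_predictions(fit$means, scene)$mean_pixel_error    # smoothed
#> [1] 0.969075
```

The smoother cuts the mean pixel error of the raw ensemble median from
1.35 px to 0.97 px, with the smoothing scalar chosen per keypoint by
marginal likelihood (here 0.550 and 0.558).

The confidently wrong case — all ensemble members agreeing on a displaced
prediction — is where inflation matters. When the wrong view carries
near-zero ensemble variance it cannot always be overridden, but it is
reliably *flagged*:

```r
spec2 <- scene_spec(V = 3, K = 2, T_ = 200, M = 5, sigma_obs = 2, seed = 1,
                    occlusions = list(list(view = 2, keypoint = 1,
                                           frames = 30:60,
                                           displacement = c(30, 0),
                                           correlated = TRUE)))
scene2 <- simulate_scene(spec2)
obs2 <- aggregate_ensemble(scene2$ensemble)
fit2 <- smooth_all_keypoints(obs2, mode = "nonlinear", rig = scene2$rig,
                             inflate = TRUE)
# posterior predictive variance of the corrupted view, frames 30-60:
mean(fit2$cov[30:60, 2, 1, 1, 1])          # with inflation
#> [1] 15.32614                             # (0.00022 without inflation)
kept <- quality_filter(frame_quality_posterior(fit2), keep_fraction = 0.6)
sum(30:60 %in% kept)
#> [1] 0
```

Without inflation the corrupted frames report a posterior predictive
variance of ~2e-4 px^2 — confidently wrong; with inflation it rises to
~15 px^2, and the pseudo-label quality filter consequently discards all 31
corrupted frames. That flagging signal is exactly what
`quality_filter()` / `diversity_select()` use to pick trustworthy, diverse
pseudo-label frames for distillation.

The same pipeline is scriptable from a shell via the thin wrappers in
`inst/cli/` (`mveks-simulate`, `mveks-smooth`, `mveks-select`,
`mveks-evaluate`), which read/write the community CSV dialect
(scorer/bodyparts/coords header) and TOML calibration files.

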