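# Synthetic multi-camera scenes: circular rigs, smooth latent 3D
# trajectories (random walk), rigid keypoint constellations, ensemble
# predictions with heteroscedastic noise, and injected confident-wrong
# occlusion segments. Every downstream module is testable against these
# scenes with no external data.

#' Build a circular camera rig
#'
#' Places `V` cameras evenly on a circle of the given radius around the
#' world origin (optionally spanning only part of the circle), each looking
#' at the origin with the world z-axis up. A nonzero `distortion_level`
#' scales a fixed set of base distortion coefficients.
#'
#' @param V Number of cameras (>= 2).
#' @param radius Circle radius, world units (default 3).
#' @param focal Focal length in pixels (default 1200; with the default
#'   radius this gives a narrow field of view, i.e. a near-affine regime for
#'   subjects of ~0.2 world units).
#' @param image_size Length-2 `(width, height)` pixels (default 400 x 400).
#' @param distortion_level Scalar in `[0, 1]`-ish scaling the base
#'   coefficients `(-0.2, 0.05, 0.002, -0.002, 0.01)`; 0 gives an ideal
#'   pinhole (default 0).
#' @param elevation Camera height above the origin plane (default 0).
#' @param arc_deg Angular span over which cameras are spread (default 360,
#'   an even full circle: cameras `360/V` degrees apart).
#' @return A [camera_rig()].
#' @export
make_rig <- function(V, radius = 3, focal = 1200, image_size = c(400, 400),
                     distortion_level = 0, elevation = 0, arc_deg = 360) {
  stopifnot(V >= 2, radius > 0, focal > 0)
  base_dist <- c(-0.2, 0.05, 0.002, -0.002, 0.01)
  angles <- if (arc_deg >= 360) {
    2 * pi * (seq_len(V) - 1) / V
  } else {
    seq(0, arc_deg * pi / 180, length.out = V)
  }
  cams <- lapply(seq_len(V), function(i) {
    a <- angles[i]
    C <- c(radius * cos(a), radius * sin(a), elevation)
    zc <- -C / sqrt(sum(C^2))           # optical axis toward origin
    up <- c(0, 0, 1)
    xc <- vcross(up, zc)
    nx <- sqrt(sum(xc^2))
    if (nx < 1e-9) { xc <- c(1, 0, 0); nx <- 1 }   # camera looking straight down
    xc <- xc / nx
    yc <- vcross(zc, xc)
    R <- rbind(xc, yc, zc)
    camera_model(
      name = sprintf("cam_%d", i - 1),
      focal = c(focal, focal),
      principal = image_size / 2,
      distortion = distortion_level * base_dist,
      rotation = rotation_axis_angle(R),
      translation = as.numeric(-R %*% C),
      size = image_size
    )
  })
  camera_rig(cams)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Specification of a synthetic multi-camera scene
#'
#' @param V,K,T_,M Counts of views, keypoints, frames, ensemble members.
#' @param s_true Smoothing scalar of the generating latent random walk.
#' @param E_true Process covariance `3 x 3` (world units^2 per frame);
#'   default `diag(2e-5, 3)` (per-frame steps of ~4.5 mm at metre scale).
#' @param sigma_obs Ensemble member noise standard deviation, pixels.
#' @param offset_scale Spread of the rigid keypoint constellation around the
#'   latent center, world units (default 0.08).
#' @param occlusions List of occlusion segments, each a list with `view`,
#'   `keypoint`, `frames` (integer vector), `displacement` (length-2 pixel
#'   offset), and `correlated` (logical: `TRUE` gives all members a common
#'   displaced value with 0.01 px member spread — the confidently wrong
#'   failure mode; `FALSE` gives independent large-noise values with 10 px
#'   spread).
#' @param seed Integer seed; the scene is fully reproducible given the spec.
#' @param rig Optional [camera_rig()]; by default built by [make_rig()] with
#'   the remaining arguments.
#' @param distortion_level,radius,focal,image_size,arc_deg Passed to
#'   [make_rig()] when `rig` is not supplied.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(V = 4, K = 3, T_ = 500, M = 5, s_true = 1,
                       E_true = diag(2e-5, 3), sigma_obs = 2,
                       offset_scale = 0.08, occlusions = list(),
                       seed = 1, rig = NULL, distortion_level = 0,
                       radius = 3, focal = 1200, image_size = c(400, 400),
                       arc_deg = 360) {
  stopifnot(V >= 2, K >= 1, T_ >= 2, M >= 2, s_true > 0, sigma_obs >= 0)
  for (oc in occlusions) {
    stopifnot(oc$view >= 1, oc$view <= V, oc$keypoint >= 1, oc$keypoint <= K,
              all(oc$frames >= 1), all(oc$frames <= T_))
  }
  structure(list(V = V, K = K, T_ = T_, M = M, s_true = s_true,
                 E_true = as.matrix(E_true), sigma_obs = sigma_obs,
                 offset_scale = offset_scale, occlusions = occlusions,
                 seed = as.integer(seed), rig = rig,
                 distortion_level = distortion_level, radius = radius,
                 focal = focal, image_size = image_size, arc_deg = arc_deg),
            class = "scene_spec")
}

#' Simulate a synthetic multi-camera scene
#'
#' Draws a latent 3D center trajectory from the random walk
#' `z_t = z_{t-1} + N(0, s_true E_true)`, attaches a fixed random rigid
#' constellation of `K` keypoint offsets, projects through the rig to exact
#' 2D ground truth, and generates `M` ensemble members as ground truth plus
#' i.i.d. Gaussian pixel noise. Occlusion segments then overwrite the listed
#' (view, keypoint, frame) entries (see [scene_spec()]).
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_scene`: `rig`, `truth3d`
#'   (`[T, K, 3]`), `truth2d` (`[T, V, K, 2]`), `ensemble`
#'   ([ensemble_predictions()]), `corrupted` (logical `[T, V, K]`), and the
#'   spec.
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  V <- spec$V; K <- spec$K; T_ <- spec$T_; M <- spec$M
  rig <- spec$rig
  if (is.null(rig)) {
    rig <- make_rig(V, radius = spec$radius, focal = spec$focal,
                    image_size = spec$image_size,
                    distortion_level = spec$distortion_level,
                    arc_deg = spec$arc_deg)
  }
  chol_E <- chol(spec$s_true * spec$E_true + diag(1e-18, 3))
  steps <- matrix(stats::rnorm(T_ * 3), T_, 3) %*% chol_E
  steps[1, ] <- 0
  center <- apply(steps, 2, cumsum)
  offsets <- matrix(stats::rnorm(K * 3, sd = spec$offset_scale), K, 3)
  truth3d <- array(NA_real_, c(T_, K, 3))
  for (k in seq_len(K)) truth3d[, k, ] <- sweep(center, 2, offsets[k, ], "+")
  truth2d <- array(NA_real_, c(T_, V, K, 2))
  for (v in seq_len(V)) {
    pts <- matrix(truth3d, T_ * K, 3)
    proj <- project_points(rig$cameras[[v]], pts)
    truth2d[, v, , ] <- array(proj, c(T_, K, 2))
  }
  coords <- array(NA_real_, c(M, T_, V, K, 2))
  nnoise <- M * T_ * V * K * 2
  noise <- array(stats::rnorm(nnoise, sd = spec$sigma_obs), c(M, T_, V, K, 2))
  for (m in seq_len(M)) {
    coords[m, , , , ] <- truth2d +
      array(noise[m, , , , , drop = FALSE], dim(truth2d))
  }
  corrupted <- array(FALSE, c(T_, V, K))
  for (oc in spec$occlusions) {
    fr <- oc$frames; v <- oc$view; k <- oc$keypoint
    corrupted[fr, v, k] <- TRUE
    correlated <- isTRUE(oc$correlated)
    spread <- if (correlated) 0.01 else 10
    for (i in seq_along(fr)) {
      t <- fr[i]
      target <- truth2d[t, v, k, ] + oc$displacement
      if (correlated) {
        coords[, t, v, k, 1] <- target[1] + stats::rnorm(M, sd = spread)
        coords[, t, v, k, 2] <- target[2] + stats::rnorm(M, sd = spread)
      } else {
        coords[, t, v, k, 1] <- target[1] + stats::rnorm(M, sd = spread)
        coords[, t, v, k, 2] <- target[2] + stats::rnorm(M, sd = spread)
      }
    }
  }
  structure(list(rig = rig, truth3d = truth3d, truth2d = truth2d,
                 ensemble = ensemble_predictions(coords, views = rig$names),
                 corrupted = corrupted, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<synthetic_scene> V=%d K=%d T=%d M=%d sigma_obs=%.3g (%d corrupted entries)\n",
              s$V, s$K, s$T_, s$M, s$sigma_obs, sum(x$corrupted)))
  invisible(x)
}

#' Evaluate predictions against synthetic ground truth
#'
#' @param pred2d Numeric array `[T, V, K, 2]` of predicted pixel coordinates.
#' @param scene A [simulate_scene()] result.
#' @param pred3d Optional `[T, K, 3]` array of 3D predictions.
#' @param strat_stds Optional per-entry ensemble standard deviations
#'   `[T, V, K]` used to stratify pixel error by difficulty percentile.
#' @param strat_percentiles Percentile thresholds for stratification
#'   (default `c(0, 50, 75, 90)`): for each, the mean error over entries
#'   whose ensemble std exceeds that percentile of all stds.
#' @return List with `pixel_error` (`[T, V, K]`), `mean_pixel_error`,
#'   `error_3d` (`[T, K]` or `NULL`), `mean_error_3d`, `reprojection`
#'   (mean reprojection error of `pred3d`, or `NULL`), and `stratified`
#'   (data frame of threshold percentile, std threshold, mean error, n).
#' @export
evaluate_predictions <- function(pred2d, scene, pred3d = NULL,
                                 strat_stds = NULL,
                                 strat_percentiles = c(0, 50, 75, 90)) {
  stopifnot(inherits(scene, "synthetic_scene"),
            all(dim(pred2d) == dim(scene$truth2d)))
  err <- sqrt((pred2d[, , , 1] - scene$truth2d[, , , 1])^2 +
                (pred2d[, , , 2] - scene$truth2d[, , , 2])^2)
  dims <- dim(scene$truth2d)
  err <- array(err, dims[1:3])
  out <- list(pixel_error = err,
              mean_pixel_error = mean(err, na.rm = TRUE),
              error_3d = NULL, mean_error_3d = NULL, reprojection = NULL,
              stratified = NULL)
  if (!is.null(pred3d)) {
    e3 <- sqrt(apply((pred3d - scene$truth3d)^2, c(1, 2), sum))
    out$error_3d <- e3
    out$mean_error_3d <- mean(e3, na.rm = TRUE)
    reproj <- numeric(dims[1])
    for (t in seq_len(dims[1])) {
      obs <- array(aperm(pred2d[t, , , , drop = FALSE], c(2, 3, 4, 1)),
                   c(dims[2], dims[3], 2))
      pts <- matrix(pred3d[t, , ], dims[3], 3)
      reproj[t] <- reprojection_error(scene$rig, obs, pts)$mean
    }
    out$reprojection <- mean(reproj, na.rm = TRUE)
  }
  if (!is.null(strat_stds)) {
    stopifnot(all(dim(strat_stds) == dims[1:3]))
    rows <- lapply(strat_percentiles, function(p) {
      thr <- stats::quantile(strat_stds, p / 100, na.rm = TRUE, names = FALSE)
      sel <- strat_stds >= thr
      data.frame(percentile = p, std_threshold = thr,
                 mean_error = mean(err[sel], na.rm = TRUE),
                 n = sum(sel, na.rm = TRUE))
    })
    out$stratified <- do.call(rbind, rows)
  }
  out
}
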