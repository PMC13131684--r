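# Training-side numeric operators: Gaussian heatmaps, soft argmax with
# confidence, the 2D -> 3D -> 2D reprojection loss, the patch-mask
# curriculum, and geometry-consistent 3D augmentation. All operators are
# pure functions over arrays; randomness always enters through an explicit
# seed.
#
# Heatmap grid convention matches the geometry module: x = column, y = row,
# origin top-left, coordinates at pixel centers (0-based). Heatmap stacks
# carry an affine grid-to-image transform (image_px = scale * heatmap_px +
# offset); by default heatmaps live at 1/4 image resolution, for which the
# center-preserving transform is scale 4, offset 1.5.

#' Construct a heatmap stack with its grid-to-image transform
#'
#' @param values Numeric array `[K, h, w]`, nonnegative.
#' @param scale,offset Affine map from heatmap to image pixel coordinates:
#'   `image = scale * heatmap + offset` (defaults 4 and `(scale - 1) / 2`,
#'   the center-preserving map for 1/4-resolution heatmaps).
#' @param missing Logical length-`K` flag for keypoints with no valid
#'   location (e.g. outside the frame).
#' @return An object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(values, scale = 4, offset = (scale - 1) / 2,
                          missing = NULL) {
  d <- dim(values)
  stopifnot(length(d) == 3)
  if (any(values < 0, na.rm = TRUE)) stop("heatmap values must be nonnegative")
  if (is.null(missing)) missing <- rep(FALSE, d[1])
  structure(list(values = values, scale = scale, offset = offset,
                 missing = missing),
            class = "heatmap_stack")
}

#' Soft argmax of a heatmap with confidence
#'
#' Spatial renormalization of the heatmap to a distribution followed by the
#' spatial expectation, yielding a subpixel location; the confidence is the
#' total normalized mass within `radius` pixels of that location.
#'
#' Two input conventions are supported. Density-scale maps (the package's
#' native convention, produced by [gaussian_heatmap()]; `logits = FALSE`)
#' are renormalized directly (`p = v / sum(v)`), which makes the expectation
#' the exact subpixel inverse of [gaussian_heatmap()] for interior points.
#' Logit-scale maps (raw network outputs; `logits = TRUE`) go through a
#' spatial softmax with temperature `tau` (`p` proportional to
#' `exp(tau * v)`), where a large `tau` (default 1000, the inference
#' setting) suppresses non-global maxima. An all-equal map returns the grid
#' centroid under either convention.
#'
#' @param heatmap Numeric matrix `[h x w]` (rows = y, columns = x);
#'   nonnegative with positive sum when `logits = FALSE`.
#' @param tau Softmax temperature, positive (used when `logits = TRUE`).
#' @param radius Confidence radius in heatmap pixels (default 3).
#' @param logits Input convention; see above (default `FALSE`).
#' @return List with `x`, `y` (0-based subpixel coordinates) and
#'   `confidence` in `[0, 1]`.
#' @export
soft_argmax <- function(heatmap, tau = 1000, radius = 3, logits = FALSE) {
  stopifnot(is.matrix(heatmap), all(is.finite(heatmap)), tau > 0)
  h <- nrow(heatmap); w <- ncol(heatmap)
  if (logits) {
    p <- exp(tau * (heatmap - max(heatmap)))
  } else {
    if (any(heatmap < 0)) stop("density-scale heatmaps must be nonnegative")
    p <- heatmap
    if (sum(p) <= 0) p <- p + 1  # all-zero map: fall back to the centroid
  }
  p <- p / sum(p)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  rows <- matrix(seq_len(h) - 1, h, w)
  x <- sum(p * cols)
  y <- sum(p * rows)
  within <- (cols - x)^2 + (rows - y)^2 <= radius^2
  list(x = x, y = y, confidence = sum(p[within]))
}

#' Generate Gaussian heatmaps for keypoint coordinates
#'
#' Isotropic Gaussian bump of standard deviation `sigma` centered at each
#' keypoint, evaluated on the pixel grid (peak value 1 at the center).
#' Keypoints outside the `[0, w) x [0, h)` grid produce an all-near-zero map
#' and are flagged missing.
#'
#' @param coords Numeric matrix `[K x 2]` of `(x, y)` heatmap-grid
#'   coordinates (may be `NA`, also flagged missing).
#' @param h,w Heatmap height and width.
#' @param sigma Gaussian standard deviation in heatmap pixels (default 1.25).
#' @param ... Passed to [heatmap_stack()] (grid transform).
#' @return A [heatmap_stack()].
#' @export
gaussian_heatmap <- function(coords, h, w, sigma = 1.25, ...) {
  if (sigma <= 0) stop("sigma must be positive")
  coords <- rbind3(coords)
  K <- nrow(coords)
  vals <- array(0, c(K, h, w))
  missing <- rep(FALSE, K)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  rows <- matrix(seq_len(h) - 1, h, w)
  for (k in seq_len(K)) {
    x <- coords[k, 1]; y <- coords[k, 2]
    if (!all(is.finite(c(x, y))) || x < 0 || x >= w || y < 0 || y >= h) {
      missing[k] <- TRUE
      if (!all(is.finite(c(x, y)))) next
    }
    vals[k, , ] <- exp(-((cols - x)^2 + (rows - y)^2) / (2 * sigma^2))
  }
  heatmap_stack(vals, missing = missing, ...)
}

#' Patch-mask curriculum fraction
#'
#' Masking starts after `start_iter` iterations at `start_frac`, increases
#' linearly to `end_frac` at `end_iter`, and stays there. Defaults follow
#' the curriculum of starting at 10% after 700 iterations and reaching 50%
#' by iteration 5000.
#'
#' @param iteration Nonnegative training iteration.
#' @param schedule List with `start_iter`, `start_frac`, `end_iter`,
#'   `end_frac` (defaults 700, 0.10, 5000, 0.50).
#' @return Masking fraction in `[0, 1]`.
#' @export
mask_fraction <- function(iteration,
                          schedule = list(start_iter = 700, start_frac = 0.10,
                                          end_iter = 5000, end_frac = 0.50)) {
  stopifnot(iteration >= 0, schedule$start_iter < schedule$end_iter,
            schedule$start_frac >= 0, schedule$end_frac <= 1)
  if (iteration < schedule$start_iter) return(0)
  if (iteration >= schedule$end_iter) return(schedule$end_frac)
  frac <- (iteration - schedule$start_iter) /
    (schedule$end_iter - schedule$start_iter)
  schedule$start_frac + frac * (schedule$end_frac - schedule$start_frac)
}

#' Sample a contiguous-patch boolean mask
#'
#' Places random rectangular blocks (dimensions uniform over 1..4 patches
#' per side) at uniform positions, accumulating their union until at least
#' `fraction` of the grid is masked. The realized fraction therefore
#' overshoots the target by at most one block area.
#'
#' @param grid_h,grid_w Patch-grid dimensions.
#' @param fraction Target masked fraction in `[0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @param max_block Maximum block side length in patches (default 4).
#' @return Logical matrix `[grid_h x grid_w]`.
#' @export
sample_patch_mask <- function(grid_h, grid_w, fraction, seed = NULL,
                              max_block = 4) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, grid_h, grid_w)
  target <- fraction * grid_h * grid_w
  if (fraction >= 1) return(matrix(TRUE, grid_h, grid_w))
  while (sum(mask) < target) {
    bh <- sample.int(min(max_block, grid_h), 1)
    bw <- sample.int(min(max_block, grid_w), 1)
    r0 <- sample.int(grid_h - bh + 1, 1)
    c0 <- sample.int(grid_w - bw + 1, 1)
    mask[r0:(r0 + bh - 1), c0:(c0 + bw - 1)] <- TRUE
  }
  mask
}

#' Multi-view reprojection loss on heatmaps
#'
#' The geometric-consistency training loss: soft-argmax each predicted
#' heatmap to 2D coordinates, map to image pixels, triangulate across all
#' camera pairs (mean), reproject the 3D points to every view, regenerate
#' Gaussian heatmaps at the reprojected locations, and score the mean
#' squared error against the ground-truth heatmaps scaled by the number of
#' heatmap pixels (`h * w`), averaged over valid keypoints and views.
#' Keypoints flagged missing, or with fewer than two valid views, are
#' excluded.
#'
#' @param pred Per-view list of predicted [heatmap_stack()] objects
#'   (length `V`, each `[K, h, w]`).
#' @param gt Per-view list of ground-truth [heatmap_stack()] objects.
#' @param rig A [camera_rig()].
#' @param tau Soft-argmax temperature (default 1000).
#' @param sigma Gaussian sigma for the reprojected heatmaps; should match
#'   the sigma used for `gt` (default 1.25).
#' @return Scalar loss (0 for geometrically consistent predictions equal to
#'   the ground truth).
#' @export
reprojection_loss <- function(pred, gt, rig, tau = 1000, sigma = 1.25) {
  V <- length(rig$cameras)
  stopifnot(length(pred) == V, length(gt) == V)
  K <- dim(pred[[1]]$values)[1]
  h <- dim(pred[[1]]$values)[2]; w <- dim(pred[[1]]$values)[3]
  # soft-argmax each view in image pixel coordinates
  obs <- array(NA_real_, c(V, K, 2))
  for (v in seq_len(V)) {
    st <- pred[[v]]
    for (k in seq_len(K)) {
      if (st$missing[k] || gt[[v]]$missing[k]) next
      sa <- soft_argmax(st$values[k, , ], tau = tau)
      obs[v, k, ] <- st$scale * c(sa$x, sa$y) + st$offset
    }
  }
  pts <- triangulate_multiview(rig, obs)
  total <- 0
  nterms <- 0L
  for (v in seq_len(V)) {
    proj <- project_points(rig$cameras[[v]], pts)     # image px
    hm_coords <- (proj - gt[[v]]$offset) / gt[[v]]$scale
    reproj <- gaussian_heatmap(hm_coords, h, w, sigma = sigma,
                               scale = gt[[v]]$scale, offset = gt[[v]]$offset)
    for (k in seq_len(K)) {
      if (!is.finite(pts[k, 1]) || gt[[v]]$missing[k]) next
      diff2 <- (reproj$values[k, , ] - gt[[v]]$values[k, , ])^2
      total <- total + mean(diff2) * h * w
      nterms <- nterms + 1L
    }
  }
  if (nterms == 0) return(0)
  total / nterms
}

#' Geometry-consistent 3D augmentation of multi-view labels
#'
#' Triangulates the 2D labels, scales the 3D keypoints about their per-axis
#' median by a single scalar drawn from `U(scale_low, scale_high)`,
#' translates each axis by a draw from `U(shift_low, shift_high)` times that
#' axis' bounding-box width, and reprojects to every view. Per view, a
#' 4-degree-of-freedom similarity transform (scale-rotation + translation)
#' is fit by least squares between the original and augmented 2D labels.
#' Keypoints that cannot be triangulated pass through unchanged and are
#' flagged.
#'
#' @param labels2d Numeric array `[V, K, 2]` of pixel labels.
#' @param rig A [camera_rig()].
#' @param params List with `scale_low`, `scale_high`, `shift_low`,
#'   `shift_high` (defaults 0.8, 1.2, -0.25, 0.25).
#' @param seed Optional integer seed.
#' @return List with `labels2d` (augmented, `[V, K, 2]`), `points3d`
#'   (augmented 3D, `[K x 3]`), `transforms` (per-view `a b tx ty` of the
#'   similarity `[[a, -b], [b, a]] x + t`), `scale`, `shift`, and `flagged`
#'   (untriangulable keypoints).
#' @export
augment_3d <- function(labels2d, rig,
                       params = list(scale_low = 0.8, scale_high = 1.2,
                                     shift_low = -0.25, shift_high = 0.25),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- length(rig$cameras)
  stopifnot(dim(labels2d)[1] == V, dim(labels2d)[3] == 2)
  K <- dim(labels2d)[2]
  pts <- triangulate_multiview(rig, labels2d)
  flagged <- !is.finite(pts[, 1])
  scale <- stats::runif(1, params$scale_low, params$scale_high)
  ok <- !flagged
  med <- apply(pts[ok, , drop = FALSE], 2, stats::median)
  widths <- apply(pts[ok, , drop = FALSE], 2, function(x) diff(range(x)))
  shift <- stats::runif(3, params$shift_low, params$shift_high) * widths
  aug <- pts
  aug[ok, ] <- sweep(sweep(sweep(pts[ok, , drop = FALSE], 2, med), 2,
                           rep(scale, 3), "*"), 2, med + shift, "+")
  out2d <- labels2d
  transforms <- matrix(NA_real_, V, 4,
                       dimnames = list(NULL, c("a", "b", "tx", "ty")))
  for (v in seq_len(V)) {
    proj <- project_points(rig$cameras[[v]], aug)
    out2d[v, ok, ] <- proj[ok, ]
    transforms[v, ] <- fit_similarity(
      matrix(labels2d[v, ok, ], sum(ok), 2), proj[ok, , drop = FALSE])
  }
  list(labels2d = out2d, points3d = aug, transforms = transforms,
       scale = scale, shift = shift, flagged = flagged)
}

#' Fit a 4-DOF similarity transform by least squares
#'
#' Finds `a, b, tx, ty` minimizing `sum || [[a, -b], [b, a]] p + t - q ||^2`
#' (uniform scale + rotation + translation) mapping points `p` to `q`.
#'
#' @param p,q Numeric matrices `[n x 2]` of corresponding points.
#' @return Named numeric vector `(a, b, tx, ty)`.
#' @export
fit_similarity <- function(p, q) {
  ok <- stats::complete.cases(p) & stats::complete.cases(q)
  p <- p[ok, , drop = FALSE]; q <- q[ok, , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(c(a = NA_real_, b = NA_real_, tx = NA_real_, ty = NA_real_))
  # linear system in (a, b, tx, ty)
  A <- rbind(cbind(p[, 1], -p[, 2], 1, 0),
             cbind(p[, 2], p[, 1], 0, 1))
  rhs <- c(q[, 1], q[, 2])
  coef <- stats::lm.fit(A, rhs)$coefficients
  stats::setNames(as.numeric(coef), c("a", "b", "tx", "ty"))
}

#' Apply a fitted similarity transform to points
#'
#' @param transform Vector `(a, b, tx, ty)` from [fit_similarity()].
#' @param p Numeric matrix `[n x 2]`.
#' @return Transformed `[n x 2]` matrix.
#' @export
apply_similarity <- function(transform, p) {
  p <- rbind3(p)
  a <- transform[1]; b <- transform[2]
  cbind(a * p[, 1] - b * p[, 2] + transform[3],
        b * p[, 1] + a * p[, 2] + transform[4], deparse.level = 0)
}
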