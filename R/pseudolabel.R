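# Uncertainty-guided pseudo-label frame selection: a quality filter on the
# posterior predictive variance followed by a diversity filter (k-means in
# 3D pose space), and export of the selected frames as training labels.

#' Per-frame quality score from the smoother posterior
#'
#' The maximum posterior predictive variance across all keypoints, views and
#' coordinates, per frame (lower is better).
#'
#' @param result An `eks_result` from [smooth_all_keypoints()].
#' @return Numeric vector of length `T`.
#' @export
frame_quality_posterior <- function(result) {
  covs <- result$cov                      # [T, V, K, 2, 2]
  d <- dim(covs)
  vars <- array(NA_real_, c(d[1], d[2], d[3], 2))
  vars[, , , 1] <- covs[, , , 1, 1]
  vars[, , , 2] <- covs[, , , 2, 2]
  apply(vars, 1, max, na.rm = TRUE)
}

#' Per-frame quality score from the factor-model predictive variance
#'
#' The predictive covariance of the cross-view factor model,
#' `Q = D + W B W'`, evaluated per frame and keypoint with the (possibly
#' inflated) ensemble variances as `D`; the score is the maximum diagonal
#' entry across keypoints, views and coordinates. This is the default
#' quality signal for pseudo-label filtering.
#'
#' @param obs A [multiview_observations()] (after inflation, if used).
#' @param models Per-keypoint list of lists with `W`, `mu` (linear case), or
#'   `"nonlinear"` with `rig` given.
#' @param rig A [camera_rig()] for the nonlinear case.
#' @return Numeric vector of length `T`.
#' @export
frame_quality_factor <- function(obs, models, rig = NULL) {
  dims <- dim(obs$coords)
  T_ <- dims[1]; V <- dims[2]; K <- dims[3]
  nonlinear <- identical(models, "nonlinear")
  if (nonlinear && is.null(rig)) stop("nonlinear quality scoring requires a rig")
  out <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    worst <- -Inf
    for (k in seq_len(K)) {
      x <- numeric(2 * V); D <- numeric(2 * V)
      for (v in seq_len(V)) {
        rows <- c(2 * v - 1, 2 * v)
        x[rows] <- obs$coords[t, v, k, ]
        D[rows] <- obs$variance[t, v, k, ]
        if (!obs$validity[t, v, k] || !all(is.finite(D[rows])))
          D[rows] <- BIG_VARIANCE
      }
      D <- pmax(D, 1e-12)
      if (nonlinear) {
        Wmu <- linearized_factor_loading(rig, x, D)
        if (is.null(Wmu)) next
        W <- Wmu$W; mu <- Wmu$mu
      } else {
        W <- models[[k]]$W
      }
      A <- crossprod(W / D, W)
      ok <- tryCatch(rcond(A) > 1e-12, error = function(e) FALSE)
      if (!ok) next
      B <- solve(A)
      qdiag <- D + rowSums((W %*% B) * W)
      worst <- max(worst, qdiag)
    }
    if (is.finite(worst)) out[t] <- worst
  }
  out
}

#' Quality filter: retain the lowest-variance frames
#'
#' Frames are ranked by their quality score (ascending; ties broken by frame
#' index, earlier first) and the lowest `floor(keep_fraction * N)` retained.
#'
#' @param sigma2_max Numeric vector of per-frame scores (e.g. from
#'   [frame_quality_factor()]).
#' @param keep_fraction Fraction of frames to keep, in `(0, 1]`
#'   (default 0.6).
#' @return Integer vector of kept frame indices (1-based, ascending).
#' @export
quality_filter <- function(sigma2_max, keep_fraction = 0.6) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  n <- length(sigma2_max)
  if (n == 0) return(integer(0))
  n_keep <- floor(keep_fraction * n)
  ord <- order(sigma2_max, seq_len(n))
  sort(ord[seq_len(n_keep)])
}

#' Diversity filter: representative frames by k-means in pose space
#'
#' Builds a pose vector per kept frame — concatenated triangulated 3D
#' keypoint coordinates when a rig is available, otherwise per-keypoint PCA
#' scores of the stacked 2D observations — clusters with k-means, and keeps
#' the frame closest to each cluster centroid. Keypoints that cannot be
#' triangulated in a frame are imputed with the per-frame centroid of the
#' valid keypoints (and flagged).
#'
#' @param kept Integer vector of frame indices (from [quality_filter()]).
#' @param coords Numeric array `[T, V, K, 2]` of 2D predictions.
#' @param rig Optional [camera_rig()].
#' @param k Number of clusters (default 3000); lowered to the number of
#'   kept frames when larger.
#' @param seed Integer seed for the k-means initialization.
#' @param latent_dim PCA dimension per keypoint for the rig-free pose space
#'   (default 3).
#' @param nstart k-means restarts (default 10).
#' @return An object of class `selection_result`: `kept_after_quality`,
#'   `selected` (frame indices, ascending), `cluster` (cluster id per
#'   selected frame), `pose_space` (pose matrix over kept frames),
#'   `imputed` (logical, frames with imputed keypoints).
#' @export
diversity_select <- function(kept, coords, rig = NULL, k = 3000, seed = 1,
                             latent_dim = 3, nstart = 10) {
  stopifnot(length(dim(coords)) == 4)
  K <- dim(coords)[3]
  if (length(kept) == 0) stop("no frames to select from")
  k_eff <- min(k, length(kept))
  imputed <- rep(FALSE, length(kept))
  if (!is.null(rig)) {
    pose <- matrix(NA_real_, length(kept), 3 * K)
    for (i in seq_along(kept)) {
      t <- kept[i]
      obs <- array(coords[t, , , , drop = FALSE], dim(coords)[2:4])
      pts <- triangulate_multiview(rig, obs)
      bad <- !is.finite(pts[, 1])
      if (any(bad)) {
        if (all(bad)) stop(sprintf("frame %d: no triangulable keypoints", t))
        centroid <- colMeans(pts[!bad, , drop = FALSE])
        pts[bad, ] <- matrix(centroid, sum(bad), 3, byrow = TRUE)
        imputed[i] <- TRUE
      }
      pose[i, ] <- as.numeric(t(pts))
    }
  } else {
    V <- dim(coords)[2]
    pose <- matrix(NA_real_, length(kept), latent_dim * K)
    for (kk in seq_len(K)) {
      X <- matrix(NA_real_, length(kept), 2 * V)
      for (v in seq_len(V)) {
        X[, 2 * v - 1] <- coords[kept, v, kk, 1]
        X[, 2 * v] <- coords[kept, v, kk, 2]
      }
      mu <- colMeans(X, na.rm = TRUE)
      Xc <- sweep(X, 2, mu)
      Xc[!is.finite(Xc)] <- 0
      sv <- svd(Xc, nu = 0, nv = latent_dim)
      pose[, (kk - 1) * latent_dim + seq_len(latent_dim)] <- Xc %*% sv$v
    }
  }
  set.seed(seed)
  if (k_eff >= nrow(pose)) {
    cl <- list(cluster = seq_len(nrow(pose)), centers = pose)
  } else {
    cl <- stats::kmeans(pose, centers = k_eff, nstart = nstart,
                        iter.max = 100)
  }
  sel_idx <- vapply(seq_len(max(cl$cluster)), function(j) {
    members <- which(cl$cluster == j)
    dists <- rowSums((pose[members, , drop = FALSE] -
                        matrix(cl$centers[j, ], length(members),
                               ncol(pose), byrow = TRUE))^2)
    members[which.min(dists)]
  }, integer(1))
  ord <- order(kept[sel_idx])
  structure(list(kept_after_quality = kept,
                 selected = kept[sel_idx][ord],
                 cluster = seq_len(max(cl$cluster))[ord],
                 pose_space = pose,
                 imputed = imputed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d kept after quality filter, %d selected\n",
              length(x$kept_after_quality), length(x$selected)))
  invisible(x)
}

#' Export selected frames as pseudo-label files
#'
#' Writes one label CSV per view in the training-label dialect (scorer /
#' bodyparts / coords header, `x` and `y` columns per keypoint), one row per
#' selected frame, with coordinates taken from the smoothed per-view
#' posterior means.
#'
#' @param selection A [diversity_select()] result (or any list with a
#'   `selected` integer vector).
#' @param result An `eks_result` from [smooth_all_keypoints()].
#' @param dir Output directory (created if missing).
#' @param scorer Scorer name written in the header (default `"mveks"`).
#' @return Named character vector of written file paths, invisibly.
#' @export
export_pseudolabels <- function(selection, result, dir, scorer = "mveks") {
  frames <- selection$selected
  if (length(frames) == 0) stop("selection is empty")
  T_ <- dim(result$means)[1]
  if (any(frames < 1 | frames > T_))
    stop("selected frame index outside prediction range")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  V <- dim(result$means)[2]
  paths <- character(V)
  for (v in seq_len(V)) {
    co <- result$means[frames, v, , , drop = FALSE]
    coords <- array(co, c(length(frames), dim(result$means)[3], 2))
    path <- file.path(dir, sprintf("labels_%s.csv", result$views[v]))
    write_labels_csv(path, coords, keypoints = result$keypoints,
                     frames = frames - 1L, scorer = scorer)
    paths[v] <- path
  }
  names(paths) <- result$views
  invisible(paths)
}
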