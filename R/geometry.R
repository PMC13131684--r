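#' Camera model with radial and tangential distortion
#'
#' A standard pinhole camera augmented with the five-coefficient
#' Brown-Conrady distortion model. Extrinsics are stored as an axis-angle
#' rotation (world-to-camera) and a translation, so a world point `X` maps to
#' camera coordinates `R X + t` before perspective division, distortion and
#' the intrinsic map.
#'
#' Pixel coordinate convention: `x` is the column (width) axis, `y` the row
#' (height) axis, origin at the top-left corner, continuous subpixel values at
#' pixel centers.
#'
#' @param name Text label, unique within a rig.
#' @param focal Length-2 numeric `(fx, fy)` in pixels, both positive.
#' @param principal Length-2 numeric `(cx, cy)` in pixels.
#' @param distortion Length-5 numeric `(k1, k2, p1, p2, k3)`, dimensionless.
#' @param rotation Axis-angle 3-vector (radians); the rotation axis scaled by
#'   the rotation angle.
#' @param translation 3-vector, world units.
#' @param size Optional length-2 integer `(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @seealso [camera_rig()], [project_points()], [undistort_points()]
#' @export
camera_model <- function(name, focal, principal,
                         distortion = c(0, 0, 0, 0, 0),
                         rotation = c(0, 0, 0),
                         translation = c(0, 0, 0),
                         size = NULL) {
  stopifnot(length(focal) == 2, length(principal) == 2,
            length(distortion) == 5, length(rotation) == 3,
            length(translation) == 3)
  if (!all(is.finite(c(focal, principal, distortion, rotation, translation))))
    stop("camera parameters must be finite")
  if (focal[1] <= 0 || focal[2] <= 0)
    stop("focal lengths must be positive")
  cam <- structure(list(
    name = as.character(name),
    focal = as.numeric(focal),
    principal = as.numeric(principal),
    distortion = as.numeric(distortion),
    rotation = as.numeric(rotation),
    translation = as.numeric(translation),
    size = if (!is.null(size)) as.numeric(size) else NULL
  ), class = "camera_model")
  R <- rotation_matrix(cam$rotation)
  if (abs(det(R) - 1) > 1e-8 || max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation does not convert to a proper orthogonal matrix")
  cam
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'> f=(%.6g, %.6g) c=(%.6g, %.6g)\n",
              x$name, x$focal[1], x$focal[2], x$principal[1], x$principal[2]))
  cat(sprintf("  distortion (k1 k2 p1 p2 k3): %s\n",
              paste(signif(x$distortion, 4), collapse = " ")))
  invisible(x)
}

#' Ordered collection of calibrated cameras
#'
#' @param cameras List of [camera_model()] objects, at least two, with unique
#'   names. The view order of the rig is the order of this list and is fixed.
#' @return An object of class `camera_rig`.
#' @export
camera_rig <- function(cameras) {
  if (length(cameras) < 2) stop("a rig needs at least 2 cameras")
  if (!all(vapply(cameras, inherits, logical(1), "camera_model")))
    stop("all elements must be camera_model objects")
  nms <- vapply(cameras, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("camera names must be unique")
  structure(list(cameras = cameras, names = nms), class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig> %d views: %s\n", length(x$cameras),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' @export
length.camera_rig <- function(x) length(x$cameras)

#' Axis-angle to rotation matrix (Rodrigues formula)
#'
#' @param axis_angle 3-vector; direction is the rotation axis, norm the angle
#'   in radians.
#' @return 3x3 proper orthogonal matrix.
#' @export
rotation_matrix <- function(axis_angle) {
  theta <- sqrt(sum(axis_angle^2))
  if (theta < 1e-12) return(diag(3))
  k <- axis_angle / theta
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)  # column-major: K %*% v == k x v
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation matrix to axis-angle
#'
#' Inverse of [rotation_matrix()]; the returned axis-angle has angle in
#' `[0, pi]`.
#'
#' @param R 3x3 rotation matrix.
#' @return Axis-angle 3-vector.
#' @export
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cos_t <- (tr - 1) / 2
  cos_t <- min(1, max(-1, cos_t))
  theta <- acos(cos_t)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta > pi - 1e-6) {
    # near-pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    # fix signs using off-diagonals
    i <- which.max(k)
    if (i == 1) { k[2] <- A[1, 2] / k[1]; k[3] <- A[1, 3] / k[1] }
    if (i == 2) { k[1] <- A[1, 2] / k[2]; k[3] <- A[2, 3] / k[2] }
    if (i == 3) { k[1] <- A[1, 3] / k[3]; k[2] <- A[2, 3] / k[3] }
    k <- k / sqrt(sum(k^2))
    return(k * theta)
  }
  k <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  k * theta
}

# Apply the Brown-Conrady distortion to normalized coordinates (n x 2).
distort_normalized <- function(xy, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Project 3D world points into a camera
#'
#' Applies the extrinsic transform, perspective division, radial and
#' tangential distortion, then the intrinsic map. Points at or behind the
#' camera plane (camera-frame depth `z <= 0`) are flagged invalid (returned as
#' `NA`), not raised as errors.
#'
#' @param camera A [camera_model()].
#' @param points Numeric matrix `K x 3` of world coordinates (a vector of
#'   length 3 is accepted for a single point). `NA` rows propagate.
#' @return Numeric matrix `K x 2` of pixel coordinates; rows are `NA` for
#'   invalid points.
#' @export
project_points <- function(camera, points) {
  points <- rbind3(points)
  R <- rotation_matrix(camera$rotation)
  Xc <- points %*% t(R) + rep(camera$translation, each = nrow(points))
  out <- matrix(NA_real_, nrow(points), 2)
  ok <- is.finite(Xc[, 3]) & Xc[, 3] > 0 &
    is.finite(Xc[, 1]) & is.finite(Xc[, 2])
  if (any(ok)) {
    xy <- cbind(Xc[ok, 1] / Xc[ok, 3], Xc[ok, 2] / Xc[ok, 3])
    xyd <- distort_normalized(xy, camera$distortion)
    out[ok, 1] <- camera$focal[1] * xyd[, 1] + camera$principal[1]
    out[ok, 2] <- camera$focal[2] * xyd[, 2] + camera$principal[2]
  }
  out
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = length(points))
  storage.mode(points) <- "double"
  points
}

#' Undistort pixel coordinates to ideal normalized coordinates
#'
#' Inverts the intrinsic map and then the distortion map by fixed-point
#' iteration (at most `max_iter` iterations, convergence tolerance `tol` in
#' normalized units). For moderate distortion the round trip
#' `distort(undistort(p))` reproduces `p` to well under 1e-6 pixels.
#'
#' @param camera A [camera_model()].
#' @param pixels Numeric matrix `K x 2` of pixel coordinates.
#' @param max_iter Maximum fixed-point iterations (default 20).
#' @param tol Convergence tolerance in normalized image units (default 1e-8).
#' @return Numeric matrix `K x 2` of normalized ideal coordinates; rows that
#'   fail to converge are `NA`.
#' @export
undistort_points <- function(camera, pixels, max_iter = 20, tol = 1e-8) {
  pixels <- rbind3(pixels)
  x0 <- (pixels[, 1] - camera$principal[1]) / camera$focal[1]
  y0 <- (pixels[, 2] - camera$principal[2]) / camera$focal[2]
  dist <- camera$distortion
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  x <- x0; y <- y0
  converged <- rep(FALSE, length(x))
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
    dy <- p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
    xn <- (x0 - dx) / rad
    yn <- (y0 - dy) / rad
    step <- pmax(abs(xn - x), abs(yn - y))
    x <- xn; y <- yn
    converged <- is.finite(step) & step < tol
    if (all(converged, na.rm = TRUE)) break
  }
  out <- cbind(x, y, deparse.level = 0)
  bad <- !converged | !is.finite(x) | !is.finite(y)
  bad[is.na(bad)] <- TRUE
  out[bad, ] <- NA_real_
  out
}

# Projection matrix [R | t] with identity intrinsics (normalized coords).
normalized_projection_matrix <- function(camera) {
  cbind(rotation_matrix(camera$rotation), camera$translation)
}

#' Triangulate keypoints from a pair of calibrated views (DLT)
#'
#' Observations are first undistorted to normalized coordinates; the
#' homogeneous direct linear transform system (two rows per view, identity
#' intrinsics) is then solved by the smallest right singular vector and
#' dehomogenized. Degenerate geometry (coincident or parallel rays, e.g. the
#' same camera used twice) yields an invalid (`NA`) entry.
#'
#' @param camA,camB [camera_model()] objects.
#' @param ptsA,ptsB Numeric matrices `K x 2` of pixel observations.
#' @return Numeric matrix `K x 3` of world coordinates; invalid rows are `NA`.
#' @export
triangulate_pair <- function(camA, camB, ptsA, ptsB) {
  ptsA <- rbind3(ptsA); ptsB <- rbind3(ptsB)
  stopifnot(nrow(ptsA) == nrow(ptsB))
  nA <- undistort_points(camA, ptsA)
  nB <- undistort_points(camB, ptsB)
  PA <- normalized_projection_matrix(camA)
  PB <- normalized_projection_matrix(camB)
  out <- matrix(NA_real_, nrow(ptsA), 3)
  for (k in seq_len(nrow(ptsA))) {
    if (!all(is.finite(c(nA[k, ], nB[k, ])))) next
    A <- rbind(
      nA[k, 1] * PA[3, ] - PA[1, ],
      nA[k, 2] * PA[3, ] - PA[2, ],
      nB[k, 1] * PB[3, ] - PB[1, ],
      nB[k, 2] * PB[3, ] - PB[2, ]
    )
    sv <- svd(A)
    # rank deficiency beyond the expected 1-dim nullspace => degenerate rays
    if (sv$d[3] < 1e-9 * max(sv$d[1], 1e-300)) next
    X <- sv$v[, 4]
    if (abs(X[4]) < 1e-12 * sqrt(sum(X[1:3]^2))) next
    out[k, ] <- X[1:3] / X[4]
  }
  out
}

#' Triangulate keypoints from all views of a rig
#'
#' Computes the unweighted mean of [triangulate_pair()] over all valid
#' unordered view pairs; a keypoint needs at least two valid views, otherwise
#' its entry is invalid (`NA`).
#'
#' @param rig A [camera_rig()].
#' @param obs Numeric array `V x K x 2` of pixel observations (`NA` marks an
#'   invalid observation).
#' @return Numeric matrix `K x 3`; invalid rows are `NA`.
#' @export
triangulate_multiview <- function(rig, obs) {
  V <- length(rig$cameras)
  stopifnot(length(dim(obs)) == 3, dim(obs)[1] == V, dim(obs)[3] == 2)
  K <- dim(obs)[2]
  acc <- matrix(0, K, 3)
  cnt <- matrix(0L, K, 3)
  for (a in seq_len(V - 1)) {
    for (b in seq((a + 1), V)) {
      ptsA <- matrix(obs[a, , ], K, 2)
      ptsB <- matrix(obs[b, , ], K, 2)
      tri <- triangulate_pair(rig$cameras[[a]], rig$cameras[[b]], ptsA, ptsB)
      ok <- is.finite(tri[, 1])
      acc[ok, ] <- acc[ok, , drop = FALSE] + tri[ok, , drop = FALSE]
      cnt[ok, ] <- cnt[ok, , drop = FALSE] + 1L
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Reprojection error of 3D points against multi-view observations
#'
#' Euclidean pixel distance between each observation and the projection of
#' the corresponding 3D point, per view, plus means over valid views.
#'
#' @param rig A [camera_rig()].
#' @param obs Numeric array `V x K x 2` of pixel observations.
#' @param points Numeric matrix `K x 3` of world points (`NA` rows excluded).
#' @return List with `per_view` (`V x K` matrix of pixel distances),
#'   `keypoint_mean` (length-`K` mean over valid views) and `mean` (overall
#'   mean over valid entries).
#' @export
reprojection_error <- function(rig, obs, points) {
  V <- length(rig$cameras)
  points <- rbind3(points)
  K <- nrow(points)
  stopifnot(length(dim(obs)) == 3, dim(obs)[1] == V, dim(obs)[2] == K)
  per_view <- matrix(NA_real_, V, K)
  for (v in seq_len(V)) {
    proj <- project_points(rig$cameras[[v]], points)
    d <- sqrt((obs[v, , 1] - proj[, 1])^2 + (obs[v, , 2] - proj[, 2])^2)
    per_view[v, ] <- d
  }
  keypoint_mean <- colMeans(per_view, na.rm = TRUE)
  keypoint_mean[!is.finite(keypoint_mean)] <- NA_real_
  overall <- mean(per_view, na.rm = TRUE)
  list(per_view = per_view, keypoint_mean = keypoint_mean, mean = overall)
}
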