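#' Container for multi-member, multi-view keypoint predictions
#'
#' @param coords Numeric array `[M, T, V, K, 2]`: ensemble members x frames x
#'   views x keypoints x (x, y) pixel coordinates. `NA`/`NaN` marks a missing
#'   prediction.
#' @param likelihood Optional numeric array `[M, T, V, K]` of per-prediction
#'   confidences in `[0, 1]`.
#' @param keypoints Optional character vector of keypoint names (length `K`).
#' @param views Optional character vector of view names (length `V`).
#' @return An object of class `ensemble_predictions`.
#' @export
ensemble_predictions <- function(coords, likelihood = NULL,
                                 keypoints = NULL, views = NULL) {
  d <- dim(coords)
  if (length(d) != 5 || d[5] != 2)
    stop("coords must be an [M, T, V, K, 2] array")
  if (d[1] < 2)
    stop("at least 2 ensemble members are required (variance undefined for M < 2)")
  if (!is.null(likelihood) && !all(dim(likelihood) == d[1:4]))
    stop("likelihood must be an [M, T, V, K] array matching coords")
  if (is.null(keypoints)) keypoints <- paste0("kp", seq_len(d[4]))
  if (is.null(views)) views <- paste0("view", seq_len(d[3]))
  stopifnot(length(keypoints) == d[4], length(views) == d[3])
  structure(list(coords = coords, likelihood = likelihood,
                 keypoints = keypoints, views = views),
            class = "ensemble_predictions")
}

#' @export
print.ensemble_predictions <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<ensemble_predictions> M=%d members, T=%d frames, V=%d views, K=%d keypoints\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Container for aggregated multi-view observations
#'
#' The smoother input: per-frame, per-view, per-keypoint 2D coordinates
#' (stacked per keypoint into the observation vector) with diagonal
#' observation variances from the ensemble spread.
#'
#' @param coords Numeric array `[T, V, K, 2]` pixels.
#' @param variance Numeric array `[T, V, K, 2]` pixels^2, nonnegative.
#' @param validity Logical array `[T, V, K]`; invalid entries are excluded
#'   from all downstream likelihoods (given effectively infinite variance).
#' @param keypoints,views Optional name vectors.
#' @return An object of class `multiview_observations`.
#' @export
multiview_observations <- function(coords, variance, validity,
                                   keypoints = NULL, views = NULL) {
  d <- dim(coords)
  if (length(d) != 4 || d[4] != 2) stop("coords must be [T, V, K, 2]")
  stopifnot(all(dim(variance) == d), all(dim(validity) == d[1:3]))
  if (any(variance < 0, na.rm = TRUE)) stop("variance must be nonnegative")
  if (is.null(keypoints)) keypoints <- paste0("kp", seq_len(d[3]))
  if (is.null(views)) views <- paste0("view", seq_len(d[2]))
  structure(list(coords = coords, variance = variance, validity = validity,
                 keypoints = keypoints, views = views),
            class = "multiview_observations")
}

#' @export
print.multiview_observations <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<multiview_observations> T=%d frames, V=%d views, K=%d keypoints (%.1f%% valid)\n",
              d[1], d[2], d[3], 100 * mean(x$validity)))
  invisible(x)
}

#' Aggregate an ensemble into smoother observations
#'
#' Computes the coordinate-wise median (the observation) and the
#' coordinate-wise variance (the diagonal observation noise) across ensemble
#' members. Members with missing (`NA`) predictions are dropped per entry; an
#' entry with fewer than 2 finite members is marked invalid. For an even
#' number of members the median is the midpoint of the two central values.
#'
#' @param preds An [ensemble_predictions()].
#' @param ddof Delta degrees of freedom for the variance denominator
#'   (`M - ddof`); 1 (default) gives the unbiased sample variance, 0 the
#'   population variance.
#' @return A [multiview_observations()].
#' @export
aggregate_ensemble <- function(preds, ddof = 1) {
  stopifnot(inherits(preds, "ensemble_predictions"), ddof %in% c(0, 1))
  co <- preds$coords
  d <- dim(co)
  M <- d[1]
  # collapse to M x (T*V*K*2) for columnwise stats
  flat <- matrix(co, nrow = M)
  fin <- is.finite(flat)
  nfin <- colSums(fin)
  med <- numeric(ncol(flat))
  vr <- numeric(ncol(flat))
  complete <- nfin == M
  if (any(complete)) {
    sub <- flat[, complete, drop = FALSE]
    med[complete] <- apply(sub, 2, stats::median)
    mu <- colMeans(sub)
    vr[complete] <- colSums((sub - rep(mu, each = M))^2) / (M - ddof)
  }
  partial <- which(!complete)
  for (j in partial) {
    x <- flat[fin[, j], j]
    if (length(x) >= 2) {
      med[j] <- stats::median(x)
      vr[j] <- sum((x - mean(x))^2) / (length(x) - ddof)
    } else {
      med[j] <- NA_real_
      vr[j] <- NA_real_
    }
  }
  coords <- array(med, d[2:5])
  variance <- array(vr, d[2:5])
  nfin_arr <- array(nfin, d[2:5])
  validity <- array(nfin_arr[, , , 1, drop = FALSE] >= 2 &
                      nfin_arr[, , , 2, drop = FALSE] >= 2, d[2:4])
  if (ddof == 1 && M < 2) stop("sample variance needs at least 2 members")
  multiview_observations(coords, variance, validity,
                         keypoints = preds$keypoints, views = preds$views)
}
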