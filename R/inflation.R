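# Cross-view inconsistency detection and variance inflation.
#
# The stacked 2V-dimensional observation of one keypoint at one frame is
# modeled with a factor-analysis observation model x ~ N(W z + mu, D) with
# diagonal D from the ensemble variance and an uninformative prior on the
# latent z, giving posterior matrix B = (W' D^-1 W)^-1. For each view the
# leave-one-out posterior predictive (from the remaining views only) yields
# a Mahalanobis distance — a multivariate z-score for how consistent that
# view's prediction is with the rest of the rig. Views whose distance
# exceeds a threshold have their observation variance multiplied by a fixed
# factor until consistency (or an iteration cap) is reached.

#' Factor-analysis observation model for one frame of one keypoint
#'
#' @param W Loading matrix `[2V x d]`.
#' @param mu Offset vector, length `2V`.
#' @param D Diagonal observation variances, length `2V`, positive.
#' @return An object of class `factor_model`.
#' @export
factor_model <- function(W, mu, D) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == length(mu), length(D) == length(mu), all(D > 0))
  structure(list(W = W, mu = as.numeric(mu), D = as.numeric(D),
                 V = nrow(W) / 2, d = ncol(W)),
            class = "factor_model")
}

# B = (W' D^-1 W)^-1 restricted to rows `rows`; NULL when rank-deficient.
loo_posterior_matrix <- function(model, rows) {
  Wr <- model$W[rows, , drop = FALSE]
  Dr <- model$D[rows]
  A <- crossprod(Wr / Dr, Wr)
  if (nrow(Wr) < model$d) return(NULL)
  ok <- tryCatch(rcond(A) > 1e-12, error = function(e) FALSE)
  if (!ok) return(NULL)
  solve(A)
}

#' Leave-one-out posterior predictive for one view
#'
#' Conditions the factor model on all views except `v` (uninformative latent
#' prior) and returns the predictive mean and covariance for view `v`:
#' `x'_v = W_v mu_{z|x_-v} + mu_v` and `Q_v = D_v + W_v B W_v'`, with `B`
#' computed from the remaining views.
#'
#' @param x Stacked observation vector, length `2V`.
#' @param model A [factor_model()].
#' @param v View index.
#' @return List with `mean` (length 2), `cov` (`2 x 2`), or `NULL` when the
#'   leave-one-out system is rank-deficient (view skipped).
#' @export
loo_predictive <- function(x, model, v) {
  rows_v <- c(2 * v - 1, 2 * v)
  rows_rest <- setdiff(seq_along(model$mu), rows_v)
  keep <- rows_rest[is.finite(x[rows_rest]) & model$D[rows_rest] > 0]
  B <- loo_posterior_matrix(model, keep)
  if (is.null(B)) return(NULL)
  Wr <- model$W[keep, , drop = FALSE]
  Dr <- model$D[keep]
  mu_z <- as.numeric(B %*% crossprod(Wr / Dr, x[keep] - model$mu[keep]))
  Wv <- model$W[rows_v, , drop = FALSE]
  list(mean = as.numeric(Wv %*% mu_z + model$mu[rows_v]),
       cov = diag(model$D[rows_v], 2) + Wv %*% B %*% t(Wv))
}

#' Cross-view Mahalanobis inconsistency score for one view
#'
#' Square root of the quadratic form
#' `(x_v - x'_v)' Q_v^-1 (x_v - x'_v)` where `x'_v`, `Q_v` come from the
#' leave-one-out posterior predictive — the multivariate analogue of a
#' z-score for view `v`'s agreement with the remaining views.
#'
#' @inheritParams loo_predictive
#' @return Nonnegative scalar; 0 when the leave-one-out system is
#'   rank-deficient (view skipped).
#' @export
mahalanobis_view <- function(x, model, v) {
  pred <- loo_predictive(x, model, v)
  if (is.null(pred)) return(0)
  r <- x[c(2 * v - 1, 2 * v)] - pred$mean
  if (!all(is.finite(r))) return(0)
  Q <- pred$cov
  ch <- tryCatch(chol(Q), error = function(e) {
    Q2 <- (Q + t(Q)) / 2
    diag(Q2) <- diag(Q2) + 1e-10 * max(diag(Q2))
    chol(Q2)
  })
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  sqrt(max(0, sum(r * alpha)))
}

# One frame/keypoint inflation loop: repeatedly inflate the currently most
# inconsistent view (one x10 multiplication per round) until every view
# falls below the threshold or the per-view cap is hit. Targeting the worst
# view first isolates the actual outlier: once the inconsistent view is
# down-weighted, the distances of the views it was contaminating collapse
# without those views ever being inflated. With exactly two views the
# outlier cannot be identified, so both views are inflated together.
inflate_frame <- function(x, W, mu, D, threshold, factor, max_rounds) {
  V <- length(mu) / 2
  n_infl <- integer(V)
  unresolved <- logical(V)
  dist <- numeric(V)
  compute_all <- function(D) {
    m <- factor_model(W, mu, pmax(D, 1e-12))
    vapply(seq_len(V), function(v) mahalanobis_view(x, m, v), numeric(1))
  }
  two_view <- V == 2
  repeat {
    dist <- compute_all(D)
    if (two_view) {
      if (any(dist >= threshold)) {
        if (all(n_infl < max_rounds)) {
          D <- D * factor          # inflate both views
          n_infl <- n_infl + 1L
          next
        }
        unresolved <- dist >= threshold
      }
      break
    }
    flag <- which(dist >= threshold & n_infl < max_rounds)
    if (length(flag) == 0) {
      unresolved <- dist >= threshold
      break
    }
    v <- flag[which.max(dist[flag])]
    rows <- c(2 * v - 1, 2 * v)
    D[rows] <- D[rows] * factor
    n_infl[v] <- n_infl[v] + 1L
  }
  list(D = D, n_inflations = n_infl, distances = dist,
       unresolved = unresolved)
}

#' Iterative cross-view variance inflation
#'
#' Sweeps all frames and keypoints; for each, any view whose leave-one-out
#' Mahalanobis distance is at or above `threshold` has its two diagonal
#' observation-variance entries multiplied by `factor`, distances are
#' recomputed, and the process repeats until all views fall below the
#' threshold or a per-view round cap is hit. With exactly two views the
#' inconsistent view cannot be identified, so both views are inflated
#' together. Inflating a view's variance leaves its leave-one-out prediction
#' unchanged and grows its predictive covariance, so the distance decreases
#' monotonically and the sweep terminates.
#'
#' @param obs A [multiview_observations()].
#' @param models Per-keypoint observation models: either a list of `K`
#'   [factor_model()]-style lists with `W` (`2V x d`) and `mu` (static, the
#'   linear/PCA case), or `"nonlinear"` with `rig` supplied, in which case
#'   the loading is the per-frame Jacobian linearization of the camera
#'   projection about the triangulated estimate.
#' @param rig A [camera_rig()]; required for `models = "nonlinear"`.
#' @param threshold Mahalanobis distance threshold (default 5).
#' @param factor Variance multiplication factor per round (default 10).
#' @param max_rounds Per-view cap on inflation rounds (default 25).
#' @return List with `observations` (a [multiview_observations()] with
#'   inflated variances) and `report` (an `inflation_report`: data frame of
#'   inflated entries, final distance array `[T, V, K]`, unresolved flags,
#'   per-keypoint inflation fractions).
#' @export
inflate_variance <- function(obs, models, rig = NULL, threshold = 5,
                             factor = 10, max_rounds = 25) {
  stopifnot(inherits(obs, "multiview_observations"))
  dims <- dim(obs$coords)
  T_ <- dims[1]; V <- dims[2]; K <- dims[3]
  nonlinear <- identical(models, "nonlinear")
  if (nonlinear && is.null(rig))
    stop("models = 'nonlinear' requires a camera rig")
  variance <- obs$variance
  final_dist <- array(0, c(T_, V, K))
  recs <- list()
  unresolved_any <- array(FALSE, c(T_, V, K))
  for (k in seq_len(K)) {
    ko <- keypoint_observations(obs, k)
    for (t in seq_len(T_)) {
      x <- ko$y[t, ]
      D <- ko$vars[t, ]
      valid_views <- which(is.finite(x[seq(1, 2 * V, 2)]) &
                             is.finite(x[seq(2, 2 * V, 2)]))
      if (length(valid_views) < 2) next
      if (nonlinear) {
        Wmu <- linearized_factor_loading(rig, x, D)
        if (is.null(Wmu)) next
        W <- Wmu$W; mu <- Wmu$mu
      } else {
        W <- models[[k]]$W; mu <- models[[k]]$mu
      }
      res <- inflate_frame(x, W, mu, D, threshold, factor, max_rounds)
      final_dist[t, , k] <- res$distances
      unresolved_any[t, , k] <- res$unresolved
      infl <- which(res$n_inflations > 0)
      for (v in infl) {
        variance[t, v, k, ] <- variance[t, v, k, ] * factor^res$n_inflations[v]
        recs[[length(recs) + 1]] <-
          data.frame(frame = t, view = v, keypoint = k,
                     n_inflations = res$n_inflations[v])
      }
    }
  }
  inflated <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(0), view = integer(0), keypoint = integer(0),
               n_inflations = integer(0))
  frac <- vapply(seq_len(K), function(k) {
    sum(inflated$keypoint == k) / (T_ * V)
  }, numeric(1))
  report <- structure(list(
    inflated = inflated,
    final_distances = final_dist,
    unresolved = unresolved_any,
    total_inflation_fraction = frac,
    threshold = threshold, factor = factor, max_rounds = max_rounds
  ), class = "inflation_report")
  obs2 <- obs
  obs2$variance <- variance
  list(observations = obs2, report = report)
}

# Per-frame affine linearization of the camera projections about the
# triangulated estimate: W = stacked Jacobians, mu = h(z0) - W z0.
linearized_factor_loading <- function(rig, x, D) {
  V <- length(rig$cameras)
  obs <- array(NA_real_, c(V, 1, 2))
  for (v in seq_len(V)) obs[v, 1, ] <- x[c(2 * v - 1, 2 * v)]
  z0 <- triangulate_multiview(rig, obs)[1, ]
  if (!all(is.finite(z0))) return(NULL)
  W <- matrix(0, 2 * V, 3)
  mu <- numeric(2 * V)
  for (v in seq_len(V)) {
    pj <- project_with_jacobian(rig$cameras[[v]], z0)
    rows <- c(2 * v - 1, 2 * v)
    if (!pj$valid) return(NULL)
    W[rows, ] <- pj$J
    mu[rows] <- pj$uv - as.numeric(pj$J %*% z0)
  }
  list(W = W, mu = mu)
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("<inflation_report> %d inflated entries; max final distance %.3f; %d unresolved\n",
              nrow(x$inflated), max(x$final_distances), sum(x$unresolved)))
  invisible(x)
}
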