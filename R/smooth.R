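#' Smooth all keypoints of a multi-view observation set
#'
#' Runs the multi-view Ensemble Kalman smoother independently for every
#' keypoint (results do not depend on execution order), optionally preceded
#' by cross-view variance inflation. In `"linear"` mode the observation
#' model is the PCA subspace estimated by [init_linear()]; in `"nonlinear"`
#' mode the camera rig projects a 3D latent directly ([extended_kalman_smooth()]).
#' The smoothing scalar is optimized per keypoint by marginal likelihood
#' unless a fixed value is given.
#'
#' @param obs A [multiview_observations()].
#' @param mode `"linear"` or `"nonlinear"`.
#' @param rig A [camera_rig()]; required for nonlinear mode.
#' @param latent_dim Latent dimension for linear mode (default 3).
#' @param s `"auto"` (optimize per keypoint) or a fixed positive scalar.
#' @param inflate Logical: run [inflate_variance()] before smoothing.
#' @param inflate_threshold,inflate_factor,inflate_max_rounds Inflation
#'   settings (defaults 5, 10, 25).
#' @param low_var_quantile Passed to [init_linear()].
#' @return An object of class `eks_result`: `means` (`[T, V, K, 2]` smoothed
#'   per-view coordinates), `cov` (`[T, V, K, 2, 2]` posterior predictive
#'   covariance blocks), `latents` (per-keypoint smoothed latent
#'   trajectories), `s` and `loglik` per keypoint, `mode`, and
#'   `inflation_report` (or `NULL`).
#' @export
smooth_all_keypoints <- function(obs, mode = c("linear", "nonlinear"),
                                 rig = NULL, latent_dim = 3, s = "auto",
                                 inflate = FALSE, inflate_threshold = 5,
                                 inflate_factor = 10, inflate_max_rounds = 25,
                                 low_var_quantile = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(obs, "multiview_observations"))
  if (mode == "nonlinear" && is.null(rig))
    stop("nonlinear mode requires camera calibration (rig); use mode = 'linear' without calibration")
  dims <- dim(obs$coords)
  T_ <- dims[1]; V <- dims[2]; K <- dims[3]
  auto_s <- identical(s, "auto")
  if (!auto_s) stopifnot(is.numeric(s), s > 0)

  # per-keypoint linear models are needed for linear smoothing and for
  # linear-mode inflation
  lin_models <- NULL
  if (mode == "linear" || (inflate && is.null(rig))) {
    lin_models <- lapply(seq_len(K), function(k) {
      ko <- keypoint_observations(obs, k)
      init_linear(ko$y, ko$vars, d = latent_dim,
                  low_var_quantile = low_var_quantile,
                  keypoint = obs$keypoints[k])
    })
  }

  inflation_report <- NULL
  if (inflate) {
    models <- if (!is.null(rig)) "nonlinear" else
      lapply(lin_models, function(m) list(W = m$model$W, mu = m$model$mu))
    inf <- inflate_variance(obs, models, rig = rig,
                            threshold = inflate_threshold,
                            factor = inflate_factor,
                            max_rounds = inflate_max_rounds)
    obs <- inf$observations
    inflation_report <- inf$report
  }

  means <- array(NA_real_, c(T_, V, K, 2))
  covs <- array(NA_real_, c(T_, V, K, 2, 2))
  latents <- vector("list", K)
  s_out <- numeric(K)
  ll_out <- numeric(K)
  for (k in seq_len(K)) {
    ko <- keypoint_observations(obs, k)
    if (mode == "linear") {
      ini <- lin_models[[k]]
      dyn <- ini$dyn
      if (auto_s) {
        opt <- optimize_smoothing(ko$y, ko$vars, ini$model, dyn)
        dyn$s <- opt$s
      } else dyn$s <- s
      fit <- kalman_smooth(ko$y, ko$vars, ini$model, dyn)
    } else {
      nlm <- nonlinear_observation_model(rig)
      ini <- init_nonlinear(ko$y, ko$vars, rig)
      dyn <- ini$dyn
      if (auto_s) {
        opt <- optimize_smoothing_nonlinear(ko$y, ko$vars, nlm, dyn,
                                            init = ini$init)
        dyn$s <- opt$s
      } else dyn$s <- s
      fit <- extended_kalman_smooth(ko$y, ko$vars, nlm, dyn, init = ini$init)
    }
    means[, , k, ] <- fit$output$means
    covs[, , k, , ] <- fit$output$cov
    latents[[k]] <- fit$latent
    s_out[k] <- dyn$s
    ll_out[k] <- fit$latent$loglik
  }
  structure(list(means = means, cov = covs, latents = latents,
                 s = stats::setNames(s_out, obs$keypoints),
                 loglik = stats::setNames(ll_out, obs$keypoints),
                 mode = mode, keypoints = obs$keypoints, views = obs$views,
                 inflation_report = inflation_report),
            class = "eks_result")
}

#' @export
print.eks_result <- function(x, ...) {
  d <- dim(x$means)
  cat(sprintf("<eks_result> mode=%s, T=%d frames, V=%d views, K=%d keypoints\n",
              x$mode, d[1], d[2], d[3]))
  cat("  s per keypoint:", paste(signif(x$s, 4), collapse = ", "), "\n")
  if (!is.null(x$inflation_report))
    cat(sprintf("  inflation: %d entries inflated\n", nrow(x$inflation_report$inflated)))
  invisible(x)
}
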