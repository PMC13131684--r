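# Linear multi-view Ensemble Kalman filter-smoother.
#
# Model, per keypoint:
#   z_t | z_{t-1} ~ N(z_{t-1}, s E)          (latent random walk)
#   x_t | z_t     ~ N(W z_t + mu_x, D_t)     (stacked per-view observations)
# with x_t the (x1, y1, ..., xV, yV) stack and D_t diagonal from the
# ensemble variance. Invalid observations enter with variance BIG_VARIANCE
# so the recursions stay shape-stable.

BIG_VARIANCE <- 1e12

#' Linear observation model for the multi-view smoother
#'
#' @param W Loading matrix `[2V x d]`, full column rank.
#' @param mu Offset vector, length `2V` (pixels).
#' @return An object of class `linear_observation_model`.
#' @export
linear_observation_model <- function(W, mu) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == length(mu))
  if (qr(W)$rank < ncol(W)) stop("loading matrix W must have full column rank")
  structure(list(W = W, mu = as.numeric(mu), d = ncol(W)),
            class = "linear_observation_model")
}

#' Latent dynamics model
#'
#' @param E Process covariance `[d x d]`, symmetric positive semidefinite.
#' @param s Positive smoothing scalar; scales `E` in the latent random walk.
#'   Small `s` smooths strongly, large `s` tracks the observations.
#' @return An object of class `dynamics_model`.
#' @export
dynamics_model <- function(E, s = 1) {
  E <- as.matrix(E)
  stopifnot(nrow(E) == ncol(E), s > 0)
  if (max(abs(E - t(E))) > 1e-8 * max(abs(E), 1e-300))
    stop("E must be symmetric")
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300)) stop("E must be PSD")
  structure(list(E = (E + t(E)) / 2, s = as.numeric(s)),
            class = "dynamics_model")
}

# Extract the stacked observation matrix [T x 2V] and variances for one
# keypoint from a multiview_observations object.
keypoint_observations <- function(obs, k) {
  d <- dim(obs$coords)
  T_ <- d[1]; V <- d[2]
  y <- matrix(NA_real_, T_, 2 * V)
  vr <- matrix(BIG_VARIANCE, T_, 2 * V)
  for (v in seq_len(V)) {
    y[, 2 * v - 1] <- obs$coords[, v, k, 1]
    y[, 2 * v] <- obs$coords[, v, k, 2]
    vv <- cbind(obs$variance[, v, k, 1], obs$variance[, v, k, 2])
    ok <- obs$validity[, v, k] & is.finite(vv[, 1]) & is.finite(vv[, 2])
    vr[ok, 2 * v - 1] <- vv[ok, 1]
    vr[ok, 2 * v] <- vv[ok, 2]
    y[!ok, c(2 * v - 1, 2 * v)] <- NA_real_
  }
  list(y = y, vars = vr)
}

#' Initialize the linear smoother from ensemble observations
#'
#' Frames whose maximum ensemble variance (across views and coordinates) lies
#' below the `low_var_quantile` quantile are used to estimate the loading and
#' offset by principal component analysis: `mu` is the mean of the selected
#' observations and `W` holds the top-`d` principal directions scaled by the
#' corresponding singular values (so latent coordinates are approximately
#' unit-variance). The process covariance `E` is the covariance of the first
#' differences of the PCA projections, and the initial smoothing scalar is
#' the mean (over latent dimensions) of the standard deviations of those
#' differences.
#'
#' @param y Observation matrix `[T x 2V]` for one keypoint (`NA` = invalid).
#' @param vars Variance matrix `[T x 2V]`.
#' @param d Latent dimension (default 3: a 3D latent space).
#' @param low_var_quantile Quantile of per-frame maximum ensemble variance
#'   below which frames are used for the PCA fit (default 0.5).
#' @param keypoint Name used in error messages.
#' @return List with `model` ([linear_observation_model()]), `dyn`
#'   ([dynamics_model()] with the initial `s`), and `info` (selected frames,
#'   PCA variance fractions).
#' @export
init_linear <- function(y, vars, d = 3, low_var_quantile = 0.5,
                        keypoint = "keypoint") {
  complete <- rowSums(!is.finite(y)) == 0
  if (sum(complete) < 10)
    stop(sprintf("%s: need at least 10 fully observed frames", keypoint))
  maxvar <- apply(vars, 1, max)
  thr <- stats::quantile(maxvar[complete], low_var_quantile, names = FALSE)
  sel <- complete & maxvar <= thr
  if (sum(sel) < max(d + 1, 3)) sel <- complete
  X <- y[sel, , drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  sdev <- sv$d / sqrt(max(1, nrow(X) - 1))
  if (sum(sv$d > max(sv$d[1], 1e-300) * 1e-10) < d)
    stop(sprintf("%s: observations have rank < %d after filtering", keypoint, d))
  Vd <- sv$v[, seq_len(d), drop = FALSE]
  W <- Vd %*% diag(sdev[seq_len(d)], d)
  # project all complete frames; first differences between adjacent frames
  proj <- sweep(y[complete, , drop = FALSE], 2, mu) %*% Vd %*%
    diag(1 / sdev[seq_len(d)], d)
  idx <- which(complete)
  adjacent <- which(diff(idx) == 1)
  dif <- proj[adjacent + 1, , drop = FALSE] - proj[adjacent, , drop = FALSE]
  if (nrow(dif) < 2)
    stop(sprintf("%s: not enough adjacent frames to estimate dynamics", keypoint))
  E <- stats::cov(dif)
  # guard against degenerate (near-singular) process covariance
  eps <- 1e-10 * mean(diag(E))
  if (eps > 0) E <- E + diag(eps, d)
  s_init <- mean(apply(dif, 2, stats::sd))
  if (!is.finite(s_init) || s_init <= 0) s_init <- 1
  list(model = linear_observation_model(W, mu),
       dyn = dynamics_model(E, s_init),
       info = list(selected = which(sel),
                   var_explained = cumsum(sdev^2) / sum(sdev^2)))
}

# Forward Kalman filter. Returns filtered and predicted moments plus the
# marginal log-likelihood accumulated from the innovations.
kalman_filter <- function(y, vars, W, mu, E, s, m0, P0) {
  T_ <- nrow(y); n <- ncol(y); d <- ncol(W)
  Wt <- t(W)
  Q <- s * E
  mf <- matrix(0, T_, d)
  Pf <- array(0, c(d, d, T_))
  mp <- matrix(0, T_, d)
  Pp <- array(0, c(d, d, T_))
  loglik <- 0
  jitter_events <- 0L
  m <- m0
  P <- P0
  y_ <- y
  miss <- !is.finite(y_)
  if (any(miss)) {
    mu_mat <- matrix(mu, T_, n, byrow = TRUE)
    y_[miss] <- mu_mat[miss]
    vars[miss] <- BIG_VARIANCE
  }
  const <- -0.5 * n * log(2 * pi)
  for (t in seq_len(T_)) {
    if (t > 1) P <- P + Q
    mp[t, ] <- m
    Pp[, , t] <- P
    Dv <- vars[t, ]
    WP <- W %*% P                      # n x d
    S <- WP %*% Wt
    diag(S) <- diag(S) + Dv
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      jitter_events <- jitter_events + 1L
      S <- (S + t(S)) / 2
      diag(S) <- diag(S) + 1e-8 * max(diag(S))
      ch <- chol(S)
    }
    innov <- y_[t, ] - as.numeric(W %*% m) - mu
    alpha <- backsolve(ch, forwardsolve(t(ch), innov))
    loglik <- loglik + const - sum(log(diag(ch))) - 0.5 * sum(innov * alpha)
    # K = P W' S^-1 ; compute via solves against chol
    KT <- backsolve(ch, forwardsolve(t(ch), WP))   # n x d = S^-1 W P
    K <- t(KT)                                     # d x n
    m <- m + as.numeric(K %*% innov)
    P <- P - K %*% WP
    P <- (P + t(P)) / 2
    mf[t, ] <- m
    Pf[, , t] <- P
  }
  list(mf = mf, Pf = Pf, mp = mp, Pp = Pp, loglik = loglik,
       jitter_events = jitter_events)
}

# Rauch-Tung-Striebel smoother for the identity-dynamics random walk.
rts_smoother <- function(fl) {
  T_ <- nrow(fl$mf); d <- ncol(fl$mf)
  ms <- fl$mf
  Ps <- fl$Pf
  if (T_ > 1) {
    for (t in seq(T_ - 1, 1)) {
      Pp1 <- fl$Pp[, , t + 1]
      G <- t(solve(Pp1, fl$Pf[, , t]))   # Pf[t] %*% solve(Pp1), symmetric-safe
      ms[t, ] <- fl$mf[t, ] + as.numeric(G %*% (ms[t + 1, ] - fl$mp[t + 1, ]))
      P <- fl$Pf[, , t] + G %*% (Ps[, , t + 1] - Pp1) %*% t(G)
      Ps[, , t] <- (P + t(P)) / 2
    }
  }
  list(means = ms, covs = Ps)
}

# GLS estimate of the latent from a single stacked observation.
gls_latent <- function(x, vars, W, mu) {
  ok <- is.finite(x)
  Wv <- W[ok, , drop = FALSE]
  A <- crossprod(Wv / vars[ok], Wv)
  b <- crossprod(Wv / vars[ok], x[ok] - mu[ok])
  as.numeric(solve(A, b))
}

#' Run the linear multi-view Kalman smoother for one keypoint
#'
#' Forward Kalman filter followed by a Rauch-Tung-Striebel smoothing pass
#' under the random-walk latent model. The marginal log-likelihood is
#' accumulated from the filter innovations. Per-view outputs are obtained by
#' mapping the smoothed latents through the observation model, with posterior
#' predictive covariance `W_v S_t W_v' + D_{v,t}` per view.
#'
#' @param y Observation matrix `[T x 2V]` (`NA` = invalid; such entries are
#'   given effectively infinite variance).
#' @param vars Variance matrix `[T x 2V]`.
#' @param model A [linear_observation_model()].
#' @param dyn A [dynamics_model()].
#' @param init Optional list with `mean` (length `d`) and `cov` (`d x d`) for
#'   the first-frame state prior; by default the mean is the generalized
#'   least squares estimate from the first fully valid frame and the
#'   covariance `10 E`.
#' @return List of class `eks_fit` with `latent` (smoothed means `[T x d]`,
#'   covariances `[d x d x T]`, `loglik`), `output` (per-view means
#'   `[T, V, 2]` and predictive covariance blocks `[T, V, 2, 2]`), and
#'   `jitter_events`.
#' @export
kalman_smooth <- function(y, vars, model, dyn, init = NULL) {
  stopifnot(inherits(model, "linear_observation_model"),
            inherits(dyn, "dynamics_model"))
  vars <- pmax(vars, 1e-12)
  if (is.null(init)) {
    t1 <- which(rowSums(is.finite(y)) > 0)[1]
    if (is.na(t1)) stop("no valid observations")
    m0 <- tryCatch(gls_latent(y[t1, ], vars[t1, ], model$W, model$mu),
                   error = function(e) rep(0, model$d))
    P0 <- 10 * dyn$E
  } else {
    m0 <- init$mean
    P0 <- as.matrix(init$cov)
  }
  fl <- kalman_filter(y, vars, model$W, model$mu, dyn$E, dyn$s, m0, P0)
  sm <- rts_smoother(fl)
  out <- project_posterior(sm$means, sm$covs, model, vars)
  structure(list(
    latent = list(means = sm$means, covs = sm$covs, loglik = fl$loglik),
    output = out,
    jitter_events = fl$jitter_events
  ), class = "eks_fit")
}

# Map smoothed latents to per-view means and 2x2 predictive covariances.
project_posterior <- function(means, covs, model, vars) {
  T_ <- nrow(means)
  V <- nrow(model$W) / 2
  mu_out <- array(NA_real_, c(T_, V, 2))
  cov_out <- array(NA_real_, c(T_, V, 2, 2))
  fitted <- means %*% t(model$W) +
    matrix(model$mu, T_, length(model$mu), byrow = TRUE)
  for (v in seq_len(V)) {
    rows <- c(2 * v - 1, 2 * v)
    Wv <- model$W[rows, , drop = FALSE]
    mu_out[, v, ] <- fitted[, rows]
    for (t in seq_len(T_)) {
      Cv <- Wv %*% covs[, , t] %*% t(Wv)
      Dv <- vars[t, rows]
      Dv[!is.finite(Dv) | Dv >= BIG_VARIANCE] <- BIG_VARIANCE
      cov_out[t, v, , ] <- Cv + diag(Dv, 2)
    }
  }
  list(means = mu_out, cov = cov_out)
}

# Marginal log-likelihood as a function of log s (shared by the optimizer).
loglik_log_s <- function(log_s, y, vars, model, dyn, init = NULL) {
  dyn2 <- dyn
  dyn2$s <- exp(log_s)
  if (is.null(init)) {
    t1 <- which(rowSums(is.finite(y)) > 0)[1]
    m0 <- tryCatch(gls_latent(y[t1, ], vars[t1, ], model$W, model$mu),
                   error = function(e) rep(0, model$d))
    init <- list(mean = m0, cov = 10 * dyn$E)
  }
  fl <- kalman_filter(y, pmax(vars, 1e-12), model$W, model$mu, dyn2$E, dyn2$s,
                      init$mean, as.matrix(init$cov))
  fl$loglik
}

#' Optimize the smoothing scalar by marginal likelihood
#'
#' Maximizes the Kalman-filter marginal log-likelihood over `log s` by
#' gradient ascent (central-difference gradient, learning rate 0.25).
#' Steps producing a non-finite or decreased likelihood are rejected and the
#' step size halved. Iteration stops after `max_iter` steps or when the
#' accepted change in `log s` falls below `tol`.
#'
#' @param y,vars Observations and variances for one keypoint (`[T x 2V]`).
#' @param model A [linear_observation_model()].
#' @param dyn A [dynamics_model()]; its `s` is the starting value.
#' @param lr Learning rate on `log s` (default 0.25).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on `|delta log s|` (default 1e-4).
#' @param max_step Cap on a single step in `log s` (default 1).
#' @return List with `s` (the optimum), `loglik` at the optimum, `loglik0` at
#'   the start, and `iterations`. Always satisfies `loglik >= loglik0`.
#' @export
optimize_smoothing <- function(y, vars, model, dyn, lr = 0.25,
                               max_iter = 100, tol = 1e-4, max_step = 1) {
  f <- function(ls) loglik_log_s(ls, y, vars, model, dyn)
  res <- ascend_log_s(f, log(dyn$s), lr = lr, max_iter = max_iter,
                      tol = tol, max_step = max_step)
  list(s = exp(res$log_s), loglik = res$value, loglik0 = res$value0,
       iterations = res$iterations)
}

# Shared 1-D gradient-ascent core over log s.
ascend_log_s <- function(f, log_s0, lr = 0.25, max_iter = 100, tol = 1e-4,
                         max_step = 1, h = 1e-3) {
  ls <- log_s0
  fval <- f(ls)
  if (!is.finite(fval)) stop("initial smoothing value gives non-finite likelihood")
  f0 <- fval
  step_scale <- 1
  iterations <- 0
  for (i in seq_len(max_iter)) {
    iterations <- i
    gp <- f(ls + h); gm <- f(ls - h)
    if (!is.finite(gp) || !is.finite(gm)) { step_scale <- step_scale / 2; next }
    g <- (gp - gm) / (2 * h)
    step <- step_scale * lr * g
    step <- max(-max_step, min(max_step, step))
    accepted <- FALSE
    for (halve in 1:12) {
      cand <- ls + step
      fc <- f(cand)
      if (is.finite(fc) && fc >= fval - 1e-10) {
        ls <- cand; fval <- fc; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    if (abs(step) < tol) break
  }
  list(log_s = ls, value = fval, value0 = f0, iterations = iterations)
}
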