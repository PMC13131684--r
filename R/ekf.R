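# Nonlinear multi-view Ensemble Kalman filter-smoother.
#
# The latent state is the 3D world position of the keypoint; each view
# observes it through the full camera model (extrinsics, perspective
# division, radial/tangential distortion, intrinsics). An extended Kalman
# filter linearizes the projection per frame; smoothing reuses the
# Rauch-Tung-Striebel pass with the stored linearizations.

#' Project a 3D point and compute the analytic projection Jacobian
#'
#' @param camera A [camera_model()].
#' @param point Length-3 world coordinates.
#' @return List with `uv` (pixel coordinates), `J` (`2 x 3` Jacobian with
#'   respect to the world point) and `valid` (`FALSE` when the point is at or
#'   behind the camera plane, in which case `uv`/`J` are `NA`).
#' @export
project_with_jacobian <- function(camera, point) {
  R <- rotation_matrix(camera$rotation)
  Xc <- as.numeric(R %*% point + camera$translation)
  if (!all(is.finite(Xc)) || Xc[3] <= 0) {
    return(list(uv = c(NA_real_, NA_real_), J = matrix(NA_real_, 2, 3),
                valid = FALSE))
  }
  z <- Xc[3]
  x <- Xc[1] / z; y <- Xc[2] / z
  dist <- camera$distortion
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  g <- 2 * (k1 + 2 * k2 * r2 + 3 * k3 * r2^2)
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  u <- camera$focal[1] * xd + camera$principal[1]
  v <- camera$focal[2] * yd + camera$principal[2]
  # d(xd, yd) / d(x, y)
  dxd_dx <- rad + g * x^2 + 2 * p1 * y + 6 * p2 * x
  dxd_dy <- g * x * y + 2 * p1 * x + 2 * p2 * y
  dyd_dx <- g * x * y + 2 * p1 * x + 2 * p2 * y
  dyd_dy <- rad + g * y^2 + 6 * p1 * y + 2 * p2 * x
  A <- rbind(c(camera$focal[1] * dxd_dx, camera$focal[1] * dxd_dy),
             c(camera$focal[2] * dyd_dx, camera$focal[2] * dyd_dy))
  # d(x, y) / d(Xc)
  B <- rbind(c(1 / z, 0, -Xc[1] / z^2),
             c(0, 1 / z, -Xc[2] / z^2))
  J <- A %*% B %*% R
  list(uv = c(u, v), J = J, valid = TRUE)
}

#' Nonlinear observation model: a camera rig plus per-frame noise
#'
#' @param rig A [camera_rig()].
#' @return An object of class `nonlinear_observation_model`.
#' @export
nonlinear_observation_model <- function(rig) {
  stopifnot(inherits(rig, "camera_rig"))
  structure(list(rig = rig, V = length(rig$cameras)),
            class = "nonlinear_observation_model")
}

#' Initialize the nonlinear smoother from triangulated observations
#'
#' Triangulates the per-frame median observations, estimates the process
#' covariance from the first differences of the triangulated trajectory, and
#' initializes the state prior at the first triangulable frame.
#'
#' @param y Observation matrix `[T x 2V]` for one keypoint.
#' @param vars Variance matrix `[T x 2V]`.
#' @param rig A [camera_rig()].
#' @return List with `dyn` ([dynamics_model()]), `init` (state prior), and
#'   `traj` (the triangulated trajectory, `[T x 3]`, `NA` where fewer than
#'   two views are valid).
#' @export
init_nonlinear <- function(y, vars, rig) {
  V <- length(rig$cameras)
  T_ <- nrow(y)
  traj <- matrix(NA_real_, T_, 3)
  for (t in seq_len(T_)) {
    obs <- array(NA_real_, c(V, 1, 2))
    for (v in seq_len(V)) obs[v, 1, ] <- y[t, c(2 * v - 1, 2 * v)]
    nvalid <- sum(is.finite(obs[, 1, 1]) & is.finite(obs[, 1, 2]))
    if (nvalid >= 2) traj[t, ] <- triangulate_multiview(rig, obs)[1, ]
  }
  ok <- which(is.finite(traj[, 1]))
  if (length(ok) < 3) stop("too few triangulable frames to initialize dynamics")
  adjacent <- ok[which(diff(ok) == 1)]
  dif <- traj[adjacent + 1, , drop = FALSE] - traj[adjacent, , drop = FALSE]
  E <- stats::cov(dif)
  E <- E + diag(1e-10 * max(mean(diag(E)), 1e-12), 3)
  s_init <- mean(apply(dif, 2, stats::sd))
  if (!is.finite(s_init) || s_init <= 0) s_init <- 1
  list(dyn = dynamics_model(E, s_init),
       init = list(mean = traj[ok[1], ], cov = 10 * E),
       traj = traj)
}

# Extended Kalman filter for the camera-projection observation model.
# Views whose linearization point falls behind the camera are dropped for
# that frame (variance -> BIG_VARIANCE, zero Jacobian).
ekf_filter <- function(y, vars, rig, E, s, m0, P0) {
  V <- length(rig$cameras)
  T_ <- nrow(y); n <- 2 * V
  Q <- s * E
  mf <- matrix(0, T_, 3)
  Pf <- array(0, c(3, 3, T_))
  mp <- matrix(0, T_, 3)
  Pp <- array(0, c(3, 3, T_))
  Hs <- array(0, c(n, 3, T_))       # stored linearizations for the smoother
  loglik <- 0
  dropped <- 0L
  m <- m0
  P <- P0
  for (t in seq_len(T_)) {
    if (t > 1) P <- P + Q
    mp[t, ] <- m
    Pp[, , t] <- P
    H <- matrix(0, n, 3)
    h <- numeric(n)
    Dv <- vars[t, ]
    yt <- y[t, ]
    for (v in seq_len(V)) {
      rows <- c(2 * v - 1, 2 * v)
      pj <- project_with_jacobian(rig$cameras[[v]], m)
      obs_ok <- all(is.finite(yt[rows]))
      if (pj$valid && obs_ok) {
        H[rows, ] <- pj$J
        h[rows] <- pj$uv
      } else {
        if (obs_ok && !pj$valid) dropped <- dropped + 1L
        h[rows] <- 0
        yt[rows] <- 0                 # zero innovation
        Dv[rows] <- BIG_VARIANCE
      }
      bad <- !is.finite(Dv[rows])
      Dv[rows][bad] <- BIG_VARIANCE
    }
    HP <- H %*% P
    S <- HP %*% t(H)
    diag(S) <- diag(S) + Dv
    ch <- tryCatch(chol(S), error = function(e) {
      S2 <- (S + t(S)) / 2
      diag(S2) <- diag(S2) + 1e-8 * max(diag(S2))
      chol(S2)
    })
    innov <- yt - h
    alpha <- backsolve(ch, forwardsolve(t(ch), innov))
    loglik <- loglik - 0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * sum(innov * alpha)
    KT <- backsolve(ch, forwardsolve(t(ch), HP))
    K <- t(KT)
    m <- m + as.numeric(K %*% innov)
    P <- P - K %*% HP
    P <- (P + t(P)) / 2
    mf[t, ] <- m
    Pf[, , t] <- P
    Hs[, , t] <- H
  }
  list(mf = mf, Pf = Pf, mp = mp, Pp = Pp, loglik = loglik,
       dropped_views = dropped, Hs = Hs)
}

#' Run the nonlinear multi-view Kalman smoother for one keypoint
#'
#' Extended Kalman filter with the analytic projection Jacobian, followed by
#' Rauch-Tung-Striebel smoothing with the stored linearizations. The latent
#' is the 3D world position of the keypoint; by default the initial state is
#' triangulated from the first valid frame.
#'
#' @param y Observation matrix `[T x 2V]` (stacked `(x1, y1, ..., xV, yV)`).
#' @param vars Variance matrix `[T x 2V]`.
#' @param model A [nonlinear_observation_model()].
#' @param dyn A [dynamics_model()] with a 3x3 process covariance.
#' @param init Optional state prior (list `mean`, `cov`); defaults to the
#'   [init_nonlinear()] triangulation-based prior.
#' @return List of class `eks_fit`: `latent` (smoothed 3D means `[T x 3]`,
#'   covariances, `loglik`), `output` (per-view reprojected means `[T, V, 2]`
#'   and linearized predictive covariances `[T, V, 2, 2]`), and
#'   `dropped_views` (count of view-frames behind a camera).
#' @export
extended_kalman_smooth <- function(y, vars, model, dyn, init = NULL) {
  stopifnot(inherits(model, "nonlinear_observation_model"),
            inherits(dyn, "dynamics_model"), nrow(dyn$E) == 3)
  rig <- model$rig
  vars <- pmax(vars, 1e-12)
  if (is.null(init)) init <- init_nonlinear(y, vars, rig)$init
  fl <- ekf_filter(y, vars, rig, dyn$E, dyn$s, init$mean, as.matrix(init$cov))
  sm <- rts_smoother(fl)
  V <- length(rig$cameras)
  T_ <- nrow(y)
  mu_out <- array(NA_real_, c(T_, V, 2))
  cov_out <- array(NA_real_, c(T_, V, 2, 2))
  for (t in seq_len(T_)) {
    for (v in seq_len(V)) {
      pj <- project_with_jacobian(rig$cameras[[v]], sm$means[t, ])
      if (!pj$valid) next
      rows <- c(2 * v - 1, 2 * v)
      Dv <- vars[t, rows]
      Dv[!is.finite(Dv) | Dv >= BIG_VARIANCE] <- BIG_VARIANCE
      mu_out[t, v, ] <- pj$uv
      cov_out[t, v, , ] <- pj$J %*% sm$covs[, , t] %*% t(pj$J) + diag(Dv, 2)
    }
  }
  structure(list(
    latent = list(means = sm$means, covs = sm$covs, loglik = fl$loglik),
    output = list(means = mu_out, cov = cov_out),
    dropped_views = fl$dropped_views
  ), class = "eks_fit")
}

#' Optimize the smoothing scalar for the nonlinear smoother
#'
#' Same gradient-ascent procedure as [optimize_smoothing()], with the
#' extended-Kalman-filter marginal log-likelihood as the objective.
#'
#' @inheritParams optimize_smoothing
#' @param model A [nonlinear_observation_model()].
#' @param init State prior passed to the filter (kept fixed during the
#'   search); defaults to the triangulation-based prior.
#' @return List with `s`, `loglik`, `loglik0`, `iterations`.
#' @export
optimize_smoothing_nonlinear <- function(y, vars, model, dyn, init = NULL,
                                         lr = 0.25, max_iter = 100,
                                         tol = 1e-4, max_step = 1) {
  rig <- model$rig
  vars <- pmax(vars, 1e-12)
  if (is.null(init)) init <- init_nonlinear(y, vars, rig)$init
  f <- function(ls) {
    ekf_filter(y, vars, rig, dyn$E, exp(ls), init$mean,
               as.matrix(init$cov))$loglik
  }
  res <- ascend_log_s(f, log(dyn$s), lr = lr, max_iter = max_iter,
                      tol = tol, max_step = max_step)
  list(s = exp(res$log_s), loglik = res$value, loglik0 = res$value0,
       iterations = res$iterations)
}
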