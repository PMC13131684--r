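# Shared fixtures, all generated in code.

# A camera with nonzero distortion and a generic pose.
random_camera <- function(seed = 1, distortion = TRUE) {
  set.seed(seed)
  camera_model(
    name = sprintf("rc%d", seed),
    focal = runif(2, 800, 1200),
    principal = runif(2, 180, 220),
    distortion = if (distortion)
      c(runif(1, -0.3, 0.3), runif(1, -0.1, 0.1),
        runif(1, -0.01, 0.01), runif(1, -0.01, 0.01), runif(1, -0.05, 0.05))
    else rep(0, 5),
    rotation = runif(3, -0.5, 0.5),
    translation = c(runif(2, -0.3, 0.3), runif(1, 2.5, 3.5))
  )
}

# True affine observation model of a (near-affine) rig, linearized at the
# world origin: W = stacked Jacobians, mu = projections of the origin.
true_affine_model <- function(rig) {
  V <- length(rig$cameras)
  W <- matrix(0, 2 * V, 3)
  mu <- numeric(2 * V)
  for (v in seq_len(V)) {
    pj <- project_with_jacobian(rig$cameras[[v]], c(0, 0, 0))
    rows <- c(2 * v - 1, 2 * v)
    W[rows, ] <- pj$J
    mu[rows] <- pj$uv
  }
  list(W = W, mu = mu)
}

# Stacked [T x 2V] observations of one keypoint, plus variances.
stacked_obs <- function(obs, k) mveks:::keypoint_observations(obs, k)

# Exact observations from the linear generative model x = W z + mu + noise,
# z a random walk with step covariance s_true * E. Returns everything the
# recovery tests need.
simulate_linear_model <- function(T_, W, mu, E, s_true, sigma, seed) {
  set.seed(seed)
  d <- ncol(W)
  steps <- matrix(rnorm(T_ * d), T_, d) %*% chol(s_true * E)
  steps[1, ] <- 0
  z <- apply(steps, 2, cumsum)
  y <- z %*% t(W) + matrix(mu, T_, nrow(W), byrow = TRUE) +
    matrix(rnorm(T_ * nrow(W), sd = sigma), T_, nrow(W))
  list(y = y, vars = matrix(sigma^2, T_, nrow(W)), z = z)
}

# Dense joint-Gaussian posterior/likelihood for the random-walk model; the
# brute-force oracle for the Kalman recursions.
dense_gaussian_oracle <- function(y, vars, W, mu, E, s, m0, P0) {
  T_ <- nrow(y); n <- ncol(y); d <- ncol(W)
  Sz <- matrix(0, d * T_, d * T_)
  mz <- rep(m0, T_)
  for (t1 in seq_len(T_)) for (t2 in seq_len(T_)) {
    tm <- min(t1, t2)
    Sz[((t1 - 1) * d + 1):(t1 * d), ((t2 - 1) * d + 1):(t2 * d)] <-
      P0 + (tm - 1) * s * E
  }
  H <- matrix(0, n * T_, d * T_)
  muy <- rep(mu, T_)
  for (t in seq_len(T_)) {
    H[((t - 1) * n + 1):(t * n), ((t - 1) * d + 1):(t * d)] <- W
  }
  R <- diag(as.numeric(t(vars)))
  yv <- as.numeric(t(y))
  Syy <- H %*% Sz %*% t(H) + R
  Szy <- Sz %*% t(H)
  resid <- yv - H %*% mz - muy
  post_mean <- mz + Szy %*% solve(Syy, resid)
  post_cov <- Sz - Szy %*% solve(Syy, t(Szy))
  ll <- -0.5 * (n * T_ * log(2 * pi) +
                  as.numeric(determinant(Syy)$modulus) +
                  as.numeric(t(resid) %*% solve(Syy, resid)))
  means <- matrix(post_mean, T_, d, byrow = TRUE)
  covs <- array(0, c(d, d, T_))
  for (t in seq_len(T_)) {
    idx <- ((t - 1) * d + 1):(t * d)
    covs[, , t] <- post_cov[idx, idx]
  }
  list(means = means, covs = covs, loglik = ll)
}

expect_psd <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev), 1))
}
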