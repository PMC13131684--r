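# Helper: a generic factor model and a consistent observation on its
# manifold.
fm_instance <- function(seed = 1, V = 3, d = 3) {
  set.seed(seed)
  W <- matrix(rnorm(2 * V * d), 2 * V, d)
  mu <- rnorm(2 * V, sd = 5)
  D <- runif(2 * V, 0.5, 2)
  z <- rnorm(d)
  x <- as.numeric(W %*% z + mu)
  list(W = W, mu = mu, D = D, z = z, x = x)
}

test_that("consistent observations are predicted exactly, view by view", {
  inst <- fm_instance(seed = 2)
  m <- factor_model(inst$W, inst$mu, inst$D)
  for (v in 1:3) {
    pred <- loo_predictive(inst$x, m, v)
    expect_equal(pred$mean, inst$x[c(2 * v - 1, 2 * v)], tolerance = 1e-8)
    expect_equal(mahalanobis_view(inst$x, m, v), 0, tolerance = 1e-6)
  }
})

test_that("leave-one-out predictive matches the large-prior conditional Gaussian oracle", {
  # oracle: joint Gaussian of x with latent prior N(0, sigma2 I),
  # sigma2 = 1e8 (uninformative limit), conditioned on the other views
  loo_oracle <- function(W, mu, D, x, v, sigma2 = 1e8) {
    S <- sigma2 * W %*% t(W) + diag(D)
    rows_v <- c(2 * v - 1, 2 * v)
    rows_o <- setdiff(seq_along(mu), rows_v)
    Svv <- S[rows_v, rows_v]
    Svo <- S[rows_v, rows_o, drop = FALSE]
    Soo <- S[rows_o, rows_o]
    mean_v <- mu[rows_v] + Svo %*% solve(Soo, x[rows_o] - mu[rows_o])
    cov_v <- Svv - Svo %*% solve(Soo, t(Svo))
    list(mean = as.numeric(mean_v), cov = cov_v)
  }
  for (seed in 1:5) {
    inst <- fm_instance(seed = seed + 10, V = 2, d = 1)
    set.seed(seed)
    x <- inst$x + rnorm(4)
    m <- factor_model(inst$W, inst$mu, inst$D)
    for (v in 1:2) {
      pred <- loo_predictive(x, m, v)
      orc <- loo_oracle(inst$W, inst$mu, inst$D, x, v)
      expect_equal(pred$mean, orc$mean, tolerance = 1e-3)
      expect_equal(pred$cov, orc$cov, tolerance = 1e-3)
    }
  }
  # and a 3-view d=3 instance
  inst <- fm_instance(seed = 30, V = 3, d = 3)
  set.seed(30)
  x <- inst$x + rnorm(6)
  m <- factor_model(inst$W, inst$mu, inst$D)
  for (v in 1:3) {
    pred <- loo_predictive(x, m, v)
    orc <- loo_oracle(inst$W, inst$mu, inst$D, x, v)
    expect_equal(pred$mean, orc$mean, tolerance = 1e-3)
    expect_equal(pred$cov, orc$cov, tolerance = 1e-3)
  }
})

test_that("inflating a view's variance leaves its prediction unchanged and shrinks its distance", {
  inst <- fm_instance(seed = 5)
  x <- inst$x + c(8, -6, rep(0, 4))       # perturb view 1
  m1 <- factor_model(inst$W, inst$mu, inst$D)
  D2 <- inst$D
  D2[1:2] <- D2[1:2] * 10
  m2 <- factor_model(inst$W, inst$mu, D2)
  p1 <- loo_predictive(x, m1, 1)
  p2 <- loo_predictive(x, m2, 1)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
  expect_lt(mahalanobis_view(x, m2, 1), mahalanobis_view(x, m1, 1))
})

test_that("Mahalanobis distance reduces to the Euclidean norm under identity covariance", {
  # construct Q_v = I by using huge other-view precision (B -> 0) and D_v = 1
  set.seed(8)
  W <- matrix(rnorm(12), 6, 2)
  mu <- rep(0, 6)
  D <- c(1, 1, rep(1e-12, 4))
  m <- factor_model(W, mu, D)
  pred <- loo_predictive(rep(0, 6), m, 1)
  x <- rep(0, 6)
  x[1:2] <- pred$mean + c(3, 4)
  # B ~ 0, so Q_1 ~ diag(D_1) = I and the distance is the Euclidean norm
  expect_equal(mahalanobis_view(x, m, 1), 5, tolerance = 1e-4)
})

test_that("Mahalanobis distance matches a direct solve-and-dot evaluation", {
  for (seed in 1:5) {
    inst <- fm_instance(seed = seed + 50)
    set.seed(seed)
    x <- inst$x + rnorm(6, sd = 3)
    m <- factor_model(inst$W, inst$mu, inst$D)
    for (v in 1:3) {
      pred <- loo_predictive(x, m, v)
      r <- x[c(2 * v - 1, 2 * v)] - pred$mean
      expect_equal(mahalanobis_view(x, m, v),
                   sqrt(as.numeric(t(r) %*% solve(pred$cov, r))),
                   tolerance = 1e-10)
    }
  }
})

# A consistent 3-view frame with one displaced, confidently wrong view.
corrupt_frame <- function(displacement = c(30, 0), bad_view = 2,
                          var_good = 4, var_bad = 1e-4, seed = 7) {
  rig <- make_rig(3, arc_deg = 360)
  X <- matrix(c(0.05, -0.02, 0.01), 1, 3)
  x <- numeric(6)
  for (v in 1:3) x[c(2 * v - 1, 2 * v)] <- project_points(rig$cameras[[v]], X)
  D <- rep(var_good, 6)
  rows <- c(2 * bad_view - 1, 2 * bad_view)
  x[rows] <- x[rows] + displacement
  D[rows] <- var_bad
  Wmu <- mveks:::linearized_factor_loading(rig, x, D)
  list(x = x, D = D, W = Wmu$W, mu = Wmu$mu, rig = rig)
}

test_that("consistent confident frames require no inflation", {
  cf <- corrupt_frame(displacement = c(0, 0), var_bad = 4)
  res <- mveks:::inflate_frame(cf$x, cf$W, cf$mu, cf$D, threshold = 5,
                               factor = 10, max_rounds = 25)
  expect_identical(res$n_inflations, integer(3))
  expect_identical(res$D, cf$D)
  expect_true(all(res$distances < 5))
})

test_that("a displaced confident view is singled out and inflated until consistent", {
  cf <- corrupt_frame()
  res <- mveks:::inflate_frame(cf$x, cf$W, cf$mu, cf$D, threshold = 5,
                               factor = 10, max_rounds = 25)
  expect_gt(res$n_inflations[2], 0)
  expect_identical(res$n_inflations[c(1, 3)], c(0L, 0L))
  expect_lt(res$distances[2], 5)
  expect_false(any(res$unresolved))
  # oracle: explicit loop multiplying the bad view by 10 until the
  # closed-form distance drops below 5 (other views untouched)
  D <- cf$D
  n <- 0L
  repeat {
    m <- factor_model(cf$W, cf$mu, D)
    if (mahalanobis_view(cf$x, m, 2) < 5) break
    D[3:4] <- D[3:4] * 10
    n <- n + 1L
  }
  expect_identical(res$n_inflations[2], n)
})

test_that("with two views both variances are inflated the same number of rounds", {
  rig <- make_rig(2, arc_deg = 90)
  X <- matrix(c(0.05, -0.02, 0.01), 1, 3)
  x <- numeric(4)
  for (v in 1:2) x[c(2 * v - 1, 2 * v)] <- project_points(rig$cameras[[v]], X)
  x[3:4] <- x[3:4] + c(25, 0)
  D <- rep(0.01, 4)
  # 2-view case needs d <= 2: project the linearization onto its top-2
  # right singular vectors (a rank-2 loading)
  Wmu <- mveks:::linearized_factor_loading(rig, x, D)
  sv <- svd(Wmu$W)
  W2 <- Wmu$W %*% sv$v[, 1:2]
  res <- mveks:::inflate_frame(x, W2, Wmu$mu, D, threshold = 5,
                               factor = 10, max_rounds = 25)
  expect_gt(res$n_inflations[1], 0)
  expect_equal(res$n_inflations[1], res$n_inflations[2])
})

test_that("inflation never decreases variance and is idempotent at convergence", {
  sp <- scene_spec(V = 3, K = 2, T_ = 40, M = 5, sigma_obs = 2, seed = 61,
                   occlusions = list(list(view = 1, keypoint = 2,
                                          frames = 10:20,
                                          displacement = c(25, -10),
                                          correlated = TRUE)))
  sc <- simulate_scene(sp)
  obs <- aggregate_ensemble(sc$ensemble)
  inf1 <- inflate_variance(obs, "nonlinear", rig = sc$rig)
  expect_true(all(inf1$observations$variance >= obs$variance - 1e-12,
                  na.rm = TRUE))
  expect_gt(nrow(inf1$report$inflated), 0)
  expect_false(any(inf1$report$unresolved))
  expect_true(all(inf1$report$final_distances < 5))
  # second pass is a no-op
  inf2 <- inflate_variance(inf1$observations, "nonlinear", rig = sc$rig)
  expect_equal(inf2$observations$variance, inf1$observations$variance,
               tolerance = 1e-12)
  expect_identical(nrow(inf2$report$inflated), 0L)
  # report bookkeeping
  expect_true(all(inf1$report$inflated$keypoint == 2))
  expect_equal(inf1$report$total_inflation_fraction[1], 0)
})

test_that("rank-deficient leave-one-out systems report zero distance and are skipped", {
  # V=2 with d=3: only 2 equations remain per leave-one-out
  W <- matrix(rnorm(12), 4, 3)
  m <- factor_model(W, rep(0, 4), rep(1, 4))
  expect_equal(mahalanobis_view(c(50, 50, -30, 10), m, 1), 0)
  expect_null(loo_predictive(c(50, 50, -30, 10), m, 1))
})
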