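test_that("soft argmax localizes peaks and handles symmetric maps", {
  hm <- matrix(0, 12, 10)
  hm[8, 4] <- 1                       # row 8, col 4 -> (x=3, y=7) 0-based
  sa <- soft_argmax(hm, tau = 1000)
  expect_equal(c(sa$x, sa$y), c(3, 7), tolerance = 1e-9)
  expect_gt(sa$confidence, 0.999)
  # two equal peaks in one row -> midpoint in x
  hm2 <- matrix(0, 5, 11)
  hm2[3, c(3, 9)] <- 1                # columns 2 and 8 0-based
  sa2 <- soft_argmax(hm2, tau = 1)
  expect_equal(sa2$x, 5, tolerance = 1e-9)
  expect_equal(sa2$y, 2, tolerance = 1e-9)
  # all-equal map -> grid centroid
  sa3 <- soft_argmax(matrix(1, 7, 9), tau = 1)
  expect_equal(c(sa3$x, sa3$y), c(4, 3), tolerance = 1e-12)
})

test_that("soft argmax matches the explicit normalized expectation oracle", {
  set.seed(71)
  for (i in 1:5) {
    hm <- matrix(runif(15 * 13), 15, 13)
    # density convention: normalized weighted average of the grid
    sa <- soft_argmax(hm, tau = 1)
    p <- hm / sum(hm)
    expect_equal(sa$x, sum(p * matrix(0:12, 15, 13, byrow = TRUE)),
                 tolerance = 1e-8)
    expect_equal(sa$y, sum(p * matrix(0:14, 15, 13)), tolerance = 1e-8)
    # logit convention: softmax at temperature tau
    tau <- c(0.5, 1, 5, 100, 1000)[i]
    sa_l <- soft_argmax(hm, tau = tau, logits = TRUE)
    pl <- exp(tau * (hm - max(hm)))
    pl <- pl / sum(pl)
    expect_equal(sa_l$x, sum(pl * matrix(0:12, 15, 13, byrow = TRUE)),
                 tolerance = 1e-8)
    expect_equal(sa_l$y, sum(pl * matrix(0:14, 15, 13)), tolerance = 1e-8)
    expect_equal(sum(pl), 1, tolerance = 1e-6)
  }
})

test_that("soft argmax is equivariant to heatmap flips", {
  set.seed(72)
  hm <- matrix(runif(16 * 12), 16, 12)
  sa <- soft_argmax(hm, tau = 2)
  sa_h <- soft_argmax(hm[, ncol(hm):1], tau = 2)     # horizontal flip
  sa_v <- soft_argmax(hm[nrow(hm):1, ], tau = 2)     # vertical flip
  expect_equal(sa_h$x, (ncol(hm) - 1) - sa$x, tolerance = 1e-9)
  expect_equal(sa_h$y, sa$y, tolerance = 1e-9)
  expect_equal(sa_v$y, (nrow(hm) - 1) - sa$y, tolerance = 1e-9)
  expect_equal(sa_v$x, sa$x, tolerance = 1e-9)
})

test_that("gaussian heatmaps round-trip through soft argmax and flag off-grid points", {
  pts <- rbind(c(11.3, 6.7), c(3.1, 14.9))
  st <- gaussian_heatmap(pts, h = 20, w = 24, sigma = 1.25)
  for (k in 1:2) {
    sa <- soft_argmax(st$values[k, , ], tau = 1000)
    expect_lt(abs(sa$x - pts[k, 1]), 0.1)
    expect_lt(abs(sa$y - pts[k, 2]), 0.1)
    # peak at the nearest grid point is the max of the map
    peak <- which(st$values[k, , ] == max(st$values[k, , ]), arr.ind = TRUE)
    expect_equal(as.numeric(peak), round(rev(pts[k, ])) + 1)
  }
  # far-outside coordinates flagged missing
  st2 <- gaussian_heatmap(rbind(c(-50, 3), c(5, 5)), h = 20, w = 24)
  expect_identical(st2$missing, c(TRUE, FALSE))
  expect_error(gaussian_heatmap(rbind(c(1, 1)), 10, 10, sigma = 0), "sigma")
})

test_that("mask curriculum interpolates between the scheduled anchors", {
  expect_equal(mask_fraction(0), 0)
  expect_equal(mask_fraction(699), 0)
  expect_equal(mask_fraction(700), 0.10)
  expect_equal(mask_fraction(5000), 0.50)
  expect_equal(mask_fraction(100000), 0.50)
  expect_equal(mask_fraction(2850), 0.30)   # midpoint
  fr <- vapply(seq(0, 6000, by = 50), mask_fraction, numeric(1))
  expect_true(all(diff(fr) >= -1e-12))      # nondecreasing
})

test_that("patch masks hit the target fraction within one block and are reproducible", {
  expect_identical(sample_patch_mask(16, 16, 0, seed = 1),
                   matrix(FALSE, 16, 16))
  expect_identical(sample_patch_mask(16, 16, 1, seed = 1),
                   matrix(TRUE, 16, 16))
  m1 <- sample_patch_mask(16, 16, 0.5, seed = 42)
  m2 <- sample_patch_mask(16, 16, 0.5, seed = 42)
  expect_identical(m1, m2)
  frac <- mean(m1)
  expect_gte(frac, 0.5)
  expect_lte(frac, 0.5 + 16 / 256)          # overshoot at most one 4x4 block
})

test_that("reprojection loss vanishes on geometrically consistent predictions", {
  rig <- make_rig(3, arc_deg = 150)
  X <- rbind(c(0.05, -0.03, 0.02), c(-0.04, 0.06, -0.01))
  h <- 100; w <- 100
  gt <- list(); pred <- list()
  for (v in 1:3) {
    px <- project_points(rig$cameras[[v]], X)
    hm_xy <- (px - 1.5) / 4                  # image -> quarter-res grid
    st <- gaussian_heatmap(hm_xy, h, w)
    gt[[v]] <- st
    pred[[v]] <- st
  }
  expect_lt(reprojection_loss(pred, gt, rig), 1e-10)
})

test_that("reprojection loss matches a stage-by-stage oracle and ignores keypoint order", {
  rig <- make_rig(2, arc_deg = 90)
  X <- rbind(c(0.05, -0.03, 0.02), c(-0.06, 0.01, 0.04))
  h <- 100; w <- 100
  gt <- list(); pred <- list()
  for (v in 1:2) {
    px <- project_points(rig$cameras[[v]], X)
    gt[[v]] <- gaussian_heatmap((px - 1.5) / 4, h, w)
    px_p <- px
    if (v == 2) px_p <- px_p + matrix(c(6, -4), 2, 2, byrow = TRUE)
    pred[[v]] <- gaussian_heatmap((px_p - 1.5) / 4, h, w)
  }
  loss <- reprojection_loss(pred, gt, rig)
  # oracle: chain the five stages by hand
  obs <- array(NA_real_, c(2, 2, 2))
  for (v in 1:2) for (k in 1:2) {
    sa <- soft_argmax(pred[[v]]$values[k, , ], tau = 1000)
    obs[v, k, ] <- 4 * c(sa$x, sa$y) + 1.5
  }
  pts <- triangulate_multiview(rig, obs)
  total <- 0; nterms <- 0
  for (v in 1:2) {
    proj <- project_points(rig$cameras[[v]], pts)
    rp <- gaussian_heatmap((proj - 1.5) / 4, h, w)
    for (k in 1:2) {
      total <- total + mean((rp$values[k, , ] - gt[[v]]$values[k, , ])^2) * h * w
      nterms <- nterms + 1
    }
  }
  expect_equal(loss, total / nterms, tolerance = 1e-10)
  expect_gt(loss, 0)
  # keypoint order invariance
  perm_stack <- function(st) heatmap_stack(st$values[2:1, , , drop = FALSE],
                                           missing = st$missing[2:1])
  loss_perm <- reprojection_loss(lapply(pred, perm_stack),
                                 lapply(gt, perm_stack), rig)
  expect_equal(loss_perm, loss, tolerance = 1e-12)
})

test_that("3D augmentation preserves cross-view consistency and degenerates to identity", {
  rig <- make_rig(4, arc_deg = 360)
  set.seed(77)
  X <- cbind(runif(6, -0.1, 0.1), runif(6, -0.1, 0.1), runif(6, -0.1, 0.1))
  labels <- array(NA_real_, c(4, 6, 2))
  for (v in 1:4) labels[v, , ] <- project_points(rig$cameras[[v]], X)
  # identity parameters -> labels unchanged, fitted transforms ~ identity
  aug_id <- augment_3d(labels, rig,
                       params = list(scale_low = 1, scale_high = 1,
                                     shift_low = 0, shift_high = 0),
                       seed = 1)
  expect_equal(aug_id$labels2d, labels, tolerance = 1e-6)
  expect_equal(unname(aug_id$transforms[, "a"]), rep(1, 4), tolerance = 1e-6)
  expect_equal(unname(aug_id$transforms[, "b"]), rep(0, 4), tolerance = 1e-6)
  # generic draw: triangulating the augmented labels recovers the augmented 3D
  aug <- augment_3d(labels, rig, seed = 5)
  tri <- triangulate_multiview(rig, aug$labels2d)
  expect_lt(max(abs(tri - aug$points3d)), 1e-5)
  # reprojection error of augmented labels against augmented points is ~ 0
  re <- reprojection_error(rig, aug$labels2d, aug$points3d)
  expect_lt(re$mean, 1e-6)
  expect_gte(aug$scale, 0.8); expect_lte(aug$scale, 1.2)
})

test_that("similarity fitting recovers a known scale-rotation-translation exactly", {
  set.seed(79)
  p <- matrix(rnorm(20), 10, 2)
  s <- 1.3; th <- 0.4; tr <- c(2, -5)
  Rm <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q <- t(Rm %*% t(p)) + matrix(tr, 10, 2, byrow = TRUE)
  tf <- fit_similarity(p, q)
  expect_equal(unname(tf["a"]), s * cos(th), tolerance = 1e-10)
  expect_equal(unname(tf["b"]), s * sin(th), tolerance = 1e-10)
  expect_equal(unname(tf[c("tx", "ty")]), tr, tolerance = 1e-10)
  expect_equal(apply_similarity(tf, p), q, tolerance = 1e-10)
})
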