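test_that("pinhole projection maps optical-axis and offset points correctly", {
  cam <- camera_model("c", focal = c(100, 100), principal = c(50, 50))
  expect_equal(as.numeric(project_points(cam, c(0, 0, 1))), c(50, 50))
  expect_equal(as.numeric(project_points(cam, c(0.1, 0, 1))), c(60, 50))
})

test_that("projection matches an independent term-by-term distortion oracle", {
  # independent evaluation of extrinsics + perspective + Brown-Conrady
  oracle_project <- function(cam, X) {
    R <- rotation_matrix(cam$rotation)
    Xc <- as.numeric(R %*% X + cam$translation)
    x <- Xc[1] / Xc[3]; y <- Xc[2] / Xc[3]
    k1 <- cam$distortion[1]; k2 <- cam$distortion[2]
    p1 <- cam$distortion[3]; p2 <- cam$distortion[4]; k3 <- cam$distortion[5]
    r2 <- x * x + y * y
    radial <- 1 + k1 * r2 + k2 * r2 * r2 + k3 * r2 * r2 * r2
    xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
    yd <- y * radial + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
    c(cam$focal[1] * xd + cam$principal[1],
      cam$focal[2] * yd + cam$principal[2])
  }
  for (seed in 1:5) {
    cam <- random_camera(seed)
    set.seed(seed + 100)
    X <- runif(3, -0.3, 0.3) + c(0, 0, 0.5)
    expect_equal(as.numeric(project_points(cam, X)), oracle_project(cam, X),
                 tolerance = 1e-12)
  }
})

test_that("points behind the camera are flagged invalid, not errors", {
  cam <- camera_model("c", c(100, 100), c(50, 50))
  out <- project_points(cam, rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1)))
  expect_true(all(is.na(out[1:2, ])))
  expect_false(anyNA(out[3, ]))
})

test_that("undistortion inverts the distortion map on a grid", {
  cam <- camera_model("c", c(900, 950), c(200, 210),
                      distortion = c(0.3, 0.1, 0.01, -0.01, 0.02),
                      translation = c(0, 0, 3))
  grid <- as.matrix(expand.grid(x = seq(-0.15, 0.15, length.out = 7),
                                y = seq(-0.15, 0.15, length.out = 7)))
  xyd <- mveks:::distort_normalized(grid, cam$distortion)
  px <- cbind(cam$focal[1] * xyd[, 1] + cam$principal[1],
              cam$focal[2] * xyd[, 2] + cam$principal[2])
  norm <- undistort_points(cam, px)
  expect_lt(max(abs(norm - grid)) * max(cam$focal), 1e-6)  # in pixel units
})

test_that("undistortion of the principal point is the origin and zero distortion is the inverse intrinsic map", {
  cam0 <- camera_model("c", c(800, 850), c(190, 205))
  px <- rbind(c(190, 205), c(300, 100))
  norm <- undistort_points(cam0, px)
  expect_equal(norm[1, ], c(0, 0))
  expect_equal(norm[2, ], c((300 - 190) / 800, (100 - 205) / 850))
  camd <- camera_model("d", c(800, 850), c(190, 205),
                       distortion = c(-0.2, 0.05, 0.005, -0.003, 0.01))
  expect_equal(as.numeric(undistort_points(camd, c(190, 205))), c(0, 0))
})

test_that("pair triangulation inverts projection, with and without distortion", {
  set.seed(5)
  for (distort in c(FALSE, TRUE)) {
    camA <- random_camera(11, distortion = distort)
    camB <- random_camera(12, distortion = distort)
    X <- rbind(c(0.1, -0.05, 0.2), c(-0.2, 0.1, -0.1))
    tri <- triangulate_pair(camA, camB,
                            project_points(camA, X), project_points(camB, X))
    expect_lt(max(abs(tri - X)), if (distort) 1e-5 else 1e-6)
  }
})

test_that("triangulating with the same camera twice is degenerate", {
  cam <- random_camera(3, distortion = FALSE)
  X <- c(0.1, 0.05, 0.2)
  p <- project_points(cam, X)
  expect_true(all(is.na(triangulate_pair(cam, cam, p, p))))
})

test_that("multiview triangulation equals the mean over all view pairs", {
  rig <- make_rig(4, arc_deg = 150)
  X <- rbind(c(0.1, -0.1, 0.05), c(-0.05, 0.15, -0.1))
  obs <- array(NA_real_, c(4, 2, 2))
  for (v in 1:4) obs[v, , ] <- project_points(rig$cameras[[v]], X)
  # consistent views: result equals any pairwise triangulation
  tm <- triangulate_multiview(rig, obs)
  expect_equal(tm, triangulate_pair(rig$cameras[[1]], rig$cameras[[2]],
                                    obs[1, , ], obs[2, , ]),
               tolerance = 1e-8)
  # perturb one view: result equals the hand-computed mean over all 6 pairs
  obs[2, 1, ] <- obs[2, 1, ] + c(4, -3)
  acc <- matrix(0, 2, 3); np <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    acc <- acc + triangulate_pair(rig$cameras[[a]], rig$cameras[[b]],
                                  obs[a, , ], obs[b, , ])
    np <- np + 1
  }
  expect_equal(triangulate_multiview(rig, obs), acc / np, tolerance = 1e-10)
})

test_that("fewer than two valid views yields an invalid keypoint", {
  rig <- make_rig(3, arc_deg = 120)
  obs <- array(NA_real_, c(3, 1, 2))
  obs[1, 1, ] <- c(200, 200)
  expect_true(all(is.na(triangulate_multiview(rig, obs))))
})

test_that("reprojection error is zero on consistent scenes and matches direct evaluation", {
  rig <- make_rig(2, arc_deg = 90)
  X <- matrix(c(0.05, -0.1, 0.1), 1, 3)
  obs <- array(NA_real_, c(2, 1, 2))
  for (v in 1:2) obs[v, 1, ] <- project_points(rig$cameras[[v]], X)
  expect_equal(reprojection_error(rig, obs, X)$mean, 0, tolerance = 1e-9)
  # shift one view by (3, 4), re-triangulate, compare to direct distances
  obs[2, 1, ] <- obs[2, 1, ] + c(3, 4)
  pt <- triangulate_multiview(rig, obs)
  re <- reprojection_error(rig, obs, pt)
  d <- sapply(1:2, function(v)
    sqrt(sum((obs[v, 1, ] - project_points(rig$cameras[[v]], pt))^2)))
  expect_equal(as.numeric(re$per_view), d, tolerance = 1e-10)
  expect_equal(re$mean, mean(d), tolerance = 1e-10)
  # invalid keypoints are excluded from the mean
  obs2 <- array(NA_real_, c(2, 2, 2))
  obs2[, 1, ] <- obs[, 1, ]
  pts2 <- rbind(pt, c(NA, NA, NA))
  expect_equal(reprojection_error(rig, obs2, pts2)$mean, re$mean,
               tolerance = 1e-12)
})

test_that("project-triangulate round trip holds for 2..6 views and is camera-order invariant", {
  X <- rbind(c(0.12, -0.08, 0.03), c(-0.1, 0.02, 0.14), c(0, 0.1, -0.05))
  for (V in 2:6) {
    rig <- make_rig(V, arc_deg = if (V == 2) 90 else 360)
    obs <- array(NA_real_, c(V, 3, 2))
    for (v in seq_len(V)) obs[v, , ] <- project_points(rig$cameras[[v]], X)
    tm <- triangulate_multiview(rig, obs)
    expect_lt(max(abs(tm - X)), 1e-5)
    # reversing camera order leaves the pair mean unchanged
    rig_rev <- camera_rig(rev(rig$cameras))
    tm_rev <- triangulate_multiview(rig_rev, obs[V:1, , , drop = FALSE])
    expect_equal(tm_rev, tm, tolerance = 1e-10)
  }
})

test_that("axis-angle/rotation-matrix round trips preserve the rotation", {
  set.seed(9)
  for (i in 1:10) {
    aa <- runif(3, -1, 1) * runif(1, 0.01, 3)
    R <- rotation_matrix(aa)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    R2 <- rotation_matrix(rotation_axis_angle(R))
    expect_equal(R2, R, tolerance = 1e-8)
  }
  # near-pi rotation
  aa <- c(pi - 1e-4, 0, 0)
  expect_equal(rotation_matrix(rotation_axis_angle(rotation_matrix(aa))),
               rotation_matrix(aa), tolerance = 1e-6)
})
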