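test_that("intrinsics parsing accepts JSON and plain text, rejects junk", {
  d <- withr::local_tempdir()
  K <- matrix(c(500, 0, 128, 0, 510, 120, 0, 0, 1), 3, byrow = TRUE)
  jp <- file.path(d, "K.json")
  jsonlite::write_json(list(K = K), jp, digits = NA)
  expect_equal(unclass(read_intrinsics(jp)), K, ignore_attr = TRUE)
  tp <- file.path(d, "K.txt")
  writeLines(paste(apply(K, 1, paste, collapse = " "), collapse = "\n"), tp)
  expect_equal(unclass(read_intrinsics(tp)), K, ignore_attr = TRUE)
  expect_error(camera_intrinsics(matrix(1, 3, 3)), "upper-triangular")
  expect_error(camera_intrinsics(diag(c(-1, 1, 1))), "positive focal")
})

test_that("eight-point F matches the hand-built rig exactly at zero noise", {
  rig <- oracle_rig(angle_deg = 10, n = 40, seed = 3)
  # algebraic consistency on all correspondences
  F8 <- fundamental_8pt(rig$x1[1:8, ], rig$x2[1:8, ])
  # residual in normalised camera coordinates: n2' (K' F K) n1 with the
  # induced matrix scaled to unit Frobenius norm
  n1 <- cbind(rig$x1, 1) %*% t(solve(rig$K))
  n2 <- cbind(rig$x2, 1) %*% t(solve(rig$K))
  En <- t(rig$K) %*% F8 %*% rig$K
  En <- En / sqrt(sum(En^2))
  expect_lt(max(abs(rowSums((n2 %*% En) * n1))), 1e-8)
  expect_same_f(F8, rig$F, tol = 1e-6)
})

test_that("RANSAC eight-point survives planted epipolar outliers", {
  rig <- oracle_rig(angle_deg = 12, n = 60, seed = 5)
  x2 <- rig$x2
  x2[51:60, ] <- x2[51:60, ] + cbind(runif(10, 30, 60), runif(10, -60, -30))
  fr <- fundamental_8pt_ransac(rig$x1, x2, ransac_config(seed = 2))
  expect_setequal(fr$inliers, 1:50)
  expect_same_f(fr$F, rig$F, tol = 1e-6)
  expect_error(fundamental_8pt_ransac(rig$x1[1:8, ], x2[1:8, ]),
               class = "ringsift_too_few_matches")
})

test_that("Sampson distances match the textbook oracle and bound inliers", {
  rig <- oracle_rig(angle_deg = 8, n = 30, seed = 9)
  set.seed(1)
  x1 <- rig$x1 + matrix(rnorm(60), ncol = 2)
  x2 <- rig$x2 + matrix(rnorm(60), ncol = 2)
  s <- sampson_distance(rig$F, x1, x2)
  expect_equal(s, oracle_sampson(rig$F, x1, x2), tolerance = 1e-10)
  fr <- fundamental_8pt_ransac(x1, x2, ransac_config(seed = 1))
  expect_lt(median(sampson_distance(fr$F, x1[fr$inliers, ],
                                    x2[fr$inliers, ])), 2)
})

test_that("essential matrix construction and enforcement follow E = K2' F K1", {
  rig <- oracle_rig(angle_deg = 10, n = 30, seed = 4)
  E <- essential_from_f(rig$F, rig$K, rig$K)
  sv <- svd(E)$d
  expect_equal(sv[3], 0, tolerance = 1e-12 * sv[1])
  expect_equal(sv[1], sv[2], tolerance = 1e-9)
  expect_same_f(E, rig$E, tol = 1e-6)
  # identity intrinsics: E equals F after singular-value projection
  Fn <- rig$F
  expect_equal(essential_from_f(Fn, diag(3), diag(3)),
               {
                 s <- svd(Fn); m <- mean(s$d[1:2])
                 s$u %*% diag(c(m, m, 0)) %*% t(s$v)
               }, tolerance = 1e-12)
  expect_error(essential_from_f(rig$F, matrix(0, 3, 3), rig$K))
})

test_that("essential decomposition recovers the canonical stereo pose", {
  # R = I, t = (1, 0, 0)
  rig <- oracle_rig(angle_deg = 0, tx = 1, n = 40, seed = 6)
  E <- essential_from_pose(rig$R, rig$t)
  expect_equal(rig$R, diag(3))
  dec <- decompose_essential(E, rig$x1, rig$x2, rig$K, rig$K)
  expect_equal(dec$R, diag(3), tolerance = 1e-6)
  expect_equal(dec$t, c(1, 0, 0), tolerance = 1e-6)
  expect_length(dec$candidates, 4L)

  # 10 degree rotation about y
  rig10 <- oracle_rig(angle_deg = 10, n = 40, seed = 6)
  dec10 <- decompose_essential(essential_from_pose(rig10$R, rig10$t),
                               rig10$x1, rig10$x2, rig10$K, rig10$K)
  expect_lt(abs(rotation_angle_deg(dec10$R) - 10), 0.01)
  expect_lt(rotation_angle_deg(dec10$R %*% t(rig10$R)), 1e-4)
})

test_that("DLT triangulation round-trips exactly and flags degeneracy", {
  K <- matrix(c(800, 0, 320, 0, 800, 240, 0, 0, 1), 3, byrow = TRUE)
  P1 <- camera_projection(K, diag(3), c(0, 0, 0))
  P2 <- camera_projection(K, diag(3), c(-1, 0, 0))
  M <- c(0, 0, 5)
  m1 <- K %*% M; m1 <- m1[1:2] / m1[3]
  m2 <- K %*% (M + c(-1, 0, 0)); m2 <- m2[1:2] / m2[3]
  X <- triangulate(P1, P2, m1, m2)
  expect_lt(max(abs(X - M)), 1e-9)
  expect_error(triangulate(P1, P1, m1, m1),
               class = "ringsift_degenerate_geometry")
})

test_that("noisy triangulation error matches the straight-loop DLT oracle", {
  rig <- oracle_rig(angle_deg = 10, n = 100, seed = 12)
  P1 <- camera_projection(rig$K, diag(3), c(0, 0, 0))
  P2 <- camera_projection(rig$K, rig$R, rig$t)
  set.seed(12)
  x1 <- rig$x1 + matrix(rnorm(200), ncol = 2)
  x2 <- rig$x2 + matrix(rnorm(200), ncol = 2)
  tri <- triangulate_points(P1, P2, x1, x2)
  ora <- oracle_triangulate(P1, P2, x1, x2)
  expect_equal(tri$X, ora, tolerance = 1e-6)
  med_err <- median(sqrt(rowSums((tri$X - rig$X)^2)))
  med_err_oracle <- median(sqrt(rowSums((ora - rig$X)^2)))
  expect_equal(med_err, med_err_oracle, tolerance = 1e-9)
  # multi-view triangulation agrees at two views
  X2 <- t(vapply(seq_len(nrow(x1)), function(i)
    triangulate_multiview(list(P1, P2), rbind(x1[i, ], x2[i, ])),
    numeric(3)))
  expect_equal(X2, tri$X, tolerance = 1e-9)
})

test_that("global scale is unconstrained: scaling t and M fixes reprojections", {
  rig <- oracle_rig(angle_deg = 10, n = 20, seed = 20)
  for (s in c(0.5, 3)) {
    P2 <- camera_projection(rig$K, rig$R, rig$t * s)
    Xs <- rig$X * s
    pr <- cbind(Xs, 1) %*% t(P2)
    pr <- pr[, 1:2] / pr[, 3]
    expect_equal(pr, rig$x2, tolerance = 1e-9)
  }
})

test_that("two-view geometry on a rig recovers pose and structure", {
  rig <- make_rig(n_points = 60, n_cameras = 2, noise_sigma = 0, seed = 2)
  g <- two_view_geometry(rig$observations[[1]], rig$observations[[2]], rig$K)
  expect_lt(rotation_angle_deg(g$R %*% t(rig$R12)), 1e-4)
  expect_lt(angle_between_deg(g$t, rig$t12), 1e-4)
  tri <- g$triangulated
  expect_true(all(tri$finite))
  expect_true(all(tri$depth1 > 0 & tri$depth2 > 0))
  al <- align_similarity(tri$X, rig$points3d[g$inliers, ])
  expect_lt(al$rmse, 1e-9)
  # epipolar residuals of survivors bounded by the Sampson threshold
  expect_lt(max(sampson_distance(g$F, rig$observations[[1]][g$inliers, ],
                                 rig$observations[[2]][g$inliers, ])), 2)
})

test_that("identical views are rejected as low-parallax", {
  rig <- make_rig(n_points = 40, n_cameras = 2, noise_sigma = 0, seed = 3)
  o <- rig$observations[[1]]
  expect_error(two_view_geometry(o, o, rig$K),
               class = "ringsift_low_parallax")
})

test_that("similarity alignment matches vegan's Procrustes solution", {
  skip_if_not_installed("vegan")
  set.seed(8)
  A <- matrix(rnorm(60), 20, 3)
  ang <- 0.6
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, byrow = TRUE)
  B <- 1.7 * A %*% t(Rz) + matrix(rep(c(3, -2, 5), each = 20), 20)
  al <- align_similarity(A, B)
  expect_lt(al$rmse, 1e-9)
  # perturbed pairing: both solvers must agree on the residual error
  B2 <- B + matrix(rnorm(60, 0, 0.2), 20, 3)
  al2 <- align_similarity(A, B2)
  pv <- vegan::procrustes(B2, A, scale = TRUE)  # rotate/scale A onto B2
  expect_equal(al2$rmse, sqrt(mean(residuals(pv)^2)), tolerance = 1e-8)
})

test_that("PnP registers a view against noisy structure", {
  rig <- make_rig(n_points = 80, n_cameras = 3, noise_sigma = 0.5, seed = 6)
  # structure in world frame with mild noise
  set.seed(6)
  X <- rig$points3d + matrix(rnorm(240, 0, 0.002), ncol = 3)
  cm <- rig$cameras[[3]]
  pnp <- pnp_ransac(X, rig$observations[[3]], rig$K,
                    ransac_config(inlier_threshold = 4, seed = 2))
  expect_lt(rotation_angle_deg(pnp$R %*% t(cm$R)), 0.5)
  expect_lt(max(abs(pnp$t - cm$t)), 0.05)
})
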