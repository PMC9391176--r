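test_that("texture generation is deterministic and feature-rich", {
  a <- make_texture(256, 256, seed = 7)
  b <- make_texture(256, 256, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, make_texture(256, 256, seed = 8)$pixels))
  kps <- detect_extrema(build_scale_space(a))
  expect_gte(nrow(kps), 50L)
  expect_error(make_texture(32, 32), "64x64")
})

test_that("well-separated blobs each produce a nearby keypoint", {
  tex <- make_texture(256, 256, seed = 3, style = "blobs", n_blobs = 10)
  centers <- attr(tex, "blob_centers")
  expect_equal(nrow(centers), 10L)
  kps <- detect_extrema(build_scale_space(tex))
  expect_gte(nrow(kps), 10L)
  hit <- vapply(seq_len(nrow(centers)), function(i)
    min(sqrt((kps$x - centers[i, 1])^2 + (kps$y - centers[i, 2])^2)) <= 3,
    logical(1))
  expect_gte(sum(hit), 10L)
})

test_that("warp fixtures carry an exact ground-truth homography", {
  tex <- make_texture(128, 128, seed = 4)
  idf <- make_warp_pair(tex, list(type = "identity"))
  expect_equal(idf$H_true, diag(3))
  expect_identical(idf$image_b$pixels, tex$pixels)
  expect_true(all(idf$valid_region))

  th <- 30 * pi / 180
  rotf <- make_warp_pair(tex, list(type = "rotation", theta = th))
  cx <- (128 - 1) / 2
  Tm <- matrix(c(1, 0, cx, 0, 1, cx, 0, 0, 1), 3, byrow = TRUE)
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  Hhand <- Tm %*% Rm %*% solve(Tm)
  expect_equal(rotf$H_true, Hhand, tolerance = 1e-12)
  # the valid-region invariant: mapped points land inside image_b
  idx <- which(rotf$valid_region, arr.ind = TRUE)
  smp <- idx[seq(1, nrow(idx), length.out = 50), , drop = FALSE]
  fwd <- apply_homography(rotf$H_true, cbind(smp[, 2] - 1, smp[, 1] - 1))
  expect_true(all(fwd >= 0 & fwd <= 127))

  blurf <- make_warp_pair(tex, list(type = "blur", sigma = 2))
  expect_equal(blurf$H_true, diag(3))
  expect_false(identical(blurf$image_b$pixels, tex$pixels))

  expect_error(make_warp_pair(tex, list(type = "scale", s = 8)), "25%")
})

test_that("camera rigs are reproducible, in-frame, and internally consistent", {
  r1 <- make_rig(n_points = 30, n_cameras = 2, noise_sigma = 0.5, seed = 5)
  r2 <- make_rig(n_points = 30, n_cameras = 2, noise_sigma = 0.5, seed = 5)
  expect_identical(r1$observations, r2$observations)
  expect_identical(r1$points3d, r2$points3d)

  r0 <- make_rig(n_points = 30, n_cameras = 3, noise_sigma = 0, seed = 5)
  for (ci in 1:3) {
    o <- r0$observations[[ci]]
    expect_true(all(o[, 1] >= 0 & o[, 1] <= 3071 &
                    o[, 2] >= 0 & o[, 2] <= 2047))
    # zero-noise observations are exact projections
    cm <- r0$cameras[[ci]]
    Xh <- cbind(r0$points3d, 1) %*% t(camera_projection(cm$K, cm$R, cm$t))
    expect_equal(o, cbind(Xh[, 1] / Xh[, 3], Xh[, 2] / Xh[, 3]),
                 tolerance = 1e-10)
  }
  # noise-free triangulation round-trips the planted points
  P1 <- camera_projection(r0$K, r0$cameras[[1]]$R, r0$cameras[[1]]$t)
  P2 <- camera_projection(r0$K, r0$cameras[[2]]$R, r0$cameras[[2]]$t)
  tri <- triangulate_points(P1, P2, r0$observations[[1]],
                            r0$observations[[2]])
  expect_lt(max(abs(tri$X - r0$points3d)), 1e-8)
  # emitted ground-truth F agrees with the eight-point solution
  F8 <- fundamental_8pt(r0$observations[[1]], r0$observations[[2]])
  expect_same_f(F8, r0$F12, tol = 1e-6)
})

test_that("relief scenes render consistently with their ground truth", {
  sc <- make_relief_scene(n_views = 2, size = 128, seed = 3)
  expect_length(sc$images, 2L)
  # the surface point behind a pixel reprojects onto that pixel
  uv <- cbind(c(30, 64, 100), c(40, 64, 90))
  for (v in 1:2) {
    S <- sc$surface_point(v, uv)
    cm <- sc$cameras[[v]]
    pr <- t(apply(S, 1, function(X) {
      q <- sc$K %*% (cm$R %*% X + cm$t); q[1:2] / q[3]
    }))
    expect_equal(pr, uv, tolerance = 1e-3, ignore_attr = TRUE)
  }
})
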