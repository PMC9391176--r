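# a single Gaussian intensity blob on a flat background
blob_image <- function(size, cx, cy, sigma_b, amp = 200, bg = 20) {
  ys <- matrix(seq_len(size) - 1, size, size)
  xs <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  gray_image(pmin(bg + amp * exp(-((xs - cx)^2 + (ys - cy)^2) /
                                   (2 * sigma_b^2)), 255))
}

test_that("scale space has the pyramid structure and zeroes out on constants", {
  img <- gray_image(matrix(77, 64, 64))
  ss <- build_scale_space(img)
  expect_s3_class(ss, "scale_space")
  expect_gte(ss$n_octaves, 4L)   # 64 px with an 8 px smallest octave
  expect_length(ss$octaves[[1L]]$gauss, ss$n_intervals + 3L)
  expect_length(ss$octaves[[1L]]$dog, ss$n_intervals + 2L)
  expect_equal(ss$k, 2^(1 / ss$n_intervals))
  for (o in seq_len(ss$n_octaves))
    for (d in ss$octaves[[o]]$dog)
      expect_lt(max(abs(d)), 1e-9)
  expect_equal(nrow(detect_extrema(ss)), 0L)
  expect_error(build_scale_space(img, octaves = 12), "octaves")
})

test_that("the strongest DoG response of a Gaussian blob sits at its scale", {
  sigma_b <- 4
  img <- blob_image(96, 47.5, 47.5, sigma_b)
  ss <- build_scale_space(img)
  # oracle: centre response of a difference of two Gaussian blurs of a
  # Gaussian blob of amplitude A and scale s_b is
  #   A s_b^2 (1/(s_b^2 + s1^2) - 1/(s_b^2 + s2^2)) (2-D closed form),
  # evaluated on the pyramid's absolute scale ladder
  best <- pred <- list(scale = NA, val = -Inf)
  for (o in seq_len(ss$n_octaves)) {
    fac <- 2^(o - 1)
    for (j in seq_along(ss$octaves[[o]]$dog)) {
      d <- ss$octaves[[o]]$dog[[j]]
      s1 <- ss$sigmas[j] * fac; s2 <- ss$sigmas[j + 1L] * fac
      mid <- sqrt(s1 * s2)
      ctr <- max(abs(d))
      if (ctr > best$val) best <- list(scale = mid, val = ctr)
      p <- abs(sigma_b^2 * (1 / (sigma_b^2 + s1^2) - 1 / (sigma_b^2 + s2^2)))
      if (p > pred$val) pred <- list(scale = mid, val = p)
    }
  }
  # adjacent octaves duplicate one scale band, so compare the band's
  # absolute scale (within one ladder step), not its indices
  expect_lt(abs(log(best$scale / pred$scale)), log(ss$k) + 1e-9)
  # and the oracle's preferred band must sit at the blob's scale
  expect_lt(abs(log(pred$scale / sigma_b)), log(2))
})

test_that("isolated blobs are detected at their centres", {
  img <- blob_image(96, 47.5, 47.5, 4)
  ss <- build_scale_space(img)
  kps <- detect_extrema(ss)
  expect_gte(nrow(kps), 1L)
  d <- sqrt((kps$x - 47.5)^2 + (kps$y - 47.5)^2)
  expect_lt(min(d), 1.5)

  two <- blob_image(128, 31.5, 31.5, 4)
  two$pixels <- pmin(two$pixels +
    blob_image(128, 95.5, 95.5, 4, bg = 0)$pixels, 255)
  kps2 <- detect_extrema(build_scale_space(two))
  expect_gte(nrow(kps2), 2L)
  d1 <- min(sqrt((kps2$x - 31.5)^2 + (kps2$y - 31.5)^2))
  d2 <- min(sqrt((kps2$x - 95.5)^2 + (kps2$y - 95.5)^2))
  expect_lt(d1, 1.5); expect_lt(d2, 1.5)
})

test_that("detection is deterministic", {
  tex <- make_texture(128, 128, seed = 5)
  k1 <- detect_extrema(build_scale_space(tex))
  k2 <- detect_extrema(build_scale_space(tex))
  expect_identical(k1, k2)
})

test_that("orientation assignment follows the dominant gradient direction", {
  # ramp in x: every gradient vector points along +x
  ramp <- gray_image(matrix(rep(seq(0, 250, length.out = 64), times = 64),
                            64, 64, byrow = TRUE))
  ss <- build_scale_space(ramp, octaves = 1L)
  kp <- data.frame(x = 32, y = 32, sigma = 1.6, octave = 1L, layer = 2,
                   x_oct = 32, y_oct = 32, sigma_oct = 1.6, response = 1)
  ok <- assign_orientations(kp, ss, field_order = 1L)
  expect_gte(nrow(ok), 1L)
  expect_lt(abs(ok$theta[1L]), 10 * pi / 180 + 1e-9)

  # same neighbourhood rotated 90 degrees: gradients along +y
  ramp_y <- gray_image(t(ramp$pixels))
  ss_y <- build_scale_space(ramp_y, octaves = 1L)
  ok_y <- assign_orientations(kp, ss_y, field_order = 1L)
  expect_lt(abs(ok_y$theta[1L] - pi / 2), 10 * pi / 180 + 1e-9)

  # featureless neighbourhood: keypoint dropped
  flat <- build_scale_space(gray_image(matrix(100, 64, 64)), octaves = 1L)
  expect_equal(nrow(assign_orientations(kp, flat)), 0L)
})

test_that("keypoints survive a 90-degree rotation at matching locations", {
  tex <- make_texture(128, 128, seed = 9)
  rot <- gray_image(t(tex$pixels)[, 128:1])  # rotate 90 deg clockwise
  k1 <- detect_extrema(build_scale_space(tex))
  k2 <- detect_extrema(build_scale_space(rot))
  expect_gt(nrow(k1), 20L)
  # map original keypoints through the rotation: (x, y) -> (127 - y, x)
  mx <- 127 - k1$y; my <- k1$x
  ok <- vapply(seq_along(mx), function(i)
    min(sqrt((k2$x - mx[i])^2 + (k2$y - my[i])^2)) <= 2, logical(1L))
  expect_gte(mean(ok), 0.8)
})
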