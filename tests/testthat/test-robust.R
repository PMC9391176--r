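# keypoint tables + matches realising a planted homography with
# `n_out` displaced mismatches appended
planted_h_matches <- function(n_in, n_out, H, seed, noise = 0,
                              displacement = 30) {
  set.seed(seed)
  n <- n_in + n_out
  xy <- cbind(runif(n, 10, 246), runif(n, 10, 246))
  uv <- apply_homography(H, xy)
  if (noise > 0) uv <- uv + matrix(rnorm(2 * n, 0, noise), ncol = 2)
  if (n_out > 0) {
    ang <- runif(n_out, 0, 2 * pi)
    d <- displacement + runif(n_out, 0, 20)
    idx <- (n_in + 1):n
    uv[idx, ] <- uv[idx, ] + cbind(d * cos(ang), d * sin(ang))
  }
  list(kr = planted_keypoints(xy, numeric(n)),
       kt = planted_keypoints(uv, numeric(n)),
       m = match_set(1:n, 1:n, sort(runif(n))))
}

test_that("trimming removes the floor(fraction * N) worst pairs in order", {
  m10 <- match_set(1:10, 1:10, seq(0.01, 0.10, by = 0.01))
  t10 <- trim_matches(m10, 0.2)
  expect_equal(nrow(t10), 8L)
  expect_equal(max(t10$desc_distance), 0.08)
  expect_true(!is.unsorted(t10$desc_distance))

  m5 <- match_set(1:5, 1:5, seq(0.1, 0.5, by = 0.1))
  expect_equal(nrow(trim_matches(m5, 0.2)), 4L)

  m0 <- match_set(integer(0), integer(0))
  expect_equal(nrow(trim_matches(m0, 0.2)), 0L)
})

test_that("minimal homography fits are exact and reject collinear samples", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fit_homography_minimal(sq, sq), diag(3), tolerance = 1e-9)

  shifted <- sweep(sq, 2, c(5, -3), `+`)
  Ht <- fit_homography_minimal(sq, shifted)
  expect_equal(Ht, matrix(c(1, 0, 5, 0, 1, -3, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(apply_homography(Ht, sq), shifted, tolerance = 1e-9)

  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1))
  expect_error(fit_homography_minimal(bad, sq),
               class = "ringsift_degenerate")
})

test_that("zero-noise consensus recovers the exact homography and all pairs", {
  H <- matrix(c(0.95, 0.08, 4, -0.06, 1.02, -7, 1e-4, -8e-5, 1),
              3, byrow = TRUE)
  p <- planted_h_matches(30, 0, H, seed = 1)
  fit <- ransac_refine(p$m, p$kr, p$kt, ransac_config(seed = 1))
  expect_equal(nrow(fit$matches), 30L)
  expect_lt(max(abs(fit$H / fit$H[3, 3] - H / H[3, 3])) / max(abs(H)), 1e-6)
})

test_that("planted outliers are removed exactly at threshold 2", {
  H <- matrix(c(1.05, -0.1, 12, 0.12, 0.98, -5, 0, 0, 1), 3, byrow = TRUE)
  p <- planted_h_matches(24, 6, H, seed = 7, displacement = 25)
  fit <- ransac_refine(p$m, p$kr, p$kt, ransac_config(seed = 3))
  expect_setequal(fit$inliers, 1:24)
  # every returned inlier satisfies the symmetric transfer bound
  src <- as.matrix(p$kr[fit$matches$ref, 1:2])
  dst <- as.matrix(p$kt[fit$matches$tgt, 1:2])
  fwd <- sqrt(rowSums((apply_homography(fit$H, src) - dst)^2))
  bwd <- sqrt(rowSums((apply_homography(solve(fit$H), dst) - src)^2))
  expect_true(all(fwd < 2 & bwd < 2))
})

test_that("RANSAC output is bit-identical for a fixed seed", {
  H <- matrix(c(1, 0.05, 3, -0.04, 1, 2, 0, 0, 1), 3, byrow = TRUE)
  p <- planted_h_matches(25, 5, H, seed = 11, noise = 0.3)
  f1 <- ransac_refine(p$m, p$kr, p$kt, ransac_config(seed = 99))
  f2 <- ransac_refine(p$m, p$kr, p$kt, ransac_config(seed = 99))
  expect_identical(f1$H, f2$H)
  expect_identical(f1$inliers, f2$inliers)
})

test_that("degenerate sizes raise distinguishable failures", {
  H <- diag(3)
  p <- planted_h_matches(4, 0, H, seed = 2)
  expect_error(ransac_refine(p$m, p$kr, p$kt, ransac_config()),
               class = "ringsift_too_few_matches")
  # enough pairs but no homography-consistent consensus
  set.seed(5)
  kr <- planted_keypoints(cbind(runif(12, 0, 100), runif(12, 0, 100)), 0)
  kt <- planted_keypoints(cbind(runif(12, 0, 100), runif(12, 0, 100)), 0)
  m <- match_set(1:12, 1:12, sort(runif(12)))
  expect_error(ransac_refine(m, kr, kt,
                             ransac_config(inlier_threshold = 0.001,
                                           max_iterations = 50)),
               class = "ringsift_no_consensus")
})

test_that("inlier recall stays above 95% across seeded noisy runs", {
  H <- matrix(c(1.02, 0.06, 8, -0.05, 0.97, -3, 0, 0, 1), 3, byrow = TRUE)
  recalls <- vapply(1:25, function(s) {
    p <- planted_h_matches(21, 9, H, seed = s, noise = 0.4)  # 30% outliers
    fit <- ransac_refine(p$m, p$kr, p$kt, ransac_config(seed = s))
    mean(1:21 %in% fit$inliers)
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})
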