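unit_rows <- function(m) m / sqrt(rowSums(m^2))

test_that("NNDR matching follows the arccos-distance arithmetic", {
  # orthogonal unit descriptors match themselves at distance 0
  d <- diag(8L)[1:4, ]
  m <- nndr_match(d, d, 0.8)
  expect_s3_class(m, "match_set")
  expect_equal(m$ref, m$tgt)
  expect_true(all(m$desc_distance == 0))
  expect_true(all(m$nndr == 0))

  # ref u; targets u and one at angle 0.8: nndr = 0 / 0.8 = 0
  u <- c(1, rep(0, 7))
  v2 <- c(cos(0.8), sin(0.8), rep(0, 6))
  m2 <- nndr_match(rbind(u), rbind(u, v2), 1e-9)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$nndr, 0)

  # targets at distances 0.5 and 0.6: ratio 0.833 rejected at 0.8
  t1 <- c(cos(0.5), sin(0.5), rep(0, 6))
  t2 <- c(cos(0.6), 0, sin(0.6), rep(0, 5))
  m3 <- nndr_match(rbind(u), rbind(t1, t2), 0.8)
  expect_equal(nrow(m3), 0L)
  m4 <- nndr_match(rbind(u), rbind(t1, t2), 0.85)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$nndr, 0.5 / 0.6, tolerance = 1e-9)

  # fewer than 2 targets: all pass, nndr defined as 0
  expect_warning(m5 <- nndr_match(rbind(u, v2), rbind(u), 0.8), "fewer")
  expect_true(all(m5$nndr == 0))
})

test_that("duplicate target claims resolve to the smaller distance", {
  u1 <- c(1, rep(0, 7))
  u2 <- c(cos(0.3), sin(0.3), rep(0, 6))
  tgt <- rbind(u1, c(0, 0, 1, rep(0, 5)))
  m <- nndr_match(rbind(u1, u2), tgt, 0.99)
  expect_equal(sum(m$tgt == 1L), 1L)
  expect_equal(m$ref[m$tgt == 1L], 1L)  # closer reference wins
  expect_true(!is.unsorted(m$desc_distance))
})

test_that("pair geometry returns Euclidean distance and wrapped angle", {
  a <- data.frame(x = 0, y = 0, theta = 0)
  b <- data.frame(x = 3, y = 4, theta = pi / 2)
  expect_equal(unname(pair_geometry(a, a)), c(0, 0))
  g <- pair_geometry(a, b)
  expect_equal(unname(g), c(5, pi / 2))
  c1 <- data.frame(x = 0, y = 0, theta = 3)
  c2 <- data.frame(x = 1, y = 0, theta = -3)
  expect_equal(unname(pair_geometry(c1, c2)["delta_theta"]), 2 * pi - 6,
               tolerance = 1e-12)
})

test_that("voting keeps translation-consistent matches and agrees with the oracle", {
  set.seed(5)
  n <- 25
  xy <- cbind(runif(n, 0, 200), runif(n, 0, 200))
  th <- runif(n, -pi, pi)
  kr <- planted_keypoints(xy, th)
  kt <- planted_keypoints(sweep(xy, 2, c(17, -9), `+`), th)
  m <- match_set(1:n, 1:n, sort(runif(n)), runif(n, 0, 0.8))
  out <- vote_filter(m, kr, kt)
  expect_equal(nrow(out), n)          # perfectly consistent: all kept
  expect_true(all(out$dot1 < 1e-9))
  o <- oracle_vote_dots(kr$x, kr$y, kr$theta, kt$x, kt$y, kt$theta)
  expect_equal(out$dot1, o$dot1, tolerance = 1e-12)
  expect_equal(out$dot2, o$dot2, tolerance = 1e-12)
})

test_that("voting dot products match the oracle on random geometry", {
  set.seed(6)
  n <- 30
  kr <- planted_keypoints(cbind(runif(n, 0, 256), runif(n, 0, 256)),
                          runif(n, -pi, pi))
  kt <- planted_keypoints(cbind(runif(n, 0, 256), runif(n, 0, 256)),
                          runif(n, -pi, pi))
  m <- match_set(1:n, 1:n, sort(runif(n)))
  out <- vote_filter(m, kr, kt, T_theta = Inf, T_d = Inf)
  o <- oracle_vote_dots(kr$x, kr$y, kr$theta, kt$x, kt$y, kt$theta)
  expect_equal(out$dot1, o$dot1, tolerance = 1e-12)
  expect_equal(out$dot2, o$dot2, tolerance = 1e-12)
  expect_true(all(out$dot1 >= 0 & out$dot1 <= 2))
  expect_true(all(out$dot2 >= 0 & out$dot2 <= 2))
})

test_that("a planted 50 px mismatch is removed at the printed thresholds", {
  set.seed(42)
  n <- 20
  xy <- cbind(runif(n + 1, 20, 236), runif(n + 1, 20, 236))
  rot <- 0.3; s <- 1.1
  Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  tgt_xy <- s * xy %*% t(Rm) + 10
  tgt_xy[n + 1, 1] <- tgt_xy[n + 1, 1] + 50    # the planted mismatch
  th <- runif(n + 1, -pi, pi)
  th_t <- th + rot
  th_t[n + 1] <- runif(1, -pi, pi)
  kr <- planted_keypoints(xy, th)
  kt <- planted_keypoints(tgt_xy, th_t)
  m <- match_set(1:(n + 1), 1:(n + 1), seq(0.1, 0.3, length.out = n + 1))
  out <- vote_filter(m, kr, kt, T_theta = 0.3, T_d = 0.4)
  all_dots <- vote_filter(m, kr, kt, T_theta = Inf, T_d = Inf)
  # the planted pair carries the largest distance dissimilarity
  expect_equal(which.max(all_dots$dot1), n + 1L)
  expect_false((n + 1L) %in% out$ref)
  expect_gte(sum(out$ref <= n), 18L)
})

test_that("voting is invariant to a global rigid transform of either image", {
  set.seed(9)
  n <- 20
  kr <- planted_keypoints(cbind(runif(n, 0, 100), runif(n, 0, 100)),
                          runif(n, -pi, pi))
  kt <- planted_keypoints(cbind(runif(n, 0, 100), runif(n, 0, 100)),
                          runif(n, -pi, pi))
  m <- match_set(1:n, 1:n, sort(runif(n)))
  base <- vote_filter(m, kr, kt, T_theta = Inf, T_d = Inf)
  a <- 0.7
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  kr2 <- planted_keypoints(as.matrix(kr[, 1:2]) %*% t(Rm) + 31,
                           kr$theta + a)
  moved <- vote_filter(m, kr2, kt, T_theta = Inf, T_d = Inf)
  expect_equal(moved$dot1, base$dot1, tolerance = 1e-9)
  expect_equal(moved$dot2, base$dot2, tolerance = 1e-9)
})

test_that("voting never adds pairs and passes tiny sets through", {
  kr <- planted_keypoints(cbind(c(0, 10), c(0, 10)), c(0, 1))
  kt <- kr
  m <- match_set(1:2, 1:2, c(0.1, 0.2))
  expect_warning(out <- vote_filter(m, kr, kt), "voting skipped")
  expect_equal(nrow(out), 2L)
})
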