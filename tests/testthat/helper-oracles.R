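# Independent straight-loop oracles. These deliberately share no code
# with the package: plain nested loops and textbook formulas, used to
# cross-check the vectorised production implementations.

# 3x3 correlation with edge replication, nested loops
oracle_sobel <- function(px, axis) {
  Bx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  By <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  B <- if (axis == "horizontal") Bx else By
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- min(max(r + dr, 1), h)
      cc <- min(max(c + dc, 1), w)
      acc <- acc + B[dr + 2, dc + 2] * px[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# unnormalised concentric-ring accumulation, one pixel at a time
oracle_descriptor <- function(x, y, theta, sigma, field, rings = 8,
                              bins = 8, radius_per_ring = 1,
                              scale_radius = TRUE, base_sigma = 1.6) {
  rw <- if (scale_radius) radius_per_ring * sigma / base_sigma
        else radius_per_ring
  rmax <- rings * rw
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  vec <- numeric(rings * bins)
  for (r in 1:h) for (c in 1:w) {
    dx <- (c - 1) - x; dy <- (r - 1) - y
    d <- sqrt(dx^2 + dy^2)
    if (d > rmax) next
    ring <- max(ceiling(d / rw) - 1, 0)
    if (ring > rings - 1) next
    m <- field$magnitude[r, c]
    a <- (field$orientation[r, c] - theta) %% (2 * pi)
    pos <- a / (2 * pi / bins)
    b0 <- floor(pos); frac <- pos - b0
    b0 <- b0 %% bins; b1 <- (b0 + 1) %% bins
    wgt <- m * exp(-ring^2 / 32)
    vec[ring * bins + b0 + 1] <- vec[ring * bins + b0 + 1] + wgt * (1 - frac)
    vec[ring * bins + b1 + 1] <- vec[ring * bins + b1 + 1] + wgt * frac
  }
  vec
}

# quadratic straight-loop evaluation of the voting dot products
oracle_vote_dots <- function(xr, yr, tr, xt, yt, tt) {
  n <- length(xr)
  one_minus_corr <- function(u, v) {
    u <- u - mean(u); v <- v - mean(v)
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 && nv == 0) return(0)
    if (nu == 0 || nv == 0) return(2)
    1 - sum((u / nu) * (v / nv))
  }
  dot1 <- dot2 <- numeric(n)
  for (i in 1:n) {
    dr <- dt <- ar <- at <- numeric(0)
    for (j in 1:n) {
      if (j == i) next
      dr <- c(dr, sqrt((xr[j] - xr[i])^2 + (yr[j] - yr[i])^2))
      dt <- c(dt, sqrt((xt[j] - xt[i])^2 + (yt[j] - yt[i])^2))
      ar <- c(ar, (tr[j] - tr[i]) %% (2 * pi))
      at <- c(at, (tt[j] - tt[i]) %% (2 * pi))
    }
    dot1[i] <- one_minus_corr(dr, dt)
    dot2[i] <- one_minus_corr(ar, at)
  }
  list(dot1 = dot1, dot2 = dot2)
}

# textbook first-order point-to-epipolar-constraint distance
oracle_sampson <- function(F, x1, x2) {
  n <- nrow(x1)
  out <- numeric(n)
  for (i in 1:n) {
    p1 <- c(x1[i, 1], x1[i, 2], 1)
    p2 <- c(x2[i, 1], x2[i, 2], 1)
    Fp1 <- F %*% p1
    Ftp2 <- t(F) %*% p2
    num <- (sum(p2 * Fp1))^2
    den <- Fp1[1]^2 + Fp1[2]^2 + Ftp2[1]^2 + Ftp2[2]^2
    out[i] <- sqrt(num / den)
  }
  out
}

# straight-loop homogeneous DLT triangulation via explicit 4x4 SVD
oracle_triangulate <- function(P1, P2, x1, x2) {
  n <- nrow(x1)
  out <- matrix(NA_real_, n, 3)
  for (i in 1:n) {
    A <- rbind(x1[i, 1] * P1[3, ] - P1[1, ],
               x1[i, 2] * P1[3, ] - P1[2, ],
               x2[i, 1] * P2[3, ] - P2[1, ],
               x2[i, 2] * P2[3, ] - P2[2, ])
    ev <- eigen(t(A) %*% A, symmetric = TRUE)
    v <- ev$vectors[, 4]
    out[i, ] <- v[1:3] / v[4]
  }
  out
}

# hand-built two-camera rig (independent of make_rig): canonical
# stereo with rotation about y and translation along x
oracle_rig <- function(angle_deg = 10, tx = 1, n = 40, seed = 1,
                       f = 1000, pp = 500) {
  set.seed(seed)
  K <- matrix(c(f, 0, pp, 0, f, pp, 0, 0, 1), 3, byrow = TRUE)
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
              3, byrow = TRUE)
  t <- c(tx, 0, 0)
  X <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, 8, 12))
  p1 <- t(apply(X, 1, function(Xi) { q <- K %*% Xi; q[1:2] / q[3] }))
  p2 <- t(apply(X, 1, function(Xi) {
    q <- K %*% (R %*% Xi + t); q[1:2] / q[3]
  }))
  skew <- matrix(c(0, -t[3], t[2], t[3], 0, -t[1], -t[2], t[1], 0),
                 3, byrow = TRUE)
  E <- skew %*% R
  F <- t(solve(K)) %*% E %*% solve(K)
  list(K = K, R = R, t = t, X = X, x1 = p1, x2 = p2, E = E, F = F)
}

# keypoint tables for planted matching experiments
planted_keypoints <- function(xy, theta) {
  data.frame(x = xy[, 1], y = xy[, 2], theta = theta)
}

expect_same_f <- function(Fa, Fb, tol = 1e-6) {
  na <- Fa / sqrt(sum(Fa^2)); nb <- Fb / sqrt(sum(Fb^2))
  if (sum((na - nb)^2) > sum((na + nb)^2)) nb <- -nb
  expect_lt(max(abs(na - nb)), tol)
}
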