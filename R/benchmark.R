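#' Seeded matcher benchmark on warped texture fixtures
#'
#' Generates one warp fixture per seed — cycling through rotation
#' (up to 30 degrees), scale (0.8--1.25), blur (sigma up to 2) and
#' gamma (0.7--1.4) transforms, parameters drawn per seed within those
#' ranges — runs the full matching chain, and scores every stage by
#' the fraction of surviving pairs that are correct under the 2 px
#' ground-truth criterion.
#'
#' @param seeds integer vector of fixture seeds.
#' @param size square texture size in pixels (default 256).
#' @param config a [pipeline_config()].
#' @param tol correctness tolerance in pixels (default 2).
#' @return A data frame with one row per seed: the transform type,
#'   per-stage correct-match rates (`rate_nndr`, `rate_vote`,
#'   `rate_trim`, `rate_ransac`) and surviving pair counts.
#' @export
benchmark_matcher <- function(seeds = 1:10, size = 256L,
                              config = pipeline_config(), tol = 2) {
  types <- c("rotation", "scale", "blur", "gamma")
  rows <- lapply(seq_along(seeds), function(i) {
    seed <- seeds[i]
    type <- types[(i - 1L) %% length(types) + 1L]
    tr <- with_seed(seed * 1000L + 17L, switch(type,
      rotation = list(type = "rotation",
                      theta = stats::runif(1, -30, 30) * pi / 180),
      scale = list(type = "scale", s = stats::runif(1, 0.8, 1.25)),
      blur = list(type = "blur", sigma = stats::runif(1, 0.5, 2)),
      gamma = list(type = "gamma", g = stats::runif(1, 0.7, 1.4))))
    wp <- make_warp_pair(make_texture(size, size, seed = seed), tr)
    det_a <- detect_and_describe(wp$image_a, config)
    det_b <- detect_and_describe(wp$image_b, config)
    mr <- match_images(det_a, det_b, config)
    rates <- vapply(mr$stages, function(m)
      correct_match_rate(m, det_a$keypoints, det_b$keypoints, wp$H_true,
                         tol = tol), numeric(1L))
    data.frame(seed = seed, type = type,
               rate_nndr = rates[["nndr"]], rate_vote = rates[["vote"]],
               rate_trim = rates[["trim"]], rate_ransac = rates[["ransac"]],
               n_nndr = mr$counts[["nndr"]], n_vote = mr$counts[["vote"]],
               n_trim = mr$counts[["trim"]],
               n_ransac = mr$counts[["ransac"]])
  })
  do.call(rbind, rows)
}

#' Planted homography-outlier experiment
#'
#' Builds `n_in` correspondences exactly consistent with a random
#' similarity-plus-perspective homography and `n_out` mismatches
#' displaced by at least `displacement` pixels, runs the trimmed
#' RANSAC stage, and reports whether exactly the planted inliers
#' survive.
#'
#' @param seed integer seed (drives geometry and RANSAC).
#' @param n_in,n_out planted inlier / outlier counts.
#' @param displacement minimum outlier displacement in pixels.
#' @param cfg a [ransac_config()].
#' @return A list with `exact` (logical), `inliers` (indices),
#'   `H` (fitted homography).
#' @export
planted_outlier_trial <- function(seed, n_in = 24L, n_out = 6L,
                                  displacement = 20,
                                  cfg = ransac_config()) {
  n <- n_in + n_out
  dat <- with_seed(seed * 100L + 3L, {
    H <- matrix(c(1 + stats::rnorm(1, 0, 0.05), stats::rnorm(1, 0, 0.05),
                  stats::runif(1, -10, 10),
                  stats::rnorm(1, 0, 0.05), 1 + stats::rnorm(1, 0, 0.05),
                  stats::runif(1, -10, 10),
                  stats::rnorm(1, 0, 1e-4), stats::rnorm(1, 0, 1e-4), 1),
                3L, byrow = TRUE)
    xy <- cbind(stats::runif(n, 10, 246), stats::runif(n, 10, 246))
    uv <- apply_homography(H, xy)
    ang <- stats::runif(n_out, 0, 2 * pi)
    dd <- displacement + stats::runif(n_out, 0, 20)
    idx <- (n_in + 1L):n
    uv[idx, ] <- uv[idx, ] + cbind(dd * cos(ang), dd * sin(ang))
    list(xy = xy, uv = uv)
  })
  kr <- data.frame(x = dat$xy[, 1L], y = dat$xy[, 2L], theta = 0)
  kt <- data.frame(x = dat$uv[, 1L], y = dat$uv[, 2L], theta = 0)
  m <- match_set(seq_len(n), seq_len(n), seq(0, 0.1, length.out = n))
  cfg$seed <- seed
  fit <- ransac_refine(m, kr, kt, cfg)
  planted <- sort(fit$matches$ref)
  list(exact = identical(planted, seq_len(n_in)),
       inliers = planted, H = fit$H)
}
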