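#' RANSAC configuration
#'
#' Bundles the tunables of the trimmed-RANSAC mismatch-removal stage
#' (and, with a different `sample_size`, of the eight-point fundamental
#' stage): the fraction of worst-quality pairs dropped before sampling,
#' the minimal sample size, the inlier residual threshold in pixels,
#' the iteration budget with adaptive early stopping, and the seed that
#' makes runs bit-reproducible.
#'
#' @param trim_fraction fraction of pairs (worst descriptor distance)
#'   deleted before RANSAC; default 0.2.
#' @param sample_size minimal sample size; 4 determines a homography.
#' @param inlier_threshold residual threshold in pixels; default 2.
#' @param max_iterations hard iteration cap (default 2000).
#' @param confidence adaptive-stopping confidence (default 0.995).
#' @param seed integer RNG seed (default 1).
#' @return A `ransac_config` list.
#' @export
ransac_config <- function(trim_fraction = 0.2, sample_size = 4L,
                          inlier_threshold = 2, max_iterations = 2000L,
                          confidence = 0.995, seed = 1L) {
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("`trim_fraction` must be in [0, 1)", call. = FALSE)
  if (sample_size < 4L) stop("`sample_size` must be >= 4", call. = FALSE)
  if (inlier_threshold <= 0)
    stop("`inlier_threshold` must be positive", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  structure(list(trim_fraction = trim_fraction,
                 sample_size = as.integer(sample_size),
                 inlier_threshold = inlier_threshold,
                 max_iterations = as.integer(max_iterations),
                 confidence = confidence, seed = as.integer(seed)),
            class = "ransac_config")
}

#' Trim the worst-quality matches
#'
#' Matches are kept sorted by ascending descriptor distance (the
#' matching-quality order); the worst `floor(trim_fraction * N)` pairs
#' are deleted and the ordering of the survivors is preserved.
#'
#' @param matches a `match_set` sorted by `desc_distance`.
#' @param trim_fraction fraction to remove (default 0.2).
#' @return The trimmed `match_set`.
#' @export
trim_matches <- function(matches, trim_fraction = 0.2) {
  n <- nrow(matches)
  if (n == 0L) return(new_match_set(as.data.frame(matches), "trim"))
  df <- as.data.frame(matches)
  df <- df[order(df$desc_distance), , drop = FALSE]
  n_drop <- floor(trim_fraction * n)
  keep <- seq_len(n - n_drop)
  new_match_set(df[keep, , drop = FALSE], "trim")
}

# seeded execution that never clobbers the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

collinear_triple <- function(pts, tol = 1e-8) {
  cmb <- utils::combn(nrow(pts), 3L)
  scale2 <- max(stats::dist(pts))^2
  if (scale2 == 0) return(TRUE)
  for (j in seq_len(ncol(cmb))) {
    a <- pts[cmb[1L, j], ]; b <- pts[cmb[2L, j], ]; cc <- pts[cmb[3L, j], ]
    area2 <- abs((b[1] - a[1]) * (cc[2] - a[2]) -
                 (b[2] - a[2]) * (cc[1] - a[1]))
    if (area2 < tol * scale2) return(TRUE)
  }
  FALSE
}

#' Exact homography from four point pairs
#'
#' Direct linear transform on exactly four correspondences, giving the
#' 3x3 plane-projective matrix that maps each reference point to its
#' target. The sample is rejected (an error of class
#' `ringsift_degenerate`) when any three of the four reference points
#' are collinear, since the homography is then under-determined.
#'
#' @param src,dst 4x2 matrices of 0-based pixel coordinates.
#' @return A 3x3 homography with `H[3, 3] == 1` (or unit Frobenius norm
#'   if that entry vanishes).
#' @export
fit_homography_minimal <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != 4L || nrow(dst) != 4L)
    stop("exactly 4 point pairs required", call. = FALSE)
  if (collinear_triple(src) || collinear_triple(dst))
    stop(structure(class = c("ringsift_degenerate", "error", "condition"),
                   list(message = "degenerate sample: collinear points",
                        call = sys.call(-1L))))
  homography_dlt(src, dst)
}

# DLT solve (n >= 4) without normalisation; see fit_homography for the
# Hartley-normalised least-squares version
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- src[i, 1L]; y <- src[i, 2L]; u <- dst[i, 1L]; v <- dst[i, 2L]
    A[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2L * i, ]      <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  hvec <- nullspace_min(A)
  H <- matrix(hvec, 3L, 3L, byrow = TRUE)
  normalize_homography(H)
}

# right singular vector of the smallest singular value (works for
# wide matrices too, where svd() would otherwise drop it)
nullspace_min <- function(A) {
  v <- svd(A, nu = 0L, nv = ncol(A))$v
  v[, ncol(A)]
}

normalize_homography <- function(H) {
  if (abs(H[3L, 3L]) > 1e-10) H / H[3L, 3L]
  else H / sqrt(sum(H^2))
}

#' Least-squares homography (normalised DLT)
#'
#' Hartley-normalised direct linear transform over all supplied pairs;
#' used by the RANSAC refit step.
#'
#' @param src,dst nx2 coordinate matrices, n >= 4.
#' @return A 3x3 homography.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4L) stop("need at least 4 pairs", call. = FALSE)
  n1 <- hartley_normalization(src)
  n2 <- hartley_normalization(dst)
  Hn <- homography_dlt(apply_homography(n1$T, src),
                       apply_homography(n2$T, dst))
  normalize_homography(solve(n2$T) %*% Hn %*% n1$T)
}

hartley_normalization <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1L],
                0, s, -s * ctr[2L],
                0, 0, 1), 3L, 3L, byrow = TRUE)
  list(T = T, scale = s, center = ctr)
}

#' Apply a homography to 2-D points
#'
#' @param H 3x3 matrix.
#' @param xy nx2 matrix (or length-2 vector) of points.
#' @return nx2 matrix of mapped points.
#' @export
apply_homography <- function(H, xy) {
  xy <- if (is.null(dim(xy))) matrix(xy, 1L) else as.matrix(xy)
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3L]
}

homography_residuals <- function(H, src, dst) {
  fwd <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
  bwd <- sqrt(rowSums((apply_homography(solve(H), dst) - src)^2))
  list(forward = fwd, backward = bwd)
}

#' Trimmed RANSAC refinement of a match set
#'
#' Repeatedly samples 4 non-degenerate pairs, fits an exact homography,
#' and scores it by the number of pairs whose symmetric transfer
#' distance (forward and backward each) is below `inlier_threshold`.
#' The iteration count adapts to the best consensus found (standard
#' stopping rule at `confidence`, capped at `max_iterations`). The best
#' model is then refit by least squares on its inliers and
#' re-classified until the inlier set is stable. Output is bit-identical
#' for a fixed seed. Trimming ([trim_matches()]) is the caller's first
#' step; this function assumes it already happened when used inside the
#' full pipeline.
#'
#' @param matches a `match_set`.
#' @param kps_ref,kps_tgt keypoint tables the match indices refer to.
#' @param cfg a [ransac_config()].
#' @return A list of class `ransac_fit`: `matches` (inlier
#'   `match_set`), `H` (3x3), `inliers` (row indices into the input),
#'   `iterations`.
#' @export
ransac_refine <- function(matches, kps_ref, kps_tgt, cfg = ransac_config()) {
  n <- nrow(matches)
  if (n <= cfg$sample_size)
    stop(structure(class = c("ringsift_too_few_matches", "error", "condition"),
                   list(message = paste0("too few matches for RANSAC: ", n,
                                         " <= sample size ", cfg$sample_size),
                        call = sys.call(-1L))))
  src <- cbind(kps_ref$x[matches$ref], kps_ref$y[matches$ref])
  dst <- cbind(kps_tgt$x[matches$tgt], kps_tgt$y[matches$tgt])
  res <- with_seed(cfg$seed,
                   ransac_loop(src, dst, cfg,
                               fit_min = function(s, d) fit_homography_minimal(s, d),
                               fit_ls = function(s, d) fit_homography(s, d),
                               resid = function(M, s, d) {
                                 r <- homography_residuals(M, s, d)
                                 pmax(r$forward, r$backward)
                               }))
  if (is.null(res))
    stop(structure(class = c("ringsift_no_consensus", "error", "condition"),
                   list(message = "RANSAC found no consensus model",
                        call = sys.call(-1L))))
  df <- as.data.frame(matches)[res$inliers, , drop = FALSE]
  structure(list(matches = new_match_set(df, "ransac"),
                 H = res$model, inliers = res$inliers,
                 iterations = res$iterations),
            class = "ransac_fit")
}

# generic RANSAC engine shared by the homography and fundamental stages
ransac_loop <- function(src, dst, cfg, fit_min, fit_ls, resid) {
  n <- nrow(src)
  m <- cfg$sample_size
  best_inl <- integer(0)
  best_score <- -Inf
  it <- 0L
  max_it <- cfg$max_iterations
  consecutive_degenerate <- 0L
  while (it < max_it) {
    it <- it + 1L
    smp <- sample.int(n, m)
    M <- tryCatch(fit_min(src[smp, , drop = FALSE], dst[smp, , drop = FALSE]),
                  ringsift_degenerate = function(e) NULL,
                  error = function(e) NULL)
    if (is.null(M)) {
      consecutive_degenerate <- consecutive_degenerate + 1L
      if (consecutive_degenerate > 200L) break
      next
    }
    consecutive_degenerate <- 0L
    r <- resid(M, src, dst)
    inl <- which(is.finite(r) & r < cfg$inlier_threshold)
    score <- length(inl) - sum(r[inl]) / (cfg$inlier_threshold * n)
    if (score > best_score) {
      best_score <- score
      best_inl <- inl
      w <- length(inl) / n
      if (w > 0) {
        denom <- log1p(-min(w^m, 1 - 1e-12))
        need <- ceiling(log(1 - cfg$confidence) / denom)
        max_it <- min(cfg$max_iterations, max(it, need))
      }
    }
  }
  if (length(best_inl) <= m) return(NULL)
  # refit on the consensus and re-classify until the inlier set is stable;
  # the returned inliers are always classified under the returned model
  inl <- best_inl
  final_M <- NULL; final_inl <- integer(0)
  for (pass in 1:20) {
    M <- tryCatch(fit_ls(src[inl, , drop = FALSE], dst[inl, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(M)) break
    r <- resid(M, src, dst)
    new_inl <- which(is.finite(r) & r < cfg$inlier_threshold)
    if (length(new_inl) <= m) break
    final_M <- M; final_inl <- new_inl
    if (identical(new_inl, inl)) break
    inl <- new_inl
  }
  if (is.null(final_M)) return(NULL)
  list(model = final_M, inliers = final_inl, iterations = it)
}
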