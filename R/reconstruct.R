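#' Match two described images through all filtering stages
#'
#' Runs the full correspondence chain — NNDR initial matching,
#' neighbourhood-voting consistency filter, 20% distance trim, and the
#' RANSAC homography stage — returning the surviving match set of each
#' stage together with the fitted homography.
#'
#' @param det_a,det_b results of [detect_and_describe()] for the
#'   reference and target image.
#' @param config a [pipeline_config()].
#' @return A list of class `match_result`: `stages` (named list of
#'   `match_set`s: nndr, vote, trim, ransac), `H`, `counts`,
#'   `keypoints_ref`, `keypoints_tgt`.
#' @export
match_images <- function(det_a, det_b, config = pipeline_config()) {
  m_nndr <- nndr_match(det_a$descriptors, det_b$descriptors,
                       config$nndr_ratio)
  m_vote <- vote_filter(m_nndr, det_a$keypoints, det_b$keypoints,
                        T_theta = config$T_theta, T_d = config$T_d)
  m_trim <- trim_matches(m_vote, config$trim_fraction)
  fit <- ransac_refine(m_trim, det_a$keypoints, det_b$keypoints,
                       homography_ransac_config(config))
  stages <- list(nndr = m_nndr, vote = m_vote, trim = m_trim,
                 ransac = fit$matches)
  structure(list(stages = stages, H = fit$H,
                 counts = vapply(stages, nrow, integer(1L)),
                 keypoints_ref = det_a$keypoints,
                 keypoints_tgt = det_b$keypoints),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "),
      ">\n", sep = "")
  invisible(x)
}

match_coords <- function(mr, stage = "ransac") {
  m <- mr$stages[[stage]]
  list(ref = cbind(mr$keypoints_ref$x[m$ref], mr$keypoints_ref$y[m$ref]),
       tgt = cbind(mr$keypoints_tgt$x[m$tgt], mr$keypoints_tgt$y[m$tgt]),
       ref_idx = m$ref, tgt_idx = m$tgt)
}

default_intrinsics <- function(img) {
  f <- 1.2 * max(img$width, img$height)
  camera_intrinsics(matrix(c(f, 0, (img$width - 1) / 2,
                             0, f, (img$height - 1) / 2,
                             0, 0, 1), 3L, byrow = TRUE))
}

#' Sparse reconstruction from two or three images
#'
#' The full pipeline: preprocessing and description of each image,
#' staged matching of the first pair, RANSAC eight-point epipolar
#' geometry, essential-matrix pose recovery (unit baseline),
#' triangulation, and — with a third image — registration of view 3 by
#' RANSAC DLT-PnP against the already-triangulated structure followed
#' by triangulation of the new view-2/view-3 tracks. Points must have
#' positive depth in their views and reprojection error below
#' `config$reproj_ceiling` to enter the cloud.
#'
#' @param images list of 2 or 3 [gray_image]s or image file paths.
#' @param K a [camera_intrinsics()] matrix shared by all views, or
#'   `NULL` to fall back to an approximate guess (focal =
#'   `1.2 * max(width, height)`, principal point at the image centre),
#'   flagged `approximate_k` in the result.
#' @param config a [pipeline_config()].
#' @return An object of class `reconstruction`: `cloud`
#'   ([point_cloud()]), `poses` (per image `R`, `t`; image 1 is the
#'   world frame), `geometry` (the first pair's `two_view_geometry`),
#'   `report` (stage counts, inlier ratios, mean reprojection error,
#'   point count), `approximate_k`.
#' @export
reconstruct <- function(images, K = NULL, config = pipeline_config()) {
  if (!is.list(images) || length(images) < 2L || length(images) > 3L)
    stop("`images` must be a list of 2 or 3 images or paths", call. = FALSE)
  images <- lapply(images, function(im)
    if (is.character(im)) load_gray(im) else as_gray_image(im))
  approximate_k <- is.null(K)
  if (approximate_k) K <- default_intrinsics(images[[1L]])
  K <- camera_intrinsics(K)

  stage <- "detect"
  dets <- lapply(images, detect_and_describe, config = config)

  stage <- "match(1,2)"
  mr12 <- wrap_stage(stage, match_images(dets[[1L]], dets[[2L]], config))
  co <- match_coords(mr12, "ransac")
  if (nrow(co$ref) < 8L)
    stop("reconstruction failure at ", stage, ": fewer than 8 surviving ",
         "matches", call. = FALSE)

  stage <- "two-view geometry"
  geom <- wrap_stage(stage,
                     two_view_geometry(co$ref, co$tgt, K,
                                       cfg = epipolar_ransac_config(config)))
  tri <- geom$triangulated
  ok <- tri$finite & !is.na(tri$depth1) & tri$depth1 > 0 & tri$depth2 > 0 &
    tri$err1 < config$reproj_ceiling & tri$err2 < config$reproj_ceiling
  ok[is.na(ok)] <- FALSE
  pts <- tri$X[ok, , drop = FALSE]
  kp1_ids <- co$ref_idx[geom$inliers][ok]
  kp2_ids <- co$tgt_idx[geom$inliers][ok]
  errs <- c(tri$err1[ok], tri$err2[ok])
  tracks <- lapply(seq_len(nrow(pts)), function(i)
    cbind(image_id = c(1L, 2L), keypoint_id = c(kp1_ids[i], kp2_ids[i])))
  gray_at <- function(img, kps, ids) {
    v <- bilinear_sample(img$pixels, kps$x[ids], kps$y[ids])
    v[is.na(v)] <- 128
    cbind(v, v, v)
  }
  cols <- gray_at(images[[1L]], dets[[1L]]$keypoints, kp1_ids)
  poses <- list(list(R = diag(3L), t = c(0, 0, 0)),
                list(R = geom$R, t = geom$t))
  report <- list(
    n_keypoints = vapply(dets, function(d) nrow(d$keypoints), integer(1L)),
    counts_12 = as.list(mr12$counts),
    epipolar_inliers = length(geom$inliers),
    epipolar_inlier_ratio = length(geom$inliers) / nrow(co$ref),
    approximate_k = approximate_k)

  if (length(images) == 3L) {
    stage <- "match(2,3)"
    mr23 <- wrap_stage(stage, match_images(dets[[2L]], dets[[3L]], config))
    co23 <- match_coords(mr23, "ransac")
    # keypoints of image 2 that already have 3-D structure
    idx_in_cloud <- match(co23$ref_idx, kp2_ids)
    known <- !is.na(idx_in_cloud)
    stage <- "register view 3 (PnP)"
    if (sum(known) < 7L)
      stop("reconstruction failure at ", stage, ": only ", sum(known),
           " 2D-3D correspondences", call. = FALSE)
    pnp <- wrap_stage(stage,
                      pnp_ransac(pts[idx_in_cloud[known], , drop = FALSE],
                                 co23$tgt[known, , drop = FALSE], K,
                                 epipolar_ransac_config(config)))
    poses[[3L]] <- list(R = pnp$R, t = pnp$t)
    P2 <- geom$P2
    P3 <- camera_projection(K, pnp$R, pnp$t)
    # extend tracks observed in view 3
    known_rows <- which(known)[pnp$inliers]
    for (r in known_rows) {
      ci <- idx_in_cloud[r]
      tracks[[ci]] <- rbind(tracks[[ci]],
                            c(3L, co23$tgt_idx[r]))
    }
    # triangulate brand-new view-2/view-3 tracks
    new_rows <- which(!known)
    if (length(new_rows) > 0L) {
      t3 <- triangulate_points(P2, P3,
                               co23$ref[new_rows, , drop = FALSE],
                               co23$tgt[new_rows, , drop = FALSE])
      ok3 <- t3$finite & !is.na(t3$depth1) & t3$depth1 > 0 & t3$depth2 > 0 &
        t3$err1 < config$reproj_ceiling & t3$err2 < config$reproj_ceiling
      ok3[is.na(ok3)] <- FALSE
      if (any(ok3)) {
        nr <- new_rows[ok3]
        pts <- rbind(pts, t3$X[ok3, , drop = FALSE])
        errs <- c(errs, t3$err1[ok3], t3$err2[ok3])
        tracks <- c(tracks, lapply(seq_along(nr), function(i)
          cbind(image_id = c(2L, 3L),
                keypoint_id = c(co23$ref_idx[nr[i]], co23$tgt_idx[nr[i]]))))
        cols <- rbind(cols, gray_at(images[[2L]], dets[[2L]]$keypoints,
                                    co23$ref_idx[nr]))
      }
    }
    report$counts_23 <- as.list(mr23$counts)
    report$pnp_inliers <- length(pnp$inliers)
  }

  report$n_points <- nrow(pts)
  report$mean_reprojection_error <- mean(errs)
  structure(list(cloud = point_cloud(pts, colors = cols, tracks = tracks),
                 poses = poses, geometry = geom, matches = mr12,
                 report = report, K = K, approximate_k = approximate_k),
            class = "reconstruction")
}

wrap_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("reconstruction failure at ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction: %d points, %d views, mean reproj %.3f px%s>\n",
              x$report$n_points, length(x$poses),
              x$report$mean_reprojection_error,
              if (x$approximate_k) ", approximate K" else ""))
  invisible(x)
}

#' Geometry-only reconstruction of a synthetic rig
#'
#' Runs the epipolar half of the pipeline on a [make_rig()] fixture's
#' observations (the correspondences are known, so the descriptor
#' stages are bypassed): RANSAC eight-point `F` on the bootstrap pair,
#' essential-matrix pose, triangulation, and — for a 3-camera rig —
#' PnP registration of the remaining view followed by multi-view
#' re-triangulation of every track. With three cameras the bootstrap
#' pair is views 1 and 3: on an arc they have twice the baseline of
#' adjacent views, and the initial pair's conditioning dominates the
#' accuracy of everything downstream (the usual initial-pair selection
#' rule of incremental structure from motion). Useful for measuring
#' pose and structure recovery against the planted ground truth.
#'
#' @param rig a `rig_fixture`.
#' @param cfg a [ransac_config()] (Sampson/reprojection threshold in
#'   pixels).
#' @param reproj_ceiling acceptance ceiling for triangulated points, px.
#' @return A list: `points` (planted-index-aligned nx3 matrix, NA rows
#'   for unrecovered points), `recovered` (logical), `poses`, `R`, `t`
#'   (first-pair relative pose), `inliers`.
#' @export
reconstruct_rig <- function(rig, cfg = ransac_config(),
                            reproj_ceiling = 2 * cfg$inlier_threshold) {
  stopifnot(inherits(rig, "rig_fixture"))
  K <- rig$K
  n_cam <- length(rig$observations)
  boot <- if (n_cam >= 3L) c(1L, 3L) else c(1L, 2L)
  oa <- rig$observations[[boot[1L]]]; ob <- rig$observations[[boot[2L]]]
  geom <- two_view_geometry(oa, ob, K, cfg = cfg)
  n <- nrow(oa)
  pts <- matrix(NA_real_, n, 3L)
  tri <- geom$triangulated
  ok <- tri$finite & tri$depth1 > 0 & tri$depth2 > 0 &
    tri$err1 < reproj_ceiling & tri$err2 < reproj_ceiling
  ok[is.na(ok)] <- FALSE
  pts[geom$inliers[ok], ] <- tri$X[ok, , drop = FALSE]
  poses <- vector("list", n_cam)
  poses[[boot[1L]]] <- list(R = diag(3L), t = c(0, 0, 0))
  poses[[boot[2L]]] <- list(R = geom$R, t = geom$t)
  if (n_cam >= 3L) {
    mid <- setdiff(seq_len(n_cam), boot)[1L]
    om <- rig$observations[[mid]]
    have <- which(!is.na(pts[, 1L]))
    # the 3-D input is itself noisy; the PnP tolerance floor is the
    # reprojection ceiling and pnp_ransac adapts it upward to the
    # structure noise when needed
    pnp_cfg <- cfg
    pnp_cfg$inlier_threshold <- reproj_ceiling
    pnp <- pnp_ransac(pts[have, , drop = FALSE], om[have, , drop = FALSE],
                      K, pnp_cfg)
    poses[[mid]] <- list(R = pnp$R, t = pnp$t)
    # with all poses known, re-triangulate every track from all of its
    # observations (widest baseline, noise averaged down)
    Ps <- lapply(poses, function(p) camera_projection(K, p$R, p$t))
    obs <- rig$observations
    for (i in seq_len(n)) {
      X <- triangulate_multiview(Ps, do.call(rbind, lapply(obs, function(o)
        o[i, ])))
      if (is.null(X)) next
      good <- vapply(seq_along(Ps), function(v) {
        Xh <- Ps[[v]] %*% c(X, 1)
        Xh[3L] > 0 && sqrt(sum((Xh[1:2] / Xh[3L] - obs[[v]][i, ])^2)) <
          max(reproj_ceiling, pnp$threshold)
      }, logical(1L))
      if (sum(good) >= 2L) pts[i, ] <- X else pts[i, ] <- NA_real_
    }
  }
  list(points = pts, recovered = !is.na(pts[, 1L]), poses = poses,
       R = geom$R, t = geom$t, inliers = geom$inliers, geometry = geom,
       bootstrap_pair = boot)
}
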