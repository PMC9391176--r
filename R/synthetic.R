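#' Deterministic synthetic texture images
#'
#' Generates textured grayscale images rich enough for the keypoint
#' detector to latch onto, as stand-ins for real multi-view imagery.
#' Three styles are available: `"filtered-noise"` (Gaussian-smoothed
#' white noise, a dense isotropic texture), `"blobs"` (Gaussian spots of
#' random polarity on a mid-gray background, with a minimum separation
#' so each blob yields its own detection), and `"checker-noise"`
#' (a checkerboard perturbed by smoothed noise). All styles are pure
#' functions of their arguments including `seed`.
#'
#' @param width,height image size in pixels, each at least 64.
#' @param seed integer RNG seed.
#' @param style texture family.
#' @param n_blobs number of spots for the `"blobs"` style.
#' @return A [gray_image].
#' @export
make_texture <- function(width = 256L, height = 256L, seed = 1L,
                         style = c("filtered-noise", "blobs",
                                   "checker-noise"),
                         n_blobs = 40L) {
  style <- match.arg(style)
  if (width < 64L || height < 64L)
    stop("texture must be at least 64x64", call. = FALSE)
  px <- with_seed(seed, switch(style,
    "filtered-noise" = {
      # three-octave mixture: fine speckle for dense detections plus
      # coarser structure that survives blur degradations up to
      # sigma ~2; histogram-equalised for full contrast
      z <- 0.45 * rescale01(gaussian_blur(
             matrix(stats::runif(height * width), height, width), 1.5)) +
           0.35 * rescale01(gaussian_blur(
             matrix(stats::runif(height * width), height, width), 4)) +
           0.20 * rescale01(gaussian_blur(
             matrix(stats::runif(height * width), height, width), 10))
      matrix(255 * (rank(z) - 1) / (length(z) - 1), height, width)
    },
    "blobs" = {
      bg <- matrix(128, height, width)
      centers <- poisson_disc(n_blobs, width, height, min_sep = 28)
      ys <- matrix(seq_len(height) - 1, height, width)
      xs <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
      for (i in seq_len(nrow(centers))) {
        sg <- stats::runif(1, 2.5, 4)
        amp <- sample(c(-1, 1), 1L) * stats::runif(1, 95, 125)
        bg <- bg + amp * exp(-((xs - centers[i, 1L])^2 +
                               (ys - centers[i, 2L])^2) / (2 * sg^2))
      }
      pmin(pmax(bg, 0), 255)
    },
    "checker-noise" = {
      ys <- matrix(seq_len(height) - 1, height, width)
      xs <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
      board <- ifelse(((xs %/% 16) + (ys %/% 16)) %% 2 == 0, 90, 170)
      noise <- gaussian_blur(matrix(stats::rnorm(height * width, 0, 30),
                                    height, width), 1)
      pmin(pmax(board + noise, 0), 255)
    }))
  out <- gray_image(px)
  if (style == "blobs")
    attr(out, "blob_centers") <-
      with_seed(seed, poisson_disc(n_blobs, width, height, min_sep = 28))
  out
}

rescale01 <- function(z) {
  rng <- range(z)
  if (diff(rng) == 0) return(z * 0)
  (z - rng[1L]) / diff(rng)
}

# rejection-sampled centers with a minimum pairwise separation,
# kept away from the border so blob support stays in frame
poisson_disc <- function(n, width, height, min_sep) {
  pts <- matrix(NA_real_, 0L, 2L)
  tries <- 0L
  while (nrow(pts) < n && tries < 20000L) {
    tries <- tries + 1L
    p <- c(stats::runif(1, 20, width - 21), stats::runif(1, 20, height - 21))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2)) >= min_sep)
      pts <- rbind(pts, p)
  }
  unname(pts)
}

#' Warped image pair with exact ground-truth homography
#'
#' Produces a fixture for matcher tests: `image_b` is `image_a` mapped
#' through a known homography (bilinear resampling) and/or degraded
#' (blur, gamma), with `H_true` recorded so a candidate correspondence
#' `(p_a, p_b)` can be labelled correct iff
#' `|H_true p_a - p_b| <= 2` px. `valid_region` marks the pixels of
#' `image_a` that land inside `image_b`.
#'
#' @param base a [gray_image] to warp.
#' @param transform a list with `type` in `"identity"`, `"rotation"`
#'   (`theta`, radians, about the image centre), `"scale"` (`s`, about
#'   the centre), `"projective"` (`H`, a 3x3 matrix), `"blur"`
#'   (`sigma`), `"gamma"` (`g`); geometric and photometric entries may
#'   be combined by also supplying `blur_sigma` / `gamma` alongside a
#'   geometric type.
#' @param seed unused at present (degradations are deterministic);
#'   kept so fixtures are fully specified by their arguments.
#' @return A `warp_fixture` list: `image_a`, `image_b`, `H_true`,
#'   `valid_region`, `transform`.
#' @export
make_warp_pair <- function(base, transform = list(type = "identity"),
                           seed = 0L) {
  base <- as_gray_image(base)
  w <- base$width; h <- base$height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  type <- transform$type %||% "identity"
  H <- switch(type,
    identity = diag(3L),
    rotation = {
      th <- transform$theta
      Tn <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3L, byrow = TRUE)
      Rt <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                   3L, byrow = TRUE)
      Tp <- matrix(c(1, 0, cx, 0, 1, cy, 0, 0, 1), 3L, byrow = TRUE)
      Tp %*% Rt %*% Tn
    },
    scale = {
      s <- transform$s
      matrix(c(s, 0, cx * (1 - s), 0, s, cy * (1 - s), 0, 0, 1),
             3L, byrow = TRUE)
    },
    projective = normalize_homography(as.matrix(transform$H)),
    blur = diag(3L),
    gamma = diag(3L),
    stop("unknown transform type: ", type, call. = FALSE))

  px <- base$pixels
  if (!identical(H, diag(3L)) && sum((H - diag(3L))^2) > 0) {
    Hinv <- solve(H)
    ys <- rep(seq_len(h) - 1, times = w)
    xs <- rep(seq_len(w) - 1, each = h)
    src <- apply_homography(Hinv, cbind(xs, ys))
    vals <- bilinear_sample(px, src[, 1L], src[, 2L])
    vals[is.na(vals)] <- 0
    out <- matrix(vals, h, w)
  } else out <- px

  bs <- if (type == "blur") transform$sigma else transform$blur_sigma
  if (!is.null(bs) && bs > 0) out <- gaussian_blur(out, bs)
  gm <- if (type == "gamma") transform$g else transform$gamma
  if (!is.null(gm)) out <- 255 * (pmin(pmax(out, 0), 255) / 255)^gm

  ys <- rep(seq_len(h) - 1, times = w)
  xs <- rep(seq_len(w) - 1, each = h)
  fwd <- apply_homography(H, cbind(xs, ys))
  valid <- matrix(fwd[, 1L] >= 0 & fwd[, 1L] <= w - 1 &
                  fwd[, 2L] >= 0 & fwd[, 2L] <= h - 1, h, w)
  if (mean(valid) < 0.25)
    stop("warp maps less than 25% of pixels into frame; fixture rejected",
         call. = FALSE)
  structure(list(image_a = base, image_b = gray_image(out),
                 H_true = H, valid_region = valid, transform = transform),
            class = "warp_fixture")
}

#' Multi-view camera rig with planted 3-D geometry
#'
#' Samples `n_points` 3-D points inside a sphere of unit diameter
#' centred at the origin, places 2 or 3 cameras on a circular arc
#' (default 10 degrees apart, i.e. scene depth about 5 baselines) all
#' aimed at the scene centre, and projects every point through every
#' camera, optionally adding seeded Gaussian pixel noise. The camera
#' model is a calibrated DSLR-class sensor (3072x2048, 2760 px focal
#' length, the capture geometry of the classic fountain benchmark);
#' every planted point is guaranteed to project inside the image
#' bounds of every camera, with margin for noise, and observations are
#' bit-reproducible from the seed.
#' Ground-truth relative essential/fundamental matrices for the first
#' camera pair are emitted alongside.
#'
#' @param n_points number of 3-D points (>= 20).
#' @param n_cameras 2 or 3.
#' @param noise_sigma observation noise standard deviation in pixels.
#' @param seed integer seed.
#' @param separation_deg angular camera separation on the arc.
#' @return A `rig_fixture`: `points3d` (nx3), `cameras` (list of
#'   `K`, `R`, `t`, with `x_cam = R x_world + t`), `observations`
#'   (list of nx2), `E12`, `F12`, `seed`.
#' @export
make_rig <- function(n_points = 50L, n_cameras = 2L, noise_sigma = 0,
                     seed = 1L, separation_deg = 10) {
  if (n_points < 20L) stop("`n_points` must be >= 20", call. = FALSE)
  if (!n_cameras %in% c(2L, 3L))
    stop("`n_cameras` must be 2 or 3", call. = FALSE)
  # calibrated DSLR-class camera: 3072x2048 sensor, 2760 px focal
  # (matches the capture geometry of the classic fountain benchmark)
  K <- camera_intrinsics(matrix(c(2760, 0, 1536,
                                  0, 2760, 1024,
                                  0, 0, 1), 3L, byrow = TRUE))
  dist <- 2.5
  angles <- if (n_cameras == 2L)
    c(-separation_deg / 2, separation_deg / 2) * pi / 180
  else c(-separation_deg, 0, separation_deg) * pi / 180
  cams <- lapply(angles, function(a) {
    C <- dist * c(sin(a), 0, -cos(a))
    z <- -C / sqrt(sum(C^2))            # toward the origin
    xax <- c(z[3L], 0, -z[1L]); xax <- xax / sqrt(sum(xax^2))
    yax <- c(z[2L] * xax[3L] - z[3L] * xax[2L],
             z[3L] * xax[1L] - z[1L] * xax[3L],
             z[1L] * xax[2L] - z[2L] * xax[1L])
    R <- rbind(xax, yax, z); dimnames(R) <- NULL
    list(K = K, R = R, t = as.numeric(-R %*% C), C = C)
  })
  pts <- with_seed(seed, {
    out <- matrix(NA_real_, 0L, 3L)
    while (nrow(out) < n_points) {
      cand <- matrix(stats::runif(3L * n_points * 2L, -0.5, 0.5),
                     ncol = 3L)
      cand <- cand[rowSums(cand^2) <= 0.45^2, , drop = FALSE]
      ok <- apply(cand, 1L, function(X)
        all(vapply(cams, function(cm) {
          p <- project_point(cm, X)
          p[3L] > 0 && p[1L] >= 32 && p[1L] <= 3039 &&
            p[2L] >= 32 && p[2L] <= 2015
        }, logical(1L))))
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n_points), , drop = FALSE]
  })
  obs <- with_seed(seed + 1L, lapply(cams, function(cm) {
    Xh <- cbind(pts, 1) %*% t(camera_projection(cm$K, cm$R, cm$t))
    o <- cbind(Xh[, 1L] / Xh[, 3L], Xh[, 2L] / Xh[, 3L])
    if (noise_sigma > 0)
      o <- o + matrix(stats::rnorm(length(o), 0, noise_sigma), ncol = 2L)
    o
  }))
  R12 <- cams[[2L]]$R %*% t(cams[[1L]]$R)
  t12 <- cams[[2L]]$t - R12 %*% cams[[1L]]$t
  structure(list(points3d = pts, cameras = cams, observations = obs,
                 E12 = essential_from_pose(R12, as.numeric(t12)),
                 F12 = fundamental_from_pose(R12, as.numeric(t12), K, K),
                 R12 = R12, t12 = as.numeric(t12),
                 K = K, noise_sigma = noise_sigma, seed = seed),
            class = "rig_fixture")
}

project_point <- function(cam, X) {
  p <- cam$K %*% (cam$R %*% X + cam$t)
  c(p[1L] / p[3L], p[2L] / p[3L], p[3L])
}

#' Rendered multi-view scene over a textured relief surface
#'
#' Ray-casts 2 or 3 pinhole views of a textured height-field surface
#' `z(x, y) = z0 + A * g(x, y)` (smooth random relief `g` in
#' `[-1, 1]`), giving photometrically consistent images with known
#' camera poses and an exact pixel-to-surface ground-truth mapping —
#' the full-pipeline analogue of [make_rig()]. Cameras translate along
#' x with a slight toe-in so all aim at the surface centre.
#'
#' @param n_views 2 or 3.
#' @param size square image side in pixels.
#' @param seed integer seed for texture and relief.
#' @param relief_amplitude `A`, in world units (surface extent ~3).
#' @param baseline camera spacing along x in world units.
#' @return A `scene_fixture`: `images` (list of [gray_image]), `K`,
#'   `cameras` (R, t per view), and `surface_point(view, xy)` mapping
#'   0-based pixel coordinates to ground-truth 3-D surface points.
#' @export
make_relief_scene <- function(n_views = 3L, size = 256L, seed = 1L,
                              relief_amplitude = 0.35, baseline = 0.25) {
  if (!n_views %in% c(2L, 3L)) stop("`n_views` must be 2 or 3", call. = FALSE)
  z0 <- 3
  f <- size
  K <- camera_intrinsics(matrix(c(f, 0, (size - 1) / 2,
                                  0, f, (size - 1) / 2,
                                  0, 0, 1), 3L, byrow = TRUE))
  ext <- 2.2   # textured half-extent in world units
  ngrid <- 768L
  # two-octave texture so features survive the renderer's ~2:1
  # texture-to-pixel sampling and populate several detector scales
  tex <- with_seed(seed, {
    z1 <- gaussian_blur(matrix(stats::runif(ngrid * ngrid), ngrid, ngrid), 4)
    z2 <- gaussian_blur(matrix(stats::runif(ngrid * ngrid), ngrid, ngrid),
                        12)
    z <- 0.6 * rescale01(z1) + 0.4 * rescale01(z2)
    # histogram-equalise: blurred noise is strongly mid-weighted and
    # would render with too little contrast for the detector
    matrix(255 * (rank(z) - 1) / (length(z) - 1), ngrid, ngrid)
  })
  relief <- with_seed(seed + 1L, {
    z <- gaussian_blur(matrix(stats::rnorm(96L * 96L), 96L, 96L), 6)
    2 * rescale01(z) - 1
  })
  # world (x, y) in [-ext, ext] -> bilinear samples of the two grids
  grid_sample <- function(gridm, x, y) {
    n <- nrow(gridm)
    gx <- (x + ext) / (2 * ext) * (n - 1)
    gy <- (y + ext) / (2 * ext) * (n - 1)
    gx <- pmin(pmax(gx, 0), n - 1); gy <- pmin(pmax(gy, 0), n - 1)
    bilinear_sample(gridm, gx, gy)
  }
  height_at <- function(x, y) z0 + relief_amplitude * grid_sample(relief, x, y)

  xs0 <- if (n_views == 2L) c(-baseline / 2, baseline / 2)
         else c(-baseline, 0, baseline)
  cams <- lapply(xs0, function(x0) {
    C <- c(x0, 0, 0)
    phi <- atan2(x0, z0)   # toe-in about y so the axis hits (0, 0, z0)
    R <- matrix(c(cos(phi), 0, -sin(phi),
                  0, 1, 0,
                  sin(phi), 0, cos(phi)), 3L, byrow = TRUE)
    list(R = R, t = as.numeric(-R %*% C), C = C)
  })

  cast <- function(cam, u, v) {
    Kinv <- solve(K)
    d <- cbind(u, v, 1) %*% t(Kinv) %*% cam$R  # world-frame ray directions
    x <- y <- rep(NA_real_, length(u))
    zt <- rep(z0, length(u))
    for (iter in 1:5) {
      tpar <- (zt - cam$C[3L]) / d[, 3L]
      x <- cam$C[1L] + tpar * d[, 1L]
      y <- cam$C[2L] + tpar * d[, 2L]
      zt <- height_at(x, y)
    }
    cbind(x, y, zt)
  }

  uu <- rep(seq_len(size) - 1, each = size)   # column-major over (y, x)
  vv <- rep(seq_len(size) - 1, times = size)
  images <- lapply(cams, function(cam) {
    P <- cast(cam, uu, vv)
    vals <- grid_sample(tex, P[, 1L], P[, 2L])
    vals[is.na(vals)] <- 0
    gray_image(matrix(vals, size, size))
  })
  surface_point <- function(view, xy) {
    xy <- if (is.null(dim(xy))) matrix(xy, 1L) else as.matrix(xy)
    cast(cams[[view]], xy[, 1L], xy[, 2L])
  }
  structure(list(images = images, K = K, cameras = cams,
                 surface_point = surface_point, z0 = z0,
                 relief_amplitude = relief_amplitude, seed = seed),
            class = "scene_fixture")
}
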