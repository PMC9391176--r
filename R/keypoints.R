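#' Build a Gaussian / difference-of-Gaussian scale space
#'
#' Classical SIFT pyramid: each octave holds `layers_per_octave + 3`
#' Gaussian layers with scale steps `k = 2^(1/layers_per_octave)`,
#' adjacent layers are differenced into DoG layers, and the next octave
#' starts from the layer with twice the base scale downsampled by 2
#' (every other pixel). The input is assumed to carry a nominal blur of
#' 0.5 px; the first layer is brought up to `base_sigma` accordingly.
#'
#' @param img a [gray_image].
#' @param octaves number of octaves; default `NULL` derives it from the
#'   image size so the smallest octave is at least 8 px on a side.
#' @param layers_per_octave scale-space intervals per octave (>= 3).
#' @param base_sigma blur of the first layer of each octave, in pixels
#'   of that octave's grid.
#' @return A `scale_space` object: per octave, the Gaussian layer
#'   matrices, DoG matrices and octave-relative layer scales.
#' @export
build_scale_space <- function(img, octaves = NULL, layers_per_octave = 3L,
                              base_sigma = 1.6) {
  img <- as_gray_image(img)
  if (layers_per_octave < 3L)
    stop("`layers_per_octave` must be at least 3", call. = FALSE)
  if (base_sigma <= 0) stop("`base_sigma` must be positive", call. = FALSE)
  min_dim <- min(img$width, img$height)
  max_oct <- max(1L, floor(log2(min_dim / 8)) + 1L)
  if (is.null(octaves)) octaves <- max_oct
  if (octaves < 1L) stop("`octaves` must be at least 1", call. = FALSE)
  if (octaves > max_oct)
    stop("image of size ", img$width, "x", img$height, " supports at most ",
         max_oct, " octaves (requested ", octaves, ")", call. = FALSE)

  s <- as.integer(layers_per_octave)
  k <- 2^(1 / s)
  n_gauss <- s + 3L
  sigmas <- base_sigma * k^(seq_len(n_gauss) - 1L)
  # incremental blurs between successive layers within an octave
  inc <- c(NA, sqrt(sigmas[-1L]^2 - sigmas[-n_gauss]^2))

  assumed_blur <- 0.5
  cur <- gaussian_blur(img$pixels,
                       sqrt(max(base_sigma^2 - assumed_blur^2, 0.01)))
  oct_list <- vector("list", octaves)
  for (o in seq_len(octaves)) {
    gauss <- vector("list", n_gauss)
    gauss[[1L]] <- cur
    for (i in 2L:n_gauss)
      gauss[[i]] <- gaussian_blur(gauss[[i - 1L]], inc[i])
    dog <- vector("list", n_gauss - 1L)
    for (i in seq_len(n_gauss - 1L)) dog[[i]] <- gauss[[i + 1L]] - gauss[[i]]
    oct_list[[o]] <- list(gauss = gauss, dog = dog)
    if (o < octaves) {
      dsrc <- gauss[[s + 1L]]  # sigma = 2 * base_sigma
      cur <- dsrc[seq(1L, nrow(dsrc), by = 2L), seq(1L, ncol(dsrc), by = 2L)]
    }
  }
  structure(list(octaves = oct_list, n_octaves = octaves, n_intervals = s,
                 k = k, base_sigma = base_sigma, sigmas = sigmas,
                 width = img$width, height = img$height),
            class = "scale_space")
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf("<scale_space %d octaves x %d intervals, base sigma %.2f>\n",
              x$n_octaves, x$n_intervals, x$base_sigma))
  invisible(x)
}

# 3x3 neighbourhood shift with edge replication
shift_mat <- function(A, dy, dx) {
  h <- nrow(A); w <- ncol(A)
  ry <- pmin(pmax(seq_len(h) + dy, 1L), h)
  rx <- pmin(pmax(seq_len(w) + dx, 1L), w)
  A[ry, rx]
}

neigh_extreme <- function(A, fun, include_center) {
  out <- NULL
  for (dy in -1:1) for (dx in -1:1) {
    if (!include_center && dy == 0L && dx == 0L) next
    s <- shift_mat(A, dy, dx)
    out <- if (is.null(out)) s else fun(out, s)
  }
  out
}

#' Detect scale-space extrema (keypoints)
#'
#' Finds pixels that are strict extrema among their 26 scale-space
#' neighbours, refines them to sub-pixel position and scale by a
#' quadratic fit, and rejects low-contrast and edge-like responses
#' (principal-curvature ratio test on the 2x2 spatial Hessian).
#' Detection is fully deterministic.
#'
#' @param ss a `scale_space` from [build_scale_space()].
#' @param contrast_threshold minimum refined |DoG| response on the
#'   0--1 intensity scale (Lowe's classic 0.03).
#' @param edge_ratio maximum ratio of principal curvatures (classic 10).
#' @return A data frame of keypoints with 0-based base-image coordinates
#'   `x`, `y`, scale `sigma` (px), integer `octave`, continuous refined
#'   `layer`, octave-local `x_oct`, `y_oct`, `sigma_oct` and the refined
#'   DoG `response`. Orientations are not yet assigned.
#' @export
detect_extrema <- function(ss, contrast_threshold = 0.03, edge_ratio = 10) {
  stopifnot(inherits(ss, "scale_space"))
  pre_thr <- 0.5 * contrast_threshold * 255
  rows <- list(); nr <- 0L
  for (o in seq_len(ss$n_octaves)) {
    dog <- ss$octaves[[o]]$dog
    nd <- length(dog)
    h <- nrow(dog[[1L]]); w <- ncol(dog[[1L]])
    if (h < 3L || w < 3L) next
    for (j in 2L:(nd - 1L)) {
      cur <- dog[[j]]
      mx <- pmax(neigh_extreme(dog[[j - 1L]], pmax, TRUE),
                 neigh_extreme(cur, pmax, FALSE),
                 neigh_extreme(dog[[j + 1L]], pmax, TRUE))
      mn <- pmin(neigh_extreme(dog[[j - 1L]], pmin, TRUE),
                 neigh_extreme(cur, pmin, FALSE),
                 neigh_extreme(dog[[j + 1L]], pmin, TRUE))
      cand <- (abs(cur) > pre_thr) & ((cur > mx) | (cur < mn))
      cand[c(1L, h), ] <- FALSE
      cand[, c(1L, w)] <- FALSE
      idx <- which(cand, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      for (ii in seq_len(nrow(idx))) {
        kp <- refine_extremum(dog, idx[ii, 1L], idx[ii, 2L], j,
                              contrast_threshold, edge_ratio)
        if (!is.null(kp)) {
          nr <- nr + 1L
          rows[[nr]] <- c(kp, octave = o)
        }
      }
    }
  }
  if (nr == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      octave = integer(0), layer = numeric(0),
                      x_oct = numeric(0), y_oct = numeric(0),
                      sigma_oct = numeric(0), response = numeric(0)))
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  scale_fac <- 2^(df$octave - 1)
  out <- data.frame(
    x = df$x_oct * scale_fac,
    y = df$y_oct * scale_fac,
    sigma = ss$base_sigma * ss$k^(df$layer - 1) * scale_fac,
    octave = as.integer(df$octave),
    layer = df$layer,
    x_oct = df$x_oct, y_oct = df$y_oct,
    sigma_oct = ss$base_sigma * ss$k^(df$layer - 1),
    response = df$response)
  # clamp: quadratic refinement can nudge a point marginally outside
  out <- out[out$x >= 0 & out$x < ss$width &
             out$y >= 0 & out$y < ss$height, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quadratic sub-pixel/sub-scale refinement of one candidate extremum;
# returns c(x_oct, y_oct, layer, response) or NULL if rejected
refine_extremum <- function(dog, r, c, j, contrast_threshold, edge_ratio,
                            max_iter = 5L) {
  nd <- length(dog)
  h <- nrow(dog[[1L]]); w <- ncol(dog[[1L]])
  for (it in seq_len(max_iter)) {
    Dm <- dog[[j - 1L]]; D0 <- dog[[j]]; Dp <- dog[[j + 1L]]
    v <- D0[r, c]
    g <- c((D0[r, c + 1L] - D0[r, c - 1L]) / 2,
           (D0[r + 1L, c] - D0[r - 1L, c]) / 2,
           (Dp[r, c] - Dm[r, c]) / 2)
    dxx <- D0[r, c + 1L] - 2 * v + D0[r, c - 1L]
    dyy <- D0[r + 1L, c] - 2 * v + D0[r - 1L, c]
    dss <- Dp[r, c] - 2 * v + Dm[r, c]
    dxy <- (D0[r + 1L, c + 1L] - D0[r + 1L, c - 1L] -
            D0[r - 1L, c + 1L] + D0[r - 1L, c - 1L]) / 4
    dxs <- (Dp[r, c + 1L] - Dp[r, c - 1L] -
            Dm[r, c + 1L] + Dm[r, c - 1L]) / 4
    dys <- (Dp[r + 1L, c] - Dp[r - 1L, c] -
            Dm[r + 1L, c] + Dm[r - 1L, c]) / 4
    H <- matrix(c(dxx, dxy, dxs,
                  dxy, dyy, dys,
                  dxs, dys, dss), 3L, 3L)
    off <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(NULL)
    # move to the neighbouring cell only for offsets beyond 0.6 px;
    # a strict 0.5 cutoff oscillates on extrema at half-pixel centres
    if (all(abs(off) < 0.6)) {
      response <- v + 0.5 * sum(g * off)
      if (abs(response) / 255 < contrast_threshold) return(NULL)
      tr <- dxx + dyy
      det <- dxx * dyy - dxy^2
      if (det <= 0 || tr^2 / det >= (edge_ratio + 1)^2 / edge_ratio)
        return(NULL)
      return(c(x_oct = (c - 1L) + off[1L],
               y_oct = (r - 1L) + off[2L],
               layer = j + off[3L],
               response = response))
    }
    c <- c + as.integer(round(off[1L]))
    r <- r + as.integer(round(off[2L]))
    j <- j + as.integer(round(off[3L]))
    if (r < 2L || r > h - 1L || c < 2L || c > w - 1L ||
        j < 2L || j > nd - 1L) return(NULL)
  }
  NULL
}

# cache of per-layer gradient fields, keyed octave/gauss-layer/order
field_cache <- function(ss, order) {
  cache <- new.env(parent = emptyenv())
  function(octave, gauss_layer) {
    key <- paste(octave, gauss_layer, sep = "_")
    f <- cache[[key]]
    if (is.null(f)) {
      sig <- ss$sigmas[gauss_layer]
      f <- gradient_field_of_order(ss$octaves[[octave]]$gauss[[gauss_layer]],
                                   sig, order)
      cache[[key]] <- f
    }
    f
  }
}

# gaussian gauss-layer index nearest a keypoint's continuous layer
nearest_gauss_layer <- function(layer, n_gauss) {
  as.integer(pmin(pmax(round(layer), 1L), n_gauss))
}

wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

#' Assign main and auxiliary orientations to keypoints
#'
#' For each keypoint a 36-bin orientation histogram is accumulated over
#' a Gaussian-weighted circular neighbourhood of radius
#' `3 * 1.5 * sigma` (octave-local), weighted by gradient magnitude of
#' the selected Sobel field (second-order by default). The histogram is
#' lightly smoothed, the dominant peak becomes the main orientation
#' (parabolic interpolation across the peak bin), and every other local
#' peak at or above 80% of the maximum spawns a duplicated keypoint row
#' with that auxiliary orientation. Keypoints whose neighbourhood
#' carries no gradient evidence are dropped.
#'
#' @param kps keypoint data frame from [detect_extrema()].
#' @param ss the `scale_space` the keypoints were detected in.
#' @param field_order 1 or 2: which Sobel gradient field drives the
#'   histogram (and later the descriptor). Default 2.
#' @param n_bins histogram bins (default 36, i.e. 10 degrees per bin).
#' @param peak_ratio auxiliary-peak acceptance ratio (default 0.8).
#' @return The keypoint data frame with columns `theta` (radians in
#'   \eqn{(-\pi, \pi]}) and `is_aux`; one row per orientation.
#' @export
assign_orientations <- function(kps, ss, field_order = 2L, n_bins = 36L,
                                peak_ratio = 0.8) {
  stopifnot(inherits(ss, "scale_space"))
  if (nrow(kps) == 0L) {
    kps$theta <- numeric(0); kps$is_aux <- logical(0)
    return(kps)
  }
  get_field <- field_cache(ss, field_order)
  n_gauss <- ss$n_intervals + 3L
  out <- vector("list", nrow(kps)); no <- 0L
  for (i in seq_len(nrow(kps))) {
    kp <- kps[i, ]
    gl <- nearest_gauss_layer(kp$layer, n_gauss)
    fld <- get_field(kp$octave, gl)
    hist <- orientation_histogram(fld, kp$x_oct, kp$y_oct, kp$sigma_oct,
                                  n_bins)
    if (is.null(hist)) next
    thetas <- histogram_peaks(hist, peak_ratio)
    if (length(thetas) == 0L) next
    for (t_i in seq_along(thetas)) {
      no <- no + 1L
      row <- kp
      row$theta <- thetas[t_i]
      row$is_aux <- t_i > 1L
      out[[no]] <- row
    }
  }
  if (no == 0L) {
    kps <- kps[0L, ]
    kps$theta <- numeric(0); kps$is_aux <- logical(0)
    return(kps)
  }
  res <- do.call(rbind, out[seq_len(no)])
  rownames(res) <- NULL
  res
}

orientation_histogram <- function(fld, x_oct, y_oct, sigma_oct, n_bins) {
  h <- nrow(fld$magnitude); w <- ncol(fld$magnitude)
  radius <- max(1L, as.integer(round(3 * 1.5 * sigma_oct)))
  r0 <- floor(y_oct) - radius; r1 <- floor(y_oct) + radius + 1L
  c0 <- floor(x_oct) - radius; c1 <- floor(x_oct) + radius + 1L
  rr <- max(r0, 0L):min(r1, h - 1L)
  cc <- max(c0, 0L):min(c1, w - 1L)
  if (r0 > h - 1L || r1 < 0L || c0 > w - 1L || c1 < 0L) return(NULL)
  sub_m <- fld$magnitude[rr + 1L, cc + 1L, drop = FALSE]
  sub_o <- fld$orientation[rr + 1L, cc + 1L, drop = FALSE]
  dy <- matrix(rr - y_oct, length(rr), length(cc))
  dx <- matrix(cc - x_oct, length(rr), length(cc), byrow = TRUE)
  d2 <- dx^2 + dy^2
  keep <- d2 <= radius^2
  if (!any(keep)) return(NULL)
  sigw <- 1.5 * sigma_oct
  wgt <- exp(-d2[keep] / (2 * sigw^2)) * sub_m[keep]
  if (sum(wgt) <= 0) return(NULL)
  ang01 <- (sub_o[keep] %% (2 * pi)) / (2 * pi)
  bin <- pmin(floor(ang01 * n_bins) + 1L, n_bins)
  hist <- numeric(n_bins)
  agg <- rowsum(wgt, bin)
  hist[as.integer(rownames(agg))] <- agg[, 1L]
  # two passes of circular [1,1,1]/3 smoothing
  for (pass in 1:2) {
    prv <- c(hist[n_bins], hist[-n_bins])
    nxt <- c(hist[-1L], hist[1L])
    hist <- (prv + hist + nxt) / 3
  }
  if (max(hist) <= 0) return(NULL)
  hist
}

histogram_peaks <- function(hist, peak_ratio) {
  n <- length(hist)
  prv <- c(hist[n], hist[-n]); nxt <- c(hist[-1L], hist[1L])
  peaks <- which(hist > prv & hist > nxt & hist >= peak_ratio * max(hist))
  if (length(peaks) == 0L) peaks <- which.max(hist)
  vals <- hist[peaks]
  ord <- order(vals, decreasing = TRUE)
  peaks <- peaks[ord]
  vapply(peaks, function(p) {
    hm <- hist[if (p == 1L) n else p - 1L]
    hp <- hist[if (p == n) 1L else p + 1L]
    den <- hm - 2 * hist[p] + hp
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (hm - hp) / den
    delta <- max(min(delta, 0.5), -0.5)
    wrap_pi(2 * pi * (p - 0.5 + delta) / n)
  }, numeric(1L))
}
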