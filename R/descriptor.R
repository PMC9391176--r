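#' Ring weight for the concentric-ring descriptor
#'
#' Pixels closer to the keypoint influence the descriptor more than
#' distant ones. Weights follow a Gaussian falloff in the ring index,
#' `w(r) = exp(-r^2 / (2 * 4^2))`, normalised so the innermost ring has
#' weight exactly 1; they are strictly positive and monotonically
#' non-increasing outward.
#'
#' @param ring_index integer ring index (or vector) in `0..7`.
#' @return Numeric weight(s) in `(0, 1]`.
#' @export
ring_weight <- function(ring_index) {
  if (length(ring_index) == 0L || any(!is.finite(ring_index)) ||
      any(ring_index != round(ring_index)) ||
      any(ring_index < 0) || any(ring_index > 7))
    stop("`ring_index` must be integer(s) in 0..7", call. = FALSE)
  exp(-ring_index^2 / (2 * 4^2))
}

#' Build one 64-dimensional concentric-ring descriptor
#'
#' The keypoint's neighbourhood is divided into 8 concentric rings of
#' equal width around the keypoint; within each ring, gradient
#' magnitude (times the ring weight) is accumulated into 8 orientation
#' bins of 45 degrees whose origin is the keypoint's main orientation,
#' with linear interpolation between the two adjacent bins. Rotating
#' all measured orientations by `-theta` makes the descriptor rotation
#' invariant. The 64 accumulated values (ring-major, innermost ring
#' first) are finally scaled to unit Euclidean norm.
#'
#' Ring width defaults to 1 px at the detection layer's grid, scaled by
#' `sigma / base_sigma` when `scale_radius` is `TRUE` (the default), so
#' the support grows with detected scale and the descriptor is
#' scale-covariant. A pixel falling exactly on a ring boundary is
#' assigned to the inner ring.
#'
#' @param x,y keypoint centre, 0-based continuous coordinates in the
#'   grid of `field`.
#' @param theta keypoint reference orientation in radians.
#' @param sigma keypoint scale in the same grid (px).
#' @param field a `gradient_field` computed on the keypoint's layer.
#' @param rings,bins ring and orientation-bin counts (8 and 8).
#' @param radius_per_ring ring width in px at `sigma == base_sigma`.
#' @param scale_radius logical; scale ring width with `sigma`.
#' @param base_sigma reference scale for ring-width scaling.
#' @param normalize if `FALSE`, return the raw accumulation (used by
#'   cross-checking code).
#' @return Numeric vector of length `rings * bins`, or `NULL` when the
#'   accumulation is identically zero (featureless neighbourhood) or
#'   the support lies entirely off-image.
#' @export
build_descriptor <- function(x, y, theta, sigma, field,
                             rings = 8L, bins = 8L, radius_per_ring = 1,
                             scale_radius = TRUE, base_sigma = 1.6,
                             normalize = TRUE) {
  stopifnot(inherits(field, "gradient_field"))
  rw <- if (scale_radius) radius_per_ring * sigma / base_sigma
        else radius_per_ring
  rmax <- rings * rw
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  r0 <- max(floor(y - rmax), 0L); r1 <- min(ceiling(y + rmax), h - 1L)
  c0 <- max(floor(x - rmax), 0L); c1 <- min(ceiling(x + rmax), w - 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  mag <- field$magnitude[rr + 1L, cc + 1L, drop = FALSE]
  ori <- field$orientation[rr + 1L, cc + 1L, drop = FALSE]
  dy <- matrix(rr - y, length(rr), length(cc))
  dx <- matrix(cc - x, length(rr), length(cc), byrow = TRUE)
  dist <- sqrt(dx^2 + dy^2)
  keep <- dist <= rmax
  if (!any(keep)) return(NULL)
  dist <- dist[keep]; m <- mag[keep]; a <- ori[keep]
  # boundary pixels belong to the inner ring (ceiling rule)
  ring <- pmax(ceiling(dist / rw) - 1, 0)
  ok <- ring <= rings - 1
  ring <- ring[ok]; m <- m[ok]; a <- a[ok]
  if (length(m) == 0L) return(NULL)
  wgt <- m * exp(-ring^2 / (2 * 4^2))
  ang <- (a - theta) %% (2 * pi)
  pos <- ang / (2 * pi / bins)
  b0 <- floor(pos)
  frac <- pos - b0
  b0 <- b0 %% bins
  b1 <- (b0 + 1) %% bins
  idx0 <- ring * bins + b0 + 1
  idx1 <- ring * bins + b1 + 1
  vec <- numeric(rings * bins)
  acc0 <- rowsum(wgt * (1 - frac), idx0)
  vec[as.integer(rownames(acc0))] <- acc0[, 1L]
  acc1 <- rowsum(wgt * frac, idx1)
  vec[as.integer(rownames(acc1))] <-
    vec[as.integer(rownames(acc1))] + acc1[, 1L]
  if (!normalize) return(vec)
  nrm <- sqrt(sum(vec^2))
  if (nrm <= 0) return(NULL)
  vec / nrm
}

#' Compute descriptors for a set of oriented keypoints
#'
#' Runs [build_descriptor()] for every keypoint row against the gradient
#' field of its detection layer (computed lazily per octave/layer).
#' Keypoints whose descriptor is rejected are removed, so the returned
#' keypoint table and descriptor matrix stay aligned row for row.
#'
#' @param kps oriented keypoints from [assign_orientations()].
#' @param ss the `scale_space` they came from.
#' @param field_order which Sobel field feeds the descriptor (default 2).
#' @inheritParams build_descriptor
#' @return A list with `keypoints` (data frame) and `descriptors`
#'   (numeric matrix, one unit-norm row of length `rings * bins` per
#'   keypoint).
#' @export
compute_descriptors <- function(kps, ss, field_order = 2L, rings = 8L,
                                bins = 8L, radius_per_ring = 1,
                                scale_radius = TRUE) {
  stopifnot(inherits(ss, "scale_space"))
  nd <- rings * bins
  if (nrow(kps) == 0L)
    return(list(keypoints = kps,
                descriptors = matrix(numeric(0), 0L, nd)))
  get_field <- field_cache(ss, field_order)
  n_gauss <- ss$n_intervals + 3L
  desc <- matrix(NA_real_, nrow(kps), nd)
  ok <- logical(nrow(kps))
  for (i in seq_len(nrow(kps))) {
    kp <- kps[i, ]
    fld <- get_field(kp$octave, nearest_gauss_layer(kp$layer, n_gauss))
    v <- build_descriptor(kp$x_oct, kp$y_oct, kp$theta, kp$sigma_oct, fld,
                          rings = rings, bins = bins,
                          radius_per_ring = radius_per_ring,
                          scale_radius = scale_radius,
                          base_sigma = ss$base_sigma)
    if (!is.null(v)) { desc[i, ] <- v; ok[i] <- TRUE }
  }
  kout <- kps[ok, , drop = FALSE]
  rownames(kout) <- NULL
  list(keypoints = kout, descriptors = desc[ok, , drop = FALSE])
}

#' Detect, orient and describe in one call
#'
#' Convenience wrapper running median filtering, scale-space
#' construction, extremum detection, orientation assignment and
#' descriptor computation with the settings of a [pipeline_config()].
#'
#' @param img a [gray_image] (or matrix).
#' @param config a [pipeline_config()].
#' @return A list with `keypoints` and `descriptors` as in
#'   [compute_descriptors()].
#' @export
detect_and_describe <- function(img, config = pipeline_config()) {
  img <- as_gray_image(img)
  prepped <- median_filter(img, config$median_window)
  ss <- build_scale_space(prepped,
                          layers_per_octave = config$layers_per_octave,
                          base_sigma = config$base_sigma)
  kps <- detect_extrema(ss, config$contrast_threshold, config$edge_ratio)
  kps <- assign_orientations(kps, ss, field_order = config$field_order)
  compute_descriptors(kps, ss, field_order = config$field_order,
                      rings = config$rings, bins = config$bins,
                      radius_per_ring = config$radius_per_ring)
}

#' Serialise keypoints + descriptors to a plain-text table
#'
#' One row per keypoint: `x`, `y`, `sigma`, `theta` followed by the 64
#' descriptor components, tab-separated with a header. Intended for
#' cross-implementation comparison.
#'
#' @param det result of [detect_and_describe()] / [compute_descriptors()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(det, path) {
  k <- det$keypoints; d <- det$descriptors
  tab <- cbind(k[, c("x", "y", "sigma", "theta")], d)
  colnames(tab) <- c("x", "y", "sigma", "theta",
                     paste0("v", seq_len(ncol(d))))
  utils::write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
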