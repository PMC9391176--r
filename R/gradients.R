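#' Sobel convolution of an image
#'
#' Correlates the image with one of the two 3x3 Sobel templates
#' \deqn{B_x = \begin{pmatrix}-1&0&1\\-2&0&2\\-1&0&1\end{pmatrix},\quad
#'       B_y = \begin{pmatrix}-1&-2&-1\\0&0&0\\1&2&1\end{pmatrix}}
#' producing the signed horizontal (response to variation along +x) or
#' vertical derivative estimate. Borders are edge-replicated and the
#' output has the same shape as the input. On a horizontal unit ramp
#' `I(x, y) = x` the interior horizontal response is exactly 8.
#'
#' @param img a [gray_image] or plain numeric matrix.
#' @param axis `"horizontal"` for \eqn{B_x}, `"vertical"` for \eqn{B_y}.
#' @return A numeric matrix of signed responses, same shape as the input.
#' @export
sobel_convolve <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  px <- if (inherits(img, "gray_image")) img$pixels else as.matrix(img)
  h <- nrow(px); w <- ncol(px)
  # replicate-padded index helpers
  up <- c(1L, seq_len(h - 1L)); dn <- c(seq_len(h)[-1L], h)
  lf <- c(1L, seq_len(w - 1L)); rt <- c(seq_len(w)[-1L], w)
  if (axis == "horizontal") {
    (px[up, rt] + 2 * px[, rt] + px[dn, rt]) -
    (px[up, lf] + 2 * px[, lf] + px[dn, lf])
  } else {
    (px[dn, lf] + 2 * px[dn, ] + px[dn, rt]) -
    (px[up, lf] + 2 * px[up, ] + px[up, rt])
  }
}

new_gradient_field <- function(magnitude, orientation, gx, gy, scale_sigma,
                               order) {
  structure(list(magnitude = magnitude, orientation = orientation,
                 gx = gx, gy = gy, scale_sigma = scale_sigma,
                 order = order),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field order %d, %dx%d, sigma %.3f>\n",
              x$order, ncol(x$magnitude), nrow(x$magnitude), x$scale_sigma))
  invisible(x)
}

#' First-order Sobel gradient field
#'
#' Computes per-pixel gradient magnitude
#' \eqn{G^1_\sigma = \sqrt{(G^1_{x,\sigma})^2 + (G^1_{y,\sigma})^2}} and
#' orientation from the Sobel derivatives of a Gaussian scale-space
#' layer. The caller is responsible for `img` already carrying the blur
#' of scale `sigma` (the scale-space builder does this upstream).
#' Orientation is the quadrant-aware angle `atan2(gy, gx)` in
#' \eqn{(-\pi, \pi]}; pixels of zero magnitude get orientation 0 by
#' convention and zero weight everywhere downstream, so the convention
#' is unobservable.
#'
#' @param img a [gray_image] or numeric matrix (a scale-space layer).
#' @param sigma the Gaussian scale of that layer (recorded, not applied).
#' @return A `gradient_field` with elements `magnitude`, `orientation`,
#'   `gx`, `gy`, `scale_sigma`.
#' @export
first_order_field <- function(img, sigma = 1) {
  px <- if (inherits(img, "gray_image")) img$pixels else as.matrix(img)
  gx <- sobel_convolve(px, "horizontal")
  gy <- sobel_convolve(px, "vertical")
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)
  ori[mag == 0] <- 0
  ori[ori <= -pi] <- pi
  new_gradient_field(mag, ori, gx, gy, sigma, order = 1L)
}

#' Second-order Sobel gradient field
#'
#' Re-applies the Sobel templates to the *magnitude* raster of a
#' first-order field, yielding
#' \eqn{G^2_\sigma = \sqrt{(G^2_{x,\sigma})^2 + (G^2_{y,\sigma})^2}}
#' and the corresponding quadrant-aware direction. This second-order
#' field is what the orientation-assignment and descriptor stages
#' consume by default: it responds to curvature of the gradient
#' magnitude rather than to raw intensity ramps, which suppresses the
#' broad edge responses that plain difference-of-Gaussian detection
#' over-weights.
#'
#' @param first a `gradient_field` produced by [first_order_field()].
#' @return A `gradient_field` of order 2 at the same scale.
#' @export
second_order_field <- function(first) {
  if (!inherits(first, "gradient_field") || first$order != 1L)
    stop("`first` must be a first-order gradient_field", call. = FALSE)
  gx2 <- sobel_convolve(first$magnitude, "horizontal")
  gy2 <- sobel_convolve(first$magnitude, "vertical")
  mag <- sqrt(gx2^2 + gy2^2)
  ori <- atan2(gy2, gx2)
  ori[mag == 0] <- 0
  ori[ori <= -pi] <- pi
  new_gradient_field(mag, ori, gx2, gy2, first$scale_sigma, order = 2L)
}

# Gradient field of the requested order for a raw layer matrix.
gradient_field_of_order <- function(layer, sigma, order = 2L) {
  f1 <- first_order_field(layer, sigma)
  if (order == 1L) f1 else second_order_field(f1)
}

#' Gaussian blur by separable convolution
#'
#' Separable Gaussian filtering with replicate boundary handling,
#' implemented as banded matrix products so results are bit-reproducible
#' across platforms. Kernel support is truncated at `3.5 * sigma`.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0`
#'   returns the input unchanged.
#' @return A numeric matrix (same shape).
#' @export
gaussian_blur <- function(img, sigma) {
  px <- if (inherits(img, "gray_image")) img$pixels else as.matrix(img)
  if (sigma <= 0) return(px)
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  conv_mat <- function(n) {
    cm <- matrix(0, n, n)
    idx <- seq_len(n)
    for (o in -r:r) {
      j <- pmin(pmax(idx + o, 1L), n)
      cm[cbind(idx, j)] <- cm[cbind(idx, j)] + g[o + r + 1L]
    }
    cm
  }
  conv_mat(nrow(px)) %*% px %*% t(conv_mat(ncol(px)))
}
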