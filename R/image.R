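#' Grayscale image container
#'
#' A `gray_image` holds a single-channel intensity raster on the 0--255
#' scale in floating-point representation. Pixel coordinates throughout
#' the package are 0-based, with `x` the column index growing rightward,
#' `y` the row index growing downward, and pixel centres at integer
#' coordinates. Internally pixels are stored as a base matrix indexed
#' `[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`; at least
#'   3x3 so that a Sobel window fits.
#' @return An object of class `gray_image` with elements `pixels`,
#'   `width` and `height`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3 pixels (got ",
         nrow(pixels), "x", ncol(pixels), ")", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels,
                 width = ncol(pixels),
                 height = nrow(pixels)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, range [%.1f, %.1f]>\n",
              x$width, x$height, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) c(x$height, x$width)

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) x else gray_image(as.matrix(x))
}

#' Load an image file as grayscale
#'
#' Reads a PNG, TIFF or JPEG file (JPEG requires the suggested EBImage
#' package) and collapses colour channels to luminance using the
#' ITU-R BT.601 weights 0.299/0.587/0.114. 8-bit values are preserved
#' exactly on the 0--255 scale; an alpha channel, if present, is ignored.
#'
#' @param path path to an existing image file.
#' @return A [gray_image].
#' @export
load_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = read_jpeg_ebimage(path),
    stop("unrecognised image extension '", ext, "' for: ", path,
         call. = FALSE))
  if (is.list(arr)) arr <- arr[[1L]]  # multi-page TIFF: first page
  px <- collapse_luminance(arr) * 255
  if (length(px) == 0L)
    stop("zero-sized image: ", path, call. = FALSE)
  gray_image(px)
}

# JPEG decoding is delegated to EBImage when available; PNG/TIFF have
# dedicated lightweight readers so the hard dependency stays small.
read_jpeg_ebimage <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("reading JPEG requires the EBImage package; ",
         "convert to PNG or TIFF instead: ", path, call. = FALSE)
  a <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores x (width) as the first dimension; transpose to row = y
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

# BT.601 luminance on a [0,1] array as returned by png/tiff readers
collapse_luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc == 1L) return(arr[, , 1L])
    if (nc == 2L) return(arr[, , 1L])           # gray + alpha
    return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Median filtering with edge replication
#'
#' Replaces every pixel by the median of its `window` x `window`
#' neighbourhood. Borders are handled by edge replication, so the output
#' has the same dimensions as the input. The filter is idempotent on
#' constant images and never creates intensities absent from the input.
#'
#' @param img a [gray_image].
#' @param window odd integer window side, at least 3. Defaults to 3.
#' @return A filtered [gray_image].
#' @export
median_filter <- function(img, window = 3L) {
  img <- as_gray_image(img)
  if (length(window) != 1L || !is.finite(window) || window != round(window))
    stop("`window` must be a single integer", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("`window` must be an odd integer >= 3 (got ", window, ")",
         call. = FALSE)
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  r <- window %/% 2L
  k2 <- window * window
  stack <- matrix(0, h * w, k2)
  j <- 1L
  for (dy in -r:r) {
    ry <- pmin(pmax(seq_len(h) + dy, 1L), h)
    for (dx in -r:r) {
      rx <- pmin(pmax(seq_len(w) + dx, 1L), w)
      stack[, j] <- px[ry, rx]
      j <- j + 1L
    }
  }
  med <- row_median_odd(stack)
  gray_image(matrix(med, h, w))
}

# median of each row for a matrix with an odd number of columns,
# without calling stats::median once per pixel
row_median_odd <- function(m) {
  k <- ncol(m)
  half <- (k + 1L) %/% 2L
  sorted <- apply(m, 1L, function(v) sort.int(v, partial = half)[half])
  as.numeric(sorted)
}

# bilinear interpolation of matrix `px` at 0-based continuous (x, y);
# points outside the grid return NA
bilinear_sample <- function(px, x, y) {
  h <- nrow(px); w <- ncol(px)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1
  x0c <- pmin(pmax(x0, 0), w - 1); y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1);     y1c <- pmin(y0c + 1, h - 1)
  i00 <- y0c + 1 + x0c * h; i10 <- y0c + 1 + x1c * h
  i01 <- y1c + 1 + x0c * h; i11 <- y1c + 1 + x1c * h
  v <- (1 - fy) * ((1 - fx) * px[i00] + fx * px[i10]) +
       fy       * ((1 - fx) * px[i01] + fx * px[i11])
  v[!ok] <- NA_real_
  v
}

#' Write a grayscale image to PNG
#'
#' @param img a [gray_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(pmin(pmax(img$pixels / 255, 0), 1), target = path)
  invisible(path)
}
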