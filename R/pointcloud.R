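#' Sparse point cloud
#'
#' Triangulated 3-D feature points with optional per-point colour and
#' the track (image id, keypoint id) of the observations each point was
#' reconstructed from. Coordinates carry an arbitrary global scale (the
#' first camera pair's baseline is normalised to 1).
#'
#' @param points nx3 matrix of finite 3-D coordinates.
#' @param colors optional nx3 matrix of 0--255 RGB values.
#' @param tracks optional list (length n) of 2-column matrices
#'   `(image_id, keypoint_id)`; every point needs >= 2 observations.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points, colors = NULL, tracks = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || !all(is.finite(points)))
    stop("`points` must be a finite nx3 matrix", call. = FALSE)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == nrow(points), ncol(colors) == 3L)
    colors[] <- pmin(pmax(round(colors), 0), 255)
  }
  if (!is.null(tracks)) {
    stopifnot(length(tracks) == nrow(points))
    if (any(vapply(tracks, nrow, integer(1L)) < 2L))
      stop("every point needs at least 2 observations", call. = FALSE)
  }
  structure(list(points = points, colors = colors, tracks = tracks),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s>\n", nrow(x$points),
              if (is.null(x$colors)) "" else ", with colors"))
  invisible(x)
}

#' Write a point cloud as binary little-endian PLY
#'
#' Vertices are written as float32 `x, y, z`, plus `uchar red, green,
#' blue` when the cloud carries colours.
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  header <- c("ply",
              "format binary_little_endian 1.0",
              paste("element vertex", n),
              "property float x", "property float y", "property float z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  for (i in seq_len(n)) {
    writeBin(as.numeric(cloud$points[i, ]), con, size = 4L,
             endian = "little")
    if (has_col)
      writeBin(as.raw(cloud$colors[i, ]), con)
  }
  invisible(path)
}

#' Read a binary little-endian PLY point cloud
#'
#' Supports the vertex layout written by [write_ply()] (float32
#' coordinates, optional uchar RGB).
#'
#' @param path PLY file path.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  n <- NULL; props <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header", call. = FALSE)
    if (grepl("^element vertex ", line))
      n <- as.integer(sub("^element vertex ", "", line))
    if (grepl("^property ", line))
      props <- c(props, line)
    if (line == "end_header") break
  }
  if (is.null(n)) stop("no vertex element in PLY header", call. = FALSE)
  has_col <- any(grepl("uchar red", props))
  pts <- matrix(NA_real_, n, 3L)
  cols <- if (has_col) matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    pts[i, ] <- readBin(con, numeric(), n = 3L, size = 4L,
                        endian = "little")
    if (has_col)
      cols[i, ] <- as.integer(readBin(con, raw(), n = 3L))
  }
  point_cloud(pts, cols)
}

#' Write camera poses as JSON
#'
#' One record per image: the 3x3 rotation (row-major) and the
#' translation 3-vector of the world-to-camera map `x = R X + t`.
#'
#' @param poses list of lists with elements `R` and `t`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_poses_json <- function(poses, path) {
  out <- lapply(seq_along(poses), function(i)
    list(image = i,
         R = as.numeric(t(poses[[i]]$R)),
         t = as.numeric(poses[[i]]$t)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
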