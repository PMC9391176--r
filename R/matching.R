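new_match_set <- function(df, stage) {
  structure(df, class = c("match_set", "data.frame"), stage = stage)
}

#' Construct a match set
#'
#' Builds the candidate-correspondence container used by the filtering
#' stages, e.g. for planted matching experiments. Rows are sorted by
#' ascending descriptor distance.
#'
#' @param ref,tgt 1-based keypoint indices into the reference / target
#'   keypoint tables.
#' @param desc_distance arccos descriptor distances in `[0, pi]`.
#' @param nndr nearest-neighbour distance ratios in `[0, 1]`.
#' @param stage label of the producing stage (default `"nndr"`).
#' @return A `match_set` data frame.
#' @export
match_set <- function(ref, tgt, desc_distance = numeric(length(ref)),
                      nndr = numeric(length(ref)), stage = "nndr") {
  stopifnot(length(tgt) == length(ref),
            all(desc_distance >= 0 & desc_distance <= pi),
            all(nndr >= 0 & nndr <= 1))
  df <- data.frame(ref = as.integer(ref), tgt = as.integer(tgt),
                   desc_distance = desc_distance, nndr = nndr)
  df <- df[order(df$desc_distance, df$ref), , drop = FALSE]
  rownames(df) <- NULL
  new_match_set(df, stage)
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: %d pairs after stage '%s'>\n",
              nrow(x), attr(x, "stage")))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Initial matching by nearest-neighbour distance ratio
#'
#' Descriptor distance is the arc-cosine of the inner product of the
#' two unit vectors (an angle in `[0, pi]`). For every reference
#' descriptor the nearest and second-nearest target descriptors are
#' found; the pair is kept when `nearest / second_nearest` is below
#' `ratio_threshold`. Target keypoints claimed by several reference
#' keypoints are resolved one-to-one in favour of the smallest
#' distance. Pairs are returned sorted by ascending descriptor
#' distance (best matches first).
#'
#' @param desc_ref,desc_tgt unit-normalised descriptor matrices (one
#'   row per keypoint) from [compute_descriptors()].
#' @param ratio_threshold NNDR acceptance threshold (default 0.8).
#' @return A `match_set` data frame with columns `ref`, `tgt` (1-based
#'   row indices into the two keypoint tables), `desc_distance` and
#'   `nndr`. With fewer than two target descriptors no ratio can be
#'   formed; all pairs pass with `nndr = 0` and a warning.
#' @export
nndr_match <- function(desc_ref, desc_tgt, ratio_threshold = 0.8) {
  if (!is.matrix(desc_ref) || !is.matrix(desc_tgt) ||
      nrow(desc_ref) == 0L || nrow(desc_tgt) == 0L)
    stop("descriptor matrices must be non-empty", call. = FALSE)
  if (ncol(desc_ref) != ncol(desc_tgt))
    stop("descriptor dimensionality differs between images", call. = FALSE)
  S <- desc_ref %*% t(desc_tgt)
  D <- acos(pmin(pmax(S, -1), 1))
  n <- nrow(D)
  if (ncol(D) < 2L) {
    warning("fewer than 2 target descriptors: NNDR undefined, ",
            "all pairs pass with nndr = 0")
    best <- rep(1L, n)
    d1 <- D[, 1L]
    nndr <- rep(0, n)
    keep <- rep(TRUE, n)
  } else {
    best <- max.col(-D, ties.method = "first")
    d1 <- D[cbind(seq_len(n), best)]
    D2 <- D
    D2[cbind(seq_len(n), best)] <- Inf
    d2 <- D2[cbind(seq_len(n), max.col(-D2, ties.method = "first"))]
    nndr <- ifelse(d2 > 0, d1 / d2, ifelse(d1 > 0, 1, 0))
    keep <- nndr < ratio_threshold
  }
  df <- data.frame(ref = seq_len(n), tgt = best,
                   desc_distance = d1, nndr = nndr)[keep, , drop = FALSE]
  # one-to-one: a target claimed twice goes to the smaller distance
  df <- df[order(df$desc_distance, df$ref), , drop = FALSE]
  df <- df[!duplicated(df$tgt), , drop = FALSE]
  rownames(df) <- NULL
  new_match_set(df, "nndr")
}

#' Same-image geometry of two keypoints
#'
#' Euclidean distance and wrapped main-orientation difference between
#' two keypoints of the same image — the per-pair quantities the
#' neighbourhood-voting filter is built from.
#'
#' @param kp_a,kp_b single keypoint rows (need `x`, `y`, `theta`).
#' @return `c(d = pixels, delta_theta = radians in (-pi, pi])`.
#' @export
pair_geometry <- function(kp_a, kp_b) {
  d <- sqrt((kp_b$x - kp_a$x)^2 + (kp_b$y - kp_a$y)^2)
  c(d = d, delta_theta = wrap_pi(kp_b$theta - kp_a$theta))
}

# one minus the inner product of the two rows after mean-centering and
# unit normalisation (= 1 - Pearson correlation). Raw non-negative rows
# always have cosine near 1, which would make any threshold below ~0.9
# inert; centering makes the consistency statistic discriminative.
row_dissimilarity <- function(u, v) {
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(0)
  if (nu == 0 || nv == 0) return(2)
  1 - sum((u / nu) * (v / nv))
}

#' Neighbourhood-voting consistency filter
#'
#' A correct correspondence should see the *other* matched keypoints at
#' consistent relative positions and orientations in both images. For
#' each candidate pair `m`, the row vector of distances from `m`'s
#' reference keypoint to every other matched reference keypoint is
#' compared against the analogous row in the target image (and likewise
#' for wrapped orientation differences, mapped to `[0, 2pi)`). Each row
#' is mean-centered and unit-normalised; `dot1` (distance) and `dot2`
#' (direction) are one minus the inner product of the paired rows, a
#' dissimilarity in `[0, 2]` that is 0 for perfectly consistent
#' geometry. The pair survives iff `dot1 < T_d` and `dot2 < T_theta`.
#'
#' Both statistics are invariant to a global rigid transform applied to
#' either image's keypoints, so the filter tolerates arbitrary
#' rotation/translation and (for `dot1`, through the normalisation)
#' uniform scaling between the views.
#'
#' @param matches a `match_set` (from [nndr_match()]).
#' @param kps_ref,kps_tgt the two keypoint tables the indices refer to.
#' @param T_theta direction threshold (default 0.3).
#' @param T_d distance threshold (default 0.4).
#' @return The filtered `match_set`, with diagnostic columns `dot1` and
#'   `dot2`. Two or fewer candidates have no neighbourhood to vote
#'   with and pass unchanged with a warning.
#' @export
vote_filter <- function(matches, kps_ref, kps_tgt,
                        T_theta = 0.3, T_d = 0.4) {
  n <- nrow(matches)
  if (n <= 2L) {
    warning("<= 2 candidate pairs: neighbourhood voting skipped")
    return(new_match_set(as.data.frame(matches), "vote"))
  }
  xr <- kps_ref$x[matches$ref]; yr <- kps_ref$y[matches$ref]
  tr <- kps_ref$theta[matches$ref]
  xt <- kps_tgt$x[matches$tgt]; yt <- kps_tgt$y[matches$tgt]
  tt <- kps_tgt$theta[matches$tgt]
  Dr <- as.matrix(stats::dist(cbind(xr, yr)))
  Dt <- as.matrix(stats::dist(cbind(xt, yt)))
  Ar <- (outer(tr, tr, function(a, b) b - a)) %% (2 * pi)
  At <- (outer(tt, tt, function(a, b) b - a)) %% (2 * pi)
  dot1 <- dot2 <- numeric(n)
  for (i in seq_len(n)) {
    dot1[i] <- row_dissimilarity(Dr[i, -i], Dt[i, -i])
    dot2[i] <- row_dissimilarity(Ar[i, -i], At[i, -i])
  }
  df <- as.data.frame(matches)
  df$dot1 <- dot1
  df$dot2 <- dot2
  keep <- dot1 < T_d & dot2 < T_theta
  new_match_set(df[keep, , drop = FALSE], "vote")
}

#' Serialise a match set to a plain-text table
#'
#' Tab-separated with header: reference and target coordinates,
#' descriptor distance, NNDR and the stage the set came from.
#'
#' @param matches a `match_set`.
#' @param kps_ref,kps_tgt the keypoint tables.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, kps_ref, kps_tgt, path) {
  df <- as.data.frame(matches)
  out <- data.frame(
    ref_x = round(kps_ref$x[df$ref], 6), ref_y = round(kps_ref$y[df$ref], 6),
    tgt_x = round(kps_tgt$x[df$tgt], 6), tgt_y = round(kps_tgt$y[df$tgt], 6),
    desc_distance = round(df$desc_distance, 9),
    nndr = round(df$nndr, 9),
    stage = rep(attr(matches, "stage") %||% "unknown", nrow(df)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
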