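# --- 3D needle pose from gated depth points -----------------------------

#' Needle pose
#'
#' A needle pose is a base point (at the grabber end), a unit direction and
#' the needle length; the tip is `base + length * direction`. Coordinates
#' in mm.
#'
#' @param base Length-3 base point (mm).
#' @param direction Length-3 direction (normalized internally; must be
#'   non-degenerate).
#' @param length Needle length in mm (> 0).
#' @return An object of class `needle_pose` with fields base, tip,
#'   direction, length.
#' @export
needle_pose <- function(base, direction, length) {
  base <- as.numeric(base); direction <- as.numeric(direction)
  stopifnot(length(base) == 3, length(direction) == 3, is.finite(length))
  if (length <= 0) stop("needle length must be positive")
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("degenerate needle direction")
  direction <- direction / nd
  structure(list(base = base, direction = direction,
                 tip = base + length * direction, length = length),
            class = "needle_pose")
}

#' Filter a depth cloud to the sensor's near-range gate
#'
#' Near-range high-frequency depth sensing (AHAT-like) is reliable only in
#' a limited range band; points outside it are dropped on ingest.
#'
#' @param points Nx3 matrix in the depth camera frame (mm).
#' @param range c(min, max) Euclidean distance from the camera origin (mm).
#' @return Filtered Nx3 matrix with attribute `"n_dropped"`.
#' @export
range_gate <- function(points, range = c(300, 1000)) {
  points <- as_points3(points)
  d <- sqrt(rowSums(points^2))
  keep <- d >= range[1] & d <= range[2]
  out <- points[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Gate world points against a detected image line
#'
#' Projects each point into the PV image and keeps exactly those whose
#' perpendicular pixel distance to the line `u cos(theta) + v sin(theta) = r`
#' is at most `pixel_tol`. Points behind the PV camera are skipped and
#' counted.
#'
#' @param points Nx3 matrix of world points (mm).
#' @param line List or one-row data.frame with `r`, `theta`.
#' @param rig A [camera_rig()].
#' @param pixel_tol Gate half-width in pixels (> 0).
#' @return Nx3 matrix of retained world points with attribute
#'   `"n_behind"` (points skipped for being behind the camera).
#' @export
gate_points <- function(points, line, rig, pixel_tol = 4) {
  stopifnot(pixel_tol > 0)
  points <- as_points3(points)
  if (nrow(points) == 0) {
    out <- points; attr(out, "n_behind") <- 0L; return(out)
  }
  uv <- world_to_pixel(points, rig, allow_behind = TRUE)
  behind <- !is.finite(uv[, 1])
  dist <- abs(uv[, 1] * cos(line$theta[[1]]) + uv[, 2] * sin(line$theta[[1]]) -
                line$r[[1]])
  keep <- !behind & dist <= pixel_tol
  out <- points[keep, , drop = FALSE]
  attr(out, "n_behind") <- sum(behind)
  out
}

# perpendicular residuals of points to the line (p0, d)
line_residuals <- function(points, p0, d) {
  rel <- sweep(points, 2, p0)
  proj <- rel %*% d
  sqrt(pmax(rowSums(rel^2) - proj^2, 0))
}

# orthogonal least-squares line: centroid + principal axis
tls_line <- function(points) {
  p0 <- colMeans(points)
  sv <- svd(sweep(points, 2, p0), nu = 0, nv = 3)
  list(p0 = p0, d = sv$v[, 1])
}

#' Fit a 3D line to a point cloud (orthogonal regression with outlier
#' rejection)
#'
#' Total least squares via the principal axis of the point scatter
#' (rotation-invariant, unlike coordinate-wise regression), iterated with a
#' robust MAD rule: points whose perpendicular residual deviates from the
#' median residual by more than `mad_mult` scaled MADs are dropped and the
#' line refit. The deviation-from-median form keeps points lying on a
#' curved surface at a constant offset from the axis (e.g. a cylindrical
#' grabber) while rejecting gross outliers.
#'
#' @param points Nx3 world points (mm), N >= 2 after filtering.
#' @param mad_mult Outlier cut in scaled MADs (default 2.5).
#' @param iters Number of fit/reject rounds (default 2: fit, reject, refit).
#' @return List of class `needle_line3d`: `p0` (inlier centroid), `d` (unit
#'   direction), `inliers` (logical), `residual_rms` (mm).
#' @export
fit_line3d <- function(points, mad_mult = 2.5, iters = 2) {
  points <- as_points3(points)
  if (nrow(points) < 2) stop("need at least 2 points to fit a line")
  keep <- rep(TRUE, nrow(points))
  fit <- NULL
  for (it in seq_len(iters)) {
    if (sum(keep) < 2) stop("fewer than 2 inliers remain; cannot fit line")
    fit <- tls_line(points[keep, , drop = FALSE])
    if (it == iters) break
    res <- line_residuals(points, fit$p0, fit$d)
    med <- stats::median(res[keep])
    madv <- 1.4826 * stats::median(abs(res[keep] - med))
    thr <- max(mad_mult * madv, 1e-6)
    keep <- abs(res - med) <= thr
  }
  res <- line_residuals(points[keep, , drop = FALSE], fit$p0, fit$d)
  structure(list(p0 = fit$p0, d = fit$d, inliers = keep,
                 residual_rms = sqrt(mean(res^2))),
            class = "needle_line3d")
}

#' Estimate the needle tip from a fitted grabber line
#'
#' The needle is invisible to the depth sensor, so its pose is extrapolated
#' from the grabber: the base is the projection of the grabber centroid
#' onto the fitted line advanced by `base_offset` along the needle
#' direction, and the tip lies `needle_length` further. The direction sign
#' is chosen to point away from the grabber centroid (towards the fitted
#' line's anchor); when the centroid projects onto the anchor itself - the
#' usual case when the fitted cloud *is* the grabber - an `orient_hint`
#' vector must disambiguate.
#'
#' @param line A `needle_line3d` from [fit_line3d()].
#' @param grabber_centroid Length-3 reference point on/near the grabber (mm).
#' @param needle_length Needle length (mm, > 0).
#' @param base_offset Distance (mm) from the projected centroid to the
#'   needle base along the direction (e.g. half the grabber length when the
#'   centroid is the grabber's middle).
#' @param orient_hint Optional length-3 vector whose sign along the line
#'   resolves the direction when the centroid rule is ambiguous.
#' @return A [needle_pose()].
#' @export
estimate_tip <- function(line, grabber_centroid, needle_length,
                         base_offset = 0, orient_hint = NULL) {
  stopifnot(inherits(line, "needle_line3d"), needle_length > 0)
  g <- as.numeric(grabber_centroid)
  d <- line$d / sqrt(sum(line$d^2))
  if (!all(is.finite(d))) stop("degenerate line direction")
  q <- line$p0 + sum((g - line$p0) * d) * d  # projection of centroid
  s <- sum((line$p0 - q) * d)                # anchor position along line
  if (abs(s) > 1e-9) {
    if (s < 0) d <- -d
  } else if (!is.null(orient_hint)) {
    if (sum(as.numeric(orient_hint) * d) < 0) d <- -d
  }
  base <- q + base_offset * d
  needle_pose(base, d, needle_length)
}
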