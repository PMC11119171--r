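#' Camera intrinsics
#'
#' Pinhole intrinsic parameters of a camera. Focal lengths and principal
#' point are in pixels; pixels are 0-based with origin at the top-left
#' corner, u rightward, v downward.
#'
#' @param fx,fy Focal lengths in pixels (must be > 0).
#' @param cx,cy Principal point in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' K <- camera_intrinsics(500, 500, 320, 240)
#' intrinsics_matrix(K)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  stopifnot(is.finite(fx), is.finite(fy), is.finite(cx), is.finite(cy))
  if (fx <= 0 || fy <= 0)
    stop("focal lengths fx, fy must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' @rdname camera_intrinsics
#' @param K A `camera_intrinsics` object.
#' @export
intrinsics_matrix <- function(K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  matrix(c(K$fx, 0, K$cx,
           0, K$fy, K$cy,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Rigid transform (rotation + translation)
#'
#' A rigid body transform mapping points as `p' = R p + t`. The convention
#' throughout the package is that camera extrinsics map world coordinates to
#' camera coordinates. Translations are in millimetres.
#'
#' @param R 3x3 rotation matrix; must be orthonormal with det +1 (1e-9).
#' @param t Numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3,
            all(is.finite(R)), all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation (det != +1 within 1e-9)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' If `T` maps `p' = R p + t` the inverse maps `p = R' p' - R' t`.
#'
#' @param T A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$R)
  rigid_transform(Rt, -as.numeric(Rt %*% T$t))
}

#' Compose rigid transforms
#'
#' `compose_rigid(A, B)` applies `B` first, then `A`.
#'
#' @param A,B `rigid_transform` objects.
#' @return The composed `rigid_transform` A o B.
#' @export
compose_rigid <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  rigid_transform(A$R %*% B$R, as.numeric(A$R %*% B$t) + A$t)
}

#' @rdname rigid_transform
#' @param T A `rigid_transform`.
#' @export
rigid_matrix <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- T$R
  M[1:3, 4] <- T$t
  M
}

#' Apply a rigid transform to points
#'
#' @param T A `rigid_transform`.
#' @param points Nx3 matrix of points (a length-3 vector is accepted).
#' @return Nx3 matrix of transformed points.
#' @export
transform_points <- function(T, points) {
  stopifnot(inherits(T, "rigid_transform"))
  points <- as_points3(points)
  if (nrow(points) == 0L) return(points)
  sweep(points %*% t(T$R), 2, T$t, "+")
}

# coerce a vector or matrix to an Nx3 numeric matrix
as_points3 <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) %% 3 == 0)
    points <- matrix(as.numeric(points), ncol = 3, byrow = TRUE)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Camera rig: PV (photo-video) RGB camera + depth camera
#'
#' Holds the intrinsics of the RGB camera and the world->camera extrinsics of
#' both cameras of a head-mounted sensing rig, plus the RGB image size.
#'
#' @param pv_intrinsics `camera_intrinsics` of the RGB camera.
#' @param pv_extrinsics `rigid_transform` mapping world -> PV camera frame.
#' @param depth_extrinsics `rigid_transform` mapping world -> depth camera frame.
#' @param image_size Integer c(width, height) in pixels.
#' @return An object of class `camera_rig`.
#' @export
camera_rig <- function(pv_intrinsics, pv_extrinsics = rigid_transform(),
                       depth_extrinsics = rigid_transform(),
                       image_size = c(640L, 480L)) {
  stopifnot(inherits(pv_intrinsics, "camera_intrinsics"),
            inherits(pv_extrinsics, "rigid_transform"),
            inherits(depth_extrinsics, "rigid_transform"),
            length(image_size) == 2, all(image_size > 0))
  structure(list(pv_intrinsics = pv_intrinsics,
                 pv_extrinsics = pv_extrinsics,
                 depth_extrinsics = depth_extrinsics,
                 image_size = as.integer(image_size)),
            class = "camera_rig")
}

#' Depth-camera points to world coordinates
#'
#' Applies the inverse of the depth camera's world->camera extrinsics,
#' i.e. multiplies by the inverted extrinsic matrix.
#'
#' @param points Nx3 matrix in the depth camera frame (mm).
#' @param depth_extrinsics `rigid_transform` mapping world -> depth camera.
#' @return Nx3 matrix in world coordinates (mm).
#' @export
depth_to_world <- function(points, depth_extrinsics) {
  transform_points(invert_rigid(depth_extrinsics), points)
}

#' World points to depth-camera coordinates
#'
#' @inheritParams depth_to_world
#' @export
world_to_depth <- function(points, depth_extrinsics) {
  transform_points(depth_extrinsics, points)
}

# project camera-frame points through intrinsics; returns u, v and depth z
project_camera <- function(points_cam, K) {
  z <- points_cam[, 3]
  cbind(u = K$fx * points_cam[, 1] / z + K$cx,
        v = K$fy * points_cam[, 2] / z + K$cy,
        z = z)
}

#' Project world points into the PV image
#'
#' Transforms points to the PV camera frame and projects them through the
#' pinhole model: `u = fx x/z + cx`, `v = fy y/z + cy`.
#'
#' @param points Nx3 matrix of world points (mm), or a length-3 vector.
#' @param rig A `camera_rig`.
#' @param allow_behind If `TRUE`, points with camera-frame z <= 1e-9 produce
#'   `NA` pixels instead of an error (used for gating, where such points are
#'   skipped and counted).
#' @return Nx2 matrix of pixel coordinates (columns u, v), with attribute
#'   `"z"` holding camera-frame depths.
#' @export
world_to_pixel <- function(points, rig, allow_behind = FALSE) {
  stopifnot(inherits(rig, "camera_rig"))
  pts_cam <- transform_points(rig$pv_extrinsics, points)
  if (nrow(pts_cam) == 0L) {
    out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("u", "v")))
    attr(out, "z") <- numeric(0)
    return(out)
  }
  uvz <- project_camera(pts_cam, rig$pv_intrinsics)
  behind <- uvz[, "z"] <= 1e-9
  if (any(behind)) {
    if (!allow_behind)
      stop("point(s) behind the PV camera (camera-frame z <= 1e-9)")
    uvz[behind, c("u", "v")] <- NA_real_
  }
  out <- uvz[, c("u", "v"), drop = FALSE]
  attr(out, "z") <- unname(uvz[, "z"])
  out
}

#' Back-project a pixel to a world point at a known camera depth
#'
#' Inverse of [world_to_pixel()] given the camera-frame depth z of the point.
#'
#' @param uv Length-2 pixel coordinates (u, v) or Nx2 matrix.
#' @param z Camera-frame depth(s), mm (> 0).
#' @param rig A `camera_rig`.
#' @return Nx3 matrix of world points.
#' @export
pixel_to_world <- function(uv, z, rig) {
  stopifnot(inherits(rig, "camera_rig"), all(z > 0))
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2, byrow = TRUE)
  K <- rig$pv_intrinsics
  pts_cam <- cbind((uv[, 1] - K$cx) / K$fx * z,
                   (uv[, 2] - K$cy) / K$fy * z,
                   z)
  transform_points(invert_rigid(rig$pv_extrinsics), pts_cam)
}
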