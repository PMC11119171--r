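# --- synthetic scene simulator ------------------------------------------
#
# Stands in for the headset hardware: renders a grabber+needle tool into a
# PV-style greyscale image, generates near-range depth returns on the
# grabber only (the thin needle yields no depth returns), and carries full
# ground truth for every stage of the pipeline.

#' Simulator configuration
#'
#' Defaults encode the study conditions: a 160 mm needle held upright about
#' 400 mm in front of the headset (the working distance at which near-range
#' depth sensing performs best), 2 mm depth noise, and a cylindrical
#' grabber 80 mm long and 12 mm in diameter coaxial with the needle.
#'
#' @param needle_length Needle length in mm (120 and 160 are the studied
#'   sizes).
#' @param distance Distance of the tool from the headset (mm); must lie in
#'   the near-depth range gate 300-1000 mm.
#' @param rotation Rotation about the needle axis (degrees).
#' @param tilt In-plane tilt of the needle axis away from vertical
#'   (degrees).
#' @param noise_px Std of additive Gaussian image noise (intensity units).
#' @param noise_depth Std of Gaussian depth-point noise (mm).
#' @param seed Integer seed (required; one seeded generator per call).
#' @param grabber_length,grabber_radius Grabber cylinder size (mm).
#' @param needle_radius Rendered needle half-width (mm).
#' @param n_axial,n_circ Depth sampling grid on the grabber surface.
#' @param image_size c(width, height) of the rendered image (px).
#' @param fx,fy,cx,cy PV camera intrinsics (px).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(needle_length = 160, distance = 400, rotation = 0,
                       tilt = 0, noise_px = 0.01, noise_depth = 2, seed,
                       grabber_length = 80, grabber_radius = 6,
                       needle_radius = 1.5, n_axial = 41, n_circ = 24,
                       image_size = c(400L, 400L),
                       fx = 350, fy = 350, cx = 200, cy = 200) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  structure(list(needle_length = needle_length, distance = distance,
                 rotation = rotation, tilt = tilt, noise_px = noise_px,
                 noise_depth = noise_depth, seed = as.integer(seed),
                 grabber_length = grabber_length,
                 grabber_radius = grabber_radius,
                 needle_radius = needle_radius,
                 n_axial = n_axial, n_circ = n_circ,
                 image_size = as.integer(image_size),
                 fx = fx, fy = fy, cx = cx, cy = cy),
            class = "sim_config")
}

#' Default camera rig for the simulator
#'
#' World frame = headset frame. The depth camera sits 15 mm below the world
#' origin and the PV camera 10 mm to its right, both looking along +z.
#'
#' @param config A [sim_config()].
#' @return A [camera_rig()].
#' @export
default_rig <- function(config) {
  camera_rig(
    pv_intrinsics = camera_intrinsics(config$fx, config$fy, config$cx, config$cy),
    pv_extrinsics = rigid_transform(diag(3), c(-10, 0, 0)),
    depth_extrinsics = rigid_transform(diag(3), c(0, -15, 0)),
    image_size = config$image_size)
}

# unit vectors orthogonal to d
orthonormal_frame <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * d) * d
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(d[2] * n1[3] - d[3] * n1[2],
          d[3] * n1[1] - d[1] * n1[3],
          d[1] * n1[2] - d[2] * n1[1])
  list(n1 = n1, n2 = n2)
}

# Hough (r, theta in [0, pi)) line through two image points
line_from_points <- function(p1, p2) {
  v <- p2 - p1
  n <- c(-v[2], v[1])
  n <- n / sqrt(sum(n^2))
  theta <- atan2(n[2], n[1])
  if (theta < 0) theta <- theta + pi
  if (theta >= pi) theta <- theta - pi
  r <- p1[1] * cos(theta) + p1[2] * sin(theta)
  # keep the (r, theta) representative consistent with n as computed
  list(r = r, theta = theta)
}

# distance from pixel grid to a 2D segment [a, b]; returns matrix
segment_distance_field <- function(h, w, a, b) {
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), times = w), h, w)
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((u - a[1]) * ab[1] + (v - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((u - (a[1] + t * ab[1]))^2 + (v - (a[2] + t * ab[2]))^2)
}

#' Simulate one frame of the needle scene
#'
#' Renders the tool (bright grabber cylinder + thinner needle on a dark
#' background, anti-aliased edges, Gaussian pixel noise), samples depth
#' returns on the grabber surface only (plus Gaussian depth noise, in the
#' depth-camera frame), and returns the camera rig and full ground truth.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param rig Optional [camera_rig()] (defaults to [default_rig()]).
#' @param shift Optional world translation of the whole tool (mm), used by
#'   [simulate_sequence()] to move the tool between frames.
#' @return List of class `sim_frame`: `image` (h x w matrix in \[0,1\]),
#'   `cloud` (Nx3 depth-frame points, mm), `rig`, and `truth` - a list with
#'   `pose` (true [needle_pose()], world), `line` (true image line r/theta),
#'   `footprint` (logical grabber mask), `clean_cloud` (noise-free depth
#'   points), `grabber_centroid` (world).
#' @export
simulate_frame <- function(config, rig = NULL, shift = c(0, 0, 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(rig)) rig <- default_rig(config)
  w <- rig$image_size[1]; h <- rig$image_size[2]
  tilt <- config$tilt * pi / 180
  d <- c(sin(tilt), -cos(tilt), 0)           # needle direction (towards tip)
  base <- c(0, 40, config$distance) + shift  # grabber-end needle origin
  pose <- needle_pose(base, d, config$needle_length)
  rear <- base - config$grabber_length * d
  centroid <- base - config$grabber_length / 2 * d

  # ground-truth image line through the projected needle axis
  uv <- world_to_pixel(rbind(base, pose$tip, rear, centroid), rig)
  true_line <- line_from_points(uv[1, ], uv[2, ])

  # analytic footprint + rendering (projected radii at the grabber center z)
  zc <- attr(uv, "z")
  r_grab_px <- rig$pv_intrinsics$fx * config$grabber_radius / zc[4]
  r_ndl_px <- max(rig$pv_intrinsics$fx * config$needle_radius / zc[1], 1.0)
  dg <- segment_distance_field(h, w, uv[3, ], uv[1, ])   # rear -> base
  dn <- segment_distance_field(h, w, uv[1, ], uv[2, ])   # base -> tip
  bg <- 0.12
  alpha_g <- pmin(pmax(r_grab_px + 0.5 - dg, 0), 1)
  alpha_n <- pmin(pmax(r_ndl_px + 0.5 - dn, 0), 1)
  image <- bg + alpha_g * (0.80 - bg)
  image <- pmax(image, bg + alpha_n * (0.55 - bg))
  footprint <- dg <= r_grab_px

  # depth returns: regular grid over the full grabber surface
  fr <- orthonormal_frame(d)
  rot <- config$rotation * pi / 180
  s <- seq(0, config$grabber_length, length.out = config$n_axial)
  phi <- rot + 2 * pi * (0:(config$n_circ - 1)) / config$n_circ
  grid <- expand.grid(s = s, phi = phi)
  axis_pts <- t(vapply(grid$s, function(si) rear + si * d, numeric(3)))
  radial <- outer(cos(grid$phi), fr$n1) + outer(sin(grid$phi), fr$n2)
  surf_world <- axis_pts + config$grabber_radius * radial
  clean_cloud <- world_to_depth(surf_world, rig$depth_extrinsics)

  withr::with_seed(config$seed, {
    if (config$noise_px > 0) {
      image <- image + matrix(stats::rnorm(h * w, 0, config$noise_px), h, w)
      image <- pmin(pmax(image, 0), 1)
    }
    cloud <- clean_cloud
    if (config$noise_depth > 0)
      cloud <- cloud + matrix(stats::rnorm(length(cloud), 0, config$noise_depth),
                              nrow(cloud), 3)
  })

  rng <- sqrt(rowSums(cloud^2))
  if (all(rng < 300 | rng > 1000)) {
    warning("tool outside the 300-1000 mm depth range gate; empty cloud")
    cloud <- cloud[0, , drop = FALSE]
  }

  structure(list(image = image, cloud = cloud, rig = rig,
                 truth = list(pose = pose, line = true_line,
                              footprint = footprint,
                              clean_cloud = clean_cloud,
                              grabber_centroid = centroid)),
            class = "sim_frame")
}

#' Simulate a frame sequence under constant motion
#'
#' Frame k (0-based) translates the true base by `k * velocity` and rotates
#' the tool about its axis by `k * rot_rate`; per-frame sensor noise is
#' independent (seed derived per frame).
#'
#' @param config A [sim_config()] (its seed seeds the whole sequence).
#' @param n_frames Number of frames (>= 1).
#' @param motion List with `velocity` (length-3 mm/frame, world) and
#'   `rot_rate` (degrees/frame about the needle axis).
#' @return List of `sim_frame` objects.
#' @export
simulate_sequence <- function(config, n_frames,
                              motion = list(velocity = c(0, 0, 0),
                                            rot_rate = 0)) {
  stopifnot(n_frames >= 1)
  vel <- motion$velocity %||% c(0, 0, 0)
  rr <- motion$rot_rate %||% 0
  lapply(seq_len(n_frames) - 1L, function(k) {
    ck <- config
    ck$seed <- (config$seed + 9973L * k) %% .Machine$integer.max
    ck$rotation <- config$rotation + k * rr
    simulate_frame(ck, default_rig(config), shift = k * vel)
  })
}

#' Phantom with imitation lesions
#'
#' @param lesions Data.frame or list of lesions with center (x, y, z in mm)
#'   and radius (mm > 0); pass a data.frame with columns x, y, z, radius.
#' @param skin_point Length-3 skin reference point from which punctures are
#'   performed.
#' @return Object of class `phantom`.
#' @export
phantom <- function(lesions, skin_point = c(0, 0, 0)) {
  if (!is.data.frame(lesions))
    lesions <- do.call(rbind, lapply(lesions, function(l)
      data.frame(x = l$center[1], y = l$center[2], z = l$center[3],
                 radius = l$radius)))
  stopifnot(all(c("x", "y", "z", "radius") %in% names(lesions)),
            all(lesions$radius > 0))
  structure(list(lesions = lesions, skin_point = as.numeric(skin_point)),
            class = "phantom")
}

# rotate unit vector d by `angle` radians about a random perpendicular axis
perturb_direction <- function(d, angle) {
  fr <- orthonormal_frame(d)
  phi <- stats::runif(1, 0, 2 * pi)
  axis_perp <- cos(phi) * fr$n1 + sin(phi) * fr$n2
  d * cos(angle) + axis_perp * sin(angle)
}

#' Simulate a material-collection (puncture) study
#'
#' Repeated punctures towards one lesion: each puncture plans the straight
#' trajectory from the phantom's skin point to the lesion center, executes
#' it with an angular error (rotation of the insertion direction by an
#' angle drawn from N(0, sigma_angle), about a random perpendicular axis)
#' and a translational error (isotropic Gaussian, sigma_translation), and
#' records whether the final tip landed inside the lesion.
#'
#' @param phantom A [phantom()].
#' @param lesion_index Row index of the target lesion.
#' @param n_punctures Number of punctures (>= 1).
#' @param error_model List with `sigma_translation` (mm) and `sigma_angle`
#'   (degrees).
#' @param seed Integer seed.
#' @return data.frame with one row per puncture: `hit`, tip coordinates,
#'   `tip_displacement` (mm from lesion center) and `distance_to_lesion`
#'   (mm from lesion surface, 0 when inside).
#' @export
simulate_puncture_study <- function(phantom, lesion_index, n_punctures,
                                    error_model = list(sigma_translation = 1,
                                                       sigma_angle = 2),
                                    seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), n_punctures >= 1)
  if (lesion_index < 1 || lesion_index > nrow(phantom$lesions))
    stop("invalid lesion index")
  les <- phantom$lesions[lesion_index, ]
  center <- as.numeric(les[c("x", "y", "z")])
  entry <- phantom$skin_point
  depth <- sqrt(sum((center - entry)^2))
  dir <- (center - entry) / depth
  st <- error_model$sigma_translation %||% 0
  sa <- (error_model$sigma_angle %||% 0) * pi / 180
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_punctures), function(i) {
      dperp <- if (sa > 0) perturb_direction(dir, stats::rnorm(1, 0, sa)) else dir
      tip <- entry + depth * dperp +
        if (st > 0) stats::rnorm(3, 0, st) else c(0, 0, 0)
      disp <- sqrt(sum((tip - center)^2))
      data.frame(puncture = i, hit = disp <= les$radius,
                 tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
                 tip_displacement = disp,
                 distance_to_lesion = max(0, disp - les$radius))
    })
    do.call(rbind, recs)
  })
}
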