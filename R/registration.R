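# --- paired-point registration, transform chain, trajectory guidance ----

#' Similarity transform (uniform scale + rotation + translation)
#'
#' Maps points as `p' = s R p + t`.
#'
#' @param s Scale factor (> 0).
#' @param R 3x3 proper rotation (1e-9 tolerance).
#' @param t Length-3 translation (mm).
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(s = 1, R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  stopifnot(length(t) == 3, all(dim(R) == c(3, 3)), is.finite(s))
  if (s <= 0) stop("scale must be positive")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation within 1e-9")
  structure(list(s = s, R = R, t = t), class = "similarity_transform")
}

#' @rdname similarity_transform
#' @param T A `similarity_transform`.
#' @export
similarity_matrix <- function(T) {
  stopifnot(inherits(T, "similarity_transform"))
  M <- diag(4)
  M[1:3, 1:3] <- T$s * T$R
  M[1:3, 4] <- T$t
  M
}

#' Apply a similarity transform to points
#'
#' @param T A `similarity_transform`.
#' @param points Nx3 matrix or length-3 vector.
#' @return Nx3 matrix of transformed points.
#' @export
apply_similarity <- function(T, points) {
  stopifnot(inherits(T, "similarity_transform"))
  points <- as_points3(points)
  sweep(T$s * (points %*% t(T$R)), 2, T$t, "+")
}

#' Compose similarity transforms
#'
#' `compose_similarity(A, B)` applies `B` first, then `A`.
#'
#' @param A,B `similarity_transform` objects.
#' @export
compose_similarity <- function(A, B) {
  similarity_transform(A$s * B$s, A$R %*% B$R,
                       A$s * as.numeric(A$R %*% B$t) + A$t)
}

#' Paired-point marker registration (least-squares similarity)
#'
#' Closed-form Umeyama solution for the similarity transform minimizing
#' the sum of squared distances between corresponding markers,
#' `sum_i || s R x_i + t - y_i ||^2`. With `fix_scale = TRUE` the scale is
#' constrained to 1 (rigid registration, preserving the real scale of the
#' patient scan). Correspondences are matched by marker id (rownames).
#'
#' @param source Nx3 matrix of source markers (rownames = ids).
#' @param destination Nx3 matrix of destination markers (rownames = ids).
#' @param fix_scale Force s = 1.
#' @return List with `transform` (a [similarity_transform()] mapping source
#'   to destination) and `fre` - the fiducial registration error, the RMS
#'   residual over correspondences (mm).
#' @export
register_markers <- function(source, destination, fix_scale = FALSE) {
  source <- as_points3(source); destination <- as_points3(destination)
  if (!is.null(rownames(source)) && !is.null(rownames(destination))) {
    common <- intersect(rownames(source), rownames(destination))
    if (length(common) < 3)
      stop("need at least 3 common marker ids (got ", length(common), ")")
    source <- source[common, , drop = FALSE]
    destination <- destination[common, , drop = FALSE]
  } else if (nrow(source) != nrow(destination)) {
    stop("marker sets differ in size and carry no ids to match on")
  }
  n <- nrow(source)
  if (n < 3) stop("need at least 3 marker correspondences")
  mx <- colMeans(source); my <- colMeans(destination)
  Xc <- sweep(source, 2, mx); Yc <- sweep(destination, 2, my)
  var_x <- sum(Xc^2) / n
  if (var_x < 1e-12) stop("degenerate marker geometry (coincident points)")
  Sigma <- crossprod(Yc, Xc) / n
  sv <- svd(Sigma)
  # collinear configurations leave the rotation about the line unconstrained
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate marker geometry: markers are collinear")
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (fix_scale) 1 else sum(diag(diag(sv$d) %*% S)) / var_x
  t <- my - s * as.numeric(R %*% mx)
  T <- similarity_transform(s, R, t)
  res <- apply_similarity(T, source) - destination
  list(transform = T, fre = sqrt(mean(rowSums(res^2))))
}

#' Transform a needle pose through the device/model chain
#'
#' Applies the device-synchronisation transform `C` followed by the
#' model-registration transform `M` to the needle segment; equivalent to a
#' single application of the composed matrix product. The needle length
#' rescales by `s_M * s_C`.
#'
#' @param pose A [needle_pose()].
#' @param C,M `similarity_transform` objects (C applied first).
#' @return Transformed [needle_pose()].
#' @export
apply_chain <- function(pose, C = similarity_transform(),
                        M = similarity_transform()) {
  stopifnot(inherits(pose, "needle_pose"))
  T <- compose_similarity(M, C)
  base <- as.numeric(apply_similarity(T, pose$base))
  tip <- as.numeric(apply_similarity(T, pose$tip))
  needle_pose(base, tip - base, pose$length * T$s)
}

#' Plan a biopsy trajectory
#'
#' A straight guide line from the target (lesion) point through the skin
#' entry point, extended `extension` mm beyond the entry, above the body.
#' `n_rings` ring centers are spaced evenly along the extended segment
#' between target and line end (exclusive of both endpoints), giving the
#' operator alignment cues along the approach.
#'
#' @param target Length-3 lesion point (mm).
#' @param entry Length-3 skin entry point (mm), distinct from target.
#' @param extension Length the guide line extends beyond the entry (mm).
#' @param n_rings Number of guidance rings.
#' @return Object of class `trajectory`: target, entry, direction (unit,
#'   target -> entry), end (line endpoint), rings (n x 3 matrix).
#' @export
plan_trajectory <- function(target, entry, extension = 150, n_rings = 5) {
  target <- as.numeric(target); entry <- as.numeric(entry)
  v <- entry - target
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("target and entry points coincide")
  d <- v / nv
  end <- entry + extension * d
  ts <- seq_len(n_rings) / (n_rings + 1)
  rings <- t(vapply(ts, function(f) target + f * (end - target), numeric(3)))
  structure(list(target = target, entry = entry, direction = d,
                 extension = extension, end = end, rings = rings),
            class = "trajectory")
}

#' Read / write a trajectory JSON
#'
#' Schema: `{"target": [x,y,z], "entry": [x,y,z], "extension": mm,
#' "n_rings": k}`.
#'
#' @param path JSON path.
#' @return A [plan_trajectory()] object.
#' @export
read_trajectory <- function(path) {
  j <- jsonlite::fromJSON(path)
  plan_trajectory(as.numeric(j$target), as.numeric(j$entry),
                  extension = j$extension %||% 150,
                  n_rings = j$n_rings %||% 5)
}

#' @rdname read_trajectory
#' @param traj A `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  jsonlite::write_json(list(target = traj$target, entry = traj$entry,
                            extension = traj$extension,
                            n_rings = nrow(traj$rings)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# perpendicular distance from point p to the infinite line (p0, d)
point_line_distance <- function(p, p0, d) {
  rel <- as.numeric(p) - p0
  sqrt(max(sum(rel^2) - sum(rel * d)^2, 0))
}

#' Needle-to-trajectory alignment metrics
#'
#' Perpendicular distances of the needle base and tip to the trajectory
#' line, the acute angle between the needle and the trajectory, and a
#' discrete alignment state driving the guidance display: `ALIGNED` when
#' both distances are below `aligned_dist` and the angle below
#' `aligned_angle`; `NEAR` when both distances are below `near_dist`;
#' otherwise `OFF`.
#'
#' @param pose A [needle_pose()].
#' @param traj A [plan_trajectory()] trajectory.
#' @param thresholds List with `aligned_dist` (mm), `aligned_angle`
#'   (degrees), `near_dist` (mm).
#' @return List of class `alignment_status`: `dist_base`, `dist_tip` (mm),
#'   `angle` (degrees, in \[0, 90\]), `state`.
#' @export
alignment_metrics <- function(pose, traj,
                              thresholds = list(aligned_dist = 3,
                                                aligned_angle = 2,
                                                near_dist = 10)) {
  stopifnot(inherits(pose, "needle_pose"), inherits(traj, "trajectory"))
  db <- point_line_distance(pose$base, traj$target, traj$direction)
  dt <- point_line_distance(pose$tip, traj$target, traj$direction)
  ca <- abs(sum(pose$direction * traj$direction))
  angle <- acos(pmin(pmax(ca, 0), 1)) * 180 / pi
  state <- if (db < thresholds$aligned_dist && dt < thresholds$aligned_dist &&
               angle < thresholds$aligned_angle) "ALIGNED"
           else if (db < thresholds$near_dist && dt < thresholds$near_dist) "NEAR"
           else "OFF"
  structure(list(dist_base = db, dist_tip = dt, angle = angle, state = state),
            class = "alignment_status")
}
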