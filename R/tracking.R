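# --- temporal stabilisation: Kalman filter + exponential moving average --

#' Smoothing parameters
#'
#' @param process_noise Spectral density of the white-acceleration process
#'   noise (mm^2 per frame^3 equivalent; > 0).
#' @param measurement_noise Per-observation variance (mm^2; > 0).
#' @param alpha EMA weight in (0, 1]; 1 disables smoothing.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(process_noise = 0.5, measurement_noise = 4,
                             alpha = 0.3) {
  stopifnot(process_noise > 0, measurement_noise > 0,
            alpha > 0, alpha <= 1)
  structure(list(process_noise = process_noise,
                 measurement_noise = measurement_noise, alpha = alpha),
            class = "smoothing_params")
}

# 12-state constant-velocity model on (base xyz, direction xyz):
# x = [b(3), u(3), vb(3), vu(3)], observed block = first 6.
kalman_matrices <- function(params, dt = 1) {
  F <- diag(12)
  F[1:6, 7:12] <- dt * diag(6)
  q <- params$process_noise
  Q <- matrix(0, 12, 12)
  Q[1:6, 1:6] <- q * dt^3 / 3 * diag(6)
  Q[1:6, 7:12] <- q * dt^2 / 2 * diag(6)
  Q[7:12, 1:6] <- q * dt^2 / 2 * diag(6)
  Q[7:12, 7:12] <- q * dt * diag(6)
  H <- cbind(diag(6), matrix(0, 6, 6))
  R <- params$measurement_noise * diag(6)
  list(F = F, Q = Q, H = H, R = R)
}

#' Initialize a needle track from a first observation
#'
#' The state mean is the observation with zero velocities; the covariance
#' is inflated (100 x measurement noise) to let early observations dominate.
#'
#' @param pose A [needle_pose()] observation (world frame).
#' @param params A [smoothing_params()].
#' @param frame Frame index of the observation.
#' @return An object of class `track_state` with fields `mean` (12-vector),
#'   `cov` (12x12), `length`, `last_update`.
#' @export
track_init <- function(pose, params = smoothing_params(), frame = 0L) {
  stopifnot(inherits(pose, "needle_pose"))
  mean <- c(pose$base, pose$direction, rep(0, 6))
  cov <- diag(rep(100 * params$measurement_noise, 12))
  structure(list(mean = mean, cov = cov, length = pose$length,
                 last_update = as.integer(frame)),
            class = "track_state")
}

#' Kalman predict/update step
#'
#' Constant-velocity predict followed by a linear update on (base,
#' direction) when an observation is present; predict-only when
#' `observation` is NULL (the covariance trace then grows). The direction
#' block of the mean is renormalized to unit length after each step. A
#' non-positive-definite covariance after update triggers one
#' symmetrization retry before failing.
#'
#' @param state A `track_state`.
#' @param observation A [needle_pose()] or NULL (missed detection).
#' @param params A [smoothing_params()].
#' @return Updated `track_state`, with attribute `"innovation"` (length-6
#'   innovation vector, NA on predict-only steps).
#' @export
kalman_step <- function(state, observation = NULL, params = smoothing_params()) {
  stopifnot(inherits(state, "track_state"))
  M <- kalman_matrices(params)
  x <- M$F %*% state$mean
  P <- M$F %*% state$cov %*% t(M$F) + M$Q
  innovation <- rep(NA_real_, 6)
  if (!is.null(observation)) {
    stopifnot(inherits(observation, "needle_pose"))
    if (abs(observation$length - state$length) > 1e-6)
      stop("observation needle length does not match the track")
    z <- c(observation$base, observation$direction)
    innovation <- z - as.numeric(M$H %*% x)
    S <- M$H %*% P %*% t(M$H) + M$R
    K <- P %*% t(M$H) %*% solve(S)
    x <- x + K %*% innovation
    IKH <- diag(12) - K %*% M$H
    P <- IKH %*% P %*% t(IKH) + K %*% M$R %*% t(K)  # Joseph form
  }
  P <- (P + t(P)) / 2
  ok <- tryCatch({ chol(P); TRUE }, error = function(e) FALSE)
  if (!ok) {
    P <- (P + t(P)) / 2 + 1e-9 * diag(12)
    ok <- tryCatch({ chol(P); TRUE }, error = function(e) FALSE)
    if (!ok) stop("covariance update failed (not positive definite)")
  }
  nd <- sqrt(sum(x[4:6]^2))
  if (nd > 1e-12) x[4:6] <- x[4:6] / nd
  out <- state
  out$mean <- as.numeric(x)
  out$cov <- P
  out$last_update <- state$last_update + 1L
  attr(out, "innovation") <- as.numeric(innovation)
  out
}

#' Extract the pose from a track state
#'
#' @param state A `track_state`.
#' @return A [needle_pose()].
#' @export
track_pose <- function(state) {
  stopifnot(inherits(state, "track_state"))
  needle_pose(state$mean[1:3], state$mean[4:6], state$length)
}

#' Exponential moving average of needle poses
#'
#' Componentwise convex combination `alpha * new + (1 - alpha) * prev` of
#' base and direction; the direction is renormalized and the tip recomputed
#' from `base + length * direction`.
#'
#' @param prev,new [needle_pose()] objects with equal needle length.
#' @param alpha Weight of the new pose, in (0, 1].
#' @return Smoothed [needle_pose()].
#' @export
ema_smooth <- function(prev, new, alpha) {
  stopifnot(inherits(prev, "needle_pose"), inherits(new, "needle_pose"),
            alpha > 0, alpha <= 1)
  if (abs(prev$length - new$length) > 1e-6)
    stop("needle lengths differ between poses")
  base <- alpha * new$base + (1 - alpha) * prev$base
  dir <- alpha * new$direction + (1 - alpha) * prev$direction
  needle_pose(base, dir, new$length)
}

#' Run the full temporal smoother over an observation sequence
#'
#' Applies [kalman_step()] per frame (predict-only on NULL observations)
#' and then EMA-smooths the filtered pose (EMA applied to the Kalman
#' output; order configurable via `ema_first`).
#'
#' @param observations List of [needle_pose()] or NULL entries, in frame
#'   order.
#' @param params A [smoothing_params()].
#' @param use_ema Apply the EMA stage.
#' @param ema_first If TRUE the raw observation is EMA-smoothed before the
#'   Kalman update instead.
#' @return List with `poses` (list of smoothed [needle_pose()]) and `log`
#'   (data.frame: frame, innovation_norm, raw/filtered base coordinates).
#' @export
track_sequence <- function(observations, params = smoothing_params(),
                           use_ema = TRUE, ema_first = FALSE) {
  stopifnot(length(observations) >= 1)
  first <- Find(Negate(is.null), observations)
  if (is.null(first)) stop("no valid observations in sequence")
  state <- NULL
  ema_pose <- NULL
  poses <- vector("list", length(observations))
  log <- vector("list", length(observations))
  for (k in seq_along(observations)) {
    obs <- observations[[k]]
    if (is.null(state)) {
      if (is.null(obs)) next
      state <- track_init(obs, params, frame = k - 1L)
      filt <- track_pose(state)
      inn <- rep(0, 6)
    } else {
      if (use_ema && ema_first && !is.null(obs) && !is.null(ema_pose))
        obs <- ema_smooth(ema_pose, obs, params$alpha)
      state <- kalman_step(state, obs, params)
      filt <- track_pose(state)
      inn <- attr(state, "innovation")
    }
    if (use_ema && !ema_first) {
      ema_pose <- if (is.null(ema_pose)) filt
                  else ema_smooth(ema_pose, filt, params$alpha)
      out_pose <- ema_pose
    } else {
      ema_pose <- if (use_ema) obs else NULL
      out_pose <- filt
    }
    poses[[k]] <- out_pose
    log[[k]] <- data.frame(
      frame = k - 1L,
      innovation_norm = sqrt(sum(inn^2)),
      raw_x = if (is.null(observations[[k]])) NA_real_ else observations[[k]]$base[1],
      raw_y = if (is.null(observations[[k]])) NA_real_ else observations[[k]]$base[2],
      raw_z = if (is.null(observations[[k]])) NA_real_ else observations[[k]]$base[3],
      filt_x = out_pose$base[1], filt_y = out_pose$base[2],
      filt_z = out_pose$base[3])
  }
  list(poses = poses, log = do.call(rbind, log))
}
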