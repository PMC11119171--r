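# --- end-to-end tracking pipeline ---------------------------------------

#' Tracking pipeline options
#'
#' @param needle_length Needle length (mm).
#' @param base_offset Distance (mm) from the gated-cloud centroid to the
#'   needle base along the needle; half the grabber length when the depth
#'   returns cover the grabber uniformly.
#' @param pixel_tol Image-line gate half-width (px) for [gate_points()].
#'   The clinical default is tight (4 px); for simulated scenes use
#'   [sim_pixel_tol()] so the gate spans the full grabber silhouette.
#' @param vote_threshold Hough vote threshold.
#' @param dilate_px Mask dilation for line selection / threshold tuning.
#' @param gwo [gwo_params()] for threshold tuning, or NULL to tune with
#'   defaults seeded by `seed`; set `tune = FALSE` to use fixed fractions
#'   of the gradient range instead (faster).
#' @param tune Tune edge thresholds with the Grey Wolf Optimizer on the
#'   first frame.
#' @param smoothing A [smoothing_params()].
#' @param seed Seed for the threshold tuner.
#' @return List of class `track_options`.
#' @export
track_options <- function(needle_length = 160, base_offset = 40,
                          pixel_tol = 4, vote_threshold = 20, dilate_px = 5,
                          gwo = NULL, tune = TRUE,
                          smoothing = smoothing_params(), seed = 1L) {
  structure(list(needle_length = needle_length, base_offset = base_offset,
                 pixel_tol = pixel_tol, vote_threshold = vote_threshold,
                 dilate_px = dilate_px, gwo = gwo, tune = tune,
                 smoothing = smoothing, seed = as.integer(seed)),
            class = "track_options")
}

#' Geometry-derived pixel gate for simulated scenes
#'
#' The gate must span the projected grabber silhouette plus a margin for
#' line-detection error, so that the full symmetric surface cloud is
#' retained: `fx * grabber_radius / distance + margin`.
#'
#' @param config A [sim_config()].
#' @param margin Extra slack in pixels.
#' @return Gate half-width in pixels.
#' @export
sim_pixel_tol <- function(config, margin = 8) {
  config$fx * config$grabber_radius / config$distance + margin
}

# orientation hint: the needle (bright, visible in RGB only) extends past
# one end of the grabber, the other end faces background. Compare mean
# image intensity along the fitted line beyond both grabber ends.
needle_side_hint <- function(image, fit, rig, base_offset) {
  if (base_offset <= 0) return(NULL)
  p <- world_to_pixel(rbind(fit$p0, fit$p0 + base_offset * fit$d), rig)
  step <- p[2, ] - p[1, ]
  if (sum(step^2) < 1e-12) return(NULL)
  fs <- seq(1.3, 3.0, by = 0.1)
  sample_side <- function(sgn) {
    uv <- cbind(p[1, 1] + sgn * fs * step[1], p[1, 2] + sgn * fs * step[2])
    rr <- round(uv[, 2]) + 1; cc <- round(uv[, 1]) + 1
    keep <- rr >= 1 & rr <= nrow(image) & cc >= 1 & cc <= ncol(image)
    if (!any(keep)) return(NA_real_)
    mean(image[cbind(rr[keep], cc[keep])])
  }
  plus <- sample_side(1); minus <- sample_side(-1)
  if (!is.finite(plus) || !is.finite(minus) || abs(plus - minus) < 0.02)
    return(NULL)
  sign(plus - minus) * fit$d
}

#' Track the needle in a single frame
#'
#' Full 2D -> 3D pipeline on one frame: tool segmentation, (optionally
#' GWO-tuned) edge detection, Hough transform, line selection against the
#' mask and previous line, depth-range gating, image-line gating of the
#' world cloud, robust 3D line fit and tip extrapolation. The needle
#' direction sign is resolved from the needle-side edge pixels (the needle
#' is visible in the image but yields no depth returns).
#'
#' @param image Greyscale image matrix in \[0,1\].
#' @param cloud Nx3 depth-camera-frame point cloud (mm).
#' @param rig A [camera_rig()].
#' @param opts A [track_options()].
#' @param prev_line Previously selected image line (for motion-consistent
#'   selection), or NULL.
#' @param thresholds Optional fixed c(low, high) edge thresholds (skips
#'   tuning).
#' @return List: `pose` ([needle_pose()]), `line` (selected image line),
#'   `mask`, `edges`, `thresholds`, `n_gated`, `fit` (the `needle_line3d`).
#' @export
track_frame <- function(image, cloud, rig, opts = track_options(),
                        prev_line = NULL, thresholds = NULL) {
  mask <- segment_tool(image)
  if (is.null(thresholds)) {
    if (opts$tune) {
      params <- opts$gwo
      if (is.null(params)) {
        pre0 <- canny_precompute(image, 1)
        params <- gwo_params(bounds = rbind(c(0, 0), rep(pre0$max_mag, 2)),
                             seed = opts$seed)
      }
      thresholds <- tune_edge_thresholds(image, mask, params = params,
                                         dilate_px = opts$dilate_px)
    } else {
      pre <- canny_precompute(image, 1)
      thresholds <- c(low = 0.1 * pre$max_mag, high = 0.3 * pre$max_mag)
      attr(thresholds, "precomp") <- pre
    }
  }
  pre <- attr(thresholds, "precomp")
  edges <- detect_edges(image, thresholds[["low"]], thresholds[["high"]],
                        precomp = pre)
  cand <- hough_lines(edges, vote_threshold = opts$vote_threshold)
  sel <- select_needle_line(cand, mask, prev = prev_line,
                            dilate_px = opts$dilate_px)
  world <- depth_to_world(range_gate(cloud), rig$depth_extrinsics)
  gated <- gate_points(world, sel, rig, pixel_tol = opts$pixel_tol)
  fit <- fit_line3d(gated)
  centroid <- colMeans(gated[fit$inliers, , drop = FALSE])
  hint <- needle_side_hint(image, fit, rig,
                           base_offset = max(opts$base_offset, 20))
  pose <- estimate_tip(fit, centroid, opts$needle_length,
                       base_offset = opts$base_offset, orient_hint = hint)
  attr(pose, "n_inliers") <- sum(fit$inliers)
  attr(pose, "residual_rms") <- fit$residual_rms
  list(pose = pose, line = sel, mask = mask, edges = edges,
       thresholds = thresholds[1:2], n_gated = nrow(gated), fit = fit)
}

#' Track the needle across a frame sequence
#'
#' Runs [track_frame()] per frame (edge thresholds tuned once on the first
#' frame and reused), then stabilises the raw poses with the Kalman + EMA
#' smoother. Frames where detection fails yield a predict-only step.
#'
#' @param frames List of `sim_frame` objects (or lists with `image`,
#'   `cloud`, `rig`).
#' @param opts A [track_options()].
#' @return List: `raw` (list of raw [needle_pose()] or NULL), `smoothed`
#'   (list of smoothed poses), `lines` (selected image lines), `log`
#'   (smoother log).
#' @export
track_frames <- function(frames, opts = track_options()) {
  stopifnot(length(frames) >= 1)
  thresholds <- NULL
  prev_line <- NULL
  raw <- vector("list", length(frames))
  lines <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    res <- tryCatch(
      track_frame(fr$image, fr$cloud, fr$rig, opts,
                  prev_line = prev_line, thresholds = thresholds),
      error = function(e) NULL)
    if (!is.null(res)) {
      raw[[k]] <- res$pose
      lines[[k]] <- res$line
      prev_line <- res$line
      if (is.null(thresholds)) {
        # reuse tuned thresholds; gradients are recomputed per frame
        thresholds <- res$thresholds
        attr(thresholds, "precomp") <- NULL
      }
    }
  }
  sm <- track_sequence(raw, params = opts$smoothing)
  list(raw = raw, smoothed = sm$poses, lines = lines, log = sm$log)
}
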