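# --- 2D needle line detection -------------------------------------------
#
# Image coordinates: matrices are [row, col] = [v + 1, u + 1] with 0-based
# pixel coordinates (u rightward, v downward). A detected line is the Hough
# normal parameterisation  u*cos(theta) + v*sin(theta) = r  with
# theta in [0, pi) (the angle of the line's NORMAL, not of the line itself)
# and signed r in pixels.

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian smoothing with edge replication
gauss_smooth <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, 0L, i - half - 1L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_mat(out, i - half - 1L, 0L)
  out2
}

# Sobel gradients; gx along u (columns), gy along v (rows, downward)
sobel_gradients <- function(m) {
  gx <- (shift_mat(m, -1L, 1L) + 2 * shift_mat(m, 0L, 1L) + shift_mat(m, 1L, 1L)) -
        (shift_mat(m, -1L, -1L) + 2 * shift_mat(m, 0L, -1L) + shift_mat(m, 1L, -1L))
  gy <- (shift_mat(m, 1L, -1L) + 2 * shift_mat(m, 1L, 0L) + shift_mat(m, 1L, 1L)) -
        (shift_mat(m, -1L, -1L) + 2 * shift_mat(m, -1L, 0L) + shift_mat(m, -1L, 1L))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# non-maximum suppression of gradient magnitude along the gradient direction
nms_magnitude <- function(gr) {
  ang <- atan2(gr$gy, gr$gx) %% pi
  mag <- gr$mag
  sector <- ifelse(ang < pi / 8 | ang >= 7 * pi / 8, 0L,
            ifelse(ang < 3 * pi / 8, 1L,
            ifelse(ang < 5 * pi / 8, 2L, 3L)))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  nb <- list(`0` = list(c(0L, 1L), c(0L, -1L)),      # horizontal gradient
             `1` = list(c(1L, 1L), c(-1L, -1L)),     # 45 deg
             `2` = list(c(1L, 0L), c(-1L, 0L)),      # vertical gradient
             `3` = list(c(1L, -1L), c(-1L, 1L)))     # 135 deg
  for (s in 0:3) {
    n1 <- shift_mat(mag, nb[[s + 1]][[1]][1], nb[[s + 1]][[1]][2])
    n2 <- shift_mat(mag, nb[[s + 1]][[2]][1], nb[[s + 1]][[2]][2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  out <- mag
  out[!keep] <- 0
  out
}

# label 8-connected components of a logical matrix (EBImage bwlabel is
# 4-connected; diagonal label adjacencies are merged through igraph)
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  nlab <- max(lab)
  if (nlab <= 1) return(list(labels = lab, groups = seq_len(nlab)))
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1), , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (d[2] == 1L) { a <- a[, seq_len(ncol(a) - 1), drop = FALSE]; b <- b[, -1, drop = FALSE] }
    else            { a <- a[, -1, drop = FALSE]; b <- b[, seq_len(ncol(b) - 1), drop = FALSE] }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (is.null(pairs)) {
    groups <- seq_len(nlab)
  } else {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nlab - igraph::vcount(g)))
    groups <- igraph::components(g)$membership[seq_len(nlab)]
  }
  list(labels = lab, groups = groups)
}

# dual-threshold hysteresis on a (suppressed) gradient magnitude map:
# keep weak pixels (>= low) only in 8-connected components containing a
# strong pixel (>= high)
hysteresis_8 <- function(mag, low, high) {
  weak <- mag >= low & mag > 0
  if (!any(weak)) return(weak)
  strong <- mag >= high
  l8 <- label8(weak)
  strong_groups <- unique(l8$groups[unique(l8$labels[strong & weak])])
  keep_lab <- which(l8$groups %in% strong_groups)
  out <- weak & matrix(l8$labels %in% keep_lab, nrow(mag), ncol(mag))
  out
}

# precompute the threshold-independent part of Canny edge detection
canny_precompute <- function(image, sigma = 1) {
  sm <- gauss_smooth(image, sigma)
  gr <- sobel_gradients(sm)
  list(nms = nms_magnitude(gr), max_mag = max(gr$mag))
}

#' Canny-style edge detection with dual-threshold hysteresis
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, then hysteresis: pixels with suppressed gradient
#' magnitude >= `high` seed edges, pixels >= `low` are kept when
#' 8-connected to a seed.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param low,high Hysteresis thresholds on gradient magnitude,
#'   `0 <= low <= high`.
#' @param sigma Gaussian smoothing std in pixels (0 disables smoothing).
#' @param precomp Optional result of the internal precomputation (used by
#'   the threshold tuner to avoid recomputing gradients).
#' @return Logical matrix of edge pixels, same shape as `image`.
#' @export
detect_edges <- function(image, low, high, sigma = 1, precomp = NULL) {
  if (low < 0 || low > high) stop("thresholds must satisfy 0 <= low <= high")
  if (is.null(precomp)) precomp <- canny_precompute(image, sigma)
  hysteresis_8(precomp$nms, low, high)
}

#' Tool segmentation stand-in
#'
#' Reference segmenter for the tool-grabber region: Otsu threshold on the
#' greyscale image, morphological opening (removing thin structures such as
#' the needle itself), and selection of the largest connected component.
#' This is a deterministic plug-in point: any function producing a logical
#' mask from an image (e.g. a trained instance-segmentation model) can be
#' used in its place throughout the pipeline.
#'
#' @param image Numeric matrix in \[0,1\] (greyscale) or HxWx3 array.
#' @param open_size Diameter (px, odd) of the disc used for opening.
#' @param min_px Minimum component area; smaller results are flagged empty.
#' @return Logical matrix mask (TRUE = tool region) with attribute
#'   `"empty"` (TRUE when no foreground was found).
#' @export
segment_tool <- function(image, open_size = 5, min_px = 20) {
  if (length(dim(image)) == 3)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  img <- pmin(pmax(image, 0), 1)
  mask <- matrix(FALSE, nrow(img), ncol(img))
  if (max(img) - min(img) > 1e-6) {
    th <- EBImage::otsu(img)
    bw <- img > th
    if (any(bw)) {
      op <- EBImage::opening(bw * 1, EBImage::makeBrush(open_size, "disc"))
      lab <- label8(op > 0)
      if (max(lab$labels) > 0) {
        sizes <- tabulate(lab$labels[lab$labels > 0])
        grp_sizes <- tapply(sizes, lab$groups, sum)
        best <- as.integer(names(which.max(grp_sizes)))
        if (grp_sizes[[as.character(best)]] >= min_px)
          mask <- matrix(lab$groups[pmax(lab$labels, 1)] == best, nrow(img), ncol(img)) &
                  lab$labels > 0
      }
    }
  }
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Grey Wolf Optimizer parameters
#'
#' @param n_wolves Population size (>= 3: alpha, beta, delta leaders).
#' @param n_iters Number of iterations.
#' @param bounds 2 x d matrix (row 1 = lower, row 2 = upper) or a list of
#'   c(lower, upper) per dimension.
#' @param seed Integer random seed (required; the optimizer is deterministic
#'   for a fixed seed).
#' @return An object of class `gwo_params`.
#' @export
gwo_params <- function(n_wolves = 20, n_iters = 30, bounds, seed) {
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2))
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2)
  if (n_wolves < 3) stop("GWO needs at least 3 wolves (alpha/beta/delta)")
  if (any(bounds[1, ] >= bounds[2, ])) stop("bounds must satisfy low < high")
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  structure(list(n_wolves = as.integer(n_wolves), n_iters = as.integer(n_iters),
                 bounds = bounds, seed = as.integer(seed)),
            class = "gwo_params")
}

#' Grey Wolf Optimizer
#'
#' Canonical continuous GWO: the three best wolves (alpha, beta, delta) pull
#' the pack, the exploration parameter `a` decays linearly 2 -> 0 over the
#' iterations, and positions are clamped to the bounds. Minimizes by
#' default.
#'
#' @param fitness Function of a numeric position vector returning a finite
#'   scalar.
#' @param params A [gwo_params()] object.
#' @param maximize If TRUE, maximize `fitness` instead.
#' @return List with `par` (best position), `value` (best fitness on the
#'   original scale) and `trace` (best-so-far objective per iteration,
#'   non-increasing on the minimization scale).
#' @export
gwo_optimize <- function(fitness, params, maximize = FALSE) {
  stopifnot(inherits(params, "gwo_params"))
  d <- ncol(params$bounds)
  lo <- params$bounds[1, ]; hi <- params$bounds[2, ]
  obj <- if (maximize) function(x) -fitness(x) else fitness
  withr::with_seed(params$seed, {
    X <- t(replicate(params$n_wolves, stats::runif(d, lo, hi)))
    if (d == 1) X <- matrix(X, ncol = 1)
    f <- apply(X, 1, obj)
    if (any(!is.finite(f))) stop("fitness must be finite over the bounds")
    trace <- numeric(params$n_iters)
    best_i <- which.min(f)
    best_par <- X[best_i, ]; best_f <- f[best_i]
    for (it in seq_len(params$n_iters)) {
      a <- 2 - 2 * (it - 1) / max(1, params$n_iters - 1)
      ord <- order(f)
      leaders <- X[ord[1:3], , drop = FALSE]
      for (i in seq_len(params$n_wolves)) {
        xnew <- numeric(d)
        for (k in 1:3) {
          r1 <- stats::runif(d); r2 <- stats::runif(d)
          A <- 2 * a * r1 - a
          C <- 2 * r2
          D <- abs(C * leaders[k, ] - X[i, ])
          xnew <- xnew + (leaders[k, ] - A * D)
        }
        X[i, ] <- pmin(pmax(xnew / 3, lo), hi)
        f[i] <- obj(X[i, ])
        if (f[i] < best_f) { best_f <- f[i]; best_par <- X[i, ] }
      }
      trace[it] <- best_f
    }
    list(par = best_par,
         value = if (maximize) -best_f else best_f,
         trace = if (maximize) -trace else trace)
  })
}

#' Tune edge-detection thresholds with the Grey Wolf Optimizer
#'
#' Searches hysteresis thresholds (low, high) maximizing a tool-focus
#' fitness: the fraction of edge pixels falling inside the tool mask dilated
#' by `dilate_px`, minus a mild penalty `lambda * |E - A| / A` where E is
#' the total edge count and A the mask perimeter estimate - rewarding edge
#' maps concentrated on the tool while discouraging degenerate all-or-none
#' maps.
#'
#' @param image Greyscale matrix in \[0,1\].
#' @param mask Logical tool mask (from [segment_tool()] or a plug-in).
#' @param params [gwo_params()]; `bounds` defaults to the gradient magnitude
#'   range when constructed by this function.
#' @param sigma Smoothing passed to [detect_edges()].
#' @param dilate_px Mask dilation radius in pixels.
#' @param lambda Edge-count penalty weight.
#' @return Numeric c(low, high) with attributes `fitness`, `flagged`
#'   (TRUE when the mask was empty and defaults were returned) and
#'   `precomp` (reusable gradient precomputation).
#' @export
tune_edge_thresholds <- function(image, mask, params = NULL, sigma = 1,
                                 dilate_px = 5, lambda = 0.1) {
  pre <- canny_precompute(image, sigma)
  if (is.null(dim(mask)) || !any(mask)) {
    out <- c(low = 0.1 * pre$max_mag, high = 0.3 * pre$max_mag)
    attr(out, "flagged") <- TRUE
    attr(out, "precomp") <- pre
    return(out)
  }
  if (is.null(params))
    params <- gwo_params(bounds = rbind(c(0, 0), rep(pre$max_mag, 2)), seed = 1L)
  dmask <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * dilate_px + 1, "disc")) > 0
  perim <- sum(mask & !(EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0))
  A <- max(perim, 1)
  fit <- function(x) {
    lo <- min(x); hi <- max(x)
    e <- hysteresis_8(pre$nms, lo, hi)
    E <- sum(e)
    if (E == 0) return(-1)
    sum(e & dmask) / (E + 1e-9) - lambda * abs(E - A) / A
  }
  res <- gwo_optimize(fit, params, maximize = TRUE)
  out <- c(low = min(res$par), high = max(res$par))
  attr(out, "fitness") <- res$value
  attr(out, "flagged") <- FALSE
  attr(out, "precomp") <- pre
  out
}

#' Hough transform vote accumulator
#'
#' Direct voting implementation of the normal line parameterisation
#' `u*cos(theta) + v*sin(theta) = r`: every edge pixel votes for the nearest
#' r bin at every theta bin.
#'
#' @param edges Logical matrix of edge pixels.
#' @param rho_res r resolution in pixels.
#' @param theta_res theta resolution in radians.
#' @return List with `votes` (n_r x n_theta integer matrix), `rho` (bin
#'   centers, signed pixels) and `theta` (bin centers in \[0, pi)).
#' @export
hough_accumulator <- function(edges, rho_res = 1, theta_res = pi / 180) {
  thetas <- seq(0, pi - 1e-12, by = theta_res)
  diag_len <- sqrt((nrow(edges) - 1)^2 + (ncol(edges) - 1)^2)
  K <- ceiling((diag_len + rho_res) / rho_res)
  rhos <- (-K:K) * rho_res
  votes <- matrix(0L, length(rhos), length(thetas))
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    x <- idx[, 2] - 1  # u
    y <- idx[, 1] - 1  # v
    R <- outer(x, cos(thetas)) + outer(y, sin(thetas))
    # nearest bin center k * rho_res, ties to the lower bin; the fractional
    # part is compared exactly (adding 0.5 before floor() double-rounds)
    q <- R / rho_res
    k <- floor(q)
    bin <- k + (q - k > 0.5) + K + 1L
    for (j in seq_along(thetas)) {
      tb <- tabulate(bin[, j], nbins = length(rhos))
      votes[, j] <- votes[, j] + tb
    }
  }
  list(votes = votes, rho = rhos, theta = thetas)
}

#' Detect lines by Hough transform
#'
#' Accumulates votes with [hough_accumulator()] and returns bins whose vote
#' count exceeds `vote_threshold` (i.e. sets of collinear edge pixels larger
#' than the threshold), optionally reduced to local accumulator maxima.
#'
#' @inheritParams hough_accumulator
#' @param vote_threshold Minimum sinusoid-intersection count (>= 2); bins
#'   with votes strictly greater are returned.
#' @param nms Keep only local maxima over a 3x3 accumulator neighbourhood.
#' @return data.frame with columns `r`, `theta`, `votes`, sorted by
#'   decreasing votes. Empty edge maps give an empty data.frame.
#' @export
hough_lines <- function(edges, rho_res = 1, theta_res = pi / 180,
                        vote_threshold = 20, nms = TRUE) {
  if (vote_threshold < 2) stop("vote_threshold must be >= 2")
  acc <- hough_accumulator(edges, rho_res, theta_res)
  V <- acc$votes
  keep <- V > vote_threshold
  if (nms && any(keep)) {
    mx <- V
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      mx <- pmax(mx, shift_mat(V, dr, dc))
    }
    keep <- keep & (V >= mx)
  }
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(r = acc$rho[idx[, 1]], theta = acc$theta[idx[, 2]],
                    votes = V[keep])
  out[order(-out$votes, out$theta, out$r), , drop = FALSE]
}

# rasterize the in-image pixels of a line (r, theta); returns matrix [row,col]
line_pixels <- function(r, theta, nrow_img, ncol_img) {
  ct <- cos(theta); st <- sin(theta)
  if (abs(st) >= abs(ct)) {
    u <- 0:(ncol_img - 1)
    v <- round((r - u * ct) / st)
    keep <- v >= 0 & v < nrow_img
    cbind(row = v[keep] + 1L, col = u[keep] + 1L)
  } else {
    v <- 0:(nrow_img - 1)
    u <- round((r - v * st) / ct)
    keep <- u >= 0 & u < ncol_img
    cbind(row = v[keep] + 1L, col = u[keep] + 1L)
  }
}

# orientation-aware distance between two Hough lines: c(dtheta, dr)
line_delta <- function(r1, th1, r2, th2) {
  dth <- abs(th1 - th2)
  if (dth <= pi / 2) c(dtheta = dth, dr = abs(r1 - r2))
  else c(dtheta = pi - dth, dr = abs(r1 + r2))
}

#' Select the needle line among Hough candidates
#'
#' Scores each candidate as
#' `w_m * mask_overlap - w_theta * dtheta(prev) - w_r * dr(prev)`
#' where `mask_overlap` is the fraction of the candidate's in-image pixels
#' falling inside the tool mask dilated by `dilate_px`, and the `prev` terms
#' (zero when `prev` is NULL) measure consistency with the previously
#' tracked line. Ties are broken by higher votes, then smaller theta.
#'
#' @param candidates data.frame from [hough_lines()] (columns r, theta,
#'   votes), non-empty.
#' @param mask Logical tool mask.
#' @param prev Previous selected line (list or one-row data.frame with
#'   `r`, `theta`) or NULL.
#' @param weights Named numeric c(w_m=, w_theta=, w_r=).
#' @param dilate_px Mask dilation radius (px).
#' @return One-row data.frame (r, theta, votes) with attribute `"score"`.
#' @export
select_needle_line <- function(candidates, mask, prev = NULL,
                               weights = c(w_m = 1.0, w_theta = 0.5, w_r = 0.01),
                               dilate_px = 5) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no candidate lines: needle not detected")
  dmask <- EBImage::dilate(mask * 1, EBImage::makeBrush(2 * dilate_px + 1, "disc")) > 0
  score <- vapply(seq_len(nrow(candidates)), function(i) {
    px <- line_pixels(candidates$r[i], candidates$theta[i], nrow(mask), ncol(mask))
    ov <- if (nrow(px) == 0) 0 else mean(dmask[px])
    s <- weights[["w_m"]] * ov
    if (!is.null(prev)) {
      d <- line_delta(candidates$r[i], candidates$theta[i],
                      prev$r[[1]], prev$theta[[1]])
      s <- s - weights[["w_theta"]] * d[["dtheta"]] - weights[["w_r"]] * d[["dr"]]
    }
    s
  }, numeric(1))
  ord <- order(-score, -candidates$votes, candidates$theta)
  best <- candidates[ord[1], , drop = FALSE]
  attr(best, "score") <- score[ord[1]]
  best
}
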