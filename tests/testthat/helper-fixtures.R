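# shared fixtures and independent oracles

# smaller scene for multi-frame tests
fast_config <- function(seed, ...) {
  sim_config(seed = seed, image_size = c(200L, 200L),
             fx = 175, fy = 175, cx = 100, cy = 100, ...)
}

# random proper rotation via QR (uses the caller's RNG state)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force Hough accumulator: direct evaluation of the normal line
# equation per pixel and bin, nearest-center assignment by explicit argmin
hough_brute <- function(edges, rho_res = 1, theta_res = pi / 180) {
  thetas <- seq(0, pi - 1e-12, by = theta_res)
  diag_len <- sqrt((nrow(edges) - 1)^2 + (ncol(edges) - 1)^2)
  K <- ceiling((diag_len + rho_res) / rho_res)
  rhos <- (-K:K) * rho_res
  votes <- matrix(0L, length(rhos), length(thetas))
  idx <- which(edges, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    x <- idx[i, 2] - 1
    y <- idx[i, 1] - 1
    for (j in seq_along(thetas)) {
      r <- x * cos(thetas[j]) + y * sin(thetas[j])
      k <- which.min(abs(rhos - r))
      votes[k, j] <- votes[k, j] + 1L
    }
  }
  list(votes = votes, rho = rhos, theta = thetas)
}

# standard tracking options for a simulated scene
sim_opts <- function(cfg, tune = FALSE, seed = 1L) {
  track_options(needle_length = cfg$needle_length,
                base_offset = cfg$grabber_length / 2,
                pixel_tol = sim_pixel_tol(cfg), tune = tune, seed = seed,
                gwo = if (tune) gwo_params(10, 10, rbind(c(0, 0), c(4, 4)),
                                           seed = seed))
}

expect_pose_close <- function(est, truth, tol) {
  pe <- pose_error(est, truth)
  expect_lt(pe$base_error, tol)
  expect_lt(pe$tip_error, tol)
}
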