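test_that("image-line gating retains exactly the points near the line", {
  rig <- camera_rig(camera_intrinsics(350, 350, 200, 200),
                    image_size = c(400, 400))
  line <- list(r = 150, theta = 0)  # vertical image line u = 150
  # points constructed on the back-projection of the line
  zs <- seq(300, 800, length.out = 20)
  on_line <- pixel_to_world(cbind(150, seq(50, 350, length.out = 20)), zs, rig)
  g <- gate_points(on_line, line, rig, pixel_tol = 3)
  expect_equal(nrow(g), 20L)

  off <- pixel_to_world(c(200, 100), 500, rig)  # 50 px off the line
  expect_equal(nrow(gate_points(off, line, rig, pixel_tol = 3)), 0L)

  # brute-force oracle over a random cloud
  set.seed(8)
  cloud <- cbind(rnorm(200, 0, 80), rnorm(200, 0, 80), runif(200, 300, 900))
  g2 <- gate_points(cloud, line, rig, pixel_tol = 4)
  uv <- world_to_pixel(cloud, rig)
  keep <- abs(uv[, 1] * cos(line$theta) + uv[, 2] * sin(line$theta) - line$r) <= 4
  expect_equal(g2, cloud[keep, , drop = FALSE], ignore_attr = TRUE)

  # behind-camera points are skipped and counted
  cloud_b <- rbind(cloud[1:5, ], c(0, 0, -100))
  gb <- gate_points(cloud_b, line, rig, pixel_tol = 4)
  expect_equal(attr(gb, "n_behind"), 1L)
})

test_that("3D line fitting is exact on collinear points and robust to outliers", {
  t <- seq(0, 100, length.out = 30)
  pts <- cbind(0 * t + 2, 0 * t - 1, t)
  f <- fit_line3d(pts)
  expect_lt(min(sum((f$d - c(0, 0, 1))^2), sum((f$d + c(0, 0, 1))^2)), 1e-18)
  expect_lt(f$residual_rms, 1e-9)

  two <- rbind(c(0, 0, 0), c(1, 1, 1))
  f2 <- fit_line3d(two)
  expect_lt(abs(abs(sum(f2$d * c(1, 1, 1) / sqrt(3))) - 1), 1e-12)

  expect_error(fit_line3d(rbind(c(1, 2, 3))), "at least 2")

  # 50 collinear + 3 gross outliers 100 mm off axis
  set.seed(12)
  clean <- cbind(rnorm(50, sd = 0.01), rnorm(50, sd = 0.01),
                 seq(0, 120, length.out = 50))
  dirty <- rbind(clean, cbind(c(100, -100, 100), c(0, 100, -50), c(30, 60, 90)))
  fc <- fit_line3d(clean)
  fd <- fit_line3d(dirty)
  ang <- acos(min(abs(sum(fc$d * fd$d)), 1)) * 180 / pi
  expect_lt(ang, 0.5)
  expect_lte(sum(fd$inliers), 51)
})

test_that("line fitting is invariant under rigid transforms of the cloud", {
  set.seed(21)
  pts <- cbind(rnorm(80, sd = 1), rnorm(80, sd = 1),
               seq(-40, 40, length.out = 80))
  f0 <- fit_line3d(pts)
  for (i in 1:5) {
    T <- rigid_transform(random_rotation(), rnorm(3, sd = 100))
    f1 <- fit_line3d(transform_points(T, pts))
    d0 <- as.numeric(T$R %*% f0$d)
    expect_lt(min(sum((f1$d - d0)^2), sum((f1$d + d0)^2)), 1e-16)
    expect_equal(f1$residual_rms, f0$residual_rms, tolerance = 1e-9)
  }
})

test_that("tip extrapolation orients away from the grabber and scales with length", {
  pts <- cbind(rep(0, 20), rep(0, 20), seq(0, 80, length.out = 20))
  f <- fit_line3d(pts)
  # a base at the origin pointing +z puts the tip one needle length out
  direct160 <- needle_pose(c(0, 0, 0), c(0, 0, 1), 160)
  expect_equal(direct160$tip, c(0, 0, 160))
  expect_equal(needle_pose(c(0, 0, 0), c(0, 0, 1), 120)$tip, c(0, 0, 120))

  # base = projection of the grabber centroid, tip needle_length further
  p160 <- estimate_tip(f, c(0, 0, -10), 160, base_offset = 0)
  expect_equal(unname(p160$base), c(0, 0, -10), tolerance = 1e-9)
  expect_equal(unname(p160$tip), c(0, 0, 150), tolerance = 1e-9)
  # base_offset advances the base along the needle direction
  p160b <- estimate_tip(f, c(0, 0, -10), 160, base_offset = 10)
  expect_equal(unname(p160b$base), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(p160b$tip), c(0, 0, 160), tolerance = 1e-9)

  # grabber centroid on either end flips the tip to the opposite end
  pA <- estimate_tip(f, c(0, 0, -10), 160)
  pB <- estimate_tip(f, c(0, 0, 170), 160)
  expect_equal(pA$direction, -pB$direction, tolerance = 1e-12)
  expect_gt(sum((pA$tip - pB$tip)^2), 100^2)

  # pose invariant: tip = base + length * direction
  expect_equal(pA$tip, pA$base + pA$length * pA$direction, tolerance = 1e-9)
  expect_error(needle_pose(c(0, 0, 0), c(0, 0, 0), 100), "degenerate")
  expect_error(needle_pose(c(0, 0, 0), c(0, 0, 1), -1), "positive")
})

test_that("near-range gate drops out-of-range depth points", {
  pts <- rbind(c(0, 0, 100), c(0, 0, 500), c(0, 0, 1500), c(300, 0, 400))
  g <- range_gate(pts)
  expect_equal(nrow(g), 2L)
  expect_equal(attr(g, "n_dropped"), 2L)
})

test_that("ASCII PLY files round-trip point clouds", {
  set.seed(2)
  pts <- matrix(rnorm(60, sd = 100), ncol = 3)
  f <- tempfile(fileext = ".ply")
  write_ply(pts, f)
  back <- read_ply(f)
  expect_equal(unname(back), unname(pts), tolerance = 1e-6)
  f2 <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_little_endian 1.0", "end_header"), f2)
  expect_error(read_ply(f2), "ASCII")
})
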