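five_markers <- function() {
  m <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100),
             c(50, 60, 70))
  rownames(m) <- paste0("M", 1:5)
  m
}

test_that("marker registration recovers identity and pure translation", {
  src <- five_markers()
  r <- register_markers(src, src)
  expect_lt(r$fre, 1e-9)
  expect_lt(max(abs(r$transform$R - diag(3))), 1e-9)
  expect_equal(r$transform$s, 1, tolerance = 1e-9)

  r2 <- register_markers(src, sweep(src, 2, c(-10, 0, 0)))
  expect_equal(r2$transform$t, c(10, 0, 0), tolerance = 1e-9)
  expect_equal(r2$transform$s, 1, tolerance = 1e-9)
  expect_lt(r2$fre, 1e-9)
})

test_that("a known similarity transform is recovered to 1e-9", {
  src <- five_markers()
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # +90 deg z
  T <- similarity_transform(2, Rz, c(1, 2, 3))
  dst <- apply_similarity(T, src)
  rownames(dst) <- rownames(src)
  r <- register_markers(src, dst, fix_scale = FALSE)
  expect_lt(abs(r$transform$s - 2), 1e-9)
  expect_lt(max(abs(r$transform$R - Rz)), 1e-9)
  expect_lt(max(abs(r$transform$t - c(1, 2, 3))), 1e-9)
  expect_lt(r$fre, 1e-9)

  # constrained fit: scale forced to 1, with a real residual
  rf <- register_markers(src, dst, fix_scale = TRUE)
  expect_identical(rf$transform$s, 1)
  expect_gt(rf$fre, 0)
})

test_that("registration residual matches an independent Procrustes fit", {
  set.seed(13)
  src <- matrix(rnorm(21, sd = 50), ncol = 3)
  rownames(src) <- paste0("m", 1:7)
  T <- similarity_transform(1.4, random_rotation(), rnorm(3, sd = 30))
  dst <- apply_similarity(T, src) + matrix(rnorm(21, sd = 1), ncol = 3)
  rownames(dst) <- rownames(src)
  r <- register_markers(src, dst)
  pro <- vegan::procrustes(dst, src, symmetric = FALSE)
  expect_equal(r$transform$s, pro$scale, tolerance = 1e-9)
  expect_equal(t(r$transform$R), unname(pro$rotation), tolerance = 1e-9)
  recon <- pro$scale * src %*% pro$rotation +
    matrix(pro$translation, nrow(src), 3, byrow = TRUE)
  expect_equal(apply_similarity(r$transform, src), recon,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("FRE is invariant under a common rigid motion of both marker sets", {
  set.seed(23)
  src <- five_markers()
  dst <- apply_similarity(similarity_transform(1, random_rotation(), rnorm(3)),
                          src) + matrix(rnorm(15, sd = 0.5), ncol = 3)
  rownames(dst) <- rownames(src)
  f0 <- register_markers(src, dst)$fre
  for (i in 1:5) {
    Tc <- rigid_transform(random_rotation(), rnorm(3, sd = 100))
    f1 <- register_markers(transform_points(Tc, src) * 1,
                           transform_points(Tc, dst) * 1)$fre
    expect_equal(f1, f0, tolerance = 1e-9)
  }
})

test_that("degenerate marker geometries are rejected", {
  lin <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  rownames(lin) <- paste0("M", 1:5)
  expect_error(register_markers(lin, lin), "collinear")
  two <- five_markers()[1:2, ]
  expect_error(register_markers(two, two), "at least 3")
  # id matching: fewer than 3 shared ids fails
  a <- five_markers(); b <- five_markers()
  rownames(b) <- c("M1", "M2", "X", "Y", "Z")
  expect_error(register_markers(a, b), "common marker ids")
})

test_that("the device/model chain equals one composed matrix application", {
  pose <- needle_pose(c(10, 20, 400), c(0, 0, 1), 160)
  expect_equal(apply_chain(pose), pose)
  M2 <- similarity_transform(2, diag(3), c(0, 0, 0))
  doubled <- apply_chain(pose, M = M2)
  expect_equal(doubled$length, 320)
  expect_equal(sqrt(sum((doubled$tip - doubled$base)^2)), 320, tolerance = 1e-9)

  set.seed(41)
  for (i in 1:5) {
    C <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3, sd = 20))
    M <- similarity_transform(runif(1, 0.5, 2), random_rotation(), rnorm(3, sd = 20))
    chained <- apply_chain(pose, C, M)
    H <- similarity_matrix(M) %*% similarity_matrix(C)  # homogeneous oracle
    tip_h <- (H %*% c(pose$tip, 1))[1:3]
    base_h <- (H %*% c(pose$base, 1))[1:3]
    expect_equal(chained$tip, tip_h, tolerance = 1e-9)
    expect_equal(chained$base, base_h, tolerance = 1e-9)
  }
})

test_that("trajectory planning extends through the entry point with rings on line", {
  tr <- plan_trajectory(c(0, 0, 0), c(0, 0, 100), extension = 50, n_rings = 5)
  expect_equal(tr$end, c(0, 0, 150))
  expect_equal(tr$direction, c(0, 0, 1))
  for (i in seq_len(nrow(tr$rings))) {
    d <- tr$rings[i, ] - tr$target
    perp <- d - sum(d * tr$direction) * tr$direction
    expect_lt(sqrt(sum(perp^2)), 1e-9)
  }
  expect_error(plan_trajectory(c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("alignment metrics classify collinear, offset and crossing needles", {
  tr <- plan_trajectory(c(0, 0, 0), c(0, 0, 100))
  aligned <- alignment_metrics(needle_pose(c(0, 0, 120), c(0, 0, 1), 160), tr)
  expect_equal(aligned$dist_base, 0)
  expect_equal(aligned$dist_tip, 0)
  expect_equal(aligned$angle, 0)
  expect_equal(aligned$state, "ALIGNED")

  offset <- alignment_metrics(needle_pose(c(5, 0, 0), c(0, 0, 1), 160), tr)
  expect_equal(offset$dist_base, 5, tolerance = 1e-9)
  expect_equal(offset$dist_tip, 5, tolerance = 1e-9)
  expect_equal(offset$angle, 0)
  expect_equal(offset$state, "NEAR")

  perp <- alignment_metrics(needle_pose(c(0, -80, 50), c(0, 1, 0), 160), tr)
  expect_equal(perp$angle, 90, tolerance = 1e-9)
  expect_equal(perp$state, "OFF")
})
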