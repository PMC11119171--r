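test_that("edge detection finds nothing on uniform images", {
  expect_equal(sum(detect_edges(matrix(0.5, 20, 20), 0.1, 0.3)), 0L)
})

test_that("a vertical intensity step yields edges confined to the step", {
  img <- matrix(0, 30, 30)
  img[, 15:30] <- 1
  e <- detect_edges(img, 0.5, 1.0)
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_gt(length(cols), 0)
  expect_true(all(cols %in% 13:16))
})

test_that("edge output is monotone in the high threshold", {
  set.seed(5)
  img <- matrix(runif(900), 30, 30)
  e1 <- detect_edges(img, 0.05, 0.2)
  e2 <- detect_edges(img, 0.05, 0.5)
  expect_true(all(which(e2) %in% which(e1)))
  expect_error(detect_edges(img, 0.5, 0.2), "low <= high")
})

test_that("hysteresis keeps weak edges only when 8-connected to strong ones", {
  # crafted suppressed-magnitude map: strong segment at rows 2-3 col 2,
  # weak segment diagonally touching it, and an isolated weak pixel
  mag <- matrix(0, 7, 7)
  mag[2, 2] <- 5; mag[3, 2] <- 5          # strong
  mag[4, 3] <- 1.5; mag[5, 3] <- 1.5      # weak, diagonal contact at (3,2)
  mag[2, 6] <- 1.5                        # isolated weak
  e <- needletrack:::hysteresis_8(mag, low = 1, high = 4)
  expect_true(all(e[cbind(c(2, 3, 4, 5), c(2, 2, 3, 3))]))
  expect_false(e[2, 6])
  expect_equal(sum(e), 4L)
})

test_that("the tool segmenter isolates the grabber region", {
  cfg <- sim_config(seed = 3, noise_px = 0.01, noise_depth = 0)
  fr <- simulate_frame(cfg)
  mask <- segment_tool(fr$image)
  expect_false(attr(mask, "empty"))
  iou <- sum(mask & fr$truth$footprint) / sum(mask | fr$truth$footprint)
  expect_gte(iou, 0.9)
  # projected grabber centroid lies inside the mask
  uv <- world_to_pixel(fr$truth$grabber_centroid, fr$rig)
  expect_true(mask[round(uv[1, 2]) + 1, round(uv[1, 1]) + 1])

  black <- segment_tool(matrix(0, 50, 50))
  expect_true(attr(black, "empty"))
  expect_equal(sum(black), 0L)
})

test_that("the Grey Wolf Optimizer solves simple benchmarks", {
  p <- gwo_params(20, 50, rbind(c(-10, -10), c(10, 10)), seed = 1)
  r <- gwo_optimize(function(x) sum(x^2), p)
  expect_lt(r$value, 1e-3)
  expect_true(all(r$par >= -10 & r$par <= 10))

  p1 <- gwo_params(20, 50, rbind(-10, 10), seed = 1)
  r1 <- gwo_optimize(function(x) (x - 3)^2, p1)
  expect_lt(abs(r1$par - 3), 0.1)

  # best-so-far trace is non-increasing and the run is deterministic
  expect_true(all(diff(r$trace) <= 0))
  r2 <- gwo_optimize(function(x) sum(x^2), p)
  expect_identical(r, r2)
  expect_error(gwo_params(2, 10, rbind(0, 1), seed = 1), "3 wolves")
  expect_error(gwo_params(10, 10, rbind(1, 0), seed = 1), "bounds")
})

test_that("GWO-tuned thresholds focus edges on the tool and dominate random pairs", {
  cfg <- sim_config(seed = 6, noise_px = 0.01, noise_depth = 0)
  fr <- simulate_frame(cfg)
  mask <- segment_tool(fr$image)
  params <- gwo_params(8, 8, rbind(c(0, 0), c(4, 4)), seed = 2)
  th <- tune_edge_thresholds(fr$image, mask, params = params)
  expect_lte(th[["low"]], th[["high"]])
  e <- detect_edges(fr$image, th[["low"]], th[["high"]])
  dmask <- EBImage::dilate(mask * 1, EBImage::makeBrush(11, "disc")) > 0
  expect_gte(sum(e & dmask), 1)

  # dominance over random threshold pairs from the same seed stream
  pre <- attr(th, "precomp")
  fitness <- function(lo, hi) {
    ed <- detect_edges(fr$image, lo, hi, precomp = pre)
    E <- sum(ed)
    if (E == 0) return(-1)
    perim <- sum(mask & !(EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0))
    sum(ed & dmask) / (E + 1e-9) - 0.1 * abs(E - perim) / max(perim, 1)
  }
  set.seed(2)
  rand <- replicate(10, sort(runif(2, 0, 4)))
  rand_fit <- apply(rand, 2, function(x) fitness(x[1], x[2]))
  expect_gte(attr(th, "fitness"), max(rand_fit))

  # determinism and empty-mask fallback
  th2 <- tune_edge_thresholds(fr$image, mask, params = params)
  expect_equal(th[1:2], th2[1:2])
  thE <- tune_edge_thresholds(fr$image, matrix(FALSE, 10, 10))
  expect_true(attr(thE, "flagged"))
})

test_that("Hough transform peaks at the expected line parameters", {
  e <- matrix(FALSE, 20, 20)
  e[3:12, 6] <- TRUE                      # x = 5 (0-based col)
  l <- hough_lines(e, vote_threshold = 5)
  expect_equal(l$r[1], 5)
  expect_equal(l$theta[1], 0)
  expect_equal(l$votes[1], 10L)

  # short lines tie neighbouring theta bins; the true bin must be among
  # the maximal-vote candidates
  e2 <- matrix(FALSE, 20, 20)
  e2[4, 5:14] <- TRUE                     # y = 3
  l2 <- hough_lines(e2, vote_threshold = 5)
  expect_equal(max(l2$votes), 10L)
  hit2 <- abs(l2$r - 3) < 1e-9 & abs(l2$theta - pi / 2) < 1e-9
  expect_true(any(hit2 & l2$votes == 10L))

  ed <- matrix(FALSE, 12, 12)
  ed[cbind(1:10, 1:10)] <- TRUE           # the diagonal y = x
  l3 <- hough_lines(ed, vote_threshold = 5)
  expect_equal(max(l3$votes), 10L)
  hit3 <- abs(l3$r) < 1e-9 & abs(l3$theta - 3 * pi / 4) < 1e-9
  expect_true(any(hit3 & l3$votes == 10L))

  expect_equal(nrow(hough_lines(matrix(FALSE, 5, 5), vote_threshold = 2)), 0L)
  expect_error(hough_lines(e, vote_threshold = 1), "vote_threshold")
})

test_that("Hough accumulator equals the brute-force accumulator", {
  maps <- list()
  m <- matrix(FALSE, 12, 12); m[cbind(1:10, 1:10)] <- TRUE
  maps$diag <- m
  set.seed(11)
  for (k in 1:4) {
    m <- matrix(FALSE, 32, 32)
    m[sample(length(m), 30)] <- TRUE
    maps[[paste0("rand", k)]] <- m
  }
  for (nm in names(maps)) {
    acc <- hough_accumulator(maps[[nm]])
    ref <- hough_brute(maps[[nm]])
    expect_identical(acc$votes, ref$votes)
    expect_equal(acc$rho, ref$rho)
    expect_equal(acc$theta, ref$theta)
  }
})

test_that("needle-line selection scores mask overlap and motion consistency", {
  mask <- matrix(FALSE, 100, 100)
  mask[20:80, 48:53] <- TRUE   # vertical bar around column x = 50
  only <- data.frame(r = 10, theta = 0, votes = 30L)
  expect_equal(select_needle_line(only, mask)$r, 10)

  cands <- data.frame(r = c(50, 10), theta = c(0, 0), votes = c(30L, 30L))
  expect_equal(select_needle_line(cands, mask)$r, 50)

  # equal mask overlap, previous line decides
  cands2 <- data.frame(r = c(50, 52), theta = c(0, 0), votes = c(30L, 30L))
  prev <- list(r = 52, theta = 0)
  expect_equal(select_needle_line(cands2, mask, prev = prev)$r, 52)

  # permutation invariance
  set.seed(4)
  cands3 <- data.frame(r = c(50, 10, 90, 52), theta = c(0, 0, pi / 4, 0),
                       votes = c(30L, 40L, 25L, 28L))
  sel1 <- select_needle_line(cands3, mask, prev = prev)
  for (i in 1:5) {
    perm <- cands3[sample(nrow(cands3)), ]
    sel2 <- select_needle_line(perm, mask, prev = prev)
    expect_equal(sel2$r, sel1$r)
    expect_equal(sel2$theta, sel1$theta)
  }
  expect_error(select_needle_line(cands3[0, ], mask), "no candidate")
})
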