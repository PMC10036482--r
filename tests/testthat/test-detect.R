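test_that("temporal-median background removes static structure", {
  # constant scene vanishes entirely
  st <- ImageStack(array(0.3, dim = c(20, 30, 6)), 25, 1)
  out <- subtractBackground(st)
  expect_true(all(out@frames == 0))

  # moving spot on a pedestal of 0.4: pedestal removed, spot kept
  frames <- lapply(1:8, function(f)
    spotFrame(40, 60, cbind(20, 6 * f), amp = 0.5, sigma = 1.5, bg = 0.4))
  out <- subtractBackground(ImageStack(frames, 25, 1))
  f3 <- getFrame(out, 3)
  expect_gt(f3[20, 18], 0.45)
  expect_lt(max(f3[, 40:60]), 1e-6)

  # stationary bright wall suppressed below the moving spot
  frames <- lapply(1:8, function(f) {
    fr <- spotFrame(40, 60, cbind(20, 6 * f), amp = 0.3, sigma = 1.5)
    fr[, 50] <- fr[, 50] + 0.8
    fr
  })
  out <- subtractBackground(ImageStack(frames, 25, 1))
  expect_lt(max(getFrame(out, 4)[, 50]), 0.1)
  expect_gt(max(getFrame(out, 4)[, 20:28]), 0.25)

  expect_error(subtractBackground(ImageStack(array(0, c(4, 4, 1)), 25, 1)),
               "at least two frames")
})

test_that("intensity adjustment saturates the top fraction and is idempotent", {
  fr <- matrix(0:999, 25, 40)
  out <- adjustIntensity(fr, 0.01)
  expect_gte(mean(out == 1), 0.01)          # >= 1 percent saturated
  expect_equal(out[fr == 990][1], 1)        # the 99th percentile hits full scale
  expect_equal(adjustIntensity(out, 0.01), out, tolerance = 1e-12)
  # rank preserved below the clip point
  below <- fr < 989
  expect_true(all(diff(out[order(fr)][below[order(fr)]]) >= 0))
  # fraction 0: max maps to full scale, nothing clips
  out0 <- adjustIntensity(fr, 0)
  expect_equal(sum(out0 == 1), sum(fr == 999))
  expect_warning(adjustIntensity(matrix(5, 3, 3)), "constant")
})

test_that("Hessian eigenmap marks bright blob interiors only", {
  fr <- spotFrame(41, 41, cbind(21, 21), amp = 0.8, sigma = 4)
  mask <- hessianCandidateMask(fr, hessianSigmaPx = 1.5)
  expect_true(mask[21, 21])
  # negative-definite region of a Gaussian is a disc of about one sigma
  idx <- which(mask, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 21)^2 + (idx[, 2] - 21)^2)
  expect_lt(max(d), 4 * 1.35)
  expect_true(all(mask[19:23, 19:23]))

  # inverted (dark) spot center is not marked
  dark <- 0.8 - fr
  expect_false(hessianCandidateMask(dark, 1.5)[21, 21])
  expect_true(hessianCandidateMask(dark, 1.5, darkBlobs = TRUE)[21, 21])

  # flat frame: empty mask
  expect_false(any(hessianCandidateMask(matrix(0.5, 20, 20), 1.5)))
})

test_that("segmentation splits touching spots, one region per peak", {
  fr <- spotFrame(41, 61, rbind(c(21, 25), c(21, 35)), amp = c(0.8, 0.8),
                  sigma = c(2, 2))
  expect_equal(bruteLocalMaxima(fr, floor = 0.1), 2L)
  mask <- hessianCandidateMask(fr, 1.5)
  lab <- segmentParticles(fr, mask, detectionParams(minPeakIntensity = 0.1))
  expect_equal(max(lab), 2L)
  expect_gt(lab[21, 25], 0)
  expect_gt(lab[21, 35], 0)
  expect_true(lab[21, 25] != lab[21, 35])
})

test_that("region growth stops at the refine fraction of the peak", {
  sigma <- 4
  fr <- spotFrame(61, 61, cbind(31, 31), amp = 0.78, sigma = sigma)
  mask <- hessianCandidateMask(fr, 1.5)
  lab <- segmentParticles(fr, mask, detectionParams(minPeakIntensity = 0.1))
  idx <- which(lab == 1L, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 31)^2 + (idx[, 2] - 31)^2)
  rExpect <- sigma * sqrt(2 * log(4))     # intensity = 25 percent of peak
  expect_equal(max(d), rExpect, tolerance = 0.12)
  expect_equal(nrow(idx), pi * rExpect^2, tolerance = 0.1)
})

test_that("region growth halts at Canny edges", {
  fr <- spotFrame(41, 41, cbind(20, 26), amp = 0.9, sigma = 2)
  fr[, 32:41] <- fr[, 32:41] + 0.8        # strong step edge at column 31/32
  edges <- cannyEdges(fr, sigma = 1)
  expect_true(any(edges[, 31:33]))
  mask <- hessianCandidateMask(fr, 1.5)
  # a low refine fraction makes the region want to cross the edge line
  lab <- segmentParticles(fr, mask,
                          detectionParams(minPeakIntensity = 0.1,
                                          refineFraction = 0.02))
  spotLab <- lab[20, 26]
  expect_gt(spotLab, 0)
  idx <- which(lab == spotLab, arr.ind = TRUE)
  expect_gte(max(idx[, 2]), 29)           # grew up to the edge ...
  expect_lte(max(idx[, 2]), 31)           # ... but never onto the bright side
})

test_that("feature measurement matches geometry on analytic shapes", {
  # uniform disc of radius 5
  fr <- matrix(0, 31, 31)
  rr <- matrix(1:31, 31, 31); cc <- t(rr)
  fr[(rr - 16)^2 + (cc - 16)^2 <= 25] <- 0.7
  lab <- matrix(0L, 31, 31); lab[fr > 0] <- 1L
  obs <- measureFeatures(fr, lab)
  expect_equal(obs$x_px, 16)
  expect_equal(obs$y_px, 16)
  expect_equal(obs$area_px2, 81)
  expect_equal(obs$diameter_px, 2 * sqrt(81 / pi))
  expect_equal(obs$brightness, 0.7)

  # 2:1 anisotropic Gaussian aligned with x: orientation about 0
  fr2 <- outer(exp(-((1:41) - 21)^2 / (2 * 2^2)),
               exp(-((1:41) - 21)^2 / (2 * 4^2)))
  lab2 <- matrix(0L, 41, 41); lab2[fr2 > 0.05] <- 1L
  obs2 <- measureFeatures(fr2, lab2)
  expect_equal(obs2$orientation_rad, 0, tolerance = 1e-6)

  # doubling exposure doubles brightness, leaves geometry unchanged
  obs3 <- measureFeatures(2 * fr2, lab2)
  expect_equal(obs3$brightness, 2 * obs2$brightness)
  expect_equal(obs3$area_px2, obs2$area_px2)
  expect_equal(obs3$orientation_rad, obs2$orientation_rad)
})

test_that("detection is complete and accurate on clean rendered stacks", {
  # 8 well-separated particles, SNR >= 10, moderate motion
  truth <- linearTruth(8, 12, x0 = seq(40, 600, by = 80),
                       y0 = rep(c(40, 90), 4), vxUmPerFrame = rep(6, 8),
                       frameRate = 25)
  params <- renderParams(pixelSize = 2, frameRate = 25, psfSigmaPx = 1.5,
                         fovPx = c(70L, 400L), originUm = c(0, 0),
                         background = 0.05, brightnessPerVolume = 0.08,
                         bleachRate = 0.002, illuminationAmplitude = 0.15,
                         readNoiseSd = 0.01)
  st <- renderStack(truth, params, seed = 5)
  det <- detectParticles(st)
  p <- particlePaths(truth)
  p$x_px <- p$x_um / 2 + 0.5
  p$y_px <- p$y_um / 2 + 0.5
  err <- vapply(seq_len(nrow(p)), function(i) {
    d <- det[det$frame == p$frame[i], ]
    min(sqrt((d$x_px - p$x_px[i])^2 + (d$y_px - p$y_px[i])^2))
  }, 0)
  expect_gte(mean(err <= 0.5), 0.99)
})

test_that("pure-noise stacks yield almost no false detections", {
  set.seed(42)
  arr <- array(pmax(0.05 + rnorm(64 * 96 * 20, 0, 0.01), 0),
               dim = c(64, 96, 20))
  det <- detectParticles(ImageStack(arr, 25, 2))
  expect_lte(nrow(det) / 20, 0.1)
})

test_that("integer translation shifts centroids exactly", {
  fr <- spotFrame(50, 70, rbind(c(20, 25), c(32, 50)), amp = c(0.7, 0.5),
                  sigma = c(2, 2.5))
  shifted <- matrix(0, 50, 70)
  shifted[(1 + 4):50, (1 + 6):70] <- fr[1:(50 - 4), 1:(70 - 6)]
  seg <- function(m) {
    lab <- segmentParticles(m, hessianCandidateMask(m, 1.5),
                            detectionParams(minPeakIntensity = 0.1))
    obs <- measureFeatures(m, lab)
    obs[order(obs$x_px), ]
  }
  a <- seg(fr); b <- seg(shifted)
  expect_equal(b$x_px, a$x_px + 6, tolerance = 1e-9)
  expect_equal(b$y_px, a$y_px + 4, tolerance = 1e-9)
})
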