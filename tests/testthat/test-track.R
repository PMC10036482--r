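test_that("link cost is zero for identical observations and Inf past the gate", {
  a <- makeObs(1, 10, 10)
  b <- makeObs(2, 10, 10)
  expect_equal(linkCost(a, b), 0)
  far <- makeObs(2, 40, 10)
  expect_identical(linkCost(a, far, linkingParams(maxDisplacementPx = 20)),
                   Inf)
})

test_that("feature similarity breaks geometric ties", {
  a <- makeObs(1, 0, 0, brightness = 0.8)
  b1 <- makeObs(2, 10, 0, brightness = 0.8)   # equidistant, matching
  b2 <- makeObs(2, -10, 0, brightness = 0.4)  # equidistant, dimmer
  sc <- c(brightness = 0.1, area = 1, diameter = 1, orientation = 1)
  expect_lt(linkCost(a, b1, scales = sc), linkCost(a, b2, scales = sc))
})

test_that("crossing particles keep identity through feature contrast", {
  p <- linkingParams(maxDisplacementPx = 15)
  big <- list(brightness = 0.9, area = 60, diameter = 8.7)
  small <- list(brightness = 0.45, area = 20, diameter = 5)
  obsA <- rbind(makeObs(1, 0, 0, big$brightness, big$area, big$diameter),
                makeObs(1, 10, 0, small$brightness, small$area,
                        small$diameter))
  # they cross: the big one is now on the right
  obsB <- rbind(makeObs(2, 6, 0, small$brightness, small$area,
                        small$diameter),
                makeObs(2, 4, 0, big$brightness, big$area, big$diameter))
  sc <- c(brightness = 0.05, area = 5, diameter = 0.5, orientation = 1)
  m <- linkFrames(obsA, obsB, p, scales = sc)
  expect_equal(m[order(m$i), ]$j, c(2L, 1L))  # identities preserved
})

test_that("single in-gate candidates are matched, out-of-view ends are not", {
  p <- linkingParams(maxDisplacementPx = 20)
  m <- linkFrames(makeObs(1, 5, 5), makeObs(2, 12, 5), p)
  expect_equal(nrow(m), 1L)
  # a particle that left the field simply terminates
  m2 <- linkFrames(rbind(makeObs(1, 5, 5), makeObs(1, 100, 5)),
                   makeObs(2, 12, 5), p)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$i, 1L)
  expect_equal(nrow(linkFrames(makeObs(1, 5, 5)[0, ], makeObs(2, 1, 1), p)),
               0L)
})

test_that("assignment equals the exhaustive-search optimum (<= 6 particles)", {
  p <- linkingParams(maxDisplacementPx = 12)
  sc <- c(brightness = 0.05, area = 5, diameter = 0.5, orientation = 0.5)
  for (seed in 1:12) {
    set.seed(seed)
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    obsA <- makeObs(1, runif(nA, 0, 30), runif(nA, 0, 30),
                    brightness = runif(nA, 0.3, 1),
                    area = sample(15:60, nA, TRUE),
                    diameter = runif(nA, 4, 9),
                    orientation = runif(nA, -pi / 2, pi / 2))
    obsB <- makeObs(2, runif(nB, 0, 30), runif(nB, 0, 30),
                    brightness = runif(nB, 0.3, 1),
                    area = sample(15:60, nB, TRUE),
                    diameter = runif(nB, 4, 9),
                    orientation = runif(nB, -pi / 2, pi / 2))
    cost <- hemoflow:::linkCostMatrix(obsA, obsB, p, sc)
    m <- linkFrames(obsA, obsB, p, scales = sc)
    got <- sum(cost[cbind(m$i, m$j)])
    best <- bruteAssignment(cost)
    expect_equal(nrow(m), best$card)
    expect_equal(got, best$cost, tolerance = 1e-9)
  }
})

steadyDetections <- function(n = 5, nFrames = 30, step = 4) {
  do.call(rbind, lapply(seq_len(nFrames), function(f)
    makeObs(f, (1:n) * 40 + f * step, 10,
            brightness = 0.4 + (1:n) / 10, area = 18 + (1:n),
            diameter = 4 + (1:n) / 5)))
}

test_that("steady scenes give one trajectory per particle", {
  det <- steadyDetections()
  ts <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10))
  expect_equal(nParticles(ts), 5L)
  expect_true(all(table(trackTable(ts)$track_id) == 30))
})

test_that("a mid-sequence birth adds exactly one trajectory", {
  det <- steadyDetections()
  det <- rbind(det, makeObs(15:30, 300 + (0:15) * 4, 30))
  ts <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10))
  expect_equal(nParticles(ts), 6L)
})

test_that("gap closing bridges a single dropped detection", {
  det <- steadyDetections(n = 1)
  det <- det[det$frame != 15, ]
  noGap <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10,
                                                maxGapFrames = 0L))
  expect_equal(nParticles(noGap), 2L)
  gap <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10,
                                              maxGapFrames = 1L))
  expect_equal(nParticles(gap), 1L)
  expect_equal(nrow(trackTable(gap)), 29L)
})

test_that("trajectory filter keeps >= 25 points, boundary inclusive", {
  det <- do.call(rbind, lapply(c(a = 10, b = 24, c = 25, d = 40),
                               function(len) NULL))
  lens <- c(10, 24, 25, 40)
  det <- do.call(rbind, Map(function(len, k)
    makeObs(seq_len(len), k * 100 + seq_len(len) * 2, 10), lens, 1:4))
  ts <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10))
  expect_equal(nParticles(ts), 4L)
  kept <- suppressMessages(filterTrajectories(ts, 25L))
  expect_equal(nParticles(kept), 2L)
  expect_setequal(unname(table(trackTable(kept)$track_id)), c(25L, 40L))
  expect_warning(suppressMessages(filterTrajectories(ts, 100L)),
                 "no trajectory")
  all3 <- suppressMessages(filterTrajectories(ts, 2L))
  expect_equal(nParticles(all3), 4L)
})

test_that("shuffling observations within frames leaves trajectories unchanged", {
  det <- steadyDetections()
  set.seed(3)
  shuf <- det[sample(nrow(det)), ]
  canon <- function(ts) {
    tr <- trackTable(ts)
    tr <- tr[order(tr$track_id, tr$frame), ]
    unname(split(paste(tr$frame, tr$x_px, tr$y_px),
                 tr$track_id))[order(vapply(split(tr$x_px, tr$track_id),
                                            `[`, 0, 1))]
  }
  t1 <- buildTrajectories(det, linkingParams(maxDisplacementPx = 10))
  t2 <- buildTrajectories(shuf, linkingParams(maxDisplacementPx = 10))
  expect_equal(canon(t1), canon(t2))
})

test_that("stuck particles are flagged and excluded from kinematics", {
  moving <- makeObs(1:30, 10 + (1:30) * 3, 10)
  stuck <- makeObs(1:30, 200 + rnorm(30, 0, 0.3), 50)
  ts <- buildTrajectories(rbind(moving, stuck),
                          linkingParams(maxDisplacementPx = 10))
  ts <- flagStuckTracks(ts, stuckNoisePx = 1)
  expect_equal(length(ts@flagged), 1L)
  kin <- trajectoryKinematics(ts)
  expect_equal(nrow(kin), 1L)
  expect_equal(nrow(trajectoryKinematics(ts, dropFlagged = FALSE)), 2L)
})

test_that("assignments are strictly one-to-one", {
  p <- linkingParams(maxDisplacementPx = 20)
  # two track ends competing for a single observation: only one wins
  ends <- rbind(makeObs(1, 1, 1), makeObs(1, 2, 1))
  m <- linkFrames(ends, makeObs(2, 1.5, 1), p)
  expect_equal(nrow(m), 1L)
  expect_equal(anyDuplicated(m$j), 0L)
})
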