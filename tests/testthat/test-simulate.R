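test_that("buildWingNetwork constructs connected labeled networks", {
  # smallest legal graph: 2 longitudinal veins joined by 1 cross vein
  net <- buildWingNetwork(list(
    span_um = 3000, chord_um = 240, longitudinal = c(0.08, 0.85),
    cross = 1, labels = c("leading_edge", "trailing_edge", "wing_tip"),
    requireAllRegions = FALSE))
  expect_s4_class(net, "VeinNetwork")
  expect_equal(nrow(net@segments), 3L)

  net <- buildWingNetwork()
  expect_setequal(regionLabels(net),
                  c("leading_edge", "membrane", "wing_tip", "lattice",
                    "trailing_edge"))
  dia <- 2 * net@segments$radius_um
  lead <- net@segments$region == "leading_edge"
  expect_true(all(dia[lead] >= 170 & dia[lead] <= 250))
})

test_that("buildWingNetwork rejects inconsistent diameter ordering", {
  expect_error(
    buildWingNetwork(list(diameters = list(
      leading_edge = c(170, 250), membrane = c(80, 120),
      wing_tip = c(180, 260), lattice = c(60, 90),
      trailing_edge = c(170, 250)))),
    "inconsistent geometry")
})

test_that("VeinNetwork validity enforces radii and connectivity", {
  seg <- data.frame(node_a = "a", node_b = "b", radius_um = -1,
                    region = "lattice")
  nodes <- rbind(a = c(0, 0), b = c(100, 0))
  expect_error(methods::new("VeinNetwork", nodes = nodes, segments = seg),
               "positive")
  seg2 <- data.frame(node_a = c("a", "c"), node_b = c("b", "d"),
                     radius_um = 30, region = "lattice")
  nodes2 <- rbind(a = c(0, 0), b = c(100, 0), c = c(0, 50), d = c(100, 50))
  expect_error(methods::new("VeinNetwork", nodes = nodes2, segments = seg2),
               "connected")
})

aperiodicNet <- function(spanUm = 2000) {
  buildWingNetwork(list(
    span_um = spanUm, chord_um = 240, longitudinal = c(0.08, 0.85),
    cross = 1, labels = c("leading_edge", "trailing_edge", "wing_tip"),
    requireAllRegions = FALSE))
}

constBehaviors <- function(speed) {
  b <- flowBehavior("aperiodic", baseSpeed = speed, modDepth = 0)
  list(leading_edge = b, trailing_edge = b, wing_tip = b)
}

test_that("aperiodic constant-speed kinematics are exact", {
  truth <- simulateParticles(aperiodicNet(), constBehaviors(100),
                             nParticles = 1, duration = 2, frameRate = 10,
                             seed = 1, segmentIds = 1L)
  p <- particlePaths(truth)
  steps <- sqrt(diff(p$x_um)^2 + diff(p$y_um)^2)
  expect_equal(steps, rep(10, 19), tolerance = 1e-12)
})

test_that("pulsatile paths pulse at the imposed frequency with net transport", {
  net <- aperiodicNet(spanUm = 20000)
  beh <- constBehaviors(100)
  beh$leading_edge <- flowBehavior("pulsatile", baseSpeed = 500,
                                   pulseFreqHz = 2, reversalFraction = 0.25)
  truth <- simulateParticles(net, beh, 1, duration = 10, frameRate = 100,
                             seed = 1, segmentIds = 1L)
  p <- particlePaths(truth)
  v <- diff(p$x_um)                       # signed along-vein velocity
  # forward pulses counted by upward zero-crossings of the velocity
  up <- sum(v[-1] > 1e-9 & v[-length(v)] <= 1e-9)
  expect_equal(up, 20L, tolerance = 1)
  expect_gt(p$x_um[nrow(p)], p$x_um[1])   # net forward transport
})

test_that("pulsatile net displacement is positive over whole periods", {
  for (rev in c(0, 0.4, 0.8)) {
    t <- seq(0, 5, by = 0.001)
    v <- hemoflow:::signedPulsatile(t, 1, 300, rev)
    expect_gt(sum(v) * 0.001, 0)
  }
})

test_that("leaky particles exit the veins into the sinus polygon", {
  net <- buildWingNetwork(list(
    span_um = 4000, chord_um = 1500, longitudinal = c(0.08, 0.5, 0.85),
    cross = c(0.55, 0.87)))
  sinus <- matrix(c(2200, 200, 3400, 200, 3400, 700, 2200, 700),
                  ncol = 2, byrow = TRUE)
  beh <- list(leading_edge = flowBehavior("aperiodic", baseSpeed = 200),
              membrane = flowBehavior("leaky", baseSpeed = 500,
                                      sinusPolygon = sinus),
              wing_tip = flowBehavior("aperiodic", baseSpeed = 200),
              lattice = flowBehavior("aperiodic", baseSpeed = 200),
              trailing_edge = flowBehavior("aperiodic", baseSpeed = 200))
  memSeg <- which(net@segments$region == "membrane")[1]
  truth <- simulateParticles(net, beh, 1, duration = 3, frameRate = 30,
                             seed = 2, segmentIds = memSeg)
  p <- particlePaths(truth)
  xy <- cbind(p$x_um, p$y_um)
  outside <- !insideVeinChannel(xy, net)
  inSinus <- pracma::inpolygon(xy[, 1], xy[, 2], sinus[, 1], sinus[, 2],
                               boundary = TRUE)
  expect_true(any(outside & inSinus))
  expect_true(isLeakyTrajectory(xy, net, list(sinus)))
})

test_that("simulation is deterministic and conserves particle identities", {
  net <- aperiodicNet()
  t1 <- simulateParticles(net, constBehaviors(300), 8, 1, 25, seed = 7)
  t2 <- simulateParticles(net, constBehaviors(300), 8, 1, 25, seed = 7)
  expect_identical(particlePaths(t1), particlePaths(t2))
  p <- particlePaths(t1)
  expect_equal(unname(table(p$particle_id)), rep(25L, 8),
               ignore_attr = TRUE)       # no particle ever vanishes
})

test_that("degenerate simulation inputs are handled", {
  net <- aperiodicNet()
  empty <- simulateParticles(net, constBehaviors(300), 0, 1, 25, seed = 1)
  expect_equal(nrow(particlePaths(empty)), 0L)
  beh <- constBehaviors(300)
  beh$leading_edge <- flowBehavior("pulsatile", baseSpeed = 300,
                                   pulseFreqHz = 0.2)
  expect_warning(
    simulateParticles(net, beh, 1, duration = 1, frameRate = 25, seed = 1),
    "pulse period")
  expect_error(
    simulateParticles(net, list(leading_edge = beh$leading_edge), 1, 1, 25),
    "no flow behavior")
})

test_that("pulse frequency of noise-free waveforms is recovered within one bin", {
  for (f in c(0.5, 1.25, 2)) {
    tr <- pulsatileSpeedTrace(f, duration = 20, sampleRate = 100)
    expect_lt(abs(pulseFrequency(tr, 20) - f), 1 / 20 + 1e-9)
  }
})

test_that("FlowBehavior validity rejects bad parameters", {
  expect_error(flowBehavior("pulsatile", pulseFreqHz = 0), "pulseFreqHz")
  expect_error(flowBehavior("pulsatile", reversalFraction = 1),
               "reversalFraction")
  expect_error(flowBehavior("aperiodic", modDepth = 1), "modDepth")
  expect_error(flowBehavior("leaky"), "sinus polygon")
})
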