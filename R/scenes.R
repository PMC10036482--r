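# scenes: ready-made synthetic study scenes. Their defaults encode the
# benchmark conditions used throughout the tests: the top wing speed of
# 2.6 mm/s for velocity recovery, and the forewing (1.5) and hindwing
# (1.3) inflow/outflow maximum-velocity ratios for region recovery.

#' Straight-vein constant-speed scene
#'
#' One particle advected at a constant imposed speed along a straight
#' leading-edge vein, rendered at 100 fps and 1 um/px into a long strip
#' field of view with bleaching, uneven illumination and read noise
#' (spot SNR well above 10). The imposed speed defaults to the top of the
#' grasshopper wing velocity range (2.6 mm/s); the strip is long enough
#' that the trajectory comfortably exceeds the 25-point filter.
#'
#' @param speedMmS imposed constant speed, mm/s.
#' @param duration seconds simulated (default 1 s = 100 frames).
#' @param seed integer seed.
#' @return list(truth, params, network, linking): the ground truth, the
#'   [RenderParams-class], the network, and matched [LinkingParams-class].
#' @export
sceneConstantSpeed <- function(speedMmS = 2.6, duration = 1, seed = 1) {
  spanUm <- 1000 * speedMmS * duration * 1.15 + 200
  net <- buildWingNetwork(list(
    span_um = spanUm, chord_um = 240, longitudinal = c(0.08, 0.85),
    cross = 1, labels = c("leading_edge", "trailing_edge", "wing_tip"),
    requireAllRegions = FALSE))
  beh <- flowBehavior("aperiodic", baseSpeed = 1000 * speedMmS,
                      modDepth = 0)
  truth <- simulateParticles(net, list(leading_edge = beh,
                                       trailing_edge = beh, wing_tip = beh),
                             nParticles = 1, duration = duration,
                             frameRate = 100, seed = seed,
                             particleDiametersUm = 6, startFraction = 0.1,
                             segmentIds = 1L)
  y0 <- particlePaths(truth)$y_um[1]
  params <- renderParams(pixelSize = 1, frameRate = 100, psfSigmaPx = 1.3,
                         fovPx = c(64L, as.integer(ceiling(spanUm))),
                         originUm = c(0, y0 - 32), background = 0.04,
                         brightnessPerVolume = 0.12, bleachRate = 0.002,
                         illuminationAmplitude = 0.15, readNoiseSd = 0.01)
  linking <- linkingParams(maxDisplacementPx = ceiling(
    1.6 * 1000 * speedMmS / 100))
  list(truth = truth, params = params, network = net, linking = linking)
}

#' Two-region wing scene with an imposed inflow/outflow speed ratio
#'
#' A leading-edge and a trailing-edge vein carrying constant-speed
#' particles whose imposed maximum-velocity ratio (inflow over outflow)
#' is the scene parameter: 1.5 reproduces the forewing condition, 1.3 the
#' hindwing. Twenty particles per region by default, rendered at 50 fps
#' and 2 um/px.
#'
#' @param ratio imposed leading/trailing maximum-speed ratio.
#' @param outflowSpeedMmS trailing-edge (outflow) speed, mm/s.
#' @param nPerRegion particles per region.
#' @param duration seconds simulated.
#' @param seed integer seed.
#' @return list(truth, params, network, linking, wingFrame).
#' @export
sceneTwoRegionWing <- function(ratio = 1.5, outflowSpeedMmS = 1.0,
                               nPerRegion = 20, duration = 0.64, seed = 1) {
  spanUm <- 2000; chordUm <- 600
  net <- buildWingNetwork(list(
    span_um = spanUm, chord_um = chordUm, longitudinal = c(0.1, 0.9),
    cross = 1, labels = c("leading_edge", "trailing_edge", "wing_tip"),
    requireAllRegions = FALSE))
  vOut <- 1000 * outflowSpeedMmS
  beh <- list(
    leading_edge = flowBehavior("aperiodic", baseSpeed = ratio * vOut,
                                modDepth = 0),
    trailing_edge = flowBehavior("aperiodic", baseSpeed = vOut,
                                 modDepth = 0),
    wing_tip = flowBehavior("aperiodic", baseSpeed = vOut, modDepth = 0))
  truth <- simulateParticles(net, beh, 2 * nPerRegion, duration,
                             frameRate = 50, seed = seed,
                             particleDiametersUm = 6,
                             startFraction = 0.45, segmentIds = c(1L, 2L))
  params <- renderParams(pixelSize = 2, frameRate = 50, psfSigmaPx = 1.3,
                         fovPx = c(340L, 1040L), originUm = c(-40, -40),
                         background = 0.04, brightnessPerVolume = 0.12,
                         bleachRate = 0.002, illuminationAmplitude = 0.15,
                         readNoiseSd = 0.01)
  linking <- linkingParams(maxDisplacementPx = ceiling(
    1.3 * ratio * vOut / 50 / 2))
  wingFrame <- list(base = c(0, 0), tip = c(spanUm, 0),
                    leading = c(0, 0), trailing = c(0, chordUm))
  list(truth = truth, params = params, network = net, linking = linking,
       wingFrame = wingFrame)
}

#' Recover the region-wise maximum-velocity ratio of a two-region scene
#'
#' Runs the full measurement chain (render, detect, track, analyze,
#' region assignment, per-region summary) on a [sceneTwoRegionWing()]
#' scene and returns the recovered inflow/outflow ratio of region-mean
#' maximum velocities.
#'
#' @param scene a [sceneTwoRegionWing()] result.
#' @param seed seed for the rendering noise.
#' @return list(ratio, summary): the recovered ratio and the per-region
#'   summary table.
#' @export
recoverRegionRatio <- function(scene, seed = 1) {
  stack <- renderStack(scene$truth, scene$params, seed = seed)
  det <- detectParticles(stack)
  ts <- trackParticles(det, scene$linking,
                       pixelSize = scene$params@pixelSize,
                       frameRate = scene$params@frameRate)
  kin <- trajectoryKinematics(ts)
  startUm <- cbind(kin$start_x_px, kin$start_y_px) *
    scene$params@pixelSize - 0.5 * scene$params@pixelSize +
    rep(scene$params@originUm, each = nrow(kin))
  norm <- normalizeCoordinates(startUm, scene$wingFrame)
  kin$region <- vapply(seq_len(nrow(norm)), function(i)
    assignRegion(norm[i, ]), "")
  summ <- summarizeRegions(kin)
  list(ratio = summ$v_max_mm_s[summ$region == "leading_edge"] /
         summ$v_max_mm_s[summ$region == "trailing_edge"],
       summary = summ)
}
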