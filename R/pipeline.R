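# pipeline: orchestrate simulate -> render -> detect -> track -> analyze
# -> summarize from one config, with seeded reproducibility, and score
# results against ground truth.

behaviorFromSpec <- function(b) {
  if (is(b, "FlowBehavior")) return(b)
  if (!is.null(b$sinusPolygon) && !is.matrix(b$sinusPolygon))
    b$sinusPolygon <- matrix(unlist(b$sinusPolygon), ncol = 2, byrow = TRUE)
  do.call(flowBehavior, b)
}

#' Default pipeline configuration
#'
#' A complete runnable demo: a compact five-region wing network,
#' pulsatile flow on the leading/trailing edges, aperiodic flow in tip
#' and lattice, leaky flow through the membrane sinus, rendered at 30 fps
#' and 4 um per px with bleaching, uneven illumination and read noise.
#'
#' @return Nested configuration list for [runPipeline()].
#' @export
defaultPipelineConfig <- function() {
  sinus <- matrix(c(2200, 40, 3400, 40, 3400, 700, 2200, 700),
                  ncol = 2, byrow = TRUE)
  list(
    seed = 1,
    stages = c("simulate", "render", "detect", "track", "analyze",
               "summarize"),
    scene = list(
      network = list(span_um = 4000, chord_um = 1500,
                     longitudinal = c(0.08, 0.5, 0.85),
                     cross = c(0.55, 0.87)),
      behaviors = list(
        leading_edge = list(mode = "pulsatile", baseSpeed = 900,
                            pulseFreqHz = 0.56, reversalFraction = 0.2),
        membrane = list(mode = "leaky", baseSpeed = 500,
                        sinusPolygon = sinus),
        wing_tip = list(mode = "aperiodic", baseSpeed = 180,
                        modDepth = 0.2),
        lattice = list(mode = "aperiodic", baseSpeed = 350, modDepth = 0.2),
        trailing_edge = list(mode = "pulsatile", baseSpeed = 1100,
                             pulseFreqHz = 0.6, reversalFraction = 0.2)),
      nParticles = 12, duration = 2, frameRate = 30,
      particleDiametersUm = 6, startFraction = 0.1),
    render = list(pixelSize = 4, frameRate = 30, psfSigmaPx = 1.3,
                  fovPx = c(420L, 1050L), originUm = c(-100, -100),
                  background = 0.05, brightnessPerVolume = 0.05,
                  bleachRate = 0.002, illuminationAmplitude = 0.15,
                  readNoiseSd = 0.01),
    detect = list(), link = list(maxDisplacementPx = 12,
                                 minTrackLength = 25L),
    constants = list(), regionRadii = NULL,
    wingFrame = NULL)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on one configuration (a nested
#' list, or a YAML file path). Intermediate products are written to
#' \code{outDir} when given (truth.csv, stack.tif, detections.csv,
#' tracks.csv, kinematics.csv, summary.csv); the returned report carries
#' per-stage counts, the per-region summary, and provenance (seed and
#' config hash). A stage failure aborts with the failing stage named;
#' outputs of completed stages are retained.
#'
#' @param config nested list (see [defaultPipelineConfig()]) or YAML path.
#' @param outDir optional output directory.
#' @return Report list: seed, configHash, counts, regionSummary, and the
#'   intermediate objects (truth, stack, detections, tracks, kinematics).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  report <- list(seed = cfg$seed, configHash = rlang::hash(cfg),
                 counts = list())
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  out <- function(f) if (is.null(outDir)) NULL else file.path(outDir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  enabled <- function(s) s %in% cfg$stages

  truth <- stack <- detections <- tracks <- kin <- summary <- NULL
  rp <- do.call(renderParams, cfg$render)
  if (enabled("simulate")) stage("simulate", {
    net <- buildWingNetwork(cfg$scene$network %||% list())
    behaviors <- lapply(cfg$scene$behaviors, behaviorFromSpec)
    truth <- simulateParticles(net, behaviors, cfg$scene$nParticles,
                                cfg$scene$duration, cfg$scene$frameRate,
                                seed = cfg$seed,
                                particleDiametersUm =
                                  cfg$scene$particleDiametersUm %||% c(3, 6),
                                startFraction =
                                  cfg$scene$startFraction %||% 0.25)
    report$counts$simulate <- nParticles(truth)
    if (!is.null(outDir)) writeGroundTruth(truth, out("truth.csv"))
  })
  if (enabled("render")) stage("render", {
    stack <- renderStack(truth, rp, seed = cfg$seed + 1)
    report$counts$render <- nFrames(stack)
    if (!is.null(outDir)) writeImageStack(stack, out("stack.tif"), rp@bitDepth)
  })
  if (enabled("detect")) stage("detect", {
    detections <- detectParticles(stack, do.call(detectionParams,
                                                  cfg$detect))
    report$counts$detect <- nrow(detections)
    if (!is.null(outDir)) writeDetections(detections, out("detections.csv"))
  })
  if (enabled("track")) stage("track", {
    tracks <- trackParticles(detections, do.call(linkingParams, cfg$link),
                              pixelSize = rp@pixelSize,
                              frameRate = rp@frameRate)
    report$counts$track <- nParticles(tracks)
    if (!is.null(outDir)) writeTracks(tracks, out("tracks.csv"))
  })
  if (enabled("analyze")) stage("analyze", {
    kin <- trajectoryKinematics(tracks)
    report$counts$analyze <- nrow(kin)
    if (!is.null(outDir)) writeSchemaCSV(kin, out("kinematics.csv"),
                                         "kinematics")
  })
  if (enabled("summarize")) stage("summarize", {
    wf <- cfg$wingFrame
    if (is.null(wf)) {
      span <- cfg$scene$network$span_um %||% defaultNetworkConfig()$span_um
      chord <- cfg$scene$network$chord_um %||% defaultNetworkConfig()$chord_um
      wf <- list(base = c(0, 0), tip = c(span, 0),
                 leading = c(0, 0), trailing = c(0, chord))
    } else wf <- lapply(wf, as.numeric)
    map <- defaultRegionMap(radii = cfg$regionRadii)
    startUm <- cbind(kin$start_x_px, kin$start_y_px) * rp@pixelSize +
      rep(rp@originUm, each = nrow(kin)) - 0.5 * rp@pixelSize
    norm <- normalizeCoordinates(startUm, wf)
    kin$region <- vapply(seq_len(nrow(norm)), function(i)
      assignRegion(norm[i, ], map), "")
    summary <- summarizeRegions(kin, map,
                                do.call(fluidConstants, cfg$constants))
    report$regionSummary <- summary
    report$counts$summarize <- nrow(summary)
    if (!is.null(outDir)) writeSchemaCSV(summary, out("summary.csv"),
                                         "region_summary")
  })
  report$truth <- truth; report$stack <- stack
  report$detections <- detections; report$tracks <- tracks
  report$kinematics <- kin
  report
}

#' Convert ground truth to a pixel-space TrackSet
#'
#' The oracle pass-through: true paths become perfect trajectories
#' (features are idealized), letting every downstream stage be scored
#' against imposed values.
#'
#' @param truth a [GroundTruth-class].
#' @param params a [RenderParams-class] defining the micrometre-to-pixel
#'   mapping.
#' @return A [TrackSet-class].
#' @export
truthToTrackSet <- function(truth, params) {
  p <- particlePaths(truth)
  d <- if ("diameter_um" %in% names(p)) p$diameter_um else rep(6, nrow(p))
  tr <- data.frame(track_id = p$particle_id, frame = p$frame,
                   x_px = umToPx(p$x_um, params@originUm[1],
                                 params@pixelSize),
                   y_px = umToPx(p$y_um, params@originUm[2],
                                 params@pixelSize),
                   brightness = 1, area_px2 = pi * (d / params@pixelSize)^2 / 4,
                   diameter_px = d / params@pixelSize, orientation_rad = 0)
  tr <- tr[order(tr$track_id, tr$frame), ]
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, pixelSize = params@pixelSize,
      frameRate = frameRate(truth), flagged = integer())
}

#' Score tracking results against ground truth
#'
#' Matches true particle positions to tracked observations frame by frame
#' (greedy nearest neighbor within \code{tolPx}) and reports detection
#' recall and precision, the fraction of true consecutive links recovered
#' inside single tracks, and the identity-swap rate (fraction of
#' within-track transitions whose matched true particle changes).
#'
#' @param truth a [GroundTruth-class].
#' @param trackset a [TrackSet-class] from the same scene.
#' @param params the scene's [RenderParams-class] (micrometre-to-pixel
#'   mapping).
#' @param detections optional detections data.frame for recall/precision
#'   before track filtering (defaults to the trackset's observations).
#' @param tolPx match tolerance, pixels.
#' @return List: detectionRecall, detectionPrecision, linkRecovery,
#'   idSwapRate, nTruthLinks.
#' @export
benchmarkTracking <- function(truth, trackset, params, detections = NULL,
                              tolPx = 2) {
  p <- particlePaths(truth)
  tr <- trackTable(trackset, dropFlagged = FALSE)
  if (!nrow(p)) stop("empty ground truth")
  if (nrow(tr) && (min(tr$frame) > max(p$frame) ||
                   max(tr$frame) < min(p$frame)))
    stop("scene mismatch: trajectory frames do not overlap the ground truth")
  p$x_px <- umToPx(p$x_um, params@originUm[1], params@pixelSize)
  p$y_px <- umToPx(p$y_um, params@originUm[2], params@pixelSize)
  if (is.null(detections))
    detections <- tr[c("frame", "x_px", "y_px")]

  greedyMatch <- function(ax, ay, bx, by) {
    # returns for each a-row the matched b-row (or NA), nearest-first
    if (!length(ax) || !length(bx)) return(rep(NA_integer_, length(ax)))
    d <- sqrt(outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2)
    d[d > tolPx] <- Inf
    match <- rep(NA_integer_, length(ax))
    usedB <- logical(length(bx))
    repeat {
      if (!any(is.finite(d))) break
      k <- arrayInd(which.min(d), dim(d))
      match[k[1]] <- k[2]
      d[k[1], ] <- Inf; d[, k[2]] <- Inf
    }
    match
  }

  # detection recall / precision
  nTrue <- 0L; nHit <- 0L; nDet <- nrow(detections)
  for (f in sort(unique(p$frame))) {
    pt <- p[p$frame == f, ]
    dt <- detections[detections$frame == f, ]
    m <- greedyMatch(pt$x_px, pt$y_px, dt$x_px, dt$y_px)
    nTrue <- nTrue + nrow(pt)
    nHit <- nHit + sum(!is.na(m))
  }

  # match truth to track observations, then walk each track
  tr$match_pid <- NA_integer_
  for (f in sort(unique(tr$frame))) {
    ti <- which(tr$frame == f)
    pt <- p[p$frame == f, ]
    m <- greedyMatch(tr$x_px[ti], tr$y_px[ti], pt$x_px, pt$y_px)
    tr$match_pid[ti] <- pt$particle_id[m]
  }
  swaps <- 0L; transitions <- 0L
  recovered <- 0L
  linkKey <- character()
  for (d in split(tr, tr$track_id)) {
    pid <- d$match_pid
    ok <- !is.na(pid)
    if (sum(ok) >= 2) {
      seqp <- pid[ok]
      transitions <- transitions + length(seqp) - 1L
      swaps <- swaps + sum(diff(seqp) != 0)
    }
    same <- which(diff(d$frame) >= 1 & ok[-length(ok)] & ok[-1] &
                    pid[-length(pid)] == pid[-1])
    if (length(same))
      linkKey <- c(linkKey, paste(pid[same], d$frame[same],
                                  d$frame[same + 1]))
  }
  # true consecutive links
  truthLinks <- do.call(rbind, lapply(split(p, p$particle_id), function(d)
    data.frame(pid = d$particle_id[-nrow(d)], f1 = d$frame[-nrow(d)],
               f2 = d$frame[-1])))
  nLinks <- nrow(truthLinks)
  recovered <- sum(paste(truthLinks$pid, truthLinks$f1, truthLinks$f2) %in%
                     linkKey)
  list(detectionRecall = nHit / nTrue,
       detectionPrecision = if (nDet) nHit / nDet else NA_real_,
       linkRecovery = recovered / nLinks,
       idSwapRate = if (transitions) swaps / transitions else 0,
       nTruthLinks = nLinks)
}
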