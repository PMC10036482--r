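#' @import methods
#' @importFrom stats median mad quantile rnorm rpois runif setNames sd
#' @importFrom utils head read.csv tail write.csv
NULL

WING_REGIONS <- c("leading_edge", "membrane", "wing_tip", "lattice",
                  "trailing_edge")

BODY_REGIONS <- c("dorsal_vessel", "scutellar_branch", "pronotum",
                  "abdomen", "fw_hinge", "hw_hinge")

#' ImageStack: a grayscale fluorescence time-lapse
#'
#' Holds a T-frame grayscale movie as an H x W x T numeric array together
#' with the two pieces of physical metadata every downstream computation
#' needs: the frame rate (frames per second) and the pixel size
#' (micrometres per pixel). Pixel values are kept in floating point on a
#' nominal [0, 1] scale; integer bit depths exist only at the TIFF I/O
#' boundary.
#'
#' @slot frames numeric array, dim = c(height, width, n_frames).
#' @slot frameRate frames per second.
#' @slot pixelSize micrometres per pixel.
#' @exportClass ImageStack
setClass("ImageStack",
         representation(frames = "array",
                        frameRate = "numeric",
                        pixelSize = "numeric"))

setValidity("ImageStack", function(object) {
  msgs <- character()
  if (length(dim(object@frames)) != 3L)
    msgs <- c(msgs, "frames must be a 3-D array (height, width, n_frames)")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msgs <- c(msgs, "frameRate must be a single positive number")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageStack
#'
#' @param frames H x W x T numeric array (or a list of equally sized
#'   matrices, stacked in order).
#' @param frameRate frames per second.
#' @param pixelSize micrometres per pixel.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(frames, frameRate, pixelSize) {
  if (is.list(frames))
    frames <- simplify2array(frames)
  if (is.matrix(frames))
    frames <- array(frames, dim = c(dim(frames), 1L))
  new("ImageStack", frames = frames, frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize))
}

#' VeinNetwork: a stylized planar wing venation graph
#'
#' Nodes are 2-D positions in physical micrometres (x along the span from
#' base to tip, y along the chord from leading to trailing edge). Each
#' segment joins two nodes, carries a lumen radius, and is labeled with one
#' of the five wing regions. Leading- and trailing-edge segments must have
#' diameters in 170-250 um and be strictly wider than tip and lattice
#' segments, matching the relative vein calibers of a grasshopper wing.
#'
#' @slot nodes numeric matrix, n x 2, micrometre coordinates.
#' @slot segments data.frame with columns node_a, node_b, radius_um, region.
#' @exportClass VeinNetwork
setClass("VeinNetwork",
         representation(nodes = "matrix", segments = "data.frame"))

setValidity("VeinNetwork", function(object) {
  msgs <- character()
  seg <- object@segments
  need <- c("node_a", "node_b", "radius_um", "region")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@nodes) != 2L)
    msgs <- c(msgs, "nodes must be an n x 2 matrix")
  if (nrow(seg) == 0L)
    msgs <- c(msgs, "network must contain at least one segment")
  if (any(seg$radius_um <= 0))
    msgs <- c(msgs, "all segment radii must be positive")
  if (!all(seg$region %in% WING_REGIONS))
    msgs <- c(msgs, paste("region labels must be one of:",
                          paste(WING_REGIONS, collapse = ", ")))
  if (nrow(seg) > 0L) {
    g <- igraph::graph_from_edgelist(
      cbind(as.character(seg$node_a), as.character(seg$node_b)),
      directed = FALSE)
    if (!igraph::is_connected(g))
      msgs <- c(msgs, "vein graph must be connected")
  }
  dia <- 2 * seg$radius_um
  edge <- seg$region %in% c("leading_edge", "trailing_edge")
  fine <- seg$region %in% c("wing_tip", "lattice")
  if (any(edge) && (any(dia[edge] < 170) || any(dia[edge] > 250)))
    msgs <- c(msgs,
              "leading/trailing edge segment diameters must lie in 170-250 um")
  if (any(edge) && any(fine) && max(dia[fine]) >= min(dia[edge]))
    msgs <- c(msgs,
              "tip/lattice diameters must be strictly smaller than leading/trailing")
  if (length(msgs)) msgs else TRUE
})

#' FlowBehavior: a local hemolymph flow mode
#'
#' One of the three local flow behaviors observed in wing veins:
#' \describe{
#'   \item{pulsatile}{particles pulse forward at \code{pulseFreqHz}, then
#'     stop or retrace a fraction \code{reversalFraction} (< 1) of the
#'     forward pulse distance, giving net forward transport.}
#'   \item{aperiodic}{continuous one-directional motion whose speed
#'     modulates (depth \code{modDepth} < 1 at \code{modFreqHz}) but never
#'     reaches zero.}
#'   \item{leaky}{particles exit the vein into a membranous sinus
#'     (\code{sinusPolygon}, micrometre coordinates) and re-enter a
#'     bounding vein.}
#' }
#'
#' @slot mode "pulsatile", "aperiodic" or "leaky".
#' @slot baseSpeed peak along-vein speed, micrometres per second.
#' @slot pulseFreqHz pulsation frequency (pulsatile only), Hz.
#' @slot reversalFraction fraction of forward pulse distance retraced in
#'   [0, 1) (pulsatile only).
#' @slot modDepth,modFreqHz speed modulation of the aperiodic mode.
#' @slot sinusPolygon k x 2 micrometre polygon (leaky only).
#' @exportClass FlowBehavior
setClass("FlowBehavior",
         representation(mode = "character", baseSpeed = "numeric",
                        pulseFreqHz = "numeric", reversalFraction = "numeric",
                        modDepth = "numeric", modFreqHz = "numeric",
                        sinusPolygon = "matrix"))

setValidity("FlowBehavior", function(object) {
  msgs <- character()
  if (!object@mode %in% c("pulsatile", "aperiodic", "leaky"))
    msgs <- c(msgs, "mode must be pulsatile, aperiodic or leaky")
  if (object@baseSpeed <= 0)
    msgs <- c(msgs, "baseSpeed must be positive")
  if (object@mode == "pulsatile") {
    if (object@pulseFreqHz <= 0)
      msgs <- c(msgs, "pulseFreqHz must be positive for pulsatile flow")
    if (object@reversalFraction < 0 || object@reversalFraction >= 1)
      msgs <- c(msgs, "reversalFraction must lie in [0, 1)")
  }
  if (object@mode == "aperiodic" &&
      (object@modDepth < 0 || object@modDepth >= 1))
    msgs <- c(msgs, "modDepth must lie in [0, 1) so speed never reaches zero")
  if (object@mode == "leaky" && nrow(object@sinusPolygon) < 3L)
    msgs <- c(msgs, "leaky flow requires a sinus polygon (>= 3 vertices)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FlowBehavior
#'
#' @param mode "pulsatile", "aperiodic" or "leaky".
#' @param baseSpeed peak along-vein speed, um/s.
#' @param pulseFreqHz pulsation frequency, Hz (pulsatile).
#' @param reversalFraction fraction of forward distance retraced (pulsatile).
#' @param modDepth,modFreqHz aperiodic speed modulation depth and frequency.
#' @param sinusPolygon k x 2 matrix of micrometre vertices (leaky).
#' @return A [FlowBehavior-class] object.
#' @export
flowBehavior <- function(mode, baseSpeed = 500,
                         pulseFreqHz = 0.5, reversalFraction = 0.25,
                         modDepth = 0.4, modFreqHz = 0.5,
                         sinusPolygon = matrix(numeric(), 0, 2)) {
  new("FlowBehavior", mode = mode, baseSpeed = as.numeric(baseSpeed),
      pulseFreqHz = as.numeric(pulseFreqHz),
      reversalFraction = as.numeric(reversalFraction),
      modDepth = as.numeric(modDepth), modFreqHz = as.numeric(modFreqHz),
      sinusPolygon = sinusPolygon)
}

#' GroundTruth: true particle paths of a synthetic scene
#'
#' One row per particle per frame; positions are physical micrometres.
#' Consecutive samples of a path are exactly one frame interval apart.
#'
#' @slot paths data.frame with columns particle_id, frame, x_um, y_um,
#'   segment_id, region, diameter_um.
#' @slot frameRate frames per second.
#' @slot duration seconds simulated.
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(paths = "data.frame", frameRate = "numeric",
                        duration = "numeric"))

setValidity("GroundTruth", function(object) {
  p <- object@paths
  need <- c("particle_id", "frame", "x_um", "y_um", "segment_id", "region")
  if (!all(need %in% names(p)))
    return(paste("paths must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    bad <- vapply(split(p$frame, p$particle_id), function(f)
      any(diff(sort(f)) != 1L) || anyDuplicated(f) > 0L, logical(1))
    if (any(bad))
      return(paste("non-consecutive frame indices for particle(s):",
                   paste(names(bad)[bad], collapse = ", ")))
  }
  TRUE
})

#' RenderParams: fluorescence rendering model
#'
#' Parameters of the synthetic microscope: optics (point-spread sigma),
#' geometry (pixel size, field of view, micrometre origin), photometry
#' (background level, brightness per unit particle volume, photobleaching
#' decay per frame), illumination non-uniformity (low-order polynomial
#' multiplicative field), and the noise model (Gaussian read noise plus
#' optional Poisson shot noise).
#'
#' @slot pixelSize micrometres per pixel.
#' @slot frameRate frames per second, within the 10-100 fps imaging range.
#' @slot psfSigmaPx point-spread function sigma in pixels.
#' @slot fovPx integer c(height, width) of the field of view in pixels.
#' @slot originUm micrometre position of pixel (1, 1)'s corner.
#' @slot background baseline level on the [0, 1] intensity scale.
#' @slot brightnessPerVolume amplitude scale per cubic micrometre.
#' @slot bleachRate exponential intensity decay per frame (>= 0).
#' @slot illuminationAmplitude peak relative deviation of the smooth
#'   multiplicative illumination field (0.2 = +/-20 percent).
#' @slot readNoiseSd Gaussian read noise sd on the [0, 1] scale.
#' @slot shotNoise logical, add Poisson shot noise.
#' @slot photonsFullScale photon count mapped to intensity 1 (shot noise).
#' @slot bitDepth 8 or 16, used only when writing TIFF.
#' @exportClass RenderParams
setClass("RenderParams",
         representation(pixelSize = "numeric", frameRate = "numeric",
                        psfSigmaPx = "numeric", fovPx = "integer",
                        originUm = "numeric", background = "numeric",
                        brightnessPerVolume = "numeric", bleachRate = "numeric",
                        illuminationAmplitude = "numeric",
                        readNoiseSd = "numeric", shotNoise = "logical",
                        photonsFullScale = "numeric", bitDepth = "integer"))

setValidity("RenderParams", function(object) {
  msgs <- character()
  if (object@frameRate < 10 || object@frameRate > 100)
    msgs <- c(msgs, "frameRate must lie in the 10-100 fps imaging range")
  if (object@psfSigmaPx <= 0) msgs <- c(msgs, "psfSigmaPx must be positive")
  if (object@bleachRate < 0) msgs <- c(msgs, "bleachRate must be >= 0")
  if (object@pixelSize <= 0) msgs <- c(msgs, "pixelSize must be positive")
  if (length(object@fovPx) != 2L || any(object@fovPx < 8L))
    msgs <- c(msgs, "fovPx must be c(height, width), each >= 8 px")
  if (!object@bitDepth %in% c(8L, 16L))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (length(msgs)) msgs else TRUE
})

#' Construct RenderParams
#'
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second (10-100).
#' @param psfSigmaPx optical blur sigma, pixels.
#' @param fovPx c(height, width) in pixels.
#' @param originUm micrometre coordinates mapped to the image origin.
#' @param background baseline intensity.
#' @param brightnessPerVolume spot amplitude scale per um^3.
#' @param bleachRate photobleaching decay per frame.
#' @param illuminationAmplitude illumination field relative amplitude.
#' @param readNoiseSd Gaussian read noise sd.
#' @param shotNoise add Poisson shot noise?
#' @param photonsFullScale photons at intensity 1.
#' @param bitDepth TIFF bit depth (8 or 16).
#' @return A [RenderParams-class] object.
#' @export
renderParams <- function(pixelSize = 2, frameRate = 50, psfSigmaPx = 1.3,
                         fovPx = c(256L, 256L), originUm = c(0, 0),
                         background = 0.06, brightnessPerVolume = 5e-3,
                         bleachRate = 0, illuminationAmplitude = 0,
                         readNoiseSd = 0, shotNoise = FALSE,
                         photonsFullScale = 5000, bitDepth = 16L) {
  new("RenderParams", pixelSize = as.numeric(pixelSize),
      frameRate = as.numeric(frameRate), psfSigmaPx = as.numeric(psfSigmaPx),
      fovPx = as.integer(fovPx), originUm = as.numeric(originUm),
      background = as.numeric(background),
      brightnessPerVolume = as.numeric(brightnessPerVolume),
      bleachRate = as.numeric(bleachRate),
      illuminationAmplitude = as.numeric(illuminationAmplitude),
      readNoiseSd = as.numeric(readNoiseSd), shotNoise = as.logical(shotNoise),
      photonsFullScale = as.numeric(photonsFullScale),
      bitDepth = as.integer(bitDepth))
}

#' DetectionParams: particle segmentation settings
#'
#' @slot saturationFraction fraction of pixels saturated by the frame-wise
#'   linear intensity adjustment (default 0.01, i.e. 1 percent).
#' @slot hessianSigmaPx Gaussian scale of the Hessian eigenmap.
#' @slot refineFraction stop region growth when intensity falls below this
#'   fraction of the region's peak (default 0.25).
#' @slot cannyLow,cannyHigh hysteresis thresholds of the Canny edge
#'   detector, as fractions of the maximum gradient magnitude.
#' @slot minAreaPx discard regions smaller than this many pixels.
#' @slot backgroundWindow number of frames sampled for the temporal-median
#'   background model.
#' @slot minPeakIntensity minimum smoothed peak height (post-adjustment
#'   [0, 1] scale) for a candidate seed.
#' @slot peakSnrMin minimum peak height in robust noise units
#'   (median + peakSnrMin * MAD of the smoothed frame).
#' @slot maxRadiusPx cap on region growth radius around a peak, pixels.
#' @slot darkBlobs detect dark-on-bright instead of bright-on-dark blobs
#'   (flips the Hessian eigenvalue convention).
#' @exportClass DetectionParams
setClass("DetectionParams",
         representation(saturationFraction = "numeric",
                        hessianSigmaPx = "numeric", refineFraction = "numeric",
                        cannyLow = "numeric", cannyHigh = "numeric",
                        minAreaPx = "integer", backgroundWindow = "integer",
                        minPeakIntensity = "numeric", peakSnrMin = "numeric",
                        maxRadiusPx = "integer", darkBlobs = "logical"))

setValidity("DetectionParams", function(object) {
  msgs <- character()
  if (object@saturationFraction <= 0 || object@saturationFraction >= 0.5)
    msgs <- c(msgs, "saturationFraction must lie in (0, 0.5)")
  if (object@refineFraction <= 0 || object@refineFraction >= 1)
    msgs <- c(msgs, "refineFraction must lie in (0, 1)")
  if (object@cannyLow >= object@cannyHigh)
    msgs <- c(msgs, "cannyLow must be < cannyHigh")
  if (object@hessianSigmaPx <= 0)
    msgs <- c(msgs, "hessianSigmaPx must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct DetectionParams
#'
#' @param saturationFraction fraction of pixels saturated by the intensity
#'   adjustment.
#' @param hessianSigmaPx Hessian smoothing scale, pixels.
#' @param refineFraction region-growth stop fraction of peak intensity.
#' @param cannyLow,cannyHigh Canny hysteresis thresholds (relative).
#' @param minAreaPx minimum region area, pixels.
#' @param backgroundWindow frames sampled for the median background.
#' @param minPeakIntensity absolute smoothed-peak floor.
#' @param peakSnrMin robust peak SNR floor.
#' @param maxRadiusPx region growth radius cap.
#' @param darkBlobs detect dark blobs instead of bright ones.
#' @return A [DetectionParams-class] object.
#' @export
detectionParams <- function(saturationFraction = 0.01, hessianSigmaPx = 1.5,
                            refineFraction = 0.25, cannyLow = 0.08,
                            cannyHigh = 0.2, minAreaPx = 4L,
                            backgroundWindow = 11L, minPeakIntensity = 0.2,
                            peakSnrMin = 6, maxRadiusPx = 12L,
                            darkBlobs = FALSE) {
  new("DetectionParams", saturationFraction = as.numeric(saturationFraction),
      hessianSigmaPx = as.numeric(hessianSigmaPx),
      refineFraction = as.numeric(refineFraction),
      cannyLow = as.numeric(cannyLow), cannyHigh = as.numeric(cannyHigh),
      minAreaPx = as.integer(minAreaPx),
      backgroundWindow = as.integer(backgroundWindow),
      minPeakIntensity = as.numeric(minPeakIntensity),
      peakSnrMin = as.numeric(peakSnrMin),
      maxRadiusPx = as.integer(maxRadiusPx), darkBlobs = as.logical(darkBlobs))
}

#' LinkingParams: frame-to-frame correspondence settings
#'
#' @slot maxDisplacementPx gating radius per frame, pixels.
#' @slot featureWeights named nonnegative weights for dist, brightness,
#'   area, diameter and orientation dissimilarities; w_dist must be > 0.
#'   Defaults make distance dominant: with MAD-normalized features a
#'   homogeneous particle population turns every feature term into pure
#'   measurement noise of order one, so features serve as tie-breakers
#'   (deciding crossings, where distances tie) rather than outvoting
#'   geometry.
#' @slot maxGapFrames close gaps of up to this many missed frames.
#' @slot minTrackLength trajectories shorter than this are removed
#'   (default 25 data points).
#' @slot stuckNoisePx centroid noise scale of the stuck-particle screen;
#'   tracks whose net displacement is below twice this are flagged.
#' @exportClass LinkingParams
setClass("LinkingParams",
         representation(maxDisplacementPx = "numeric",
                        featureWeights = "numeric", maxGapFrames = "integer",
                        minTrackLength = "integer", stuckNoisePx = "numeric"))

setValidity("LinkingParams", function(object) {
  msgs <- character()
  need <- c("dist", "brightness", "area", "diameter", "orientation")
  if (!all(need %in% names(object@featureWeights)))
    msgs <- c(msgs, paste("featureWeights must be named:",
                          paste(need, collapse = ", ")))
  else {
    if (any(object@featureWeights < 0))
      msgs <- c(msgs, "feature weights must be nonnegative")
    if (object@featureWeights[["dist"]] <= 0)
      msgs <- c(msgs, "the distance weight must be positive")
  }
  if (object@minTrackLength < 2L)
    msgs <- c(msgs, "minTrackLength must be >= 2")
  if (object@maxDisplacementPx <= 0)
    msgs <- c(msgs, "maxDisplacementPx must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct LinkingParams
#'
#' @param maxDisplacementPx gating radius, px per frame.
#' @param featureWeights named weights (dist, brightness, area, diameter,
#'   orientation).
#' @param maxGapFrames allowed missed frames inside a track.
#' @param minTrackLength minimum retained trajectory length.
#' @param stuckNoisePx centroid noise scale for the stuck screen.
#' @return A [LinkingParams-class] object.
#' @export
linkingParams <- function(maxDisplacementPx = 20,
                          featureWeights = c(dist = 1, brightness = 0.15,
                                             area = 0.15, diameter = 0.15,
                                             orientation = 0.05),
                          maxGapFrames = 0L, minTrackLength = 25L,
                          stuckNoisePx = 1) {
  new("LinkingParams", maxDisplacementPx = as.numeric(maxDisplacementPx),
      featureWeights = featureWeights, maxGapFrames = as.integer(maxGapFrames),
      minTrackLength = as.integer(minTrackLength),
      stuckNoisePx = as.numeric(stuckNoisePx))
}

#' FluidConstants: physical constants of the working fluid
#'
#' Hemolymph is treated hydrodynamically as water: density rho, dynamic
#' viscosity mu (0.0010518 Pa s at 18 C), and the diffusion coefficient of
#' oxygen in water D_O2 = 1.8e-9 m^2/s used in the Peclet number.
#'
#' @slot rho density, kg/m^3.
#' @slot mu dynamic viscosity, Pa s.
#' @slot dO2 O2 diffusion coefficient in water, m^2/s.
#' @exportClass FluidConstants
setClass("FluidConstants",
         representation(rho = "numeric", mu = "numeric", dO2 = "numeric"))

setValidity("FluidConstants", function(object) {
  if (any(c(object@rho, object@mu, object@dO2) <= 0))
    "rho, mu and dO2 must all be strictly positive" else TRUE
})

#' Construct FluidConstants
#'
#' @param rho density of water, kg/m^3.
#' @param mu dynamic viscosity of water, Pa s.
#' @param dO2 diffusion coefficient of oxygen in water, m^2/s.
#' @return A [FluidConstants-class] object.
#' @export
fluidConstants <- function(rho = 1000, mu = 0.0010518, dO2 = 1.8e-9) {
  new("FluidConstants", rho = as.numeric(rho), mu = as.numeric(mu),
      dO2 = as.numeric(dO2))
}

#' TrackSet: linked particle trajectories
#'
#' One row per observation; track_id groups time-ordered observations of
#' one particle identity. Positions are pixels; pixel size and frame rate
#' are carried so kinematics are always computed in physical units.
#'
#' @slot tracks data.frame with columns track_id, frame, x_px, y_px,
#'   brightness, area_px2, diameter_px, orientation_rad.
#' @slot pixelSize micrometres per pixel.
#' @slot frameRate frames per second.
#' @slot flagged integer track_ids flagged as stuck (excluded from
#'   kinematics by default).
#' @exportClass TrackSet
setClass("TrackSet",
         representation(tracks = "data.frame", pixelSize = "numeric",
                        frameRate = "numeric", flagged = "integer"))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  need <- c("track_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(tr)))
    return(paste("tracks must have columns:", paste(need, collapse = ", ")))
  if (nrow(tr)) {
    bad <- vapply(split(tr$frame, tr$track_id),
                  function(f) any(diff(f) <= 0), logical(1))
    if (any(bad))
      return("frame indices must be strictly increasing within each track")
  }
  TRUE
})

#' RegionMap: named wing/body region polygons and vein radii
#'
#' Wing polygons live in normalized wing coordinates (span and chord each
#' in [0, 1]) and tile the unit domain; boundary points are resolved by a
#' fixed priority order. Each region carries a mean vein radius in metres
#' (with its sample size) used in the dimensionless numbers.
#'
#' @slot polygons named list of k x 2 matrices (normalized coordinates).
#' @slot radii named numeric, mean vein radius per region, metres.
#' @slot radiusN named integer, number of measurements behind each radius.
#' @slot priority character, polygon tie-break order.
#' @exportClass RegionMap
setClass("RegionMap",
         representation(polygons = "list", radii = "numeric",
                        radiusN = "integer", priority = "character"))

setValidity("RegionMap", function(object) {
  msgs <- character()
  if (!length(object@polygons))
    msgs <- c(msgs, "at least one region polygon is required")
  if (!all(names(object@polygons) %in% c(WING_REGIONS, BODY_REGIONS)))
    msgs <- c(msgs, "polygon names must be known wing or body regions")
  if (any(object@radii <= 0))
    msgs <- c(msgs, "every region radius must be positive")
  if (!all(object@priority %in% names(object@polygons)))
    msgs <- c(msgs, "priority must list polygon names")
  if (length(msgs)) msgs else TRUE
})
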