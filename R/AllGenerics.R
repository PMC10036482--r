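#' Number of frames
#' @param x an ImageStack or GroundTruth.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame rate in frames per second
#' @param x an object carrying acquisition metadata.
#' @return numeric fps.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Pixel size in micrometres per pixel
#' @param x an object carrying acquisition metadata.
#' @return numeric um/px.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Extract one frame as a matrix
#' @param x an ImageStack.
#' @param i frame index.
#' @return numeric matrix.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Ground-truth or trajectory table
#' @param x a GroundTruth or TrackSet.
#' @return data.frame of particle paths / observations.
#' @export
setGeneric("particlePaths", function(x) standardGeneric("particlePaths"))

#' Trajectory observations
#' @param x a TrackSet.
#' @param dropFlagged drop tracks flagged as stuck?
#' @return data.frame of linked observations.
#' @export
setGeneric("trackTable",
           function(x, dropFlagged = TRUE) standardGeneric("trackTable"))

#' Number of particle identities
#' @param x a GroundTruth or TrackSet.
#' @return integer count.
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Region labels present
#' @param x a VeinNetwork or RegionMap.
#' @return character vector of region labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])
setMethod("frameRate", "ImageStack", function(x) x@frameRate)
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)
setMethod("getFrame", "ImageStack", function(x, i) x@frames[, , i])

setMethod("nFrames", "GroundTruth", function(x)
  if (nrow(x@paths)) max(x@paths$frame) else 0L)
setMethod("frameRate", "GroundTruth", function(x) x@frameRate)
setMethod("particlePaths", "GroundTruth", function(x) x@paths)
setMethod("nParticles", "GroundTruth", function(x)
  length(unique(x@paths$particle_id)))

setMethod("frameRate", "TrackSet", function(x) x@frameRate)
setMethod("pixelSize", "TrackSet", function(x) x@pixelSize)
setMethod("nParticles", "TrackSet", function(x)
  length(unique(x@tracks$track_id)))
setMethod("trackTable", "TrackSet", function(x, dropFlagged = TRUE) {
  tr <- x@tracks
  if (dropFlagged && length(x@flagged))
    tr <- tr[!tr$track_id %in% x@flagged, , drop = FALSE]
  tr
})

setMethod("regionLabels", "VeinNetwork", function(x)
  sort(unique(x@segments$region)))
setMethod("regionLabels", "RegionMap", function(x) names(x@polygons))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d x %d px, %d frames @ %.3g fps, %.3g um/px\n",
              d[1], d[2], d[3], object@frameRate, object@pixelSize))
})

setMethod("show", "VeinNetwork", function(object) {
  seg <- object@segments
  cat(sprintf("VeinNetwork: %d nodes, %d segments\n",
              nrow(object@nodes), nrow(seg)))
  tab <- table(seg$region)
  for (r in names(tab)) {
    d <- 2 * seg$radius_um[seg$region == r]
    cat(sprintf("  %-13s %2d segment(s), diameter %.0f-%.0f um\n",
                r, tab[[r]], min(d), max(d)))
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d particles, %d frames @ %.3g fps (%.3g s)\n",
    nParticles(object), nFrames(object), object@frameRate, object@duration))
})

setMethod("show", "TrackSet", function(object) {
  len <- if (nrow(object@tracks))
    table(object@tracks$track_id) else integer()
  cat(sprintf("TrackSet: %d trajectories (%d flagged stuck), %s\n",
              nParticles(object), length(object@flagged),
              if (length(len))
                sprintf("lengths %d-%d", min(len), max(len)) else "empty"))
})

setMethod("show", "RegionMap", function(object) {
  cat(sprintf("RegionMap: %d regions (%s)\n", length(object@polygons),
              paste(names(object@polygons), collapse = ", ")))
})

setMethod("show", "FlowBehavior", function(object) {
  cat(sprintf("FlowBehavior: %s, base speed %.3g um/s", object@mode,
              object@baseSpeed))
  if (object@mode == "pulsatile")
    cat(sprintf(", %.3g Hz, reversal %.2f", object@pulseFreqHz,
                object@reversalFraction))
  cat("\n")
})
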