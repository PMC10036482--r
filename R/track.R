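# track: multi-parametric frame-to-frame correspondence. Candidate links
# are gated by a maximum displacement; within the gate, the cost combines
# normalized distance with brightness, area, diameter and orientation
# dissimilarities, and each frame pair is resolved by a globally optimal
# one-to-one assignment (maximum cardinality, then minimum total cost).

FEATURE_COLS <- c("brightness", "area_px2", "diameter_px", "orientation_rad")

# Robust per-stack dissimilarity scales (median absolute deviation) so the
# feature weights are unitless. Degenerate (constant) features get scale 1.
featureScales <- function(observations) {
  sc <- vapply(FEATURE_COLS, function(cc) {
    v <- observations[[cc]]
    s <- if (cc == "orientation_rad" && length(v) > 1)
      mad(v, constant = 1.4826) else mad(v)
    if (!is.finite(s) || s <= 0) 1 else s
  }, 0)
  names(sc) <- c("brightness", "area", "diameter", "orientation")
  sc
}

#' Link cost between two observations
#'
#' score = w_dist * (distance / maxDisplacement)^2 + sum over features
#' of w_f * |feature difference| / scale_f; orientation differences are
#' angular distances modulo pi. Links beyond the displacement gate are
#' forbidden (Inf). The distance term is squared: for co-moving particles
#' on a common line the *sum* of linear displacements is identical under
#' an identity swap, so a linear term cannot prefer the correct pairing,
#' while the squared term strictly favors equal small steps.
#'
#' @param a,b single-row observation data.frames (detection schema).
#' @param params a [LinkingParams-class].
#' @param scales named feature scales (brightness, area, diameter,
#'   orientation), e.g. from the per-stack robust MAD; defaults to 1.
#' @return Nonnegative score, or Inf when the link is forbidden.
#' @export
linkCost <- function(a, b, params = linkingParams(),
                     scales = c(brightness = 1, area = 1, diameter = 1,
                                orientation = 1)) {
  d <- sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2)
  if (d > params@maxDisplacementPx) return(Inf)
  w <- params@featureWeights
  w[["dist"]] * (d / params@maxDisplacementPx)^2 +
    w[["brightness"]] * abs(a$brightness - b$brightness) /
      scales[["brightness"]] +
    w[["area"]] * abs(a$area_px2 - b$area_px2) / scales[["area"]] +
    w[["diameter"]] * abs(a$diameter_px - b$diameter_px) /
      scales[["diameter"]] +
    w[["orientation"]] *
      angularDistance(a$orientation_rad, b$orientation_rad) /
      scales[["orientation"]]
}

# Dense cost matrix between two observation frames (rows: obsA).
linkCostMatrix <- function(obsA, obsB, params, scales, gateFactor = 1) {
  dx <- outer(obsA$x_px, obsB$x_px, `-`)
  dy <- outer(obsA$y_px, obsB$y_px, `-`)
  d <- sqrt(dx^2 + dy^2)
  w <- params@featureWeights
  cost <- w[["dist"]] * (d / params@maxDisplacementPx)^2 +
    w[["brightness"]] * abs(outer(obsA$brightness, obsB$brightness, `-`)) /
      scales[["brightness"]] +
    w[["area"]] * abs(outer(obsA$area_px2, obsB$area_px2, `-`)) /
      scales[["area"]] +
    w[["diameter"]] * abs(outer(obsA$diameter_px, obsB$diameter_px, `-`)) /
      scales[["diameter"]] +
    w[["orientation"]] *
      outer(obsA$orientation_rad, obsB$orientation_rad, angularDistance) /
      scales[["orientation"]]
  cost[d > params@maxDisplacementPx * gateFactor] <- Inf
  cost
}

#' Globally optimal one-to-one assignment between two frames
#'
#' Maximum-cardinality, minimum-total-cost matching over the allowed
#' (gated) pairs, via maximum-weight bipartite matching with a
#' cardinality-dominant weight offset. Unmatched observations start or
#' terminate tracks.
#'
#' @param obsA,obsB observation data.frames from consecutive (or
#'   gap-allowed) frames.
#' @param params a [LinkingParams-class].
#' @param scales feature scales (see [linkCost()]).
#' @param gateFactor multiple of the displacement gate (used for gap
#'   closing over several frames).
#' @return data.frame with columns \code{i} (row in obsA) and \code{j}
#'   (row in obsB), one row per matched pair.
#' @export
linkFrames <- function(obsA, obsB, params = linkingParams(),
                       scales = c(brightness = 1, area = 1, diameter = 1,
                                  orientation = 1),
                       gateFactor = 1) {
  nA <- nrow(obsA); nB <- nrow(obsB)
  if (nA == 0L || nB == 0L)
    return(data.frame(i = integer(), j = integer()))
  cost <- linkCostMatrix(obsA, obsB, params, scales, gateFactor)
  allowed <- which(is.finite(cost), arr.ind = TRUE)
  if (nrow(allowed) == 0L)
    return(data.frame(i = integer(), j = integer()))
  cmax <- max(cost[is.finite(cost)])
  K <- (min(nA, nB) + 1) * (cmax + 1)
  types <- c(rep(FALSE, nA), rep(TRUE, nB))
  edges <- as.vector(t(cbind(allowed[, 1], nA + allowed[, 2])))
  g <- igraph::make_bipartite_graph(types, edges = edges)
  m <- igraph::max_bipartite_match(
    g, weights = K - cost[allowed])$matching
  i <- seq_len(nA)
  j <- m[i] - nA
  keep <- !is.na(j)
  data.frame(i = i[keep], j = j[keep])
}

#' Build trajectories from per-frame observations
#'
#' Links observations frame by frame with [linkFrames()]; unmatched
#' observations start new tracks, track ends stay eligible for
#' \code{maxGapFrames} further frames (distance gate scaled by the frame
#' gap). Track ids are assigned in order of birth.
#'
#' @param detections data.frame of observations with a \code{frame}
#'   column (detection schema).
#' @param params a [LinkingParams-class].
#' @param pixelSize,frameRate acquisition metadata carried into the
#'   result.
#' @return An unfiltered [TrackSet-class] (no length filter, no stuck
#'   screen applied).
#' @export
buildTrajectories <- function(detections, params = linkingParams(),
                              pixelSize = 1, frameRate = 1) {
  cols <- c("frame", "x_px", "y_px", FEATURE_COLS)
  if (!nrow(detections)) {
    tr <- detections[c("frame", "x_px", "y_px")]
    tr$track_id <- integer()
    return(new("TrackSet", tracks = tr[c("track_id", names(tr)[1:3])],
               pixelSize = pixelSize, frameRate = frameRate,
               flagged = integer()))
  }
  scales <- featureScales(detections)
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  byFrame <- split(detections, detections$frame)
  nextId <- 0L
  # active track ends: list of (id, lastFrame, obs row)
  active <- list()
  assigned <- vector("list", length(byFrame))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    obs <- byFrame[[fi]]
    ids <- rep(NA_integer_, nrow(obs))
    if (length(active)) {
      lastFrames <- vapply(active, function(a) a$lastFrame, 0)
      gap <- f - lastFrames
      live <- which(gap >= 1 & gap <= params@maxGapFrames + 1L)
      if (length(live)) {
        ends <- do.call(rbind, lapply(active[live], `[[`, "obs"))
        # gate widens with the frame gap so gap-closed links stay physical
        gf <- max(gap[live])
        match <- linkFrames(ends, obs, params, scales, gateFactor = gf)
        if (nrow(match)) {
          # enforce per-pair gate (gateFactor above is the loosest)
          ok <- vapply(seq_len(nrow(match)), function(r) {
            e <- ends[match$i[r], ]; o <- obs[match$j[r], ]
            gapr <- f - active[[live[match$i[r]]]]$lastFrame
            sqrt((e$x_px - o$x_px)^2 + (e$y_px - o$y_px)^2) <=
              params@maxDisplacementPx * gapr
          }, TRUE)
          match <- match[ok, , drop = FALSE]
        }
        if (nrow(match)) {
          if (anyDuplicated(match$j))
            stop("internal consistency error: observation claimed twice")
          for (r in seq_len(nrow(match))) {
            ai <- live[match$i[r]]
            ids[match$j[r]] <- active[[ai]]$id
            active[[ai]]$lastFrame <- f
            active[[ai]]$obs <- obs[match$j[r], cols, drop = FALSE]
          }
        }
      }
      # retire ends whose gap allowance is exhausted
      lastFrames <- vapply(active, function(a) a$lastFrame, 0)
      active <- active[f - lastFrames <= params@maxGapFrames]
    }
    births <- which(is.na(ids))
    for (b in births) {
      nextId <- nextId + 1L
      ids[b] <- nextId
      active[[length(active) + 1L]] <-
        list(id = nextId, lastFrame = f, obs = obs[b, cols, drop = FALSE])
    }
    obs$track_id <- ids
    assigned[[fi]] <- obs
  }
  tr <- do.call(rbind, assigned)
  tr <- tr[order(tr$track_id, tr$frame), c("track_id", cols)]
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, pixelSize = pixelSize,
      frameRate = frameRate, flagged = integer())
}

#' Remove short trajectories
#'
#' Drops every trajectory with fewer than \code{minTrackLength} data
#' points (default 25; a 25-point track is retained, a 24-point track is
#' not). Removal counts are reported via message.
#'
#' @param trackset a [TrackSet-class].
#' @param minTrackLength minimum retained length.
#' @return The filtered [TrackSet-class].
#' @export
filterTrajectories <- function(trackset, minTrackLength = 25L) {
  tr <- trackset@tracks
  if (!nrow(tr)) return(trackset)
  len <- table(tr$track_id)
  keep <- as.integer(names(len)[len >= minTrackLength])
  dropped <- length(len) - length(keep)
  if (dropped > 0)
    message(dropped, " trajectorie(s) shorter than ", minTrackLength,
            " points removed")
  if (!length(keep))
    warning("no trajectory reaches ", minTrackLength, " data points")
  tr <- tr[tr$track_id %in% keep, , drop = FALSE]
  new("TrackSet", tracks = tr, pixelSize = trackset@pixelSize,
      frameRate = trackset@frameRate,
      flagged = intersect(trackset@flagged, keep))
}

#' Flag stuck particles
#'
#' Trajectories whose total net displacement is below twice the centroid
#' noise scale are flagged as stuck (particles adhering to tissue rather
#' than moving with the flow); flagged tracks are excluded from
#' kinematics by default.
#'
#' @param trackset a [TrackSet-class].
#' @param stuckNoisePx centroid noise scale, pixels.
#' @return The [TrackSet-class] with its \code{flagged} slot set.
#' @export
flagStuckTracks <- function(trackset, stuckNoisePx = 1) {
  tr <- trackset@tracks
  if (!nrow(tr)) return(trackset)
  net <- vapply(split(tr, tr$track_id), function(d)
    sqrt((d$x_px[nrow(d)] - d$x_px[1])^2 +
           (d$y_px[nrow(d)] - d$y_px[1])^2), 0)
  flagged <- as.integer(names(net)[net < 2 * stuckNoisePx])
  new("TrackSet", tracks = tr, pixelSize = trackset@pixelSize,
      frameRate = trackset@frameRate, flagged = flagged)
}

#' Detections to filtered trajectories
#'
#' Convenience chain: [buildTrajectories()], [filterTrajectories()],
#' [flagStuckTracks()].
#'
#' @param detections observation data.frame (detection schema).
#' @param params a [LinkingParams-class].
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second.
#' @return A [TrackSet-class].
#' @export
trackParticles <- function(detections, params = linkingParams(),
                           pixelSize = 1, frameRate = 1) {
  ts <- buildTrajectories(detections, params, pixelSize, frameRate)
  ts <- filterTrajectories(ts, params@minTrackLength)
  flagStuckTracks(ts, params@stuckNoisePx)
}
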