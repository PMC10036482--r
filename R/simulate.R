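# simulate: stylized wing venation, ground-truth particle motion and the
# speed waveforms behind the three local flow behaviors.

#' Default wing network configuration
#'
#' Geometry of the stylized five-region venation: span and chord in
#' micrometres, normalized chord positions of the longitudinal veins,
#' normalized span positions of the cross veins, and the per-region
#' diameter ranges (micrometres). Leading- and trailing-edge veins are the
#' widest (170-250 um diameter); tip and lattice veins are strictly
#' narrower.
#'
#' @return A named list understood by [buildWingNetwork()].
#' @export
defaultNetworkConfig <- function() {
  list(span_um = 20000, chord_um = 8000,
       longitudinal = c(0.08, 0.30, 0.50, 0.65, 0.85),
       cross = c(0.2, 0.4, 0.6, 0.75, 0.9),
       diameters = list(leading_edge = c(170, 250), membrane = c(80, 120),
                        wing_tip = c(40, 60), lattice = c(60, 90),
                        trailing_edge = c(170, 250)),
       labels = NULL, requireAllRegions = TRUE)
}

#' Build a stylized wing vein network
#'
#' Constructs a planar graph of longitudinal veins running base to tip,
#' interconnected by cross veins, in physical micrometre coordinates
#' (x: span, base at 0; y: chord, leading edge at 0). Each segment is
#' labeled with one of the five wing regions by the position of its
#' midpoint on the default region map, and receives the midpoint diameter
#' of its region's configured range.
#'
#' @param config list of overrides of [defaultNetworkConfig()]. Set
#'   \code{labels} to a character vector to force per-segment region labels
#'   (construction order), and \code{requireAllRegions = FALSE} to allow
#'   minimal networks that do not carry all five labels.
#' @return A [VeinNetwork-class] object.
#' @export
#' @examples
#' net <- buildWingNetwork()
#' regionLabels(net)
buildWingNetwork <- function(config = list()) {
  cfg <- utils::modifyList(defaultNetworkConfig(), config)
  dia <- cfg$diameters
  lo <- function(r) dia[[r]][1]; hi <- function(r) dia[[r]][2]
  if (max(hi("wing_tip"), hi("lattice")) >=
      min(lo("leading_edge"), lo("trailing_edge")))
    stop("inconsistent geometry: tip/lattice diameter range reaches the ",
         "leading/trailing edge range; edge veins must be strictly wider")

  xb <- sort(unique(c(0, cfg$cross, 1)))
  yl <- sort(cfg$longitudinal)
  nodeKey <- function(ix, iy) paste0(ix, ".", iy)
  nodes <- expand.grid(ix = seq_along(xb), iy = seq_along(yl))
  nodes$x <- xb[nodes$ix] * cfg$span_um
  nodes$y <- yl[nodes$iy] * cfg$chord_um
  rownames(nodes) <- nodeKey(nodes$ix, nodes$iy)

  segs <- list()
  # longitudinal veins, base to tip, split at cross-vein positions
  for (iy in seq_along(yl))
    for (ix in seq_len(length(xb) - 1L))
      segs[[length(segs) + 1L]] <- c(nodeKey(ix, iy), nodeKey(ix + 1L, iy))
  # cross veins connect adjacent longitudinal veins
  for (x in unique(cfg$cross)) {
    ix <- match(x, xb)
    for (iy in seq_len(length(yl) - 1L))
      segs[[length(segs) + 1L]] <- c(nodeKey(ix, iy), nodeKey(ix, iy + 1L))
  }
  segdf <- data.frame(node_a = vapply(segs, `[`, "", 1L),
                      node_b = vapply(segs, `[`, "", 2L),
                      stringsAsFactors = FALSE)

  # label by midpoint position on the default wing region map
  map <- defaultRegionMap()
  mid <- (nodes[segdf$node_a, c("x", "y")] +
            nodes[segdf$node_b, c("x", "y")]) / 2
  midn <- cbind(mid$x / cfg$span_um, mid$y / cfg$chord_um)
  segdf$region <- vapply(seq_len(nrow(midn)), function(i)
    assignRegion(midn[i, , drop = FALSE], map), "")
  if (!is.null(cfg$labels)) {
    if (length(cfg$labels) != nrow(segdf))
      stop("labels must give one region per segment (",
           nrow(segdf), " segments)")
    segdf$region <- cfg$labels
  }
  segdf$radius_um <- vapply(segdf$region,
                            function(r) mean(dia[[r]]) / 2, 0)

  # drop nodes never referenced (keeps minimal configs minimal)
  used <- unique(c(segdf$node_a, segdf$node_b))
  nm <- as.matrix(nodes[used, c("x", "y")])
  rownames(nm) <- used

  if (isTRUE(cfg$requireAllRegions) &&
      !all(WING_REGIONS %in% segdf$region))
    stop("network does not carry all five wing region labels; missing: ",
         paste(setdiff(WING_REGIONS, segdf$region), collapse = ", "))
  new("VeinNetwork", nodes = nm, segments = segdf)
}

# Signed along-vein velocity of a pulsatile behavior: forward half-sine
# pulses of peak speed A at frequency f, each followed by a reversal whose
# peak speed (and hence retraced distance) is the fraction r of the
# forward pulse.
signedPulsatile <- function(t, freqHz, amplitude = 1, reversal = 0,
                            phase = 0) {
  s <- sin(2 * pi * freqHz * t + phase)
  amplitude * pmax(s, 0) - reversal * amplitude * pmax(-s, 0)
}

# Signed along-vein velocity of an aperiodic behavior: one-directional,
# speed modulated but never zero (modDepth < 1).
signedAperiodic <- function(t, baseSpeed, modDepth = 0, modFreqHz = 0.5,
                            phase = 0) {
  baseSpeed * (1 + modDepth * sin(2 * pi * modFreqHz * t + phase))
}

#' Synthetic pulsatile speed trace
#'
#' The unsigned speed waveform of pulsatile flow: forward half-sine pulses
#' at \code{freqHz} with peak speed \code{amplitude}, separated by a stop
#' or by a shorter reversal whose peak speed is
#' \code{reversalFraction * amplitude}. With \code{reversalFraction = 0}
#' this is a rectified sinusoid with one peak per pulse period.
#'
#' @param freqHz pulsation frequency, Hz.
#' @param duration trace length, seconds.
#' @param sampleRate samples per second.
#' @param reversalFraction fraction of the forward pulse retraced, [0, 1).
#' @param amplitude peak forward speed (arbitrary units).
#' @param phase phase offset, radians.
#' @return Numeric speed series of length \code{duration * sampleRate},
#'   sampled at t = 0, 1/sampleRate, ...
#' @export
#' @examples
#' tr <- pulsatileSpeedTrace(2, duration = 10, sampleRate = 100)
#' pulseFrequency(tr, duration = 10)   # recovers 2 Hz
pulsatileSpeedTrace <- function(freqHz, duration, sampleRate,
                                reversalFraction = 0, amplitude = 1,
                                phase = 0) {
  t <- seq(0, by = 1 / sampleRate, length.out = round(duration * sampleRate))
  abs(signedPulsatile(t, freqHz, amplitude, reversalFraction, phase))
}

#' Simulate ground-truth particle motion
#'
#' Advects tracer particles through the vein network, one frame interval
#' per sample. Each network region must be assigned a [FlowBehavior-class];
#' a particle inherits the behavior of the segment it is seeded on.
#' Pulsatile particles advance in half-sine pulses with partial reversals
#' (coordinated phase, as in bulk flow near the wing base); aperiodic
#' particles move one-directionally with per-particle modulation phase;
#' leaky particles leave their vein, transit the behavior's sinus polygon
#' and re-enter the nearest bounding vein.
#'
#' @param network a [VeinNetwork-class].
#' @param behaviors named list, region label -> [FlowBehavior-class].
#' @param nParticles number of particles.
#' @param duration seconds to simulate.
#' @param frameRate frames per second.
#' @param seed integer seed; identical seed gives identical output.
#' @param particleDiametersUm diameters sampled per particle (default the
#'   injected 3 and 6 um polystyrene sizes).
#' @param startFraction particles are seeded within this leading fraction
#'   of their segment, evenly spaced with jitter so co-seeded particles
#'   never overlap.
#' @param segmentIds optional segment indices to seed on (default: all
#'   segments, cycled in seeded random order).
#' @return A [GroundTruth-class] object.
#' @export
simulateParticles <- function(network, behaviors, nParticles, duration,
                              frameRate, seed = 1,
                              particleDiametersUm = c(3, 6),
                              startFraction = 0.25, segmentIds = NULL) {
  seg <- network@segments
  regs <- unique(seg$region)
  missing <- setdiff(regs, names(behaviors))
  if (length(missing))
    stop("no flow behavior assigned for region(s): ",
         paste(missing, collapse = ", "))
  nF <- round(duration * frameRate)
  tt <- (seq_len(nF) - 1L) / frameRate
  for (r in regs) {
    b <- behaviors[[r]]
    if (b@mode == "pulsatile" && duration < 1 / b@pulseFreqHz)
      warning("duration shorter than one pulse period in region '", r,
              "'; pulse frequency is unrecoverable")
  }
  empty <- data.frame(particle_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      segment_id = integer(), region = character(),
                      diameter_um = numeric())
  if (nParticles == 0L)
    return(new("GroundTruth", paths = empty, frameRate = frameRate,
               duration = duration))

  withSeed(seed, {
    pool <- segmentIds %||% seq_len(nrow(seg))
    segOrder <- if (length(pool) > 1L) sample(pool) else pool
    assigned <- segOrder[(seq_len(nParticles) - 1L) %% length(segOrder) + 1L]
    # evenly spaced starts (with jitter) among particles sharing a segment
    rank <- stats::ave(seq_len(nParticles), assigned, FUN = seq_along)
    count <- stats::ave(seq_len(nParticles), assigned, FUN = length)
    rows <- vector("list", nParticles)
    for (i in seq_len(nParticles)) {
      si <- assigned[i]
      b <- behaviors[[seg$region[si]]]
      a <- network@nodes[seg$node_a[si], ]
      z <- network@nodes[seg$node_b[si], ]
      L <- sqrt(sum((z - a)^2))
      s0 <- (rank[i] - runif(1, 0.3, 0.7)) * startFraction * L / count[i]
      d_um <- particleDiametersUm[1L + (i - 1L) %% length(particleDiametersUm)]
      dt <- 1 / frameRate
      if (b@mode == "pulsatile") {
        v <- signedPulsatile(tt, b@pulseFreqHz, b@baseSpeed,
                             b@reversalFraction)
        s <- pmin(pmax(s0 + c(0, cumsum(v[-nF] * dt)), 0), L)
        xy <- interpPolyline(rbind(a, z), s)
        rows[[i]] <- data.frame(particle_id = i, frame = seq_len(nF),
                                x_um = xy[, 1], y_um = xy[, 2],
                                segment_id = si, region = seg$region[si],
                                diameter_um = d_um)
      } else if (b@mode == "aperiodic") {
        v <- signedAperiodic(tt, b@baseSpeed, b@modDepth, b@modFreqHz,
                             phase = runif(1, 0, 2 * pi))
        s <- pmin(pmax(s0 + c(0, cumsum(v[-nF] * dt)), 0), L)
        xy <- interpPolyline(rbind(a, z), s)
        rows[[i]] <- data.frame(particle_id = i, frame = seq_len(nF),
                                x_um = xy[, 1], y_um = xy[, 2],
                                segment_id = si, region = seg$region[si],
                                diameter_um = d_um)
      } else {
        rows[[i]] <- leakyPath(network, si, s0, b, nF, dt, i, d_um)
      }
    }
    paths <- do.call(rbind, rows)
    rownames(paths) <- NULL
    new("GroundTruth", paths = paths, frameRate = frameRate,
        duration = duration)
  })
}

# A leaky particle's prescribed vein -> sinus -> vein path: along the
# seed segment to the point nearest the sinus centroid, across the sinus
# through its centroid, re-entering the nearest other segment and
# continuing toward that segment's far end.
leakyPath <- function(network, si, s0, behavior, nF, dt, id, d_um) {
  seg <- network@segments
  a <- network@nodes[seg$node_a[si], ]
  z <- network@nodes[seg$node_b[si], ]
  ctr <- colMeans(behavior@sinusPolygon)
  # exit point: projection of the sinus centroid onto the seed segment
  u <- z - a; L2 <- sum(u^2)
  tex <- min(max(sum((ctr - a) * u) / L2, 0.25), 0.9)
  exitPt <- a + tex * u
  # re-entry: nearest point among the other segments' midpoints
  others <- setdiff(seq_len(nrow(seg)), si)
  mids <- t(vapply(others, function(j)
    (network@nodes[seg$node_a[j], ] + network@nodes[seg$node_b[j], ]) / 2,
    numeric(2)))
  j <- others[which.min(rowSums(sweep(mids, 2, ctr)^2))]
  reentry <- (network@nodes[seg$node_a[j], ] +
                network@nodes[seg$node_b[j], ]) / 2
  far <- network@nodes[seg$node_b[j], ]
  start <- a + (s0 / sqrt(L2)) * u
  way <- rbind(start, exitPt, ctr, reentry, far)
  cum <- c(0, cumsum(sqrt(rowSums(diff(way)^2))))
  s <- behavior@baseSpeed * (seq_len(nF) - 1L) * dt
  xy <- interpPolyline(way, s)
  phase <- findInterval(s, cum[c(2, 4)])   # 0 on vein, 1 in sinus, 2 re-entered
  data.frame(particle_id = id, frame = seq_len(nF),
             x_um = xy[, 1], y_um = xy[, 2],
             segment_id = ifelse(phase == 0L, si,
                                 ifelse(phase == 2L, j, NA_integer_)),
             region = ifelse(phase == 2L, seg$region[j], seg$region[si]),
             diameter_um = d_um)
}

#' Test whether points lie inside a vein channel or sinus
#'
#' A point is inside the network if it is within a segment's lumen radius
#' of that segment's centerline; sinus polygons (from leaky behaviors) are
#' checked separately.
#'
#' @param xy n x 2 micrometre positions.
#' @param network a [VeinNetwork-class].
#' @return Logical vector: within some vein channel.
#' @export
insideVeinChannel <- function(xy, network) {
  seg <- network@segments
  inside <- rep(FALSE, nrow(xy))
  for (i in seq_len(nrow(seg))) {
    a <- network@nodes[seg$node_a[i], ]
    z <- network@nodes[seg$node_b[i], ]
    u <- z - a; L2 <- sum(u^2)
    tproj <- pmin(pmax(((xy[, 1] - a[1]) * u[1] + (xy[, 2] - a[2]) * u[2]) /
                         L2, 0), 1)
    d2 <- (xy[, 1] - (a[1] + tproj * u[1]))^2 +
      (xy[, 2] - (a[2] + tproj * u[2]))^2
    inside <- inside | d2 <= seg$radius_um[i]^2
  }
  inside
}
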