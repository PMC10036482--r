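# regions: normalized wing coordinates, region assignment, per-region
# aggregation and local flow-behavior classification.

#' Default wing region map
#'
#' Schematic polygons in normalized wing coordinates (span 0 at base, 1
#' at tip; chord 0 at leading, 1 at trailing edge) that tile the unit
#' domain without overlap: a leading-edge band, the membranous sinus
#' pocket at about two-thirds span toward the leading edge, a distal
#' wing-tip cap, a trailing-edge band and the central lattice. Boundary
#' points are resolved by the priority order leading_edge, membrane,
#' wing_tip, trailing_edge, lattice. Default mean vein radii (metres)
#' follow the relative calibers of the five regions: wide leading and
#' trailing edge conduits (170-250 um diameters), narrow tip and lattice
#' veins.
#'
#' @param radii optional named numeric of per-region radii in metres.
#' @param radiusN measurements behind each radius (default 25 diameters
#'   per region).
#' @return A [RegionMap-class].
#' @export
defaultRegionMap <- function(radii = NULL, radiusN = NULL) {
  poly <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("span", "chord")
    m
  }
  polygons <- list(
    leading_edge = poly(0, 0, 0.55, 0, 0.55, 0.18, 0, 0.18),
    membrane = poly(0.55, 0, 0.85, 0, 0.85, 0.30, 0.55, 0.30),
    wing_tip = poly(0.85, 0, 1, 0, 1, 1, 0.85, 1),
    trailing_edge = poly(0, 0.75, 0.85, 0.75, 0.85, 1, 0, 1),
    lattice = poly(0, 0.18, 0.55, 0.18, 0.55, 0.30, 0.85, 0.30,
                   0.85, 0.75, 0, 0.75))
  if (is.null(radii))
    radii <- c(leading_edge = 1.05e-4, membrane = 5.0e-5, wing_tip = 1.5e-5,
               lattice = 3.75e-5, trailing_edge = 1.05e-4)
  if (is.null(radiusN))
    radiusN <- setNames(rep(25L, length(radii)), names(radii))
  new("RegionMap", polygons = polygons, radii = radii,
      radiusN = as.integer(radiusN) |> setNames(names(radiusN)),
      priority = c("leading_edge", "membrane", "wing_tip",
                   "trailing_edge", "lattice"))
}

#' Normalize positions to the wing coordinate frame
#'
#' Affine map defined by the wing landmarks: the base corner is the
#' origin, the base-to-tip vector spans [0, 1] in the span coordinate and
#' the leading-to-trailing vector spans [0, 1] in the chord coordinate.
#' Invertible whenever the two axes are independent.
#'
#' @param xy n x 2 matrix of physical positions (micrometres).
#' @param wingFrame list with micrometre landmarks \code{base},
#'   \code{tip}, \code{leading}, \code{trailing} (2-vectors).
#' @param inverse map normalized coordinates back to physical.
#' @return n x 2 matrix of normalized (span, chord) positions.
#' @export
normalizeCoordinates <- function(xy, wingFrame, inverse = FALSE) {
  e1 <- wingFrame$tip - wingFrame$base
  e2 <- wingFrame$trailing - wingFrame$leading
  A <- cbind(e1, e2)
  if (abs(det(A)) < 1e-9 * max(1, sum(e1^2), sum(e2^2)))
    stop("degenerate wing landmarks: span and chord axes are not independent")
  xy <- rbind(xy)
  if (inverse)
    return(t(A %*% t(xy)) + rep(wingFrame$base, each = nrow(xy)))
  t(solve(A) %*% (t(xy) - wingFrame$base))
}

#' Assign a trajectory to a wing region
#'
#' Returns the label of the polygon containing the trajectory's starting
#' position in normalized coordinates (boundary points go to the first
#' matching polygon in the map's priority order); positions outside the
#' unit domain are "unassigned".
#'
#' @param startNorm 1 x 2 (or length-2) normalized starting position.
#' @param regionMap a [RegionMap-class].
#' @return A region label, or "unassigned".
#' @export
assignRegion <- function(startNorm, regionMap = defaultRegionMap()) {
  p <- as.numeric(startNorm)
  if (p[1] < 0 || p[1] > 1 || p[2] < 0 || p[2] > 1) return("unassigned")
  for (nm in regionMap@priority) {
    pg <- regionMap@polygons[[nm]]
    if (pracma::inpolygon(p[1], p[2], pg[, 1], pg[, 2], boundary = TRUE))
      return(nm)
  }
  "unassigned"
}

#' Mean vein radius from repeated measurements
#'
#' @param measurements positive radii (any consistent unit).
#' @return Arithmetic mean with attribute \code{n} = sample size.
#' @export
meanVeinRadius <- function(measurements) {
  if (!length(measurements)) stop("no radius measurements supplied")
  if (any(!is.finite(measurements) | measurements <= 0))
    stop("radius measurements must all be positive")
  structure(mean(measurements), n = length(measurements))
}

#' Per-region hemodynamic summaries
#'
#' Aggregates per-trajectory kinematics by wing region: trajectory count,
#' mean maximum and median velocity, mean pulse frequency, the region's
#' mean vein radius, and the dimensionless numbers recomputed from the
#' region-level quantities (Pe and Re from r and the mean V_max converted
#' to m/s; Wo from r and the mean pulse frequency). Regions with no
#' trajectories are omitted; "unassigned" records are excluded.
#'
#' @param kin per-trajectory kinematics with a \code{region} column (see
#'   [trajectoryKinematics()] and [assignRegion()]).
#' @param regionMap a [RegionMap-class] supplying per-region radii.
#' @param constants a [FluidConstants-class].
#' @return data.frame, one row per populated region: region,
#'   n_trajectories, v_max_mm_s, v_median_mm_s, pulse_freq_hz, r_m, Pe,
#'   Re, Wo.
#' @export
summarizeRegions <- function(kin, regionMap = defaultRegionMap(),
                             constants = fluidConstants()) {
  if (!"region" %in% names(kin))
    stop("kinematics records must carry a 'region' column")
  kin <- kin[kin$region %in% names(regionMap@radii), , drop = FALSE]
  out <- lapply(split(kin, kin$region), function(d) {
    r <- regionMap@radii[[d$region[1]]]
    vmax <- mean(d$v_max_mm_s)
    f <- mean(d$pulse_freq_hz)
    data.frame(region = d$region[1], n_trajectories = nrow(d),
               v_max_mm_s = vmax, v_median_mm_s = mean(d$v_median_mm_s),
               pulse_freq_hz = f, r_m = r,
               Pe = peclet(r, vmax / 1000, constants),
               Re = reynolds(r, vmax / 1000, constants),
               Wo = womersley(r, f, constants))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(region = character(), n_trajectories = integer(),
                      v_max_mm_s = numeric(), v_median_mm_s = numeric(),
                      pulse_freq_hz = numeric(), r_m = numeric(),
                      Pe = numeric(), Re = numeric(), Wo = numeric()))
  rownames(out) <- NULL
  out[order(match(out$region, c(WING_REGIONS, BODY_REGIONS))), ,
      drop = FALSE]
}

#' Classify local flow behavior from a signed velocity series
#'
#' Pulsatile flow stops or reverses: the signed along-path velocity
#' crosses or touches zero (within a floor of \code{zeroFloorFrac} of the
#' series' maximum magnitude). Aperiodic flow keeps a constant sign and
#' never slows below that floor. The leaky label is an orthogonal
#' geometric flag (see [isLeakyTrajectory()]). Series shorter than 10
#' samples are "indeterminate".
#'
#' @param signedSeries signed along-path velocity series (mm/s).
#' @param zeroFloorFrac near-zero floor as a fraction of max |v|
#'   (default 0.05).
#' @return "pulsatile", "aperiodic" or "indeterminate".
#' @export
classifyFlowBehavior <- function(signedSeries, zeroFloorFrac = 0.05) {
  if (length(signedSeries) < 10L) return("indeterminate")
  floorV <- zeroFloorFrac * max(abs(signedSeries))
  stops <- any(abs(signedSeries) <= floorV)
  reversals <- length(unique(sign(signedSeries[signedSeries != 0]))) > 1L
  if (stops || reversals) "pulsatile" else "aperiodic"
}

#' Leaky-flow geometric flag
#'
#' TRUE when any trajectory point lies outside every vein channel and
#' inside a sinus polygon -- hemolymph that left the veins for the
#' membranous sinus.
#'
#' @param xyUm n x 2 micrometre positions of a trajectory.
#' @param network a [VeinNetwork-class].
#' @param sinusPolygons list of k x 2 micrometre polygons.
#' @return Logical flag.
#' @export
isLeakyTrajectory <- function(xyUm, network, sinusPolygons) {
  if (!length(sinusPolygons)) return(FALSE)
  outside <- !insideVeinChannel(xyUm, network)
  if (!any(outside)) return(FALSE)
  for (pg in sinusPolygons) {
    inSinus <- pracma::inpolygon(xyUm[outside, 1], xyUm[outside, 2],
                                 pg[, 1], pg[, 2], boundary = TRUE)
    if (any(inSinus)) return(TRUE)
  }
  FALSE
}
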