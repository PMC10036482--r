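# kinematics: per-trajectory flow quantities. Instantaneous velocity is
# the unsigned step speed
#   V_instant = sqrt((x_i - x_{i+1})^2 + (y_i - y_{i+1})^2) / time_i
# in mm/s; series are smoothed with a centered moving mean (window 5,
# shrinking at the ends); pulse frequency counts peaks of the normalized
# speed trace; Pe, Re and Wo follow
#   Pe = r V_max / D_O2,  Re = rho V_max r / mu,  Wo = r sqrt(f rho / mu).

#' Instantaneous velocity of a trajectory
#'
#' Euclidean step displacement (pixels converted to millimetres) divided
#' by the step's time interval (frame gap / frame rate, so gap-closed
#' links use their true elapsed time). Speeds are unsigned magnitudes.
#'
#' @param track data.frame with columns frame, x_px, y_px (one
#'   trajectory, frames strictly increasing).
#' @param pixelSize micrometres per pixel; required.
#' @param frameRate frames per second; required.
#' @return Numeric speed series, mm/s, length nrow(track) - 1.
#' @export
instantaneousVelocity <- function(track, pixelSize, frameRate) {
  if (missing(pixelSize) || is.null(pixelSize) || !is.finite(pixelSize))
    stop("pixelSize (um/px) is required: refusing to report px/frame units")
  if (missing(frameRate) || is.null(frameRate) || !is.finite(frameRate))
    stop("frameRate (fps) is required: refusing to report px/frame units")
  if (nrow(track) < 2L)
    stop("trajectory must have at least 2 points")
  d_px <- sqrt(diff(track$x_px)^2 + diff(track$y_px)^2)
  dt <- diff(track$frame) / frameRate
  (d_px * pixelSize / 1000) / dt
}

#' Centered moving mean with shrinking end windows
#'
#' For an odd window w, element i is the mean of the elements within
#' (i - (w-1)/2) .. (i + (w-1)/2) intersected with the series, so end
#' windows shrink (the first element of a window-5 mean averages 3
#' elements). Output length equals input length.
#'
#' @param series numeric vector.
#' @param window odd window length >= 1 (default 5).
#' @return Smoothed numeric vector.
#' @export
smoothVelocity <- function(series, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1")
  n <- length(series)
  if (n == 0L) return(series)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(series))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Maximum and median of a speed series
#'
#' @param series nonempty numeric speed series (typically smoothed).
#' @return Named numeric c(v_max, v_median).
#' @export
velocityStats <- function(series) {
  if (!length(series)) stop("empty velocity series")
  c(v_max = max(series), v_median = median(series))
}

# Local maxima of a series with their prominences: a peak's prominence is
# its height above the higher of the two minima separating it from
# higher ground (or the series ends).
peakProminences <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), prominence = numeric()))
  isPeak <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                    x[2:(n - 1)] >= x[3:n]) + 1L
  # drop plateau repeats: keep the first sample of equal-height runs
  if (length(isPeak) > 1L)
    isPeak <- isPeak[c(TRUE, diff(isPeak) > 1L | diff(x[isPeak]) != 0)]
  prom <- vapply(isPeak, function(i) {
    l <- i - 1L; lmin <- x[i]
    while (l >= 1L && x[l] <= x[i]) { lmin <- min(lmin, x[l]); l <- l - 1L }
    if (l < 1L) lmin <- min(x[1:i])
    r <- i + 1L; rmin <- x[i]
    while (r <= n && x[r] <= x[i]) { rmin <- min(rmin, x[r]); r <- r + 1L }
    if (r > n) rmin <- min(x[i:n])
    x[i] - max(lmin, rmin)
  }, 0)
  data.frame(index = isPeak, prominence = prom)
}

#' Pulse frequency by normalized peak counting
#'
#' Normalizes a speed trace by its maximum, accepts local maxima whose
#' prominence (height above the flanking minima) exceeds
#' \code{peakThreshold}, and reports accepted peaks per second.
#'
#' @param series numeric speed series.
#' @param duration observation window, seconds.
#' @param peakThreshold normalized prominence threshold (default 0.3).
#' @return Pulse frequency, Hz.
#' @export
#' @examples
#' pulseFrequency(pulsatileSpeedTrace(2, 10, 100), duration = 10)  # 2 Hz
pulseFrequency <- function(series, duration, peakThreshold = 0.3) {
  if (!length(series)) stop("empty velocity series")
  if (duration <= 0) stop("duration must be positive")
  mx <- max(series)
  if (mx <= 0) {
    warning("all-zero velocity series: normalization undefined, ",
            "returning 0 Hz")
    return(0)
  }
  pk <- peakProminences(series / mx)
  sum(pk$prominence > peakThreshold) / duration
}

checkPositive <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (!is.finite(args[[nm]]) || args[[nm]] <= 0)
      stop(nm, " must be strictly positive, got ", args[[nm]])
}

#' Peclet number
#'
#' Pe = r V_max / D_O2: advective over diffusive transport of oxygen.
#'
#' @param r vein radius, metres.
#' @param vMax maximum velocity, m/s.
#' @param constants a [FluidConstants-class].
#' @return Pe (dimensionless).
#' @export
peclet <- function(r, vMax, constants = fluidConstants()) {
  checkPositive(r = r, vMax = vMax)
  r * vMax / constants@dO2
}

#' Reynolds number
#'
#' Re = rho V_max r / mu: inertial over viscous forces. Re << 1 is the
#' viscous (Stokes) regime found throughout the wing.
#'
#' @inheritParams peclet
#' @return Re (dimensionless).
#' @export
reynolds <- function(r, vMax, constants = fluidConstants()) {
  checkPositive(r = r, vMax = vMax)
  constants@rho * vMax * r / constants@mu
}

#' Womersley number
#'
#' Wo = r sqrt(f rho / mu): pulsatile over viscous effects.
#'
#' @param r vein radius, metres.
#' @param f pulse frequency, Hz (>= 0).
#' @param constants a [FluidConstants-class].
#' @return Wo (dimensionless).
#' @export
womersley <- function(r, f, constants = fluidConstants()) {
  checkPositive(r = r)
  if (!is.finite(f) || f < 0) stop("f must be >= 0, got ", f)
  r * sqrt(f * constants@rho / constants@mu)
}

#' Per-trajectory kinematics
#'
#' For every (unflagged) trajectory: instantaneous velocity, moving-mean
#' smoothing, maximum and median speed, and pulse frequency over the
#' track's own observation window.
#'
#' @param trackset a [TrackSet-class].
#' @param window moving-mean window (default 5).
#' @param peakThreshold pulse-peak prominence threshold (default 0.3).
#' @param useSmoothed take v_max/v_median from the smoothed series
#'   (default) or the raw series.
#' @param dropFlagged exclude stuck-flagged tracks (default TRUE).
#' @return data.frame: track_id, n_points, start_x_px, start_y_px,
#'   v_max_mm_s, v_median_mm_s, pulse_freq_hz.
#' @export
trajectoryKinematics <- function(trackset, window = 5L, peakThreshold = 0.3,
                                 useSmoothed = TRUE, dropFlagged = TRUE) {
  tr <- trackTable(trackset, dropFlagged = dropFlagged)
  out <- lapply(split(tr, tr$track_id), function(d) {
    v <- instantaneousVelocity(d, pixelSize(trackset), frameRate(trackset))
    vs <- smoothVelocity(v, window)
    stats <- velocityStats(if (useSmoothed) vs else v)
    dur <- (d$frame[nrow(d)] - d$frame[1]) / frameRate(trackset)
    f <- suppressWarnings(pulseFrequency(vs, dur, peakThreshold))
    data.frame(track_id = d$track_id[1], n_points = nrow(d),
               start_x_px = d$x_px[1], start_y_px = d$y_px[1],
               v_max_mm_s = stats[["v_max"]],
               v_median_mm_s = stats[["v_median"]],
               pulse_freq_hz = f)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = integer(), n_points = integer(),
                      start_x_px = numeric(), start_y_px = numeric(),
                      v_max_mm_s = numeric(), v_median_mm_s = numeric(),
                      pulse_freq_hz = numeric())
  rownames(out) <- NULL
  out
}

#' Signed along-path velocity
#'
#' Projects each step displacement onto the local motion direction (the
#' moving-mean of the displacement vectors, normalized), giving a signed
#' speed series in mm/s: negative values are reversals against the
#' prevailing local direction. Input to the flow-behavior classifier.
#'
#' @param track one trajectory (frame, x_px, y_px).
#' @param pixelSize micrometres per pixel.
#' @param frameRate frames per second.
#' @param window tangent smoothing window.
#' @return Signed numeric series, mm/s, length nrow(track) - 1.
#' @export
signedVelocity <- function(track, pixelSize, frameRate, window = 5L) {
  if (nrow(track) < 2L) stop("trajectory must have at least 2 points")
  dx <- diff(track$x_px); dy <- diff(track$y_px)
  tx <- smoothVelocity(dx, window); ty <- smoothVelocity(dy, window)
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  proj <- (dx * tx + dy * ty) / nrm
  dt <- diff(track$frame) / frameRate
  (proj * pixelSize / 1000) / dt
}
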