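# detect: frame preprocessing and Hessian-eigenmap particle segmentation.
# All image math is floating point; matrices are height x width with
# x = column and y = row (1-based pixel centers).

#' Temporal-median background subtraction
#'
#' Estimates the static scene (vein walls, illumination pedestal) as the
#' per-pixel median over up to \code{backgroundWindow} evenly spaced
#' frames and subtracts it from every frame, clipping at zero. Moving
#' spots occupy any one pixel in few of the sampled frames and survive;
#' static structure is removed.
#'
#' @param stack an [ImageStack-class] with at least two frames.
#' @param params a [DetectionParams-class].
#' @return The background-subtracted [ImageStack-class].
#' @export
subtractBackground <- function(stack, params = detectionParams()) {
  nF <- nFrames(stack)
  if (nF < 2L)
    stop("background subtraction needs at least two frames; got ", nF)
  pick <- unique(round(seq(1, nF, length.out = min(params@backgroundWindow,
                                                   nF))))
  slab <- stack@frames[, , pick, drop = FALSE]
  d <- dim(slab)
  bg <- matrix(matrixStats::rowMedians(matrix(slab, d[1] * d[2], d[3])),
               d[1], d[2])
  out <- sweep(stack@frames, c(1, 2), bg, `-`)
  out[out < 0] <- 0
  ImageStack(out, frameRate(stack), pixelSize(stack))
}

#' Frame-wise linear intensity adjustment
#'
#' Linearly rescales a frame so that its (1 - saturationFraction)
#' intensity quantile maps to full scale (1.0), clipping the brightest
#' \code{saturationFraction} of pixels at the maximum. Rank-preserving
#' below the clip point and idempotent; compensates frame-to-frame for
#' photobleaching decay. The quantile is the inverse empirical CDF
#' (type 1).
#'
#' @param frame numeric matrix.
#' @param saturationFraction fraction of pixels to saturate (default 1
#'   percent).
#' @param gainCap optional cap on the rescale gain, expressed as a
#'   fraction of the frame maximum: the divisor never drops below
#'   \code{gainCap * max(frame)}. On sparse frames (signal occupying far
#'   less than the saturation fraction) the raw quantile lands on the
#'   noise floor and would amplify noise to full scale; the cap keeps the
#'   brightest structure at (or just above) full scale instead. 0
#'   disables the cap (the pure quantile mapping).
#' @return The adjusted matrix, values in [0, 1].
#' @export
adjustIntensity <- function(frame, saturationFraction = 0.01, gainCap = 0) {
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    warning("constant frame: no dynamic range, returned unchanged")
    return(frame)
  }
  q <- if (saturationFraction == 0) rng[2] else
    quantile(frame, 1 - saturationFraction, type = 1, names = FALSE)
  q <- max(q, gainCap * rng[2])
  if (q <= rng[1])
    q <- rng[2]
  pmin(frame / q, 1)
}

# Gaussian-smoothed Hessian components of a frame.
hessianComponents <- function(frame, sigma) {
  s <- EBImage::gblur(frame, sigma = sigma, boundary = "replicate")
  hxx <- matShift(s, 0, 1) - 2 * s + matShift(s, 0, -1)
  hyy <- matShift(s, 1, 0) - 2 * s + matShift(s, -1, 0)
  hxy <- (matShift(s, 1, 1) + matShift(s, -1, -1) -
            matShift(s, 1, -1) - matShift(s, -1, 1)) / 4
  list(smoothed = s, hxx = hxx, hyy = hyy, hxy = hxy)
}

#' Hessian eigenmap candidate mask
#'
#' Marks pixels where the larger eigenvalue (lambda2) of the 2x2 Hessian
#' of the Gaussian-smoothed intensity is negative, i.e. the intensity is
#' locally concave in every direction -- the interior of a bright blob.
#' For an isotropic Gaussian spot this is a connected disc of roughly one
#' sigma radius around the peak. Set \code{darkBlobs} in the params to
#' flip the convention (lambda1 positive: dark blob interiors).
#'
#' @param frame numeric matrix.
#' @param hessianSigmaPx Gaussian derivative scale, pixels.
#' @param darkBlobs detect dark blobs instead of bright ones.
#' @return Logical matrix; border pixels are FALSE.
#' @export
hessianCandidateMask <- function(frame, hessianSigmaPx = 1.5,
                                 darkBlobs = FALSE) {
  hc <- hessianComponents(frame, hessianSigmaPx)
  disc <- sqrt((hc$hxx - hc$hyy)^2 + 4 * hc$hxy^2)
  lam2 <- (hc$hxx + hc$hyy + disc) / 2           # larger eigenvalue
  lam1 <- (hc$hxx + hc$hyy - disc) / 2           # smaller eigenvalue
  mask <- if (darkBlobs) lam1 > 0 else lam2 < 0
  mask[c(1, nrow(mask)), ] <- FALSE
  mask[, c(1, ncol(mask))] <- FALSE
  mask
}

#' Canny edge detection
#'
#' Gaussian smoothing, central-difference gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding. Thresholds are absolute gradient magnitudes (intensity
#' units per pixel on the [0, 1] scale), so sharp structure boundaries
#' (vein walls, saturation rims) fire while the smooth flanks of an
#' unsaturated Gaussian spot stay below threshold; set
#' \code{relative = TRUE} for classic thresholds as fractions of the
#' frame's maximum gradient.
#'
#' @param frame numeric matrix.
#' @param low,high hysteresis thresholds (gradient units, or fractions of
#'   the maximum gradient when \code{relative}).
#' @param sigma smoothing scale, pixels.
#' @param relative interpret thresholds relative to the maximum gradient.
#' @return Logical edge matrix.
#' @export
cannyEdges <- function(frame, low = 0.08, high = 0.2, sigma = 1,
                       relative = FALSE) {
  s <- EBImage::gblur(frame, sigma = sigma, boundary = "replicate")
  h <- nrow(s); w <- ncol(s)
  # central differences with replicated borders (no spurious frame edges)
  gx <- (s[, c(2:w, w)] - s[, c(1, 1:(w - 1))]) / 2
  gy <- (s[c(2:h, h), ] - s[c(1, 1:(h - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  if (relative) {
    low <- low * mmax
    high <- high * mmax
  }
  ang <- atan2(gy, gx) %% pi
  sector <- (round(ang / (pi / 4)) %% 4) + 1    # 1: E-W, 2: NE-SW, 3: N-S, 4: NW-SE
  nb <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  keep <- matrix(FALSE, nrow(frame), ncol(frame))
  for (k in 1:4) {
    sel <- sector == k
    a <- matShift(mag, nb[[k]][1], nb[[k]][2], fill = 0)
    b <- matShift(mag, -nb[[k]][1], -nb[[k]][2], fill = 0)
    keep[sel] <- (mag >= a & mag >= b)[sel]
  }
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(lab), ncol(lab))
}

#' Segment particles from a candidate mask
#'
#' Seeds are regional maxima of the Gaussian-smoothed frame that lie in
#' the Hessian candidate mask and exceed an intensity floor (the larger
#' of \code{minPeakIntensity} and median + peakSnrMin * MAD of the
#' smoothed frame). Each seed grows a region over the pixels whose
#' intensity is at least \code{refineFraction} of that seed's peak
#' intensity, stopping at Canny edge pixels; where two seeds compete,
#' pixels belong to the nearer seed, so touching blobs split at their
#' saddle, one region per intensity peak. Regions smaller than
#' \code{minAreaPx} are discarded and counted in the rejection log.
#'
#' @param frame preprocessed numeric matrix.
#' @param mask logical candidate mask from [hessianCandidateMask()].
#' @param params a [DetectionParams-class].
#' @param smoothed optional precomputed Gaussian-smoothed frame (at
#'   \code{hessianSigmaPx}), to share work with the candidate mask.
#' @return Integer label matrix (0 = background) with attribute
#'   \code{rejected} = number of regions dropped for small area.
#' @export
segmentParticles <- function(frame, mask, params = detectionParams(),
                             smoothed = NULL) {
  sm <- smoothed %||% EBImage::gblur(frame, sigma = params@hessianSigmaPx,
                                     boundary = "replicate")
  isMax <- matrix(TRUE, nrow(sm), ncol(sm))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & sm > matShift(sm, dr, dc, fill = -Inf)
  }
  floorI <- max(params@minPeakIntensity,
                median(sm) + params@peakSnrMin * mad(sm))
  seeds <- which(isMax & mask & sm >= floorI, arr.ind = TRUE)
  labels <- matrix(0L, nrow(frame), ncol(frame))
  rejected <- 0L
  if (nrow(seeds) == 0L) {
    attr(labels, "rejected") <- rejected
    return(labels)
  }
  ord <- order(frame[seeds], decreasing = TRUE)
  seeds <- seeds[ord, , drop = FALSE]
  rmax <- params@maxRadiusPx
  lab <- 0L
  for (k in seq_len(nrow(seeds))) {
    sr <- seeds[k, 1]; sc <- seeds[k, 2]
    if (labels[sr, sc] != 0L) next               # claimed by a stronger peak
    rows <- max(1, sr - rmax):min(nrow(frame), sr + rmax)
    cols <- max(1, sc - rmax):min(ncol(frame), sc + rmax)
    win <- frame[rows, cols, drop = FALSE]
    peak <- frame[sr, sc]
    # Canny on the local window only: thresholds are absolute, so this
    # matches the full-frame edge map around the growing region
    edges <- cannyEdges(win, params@cannyLow, params@cannyHigh, sigma = 1)
    ok <- win >= params@refineFraction * peak &
      !edges & labels[rows, cols] == 0L
    # competing seeds inside the window: pixels go to the nearest seed
    near <- seeds[seeds[, 1] >= rows[1] & seeds[, 1] <= rows[length(rows)] &
                    seeds[, 2] >= cols[1] & seeds[, 2] <= cols[length(cols)], ,
                  drop = FALSE]
    if (nrow(near) > 1L) {
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      d2own <- (rr - sr)^2 + (cc - sc)^2
      for (j in seq_len(nrow(near))) {
        if (near[j, 1] == sr && near[j, 2] == sc) next
        ok <- ok & (d2own <= (rr - near[j, 1])^2 + (cc - near[j, 2])^2)
      }
    }
    comp <- EBImage::bwlabel(ok)
    id <- comp[sr - rows[1] + 1L, sc - cols[1] + 1L]
    if (id == 0L) next
    sel <- comp == id
    if (sum(sel) < params@minAreaPx) {
      rejected <- rejected + 1L
      next
    }
    lab <- lab + 1L
    sub <- labels[rows, cols]
    sub[sel] <- lab
    labels[rows, cols] <- sub
  }
  attr(labels, "rejected") <- rejected
  labels
}

#' Measure particle features
#'
#' For each labeled region: intensity-weighted centroid, pixel area,
#' equivalent-circle diameter 2 * sqrt(area / pi), mean intensity
#' (brightness), and orientation of the principal axis of the
#' intensity-weighted second central moments, in (-pi/2, pi/2].
#'
#' @param frame numeric matrix.
#' @param labels integer label matrix from [segmentParticles()].
#' @return data.frame with one [ParticleObservation] row per region:
#'   x_px, y_px, brightness, area_px2, diameter_px, orientation_rad.
#' @export
measureFeatures <- function(frame, labels) {
  lin <- which(labels != 0L)
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      brightness = numeric(), area_px2 = numeric(),
                      diameter_px = numeric(), orientation_rad = numeric())
  if (!length(lin)) return(empty)
  id <- as.integer(labels[lin])
  rr <- (lin - 1L) %% nrow(labels) + 1L
  cc <- (lin - 1L) %/% nrow(labels) + 1L
  wt <- frame[lin]
  out <- lapply(split(seq_along(lin), id), function(sel) {
    w <- wt[sel]; W <- sum(w)
    x <- sum(w * cc[sel]) / W
    y <- sum(w * rr[sel]) / W
    mu20 <- sum(w * (cc[sel] - x)^2) / W
    mu02 <- sum(w * (rr[sel] - y)^2) / W
    mu11 <- sum(w * (cc[sel] - x) * (rr[sel] - y)) / W
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    if (theta <= -pi / 2) theta <- theta + pi
    if (theta > pi / 2) theta <- theta - pi
    area <- length(sel)
    data.frame(x_px = x, y_px = y, brightness = mean(w),
               area_px2 = area, diameter_px = 2 * sqrt(area / pi),
               orientation_rad = theta)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect particles in every frame of a stack
#'
#' Full detection chain: temporal-median background subtraction,
#' frame-wise saturating intensity adjustment, Hessian candidate mask,
#' seeded segmentation, feature measurement.
#'
#' @param stack an [ImageStack-class].
#' @param params a [DetectionParams-class].
#' @return data.frame of per-frame observations (frame, x_px, y_px,
#'   brightness, area_px2, diameter_px, orientation_rad) with attribute
#'   \code{rejected} = total small-region rejections.
#' @export
detectParticles <- function(stack, params = detectionParams()) {
  sub <- subtractBackground(stack, params)
  rejected <- 0L
  out <- lapply(seq_len(nFrames(sub)), function(f) {
    fr <- suppressWarnings(
      adjustIntensity(getFrame(sub, f), params@saturationFraction,
                      gainCap = 0.5))
    hc <- hessianComponents(fr, params@hessianSigmaPx)
    disc <- sqrt((hc$hxx - hc$hyy)^2 + 4 * hc$hxy^2)
    mask <- if (params@darkBlobs) (hc$hxx + hc$hyy - disc) / 2 > 0 else
      (hc$hxx + hc$hyy + disc) / 2 < 0
    mask[c(1, nrow(mask)), ] <- FALSE
    mask[, c(1, ncol(mask))] <- FALSE
    labels <- segmentParticles(fr, mask, params, smoothed = hc$smoothed)
    rejected <<- rejected + attr(labels, "rejected")
    obs <- measureFeatures(fr, labels)
    if (nrow(obs)) cbind(frame = f, obs) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      brightness = numeric(), area_px2 = numeric(),
                      diameter_px = numeric(), orientation_rad = numeric())
  attr(out, "rejected") <- rejected
  out
}
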