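# render: turn ground-truth particle paths into fluorescence image stacks,
# emulating the microscope artifacts the detector must cope with
# (photobleaching decay, uneven illumination, read and shot noise).

#' Smooth multiplicative illumination field
#'
#' Low-order polynomial field with unit mean level and a configurable
#' relative amplitude: a linear span/chord gradient plus a mild bowl term,
#' scaled so the extreme deviation equals \code{amplitude}.
#'
#' @param fovPx c(height, width) pixels.
#' @param amplitude peak relative deviation (0.2 = +/-20 percent).
#' @return A height x width matrix of multiplicative factors.
#' @export
illuminationField <- function(fovPx, amplitude = 0.2) {
  h <- fovPx[1]; w <- fovPx[2]
  yy <- (seq_len(h) - 0.5) / h - 0.5
  xx <- (seq_len(w) - 0.5) / w - 0.5
  f <- outer(yy, xx, function(y, x) x + 0.5 * y - 0.8 * (x^2 + y^2))
  if (amplitude == 0) return(matrix(1, h, w))
  1 + amplitude * f / max(abs(f))
}

# Micrometre -> pixel-center coordinates (1-based; pixel i covers
# [(i-1)*ps, i*ps) + origin, its center at (i-0.5)*ps + origin).
umToPx <- function(u, origin, pixelSize) (u - origin) / pixelSize + 0.5

#' Render a ground-truth scene to a fluorescence image stack
#'
#' Each particle becomes a 2-D Gaussian spot whose integrated intensity is
#' proportional to its volume (diameter cubed) and decays exponentially
#' with the photobleaching rate; the spot sigma combines the optical PSF
#' with the particle's geometric radius. The pre-noise image (background
#' plus spots) is multiplied by the illumination field, then Poisson shot
#' noise and Gaussian read noise are added. Deterministic under a fixed
#' seed.
#'
#' @param truth a [GroundTruth-class].
#' @param params a [RenderParams-class]; its frame rate should match the
#'   simulation's.
#' @param seed integer seed for the noise draws.
#' @return An [ImageStack-class].
#' @export
renderStack <- function(truth, params, seed = 1) {
  p <- particlePaths(truth)
  h <- params@fovPx[1]; w <- params@fovPx[2]
  nF <- nFrames(truth)
  cx <- umToPx(p$x_um, params@originUm[1], params@pixelSize)
  cy <- umToPx(p$y_um, params@originUm[2], params@pixelSize)
  bad <- which(cx < 1 | cx > w | cy < 1 | cy > h)
  if (length(bad))
    stop(sprintf("particle %d at frame %d falls outside the field of view",
                 p$particle_id[bad[1]], p$frame[bad[1]]))
  d <- if ("diameter_um" %in% names(p)) p$diameter_um else rep(6, nrow(p))
  itot <- params@brightnessPerVolume * pi / 6 * d^3 *
    exp(-params@bleachRate * (p$frame - 1))
  sig <- sqrt(params@psfSigmaPx^2 + (d / (4 * params@pixelSize))^2)
  amp <- itot / (2 * pi * sig^2)
  illum <- illuminationField(c(h, w), params@illuminationAmplitude)

  frames <- array(0, dim = c(h, w, nF))
  byFrame <- split(seq_len(nrow(p)), p$frame)
  withSeed(seed, {
    for (f in seq_len(nF)) {
      canvas <- matrix(params@background, h, w)
      for (i in byFrame[[as.character(f)]]) {
        r <- ceiling(4 * sig[i])
        rows <- max(1, floor(cy[i] - r)):min(h, ceiling(cy[i] + r))
        cols <- max(1, floor(cx[i] - r)):min(w, ceiling(cx[i] + r))
        gy <- exp(-(rows - cy[i])^2 / (2 * sig[i]^2))
        gx <- exp(-(cols - cx[i])^2 / (2 * sig[i]^2))
        canvas[rows, cols] <- canvas[rows, cols] + amp[i] * outer(gy, gx)
      }
      canvas <- canvas * illum
      if (params@shotNoise)
        canvas <- matrix(rpois(h * w, pmax(canvas, 0) *
                                 params@photonsFullScale) /
                           params@photonsFullScale, h, w)
      if (params@readNoiseSd > 0)
        canvas <- canvas + matrix(rnorm(h * w, 0, params@readNoiseSd), h, w)
      frames[, , f] <- pmax(canvas, 0)
    }
  })
  ImageStack(frames, params@frameRate, params@pixelSize)
}
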