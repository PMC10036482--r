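# Shared fixtures and independent oracles, built in code at test time.

# Render a frame of 2-D Gaussian spots without using the package renderer
# (independent fixture for the detection tests).
spotFrame <- function(h, w, centers, amp, sigma, bg = 0) {
  fr <- matrix(bg, h, w)
  for (k in seq_len(nrow(centers))) {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    fr <- fr + amp[k] *
      exp(-((rr - centers[k, 1])^2 + (cc - centers[k, 2])^2) /
            (2 * sigma[k]^2))
  }
  fr
}

# Count strict 8-neighborhood local maxima of a matrix by direct scan.
bruteLocalMaxima <- function(m, floor = 0) {
  n <- 0L
  for (r in 2:(nrow(m) - 1)) for (cc in 2:(ncol(m) - 1)) {
    v <- m[r, cc]
    if (v > floor && all(v > m[(r - 1):(r + 1), (cc - 1):(cc + 1)][-5]))
      n <- n + 1L
  }
  n
}

# Exhaustive-search optimal assignment: maximum cardinality, then minimum
# total cost, over a (possibly Inf-gated) cost matrix.
bruteAssignment <- function(cost) {
  nA <- nrow(cost); nB <- ncol(cost)
  best <- list(card = -1L, cost = Inf)
  rec <- function(i, used, cur, cnt) {
    if (i > nA) {
      if (cnt > best$card ||
          (cnt == best$card && cur < best$cost - 1e-12))
        best <<- list(card = cnt, cost = cur)
      return(invisible())
    }
    rec(i + 1L, used, cur, cnt)
    for (j in seq_len(nB)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, cur + cost[i, j], cnt + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nB), 0, 0L)
  best
}

# Observation rows in the detection schema.
makeObs <- function(frame, x, y, brightness = 0.5, area = 20,
                    diameter = 5, orientation = 0) {
  data.frame(frame = frame, x_px = x, y_px = y, brightness = brightness,
             area_px2 = area, diameter_px = diameter,
             orientation_rad = orientation)
}

# A GroundTruth object from explicit per-particle positions.
makeTruth <- function(paths, frameRate, duration) {
  methods::new("GroundTruth", paths = paths, frameRate = frameRate,
               duration = duration)
}

# Straight-line ground truth: one row per particle per frame.
linearTruth <- function(n, nFrames, x0, y0, vxUmPerFrame, frameRate = 50,
                        diameter = 6) {
  paths <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(particle_id = i, frame = seq_len(nFrames),
               x_um = x0[i] + (seq_len(nFrames) - 1) * vxUmPerFrame[i],
               y_um = y0[i], segment_id = 1L, region = "leading_edge",
               diameter_um = diameter)
  }))
  makeTruth(paths, frameRate, nFrames / frameRate)
}
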