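# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shift a matrix by (dr, dc), padding with `fill`.
matShift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Angular distance between two orientations, modulo pi (axial data).
angularDistance <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# Linear interpolation of a polyline (k x 2) at arc-length positions s.
# Positions are clamped to [0, total length].
interpPolyline <- function(pts, s) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  cs <- c(0, cumsum(seglen))
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(pts) - 1L)
  frac <- ifelse(seglen[idx] > 0, (s - cs[idx]) / seglen[idx], 0)
  pts[idx, , drop = FALSE] +
    (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]) * frac
}
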