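# Independent brute-force oracles. These deliberately re-derive results
# with plain scalar loops / enumeration, sharing no code with the package
# implementation paths they check.

# Per-voxel phantom labels from polar coordinates: slow triple loop.
# Myocardium from the analytic annulus (the contour polygons are built to
# agree with it at every voxel centre of the fixtures used).
oraclePhantomCounts <- function(spec) {
  g <- spec$gridSize
  sp <- spec$pixelSpacingMm
  cx <- (g - 1) / 2 * sp[2L] + spec$centerOffsetMm[1L]
  cy <- (g - 1) / 2 * sp[1L] + spec$centerOffsetMm[2L]
  nMyo <- nCore <- nBorder <- 0L
  for (s in seq_len(spec$nSlices)) {
    endoR <- spec$endoRadiusMm[s]
    epiR <- spec$epiRadiusMm[s]
    scarSlice <- s >= spec$scarSliceRange[1L] && s <= spec$scarSliceRange[2L]
    for (row in seq_len(g)) {
      for (col in seq_len(g)) {
        x <- (col - 1) * sp[2L]
        y <- (row - 1) * sp[1L]
        r <- sqrt((x - cx)^2 + (y - cy)^2)
        if (r < endoR || r >= epiR) next
        nMyo <- nMyo + 1L
        if (!scarSlice || spec$scarAngularExtentDeg <= 0) next
        ang <- (atan2(y - cy, x - cx) * 180 / pi) %% 360
        d <- abs(((ang - spec$scarAngularCenterDeg) %% 360))
        d <- min(d, 360 - d)
        inWedge <- spec$scarAngularExtentDeg >= 360 ||
          d < spec$scarAngularExtentDeg / 2
        if (!inWedge) next
        w <- epiR - endoR
        if (r >= endoR + spec$scarTransmurality * w) next
        if (r < endoR + (1 - spec$borderRimFraction) * spec$scarTransmurality * w)
          nCore <- nCore + 1L
        else
          nBorder <- nBorder + 1L
      }
    }
  }
  list(myo = nMyo, core = nCore, border = nBorder)
}

# AHA segment id for one voxel, re-deriving tier and sector by if-chains.
oracleSegmentLabel <- function(x, y, tier, lvCenter, rvInsertion) {
  ref <- atan2(rvInsertion[2] - lvCenter[2], rvInsertion[1] - lvCenter[1]) * 180 / pi
  ang <- atan2(y - lvCenter[2], x - lvCenter[1]) * 180 / pi
  rel <- (ang - ref) %% 360
  if (tier == "apex") return(17L)
  if (tier %in% c("basal", "mid")) {
    k <- 0L
    if (rel >= 60 && rel < 120) k <- 1L
    else if (rel >= 120 && rel < 180) k <- 2L
    else if (rel >= 180 && rel < 240) k <- 3L
    else if (rel >= 240 && rel < 300) k <- 4L
    else if (rel >= 300) k <- 5L
    return(if (tier == "basal") 1L + k else 7L + k)
  }
  # apical: 90-degree sectors centred 0/90/180/270 from the reference
  rel2 <- (rel + 45) %% 360
  k <- 0L
  if (rel2 >= 90 && rel2 < 180) k <- 1L
  else if (rel2 >= 180 && rel2 < 270) k <- 2L
  else if (rel2 >= 270) k <- 3L
  13L + k
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracleFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by exhaustive permutation of group labels.
oracleMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  uStat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u0 <- uStat(seq_len(n1))
  mu <- n1 * n2 / 2
  all <- utils::combn(n1 + n2, n1)
  us <- apply(all, 2, uStat)
  mean(abs(us - mu) >= abs(u0 - mu) - 1e-9)
}

# voxel-count volume of a polygon region on a given grid, in ml
oracleVoxelVolume <- function(poly, gridSize, spacing, thickness, nSlices = 1L) {
  cnt <- 0L
  for (row in seq_len(gridSize)) {
    for (col in seq_len(gridSize)) {
      x <- (col - 1) * spacing[2]
      y <- (row - 1) * spacing[1]
      if (sp_pointInPoly(poly, x, y)) cnt <- cnt + 1L
    }
  }
  cnt * spacing[1] * spacing[2] * thickness * nSlices / 1000
}

# scalar ray-casting point-in-polygon, written independently
sp_pointInPoly <- function(poly, x, y) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# convenience: small fast phantom spec for tests
smallSpec <- function(...) {
  args <- list(nSlices = 4L, gridSize = 48L, pixelSpacingMm = 2,
               endoRadiusMm = 16, epiRadiusMm = 26, seed = 1L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantomSpec, args)
}

# polygon approximating a circle closely (plain inscribed, many vertices)
fineCircle <- function(center, r, n = 2000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
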