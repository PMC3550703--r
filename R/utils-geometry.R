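# Planar geometry helpers shared by the phantom, contour and volumetric code.
# Coordinates are millimetres in the image plane, origin at the centre of
# pixel (0, 0), x along columns, y along rows.

#' Test points for inclusion in a closed polygon
#'
#' Thin wrapper around [mgcv::in.out()] applying the package's voxel-centre
#' convention: a point on the boundary follows mgcv's ray-crossing rule.
#'
#' @param poly two-column matrix of vertices (mm); may be open or explicitly
#'   closed (first vertex repeated last).
#' @param pts two-column matrix of query points (mm).
#' @return logical vector, one element per row of `pts`.
#' @keywords internal
.pointsInPolygon <- function(poly, pts) {
  poly <- .closePolygon(poly)
  mgcv::in.out(poly, pts)
}

# Ensure the first vertex is repeated as the last.
.closePolygon <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (!isTRUE(all.equal(poly[1L, ], poly[nrow(poly), ], check.attributes = FALSE))) {
    poly <- rbind(poly, poly[1L, ])
  }
  poly
}

#' Area of a simple polygon in mm^2
#' @keywords internal
.polygonArea <- function(poly) {
  poly <- as.matrix(poly)
  # drop an explicit closing vertex; polyarea closes implicitly
  n <- nrow(poly)
  if (n >= 2L && isTRUE(all.equal(poly[1L, ], poly[n, ], check.attributes = FALSE))) {
    poly <- poly[-n, , drop = FALSE]
  }
  abs(pracma::polyarea(poly[, 1L], poly[, 2L]))
}

# O(n^2) vectorised segment-pair crossing test. Adjacent edges share an
# endpoint and are excluded; a polygon re-touching itself at a vertex is
# still flagged. Intended for manually drawn contours (tens to a few
# hundred vertices).
.isSimplePolygon <- function(poly) {
  poly <- .closePolygon(poly)
  n <- nrow(poly) - 1L               # number of edges
  if (n < 3L) return(FALSE)
  px <- poly[, 1L]; py <- poly[, 2L]
  # non-adjacent edge pairs: j in (i+2)..n for i in 1..(n-2), minus (1, n)
  cnt <- (n - 2L):1L
  i <- rep.int(seq_len(n - 2L), cnt)
  j <- sequence(cnt) + i + 1L
  drop <- i == 1L & j == n
  if (any(drop)) { i <- i[!drop]; j <- j[!drop] }
  if (!length(i)) return(TRUE)
  e1x <- px[i + 1L] - px[i]; e1y <- py[i + 1L] - py[i]
  e2x <- px[j + 1L] - px[j]; e2y <- py[j + 1L] - py[j]
  d1 <- e1x * (py[j] - py[i]) - e1y * (px[j] - px[i])
  d2 <- e1x * (py[j + 1L] - py[i]) - e1y * (px[j + 1L] - px[i])
  d3 <- e2x * (py[i] - py[j]) - e2y * (px[i] - px[j])
  d4 <- e2x * (py[i + 1L] - py[j]) - e2y * (px[i + 1L] - px[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Regular polygon approximating a circle
#'
#' Vertices are placed at radius `r / cos(pi/n)` so every edge is tangent to
#' the circle of radius `r`: point-in-polygon at a voxel centre then matches
#' the analytic disc `dist < r` up to a sliver of width `r (sec(pi/n) - 1)`.
#'
#' @keywords internal
.circlePolygon <- function(center, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rc <- r / cos(pi / n)
  cbind(center[1L] + rc * cos(th), center[2L] + rc * sin(th))
}

# Annular-sector polygon between radii (r0, r1) over angles [a0, a1] degrees.
.sectorPolygon <- function(center, r0, r1, a0, a1, n = 64L) {
  th <- seq(a0, a1, length.out = n) * pi / 180
  outer <- cbind(center[1L] + r1 * cos(th), center[2L] + r1 * sin(th))
  inner <- cbind(center[1L] + r0 * cos(rev(th)), center[2L] + r0 * sin(rev(th)))
  rbind(outer, inner)
}

# Grid of voxel-centre coordinates (mm) for one slice: rows vary y, cols x.
# Returns list(x, y) matrices of dim (nrow, ncol).
.voxelCenters <- function(nrow, ncol, spacing) {
  y <- matrix((seq_len(nrow) - 1) * spacing[1L], nrow, ncol)
  x <- matrix(rep((seq_len(ncol) - 1) * spacing[2L], each = nrow), nrow, ncol)
  list(x = x, y = y)
}

# Evaluate an expression with a temporarily seeded RNG, restoring (or
# removing) the caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Circular absolute difference of angles in degrees, result in [0, 180].
.angDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
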