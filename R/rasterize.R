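#' Rasterize contour polygons onto a stack's voxel grid
#'
#' Converts the polygons of a [ContourSet-class] into per-voxel logical
#' masks on the grid of a [ShortAxisStack-class]. A voxel belongs to a
#' region when its centre lies inside the relevant polygon; the myocardium
#' is the set of voxel centres inside the epicardial contour and not inside
#' the endocardial contour. Slices without the requested contour contribute
#' no voxels (all `FALSE` on that slice).
#'
#' @param contours a [ContourSet-class].
#' @param stack a [ShortAxisStack-class] supplying grid size and spacing.
#' @param what `"myocardium"` (epi minus endo), `"cavity"` (inside endo),
#'   or `"roi"` (inside the hyperenhancement ROI polygon).
#' @return logical array with the stack's dimensions.
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 3, gridSize = 48,
#'                                   pixelSpacingMm = 2))
#' myo <- rasterizeMask(truthContours(ph$truth), ph$stack, "myocardium")
#' sum(myo)
#' @export
rasterizeMask <- function(contours, stack,
                          what = c("myocardium", "cavity", "roi")) {
  stopifnot(is(contours, "ContourSet"), is(stack, "ShortAxisStack"))
  what <- match.arg(what)
  d <- dim(intensities(stack))
  if (nSlices(contours) != d[3L])
    stop("contour set has ", nSlices(contours), " slices but stack has ", d[3L])
  sp <- pixelSpacing(stack)
  vc <- .voxelCenters(d[1L], d[2L], sp)
  pts <- cbind(as.vector(vc$x), as.vector(vc$y))
  out <- array(FALSE, dim = d)

  # memoise point-in-polygon per distinct polygon: phantom stacks repeat
  # the same contour on every slice
  cache <- list()
  inPoly <- function(poly) {
    key <- paste0(nrow(poly), ":", format(poly[1L, 1L], digits = 15), ":",
                  format(sum(poly), digits = 15))
    hit <- cache[[key]]
    if (!is.null(hit) && identical(attr(hit, "poly"), poly)) return(hit)
    res <- .pointsInPolygon(poly, pts)
    attr(res, "poly") <- poly
    cache[[key]] <<- res
    res
  }

  for (s in seq_len(d[3L])) {
    sl <- contours@slices[[s]]
    m <- switch(what,
      myocardium = {
        if (is.null(sl$epi)) next
        inside <- inPoly(sl$epi)
        if (!is.null(sl$endo)) inside & !inPoly(sl$endo) else inside
      },
      cavity = {
        if (is.null(sl$endo)) next
        inPoly(sl$endo)
      },
      roi = {
        if (is.null(sl$roi)) next
        inPoly(sl$roi)
      })
    out[, , s] <- matrix(m, d[1L], d[2L])
  }
  out
}
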