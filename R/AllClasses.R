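#' @import methods
NULL

#' Short-axis CE-CMR image stack
#'
#' Container for a 3-D signal-intensity volume with its slice geometry.
#' The array is indexed `[row, col, slice]`; pixel centres sit on a regular
#' grid with `pixelSpacing(x)` millimetres between rows/columns, and slices
#' are `sliceThickness(x) + sliceGap(x)` millimetres apart centre-to-centre.
#'
#' @slot intensities numeric 3-D array of signal intensities (arbitrary
#'   units), dimension `(rows, cols, slices)`.
#' @slot pixelSpacing numeric(2), in-plane spacing in mm: `(row, col)`.
#' @slot sliceThickness slice thickness in mm.
#' @slot sliceGap inter-slice gap in mm (0 for contiguous stacks).
#' @slot baseToApex logical; `TRUE` when slice 1 is the most basal.
#'
#' @seealso [ShortAxisStack()], [readStack()], [generatePhantom()]
#' @export
setClass("ShortAxisStack",
  representation(
    intensities    = "array",
    pixelSpacing   = "numeric",
    sliceThickness = "numeric",
    sliceGap       = "numeric",
    baseToApex     = "logical"
  ),
  prototype(
    pixelSpacing = c(1, 1), sliceThickness = 10, sliceGap = 0,
    baseToApex = TRUE
  )
)

setValidity("ShortAxisStack", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3L) return("intensities must be a 3-D array (rows, cols, slices)")
  if (d[3L] < 1L) return("stack needs at least one slice")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two strictly positive lengths (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    return("sliceThickness must be a single strictly positive length (mm)")
  if (length(object@sliceGap) != 1L || object@sliceGap < 0)
    return("sliceGap must be a single non-negative length (mm)")
  TRUE
})

#' Construct a ShortAxisStack
#'
#' @param intensities 3-D numeric array `(rows, cols, slices)`.
#' @param pixelSpacing numeric(2) in-plane spacing `(row, col)` in mm; a
#'   single value is recycled to both axes.
#' @param sliceThickness slice thickness, mm.
#' @param sliceGap inter-slice gap, mm.
#' @param baseToApex `TRUE` if slice 1 is basal.
#' @return A [ShortAxisStack-class] object.
#' @examples
#' stk <- ShortAxisStack(array(0, c(16, 16, 3)), pixelSpacing = 1.4)
#' nSlices(stk)
#' @export
ShortAxisStack <- function(intensities, pixelSpacing = c(1, 1),
                           sliceThickness = 10, sliceGap = 0,
                           baseToApex = TRUE) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("ShortAxisStack",
      intensities = intensities,
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      sliceGap = as.numeric(sliceGap),
      baseToApex = isTRUE(baseToApex))
}

#' Per-slice myocardial contours with anatomical landmarks
#'
#' Holds, for each short-axis slice, the closed endocardial and epicardial
#' polygons, an optional hyperenhancement region-of-interest polygon, and
#' the two landmarks the AHA 17-segment model needs: the LV centre and the
#' anterior RV insertion point. Coordinates are millimetres in the image
#' plane with the origin at the centre of pixel (0, 0), x along columns
#' and y along rows.
#'
#' @slot slices list, one element per slice; each element a list with
#'   components `endo`, `epi`, `roi` (two-column vertex matrices or `NULL`).
#' @slot lvCenter numeric(2) LV centre (mm), or `NA` when unset.
#' @slot rvInsertion numeric(2) anterior RV insertion point (mm), or `NA`.
#' @slot phase cardiac phase label, e.g. `"ED"` or `"ES"`.
#' @export
setClass("ContourSet",
  representation(
    slices      = "list",
    lvCenter    = "numeric",
    rvInsertion = "numeric",
    phase       = "character"
  ),
  prototype(lvCenter = c(NA_real_, NA_real_),
            rvInsertion = c(NA_real_, NA_real_), phase = "ED")
)

setValidity("ContourSet", function(object) {
  if (length(object@slices) < 1L) return("ContourSet needs at least one slice")
  # stacks often repeat one polygon across slices; validate each distinct
  # polygon (and endo-in-epi pair) once
  seenSimple <- list()
  seenPair <- list()
  polyKey <- function(p) paste0(nrow(p), ":", format(p[1L, 1L], digits = 15),
                                ":", format(sum(p), digits = 15))
  for (i in seq_along(object@slices)) {
    sl <- object@slices[[i]]
    if (!is.list(sl)) return(sprintf("slice %d entry is not a list", i))
    for (what in c("endo", "epi", "roi")) {
      p <- sl[[what]]
      if (is.null(p)) next
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
        return(sprintf("slice %d %s: need a two-column matrix of >= 3 vertices", i, what))
      key <- polyKey(p)
      if (!isTRUE(identical(seenSimple[[key]], p))) {
        if (!.isSimplePolygon(p))
          return(sprintf("slice %d %s: polygon is self-intersecting", i, what))
        seenSimple[[key]] <- p
      }
    }
    if (!is.null(sl$endo) && !is.null(sl$epi) &&
        !identical(sl$endo, sl$epi)) {  # coincident contours = zero wall
      key <- paste(polyKey(sl$endo), polyKey(sl$epi))
      if (!isTRUE(seenPair[[key]])) {
        if (!all(.pointsInPolygon(sl$epi, sl$endo)))
          return(sprintf("slice %d: endocardial contour not contained in epicardial contour", i))
        seenPair[[key]] <- TRUE
      }
    }
  }
  TRUE
})

#' Construct a ContourSet
#'
#' @param slices list with one element per slice, each a list carrying
#'   two-column vertex matrices `endo`, `epi` and optionally `roi`.
#' @param lvCenter,rvInsertion numeric(2) landmarks in mm (image-plane).
#' @param phase cardiac phase label.
#' @return A [ContourSet-class] object.
#' @export
ContourSet <- function(slices, lvCenter = c(NA_real_, NA_real_),
                       rvInsertion = c(NA_real_, NA_real_), phase = "ED") {
  new("ContourSet", slices = slices, lvCenter = as.numeric(lvCenter),
      rvInsertion = as.numeric(rvInsertion), phase = as.character(phase))
}

#' AHA 17-segment label volume
#'
#' Per-voxel segment labels over a myocardial mask: 0 outside the
#' myocardium, 1-6 basal, 7-12 mid-cavity, 13-16 apical, 17 apical cap.
#'
#' @slot labels integer 3-D array of segment ids (0 = non-myocardium).
#' @slot sliceTier character vector, one of `"basal"`, `"mid"`, `"apical"`,
#'   `"apex"`, `"none"` per slice.
#' @slot referenceAngle angle (degrees) of the anterior RV insertion point
#'   relative to the LV centre; angular origin for segment numbering.
#' @export
setClass("SegmentMap",
  representation(labels = "array", sliceTier = "character",
                 referenceAngle = "numeric"))

setValidity("SegmentMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  lab <- object@labels
  if (any(lab < 0L | lab > 17L)) return("segment labels must lie in 0..17")
  if (length(object@sliceTier) != dim(lab)[3L])
    return("sliceTier needs one entry per slice")
  ok <- object@sliceTier %in% c("basal", "mid", "apical", "apex", "none")
  if (!all(ok)) return("invalid slice tier label")
  TRUE
})

#' FWHM scar-zone label volume
#'
#' Per-voxel zone labels over the myocardium produced by full-width-at-
#' half-maximum thresholding: 0 = unenhanced myocardium, 1 = peri-infarct
#' (heterogeneous) zone, 2 = infarct core. Thresholds are fractions of the
#' maximal signal intensity: core at >= 50%, peri at >= 35% and < 50%.
#'
#' @slot labels integer 3-D array of zone labels (NA outside myocardium).
#' @slot maxSI maximal signal intensity used as the FWHM reference.
#' @slot thresholds named numeric(2): absolute `peri` and `core` SI cutoffs.
#' @export
setClass("ScarMap",
  representation(labels = "array", maxSI = "numeric", thresholds = "numeric"))

setValidity("ScarMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3-D array")
  v <- object@labels[!is.na(object@labels)]
  if (length(v) && any(!v %in% 0:2)) return("zone labels must be 0 (none), 1 (peri) or 2 (core)")
  if (length(object@maxSI) != 1L || object@maxSI <= 0)
    return("maxSI must be a single positive value")
  th <- object@thresholds
  if (length(th) != 2L || is.null(names(th)) ||
      !all(c("peri", "core") %in% names(th)))
    return("thresholds must be named c(peri=, core=)")
  if (th["peri"] >= th["core"]) return("peri threshold must be below core threshold")
  TRUE
})

#' Ground truth attached to a synthetic phantom
#'
#' Noiseless voxel labels and the summary quantities they imply, used to
#' validate the analysis path. Core and border (peri) masks are disjoint
#' subsets of the myocardium; `truePct` holds core/peri/total scar as a
#' percentage of myocardial voxels, and `perSegmentScarPct` the total-scar
#' percentage per AHA segment (NA for segments absent from the phantom).
#'
#' @slot myocardium,core,border logical 3-D arrays.
#' @slot truePct named numeric(3): `core`, `peri`, `total` (% of myocardium).
#' @slot perSegmentScarPct numeric(17), % scar of segmental area.
#' @slot contours [ContourSet-class] consistent with the masks.
#' @export
setClass("PhantomTruth",
  representation(myocardium = "array", core = "array", border = "array",
                 truePct = "numeric", perSegmentScarPct = "numeric",
                 contours = "ContourSet"))

setValidity("PhantomTruth", function(object) {
  if (any(object@core & object@border)) return("core and border masks overlap")
  if (any((object@core | object@border) & !object@myocardium))
    return("scar masks must be subsets of the myocardium")
  p <- object@truePct
  if (length(p) != 3L || !all(c("core", "peri", "total") %in% names(p)))
    return("truePct must be named c(core=, peri=, total=)")
  if (any(p < 0 | p > 100)) return("percentages must lie in [0, 100]")
  if (abs(p[["total"]] - p[["core"]] - p[["peri"]]) > 1e-9)
    return("total percentage must equal core + peri")
  if (length(object@perSegmentScarPct) != 17L)
    return("perSegmentScarPct must have 17 entries")
  TRUE
})
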