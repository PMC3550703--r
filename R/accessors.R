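# Accessor generics and show methods. Slots are never reached into by user
# code; these are the supported surface.

#' @rdname ShortAxisStack-class
#' @param x,object a package object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname ShortAxisStack-class
#' @export
setMethod("intensities", "ShortAxisStack", function(x) x@intensities)

#' @rdname ShortAxisStack-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname ShortAxisStack-class
#' @export
setMethod("pixelSpacing", "ShortAxisStack", function(x) x@pixelSpacing)

#' @rdname ShortAxisStack-class
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname ShortAxisStack-class
#' @export
setMethod("sliceThickness", "ShortAxisStack", function(x) x@sliceThickness)

#' @rdname ShortAxisStack-class
#' @export
setGeneric("sliceGap", function(x) standardGeneric("sliceGap"))
#' @rdname ShortAxisStack-class
#' @export
setMethod("sliceGap", "ShortAxisStack", function(x) x@sliceGap)

#' @rdname ShortAxisStack-class
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname ShortAxisStack-class
#' @export
setMethod("nSlices", "ShortAxisStack", function(x) dim(x@intensities)[3L])
#' @rdname ContourSet-class
#' @export
setMethod("nSlices", "ContourSet", function(x) length(x@slices))

#' @rdname ContourSet-class
#' @param x a `ContourSet`.
#' @param slice slice index.
#' @param what one of `"endo"`, `"epi"`, `"roi"`.
#' @export
contourPolygon <- function(x, slice, what = c("endo", "epi", "roi")) {
  stopifnot(is(x, "ContourSet"))
  what <- match.arg(what)
  x@slices[[slice]][[what]]
}

#' @rdname ContourSet-class
#' @export
landmarks <- function(x) {
  stopifnot(is(x, "ContourSet"))
  list(lvCenter = x@lvCenter, rvInsertion = x@rvInsertion)
}

#' @rdname SegmentMap-class
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))
#' @rdname SegmentMap-class
#' @export
setMethod("segmentLabels", "SegmentMap", function(x) x@labels)

#' @rdname SegmentMap-class
#' @export
sliceTiers <- function(x) {
  stopifnot(is(x, "SegmentMap"))
  x@sliceTier
}

#' @rdname ScarMap-class
#' @export
setGeneric("zoneLabels", function(x) standardGeneric("zoneLabels"))
#' @rdname ScarMap-class
#' @export
setMethod("zoneLabels", "ScarMap", function(x) x@labels)

#' @rdname ScarMap-class
#' @export
maxSI <- function(x) {
  stopifnot(is(x, "ScarMap"))
  x@maxSI
}

#' @rdname ScarMap-class
#' @export
scarThresholds <- function(x) {
  stopifnot(is(x, "ScarMap"))
  x@thresholds
}

#' @rdname PhantomTruth-class
#' @export
truthMask <- function(x, which = c("myocardium", "core", "border")) {
  stopifnot(is(x, "PhantomTruth"))
  which <- match.arg(which)
  slot(x, which)
}

#' @rdname PhantomTruth-class
#' @export
truePercentages <- function(x) {
  stopifnot(is(x, "PhantomTruth"))
  x@truePct
}

#' @rdname PhantomTruth-class
#' @export
truthContours <- function(x) {
  stopifnot(is(x, "PhantomTruth"))
  x@contours
}

#' @rdname PhantomTruth-class
#' @export
truthSegmentScarPct <- function(x) {
  stopifnot(is(x, "PhantomTruth"))
  x@perSegmentScarPct
}

setMethod("show", "ShortAxisStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ShortAxisStack: %d x %d pixels, %d slice(s)\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  pixel spacing %.3g x %.3g mm, thickness %.3g mm, gap %.3g mm\n",
              object@pixelSpacing[1L], object@pixelSpacing[2L],
              object@sliceThickness, object@sliceGap))
  cat(sprintf("  slice order: %s\n",
              if (object@baseToApex) "base -> apex" else "apex -> base"))
})

setMethod("show", "ContourSet", function(object) {
  n <- length(object@slices)
  has <- function(w) sum(vapply(object@slices, function(s) !is.null(s[[w]]), TRUE))
  cat(sprintf("ContourSet: %d slice(s), phase %s\n", n, object@phase))
  cat(sprintf("  endo on %d, epi on %d, ROI on %d slice(s)\n",
              has("endo"), has("epi"), has("roi")))
  if (!anyNA(object@lvCenter))
    cat(sprintf("  LV centre (%.1f, %.1f) mm; RV insertion %s\n",
                object@lvCenter[1L], object@lvCenter[2L],
                if (anyNA(object@rvInsertion)) "unset"
                else sprintf("(%.1f, %.1f) mm", object@rvInsertion[1L],
                             object@rvInsertion[2L])))
})

setMethod("show", "SegmentMap", function(object) {
  segs <- sort(unique(as.vector(object@labels[object@labels > 0L])))
  cat(sprintf("SegmentMap: %d of 17 AHA segments present\n", length(segs)))
  cat("  tiers:", paste(object@sliceTier, collapse = " "), "\n")
})

setMethod("show", "ScarMap", function(object) {
  v <- object@labels[!is.na(object@labels)]
  cat(sprintf("ScarMap (FWHM): max SI %.4g; thresholds peri %.4g, core %.4g\n",
              object@maxSI, object@thresholds[["peri"]],
              object@thresholds[["core"]]))
  cat(sprintf("  myocardial voxels %d: core %d, peri %d, unenhanced %d\n",
              length(v), sum(v == 2L), sum(v == 1L), sum(v == 0L)))
})

setMethod("show", "PhantomTruth", function(object) {
  p <- object@truePct
  cat(sprintf("PhantomTruth: core %.2f%%, peri %.2f%%, total %.2f%% of myocardium\n",
              p[["core"]], p[["peri"]], p[["total"]]))
})
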