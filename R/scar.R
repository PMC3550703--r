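# FWHM scar quantification: the core/peri-infarct thresholding rule.
# Infarct core: myocardium with SI >= 50% of the maximal signal intensity.
# Heterogeneous (peri-infarct) zone: SI >= 35% and < 50% of maximal SI.
# Total scar = core + peri.

#' Maximal signal intensity within the hyperenhancement ROI
#'
#' The FWHM reference intensity: the maximum signal intensity over the
#' intersection of the hyperenhancement region of interest with the
#' myocardium. By default the single brightest voxel is used, over the
#' full stack (one reference per study); `topK > 1` averages the `topK`
#' brightest voxels, a robust variant that damps the upward bias of the
#' sample maximum under noise. `perSlice = TRUE` returns one reference per
#' slice instead.
#'
#' If the drawn ROI misses the brightest myocardial voxel, the maximum
#' over what it does cover is returned — the ROI is authoritative.
#'
#' @param stack a [ShortAxisStack-class].
#' @param myocardium logical array, the myocardial mask.
#' @param roi logical array, the hyperenhancement ROI mask.
#' @param topK number of brightest voxels averaged (1 = plain maximum).
#' @param perSlice compute a per-slice reference instead of a global one.
#' @return numeric scalar (or per-slice vector when `perSlice = TRUE`).
#' @export
maxSignalIntensity <- function(stack, myocardium, roi, topK = 1L,
                               perSlice = FALSE) {
  stopifnot(is(stack, "ShortAxisStack"))
  vol <- intensities(stack)
  if (!identical(dim(vol), dim(myocardium)) || !identical(dim(vol), dim(roi)))
    stop("alignment error: stack, myocardium and ROI grids differ")
  sel <- myocardium & roi
  if (!any(sel)) stop("ROI error: region of interest does not intersect the myocardium")
  top <- function(v) {
    if (topK <= 1L) max(v) else mean(sort(v, decreasing = TRUE)[seq_len(min(topK, length(v)))])
  }
  if (!perSlice) return(top(vol[sel]))
  vapply(seq_len(dim(vol)[3L]), function(s) {
    v <- vol[, , s][sel[, , s]]
    if (length(v)) top(v) else NA_real_
  }, numeric(1))
}

#' Classify myocardial voxels into FWHM scar zones
#'
#' Labels every myocardial voxel by the two fixed fractions of the maximal
#' signal intensity: core where SI >= 50% of `maxSI` (inclusive), peri
#' where 35% <= SI < 50%, and unenhanced below 35%. Voxels outside the
#' myocardium are `NA`.
#'
#' @param stack a [ShortAxisStack-class].
#' @param myocardium logical myocardial mask on the stack's grid.
#' @param maxSI maximal signal intensity (from [maxSignalIntensity()]).
#' @param coreFraction,periFraction threshold fractions of `maxSI`;
#'   defaults 0.50 and 0.35.
#' @return a [ScarMap-class].
#' @export
classifyZones <- function(stack, myocardium, maxSI,
                          coreFraction = 0.5, periFraction = 0.35) {
  stopifnot(is(stack, "ShortAxisStack"))
  vol <- intensities(stack)
  if (!identical(dim(vol), dim(myocardium)))
    stop("alignment error: stack and myocardium grids differ")
  if (!is.numeric(maxSI) || length(maxSI) != 1L || maxSI <= 0)
    stop("threshold error: maxSI must be a single positive intensity")
  if (periFraction >= coreFraction)
    stop("threshold error: periFraction must be below coreFraction")
  thCore <- coreFraction * maxSI
  thPeri <- periFraction * maxSI
  lab <- array(NA_integer_, dim(vol))
  v <- vol[myocardium]
  lab[myocardium] <- ifelse(v >= thCore, 2L, ifelse(v >= thPeri, 1L, 0L))
  new("ScarMap", labels = lab, maxSI = maxSI,
      thresholds = c(peri = thPeri, core = thCore))
}

#' Core, peri-infarct and total scar as percentages of the myocardium
#'
#' Voxel-counting summary of a [ScarMap-class]: each zone's voxel count as
#' a percentage of the LV myocardial voxel count; total = core + peri by
#' construction.
#'
#' @param scarMap a [ScarMap-class].
#' @param myocardium logical myocardial mask (the denominator). Defaults
#'   to the non-`NA` support of the scar map.
#' @return named numeric: `core`, `peri`, `total` (percent).
#' @export
zoneFractions <- function(scarMap, myocardium = NULL) {
  stopifnot(is(scarMap, "ScarMap"))
  lab <- zoneLabels(scarMap)
  if (is.null(myocardium)) myocardium <- !is.na(lab)
  nMyo <- sum(myocardium)
  if (nMyo == 0L) stop("domain error: empty myocardium")
  v <- lab[myocardium]
  c(core = 100 * sum(v == 2L, na.rm = TRUE) / nMyo,
    peri = 100 * sum(v == 1L, na.rm = TRUE) / nMyo,
    total = 100 * sum(v >= 1L, na.rm = TRUE) / nMyo)
}

#' Full FWHM characterization from a stack and its contours
#'
#' Convenience pipeline: rasterizes the myocardium and hyperenhancement
#' ROI from the contours, determines the maximal signal intensity,
#' classifies zones and summarizes them. Slices without an ROI polygon
#' contribute myocardium to the denominator only.
#'
#' @param stack a [ShortAxisStack-class].
#' @param contours a [ContourSet-class] with endo/epi polygons and at
#'   least one ROI polygon.
#' @inheritParams maxSignalIntensity
#' @inheritParams classifyZones
#' @return list: `scarMap` ([ScarMap-class]), `fractions` (named numeric),
#'   `myocardium` (logical array).
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 4, gridSize = 64,
#'                                   pixelSpacingMm = 2, noiseSd = 0))
#' res <- characterizeScar(ph$stack, truthContours(ph$truth))
#' all.equal(res$fractions, truePercentages(ph$truth))
#' @export
characterizeScar <- function(stack, contours, topK = 1L,
                             coreFraction = 0.5, periFraction = 0.35) {
  myo <- rasterizeMask(contours, stack, "myocardium")
  roi <- rasterizeMask(contours, stack, "roi")
  msi <- maxSignalIntensity(stack, myo, roi, topK = topK)
  sm <- classifyZones(stack, myo, msi, coreFraction = coreFraction,
                      periFraction = periFraction)
  list(scarMap = sm, fractions = zoneFractions(sm, myo), myocardium = myo)
}
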