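# Ordinal scoring layer: segmental scar percentages -> scar scores (0-4),
# transmural extent, coronary-territory means, and the wall motion score
# index.

#' Percent scar per AHA segment
#'
#' For each of the 17 segments present in the segment map, the percentage
#' of its voxels carrying scar (total scar: core plus peri-infarct zone).
#' Segments absent from the map are returned as `NA` (unobserved).
#'
#' @param scar a [ScarMap-class], or a logical array marking scar voxels.
#' @param segmentMap a [SegmentMap-class] on the same voxel grid.
#' @return numeric(17); `NA` for unobserved segments.
#' @export
segmentScarPct <- function(scar, segmentMap) {
  stopifnot(is(segmentMap, "SegmentMap"))
  seg <- segmentLabels(segmentMap)
  scarMask <- if (is(scar, "ScarMap")) {
    lab <- zoneLabels(scar)
    !is.na(lab) & lab >= 1L
  } else if (is.logical(scar) || (is.array(scar) && is.logical(as.vector(scar)))) {
    scar
  } else {
    stop("scar must be a ScarMap or a logical array")
  }
  if (!identical(dim(seg), dim(scarMask)))
    stop("alignment error: scar and segment maps are on different grids")
  out <- rep(NA_real_, 17L)
  segVec <- as.vector(seg)
  scarVec <- as.vector(scarMask)
  counts <- tabulate(segVec[segVec > 0L], nbins = 17L)
  scarCounts <- tabulate(segVec[segVec > 0L & scarVec], nbins = 17L)
  present <- counts > 0L
  out[present] <- 100 * scarCounts[present] / counts[present]
  out
}

#' Ordinal scar score from percent segmental scar
#'
#' Bins a segmental scar percentage into the five-point score: 0 = no
#' scar, 1 = 1-25%, 2 = 26-50%, 3 = 51-75%, 4 = 76-100% of the segmental
#' area. The printed integer bins are applied as the half-open continuous
#' partition (0, 25], (25, 50], (50, 75], (75, 100], with exactly 0
#' mapping to score 0.
#'
#' @param pct numeric vector of percentages in [0, 100]; `NA` passes
#'   through (unobserved segment).
#' @return integer vector of scores 0-4 (`NA` preserved).
#' @examples
#' scarScore(c(0, 10, 25, 25.4, 50, 75, 100))
#' @export
scarScore <- function(pct) {
  bad <- !is.na(pct) & (pct < 0 | pct > 100)
  if (any(bad)) stop("domain error: scar percentages must lie in [0, 100]")
  out <- rep(NA_integer_, length(pct))
  ok <- !is.na(pct)
  p <- pct[ok]
  out[ok] <- ifelse(p == 0, 0L,
              ifelse(p <= 25, 1L,
               ifelse(p <= 50, 2L,
                ifelse(p <= 75, 3L, 4L))))
  out
}

#' Transmural extent of scar
#'
#' The number of observed segments with a scar score of 3 or 4 (i.e. more
#' than half of the segmental area scarred).
#'
#' @param scores integer vector of scar scores 0-4; `NA` = unobserved.
#' @return integer count.
#' @export
transmuralExtent <- function(scores) {
  ok <- !is.na(scores)
  if (any(!scores[ok] %in% 0:4)) stop("scar scores must lie in 0..4")
  sum(scores[ok] >= 3L)
}

#' Regional scar scores per coronary territory
#'
#' Unweighted arithmetic mean of the segmental scar scores over each
#' coronary territory's observed segments; relates scar burden to the
#' LAD, RCA and LCX perfusion beds. A territory with no observed segment
#' yields `NA` with a warning.
#'
#' @param scores numeric(17) scar scores; `NA` = unobserved.
#' @param territories a territory map from [defaultTerritories()].
#' @return named numeric(3): `LAD`, `RCA`, `LCX`.
#' @export
regionalScores <- function(scores, territories = defaultTerritories()) {
  if (length(scores) != 17L) stop("need one score per AHA segment (17)")
  out <- vapply(territories, function(segs) {
    v <- scores[segs]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(out))
    warning("territory with no observed segments: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Wall motion score index
#'
#' Mean of the per-segment wall-motion grades over the observed segments:
#' 0 normal, 1 hypokinesia, 2 severe hypokinesia, 3 akinesia,
#' 4 dyskinesia. Unobserved segments must be `NA`, not 0 — the index
#' divides by the number of observed segments.
#'
#' @param motionScores numeric(17) wall-motion grades; `NA` = unobserved.
#' @return numeric scalar in [0, 4].
#' @examples
#' wmsi(c(rep(2, 10), rep(1, 4), NA, NA, NA))  # 24 / 14
#' @export
wmsi <- function(motionScores) {
  if (length(motionScores) != 17L) stop("need one grade per AHA segment (17)")
  ok <- !is.na(motionScores)
  if (!any(ok)) stop("domain error: no observed segments")
  if (any(!motionScores[ok] %in% 0:4))
    stop("domain error: wall-motion grades must lie in 0..4")
  sum(motionScores[ok]) / sum(ok)
}
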