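#' Assign AHA 17-segment labels to a myocardial mask
#'
#' Implements the standardized 17-segment model of the left ventricle.
#' Slices containing myocardium are split base-to-apex into basal, mid and
#' apical tiers of (as near as possible) equal slice counts, extra slices
#' going basal-ward. Basal and mid tiers carry six 60-degree sectors
#' (segments 1-6 and 7-12), the apical tier four 90-degree sectors
#' (13-16) rotated so sector centres fall on the anterior, septal,
#' inferior and lateral walls. Slices flagged as having a closed cavity
#' (true apex) are labelled apical cap (17) in full; when no such slice
#' exists the cap is absent — common in phantoms, whose annulus never
#' closes.
#'
#' The angular origin is the ray from the LV centre to the anterior RV
#' insertion point; sector index increases with the in-plane angle
#' `atan2(y - cy, x - cx)` measured from that ray, so segment 1 (basal
#' anterior) spans the first 60 degrees from the insertion. Rotating the
#' image and both landmarks together leaves the labels unchanged.
#'
#' @param myocardium logical 3-D array, `TRUE` on myocardial voxels,
#'   slices ordered base to apex.
#' @param lvCenter numeric(2) LV centre in mm (image plane).
#' @param rvInsertion numeric(2) anterior RV insertion point in mm.
#' @param pixelSpacing numeric(2) in-plane spacing `(row, col)` in mm.
#' @param cavityClosed logical vector, one per slice: `TRUE` where the LV
#'   cavity has closed (apex cap). Default: no cap.
#' @return a [SegmentMap-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 6, gridSize = 48,
#'                                   pixelSpacingMm = 2.8,
#'                                   endoRadiusMm = 18, epiRadiusMm = 28))
#' lm <- landmarks(truthContours(ph$truth))
#' sm <- assignSegments(truthMask(ph$truth), lm$lvCenter, lm$rvInsertion,
#'                      pixelSpacing = pixelSpacing(ph$stack))
#' table(sliceTiers(sm))
#' @export
assignSegments <- function(myocardium, lvCenter, rvInsertion, pixelSpacing,
                           cavityClosed = NULL) {
  d <- dim(myocardium)
  if (length(d) != 3L) stop("myocardium must be a 3-D logical array")
  if (anyNA(lvCenter) || length(lvCenter) != 2L)
    stop("landmark error: LV centre is required")
  if (anyNA(rvInsertion) || length(rvInsertion) != 2L)
    stop("landmark error: RV insertion point is required")
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  if (is.null(cavityClosed)) cavityClosed <- rep(FALSE, d[3L])
  stopifnot(length(cavityClosed) == d[3L])

  labels <- array(0L, d)
  refAngle <- (atan2(rvInsertion[2L] - lvCenter[2L],
                     rvInsertion[1L] - lvCenter[1L]) * 180 / pi) %% 360

  sliceHasMyo <- apply(myocardium, 3L, any)
  tier <- rep("none", d[3L])
  if (!any(sliceHasMyo)) {
    return(new("SegmentMap", labels = labels, sliceTier = tier,
               referenceAngle = refAngle))
  }

  capSlices <- which(sliceHasMyo & cavityClosed)
  bodySlices <- which(sliceHasMyo & !cavityClosed)
  tier[capSlices] <- "apex"
  if (length(bodySlices)) {
    nb <- ceiling(length(bodySlices) / 3)
    nm <- ceiling((length(bodySlices) - nb) / 2)
    na_ <- length(bodySlices) - nb - nm
    tier[bodySlices] <- rep(c("basal", "mid", "apical"), times = c(nb, nm, na_))
  }

  vc <- .voxelCenters(d[1L], d[2L], pixelSpacing)
  dx <- as.vector(vc$x) - lvCenter[1L]
  dy <- as.vector(vc$y) - lvCenter[2L]
  relAngle <- ((atan2(dy, dx) * 180 / pi) - refAngle) %% 360

  sector6 <- 1L + pmin(5L, as.integer(relAngle %/% 60))
  sector4 <- 1L + pmin(3L, as.integer(((relAngle + 45) %% 360) %/% 90))

  for (s in seq_len(d[3L])) {
    if (tier[s] == "none") next
    m <- as.vector(myocardium[, , s])
    lab <- integer(d[1L] * d[2L])
    lab[m] <- switch(tier[s],
      basal  = sector6[m],
      mid    = 6L + sector6[m],
      apical = 12L + sector4[m],
      apex   = 17L)
    labels[, , s] <- lab
  }
  new("SegmentMap", labels = labels, sliceTier = tier,
      referenceAngle = refAngle)
}

#' Coronary-territory map over the 17 AHA segments
#'
#' Returns the conventional assignment of segments to the three major
#' coronary arteries: LAD (left anterior descending) 1, 2, 7, 8, 13, 14,
#' 17; RCA (right coronary artery) 3, 4, 9, 10, 15; LCX (left circumflex)
#' 5, 6, 11, 12, 16. Institutional variants can be supplied instead; any
#' custom map must partition 1..17.
#'
#' @param lad,rca,lcx integer vectors of segment ids overriding the
#'   defaults.
#' @return named list of three integer vectors, class `territoryMap`.
#' @examples
#' sort(unlist(defaultTerritories()))
#' @export
defaultTerritories <- function(lad = c(1, 2, 7, 8, 13, 14, 17),
                               rca = c(3, 4, 9, 10, 15),
                               lcx = c(5, 6, 11, 12, 16)) {
  tm <- list(LAD = as.integer(sort(lad)), RCA = as.integer(sort(rca)),
             LCX = as.integer(sort(lcx)))
  all_ <- unlist(tm, use.names = FALSE)
  if (length(all_) != 17L || anyDuplicated(all_) ||
      !setequal(all_, 1:17))
    stop("territory partition error: LAD/RCA/LCX must partition segments 1..17")
  class(tm) <- "territoryMap"
  tm
}
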