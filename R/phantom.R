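#' Specify a synthetic short-axis CE-CMR phantom
#'
#' Builds the parameter set for [generatePhantom()]: an annular myocardium
#' (endocardial/epicardial circles) around a bright blood pool, with an
#' angular scar wedge made of a hyperenhanced core plateau and an
#' intermediate-intensity border rim, dark remote myocardium, and additive
#' Gaussian noise. Defaults emulate a dilated post-infarction ventricle on
#' a clinical late-gadolinium-enhancement protocol: 10 mm slices, ~1.4 mm
#' in-plane pixels, a 90 degree wedge at 60% transmurality.
#'
#' Signal plateaus default to core 100, border 42.5, remote 15, blood 70
#' (arbitrary units). The border level sits mid-way inside the 35-50%
#' FWHM band and remote myocardium well below 35%, so the thresholding
#' rule can recover the zones exactly on noiseless data. `noiseSd = 2`
#' gives a core-to-remote contrast-to-noise ratio of ~42, typical of a
#' diagnostic-quality LGE acquisition.
#'
#' @param nSlices number of short-axis slices.
#' @param sliceThicknessMm slice thickness, mm.
#' @param sliceGapMm inter-slice gap, mm.
#' @param pixelSpacingMm in-plane pixel spacing, mm (scalar or length 2,
#'   `(row, col)`).
#' @param gridSize pixels per image side.
#' @param endoRadiusMm,epiRadiusMm endocardial/epicardial radii, mm; scalars
#'   or per-slice vectors. `endo < epi` required on every slice.
#' @param scarAngularCenterDeg,scarAngularExtentDeg centre and full angular
#'   width of the scar wedge, degrees; extent 0 places no scar, extent
#'   >= 360 wraps the full circumference.
#' @param scarTransmurality fraction (0-1) of the wall thickness, measured
#'   from the endocardium, occupied by scar.
#' @param scarSliceRange integer two-vector, first and last slice carrying
#'   scar.
#' @param borderRimFraction fraction (0-1) of the scar's radial thickness,
#'   at its outer margin, assigned the intermediate border intensity.
#' @param siRemote,siCore,siBorder,siBlood signal-intensity plateaus
#'   (arbitrary units); `siRemote < siBorder < siCore` required, and blood
#'   above remote so that undisciplined ROIs are detectably wrong.
#' @param noiseSd standard deviation of additive Gaussian noise (SI units).
#' @param noiseModel `"gaussian"` (default) or `"rician"`.
#' @param centerOffsetMm in-plane offset of the LV centre from the grid
#'   centre, mm `(x, y)`.
#' @param rvInsertionAngleDeg angle of the anterior RV insertion landmark
#'   relative to the LV centre, degrees.
#' @param nVertices vertices per contour polygon.
#' @param seed integer seed making the noise reproducible.
#' @return a `phantomSpec` list, validated.
#' @seealso [generatePhantom()], [phantomCohort()]
#' @export
phantomSpec <- function(nSlices = 10L,
                        sliceThicknessMm = 10,
                        sliceGapMm = 0,
                        pixelSpacingMm = 1.4,
                        gridSize = 96L,
                        endoRadiusMm = 22,
                        epiRadiusMm = 32,
                        scarAngularCenterDeg = 0,
                        scarAngularExtentDeg = 90,
                        scarTransmurality = 0.6,
                        scarSliceRange = NULL,
                        borderRimFraction = 0.3,
                        siRemote = 15,
                        siCore = 100,
                        siBorder = 42.5,
                        siBlood = 70,
                        noiseSd = 2,
                        noiseModel = c("gaussian", "rician"),
                        centerOffsetMm = c(0, 0),
                        rvInsertionAngleDeg = 90,
                        nVertices = 256L,
                        seed = 1L) {
  if (length(pixelSpacingMm) == 1L) pixelSpacingMm <- rep(pixelSpacingMm, 2L)
  nSlices <- as.integer(nSlices)
  if (is.null(scarSliceRange))
    scarSliceRange <- c(max(1L, floor(nSlices * 0.25)), ceiling(nSlices * 0.75))
  endoRadiusMm <- rep_len(endoRadiusMm, nSlices)
  epiRadiusMm <- rep_len(epiRadiusMm, nSlices)
  spec <- list(
    nSlices = nSlices, sliceThicknessMm = sliceThicknessMm,
    sliceGapMm = sliceGapMm, pixelSpacingMm = pixelSpacingMm,
    gridSize = as.integer(gridSize),
    endoRadiusMm = endoRadiusMm, epiRadiusMm = epiRadiusMm,
    scarAngularCenterDeg = scarAngularCenterDeg %% 360,
    scarAngularExtentDeg = scarAngularExtentDeg,
    scarTransmurality = scarTransmurality,
    scarSliceRange = as.integer(scarSliceRange),
    borderRimFraction = borderRimFraction,
    siRemote = siRemote, siCore = siCore, siBorder = siBorder,
    siBlood = siBlood, noiseSd = noiseSd,
    noiseModel = match.arg(noiseModel),
    centerOffsetMm = centerOffsetMm,
    rvInsertionAngleDeg = rvInsertionAngleDeg %% 360,
    nVertices = as.integer(nVertices),
    seed = as.integer(seed))
  .validatePhantomSpec(spec)
  class(spec) <- "phantomSpec"
  spec
}

.validatePhantomSpec <- function(s) {
  if (s$nSlices < 1L) stop("phantom geometry error: need at least one slice")
  if (any(s$epiRadiusMm <= s$endoRadiusMm))
    stop("phantom geometry error: epicardial radius must exceed endocardial radius on every slice")
  if (s$scarTransmurality < 0 || s$scarTransmurality > 1)
    stop("scarTransmurality must lie in [0, 1]")
  if (s$borderRimFraction < 0 || s$borderRimFraction > 1)
    stop("borderRimFraction must lie in [0, 1]")
  if (s$scarAngularExtentDeg < 0) stop("scarAngularExtentDeg must be >= 0")
  if (!(s$siRemote < s$siBorder && s$siBorder < s$siCore))
    stop("signal plateaus must satisfy siRemote < siBorder < siCore")
  if (s$siBlood <= s$siRemote) stop("siBlood must exceed siRemote")
  if (s$noiseSd < 0) stop("noiseSd must be >= 0")
  half <- (s$gridSize - 1) / 2 * min(s$pixelSpacingMm)
  if (max(s$epiRadiusMm) + max(abs(s$centerOffsetMm)) >= half)
    stop("phantom geometry error: grid too small to contain the epicardial contour")
  if (s$scarSliceRange[1L] < 1L || s$scarSliceRange[2L] > s$nSlices ||
      s$scarSliceRange[1L] > s$scarSliceRange[2L])
    stop("scarSliceRange must be an increasing interval within 1..nSlices")
  invisible(TRUE)
}

#' Generate a synthetic short-axis stack with known ground truth
#'
#' Realizes the geometry described by a [phantomSpec()]: the myocardium is
#' the set of voxel centres inside the epicardial and outside the
#' endocardial contour polygon; within it, scar occupies an angular wedge
#' from the endocardium out to `scarTransmurality` of the wall, split
#' radially into a core plateau and an outer border rim carrying the
#' intermediate intensity. The returned truth holds the noiseless label
#' masks, zone percentages by voxel counting, per-AHA-segment scar
#' percentages, and a [ContourSet-class] (endo/epi on every slice, a
#' hyperenhancement ROI on scar-bearing slices) consistent with the masks.
#'
#' The same seed yields a bit-identical stack. Noise is added to the
#' intensity volume only; the truth is noiseless by construction.
#'
#' @param spec a [phantomSpec()].
#' @return list with components `stack` ([ShortAxisStack-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 4, gridSize = 64,
#'                                   pixelSpacingMm = 2, seed = 7))
#' truePercentages(ph$truth)
#' @export
generatePhantom <- function(spec) {
  if (!inherits(spec, "phantomSpec")) spec <- do.call(phantomSpec, spec)
  .validatePhantomSpec(spec)
  g <- spec$gridSize
  n <- spec$nSlices
  sp <- spec$pixelSpacingMm
  center <- c((g - 1) / 2 * sp[2L], (g - 1) / 2 * sp[1L]) + spec$centerOffsetMm

  vc <- .voxelCenters(g, g, sp)
  dx <- as.vector(vc$x) - center[1L]
  dy <- as.vector(vc$y) - center[2L]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  fullWedge <- spec$scarAngularExtentDeg >= 360
  inWedge <- if (spec$scarAngularExtentDeg <= 0) {
    rep(FALSE, length(r))
  } else if (fullWedge) {
    rep(TRUE, length(r))
  } else {
    .angDiff(theta, spec$scarAngularCenterDeg) < spec$scarAngularExtentDeg / 2
  }

  dims <- c(g, g, n)
  vol <- array(0, dims)
  myo <- array(FALSE, dims)
  coreM <- array(FALSE, dims)
  bordM <- array(FALSE, dims)
  slices <- vector("list", n)

  # per-slice polygons; rasterization reused across slices with equal radii
  rasterCache <- list()
  insideCircle <- function(rad) {
    key <- format(rad, digits = 15)
    hit <- rasterCache[[key]]
    if (!is.null(hit)) return(hit)
    poly <- .circlePolygon(center, rad, spec$nVertices)
    res <- list(poly = poly,
                inside = .pointsInPolygon(poly, cbind(as.vector(vc$x),
                                                      as.vector(vc$y))))
    rasterCache[[key]] <<- res
    res
  }

  scarSlices <- seq(spec$scarSliceRange[1L], spec$scarSliceRange[2L])
  hasScar <- spec$scarAngularExtentDeg > 0

  for (s in seq_len(n)) {
    endoR <- spec$endoRadiusMm[s]
    epiR <- spec$epiRadiusMm[s]
    endo <- insideCircle(endoR)
    epi <- insideCircle(epiR)
    myoS <- epi$inside & !endo$inside
    bloodS <- endo$inside

    img <- numeric(g * g)
    img[bloodS] <- spec$siBlood
    img[myoS] <- spec$siRemote

    coreS <- bordS <- rep(FALSE, g * g)
    if (hasScar && s %in% scarSlices) {
      w <- epiR - endoR
      scarOuter <- endoR + spec$scarTransmurality * w
      coreOuter <- endoR + (1 - spec$borderRimFraction) *
        spec$scarTransmurality * w
      scarS <- myoS & inWedge & (r < scarOuter)
      coreS <- scarS & (r < coreOuter)
      bordS <- scarS & !coreS
      img[coreS] <- spec$siCore
      img[bordS] <- spec$siBorder
    }

    vol[, , s] <- img
    myo[, , s] <- myoS
    coreM[, , s] <- coreS
    bordM[, , s] <- bordS

    roi <- NULL
    if (hasScar && s %in% scarSlices) {
      roi <- if (fullWedge) {
        .circlePolygon(center, epiR + 2, spec$nVertices)
      } else {
        a0 <- spec$scarAngularCenterDeg - spec$scarAngularExtentDeg / 2 - 5
        a1 <- spec$scarAngularCenterDeg + spec$scarAngularExtentDeg / 2 + 5
        .sectorPolygon(center, endoR * 0.5, epiR + 2, a0, a1)
      }
    }
    slices[[s]] <- list(endo = endo$poly, epi = epi$poly, roi = roi)
  }

  if (spec$noiseSd > 0) {
    vol <- .withSeed(spec$seed, {
      eps <- array(stats::rnorm(length(vol), 0, spec$noiseSd), dims)
      if (spec$noiseModel == "rician") {
        eps2 <- array(stats::rnorm(length(vol), 0, spec$noiseSd), dims)
        sqrt((vol + eps)^2 + eps2^2)
      } else {
        vol + eps
      }
    })
  }

  rvAngle <- spec$rvInsertionAngleDeg * pi / 180
  rvPoint <- center + mean(spec$epiRadiusMm) * 1.1 * c(cos(rvAngle), sin(rvAngle))
  contours <- ContourSet(slices, lvCenter = center, rvInsertion = rvPoint,
                         phase = "CE")

  nMyo <- sum(myo)
  pct <- c(core = 100 * sum(coreM) / nMyo,
           peri = 100 * sum(bordM) / nMyo,
           total = 100 * sum(coreM | bordM) / nMyo)

  segMap <- assignSegments(myo, lvCenter = center, rvInsertion = rvPoint,
                           pixelSpacing = sp)
  segPct <- segmentScarPct(coreM | bordM, segMap)

  stack <- ShortAxisStack(vol, pixelSpacing = sp,
                          sliceThickness = spec$sliceThicknessMm,
                          sliceGap = spec$sliceGapMm, baseToApex = TRUE)
  truth <- new("PhantomTruth", myocardium = myo, core = coreM, border = bordM,
               truePct = pct, perSegmentScarPct = segPct, contours = contours)
  list(stack = stack, truth = truth)
}

#' Simulate a two-group cohort of phantoms
#'
#' Draws `nPerGroup` phantoms per group, sampling any parameter given as a
#' `c(min, max)` range uniformly and independently per phantom. With
#' identical ranges in both groups the cohort is a null cohort: downstream
#' two-sample tests should reject at their nominal level only. Group sizes
#' may differ (pass a length-2 `nPerGroup`), mirroring unbalanced clinical
#' cohorts such as 66 primary- versus 29 secondary-prevention ICD
#' recipients.
#'
#' @param nPerGroup integer, phantoms per group; length 1 (both groups) or
#'   2 (`c(groupA, groupB)`).
#' @param groupParamRanges named list of two lists (group label ->
#'   parameter ranges). Each inner element is either a scalar (fixed) or a
#'   `c(min, max)` range for the matching [phantomSpec()] argument.
#' @param seed master seed; per-phantom seeds are derived from it.
#' @param baseSpec named list of [phantomSpec()] arguments shared by every
#'   phantom (e.g. a smaller `gridSize` for large simulations).
#' @return list of lists with components `stack`, `truth`, `group`.
#' @examples
#' coh <- phantomCohort(2, list(a = list(scarAngularExtentDeg = c(60, 120)),
#'                              b = list(scarAngularExtentDeg = c(60, 120))),
#'                      seed = 1,
#'                      baseSpec = list(nSlices = 2, gridSize = 32,
#'                                      pixelSpacingMm = 2.8))
#' length(coh)
#' @export
phantomCohort <- function(nPerGroup, groupParamRanges, seed = 1L,
                          baseSpec = list()) {
  stopifnot(length(groupParamRanges) == 2L, !is.null(names(groupParamRanges)))
  nPerGroup <- rep_len(as.integer(nPerGroup), 2L)
  if (any(nPerGroup < 1L)) stop("nPerGroup must be >= 1")
  groups <- names(groupParamRanges)
  total <- sum(nPerGroup)
  draws <- .withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    u <- lapply(seq_len(total), function(i) stats::runif(64L))
    list(seeds = seeds, u = u)
  })
  out <- vector("list", total)
  k <- 0L
  for (gi in 1:2) {
    ranges <- groupParamRanges[[gi]]
    for (j in seq_len(nPerGroup[gi])) {
      k <- k + 1L
      args <- baseSpec
      ui <- draws$u[[k]]
      for (pi in seq_along(ranges)) {
        pr <- ranges[[pi]]
        nm <- names(ranges)[pi]
        args[[nm]] <- if (length(pr) == 2L)
          pr[1L] + ui[pi] * (pr[2L] - pr[1L]) else pr
      }
      args$seed <- draws$seeds[k]
      ph <- generatePhantom(do.call(phantomSpec, args))
      out[[k]] <- list(stack = ph$stack, truth = ph$truth, group = groups[gi])
    }
  }
  out
}
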