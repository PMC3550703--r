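# LV volumetrics by disc summation (Simpson's method on short-axis
# contours): cavity volume, myocardial mass, ejection fraction and
# body-surface-area indexing.

#' LV cavity volume by disc summation
#'
#' Sums, over every slice carrying an endocardial contour, the polygon
#' area times the slice-to-slice distance (thickness + gap). Papillary
#' muscles are conventionally included in the cavity.
#'
#' @param contours a [ContourSet-class] with endocardial polygons.
#' @param sliceThickness slice thickness, mm.
#' @param sliceGap inter-slice gap, mm (default 0).
#' @param check verify polygons are simple (non-self-intersecting).
#' @return volume in ml.
#' @examples
#' circ <- cbind(10 * cos(seq(0, 2 * pi, length.out = 181))[-181],
#'               10 * sin(seq(0, 2 * pi, length.out = 181))[-181])
#' cs <- ContourSet(list(list(endo = circ)))
#' cavityVolume(cs, sliceThickness = 10)  # ~ pi * 1^2 * 1 cm^3
#' @export
cavityVolume <- function(contours, sliceThickness, sliceGap = 0,
                         check = TRUE) {
  .discSum(contours, "endo", sliceThickness, sliceGap, check)
}

# shared disc summation over one contour type, in ml
.discSum <- function(contours, what, sliceThickness, sliceGap, check) {
  stopifnot(is(contours, "ContourSet"), sliceThickness > 0, sliceGap >= 0)
  step <- sliceThickness + sliceGap
  total <- 0
  nWith <- 0L
  for (s in seq_len(nSlices(contours))) {
    poly <- contours@slices[[s]][[what]]
    if (is.null(poly)) next
    if (check && !.isSimplePolygon(poly))
      stop(sprintf("geometry error: slice %d %s polygon is self-intersecting",
                   s, what))
    total <- total + .polygonArea(poly) * step
    nWith <- nWith + 1L
  }
  if (nWith == 0L) stop(sprintf("no %s contour on any slice", what))
  total / 1000  # mm^3 -> ml
}

#' Myocardial mass from endo/epicardial contours
#'
#' Disc-summation myocardial volume (epicardial minus endocardial volume)
#' times myocardial density. Every included slice must carry both
#' contours, and the endocardial area may not exceed the epicardial area.
#'
#' @inheritParams cavityVolume
#' @param density myocardial density in g/ml (default 1.05).
#' @return mass in g.
#' @export
myocardialMass <- function(contours, sliceThickness, sliceGap = 0,
                           density = 1.05, check = TRUE) {
  stopifnot(is(contours, "ContourSet"), density > 0)
  step <- sliceThickness + sliceGap
  vol <- 0
  nWith <- 0L
  for (s in seq_len(nSlices(contours))) {
    sl <- contours@slices[[s]]
    if (is.null(sl$epi) && is.null(sl$endo)) next
    if (is.null(sl$epi) || is.null(sl$endo))
      stop(sprintf("slice %d: mass needs both endo and epi contours", s))
    if (check && (!.isSimplePolygon(sl$epi) || !.isSimplePolygon(sl$endo)))
      stop(sprintf("geometry error: slice %d polygon is self-intersecting", s))
    aEpi <- .polygonArea(sl$epi)
    aEndo <- .polygonArea(sl$endo)
    if (aEndo > aEpi)
      stop(sprintf("containment error: slice %d endocardial area exceeds epicardial area", s))
    vol <- vol + (aEpi - aEndo) * step
    nWith <- nWith + 1L
  }
  if (nWith == 0L) stop("no slice with both contours")
  vol / 1000 * density
}

#' Left ventricular ejection fraction
#'
#' `100 * (EDV - ESV) / EDV`, percent.
#'
#' @param edv end-diastolic volume, ml (> 0).
#' @param esv end-systolic volume, ml.
#' @return LVEF in percent.
#' @examples
#' ejectionFraction(284, 222)  # group-mean volumes -> 21.8%
#' @export
ejectionFraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("domain error: EDV must be positive")
  100 * (edv - esv) / edv
}

#' Body surface area
#'
#' Mosteller formula by default: `sqrt(height_cm * weight_kg / 3600)`;
#' DuBois-DuBois (`0.007184 * h^0.725 * w^0.425`) as an option. The two
#' differ by under ~5% over the physiologic range.
#'
#' @param heightCm height in cm (> 0).
#' @param weightKg weight in kg (> 0).
#' @param formula `"mosteller"` or `"dubois"`.
#' @return body surface area in m^2.
#' @examples
#' bodySurfaceArea(180, 80)  # exactly 2
#' @export
bodySurfaceArea <- function(heightCm, weightKg,
                            formula = c("mosteller", "dubois")) {
  if (any(heightCm <= 0) || any(weightKg <= 0))
    stop("domain error: height and weight must be positive")
  formula <- match.arg(formula)
  switch(formula,
         mosteller = sqrt(heightCm * weightKg / 3600),
         dubois = 0.007184 * heightCm^0.725 * weightKg^0.425)
}

#' Index a measurement to body surface area
#'
#' @param value measurement (e.g. volume in ml or mass in g).
#' @param bsa body surface area in m^2 (> 0).
#' @return value per m^2.
#' @export
indexToBSA <- function(value, bsa) {
  if (any(bsa <= 0)) stop("domain error: BSA must be positive")
  value / bsa
}

#' Summary LV volumetrics for one study
#'
#' Combines end-diastolic and end-systolic contour sets into the standard
#' report: EDV, ESV, stroke volume, LVEF, end-diastolic wall mass, and
#' their BSA-indexed variants when height and weight are given.
#'
#' @param edContours,esContours [ContourSet-class] at end-diastole /
#'   end-systole.
#' @param sliceThickness,sliceGap slice geometry, mm.
#' @param heightCm,weightKg anthropometrics for BSA indexing (optional).
#' @param density myocardial density, g/ml.
#' @return named list: `EDV_ml`, `ESV_ml`, `SV_ml`, `LVEF_pct`, `EDWM_g`,
#'   `bsa_m2`, `EDVi_ml_m2`, `ESVi_ml_m2`, `EDWMi_g_m2` (indexed entries
#'   `NA` without anthropometrics).
#' @export
volumetrics <- function(edContours, esContours, sliceThickness,
                        sliceGap = 0, heightCm = NA, weightKg = NA,
                        density = 1.05) {
  edv <- cavityVolume(edContours, sliceThickness, sliceGap)
  esv <- cavityVolume(esContours, sliceThickness, sliceGap)
  mass <- myocardialMass(edContours, sliceThickness, sliceGap, density)
  bsa <- if (!is.na(heightCm) && !is.na(weightKg))
    bodySurfaceArea(heightCm, weightKg) else NA_real_
  list(EDV_ml = edv, ESV_ml = esv, SV_ml = edv - esv,
       LVEF_pct = ejectionFraction(edv, esv), EDWM_g = mass, bsa_m2 = bsa,
       EDVi_ml_m2 = if (is.na(bsa)) NA_real_ else indexToBSA(edv, bsa),
       ESVi_ml_m2 = if (is.na(bsa)) NA_real_ else indexToBSA(esv, bsa),
       EDWMi_g_m2 = if (is.na(bsa)) NA_real_ else indexToBSA(mass, bsa))
}
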