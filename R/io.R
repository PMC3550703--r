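# Readers and writers for the pipeline's interchange formats: NIfTI for
# intensity volumes and label masks, JSON for contours and landmarks,
# CSV for cohort tables. All readers validate and fail loudly; no silent
# geometry defaults.

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write / read a short-axis stack as NIfTI
#'
#' `writeStack()` stores the intensity volume as NIfTI (`.nii` /
#' `.nii.gz`) with in-plane spacing and slice step in the header pixdim,
#' plus a JSON sidecar (same basename) carrying slice thickness, gap and
#' slice order explicitly. `readStack()` reads either; without a sidecar
#' the slice thickness is taken from pixdim (gap 0), and missing or
#' non-positive geometry raises a metadata error rather than defaulting.
#' NIfTI stores pixdim as 32-bit floats, so spacing round-trips to single
#' precision; voxel values round-trip exactly (stored as float64).
#'
#' @param stack a [ShortAxisStack-class].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `readStack()` returns a [ShortAxisStack-class];
#'   `writeStack()` returns `path` invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ShortAxisStack"))
  sp <- pixelSpacing(stack)
  img <- RNifti::asNifti(intensities(stack))
  RNifti::pixdim(img) <- c(sp[1L], sp[2L], sliceThickness(stack) + sliceGap(stack))
  RNifti::writeNifti(img, path)
  meta <- list(pixel_spacing_mm = sp,
               slice_thickness_mm = sliceThickness(stack),
               slice_gap_mm = sliceGap(stack),
               slice_order_base_to_apex = stack@baseToApex)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    need <- c("pixel_spacing_mm", "slice_thickness_mm")
    miss <- need[!need %in% names(meta)]
    if (length(miss))
      stop("metadata error: sidecar lacks ", paste(miss, collapse = ", "))
    sp <- as.numeric(meta$pixel_spacing_mm)
    th <- as.numeric(meta$slice_thickness_mm)
    gap <- as.numeric(meta$slice_gap_mm %||% 0)
    b2a <- isTRUE(meta$slice_order_base_to_apex %||% TRUE)
  } else {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L) stop("metadata error: NIfTI header lacks 3-D pixdim")
    sp <- pd[1:2]
    th <- pd[3L]
    gap <- 0
    b2a <- TRUE
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("metadata error: pixel spacing missing or non-positive")
  if (!is.finite(th) || th <= 0)
    stop("metadata error: slice thickness missing or non-positive")
  ShortAxisStack(arr, pixelSpacing = sp, sliceThickness = th, sliceGap = gap,
                 baseToApex = b2a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a label or mask volume as NIfTI
#'
#' Stores an integer label volume (e.g. truth masks, [SegmentMap-class]
#' or [ScarMap-class] labels with `NA` mapped to -1) on a stack's
#' geometry.
#'
#' @param labels integer/logical 3-D array matching the stack dimensions.
#' @param stack the [ShortAxisStack-class] supplying geometry.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
writeLabelVolume <- function(labels, stack, path) {
  stopifnot(is(stack, "ShortAxisStack"),
            identical(dim(labels), dim(intensities(stack))))
  lab <- labels
  if (is.logical(lab)) lab <- array(as.integer(lab), dim(lab))
  lab[is.na(lab)] <- -1L
  img <- RNifti::asNifti(array(as.integer(lab), dim(lab)))
  sp <- pixelSpacing(stack)
  RNifti::pixdim(img) <- c(sp[1L], sp[2L], sliceThickness(stack) + sliceGap(stack))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read contours and landmarks as JSON
#'
#' The JSON schema is an object with fields `phase`, `lv_center`,
#' `rv_insertion` (2-vectors, mm, or null) and `slices`: an array with
#' one object per slice, each holding `endo`, `epi`, `roi` as arrays of
#' `[x, y]` vertex pairs (mm, image-plane, origin at the centre of pixel
#' (0,0)) or null when absent. Reading validates polygon simplicity and
#' endo-within-epi containment and rejects violations.
#'
#' @param contours a [ContourSet-class].
#' @param path JSON file path.
#' @return `readContours()` returns a [ContourSet-class].
#' @export
writeContours <- function(contours, path) {
  stopifnot(is(contours, "ContourSet"))
  asPairs <- function(p) if (is.null(p)) NULL else unname(apply(p, 1L, as.numeric, simplify = FALSE))
  obj <- list(
    phase = contours@phase,
    lv_center = if (anyNA(contours@lvCenter)) NULL else contours@lvCenter,
    rv_insertion = if (anyNA(contours@rvInsertion)) NULL else contours@rvInsertion,
    slices = lapply(contours@slices, function(sl)
      list(endo = asPairs(sl$endo), epi = asPairs(sl$epi),
           roi = asPairs(sl$roi))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$slices) || !length(obj$slices))
    stop("schema error: contour JSON lacks a non-empty 'slices' array")
  toMat <- function(p) {
    if (is.null(p)) return(NULL)
    m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    if (ncol(m) != 2L) stop("schema error: vertices must be [x, y] pairs")
    m
  }
  slices <- lapply(obj$slices, function(sl)
    list(endo = toMat(sl$endo), epi = toMat(sl$epi), roi = toMat(sl$roi)))
  toPt <- function(p) if (is.null(p)) c(NA_real_, NA_real_) else as.numeric(unlist(p))
  ContourSet(slices, lvCenter = toPt(obj$lv_center),
             rvInsertion = toPt(obj$rv_insertion),
             phase = obj$phase %||% "ED")
}

#' Read a per-patient cohort table
#'
#' Reads a CSV with one row per patient. Required columns: `id` and
#' `group` (labels `"primary"` / `"secondary"`). Recognized optional
#' columns: `height_cm`, `weight_kg`, `followup_months`,
#' `appropriate_therapy`, `death` (0/1), wall-motion grades
#' `wm_1` .. `wm_17` (0-4, empty = unobserved; never encode unobserved
#' as 0), and any derived-metric columns, which pass through untouched.
#' A `mace` column (appropriate therapy and/or death) is derived when the
#' event flags are present. Violations — unknown group labels, wall-motion
#' grades outside 0-4, non-positive anthropometrics — raise schema errors.
#'
#' @param path CSV file path.
#' @param groups allowed group labels.
#' @return validated `data.frame`.
#' @export
readCohort <- function(path, groups = c("primary", "secondary")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group")
  miss <- need[!need %in% names(df)]
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    stop("schema error: unknown group label(s): ", paste(bad, collapse = ", "))
  wmCols <- grep("^wm_([1-9]|1[0-7])$", names(df), value = TRUE)
  for (cn in wmCols) {
    v <- df[[cn]]
    if (any(!is.na(v) & !(v %in% 0:4)))
      stop("schema error: wall-motion scores must lie in 0..4 (", cn, ")")
  }
  for (cn in intersect(c("height_cm", "weight_kg"), names(df))) {
    v <- df[[cn]]
    if (any(!is.na(v) & v <= 0))
      stop("schema error: non-positive ", cn)
  }
  for (cn in intersect(c("appropriate_therapy", "death"), names(df))) {
    v <- df[[cn]]
    if (any(!is.na(v) & !(v %in% 0:1)))
      stop("schema error: ", cn, " must be 0/1")
  }
  if (all(c("appropriate_therapy", "death") %in% names(df)))
    df$mace <- as.integer(df$appropriate_therapy == 1 | df$death == 1)
  df
}
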