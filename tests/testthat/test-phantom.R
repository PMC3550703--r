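test_that("degenerate geometry is rejected", {
  expect_error(smallSpec(endoRadiusMm = 26, epiRadiusMm = 26), "geometry")
  expect_error(smallSpec(endoRadiusMm = 30, epiRadiusMm = 26), "geometry")
  expect_error(smallSpec(gridSize = 16), "grid too small")
  expect_error(smallSpec(siBorder = 10), "plateaus")
})

test_that("no scar wedge means zero scar truth and no ROI", {
  ph <- generatePhantom(smallSpec(scarAngularExtentDeg = 0))
  p <- truePercentages(ph$truth)
  expect_identical(unname(p), c(0, 0, 0))
  expect_false(any(truthMask(ph$truth, "core")))
  expect_false(any(truthMask(ph$truth, "border")))
  rois <- vapply(seq_len(nSlices(truthContours(ph$truth))), function(s)
    is.null(contourPolygon(truthContours(ph$truth), s, "roi")), TRUE)
  expect_true(all(rois))
})

test_that("full-circumference fully transmural scar with no rim is all core", {
  ph <- generatePhantom(smallSpec(scarAngularExtentDeg = 360,
                                  scarTransmurality = 1,
                                  borderRimFraction = 0,
                                  scarSliceRange = c(1L, 4L)))
  p <- truePercentages(ph$truth)
  expect_equal(unname(p), c(100, 0, 100))
  expect_true(all(truthMask(ph$truth, "core")[truthMask(ph$truth)]))
})

test_that("truth fractions match a brute-force polar-coordinate voxel loop", {
  spec <- smallSpec(nSlices = 8L, scarAngularExtentDeg = 90,
                    scarTransmurality = 0.6, borderRimFraction = 0.3,
                    scarSliceRange = c(2L, 6L), seed = 42L)
  ph <- generatePhantom(spec)
  orc <- oraclePhantomCounts(spec)
  expect_identical(sum(truthMask(ph$truth)), orc$myo)
  expect_identical(sum(truthMask(ph$truth, "core")), orc$core)
  expect_identical(sum(truthMask(ph$truth, "border")), orc$border)
  expect_equal(truePercentages(ph$truth)[["core"]], 100 * orc$core / orc$myo)
  expect_equal(truePercentages(ph$truth)[["peri"]], 100 * orc$border / orc$myo)
})

test_that("truth masks satisfy their invariants", {
  for (seed in 1:5) {
    ph <- generatePhantom(smallSpec(seed = seed,
                                    scarAngularExtentDeg = 30 + 60 * seed %% 4,
                                    scarTransmurality = 0.2 * seed))
    tr <- ph$truth
    expect_false(any(truthMask(tr, "core") & truthMask(tr, "border")))
    expect_false(any((truthMask(tr, "core") | truthMask(tr, "border")) &
                       !truthMask(tr)))
    p <- truePercentages(tr)
    expect_equal(p[["total"]], p[["core"]] + p[["peri"]])
    expect_true(all(p >= 0 & p <= 100))
  }
})

test_that("same seed gives a bit-identical stack, different seed differs", {
  a <- generatePhantom(smallSpec(seed = 7L))
  b <- generatePhantom(smallSpec(seed = 7L))
  c <- generatePhantom(smallSpec(seed = 8L))
  expect_identical(intensities(a$stack), intensities(b$stack))
  expect_false(identical(intensities(a$stack), intensities(c$stack)))
})

test_that("truth percentages are invariant to whole-pixel grid translation", {
  base <- generatePhantom(smallSpec(gridSize = 56L))
  for (off in list(c(2, 0), c(0, -4), c(6, 6))) {
    shifted <- generatePhantom(smallSpec(gridSize = 56L,
                                         centerOffsetMm = off * 2))
    expect_identical(truePercentages(shifted$truth), truePercentages(base$truth))
  }
})

test_that("phantomCohort returns labelled reproducible phantoms", {
  ranges <- list(g1 = list(scarAngularExtentDeg = c(60, 120)),
                 g2 = list(scarAngularExtentDeg = c(60, 120)))
  base <- list(nSlices = 2L, gridSize = 32L, pixelSpacingMm = 2.8,
               endoRadiusMm = 18, epiRadiusMm = 28, nVertices = 64L)
  coh <- phantomCohort(1L, ranges, seed = 3L, baseSpec = base)
  expect_length(coh, 2L)
  expect_identical(vapply(coh, `[[`, "", "group"), c("g1", "g2"))
  coh2 <- phantomCohort(1L, ranges, seed = 3L, baseSpec = base)
  expect_identical(intensities(coh[[1L]]$stack), intensities(coh2[[1L]]$stack))
  coh3 <- phantomCohort(c(2L, 3L), ranges, seed = 3L, baseSpec = base)
  expect_length(coh3, 5L)
  expect_error(phantomCohort(0L, ranges), "nPerGroup")
})

test_that("disjoint scar-extent ranges give high Mann-Whitney power at n = 20", {
  base <- list(nSlices = 2L, gridSize = 32L, pixelSpacingMm = 2.8,
               endoRadiusMm = 18, epiRadiusMm = 28, nVertices = 64L,
               scarSliceRange = c(1L, 2L))
  ranges <- list(lo = list(scarAngularExtentDeg = c(50, 80)),
                 hi = list(scarAngularExtentDeg = c(120, 150)))
  hits <- 0L
  nRep <- 20L
  for (r in seq_len(nRep)) {
    coh <- phantomCohort(20L, ranges, seed = 1000L + r, baseSpec = base)
    tot <- vapply(coh, function(el) truePercentages(el$truth)[["total"]], 0)
    grp <- vapply(coh, `[[`, "", "group")
    p <- compareContinuous(tot[grp == "lo"], tot[grp == "hi"],
                           method = "mann_whitney")$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / nRep, 0.9)
})
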