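test_that("scar score bins match their printed definitions", {
  expect_identical(scarScore(0), 0L)
  expect_identical(scarScore(25), 1L)
  expect_identical(scarScore(26), 2L)
  expect_identical(scarScore(100), 4L)
  expect_identical(scarScore(25.4), 2L)   # continuous boundary at 25
  expect_identical(scarScore(c(0.1, 50, 50.1, 75, 75.1)),
                   c(1L, 2L, 3L, 3L, 4L))
  expect_identical(scarScore(NA), NA_integer_)
  expect_error(scarScore(101), "domain")
  expect_error(scarScore(-2), "domain")
})

test_that("random percentages match a lookup-table oracle and are monotone", {
  set.seed(31)
  pct <- c(0, 25, 50, 75, 100, runif(500, 0, 100))
  oracle <- vapply(pct, function(p) {
    if (p == 0) 0L
    else if (p <= 25) 1L
    else if (p <= 50) 2L
    else if (p <= 75) 3L
    else 4L
  }, integer(1))
  expect_identical(scarScore(pct), oracle)
  srt <- sort(pct)
  expect_true(all(diff(scarScore(srt)) >= 0L))
})

test_that("transmural extent counts segments scored 3 or 4", {
  expect_identical(transmuralExtent(rep(0L, 17L)), 0L)
  expect_identical(transmuralExtent(c(3L, 4L, 2L, rep(0L, 14L))), 2L)
  expect_identical(transmuralExtent(rep(4L, 17L)), 17L)
  set.seed(32)
  for (i in 1:50) {
    sc <- sample(c(0:4, NA), 17L, replace = TRUE)
    expect_identical(transmuralExtent(sc),
                     sum(sc[!is.na(sc)] %in% c(3L, 4L)))
  }
  expect_error(transmuralExtent(c(5L, rep(0L, 16L))), "0..4")
})

test_that("regional scores are territory means with unobserved dropped", {
  expect_equal(unname(regionalScores(rep(2L, 17L))), c(2, 2, 2))
  rcaOnly <- rep(0L, 17L)
  rcaOnly[defaultTerritories()$RCA] <- 3L
  rs <- regionalScores(rcaOnly)
  expect_equal(rs[["LAD"]], 0)
  expect_equal(rs[["LCX"]], 0)
  expect_equal(rs[["RCA"]], 3)
  set.seed(33)
  tm <- defaultTerritories()
  for (i in 1:50) {
    sc <- sample(c(0:4, NA), 17L, replace = TRUE)
    got <- suppressWarnings(regionalScores(sc, tm))
    for (t in names(tm)) {
      v <- sc[tm[[t]]]; v <- v[!is.na(v)]
      if (length(v)) expect_equal(got[[t]], mean(v))
      else expect_true(is.na(got[[t]]))
    }
  }
  allNA <- rep(NA_integer_, 17L)
  expect_warning(regionalScores(allNA), "no observed segments")
})

test_that("WMSI divides the score sum by observed segments only", {
  expect_equal(wmsi(rep(0L, 17L)), 0)
  expect_equal(wmsi(rep(4L, 17L)), 4)
  sc <- c(rep(2L, 10L), rep(NA, 3L), 1L, 0L, 0L, 0L)
  expect_equal(wmsi(sc), 21 / 14)
  expect_error(wmsi(rep(NA_integer_, 17L)), "no observed")
  expect_error(wmsi(c(5L, rep(0L, 16L))), "0..4")
  set.seed(34)
  for (i in 1:25) {
    sc <- sample(c(0:4, NA), 17L, replace = TRUE)
    if (all(is.na(sc))) next
    expect_gte(wmsi(sc), min(sc, na.rm = TRUE))
    expect_lte(wmsi(sc), max(sc, na.rm = TRUE))
  }
})

test_that("per-segment scar percentages match the phantom truth and an oracle", {
  ph <- generatePhantom(smallSpec(nSlices = 6L, scarSliceRange = c(2L, 5L)))
  lm <- landmarks(truthContours(ph$truth))
  segMap <- assignSegments(truthMask(ph$truth), lm$lvCenter, lm$rvInsertion,
                           pixelSpacing(ph$stack))
  scar <- truthMask(ph$truth, "core") | truthMask(ph$truth, "border")
  pct <- segmentScarPct(scar, segMap)
  expect_identical(pct, truthSegmentScarPct(ph$truth))
  # brute-force count per segment
  seg <- segmentLabels(segMap)
  for (k in 1:17) {
    nSeg <- sum(seg == k)
    if (nSeg == 0L) expect_true(is.na(pct[k]))
    else expect_equal(pct[k], 100 * sum(scar[seg == k]) / nSeg)
  }
  # segments without scar are 0%, fully scarred segments would be 100%
  expect_true(all(pct[!is.na(pct) & pct == 0] == 0))
  # recovered ScarMap route agrees on a noiseless phantom
  res <- characterizeScar(ph$stack, truthContours(ph$truth))
  ph0 <- generatePhantom(smallSpec(nSlices = 6L, scarSliceRange = c(2L, 5L),
                                   noiseSd = 0))
  res0 <- characterizeScar(ph0$stack, truthContours(ph0$truth))
  expect_identical(segmentScarPct(res0$scarMap, segMap),
                   truthSegmentScarPct(ph0$truth))
})

test_that("pipeline property: a wedge covering segments transmurally scores 3+", {
  # full-circumference transmural scar on every slice: every observed
  # segment is 100% scar, so transmural extent equals the observed count
  ph <- generatePhantom(smallSpec(nSlices = 6L, scarAngularExtentDeg = 360,
                                  scarTransmurality = 1, borderRimFraction = 0.2,
                                  scarSliceRange = c(1L, 6L), noiseSd = 0))
  lm <- landmarks(truthContours(ph$truth))
  segMap <- assignSegments(truthMask(ph$truth), lm$lvCenter, lm$rvInsertion,
                           pixelSpacing(ph$stack))
  pct <- truthSegmentScarPct(ph$truth)
  scores <- scarScore(pct)
  observed <- !is.na(scores)
  expect_identical(transmuralExtent(scores), sum(observed))
  expect_true(all(scores[observed] == 4L))
})

test_that("grid mismatch between scar and segment maps errors", {
  ph <- generatePhantom(smallSpec(nSlices = 2L))
  lm <- landmarks(truthContours(ph$truth))
  segMap <- assignSegments(truthMask(ph$truth), lm$lvCenter, lm$rvInsertion,
                           pixelSpacing(ph$stack))
  expect_error(segmentScarPct(array(TRUE, c(4, 4, 1)), segMap), "alignment")
})
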