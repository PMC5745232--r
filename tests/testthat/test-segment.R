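pops2 <- list(cancerPopulation(), feederPopulation())

## handcrafted placement table (bypasses placeCells)
mkPlacements <- function(x, y, d = 10, markerPositive = TRUE) {
  data.frame(population = "cancer", marker_positive = markerPositive,
             x = x, y = y, diameter_px = d, elongation = 1, angle = 0,
             stringsAsFactors = FALSE)
}

test_that("well-separated nuclei are each found once", {
  gx <- as.vector(outer(seq(60, 460, by = 100), rep(1, 2)))
  gy <- as.vector(outer(rep(1, 5), c(150, 350))) + gx * 0  # 5 x 2 grid
  pl <- mkPlacements(gx, gy)
  fi <- renderField(pl, pops = pops2, seed = 3)
  labs <- segmentNuclei(fi, SegmentationParams())
  expect_equal(max(labs), 10)
})

test_that("objects below the minimum width are rejected", {
  pl <- mkPlacements(256, 256, d = 2.5)  # minWidth / 2
  fi <- renderField(pl, OpticsParams(noiseSd = 0), pops = pops2)
  labs <- segmentNuclei(fi, SegmentationParams())
  expect_equal(max(labs), 0)
})

test_that("touching nuclei split only when splitTouching is on", {
  ## soft-shouldered pair 1.2 diameters apart whose footprints merge
  pl <- mkPlacements(c(250, 262), c(256, 256), d = 10)
  fi <- renderField(pl, OpticsParams(noiseSd = 5, psfSigma = 1.25),
                    pops = pops2, seed = 4)
  soft <- SegmentationParams(intensityAboveBackground = c(nuclear = 120,
                                                          marker = 600))
  on <- segmentNuclei(fi, soft)
  expect_equal(max(on), 2)
  off <- SegmentationParams(intensityAboveBackground = c(nuclear = 120,
                                                         marker = 600),
                            splitTouching = FALSE)
  expect_equal(max(segmentNuclei(fi, off)), 1)
})

test_that("blank and saturated fields yield zero regions plus a QC flag", {
  blank <- matrix(100, 256, 256)
  labs <- segmentNuclei(blank, SegmentationParams())
  expect_equal(max(labs), 0)
  expect_match(attr(labs, "qcWarning"), "blank")
  sat <- matrix(60000, 256, 256)
  sat[1, 1] <- 0  # not perfectly uniform
  labs2 <- segmentNuclei(sat, SegmentationParams())
  expect_equal(max(labs2), 0)
  expect_false(is.null(attr(labs2, "qcWarning")))
})

test_that("uniform background gives an empty marker mask", {
  mask <- segmentMarker(matrix(100, 256, 256), SegmentationParams())
  expect_false(any(mask))
})

test_that("marker mask covers a rendered positive cell's cytoplasm", {
  pl <- mkPlacements(128, 128, d = 10)
  fi <- renderField(pl, OpticsParams(imageSize = 256), pops = pops2, seed = 5)
  mask <- segmentMarker(fi, SegmentationParams())
  ## true cytoplasm footprint: disk of 1.5x nucleus radius
  xs <- matrix(rep(1:256, 256), 256)
  inFoot <- (xs - 129)^2 + (t(xs) - 129)^2 <= 7.5^2
  expect_gte(sum(mask & inFoot) / sum(inFoot), 0.5)
})

test_that("a fibroblast-only field stains below 1% in the marker channel", {
  pl <- placeCells(c(feeder = 400), pops2, seed = 6)
  fi <- renderField(pl, pops = pops2, seed = 7)
  mask <- segmentMarker(fi, SegmentationParams())
  expect_lt(mean(mask), 0.01)
})

test_that("classification is invariant to a common intensity rescaling", {
  pl <- placeCells(c(cancer = 60, feeder = 40), pops2, seed = 8)
  fi <- renderField(pl, pops = pops2, seed = 9)
  p1 <- SegmentationParams()
  cells1 <- quantifyWell(fi, p1)$cells
  k <- 3.7
  fi2 <- FieldImage(fi@nuclear * k, fi@marker * k, bitDepth = 16L)
  p2 <- SegmentationParams(intensityAboveBackground = c(nuclear = 1000 * k,
                                                        marker = 600 * k))
  cells2 <- quantifyWell(fi2, p2)$cells
  expect_equal(nrow(cells1), nrow(cells2))
  expect_equal(cells1$marker_positive, cells2$marker_positive)
  expect_equal(cells1$x, cells2$x)
})
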