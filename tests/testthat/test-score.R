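pops2 <- list(cancerPopulation(), feederPopulation())

## hand-built 40x40 frame: one circular nucleus label + configurable mask
mkFrame <- function(maskOn) {
  labels <- matrix(0L, 40, 40)
  xs <- matrix(rep(1:40, 40), 40)
  nuc <- (xs - 20)^2 + (t(xs) - 20)^2 <= 16
  labels[nuc] <- 1L
  mask <- matrix(maskOn, 40, 40)
  nuclear <- matrix(100, 40, 40) + nuc * 2000
  marker <- matrix(100, 40, 40) + mask * 1500
  list(labels = labels, mask = mask, nuclear = nuclear, marker = marker)
}

test_that("a nucleus inside the marker mask is positive, outside negative", {
  f <- mkFrame(TRUE)
  cells <- scoreCells(f$labels, f$mask, f$nuclear, f$marker)
  expect_equal(nrow(cells), 1)
  expect_true(cells$marker_positive)
  g <- mkFrame(FALSE)
  cells2 <- scoreCells(g$labels, g$mask, g$nuclear, g$marker)
  expect_false(cells2$marker_positive)
})

test_that("centroid, area and intensities are reported per nucleus", {
  f <- mkFrame(TRUE)
  cells <- scoreCells(f$labels, f$mask, f$nuclear, f$marker)
  expect_equal(cells$x, 19, tolerance = 0.01)  # 0-based centroid
  expect_equal(cells$y, 19, tolerance = 0.01)
  expect_equal(cells$nucleus_area_px2, sum(f$labels == 1L))
  expect_equal(cells$nuclear_mean, 2100)
})

test_that("mismatched frames are rejected", {
  f <- mkFrame(TRUE)
  expect_error(scoreCells(f$labels, matrix(TRUE, 30, 30), f$nuclear,
                          f$marker), "frame")
})

test_that("a mixed field is classified within 10% per class", {
  pl <- placeCells(c(cancer = 30, feeder = 20), pops2, seed = 31)
  fi <- renderField(pl, pops = pops2, seed = 32)
  wc <- quantifyWell(fi)$wellCount
  expect_lte(abs(wc$n_positive - 30), 3)
  expect_lte(abs(wc$n_negative - 20), 2)
})

test_that("positive and negative counts always sum to the total", {
  for (s in c(41, 42)) {
    pl <- placeCells(c(cancer = 150, feeder = 100), pops2, seed = s)
    wc <- quantifyWell(renderField(pl, pops = pops2, seed = s + 1))$wellCount
    expect_equal(wc$n_positive + wc$n_negative, wc$n_total)
  }
})

test_that("site order does not change the well count", {
  pl1 <- placeCells(c(cancer = 40), pops2, seed = 51)
  pl2 <- placeCells(c(cancer = 25, feeder = 10), pops2, seed = 52)
  f1 <- renderField(pl1, pops = pops2, well = "B2", site = 1L, seed = 53)
  f2 <- renderField(pl2, pops = pops2, well = "B2", site = 2L, seed = 54)
  a <- quantifyWell(list(f1, f2))$wellCount
  b <- quantifyWell(list(f2, f1))$wellCount
  expect_equal(a$n_positive, b$n_positive)
  expect_equal(a$n_negative, b$n_negative)
  expect_equal(a$n_total, b$n_total)
  expect_equal(a$n_sites, 2)
})

test_that("counts add across sites of a well", {
  mk <- function(nPos, nNeg, site, seed) {
    pl <- placeCells(c(cancer = nPos, feeder = nNeg), pops2, seed = seed)
    renderField(pl, pops = pops2, site = site, seed = seed + 100)
  }
  q <- quantifyWell(list(mk(10, 5, 1, 61), mk(7, 3, 2, 62)))
  expect_equal(q$wellCount$n_positive, 17)
  expect_equal(q$wellCount$n_negative, 8)
  expect_equal(q$wellCount$n_total, 25)
})

test_that("an empty well quantifies to zero", {
  pl <- placeCells(c(cancer = 0), pops2, seed = 1)
  fi <- renderField(pl, pops = pops2, seed = 2)
  wc <- quantifyWell(fi)$wellCount
  expect_equal(unlist(wc[c("n_total", "n_positive", "n_negative")]),
               c(n_total = 0, n_positive = 0, n_negative = 0))
})
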