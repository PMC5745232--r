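test_that("noiseless 4PL data are recovered to numerical precision", {
  doses <- c(1, 3, 10, 30, 100, 300, 1000)
  y <- 0 + (100 - 0) / (1 + (doses / 50)^1)
  f <- fit4PL(doses, y)
  expect_true(isConverged(f))
  expect_equal(ic50(f), 50, tolerance = 1e-5)
  expect_equal(hillSlope(f), 1, tolerance = 1e-5)
  expect_equal(f@top, 100, tolerance = 1e-4)
  expect_equal(f@bottom, 0, tolerance = 1e-3)
})

test_that("degenerate series do not converge and do not crash", {
  d <- doseSeries()
  f <- fit4PL(d, rep(42, length(d)))
  expect_false(isConverged(f))
  expect_match(f@message, "no dose effect")
  f2 <- fit4PL(c(1, 10, 100), c(3, 2, 1))
  expect_false(isConverged(f2))
  expect_match(f2@message, "distinct")
  expect_error(fit4PL(c(-1, 1, 10, 100, 1000), rep(1, 5)), "doses")
})

test_that("noisy Poisson replicates recover the IC50 in >= 90% of runs", {
  d <- rep(doseSeries(), each = 4)
  mu <- 20 + (1000 - 20) / (1 + (d / 90)^1)
  hits <- vapply(1:100, function(s) {
    y <- withr::with_seed(s, rpois(length(d), mu))
    f <- fit4PL(d, y)
    isConverged(f) && abs(ic50(f) - 90) / 90 <= 0.25
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("rescaling doses rescales the IC50 and leaves the slope", {
  d <- rep(doseSeries(), each = 2)
  y <- withr::with_seed(7, 5 + 95 / (1 + (d / 70)^1.3) + rnorm(length(d), 0, 2))
  f1 <- fit4PL(d, y)
  k <- 1000
  f2 <- fit4PL(d * k, y)
  expect_equal(ic50(f2) / ic50(f1), k, tolerance = 1e-4)
  expect_equal(hillSlope(f2), hillSlope(f1), tolerance = 1e-4)
})

test_that("rescaling responses leaves IC50 and slope unchanged", {
  d <- rep(doseSeries(), each = 2)
  y <- withr::with_seed(8, 10 + 90 / (1 + (d / 33)^0.9) + rnorm(length(d), 0, 2))
  f1 <- fit4PL(d, y)
  f2 <- fit4PL(d, y * 57)
  expect_equal(ic50(f2), ic50(f1), tolerance = 1e-4)
  expect_equal(hillSlope(f2), hillSlope(f1), tolerance = 1e-4)
})

test_that("a fitted curve from monotone truth is monotone in dose", {
  d <- rep(doseSeries(), each = 4)
  y <- withr::with_seed(9, rpois(length(d), 100 + 900 / (1 + d / 50)))
  f <- fit4PL(d, y)
  grid <- 10^seq(-2, 4, length.out = 100)
  expect_true(all(diff(predict4PL(f, grid)) <= 0))
})

test_that("IC50 fold ratios reproduce the published comparisons", {
  mk <- function(ic) new("DRFit", drug = "d", population = "positive",
                         bottom = 0, top = 100, hill = 1, ic50 = ic,
                         ic50CI = c(NA_real_, NA_real_), converged = TRUE,
                         message = "", residualSE = 0, n = 13L)
  expect_equal(ic50FoldRatio(mk(1300), mk(90)), 14.4, tolerance = 0.01)
  expect_equal(ic50FoldRatio(mk(166), mk(2)), 83)
  expect_equal(ic50FoldRatio(mk(77), mk(77)), 1)
  bad <- fit4PL(doseSeries(), rep(5, 12))
  expect_error(ic50FoldRatio(bad, mk(1)), "converged")
})

test_that("parameter recovery holds across the simulator grid", {
  errs <- c()
  for (ic in c(2, 50, 90, 1300)) {
    for (h in c(0.8, 1, 2)) {
      for (s in 1:2) {
        pops <- list(cancerPopulation(ic50 = ic, hill = h),
                     feederPopulation())
        p <- simCountPlate(pops, seed = s * 37 + round(ic) + round(10 * h))
        f <- fitReport(p$wells, p$map)$drugs$drug$positive
        errs <- c(errs, abs(ic50(f) - ic) / ic)
      }
    }
  }
  expect_lte(median(errs), 0.15)
})

test_that("media shifts propagate to the fitted IC50", {
  pops <- list(cancerPopulation(ic50 = 50), feederPopulation())
  icOf <- function(media, seed) {
    p <- simCountPlate(pops, seed = seed, media = MediaScenario(media))
    ic50(fitReport(p$wells, p$map)$drugs$drug$positive)
  }
  ## EGF/insulin-containing TCM shifts the operative IC50 right (4x here);
  ## removing them restores the R10 response
  expect_gt(icOf("TCM", 21) / icOf("R10", 22), 2)
  expect_lt(abs(icOf("TCM_minus_E_I", 23) - icOf("R10", 24)) / 50, 0.25)
})

test_that("series with too few doses are reported unfittable, not fatal", {
  pops <- list(cancerPopulation(ic50 = 50), feederPopulation())
  p <- simCountPlate(pops, seed = 6, doses = c(3333.3, 333.3, 33.3))
  rep <- fitReport(p$wells, p$map)
  expect_false(rep$drugs$drug$positive@converged)
  expect_match(rep$drugs$drug$positive@message, "4 distinct")
  expect_equal(nrow(rep$fold_ratios), 0)
})

test_that("bulk surrogate is a weighted sum over both populations", {
  wt <- data.frame(well = c("A1", "A2"), n_positive = c(100, 50),
                   n_negative = c(20, 20))
  b <- bulkSurrogate(wt, c(positive = 1, negative = 1))
  expect_equal(b$signal, c(120, 70))
  expect_equal(unique(b$population), "bulk")
  b2 <- bulkSurrogate(wt, c(positive = 2, negative = 0.5))
  expect_equal(b2$signal, c(210, 110))
  expect_error(bulkSurrogate(wt, c(positive = 1)), "weights")
  expect_error(bulkSurrogate(wt, c(positive = 1, negative = -1)), "weights")
})

test_that("the flatness test accepts flat and rejects sloped series", {
  d <- rep(doseSeries(), each = 4)
  flat <- withr::with_seed(11, rpois(length(d), 500))
  expect_true(doseSlopeTest(d, flat)$flat)
  sloped <- withr::with_seed(12, rpois(length(d), 200 + 800 / (1 + d / 50)))
  expect_false(doseSlopeTest(d, sloped)$flat)
})
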