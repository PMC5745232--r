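test_that("baseline is the mean of day-0 replicate wells", {
  wt <- data.frame(well = paste0("A", 1:4),
                   n_positive = c(250, 250, 254, 246),
                   n_negative = c(500, 498, 502, 500))
  pm <- data.frame(well = paste0("A", 1:4), plate_role = "day0")
  b <- baselineCounts(wt, pm)
  expect_equal(b$mean[b$population == "positive"], 250)
  expect_equal(b$n, c(4, 4))
  expect_false(attr(b, "singleWell"))
})

test_that("a single day-0 well is flagged with undefined dispersion", {
  wt <- data.frame(well = "A1", n_positive = 250, n_negative = 500)
  pm <- data.frame(well = "A1", plate_role = "day0")
  b <- baselineCounts(wt, pm)
  expect_true(attr(b, "singleWell"))
  expect_true(all(is.na(b$sd)))
  expect_error(baselineCounts(wt, data.frame(well = "A1",
                                             plate_role = "drug")),
               "day-0")
})

test_that("baseline of a simulated day-0 plate is within Poisson error", {
  wells <- vapply(1:8, function(s)
    simulateWellCounts(list(cancerPopulation(n0 = 250)), 0, 0,
                       seed = 100 + s)$sampled, numeric(1))
  expect_lt(abs(mean(wells) - 250), 4 * sqrt(250 / 8))
})

test_that("the quadrupling endpoint fires at the right timepoint", {
  r <- checkEndpoint(c(24, 48, 72), c(400, 700, 1010), baseline = 250)
  expect_true(r$reached)
  expect_equal(r$index, 3)
  r2 <- checkEndpoint(c(24, 48, 72), c(300, 400, 600), baseline = 250)
  expect_false(r2$reached)
  expect_true(is.na(r2$time))
  expect_error(checkEndpoint(c(24, 48), c(1, 2), baseline = 0), "baseline")
  expect_error(checkEndpoint(c(48, 24), c(1, 2), baseline = 10),
               "increasing")
})

test_that("the endpoint rule is scale- and time-unit invariant", {
  times <- c(24, 48, 72, 96, 120)
  counts <- c(350, 520, 760, 1080, 1500)
  a <- checkEndpoint(times, counts, 250)
  b <- checkEndpoint(times * 60, counts, 250)          # minutes
  c3 <- checkEndpoint(times, counts * 7.3, 250 * 7.3)  # rescaled counts
  expect_equal(a$index, b$index)
  expect_equal(a$index, c3$index)
})

test_that("simulated growth at 48 h doubling reaches 4x at about 96 h", {
  pop <- list(cancerPopulation(n0 = 250, doublingTime = 48))
  times <- seq(24, 168, by = 24)
  counts <- vapply(seq_along(times), function(i)
    simulateWellCounts(pop, 0, times[i], seed = 300 + i)$sampled, numeric(1))
  r <- checkEndpoint(times, counts, baseline = 250)
  expect_true(r$reached)
  expect_lte(abs(r$time - 96), 24)  # within one sampled timepoint
})

mkPlate <- function() {
  map <- data.frame(
    well = paste0("A", 1:20),
    plate_role = c(rep("day0", 4), rep("vehicle", 4), rep("drug", 12)),
    drug = c(rep("none", 4), rep("vehicle", 4), rep("gef", 12)),
    dose_nM = c(rep(0, 8), rep(c(10, 100, 1000), each = 4)),
    replicate = rep(1:4, 5), stringsAsFactors = FALSE)
  wt <- data.frame(
    well = map$well,
    n_positive = c(rep(250, 4), rep(1000, 4), rep(500, 4), rep(250, 4),
                   rep(250, 4)),
    n_negative = rep(500, 20),
    n_total = 0)
  wt$n_total <- wt$n_positive + wt$n_negative
  list(map = map, wt = wt)
}

test_that("percent-highest normalization divides by the top condition mean", {
  p <- mkPlate()
  nr <- normalizeResponse(p$wt, p$map, "percent_highest")
  pos <- nr[nr$population == "positive", ]
  expect_equal(pos$value[order(pos$dose_nM)], c(100, 50, 25, 25))
  ## ordering of condition means is preserved
  expect_equal(order(pos$mean), order(pos$value))
})

test_that("fold-of-day0 normalization divides by the baseline", {
  p <- mkPlate()
  b <- baselineCounts(p$wt, p$map)
  nr <- normalizeResponse(p$wt, p$map, "fold_of_day0", baseline = b)
  pos <- nr[nr$population == "positive", ]
  expect_equal(max(pos$value), 4)   # 1000 / 250
  neg <- nr[nr$population == "negative", ]
  expect_true(all(neg$value == 1))  # feeders flat at their baseline
})

test_that("all-zero counts cannot be percent-highest normalized", {
  p <- mkPlate()
  p$wt$n_positive <- 0
  p$wt$n_negative <- 0
  expect_error(normalizeResponse(p$wt, p$map, "percent_highest"),
               "all-zero")
})

test_that("the insensitive population's normalized series stays flat", {
  pops <- list(cancerPopulation(ic50 = 50), feederPopulation())
  p <- simCountPlate(pops, seed = 9)
  nr <- normalizeResponse(p$wells, p$map, "percent_highest")
  neg <- nr[nr$population == "negative", ]
  expect_lt(diff(range(neg$value)), 15)  # percent scale, sampling noise only
  st <- doseSlopeTest(neg$dose_nM[neg$dose_nM > 0],
                      neg$value[neg$dose_nM > 0])
  expect_true(st$flat)
})
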