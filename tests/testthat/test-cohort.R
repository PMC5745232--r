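test_that("success rates reproduce the published per-type percentages", {
  expect_equal(successRate(109, 373, rounded = TRUE), 29)
  expect_equal(successRate(148, 568, rounded = TRUE), 26)
  expect_equal(successRate(0, 10), 0)
  expect_equal(successRate(109, 373), 100 * 109 / 373)
  ## the whole packaged cohort table
  tab <- readCohortTable(exampleCohortFile())
  expected <- c(Breast = 15, Colorectal = 25, Endometrial = 9,
                `Head and neck` = 18, Lung = 29, Melanoma = 14,
                `Pancreatic/gallbladder` = 38, Thyroid = 29, Unknown = 33,
                Total = 26)
  expect_equal(tab$percent_rounded, unname(expected[tab$group]))
  expect_equal(tab$total[tab$group == "Total"], 568)
  ## rounding is half-away-from-zero: 6/16 = 37.5 -> 38
  expect_equal(successRate(6, 16, rounded = TRUE), 38)
})

test_that("invalid rate inputs are rejected", {
  expect_error(successRate(1, 0), "total")
  expect_error(successRate(5, 3), "finished")
  expect_error(successRate(-1, 3), "finished")
})

test_that("exact p-values match hand-enumerable tables", {
  expect_equal(fisherExact2x2(1, 0, 0, 1)$p.value, 1)
  ## margins (4,4,4,4): 34 of 70 equally-or-less-likely table orderings
  expect_equal(fisherExact2x2(3, 1, 1, 3)$p.value, 34 / 70)
})

test_that("the lung-vs-breast comparison is significant below 0.01", {
  r <- fisherExact2x2(109, 264, 16, 88)
  expect_lt(r$p.value, 0.01)
  ## independent implementation agrees
  expect_equal(r$p.value,
               stats::fisher.test(matrix(c(109, 264, 16, 88), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("p-values are symmetric under row/column swaps and transposition", {
  set.seed(5)
  for (i in 1:25) {
    t4 <- rpois(4, 8)
    if (sum(t4) == 0) next
    p <- fisherExact2x2(t4[1], t4[2], t4[3], t4[4])$p.value
    expect_equal(fisherExact2x2(t4[3], t4[4], t4[1], t4[2])$p.value, p)
    expect_equal(fisherExact2x2(t4[2], t4[1], t4[4], t4[3])$p.value, p)
    expect_equal(fisherExact2x2(t4[1], t4[3], t4[2], t4[4])$p.value, p)
    ## p is at least the probability of the observed table itself
    expect_gte(p + 1e-12,
               dhyper(t4[1], t4[1] + t4[3], t4[2] + t4[4], t4[1] + t4[2]))
  }
})

test_that("odds ratios are the sample cross-product with zero-cell flag", {
  r <- fisherExact2x2(10, 5, 2, 8)
  expect_equal(r$odds.ratio, (10 * 8) / (5 * 2))
  expect_false(r$zeroCells)
  r0 <- fisherExact2x2(3, 0, 2, 5)
  expect_true(r0$zeroCells)
  expect_true(is.infinite(r0$odds.ratio))
  expect_error(fisherExact2x2(-1, 1, 1, 1), "non-negative")
  expect_error(fisherExact2x2(0.5, 1, 1, 1), "integers")
})

test_that("group comparisons delegate to the exact test", {
  tab <- readCohortTable(exampleCohortFile())
  lb <- compareGroups(tab, "Lung", "Breast")
  expect_lt(lb$p.value, 0.01)
  expect_equal(lb$table, matrix(c(109, 264, 16, 88), 2, byrow = TRUE))
  ## melanoma vs thyroid agrees with the reference implementation
  mt <- compareGroups(tab, "Melanoma", "Thyroid")
  expect_equal(mt$p.value,
               stats::fisher.test(matrix(c(1, 6, 4, 10), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
  ## identical rows are indistinguishable
  same <- rbind(tab, data.frame(group = "LungCopy", finished = 109,
                                failed = 264, total = 373,
                                percent = tab$percent[tab$group == "Lung"],
                                percent_rounded = 29))
  expect_equal(compareGroups(same, "Lung", "LungCopy")$p.value, 1)
  expect_error(compareGroups(tab, "Lung", "Kidney"), "unknown group")
})

test_that("cohortAnalysis assembles rates and pairwise comparisons", {
  res <- cohortAnalysis(exampleCohortFile(),
                        comparisons = list(c("Lung", "Breast"),
                                           c("Melanoma", "Thyroid")))
  expect_equal(nrow(res$comparisons), 2)
  expect_lt(res$comparisons$p_value[1], 0.01)
  expect_true(all(res$rates$finished + res$rates$failed == res$rates$total))
})
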