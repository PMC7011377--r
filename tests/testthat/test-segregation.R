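test_that("observed phenotype ratios round half-up to two decimals", {
  expect_equal(phenotypeRatio(2243, 133), 16.86)
  expect_equal(phenotypeRatio(551, 169), 3.26)
  expect_equal(phenotypeRatio(3, 1), 3.00)
  expect_error(phenotypeRatio(92, 0), "all-green")
})

test_that("Yates chi-square reproduces the published segregation statistics", {
  expect_equal(roundHalfUp(chiSquareYates(2243, 133, c(15, 1)), 2), 1.62)
  expect_equal(roundHalfUp(chiSquareYates(551, 169, c(3, 1)), 2), 0.82)
  ## without the continuity correction the same counts give 1.73 and 0.90
  expect_equal(roundHalfUp(chiSquareYates(2243, 133, c(15, 1),
                                          correct = FALSE), 2), 1.73)
  expect_equal(roundHalfUp(chiSquareYates(551, 169, c(3, 1),
                                          correct = FALSE), 2), 0.90)
  ## perfect fit truncates to zero under the correction
  expect_equal(chiSquareYates(150, 10, c(15, 1)), 0)
  expect_error(chiSquareYates(0, 0, c(15, 1)), "empty")
})

test_that("chi-square is invariant under scaling the hypothesised ratio", {
  expect_equal(chiSquareYates(74, 26, c(3, 1)),
               chiSquareYates(74, 26, c(21, 7)))
  expect_equal(chiSquareYates(2243, 133, c(15, 1)),
               chiSquareYates(2243, 133, c(150, 10)))
})

test_that("families classify by goodness of fit against 3:1 and 15:1", {
  expect_equal(classifyFamily(92, 0)$class, "all_green")
  c31 <- classifyFamily(74, 26)
  expect_equal(c31$class, "seg_3_1")
  expect_lt(c31$chi2_3_1, 3.84)
  expect_gt(c31$chi2_15_1, 3.84)
  c151 <- classifyFamily(149, 11)
  expect_equal(c151$class, "seg_15_1")
  expect_lt(c151$chi2_15_1, 3.84)
  expect_gt(c151$chi2_3_1, 3.84)
  expect_equal(classifyFamily(50, 50)$class, "other")
  ## vectorised over a family table
  tab <- data.frame(family = c("a", "b"), green = c(100, 74),
                    yellow = c(0, 26))
  expect_equal(classifyFamily(tab)$class, c("all_green", "seg_3_1"))
})

test_that("digenic expectations from enumeration match brute force", {
  expect_equal(expectedComposition("F2_phenotypes"),
               c(green = 15L, yellow = 1L))
  expect_equal(expectedComposition("BC1_mutant_phenotypes"),
               c(green = 3L, yellow = 1L))
  expect_equal(expectedComposition("F23_family_types"),
               c(all_green = 7L, seg_3_1 = 4L, seg_15_1 = 4L))
  expect_equal(expectedComposition("F34_family_types"),
               c(seg_3_1 = 2L, all_green = 1L))
  expect_error(expectedComposition("nonsense"))

  ## brute force over all 16 x 16 gamete combinations
  f2 <- enumF2()
  yellow <- f2$d1 == 2 & f2$d2 == 2
  expect_equal(sum(!yellow) / sum(yellow), 15)
  ## family types of selfed green F2 plants by direct yellow-probability
  pYellow <- function(d) prod(ifelse(d == 2, 1, ifelse(d == 1, 0.25, 0)))
  ty <- apply(f2[!yellow, ], 1, function(d) {
    p <- pYellow(d)
    if (p == 0) "all_green" else if (p == 1 / 4) "seg_3_1" else "seg_15_1"
  })
  expect_equal(unname(table(ty)[c("all_green", "seg_3_1", "seg_15_1")] / 1),
               c(7, 4, 4), ignore_attr = TRUE)
})

test_that("Yates-corrected test is conservative for true-ratio counts", {
  set.seed(5)
  n <- 720
  rej <- replicate(400, {
    y <- rbinom(1, n, 0.25)
    chiSquareYates(n - y, y, c(3, 1)) >= 3.84
  })
  expect_lte(mean(rej), 0.08)
})

test_that("classification of simulated F2:3 families recovers 7:4:4", {
  ds <- simulateStudy(studyDesign(seed = 8, f23Families = 400L,
                                  generations = c("F1", "F2", "F23")),
                      sparseGenome())
  cls <- classifyFamily(phenotypeCounts(studyPopulation(ds, "F23"),
                                        byFamily = TRUE))
  pr <- prop.table(table(factor(cls$class,
                                c("all_green", "seg_3_1", "seg_15_1"))))
  expv <- c(7, 4, 4) / 15
  expect_true(all(abs(pr - expv) <= 3 * sqrt(expv * (1 - expv) / 400) + 0.02))
})

test_that("reciprocal F1 comparison distinguishes nuclear inheritance", {
  expect_equal(inferInheritanceMode(c(258, 0), c(226, 0)), "nuclear")
  expect_equal(inferInheritanceMode(c(10, 0), c(10, 0)), "nuclear")
  expect_equal(inferInheritanceMode(c(100, 0), c(0, 100)),
               "cytoplasmic_suspected")
  expect_error(inferInheritanceMode(c(0, 0), c(10, 0)), "empty")
})
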