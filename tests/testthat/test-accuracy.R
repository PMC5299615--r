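test_that("captured variance fraction has the right limits and ordering", {
  expect_equal(capturedFraction(1e9, 5000), 1, tolerance = 1e-5)
  # at M = Me the formula gives exactly 1/2 (direct evaluation)
  expect_equal(capturedFraction(3000, 3000), 3000 / (3000 + 3000))
  b <- capturedFraction(c(100, 1000, 10000, 1e5), 1000)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b < 1))
})

test_that("quantitative accuracy follows the N h2 / (N h2 + Me) law", {
  # tiny Me or huge N drive the accuracy to 1
  expect_equal(accuracyQuantitative(3000, 0.5, 1e-6), 1, tolerance = 1e-6)
  expect_equal(accuracyQuantitative(1e12, 0.5, 5000), 1, tolerance = 1e-4)
  # direct formula evaluation as an independent check
  expect_equal(accuracyQuantitative(3000, 0.5, 254),
               sqrt(3000 * 0.5 / (3000 * 0.5 + 254)), tolerance = 1e-12)
  expect_equal(accuracyPhenotypic(3000, 0.5, 254),
               sqrt(0.5) * accuracyQuantitative(3000, 0.5, 254))
  # MeEstimate objects are accepted everywhere a number is
  me <- meClosedFormGenome(populationGenome(100, nChr = 30))
  expect_equal(accuracyQuantitative(3000, 0.5, me),
               accuracyQuantitative(3000, 0.5, meValue(me)))
})

test_that("case-control accuracy has the stated limits", {
  rhoN <- vapply(c(500, 3000, 2e4, 1e6, 1e9), function(n)
    accuracyCaseControl(n, 0.5, 254, 0.1, 0.5), numeric(1))
  expect_true(all(diff(rhoN) > 0))
  expect_lt(rhoN[length(rhoN)], 1 + 1e-12)
  expect_gt(rhoN[length(rhoN)], 0.999)
  rhoMe <- vapply(c(100, 1000, 1e5, 1e9), function(me)
    accuracyCaseControl(3000, 0.5, me, 0.1, 0.5), numeric(1))
  expect_true(all(diff(rhoMe) < 0))
  expect_lt(rhoMe[length(rhoMe)], 1e-2)
  # a LiabilityModel can stand in for K
  expect_equal(accuracyCaseControl(3000, 0.5, 254, liabilityModel(0.1), 0.5),
               accuracyCaseControl(3000, 0.5, 254, 0.1, 0.5))
})

test_that("expected AUC is anchored at 1/2 and increases with accuracy", {
  expect_equal(expectedAUC(3000, 0.5, 1e12, 0.1, 0.5), 0.5, tolerance = 1e-4)
  aucMe <- vapply(c(100, 254, 1000, 5000, 21248), function(me)
    expectedAUC(3000, 0.5, me, 0.1, 0.5), numeric(1))
  expect_true(all(diff(aucMe) < 0))
  expect_true(all(aucMe > 0.5 & aucMe < 1))
  # strictly increasing in the underlying accuracy at fixed K: sweep N
  aucN <- vapply(c(100, 500, 3000, 2e4, 1e5), function(n)
    expectedAUC(n, 0.5, 254, 0.1, 0.5), numeric(1))
  expect_true(all(diff(aucN) > 0))
})

test_that("expected odds ratios degenerate to 1 at zero accuracy", {
  or <- expectedOR(3000, 0.5, 1e12, 0.1, 0.5, percentileContrast(0.2))
  expect_equal(or$oddsRatio, 1, tolerance = 1e-3)
  orPop <- expectedOR(3000, 0.5, 1e12, 0.1, 0.5, percentileContrast(0.01),
                      mode = "top_vs_population")
  expect_equal(orPop$oddsRatio, 1, tolerance = 1e-3)
  # stratum risks collapse to the prevalence
  expect_equal(or$pTop, 0.1, tolerance = 1e-3)
  expect_equal(orPop$pRef, 0.1)
})

test_that("expected quantities are monotone over design grids", {
  for (h2 in c(0.2, 0.8)) {
    or <- vapply(c(100, 1000, 10000), function(me)
      expectedOR(3000, h2, me, 0.1, 0.5)$oddsRatio, numeric(1))
    expect_true(all(diff(or) < 0))
  }
  orH2 <- vapply(c(0.1, 0.3, 0.5, 0.7), function(h2)
    expectedOR(3000, h2, 254, 0.1, 0.5)$oddsRatio, numeric(1))
  expect_true(all(diff(orH2) > 0))
})

test_that("stratum risk formulas agree with a bivariate-normal Monte Carlo", {
  set.seed(99)
  me <- meClosedFormGenome(populationGenome(100, nChr = 30))
  r <- sqrt(0.5) * accuracyCaseControl(3000, 0.5, me, 0.1, 0.5)
  n <- 5e5
  liab <- rnorm(n)
  score <- r * liab + sqrt(1 - r^2) * rnorm(n)
  case <- liab > qnorm(0.9)
  or <- expectedOR(3000, 0.5, me, 0.1, 0.5, percentileContrast(0.01),
                   mode = "top_vs_population")
  pTopMC <- mean(case[score > quantile(score, 0.99)])
  seMC <- sqrt(pTopMC * (1 - pTopMC) / (0.01 * n))
  expect_lt(abs(or$pTop - pTopMC), 4 * seMC + 0.005)
  aucMC <- observedAUC(score, case)
  expect_lt(abs(expectedAUC(3000, 0.5, me, 0.1, 0.5) - aucMC), 0.01)
})
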