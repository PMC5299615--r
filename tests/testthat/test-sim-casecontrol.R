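test_that("case-control simulator hits the design prevalence and ascertainment", {
  set.seed(71)
  cfg <- caseControlConfig(mSnps = 60, h2 = 0.5, K = 0.1, P = 0.5,
                           nDiscovery = 200, nTarget = 4000)
  rates <- replicate(12, {
    sim <- simulateCaseControl(cfg)
    expect_equal(sum(sim$discovery$status), 100)   # exactly N*P cases
    mean(sim$target$status)
  })
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.1), 3 * se + 0.005)

  sim <- simulateCaseControl(cfg, seed = 5)
  expect_length(intersect(sampleIds(sim$discovery$genotypes),
                          sampleIds(sim$target$genotypes)), 0)
  # liability-scale heritability is built in: genetic variance of the
  # unascertained target approaches h2
  expect_lt(abs(var(sim$target$gTrue) - 0.5), 0.1)
  # cases carry higher genetic liability than controls in the target
  expect_gt(mean(sim$target$gTrue[sim$target$status == 1]),
            mean(sim$target$gTrue[sim$target$status == 0]))
})

test_that("a weak architecture pushes discrimination toward chance level", {
  set.seed(72)
  cfg <- caseControlConfig(mSnps = 40, h2 = 0.02, K = 0.1, P = 0.5,
                           nDiscovery = 150, nTarget = 6000)
  sim <- simulateCaseControl(cfg)
  auc <- observedAUC(sim$target$gTrue, sim$target$status)
  # even the *true* genetic value discriminates only weakly: its
  # liability correlation is sqrt(h2), giving an AUC just above 1/2
  lia <- liabilityModel(0.1)
  r <- sqrt(cfg$h2)
  expected <- pnorm(r * (lia@iCase - lia@iControl) /
                      sqrt(2 - r^2 * (lia@iCase * (lia@iCase - lia@threshold) +
                                      lia@iControl * (lia@iControl - lia@threshold))))
  expect_lt(abs(auc - expected), 0.04)
  expect_lt(auc, 0.65)
})

test_that("dichotomization selects the stated case and control counts", {
  set.seed(73)
  y <- setNames(rnorm(1000), sprintf("i%d", 1:1000))
  d <- dichotomizePhenotype(y, K = 0.1, P = 0.5)
  expect_equal(sum(d$status == 1), 100)
  expect_equal(sum(d$status == 0), 100)   # 11.1% of the remaining 900
  # cases are exactly the top decile
  expect_setequal(names(d$status)[d$status == 1],
                  names(sort(y, decreasing = TRUE))[1:100])
  # median split keeps everyone
  d2 <- dichotomizePhenotype(y, K = 0.5, P = 0.5)
  expect_equal(sum(d2$status == 1), 500)
  expect_equal(sum(d2$status == 0), 500)
  expect_error(dichotomizePhenotype(rep(1, 50)), "constant")
  expect_error(dichotomizePhenotype(y, K = 0.5, P = 0.2), "infeasible")
})

test_that("family splits assign sides as designed", {
  fam <- rep(sprintf("fam%d", 1:10), each = 10)
  names(fam) <- sprintf("ind%d", 1:100)
  set.seed(74)
  fw <- splitFamilyWise(fam, 0.8)
  expect_length(fw$discovery, 80)
  # whole families stay together
  expect_true(all(table(fam[fw$discovery]) == 10))
  wf <- splitWithinFamily(fam, 0.8)
  expect_setequal(c(wf$discovery, wf$target), names(fam))
  expect_gt(length(wf$discovery), qbinom(0.001, 100, 0.8))
  expect_lt(length(wf$discovery), qbinom(0.999, 100, 0.8))
  # almost every family is split across the two sides
  expect_gt(sum(tapply(names(fam) %in% wf$discovery, fam,
                       function(x) any(x) && !all(x))), 5)
  expect_error(splitFamilyWise(rep("f1", 8)), "empty side")
  # seeded reproducibility
  set.seed(11); a <- splitWithinFamily(fam, 0.8)
  set.seed(11); b <- splitWithinFamily(fam, 0.8)
  expect_identical(a, b)
})

test_that("sib-family genotypes show pedigree-level relatedness", {
  sib <- simulateSibFamilies(nFamilies = 30, famSize = 4, mSnps = 1500,
                             seed = 75)
  grm <- buildGRM(sib$genotypes)
  A <- as.matrix(grm)
  sameFam <- outer(sib$family, sib$family, "==")
  diag(sameFam) <- FALSE
  up <- upper.tri(A)
  expect_equal(mean(A[up & sameFam]), 0.5, tolerance = 0.05)
  # in-sample frequency centering pulls unrelated pairs slightly below 0,
  # by about (n + sib-pair excess)/(number of off-diagonal cells)
  expect_equal(mean(A[up & !sameFam]), 0, tolerance = 0.05)
  expect_gt(mean(A[up & sameFam]) - mean(A[up & !sameFam]), 0.4)
  expect_equal(var(sib$gTrue), 0.5, tolerance = 1e-6)
})

test_that("within-family designs shrink Me relative to family-wise designs", {
  sib <- simulateSibFamilies(nFamilies = 50, famSize = 6, mSnps = 1000,
                             seed = 76)
  grm <- buildGRM(sib$genotypes)
  set.seed(77)
  fw <- splitFamilyWise(sib$family, 0.8)
  wf <- splitWithinFamily(sib$family, 0.8)
  meFW <- meValue(meFromGRM(grm, fw$discovery, fw$target))
  meWF <- meValue(meFromGRM(grm, wf$discovery, wf$target))
  expect_lt(meWF, meFW)
})
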