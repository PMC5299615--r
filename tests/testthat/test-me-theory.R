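test_that("SNP correlation matrix follows the spacing convention", {
  S <- snpCorrelationMatrix(populationGenome(100, mutation = FALSE), M = 3)
  m <- as.matrix(S)
  expect_equal(diag(m), rep(1, 3))
  # endpoints span the chromosome: r2 at the full length L = 1
  expect_equal(m[1, 3], 1 / (1 + 4 * 100 * 1))
  expect_equal(m[1, 2], 1 / (1 + 4 * 100 * 0.5))
  expect_true(isSymmetric(unname(m)))
  expect_error(snpCorrelationMatrix(populationGenome(100), M = 1), "M must")
  expect_error(
    snpCorrelationMatrix(populationGenome(100, nChr = 2), M = 10),
    "single chromosome")
})

test_that("weight and matrix-mean estimators solve the small cases exactly", {
  expect_equal(meValue(meFromWeights(diag(7))), 7)
  expect_equal(meValue(meMatrixMean(diag(4))), 4)
  # perfect LD: one segment (regularized solve)
  ones <- matrix(1, 5, 5)
  expect_warning(meOnes <- meFromWeights(ones), "singular")
  expect_equal(meValue(meOnes), 1, tolerance = 1e-4)
  # hand-solved 2x2 system: w = (1/(1+rho), 1/(1+rho)), Me = 2/(1+rho)
  for (rho in c(0.1, 0.5, 0.9)) {
    S2 <- matrix(c(1, rho, rho, 1), 2)
    expect_equal(meValue(meFromWeights(S2)), 2 / (1 + rho), tolerance = 1e-10)
    expect_equal(meValue(meMatrixMean(S2)), 2 / (1 + rho), tolerance = 1e-12)
  }
})

test_that("numeric estimators converge to the closed form and to each other", {
  # the discrete matrix mean approaches the integral limit once the SNP
  # spacing is well below the LD scale 1/(4 Ne); at M = 5000 that holds
  # comfortably for Ne = 100 and only to first order for Ne = 1000
  for (Ne in c(100, 1000)) {
    spec <- populationGenome(Ne, mutation = TRUE)
    closed <- meValue(meClosedFormSingle(spec))
    numeric5k <- meValue(meMatrixMean(snpCorrelationMatrix(spec, 5000)))
    expect_lt(abs(numeric5k - closed) / closed, if (Ne <= 100) 0.01 else 0.04)
  }
  spec <- populationGenome(100, mutation = TRUE)
  S <- snpCorrelationMatrix(spec, 2000)
  wgt <- meValue(meFromWeights(S))
  avg <- meValue(meMatrixMean(S))
  expect_lt(abs(wgt - avg) / avg, 0.05)
  # frozen convergence point: Ne = 100, L = 1, mutation-corrected
  expect_equal(meValue(meClosedFormSingle(spec)), 46.19, tolerance = 1e-3)
})

test_that("closed form behaves at the boundaries and is monotone in Ne", {
  # a vanishing map length collapses to r2(0): one segment under the
  # drift-only formula, two under the mutation-corrected one (r2(0) = 1/2)
  tiny <- meClosedFormSingle(populationGenome(100, chrLength = 1e-6,
                                              mutation = FALSE))
  expect_equal(meValue(tiny), 1, tolerance = 1e-3)
  tinyMut <- meClosedFormSingle(populationGenome(100, chrLength = 1e-6))
  expect_equal(meValue(tinyMut), 2, tolerance = 1e-3)
  grid <- c(50, 100, 500, 1000, 5000)
  vals <- vapply(grid, function(ne)
    meValue(meClosedFormSingle(populationGenome(ne))), numeric(1))
  expect_true(all(diff(vals) > 0))
  genomeVals <- vapply(grid, function(ne)
    meValue(meClosedFormGenome(populationGenome(ne, nChr = 30))), numeric(1))
  expect_true(all(diff(genomeVals) > 0))
})

test_that("genome closed form reduces to one chromosome and to the harmonic identity", {
  spec1 <- populationGenome(300, nChr = 1, chrLength = 2)
  expect_equal(meValue(meClosedFormGenome(spec1)),
               meValue(meClosedFormSingle(spec1)), tolerance = 1e-12)
  spec <- populationGenome(500, nChr = 22, chrLength = 1.5)
  meG <- meValue(meClosedFormGenome(spec))
  meS <- meValue(meClosedFormSingle(populationGenome(500, chrLength = 1.5)))
  n <- 22
  expect_equal(1 / meG, (n * (1 / meS) + n * (n - 1) / (3 * 500)) / n^2,
               tolerance = 1e-12)
})

test_that("the five reference genome-wide Me values are reproduced", {
  ne <- c(100, 500, 2000, 5000, 10000)
  me <- vapply(ne, function(x)
    meValue(meClosedFormGenome(populationGenome(x, nChr = 30, chrLength = 1,
                                                mutation = TRUE))), numeric(1))
  expect_equal(round(me), c(254, 1188, 4506, 10891, 21248))
})
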