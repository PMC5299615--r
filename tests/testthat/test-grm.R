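test_that("GRM standardization matches hand computation", {
  # one SNP, dosages 0 and 2: p = 0.5, Z = (-1, 1)/sqrt(0.5)
  g <- genotypeMatrix(matrix(c(0, 2), 2, 1,
                             dimnames = list(c("a", "b"), "s1")))
  A <- as.matrix(buildGRM(g))
  expect_equal(A["a", "a"], 2)
  expect_equal(A["a", "b"], -2)
  # identical genotypes give identical rows
  set.seed(1)
  geno <- hweGenotypes(3, 50)
  geno[2, ] <- geno[1, ]
  # chance-monomorphic SNPs at n = 3 are dropped with a warning by design
  A <- as.matrix(suppressWarnings(buildGRM(genotypeMatrix(geno))))
  expect_equal(A[1, 2], A[1, 1])
  expect_equal(A[2, 2], A[1, 1])
})

test_that("monomorphic SNPs are dropped and all-monomorphic input errors", {
  geno <- cbind(a = c(2, 2, 2), b = c(0, 1, 2))
  rownames(geno) <- c("x", "y", "z")
  expect_warning(grm <- buildGRM(genotypeMatrix(geno)), "monomorphic")
  expect_equal(grm@nSnps, 1)
  mono <- genotypeMatrix(matrix(2, 3, 2, dimnames = list(c("x", "y", "z"), NULL)))
  expect_error(suppressWarnings(buildGRM(mono)), "monomorphic")
})

test_that("off-diagonal relationships of unrelated individuals scale as 1/m", {
  set.seed(7)
  n <- 60
  offDiagVar <- vapply(c(500, 2000, 8000), function(m) {
    A <- as.matrix(buildGRM(genotypeMatrix(hweGenotypes(n, m))))
    off <- A[lower.tri(A)]
    # in-sample allele frequencies center each column of Z, which pins the
    # mean off-diagonal near -1/(n-1) rather than 0
    expect_lt(abs(mean(off) + 1 / (n - 1)), 0.01)
    var(off)
  }, numeric(1))
  fit <- lm(log(offDiagVar) ~ log(c(500, 2000, 8000)))
  expect_lt(abs(coef(fit)[2] + 1), 0.1)
  # and the reciprocal variance recovers the SNP count
  expect_lt(abs(1 / offDiagVar[1] - 500) / 500, 0.2)
})

test_that("meFromGRM pins the pooled-block definition and its errors", {
  set.seed(11)
  geno <- genotypeMatrix(hweGenotypes(100, 5000))
  grm <- buildGRM(geno)
  ids <- sampleIds(grm)
  disc <- ids[1:50]; targ <- ids[51:100]
  me <- meFromGRM(grm, disc, targ)
  expect_s4_class(me, "MeEstimate")
  expect_equal(meMethod(me), "grm_variance")
  # independent SNPs: Me is the SNP count up to Monte-Carlo error
  expect_lt(abs(meValue(me) - 5000) / 5000, 0.15)
  # pooled population-variance definition, computed independently
  B <- as.matrix(grm)[targ, disc]
  expect_equal(meValue(me), 1 / (mean(B^2) - mean(B)^2), tolerance = 1e-10)
  expect_length(me@details$perTargetVariance, 50)
  # permuting individuals within the sets changes nothing
  me2 <- meFromGRM(grm, sample(disc), sample(targ))
  expect_equal(meValue(me2), meValue(me))
  # degenerate inputs
  expect_error(meFromGRM(grm, disc, disc[1]), "disjoint")
  expect_error(meFromGRM(grm, character(), targ), "nonempty")
  flat <- new("Grm", values = matrix(0.5, 4, 4,
                dimnames = list(letters[1:4], letters[1:4])), nSnps = 10)
  expect_error(meFromGRM(flat, c("a", "b"), c("c", "d")), "zero variance")
})

test_that("target ranking prefers individuals with close discovery relatives", {
  set.seed(21)
  sib <- simulateSibFamilies(nFamilies = 10, famSize = 4, mSnps = 800)
  grm <- suppressWarnings(buildGRM(sib$genotypes))
  ids <- sampleIds(grm)
  # discovery: first three members of each family; target: the fourth
  # member of families 1-5 plus five unrelated singletons drawn fresh
  fam <- sib$family
  discovery <- ids[ave(seq_along(ids), fam, FUN = seq_along) <= 3]
  target <- setdiff(ids, discovery)
  ranked <- targetVarianceRanking(grm, discovery, target, 1.0)
  expect_setequal(ranked, target)
  # a target with full sibs in discovery outranks targets from families
  # whose sibs were withheld from discovery
  v <- me <- meFromGRM(grm, discovery, target)@details$perTargetVariance
  expect_equal(names(sort(v, decreasing = TRUE))[seq_len(3)],
               targetVarianceRanking(grm, discovery, target, 3 / length(target)))
  expect_length(targetVarianceRanking(grm, discovery, target, 0.25),
                floor(length(target) * 0.25))
})

test_that("relatedness pruning is greedy and deterministic", {
  ids <- c("a", "b", "c", "d", "e")
  A <- diag(5) * 0.98 + 0.02
  dimnames(A) <- list(ids, ids)
  # full-sib pair (a, b) and a related 3-clique (c, d, e)
  A["a", "b"] <- A["b", "a"] <- 0.5
  A["c", "d"] <- A["d", "c"] <- 0.3
  A["c", "e"] <- A["e", "c"] <- 0.3
  A["d", "e"] <- A["e", "d"] <- 0.3
  grm <- new("Grm", values = A, nSnps = 100)
  kept <- pruneRelatedness(grm, 0.025)
  expect_length(setdiff(c("a", "b"), kept), 1)   # one sib removed
  expect_length(intersect(c("c", "d", "e"), kept), 1)  # clique cut to one
  expect_setequal(pruneRelatedness(grm, 0.9), ids)
})

test_that("GCTA text round trip is lossless and parsing is strict", {
  set.seed(31)
  grm <- suppressWarnings(buildGRM(genotypeMatrix(hweGenotypes(8, 300))))
  prefix <- file.path(withr::local_tempdir(), "toy")
  writeGRM(grm, prefix)
  back <- readGRM(prefix)
  expect_equal(as.matrix(back), as.matrix(grm), tolerance = 1e-9)
  expect_equal(back@nSnps, grm@nSnps)
  expect_equal(sampleIds(back), sampleIds(grm))

  # minimal hand-written 2-individual file
  writeLines(c("1\t1\t100\t1.0", "2\t1\t100\t0.25", "2\t2\t100\t1.0"),
             paste0(prefix, "2.grm"))
  writeLines(c("f1\tA", "f2\tB"), paste0(prefix, "2.grm.id"))
  g2 <- readGRM(paste0(prefix, "2"))
  expect_equal(as.matrix(g2)["A", "B"], 0.25)

  writeLines(c("1\t1\t100\t1.0", "2\t1\t0.25", "2\t2\t100\t1.0"),
             paste0(prefix, "3.grm"))
  writeLines(c("f1\tA", "f2\tB"), paste0(prefix, "3.grm.id"))
  expect_error(readGRM(paste0(prefix, "3")), "line 2")
})

test_that("dosage tables round-trip through the PLINK-raw-style format", {
  set.seed(41)
  g <- genotypeMatrix(hweGenotypes(6, 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDosage(g, path)
  back <- readDosage(path)
  expect_equal(dosages(back), dosages(g))
  expect_equal(sampleIds(back), sampleIds(g))
})
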