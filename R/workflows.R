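#' Analytic theory curves over a grid of effective population sizes
#'
#' For each Ne in the grid, computes the closed-form genome-wide Me and the
#' expected prediction performance of a discovery sample of size N: the
#' true-score and phenotype correlations for a quantitative trait, and for a
#' case-control design of prevalence K and ascertainment P the expected AUC,
#' the top-vs-bottom odds ratio and the top-vs-population odds ratio.
#' Deterministic: no random numbers are consumed.
#'
#' @param neGrid numeric vector of effective population sizes (may be empty).
#' @param nChr,chrLength,mutation genome layout passed to
#'   [populationGenome()].
#' @param h2 heritability (liability scale for the case-control columns).
#' @param N discovery sample size.
#' @param K population prevalence.
#' @param P case proportion in the discovery sample.
#' @param topBottomFraction tail fraction for the top-vs-bottom odds ratio.
#' @param topPopFraction tail fraction for the top-vs-population odds ratio.
#' @return a data.frame with columns `Ne`, `Me`, `rTrue`, `rPheno`, `auc`,
#'   `orTopBottom`, `orTopPop`.
#' @examples
#' runTheoryCurves(c(100, 1000, 10000))
#' @export
runTheoryCurves <- function(neGrid, nChr = 30, chrLength = 1, mutation = TRUE,
                            h2 = 0.5, N = 3000, K = 0.1, P = 0.5,
                            topBottomFraction = 0.2, topPopFraction = 0.01) {
  if (!is.numeric(neGrid)) stop("neGrid must be numeric")
  rows <- lapply(neGrid, function(ne) {
    me <- meClosedFormGenome(populationGenome(ne, nChr, chrLength, mutation))
    data.frame(
      Ne = ne, Me = meValue(me),
      rTrue = accuracyQuantitative(N, h2, me),
      rPheno = accuracyPhenotypic(N, h2, me),
      auc = expectedAUC(N, h2, me, K, P),
      orTopBottom = expectedOR(N, h2, me, K, P,
                               percentileContrast(topBottomFraction))$oddsRatio,
      orTopPop = expectedOR(N, h2, me, K, P,
                            percentileContrast(topPopFraction),
                            mode = "top_vs_population")$oddsRatio)
  })
  if (!length(rows))
    return(data.frame(Ne = numeric(), Me = numeric(), rTrue = numeric(),
                      rPheno = numeric(), auc = numeric(),
                      orTopBottom = numeric(), orTopPop = numeric()))
  do.call(rbind, rows)
}

empiricalInterval <- function(x) {
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  mean(x) + c(-1, 1) * 1.96 * stats::sd(x)
}

validationRow <- function(quantity, observed, expected) {
  int <- empiricalInterval(observed)
  data.frame(quantity = quantity, observedMean = mean(observed),
             observedSD = stats::sd(observed), expected = expected,
             lower = int[1], upper = int[2],
             covered = if (anyNA(int)) NA else expected >= int[1] & expected <= int[2],
             stringsAsFactors = FALSE)
}

# one gene-dropping replicate: empirical Me and observed GBLUP accuracy
genedropReplicate <- function(cfg, seed) {
  sim <- simulateGenedrop(cfg, seed = seed)
  geno <- genotypeMatrix(rbind(dosages(sim$discovery), dosages(sim$target)))
  grm <- buildGRM(geno)
  discIds <- sampleIds(sim$discovery)
  targIds <- sampleIds(sim$target)
  meObs <- meFromGRM(grm, discIds, targIds)
  y <- stats::setNames(sim$phenotypes$phenotype, sim$phenotypes$id)
  scores <- gblupPredict(grm, y, discIds, targIds, h2 = cfg$h2)
  gTrue <- stats::setNames(sim$truth$g, sim$truth$id)[targIds]
  c(me = meValue(meObs), accuracy = stats::cor(gTrue, scores$score))
}

# one case-control replicate: observed AUC and odds ratios in the target set
caseControlReplicate <- function(cfg, seed) {
  sim <- simulateCaseControl(cfg, seed = seed)
  geno <- genotypeMatrix(rbind(dosages(sim$discovery$genotypes),
                               dosages(sim$target$genotypes)))
  discIds <- sampleIds(sim$discovery$genotypes)
  targIds <- sampleIds(sim$target$genotypes)
  scores <- snpBlupPredict(geno, sim$discovery$status, discIds, targIds,
                           h2 = cfg$h2)
  st <- sim$target$status[scores$id]
  c(auc = observedAUC(scores$score, st),
    orTopBottom = observedOR(scores$score, st, 0.2)$oddsRatio,
    orTopPop = observedOR(scores$score, st, 0.01,
                          reference = "population")$oddsRatio)
}

#' Replicated simulation-versus-theory validation
#'
#' Runs one of the two validation simulations for a number of replicates and
#' compares observed statistics with their theoretical expectations. For the
#' gene-dropping simulation the compared quantities are the empirical Me from
#' the discovery-target GRM block (expected: closed-form Me at the simulated
#' Ne and genome) and the GBLUP accuracy in the target set (expected:
#' [accuracyQuantitative()]). For the case-control simulation they are the
#' observed AUC and the two percentile odds ratios (expected:
#' [expectedAUC()], [expectedOR()] with Me equal to the number of simulated
#' independent SNPs). Each replicate uses the deterministic seed
#' `seed + replicate`.
#'
#' @param sim `"genedrop"` or `"casecontrol"`.
#' @param config a [genedropConfig()] or [caseControlConfig()] matching
#'   `sim`.
#' @param replicates number of replicates (with 1 replicate the empirical
#'   interval and coverage flag are NA).
#' @param seed integer base seed.
#' @return a data.frame with one row per quantity: observed mean and SD, the
#'   expected value, the empirical 95% interval (mean +/- 1.96 SD) and
#'   whether it covers the expectation.
#' @export
runValidation <- function(sim = c("genedrop", "casecontrol"), config,
                          replicates = 20, seed = 1) {
  sim <- match.arg(sim)
  stopifnot(replicates >= 1)
  if (sim == "genedrop") {
    stopifnot(inherits(config, "genedropConfig"))
    reps <- vapply(seq_len(replicates),
                   function(r) genedropReplicate(config, seed + r),
                   numeric(2))
    # drift-only r^2: a per-site rate of 1e-8 over a few hundred
    # generations contributes no mutational LD, so the 1/(1 + 4*Ne*c) form
    # is the matching expectation for gene-dropped genotypes
    spec <- populationGenome(config$Ne, config$nChr, config$chrLength,
                             mutation = FALSE)
    meExp <- meValue(if (config$nChr == 1L) meClosedFormSingle(spec)
                     else meClosedFormGenome(spec))
    rbind(validationRow("Me", reps["me", ], meExp),
          validationRow("accuracy", reps["accuracy", ],
                        accuracyQuantitative(config$nDiscovery, config$h2,
                                             meExp)))
  } else {
    stopifnot(inherits(config, "caseControlConfig"))
    reps <- vapply(seq_len(replicates),
                   function(r) caseControlReplicate(config, seed + r),
                   numeric(3))
    me <- config$mSnps
    rbind(
      validationRow("auc", reps["auc", ],
                    expectedAUC(config$nDiscovery, config$h2, me,
                                config$K, config$P)),
      validationRow("orTopBottom", reps["orTopBottom", ],
                    expectedOR(config$nDiscovery, config$h2, me, config$K,
                               config$P, percentileContrast(0.2))$oddsRatio),
      validationRow("orTopPop", reps["orTopPop", ],
                    expectedOR(config$nDiscovery, config$h2, me, config$K,
                               config$P, percentileContrast(0.01),
                               mode = "top_vs_population")$oddsRatio))
  }
}
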