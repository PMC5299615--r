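#' Configuration for the liability-threshold case-control simulator
#'
#' Parameters of the independent-SNP disease simulation: `mSnps` unlinked
#' biallelic SNPs (allele frequencies uniform on 0.05-0.95, Hardy-Weinberg
#' genotypes) with normally distributed effects on standardized dosages
#' scaled so the genetic liability variance equals `h2`; liability is genetic
#' plus normal residual and individuals are affected when it exceeds the
#' prevalence-K threshold. The discovery sample over-ascertains cases to a
#' proportion `P` by rejection sampling from the population; the target is an
#' unascertained population sample. Because the SNPs are independent, `mSnps`
#' plays the role of the effective number of chromosome segments. Defaults
#' follow the case-control validation design: Me = 254, h2 = 0.5, K = 0.1,
#' P = 0.5, N = 3000 discovery and 30,000 target individuals.
#'
#' @param mSnps number of independent SNPs (the simulated Me).
#' @param h2 heritability on the liability scale.
#' @param K population prevalence.
#' @param P case proportion in the discovery sample.
#' @param nDiscovery,nTarget sample sizes.
#' @param drawCap maximum number of population draws allowed while
#'   assembling the ascertained discovery sample, as a multiple of
#'   `nDiscovery / K`.
#' @return a validated config list of class `"caseControlConfig"`.
#' @export
caseControlConfig <- function(mSnps = 254, h2 = 0.5, K = 0.1, P = 0.5,
                              nDiscovery = 3000, nTarget = 30000,
                              drawCap = 50) {
  cfg <- list(mSnps = as.integer(mSnps), h2 = h2, K = K, P = P,
              nDiscovery = as.integer(nDiscovery),
              nTarget = as.integer(nTarget), drawCap = drawCap)
  stopifnot(cfg$mSnps >= 1, cfg$h2 > 0, cfg$h2 < 1, cfg$K > 0, cfg$K < 1,
            cfg$P > 0, cfg$P < 1, cfg$nDiscovery >= 2, cfg$nTarget >= 2)
  class(cfg) <- "caseControlConfig"
  cfg
}

# draw n population individuals: dosages, true genetic value, status
drawPopulation <- function(n, p, beta, h2, threshold, idPrefix, from = 1L) {
  m <- length(p)
  geno <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  Z <- sweep(geno, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  g <- as.numeric(Z %*% beta)
  liab <- g + stats::rnorm(n, 0, sqrt(1 - h2))
  rownames(geno) <- sprintf("%s%d", idPrefix, from - 1L + seq_len(n))
  list(geno = geno, g = g, status = as.integer(liab > threshold))
}

#' Simulate liability-threshold case-control data
#'
#' Generates an ascertained discovery sample (cases over-sampled to
#' proportion `P`) and an unascertained target population sample under the
#' independent-SNP liability threshold model described in
#' [caseControlConfig()].
#'
#' @param config a [caseControlConfig()].
#' @param seed optional integer seed.
#' @return a list with elements `discovery` and `target`, each a list of
#'   `genotypes` ([GenotypeMatrix-class]), `status` (named 0/1 vector) and
#'   `gTrue` (named true genetic liabilities); plus `effects` (per-SNP
#'   standardized effects) and `alleleFreq`.
#' @export
simulateCaseControl <- function(config, seed = NULL) {
  stopifnot(inherits(config, "caseControlConfig"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  lia <- liabilityModel(cfg$K)
  p <- stats::runif(cfg$mSnps, 0.05, 0.95)
  beta <- stats::rnorm(cfg$mSnps, 0, sqrt(cfg$h2 / cfg$mSnps))

  nCase <- round(cfg$nDiscovery * cfg$P)
  nControl <- cfg$nDiscovery - nCase
  maxDraws <- ceiling(cfg$drawCap * cfg$nDiscovery / cfg$K)
  drawn <- 0L
  caseG <- list(); caseV <- list(); ctrlG <- list(); ctrlV <- list()
  nCaseGot <- 0L; nCtrlGot <- 0L
  while (nCaseGot < nCase || nCtrlGot < nControl) {
    if (drawn >= maxDraws)
      stop("case quota not reached within the draw cap; increase drawCap")
    chunk <- min(max(2000L, ceiling((nCase - nCaseGot) / cfg$K)),
                 maxDraws - drawn)
    pop <- drawPopulation(chunk, p, beta, cfg$h2, lia@threshold, "tmp",
                          from = drawn + 1L)
    drawn <- drawn + chunk
    isCase <- pop$status == 1L
    if (nCaseGot < nCase && any(isCase)) {
      take <- which(isCase)[seq_len(min(sum(isCase), nCase - nCaseGot))]
      caseG[[length(caseG) + 1L]] <- pop$geno[take, , drop = FALSE]
      caseV[[length(caseV) + 1L]] <- pop$g[take]
      nCaseGot <- nCaseGot + length(take)
    }
    if (nCtrlGot < nControl && any(!isCase)) {
      take <- which(!isCase)[seq_len(min(sum(!isCase), nControl - nCtrlGot))]
      ctrlG[[length(ctrlG) + 1L]] <- pop$geno[take, , drop = FALSE]
      ctrlV[[length(ctrlV) + 1L]] <- pop$g[take]
      nCtrlGot <- nCtrlGot + length(take)
    }
  }
  discGeno <- rbind(do.call(rbind, caseG), do.call(rbind, ctrlG))
  discStatus <- c(rep(1L, nCase), rep(0L, nControl))
  discG <- c(unlist(caseV), unlist(ctrlV))
  ids <- sprintf("d%d", seq_len(cfg$nDiscovery))
  rownames(discGeno) <- ids
  names(discStatus) <- names(discG) <- ids

  targ <- drawPopulation(cfg$nTarget, p, beta, cfg$h2, lia@threshold, "t")
  targStatus <- targ$status
  names(targStatus) <- rownames(targ$geno)
  targG <- targ$g
  names(targG) <- rownames(targ$geno)

  snpIds <- sprintf("snp%d", seq_len(cfg$mSnps))
  colnames(discGeno) <- colnames(targ$geno) <- snpIds
  list(
    discovery = list(genotypes = genotypeMatrix(discGeno),
                     status = discStatus, gTrue = discG),
    target = list(genotypes = genotypeMatrix(targ$geno),
                  status = targStatus, gTrue = targG),
    effects = beta, alleleFreq = p)
}

#' Dichotomize a quantitative phenotype into case-control status
#'
#' Labels the top `K` fraction of phenotypes as cases and samples controls
#' from the remainder so that the case proportion among selected individuals
#' equals `P`. Ties at the cut are broken by stable sort order.
#'
#' @param values named numeric vector of phenotypes (names are ids; generated
#'   if absent).
#' @param K fraction treated as cases (mimicking a prevalence).
#' @param P case proportion among the selected individuals.
#' @return a list with `ids` (selected individuals, cases first) and
#'   `status` (named 0/1 vector over the selected individuals).
#' @export
dichotomizePhenotype <- function(values, K = 0.1, P = 0.5) {
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  n <- length(values)
  if (is.null(names(values))) names(values) <- sprintf("ind%d", seq_len(n))
  if (diff(range(values)) == 0)
    stop("phenotype is constant; ranking is undefined")
  nCase <- round(n * K)
  if (nCase < 1) stop("K too small for the sample size")
  ordDesc <- order(-values)          # stable: ties keep input order
  caseIds <- names(values)[ordDesc[seq_len(nCase)]]
  rest <- names(values)[ordDesc[-seq_len(nCase)]]
  nControl <- round(nCase * (1 - P) / P)
  if (nControl > length(rest))
    stop(sprintf("infeasible P: need %d controls but only %d candidates",
                 nControl, length(rest)))
  controlIds <- if (nControl == length(rest)) rest else sample(rest, nControl)
  status <- c(stats::setNames(rep(1L, nCase), caseIds),
              stats::setNames(rep(0L, nControl), controlIds))
  list(ids = c(caseIds, controlIds), status = status)
}

splitCheck <- function(disc, targ, what) {
  if (!length(disc) || !length(targ))
    stop(sprintf("%s split produced an empty side even after resampling", what))
  list(discovery = disc, target = targ)
}

#' Family-wise discovery/target split
#'
#' Assigns whole families to the discovery or target side: a fraction of the
#' families is sampled into discovery and the remaining families form the
#' target. Discovery and target then share only distant ancestry (a
#' large-Ne design).
#'
#' @param familyIds vector of family labels, named by individual id (names
#'   generated if absent).
#' @param fraction fraction of families assigned to discovery.
#' @return list with `discovery` and `target` id vectors.
#' @seealso [splitWithinFamily()]
#' @export
splitFamilyWise <- function(familyIds, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(names(familyIds)))
    names(familyIds) <- sprintf("ind%d", seq_along(familyIds))
  fams <- unique(familyIds)
  pick <- function() {
    nDisc <- round(length(fams) * fraction)
    discFams <- sample(fams, nDisc)
    list(disc = names(familyIds)[familyIds %in% discFams],
         targ = names(familyIds)[!familyIds %in% discFams])
  }
  s <- pick()
  if (!length(s$disc) || !length(s$targ)) s <- pick()
  splitCheck(s$disc, s$targ, "family-wise")
}

#' Within-family discovery/target split
#'
#' Assigns each individual independently to the discovery side with the given
#' probability, so families are split across the two sides and discovery and
#' target share recent common ancestors (a small-Ne design).
#'
#' @inheritParams splitFamilyWise
#' @param fraction per-individual probability of being a discovery sample.
#' @return list with `discovery` and `target` id vectors.
#' @export
splitWithinFamily <- function(familyIds, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(names(familyIds)))
    names(familyIds) <- sprintf("ind%d", seq_along(familyIds))
  pick <- function() {
    disc <- stats::runif(length(familyIds)) < fraction
    list(disc = names(familyIds)[disc], targ = names(familyIds)[!disc])
  }
  s <- pick()
  if (!length(s$disc) || !length(s$targ)) s <- pick()
  splitCheck(s$disc, s$targ, "within-family")
}

#' Simulate genotypes and a polygenic trait for full-sib families
#'
#' Builds `nFamilies` independent full-sib families: two unobserved parents
#' per family with Hardy-Weinberg genotypes at unlinked SNPs (frequencies
#' uniform on 0.1-0.9) and `famSize` offspring receiving one allele from each
#' parent per SNP. A polygenic trait with heritability `h2` is simulated from
#' all SNPs. Useful as a synthetic stand-in for family-structured cohorts
#' when contrasting family-wise and within-family prediction designs.
#'
#' @param nFamilies number of families.
#' @param famSize offspring per family.
#' @param mSnps number of unlinked SNPs.
#' @param h2 trait heritability.
#' @param seed optional integer seed.
#' @return a list with `genotypes` ([GenotypeMatrix-class]), `family` (named
#'   family labels), `phenotype` and `gTrue` (named vectors).
#' @export
simulateSibFamilies <- function(nFamilies = 60, famSize = 6, mSnps = 500,
                                h2 = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nFamilies >= 2, famSize >= 1, mSnps >= 2, h2 > 0, h2 < 1)
  p <- stats::runif(mSnps, 0.1, 0.9)
  n <- nFamilies * famSize
  geno <- matrix(0L, n, mSnps)
  family <- character(n)
  row <- 0L
  for (f in seq_len(nFamilies)) {
    par1 <- stats::rbinom(mSnps, 2L, p)
    par2 <- stats::rbinom(mSnps, 2L, p)
    for (k in seq_len(famSize)) {
      row <- row + 1L
      geno[row, ] <- stats::rbinom(mSnps, 1L, par1 / 2) +
                     stats::rbinom(mSnps, 1L, par2 / 2)
      family[row] <- sprintf("fam%d", f)
    }
  }
  ids <- sprintf("ind%d", seq_len(n))
  rownames(geno) <- ids
  colnames(geno) <- sprintf("snp%d", seq_len(mSnps))
  names(family) <- ids
  pObs <- colMeans(geno) / 2
  poly <- pObs > 0 & pObs < 1
  Z <- sweep(geno[, poly, drop = FALSE], 2L, 2 * pObs[poly], "-")
  Z <- sweep(Z, 2L, sqrt(2 * pObs[poly] * (1 - pObs[poly])), "/")
  gRaw <- as.numeric(Z %*% stats::rnorm(sum(poly)))
  g <- gRaw / stats::sd(gRaw) * sqrt(h2)
  y <- g + stats::rnorm(n, 0, sqrt(1 - h2))
  names(g) <- names(y) <- ids
  list(genotypes = genotypeMatrix(geno), family = family,
       phenotype = y, gTrue = g)
}
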