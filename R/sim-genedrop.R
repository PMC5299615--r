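#' Configuration for the gene-dropping simulator
#'
#' Parameters of the forward-in-time gene-dropping simulation: a random-mating
#' monoecious population of `Ne` breeders evolved for `generations`
#' generations with recombination (crossover count Poisson(`chrLength`) per
#' gamete and chromosome, uniform positions, no interference) and symmetric
#' per-site mutation. Founder haplotypes are initialized with independent
#' sites at allele frequency 0.5; drift then establishes the equilibrium LD
#' and frequency spectrum. The defaults follow the single-chromosome
#' validation design: Ne = 500 run for Ne generations, 20,000 equally spaced
#' sites on 1 Morgan, mutation rate 1e-8, discovery/target samples of
#' 2000/1000, 10,000 causal SNPs with MAF > 1% explaining 1% of the
#' phenotypic variance.
#'
#' @param Ne breeding population size.
#' @param generations number of generations (default `Ne`).
#' @param nSites number of equally spaced sites per chromosome.
#' @param nChr number of chromosomes.
#' @param chrLength chromosome length in Morgan.
#' @param mutationRate per-site, per-generation mutation probability.
#' @param mafMin minor-allele-frequency cut-off for SNP panel and causal
#'   sites.
#' @param nDiscovery,nTarget sample sizes drawn from the final generation
#'   (by expansion sampling when they exceed `Ne`).
#' @param nCausal number of causal SNPs.
#' @param h2 proportion of phenotypic variance explained by the causal SNPs.
#' @return a validated config list of class `"genedropConfig"`.
#' @export
genedropConfig <- function(Ne = 500, generations = Ne, nSites = 20000,
                           nChr = 1, chrLength = 1, mutationRate = 1e-8,
                           mafMin = 0.01, nDiscovery = 2000, nTarget = 1000,
                           nCausal = 10000, h2 = 0.01) {
  cfg <- list(Ne = as.integer(Ne), generations = as.integer(generations),
              nSites = as.integer(nSites), nChr = as.integer(nChr),
              chrLength = chrLength, mutationRate = mutationRate,
              mafMin = mafMin, nDiscovery = as.integer(nDiscovery),
              nTarget = as.integer(nTarget), nCausal = as.integer(nCausal),
              h2 = h2)
  stopifnot(cfg$Ne >= 2, cfg$generations >= 1, cfg$nSites >= 2, cfg$nChr >= 1,
            cfg$chrLength >= 0, cfg$mutationRate >= 0, cfg$mutationRate < 1,
            cfg$h2 > 0, cfg$h2 < 1, cfg$nCausal >= 1,
            cfg$nCausal <= cfg$nSites * cfg$nChr,
            cfg$nDiscovery >= 1, cfg$nTarget >= 1)
  class(cfg) <- "genedropConfig"
  cfg
}

# one recombinant gamete from a parent's two haplotypes.
# positionsByChr: list of site positions (Morgan) per chromosome;
# colsByChr: matching column index vectors.
recombineGamete <- function(hapA, hapB, positionsByChr, colsByChr, chrLength) {
  gamete <- hapA
  for (k in seq_along(positionsByChr)) {
    cols <- colsByChr[[k]]
    nCross <- stats::rpois(1L, chrLength)
    start <- stats::runif(1) < 0.5
    if (nCross == 0L) {
      if (!start) gamete[cols] <- hapB[cols]
    } else {
      seg <- findInterval(positionsByChr[[k]],
                          sort(stats::runif(nCross, 0, chrLength)))
      useB <- xor(seg %% 2L == 1L, start)
      gamete[cols][useB] <- hapB[cols][useB]
    }
  }
  gamete
}

# offspring haplotypes: nOff individuals, two independently drawn parents
# each (selfing allowed), one recombinant gamete per parent.
dropGeneration <- function(H, nOff, positionsByChr, colsByChr, chrLength,
                           mutationRate) {
  Ne <- nrow(H) / 2L
  out <- matrix(0L, 2L * nOff, ncol(H))
  parents <- cbind(sample.int(Ne, nOff, replace = TRUE),
                   sample.int(Ne, nOff, replace = TRUE))
  for (i in seq_len(nOff)) {
    for (s in 1:2) {
      p <- parents[i, s]
      out[2L * (i - 1L) + s, ] <- recombineGamete(
        H[2L * p - 1L, ], H[2L * p, ], positionsByChr, colsByChr, chrLength)
    }
  }
  if (mutationRate > 0) {
    nMut <- stats::rpois(1L, mutationRate * length(out))
    if (nMut > 0) {
      idx <- sample.int(length(out), min(nMut, length(out)))
      out[idx] <- 1L - out[idx]
    }
  }
  out
}

#' Forward-in-time gene-dropping simulation
#'
#' Evolves `2*Ne` haplotypes for the configured number of generations under
#' random mating, drift, recombination and mutation, then draws discovery and
#' target samples from the final generation. When the requested samples
#' exceed `Ne`, the final breeding population is expanded by generating the
#' required number of offspring from it (expansion sampling); the expansion
#' individuals form one additional generation of the same population.
#' Phenotypes for the discovery sample are built from a random causal subset
#' of MAF-passing sites: standardized causal dosages times normal effects,
#' rescaled so the causal SNPs explain `h2` of the phenotypic variance, plus
#' a normal residual.
#'
#' @param config a [genedropConfig()].
#' @param seed optional integer seed for reproducibility.
#' @return a list with elements `discovery` and `target`
#'   ([GenotypeMatrix-class] objects on the MAF-passing SNP panel),
#'   `phenotypes` (data.frame `id`, `phenotype` for the discovery sample),
#'   `truth` (data.frame `id`, `g` with true genetic values for all sampled
#'   individuals), `causalIds`, and diagnostics `siteFreq` (allele frequency
#'   of every simulated site in the sampled individuals), `positions` and
#'   `chr`.
#' @export
simulateGenedrop <- function(config, seed = NULL) {
  stopifnot(inherits(config, "genedropConfig"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  totSites <- cfg$nSites * cfg$nChr
  positions <- rep(seq(0, cfg$chrLength, length.out = cfg$nSites), cfg$nChr)
  chr <- rep(seq_len(cfg$nChr), each = cfg$nSites)
  colsByChr <- split(seq_len(totSites), chr)
  positionsByChr <- split(positions, chr)

  # founders: independent sites at frequency 0.5
  H <- matrix(stats::rbinom(2L * cfg$Ne * totSites, 1L, 0.5),
              2L * cfg$Ne, totSites)
  for (g in seq_len(cfg$generations))
    H <- dropGeneration(H, cfg$Ne, positionsByChr, colsByChr, cfg$chrLength,
                        cfg$mutationRate)

  nSample <- cfg$nDiscovery + cfg$nTarget
  Hs <- dropGeneration(H, nSample, positionsByChr, colsByChr, cfg$chrLength,
                       cfg$mutationRate)
  geno <- Hs[seq(1L, 2L * nSample, by = 2L), , drop = FALSE] +
          Hs[seq(2L, 2L * nSample, by = 2L), , drop = FALSE]
  ids <- sprintf("ind%d", seq_len(nSample))
  rownames(geno) <- ids
  colnames(geno) <- sprintf("site%d", seq_len(totSites))

  freq <- colMeans(geno) / 2
  maf <- pmin(freq, 1 - freq)
  panel <- maf > cfg$mafMin
  if (sum(panel) < 2L)
    stop("fewer than 2 sites pass the MAF filter; increase nSites or lower mafMin")
  nCausal <- min(cfg$nCausal, sum(panel))
  if (nCausal < cfg$nCausal)
    warning(sprintf("only %d MAF-passing sites available for %d causal SNPs",
                    sum(panel), cfg$nCausal))
  causal <- sort(sample(which(panel), nCausal))

  # true genetic values: standardized causal dosages times normal effects,
  # rescaled to explain h2 of the phenotypic variance
  pC <- freq[causal]
  Zc <- sweep(geno[, causal, drop = FALSE], 2L, 2 * pC, "-")
  Zc <- sweep(Zc, 2L, sqrt(2 * pC * (1 - pC)), "/")
  gRaw <- as.numeric(Zc %*% stats::rnorm(nCausal))
  gAll <- gRaw / stats::sd(gRaw) * sqrt(cfg$h2)

  discIdx <- seq_len(cfg$nDiscovery)
  targIdx <- cfg$nDiscovery + seq_len(cfg$nTarget)
  pheno <- gAll[discIdx] +
    stats::rnorm(cfg$nDiscovery, 0, sqrt(1 - cfg$h2))

  list(
    discovery = genotypeMatrix(geno[discIdx, panel, drop = FALSE]),
    target = genotypeMatrix(geno[targIdx, panel, drop = FALSE]),
    phenotypes = data.frame(id = ids[discIdx], phenotype = pheno,
                            stringsAsFactors = FALSE),
    truth = data.frame(id = ids, g = gAll, stringsAsFactors = FALSE),
    causalIds = colnames(geno)[causal],
    siteFreq = freq, positions = positions, chr = chr)
}
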