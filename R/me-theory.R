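#' Population and genome specification
#'
#' Bundles the parameters that determine the effective number of chromosome
#' segments: effective population size `Ne`, the genome layout (`nChr`
#' chromosomes of `chrLength` Morgan each), and the expected-LD formula. With
#' `mutation = TRUE` the expected squared correlation between two loci at
#' genetic distance c Morgan is r^2 = 1/(2 + 4*Ne*c), the form that accounts
#' for recurrent mutation; otherwise r^2 = 1/(1 + 4*Ne*c).
#'
#' @param Ne effective population size (>= 1).
#' @param nChr number of chromosomes (>= 1).
#' @param chrLength genetic length of each chromosome in Morgan (> 0).
#' @param mutation use the mutation-corrected r^2 formula (default TRUE).
#' @return a [PopulationGenomeSpec-class].
#' @examples
#' populationGenome(100, nChr = 30, chrLength = 1)
#' @export
populationGenome <- function(Ne, nChr = 1L, chrLength = 1, mutation = TRUE) {
  new("PopulationGenomeSpec", Ne = as.numeric(Ne), nChr = as.integer(nChr),
      chrLength = as.numeric(chrLength), mutation = isTRUE(mutation))
}

# expected r^2 at genetic distance c (Morgan) under the spec's LD formula
expectedR2 <- function(c, Ne, mutation = TRUE) {
  1 / ((if (mutation) 2 else 1) + 4 * Ne * c)
}

#' Expected squared-correlation matrix of equally spaced SNPs
#'
#' Builds the M x M Toeplitz matrix S of expected squared correlations between
#' M SNPs equally spaced along a single chromosome, spanning the full length
#' with inter-SNP distance `chrLength/(M-1)` (endpoints included). Entry (i,j)
#' is r^2 at distance |i-j| * spacing under the spec's LD formula.
#'
#' @param spec a single-chromosome [PopulationGenomeSpec-class].
#' @param M number of SNPs (>= 2).
#' @return a [SnpCorrelationMatrix-class].
#' @examples
#' S <- snpCorrelationMatrix(populationGenome(100), M = 100)
#' meMatrixMean(S)
#' @export
snpCorrelationMatrix <- function(spec, M) {
  stopifnot(is(spec, "PopulationGenomeSpec"))
  if (spec@nChr != 1L)
    stop("snpCorrelationMatrix is defined for a single chromosome")
  if (!is.numeric(M) || length(M) != 1L || M < 2)
    stop("M must be a single count >= 2")
  M <- as.integer(M)
  spacing <- spec@chrLength / (M - 1)
  r2 <- expectedR2((0:(M - 1)) * spacing, spec@Ne, spec@mutation)
  idx <- abs(outer(seq_len(M), seq_len(M), "-")) + 1L
  S <- matrix(r2[idx], M, M)
  diag(S) <- 1
  new("SnpCorrelationMatrix", values = S, spacing = spacing, spec = spec)
}

# regularized symmetric solve used by meFromWeights
solveWeights <- function(S, ridge = 1e-8, kappaMax = 1e12) {
  e <- rep(1, nrow(S))
  kap <- kappa(S, exact = FALSE)
  if (!is.finite(kap) || kap > kappaMax) {
    warning(sprintf(
      "correlation matrix nearly singular (condition number %.3g); adding ridge %g",
      kap, ridge))
    S <- S + diag(ridge, nrow(S))
  }
  w <- tryCatch(solve(S, e), error = function(err) {
    stop("weight system could not be solved even after regularization: ",
         conditionMessage(err))
  })
  w
}

#' Me from SNP weights (exact linear-system form)
#'
#' Solves the linear system S w = 1 on the SNP squared-correlation matrix and
#' returns Me as the sum of the weights. For independent SNPs (S = I) every
#' weight is 1 and Me = M; under perfect LD the weights sum to 1. Nearly
#' singular matrices are ridge-regularized with a warning.
#'
#' @param S a [SnpCorrelationMatrix-class] or a plain symmetric matrix of
#'   squared correlations.
#' @param ridge diagonal stabilizer applied when the condition number exceeds
#'   `kappaMax`.
#' @param kappaMax condition-number threshold for regularization.
#' @return a [MeEstimate-class] with method `"weights"`.
#' @examples
#' meFromWeights(diag(5))                      # 5 independent SNPs -> Me = 5
#' @export
meFromWeights <- function(S, ridge = 1e-8, kappaMax = 1e12) {
  m <- if (is(S, "SnpCorrelationMatrix")) S@values else as.matrix(S)
  if (!isSymmetric(unname(m))) stop("S must be symmetric")
  w <- solveWeights(m, ridge = ridge, kappaMax = kappaMax)
  new("MeEstimate", value = sum(w), method = "weights",
      details = list(weights = w))
}

#' Me from the matrix-mean approximation
#'
#' Approximates 1/Me by the mean of all M^2 entries of the SNP
#' squared-correlation matrix. This is the approximation whose M -> infinity
#' limit yields the closed-form expressions evaluated by
#' [meClosedFormSingle()].
#'
#' @param S a [SnpCorrelationMatrix-class] or plain symmetric matrix.
#' @return a [MeEstimate-class] with method `"matrix_mean"`.
#' @examples
#' meMatrixMean(diag(4))   # Me = 16/4 = 4
#' @export
meMatrixMean <- function(S) {
  m <- if (is(S, "SnpCorrelationMatrix")) S@values else as.matrix(S)
  if (!isSymmetric(unname(m))) stop("S must be symmetric")
  new("MeEstimate", value = nrow(m)^2 / sum(m), method = "matrix_mean",
      details = list(M = nrow(m)))
}

# 1/Me for one chromosome of length L: the M -> infinity limit of the matrix
# mean, 2 * integral_0^1 (1-x) r2(x*L) dx, which with a = 4*Ne*L and
# b = 1 (no mutation) or 2 evaluates to 2*((a+b)*log((a+b)/b) - a)/a^2.
invMeSingle <- function(Ne, L, mutation) {
  a <- 4 * Ne * L
  b <- if (mutation) 2 else 1
  # zero map length: every r2 equals r2(0) = 1/b, hence Me -> b (a single
  # segment under the drift-only formula, 2 under the mutation-corrected one)
  if (a == 0) return(1 / b)
  2 * ((a + b) * log((a + b) / b) - a) / a^2
}

#' Closed-form Me for a single chromosome
#'
#' Evaluates the analytic limit of the matrix-mean approximation for one
#' chromosome of length L Morgan: 1/Me = 2 * integral of (1-x) r^2(xL) over
#' x in (0,1), with r^2 the spec's LD formula. A zero-length region returns
#' the r^2(0) limit: Me = 1 under the drift-only formula (all loci perfectly
#' correlated), Me = 2 under the mutation-corrected one.
#'
#' @param spec a single-chromosome [PopulationGenomeSpec-class].
#' @return a [MeEstimate-class] with method `"closed_form"`.
#' @examples
#' meClosedFormSingle(populationGenome(100))   # about 46.2 segments
#' @export
meClosedFormSingle <- function(spec) {
  stopifnot(is(spec, "PopulationGenomeSpec"))
  if (spec@nChr != 1L)
    stop("meClosedFormSingle expects a single chromosome; use meClosedFormGenome")
  new("MeEstimate",
      value = 1 / invMeSingle(spec@Ne, spec@chrLength, spec@mutation),
      method = "closed_form", details = list(spec = spec))
}

#' Closed-form Me for a multi-chromosome genome
#'
#' Combines per-chromosome segment counts with the covariance of genomic
#' relationships between chromosomes. The nChr x nChr covariance matrix has
#' diagonal 1/Me_single (from the single-chromosome closed form) and
#' off-diagonal 1/(3*Ne) (the summed variance of relationships contributed by
#' common ancestry in previous generations); 1/Me_genome is the mean of all
#' its entries. With one chromosome this reduces exactly to
#' [meClosedFormSingle()].
#'
#' @param spec a [PopulationGenomeSpec-class]; chromosomes are assumed to have
#'   equal length.
#' @return a [MeEstimate-class] with method `"closed_form"`.
#' @examples
#' ## 30 chromosomes of 1 Morgan at Ne = 100: about 254 segments
#' meClosedFormGenome(populationGenome(100, nChr = 30, chrLength = 1))
#' @export
meClosedFormGenome <- function(spec) {
  stopifnot(is(spec, "PopulationGenomeSpec"))
  n <- spec@nChr
  invSingle <- invMeSingle(spec@Ne, spec@chrLength, spec@mutation)
  # mean of the n x n covariance matrix: n diagonal entries of 1/Me_single
  # and n*(n-1) off-diagonals of 1/(3*Ne)
  invGenome <- (n * invSingle + n * (n - 1) / (3 * spec@Ne)) / n^2
  new("MeEstimate", value = 1 / invGenome, method = "closed_form",
      details = list(spec = spec, meSingle = 1 / invSingle))
}
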