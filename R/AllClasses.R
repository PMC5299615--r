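#' @import methods
NULL

#' LiabilityModel: truncated-normal machinery for a disease prevalence
#'
#' Holds the quantities of the liability threshold model for a disease with
#' population prevalence \code{K}: the threshold \code{t} on the standard
#' normal liability scale, the density \code{z} at the threshold, and the mean
#' liabilities of affected (\code{iCase}) and unaffected (\code{iControl})
#' individuals. Construct with [liabilityModel()].
#'
#' @slot K population prevalence, in (0, 1).
#' @slot threshold liability threshold t, the upper-K standard-normal quantile.
#' @slot density standard-normal density z at the threshold.
#' @slot iCase mean liability of cases, z/K.
#' @slot iControl mean liability of controls, -z/(1-K).
#'
#' @seealso [liabilityModel()], [expectedAUC()], [expectedOR()]
#' @export
setClass("LiabilityModel",
  representation(K = "numeric", threshold = "numeric", density = "numeric",
                 iCase = "numeric", iControl = "numeric"))

setValidity("LiabilityModel", function(object) {
  msg <- character()
  if (length(object@K) != 1L || !is.finite(object@K) ||
      object@K <= 0 || object@K >= 1)
    msg <- c(msg, "K must be a single value in (0, 1)")
  else {
    if (abs(stats::pnorm(object@threshold, lower.tail = FALSE) - object@K) > 1e-10)
      msg <- c(msg, "threshold is not the upper-K quantile")
    if (abs(object@density - stats::dnorm(object@threshold)) > 1e-12)
      msg <- c(msg, "density is not dnorm(threshold)")
    # overall mean liability must be zero
    if (abs(object@K * object@iCase + (1 - object@K) * object@iControl) > 1e-12)
      msg <- c(msg, "K*iCase + (1-K)*iControl must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' PercentileContrast: strata of ranked genetic profile scores
#'
#' Describes a top and a bottom stratum of the standardized profile-score
#' distribution: the tail fractions, the truncation thresholds and the mean
#' standardized score within each stratum. Construct with
#' [percentileContrast()]. Stratum means are in standard-deviation units;
#' scaling to a particular score variance is left to the accuracy calculators.
#'
#' @slot topFraction,bottomFraction tail fractions in (0, 1).
#' @slot tTop,tBottom thresholds truncating the top/bottom strata.
#' @slot iTop,iBottom mean standardized score within each stratum.
#' @export
setClass("PercentileContrast",
  representation(topFraction = "numeric", bottomFraction = "numeric",
                 tTop = "numeric", tBottom = "numeric",
                 iTop = "numeric", iBottom = "numeric"))

setValidity("PercentileContrast", function(object) {
  msg <- character()
  for (f in c(object@topFraction, object@bottomFraction))
    if (!is.finite(f) || f <= 0 || f >= 1)
      msg <- c(msg, "fractions must lie in (0, 1)")
  if (!length(msg)) {
    if (object@iTop <= 0) msg <- c(msg, "iTop must be positive (upper tail)")
    if (object@iBottom >= 0) msg <- c(msg, "iBottom must be negative (lower tail)")
  }
  if (length(msg)) msg else TRUE
})

#' PopulationGenomeSpec: effective size and genome layout
#'
#' The population/genome parameters that determine the effective number of
#' chromosome segments: effective population size \code{Ne}, number of
#' chromosomes, per-chromosome genetic length in Morgan, and whether the
#' expected squared LD correlation uses the mutation-corrected form
#' r^2 = 1/(2 + 4 Ne c) instead of 1/(1 + 4 Ne c). Construct with
#' [populationGenome()].
#'
#' @slot Ne effective population size (>= 1).
#' @slot nChr number of chromosomes (>= 1).
#' @slot chrLength genetic length per chromosome, Morgan (> 0).
#' @slot mutation logical; use the mutation-corrected r^2 formula.
#' @export
setClass("PopulationGenomeSpec",
  representation(Ne = "numeric", nChr = "integer", chrLength = "numeric",
                 mutation = "logical"))

setValidity("PopulationGenomeSpec", function(object) {
  msg <- character()
  if (!is.finite(object@Ne) || object@Ne < 1) msg <- c(msg, "Ne must be >= 1")
  if (object@nChr < 1L) msg <- c(msg, "nChr must be >= 1")
  if (!is.finite(object@chrLength) || object@chrLength <= 0)
    msg <- c(msg, "chrLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' SnpCorrelationMatrix: expected squared correlations of equally spaced SNPs
#'
#' An M x M Toeplitz matrix of expected squared correlation coefficients (r^2)
#' between M SNPs equally spaced along a single chromosome, under
#' r^2(c) = 1/(1 + 4 Ne c) or its mutation-corrected variant. Construct with
#' [snpCorrelationMatrix()]; feed to [meFromWeights()] / [meMatrixMean()].
#'
#' @slot values the M x M matrix of squared correlations.
#' @slot spacing inter-SNP distance in Morgan.
#' @slot spec the [PopulationGenomeSpec-class] that produced it.
#' @export
setClass("SnpCorrelationMatrix",
  representation(values = "matrix", spacing = "numeric",
                 spec = "PopulationGenomeSpec"))

setValidity("SnpCorrelationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else {
    if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    if (any(v < -1e-12) || any(v > 1 + 1e-12)) msg <- c(msg, "entries must be in [0, 1]")
    if (!isSymmetric(unname(v))) msg <- c(msg, "matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' MeEstimate: an effective number of chromosome segments with provenance
#'
#' Wraps a value of Me together with the method that produced it: SNP weights
#' ("weights"), the matrix-mean approximation ("matrix_mean"), the closed-form
#' integral ("closed_form"), or the variance of discovery-by-target genomic
#' relationships ("grm_variance"). Extract the value with [meValue()].
#'
#' @slot value the Me estimate (> 0).
#' @slot method one of "weights", "matrix_mean", "closed_form", "grm_variance".
#' @slot details method-specific extras, e.g. the per-target relationship
#'   variance vector for the GRM method.
#' @export
setClass("MeEstimate",
  representation(value = "numeric", method = "character", details = "list"))

setValidity("MeEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1L || !is.finite(object@value) || object@value <= 0)
    msg <- c(msg, "value must be a single positive number")
  if (!object@method %in% c("weights", "matrix_mean", "closed_form", "grm_variance"))
    msg <- c(msg, "unknown method")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: SNP dosages with allele frequencies
#'
#' An individuals-by-SNPs matrix of allele dosages in {0, 1, 2} (NA allowed)
#' with row names as individual ids and column names as SNP ids, plus per-SNP
#' allele frequencies. Construct with [genotypeMatrix()].
#'
#' @slot dosages numeric matrix, individuals x SNPs, entries in [0, 2] or NA.
#' @slot alleleFreq per-SNP frequency of the counted allele, in [0, 1].
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", alleleFreq = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (is.null(rownames(d))) msg <- c(msg, "dosages must have individual ids as rownames")
  if (length(object@alleleFreq) != ncol(d))
    msg <- c(msg, "alleleFreq length must equal the number of SNPs")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (any(!is.na(object@alleleFreq) &
          (object@alleleFreq < 0 | object@alleleFreq > 1)))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "individual ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Grm: genomic relationship matrix
#'
#' A square symmetric matrix of genomic relationships with individual ids as
#' dimnames and the number of SNPs used to build it. Construct with
#' [buildGRM()] or [readGRM()].
#'
#' @slot values symmetric numeric matrix of relationships.
#' @slot nSnps number of SNPs the matrix is based on.
#' @export
setClass("Grm", representation(values = "matrix", nSnps = "numeric"))

setValidity("Grm", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else if (!isSymmetric(unname(v), tol = 1e-8)) msg <- c(msg, "matrix must be symmetric")
  if (is.null(rownames(v))) msg <- c(msg, "individual ids required as dimnames")
  else if (anyDuplicated(rownames(v))) msg <- c(msg, "individual ids must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LiabilityModel", function(object) {
  cat("LiabilityModel (liability threshold model)\n",
      sprintf("  K = %g, t = %.5f, z = %.5f\n", object@K, object@threshold,
              object@density),
      sprintf("  mean liability: cases %.5f, controls %.5f\n",
              object@iCase, object@iControl), sep = "")
})

setMethod("show", "PercentileContrast", function(object) {
  cat("PercentileContrast of ranked profile scores\n",
      sprintf("  top %g%%:    t = %.5f, mean score = %.5f\n",
              100 * object@topFraction, object@tTop, object@iTop),
      sprintf("  bottom %g%%: t = %.5f, mean score = %.5f\n",
              100 * object@bottomFraction, object@tBottom, object@iBottom),
      sep = "")
})

setMethod("show", "PopulationGenomeSpec", function(object) {
  cat(sprintf(
    "PopulationGenomeSpec: Ne = %g, %d chromosome(s) x %g Morgan, r2 = 1/(%d + 4*Ne*c)\n",
    object@Ne, object@nChr, object@chrLength, if (object@mutation) 2L else 1L))
})

setMethod("show", "SnpCorrelationMatrix", function(object) {
  cat(sprintf(
    "SnpCorrelationMatrix: %d equally spaced SNPs, spacing %g Morgan (Ne = %g)\n",
    nrow(object@values), object@spacing, object@spec@Ne))
})

setMethod("show", "MeEstimate", function(object) {
  cat(sprintf("MeEstimate: Me = %.4g (method: %s)\n", object@value, object@method))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs\n",
              nrow(object@dosages), ncol(object@dosages)))
})

setMethod("show", "Grm", function(object) {
  cat(sprintf("Grm: %d individuals, built from %g SNPs\n",
              nrow(object@values), object@nSnps))
})
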