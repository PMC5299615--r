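#' Proportion of genetic variance captured by observed variants
#'
#' With M observed variants and Me effective chromosome segments, the markers
#' capture a fraction b = M/(M + Me) of the genetic variance; b approaches 1
#' for dense genotyping.
#'
#' @param M number of observed variants (>= 1).
#' @param me effective number of chromosome segments, a [MeEstimate-class] or
#'   positive number.
#' @return b in (0, 1).
#' @export
capturedFraction <- function(M, me) {
  Me <- meValue(me)
  if (!is.numeric(M) || any(M < 1)) stop("M must be >= 1")
  M / (M + Me)
}

#' Expected accuracy of genomic prediction for a quantitative trait
#'
#' Expected correlation between true and estimated genetic profile scores for
#' a discovery set of N phenotyped individuals, trait heritability h2 and Me
#' effective segments: r = sqrt(b * N h2 b / (N h2 b + Me)), with b the
#' captured-variance fraction (b = 1 when `M` is omitted, the dense-marker
#' simplification).
#'
#' @param N discovery sample size.
#' @param h2 trait heritability in (0, 1].
#' @param me a [MeEstimate-class] or positive number.
#' @param M optional observed variant count; when supplied, b is computed via
#'   [capturedFraction()].
#' @return the expected correlation between true and estimated scores.
#' @examples
#' me <- meClosedFormGenome(populationGenome(100, nChr = 30))
#' accuracyQuantitative(3000, 0.5, me)
#' @export
accuracyQuantitative <- function(N, h2, me, M = NULL) {
  Me <- meValue(me)
  stopifnot(N >= 1, h2 > 0, h2 <= 1)
  b <- if (is.null(M)) 1 else capturedFraction(M, Me)
  sqrt(b * N * h2 * b / (N * h2 * b + Me))
}

#' Expected correlation between phenotypes and estimated profile scores
#'
#' The expected accuracy measured against phenotypes rather than true genetic
#' values: sqrt(h2) times [accuracyQuantitative()].
#'
#' @inheritParams accuracyQuantitative
#' @return the expected phenotype-score correlation.
#' @examples
#' accuracyPhenotypic(3394, 0.8, 4434)   # about 0.551
#' @export
accuracyPhenotypic <- function(N, h2, me, M = NULL) {
  sqrt(h2) * accuracyQuantitative(N, h2, me, M)
}

# observed-scale (0/1) heritability for an ascertained case-control sample:
# h2 * z^2 * P(1-P) / (K^2 (1-K)^2)
h2CaseControl <- function(h2, lia, P) {
  h2 * lia@density^2 * P * (1 - P) / (lia@K^2 * (1 - lia@K)^2)
}

asLiability <- function(K) {
  if (is(K, "LiabilityModel")) K else liabilityModel(K)
}

#' Expected accuracy of genomic prediction in a case-control design
#'
#' Expected correlation between true and estimated genetic profile scores on
#' the observed 0/1 disease scale, for a discovery sample of N individuals of
#' which a proportion P are cases, a disease of prevalence K and liability
#' heritability h2. The liability heritability is converted to the
#' ascertained observed scale via h2_01 = h2 z^2 P(1-P) / (K^2 (1-K)^2) and
#' plugged into the quantitative-trait formula:
#' rho = sqrt(N h2_01 / (N h2_01 + Me)).
#'
#' @param N discovery sample size (cases + controls).
#' @param h2 heritability on the liability scale.
#' @param me a [MeEstimate-class] or positive number.
#' @param K population prevalence, or a [LiabilityModel-class].
#' @param P proportion of cases in the discovery sample.
#' @return the expected 0/1-scale correlation between true and estimated
#'   scores.
#' @export
accuracyCaseControl <- function(N, h2, me, K, P) {
  Me <- meValue(me)
  lia <- asLiability(K)
  stopifnot(N >= 1, h2 > 0, h2 <= 1, P > 0, P < 1)
  h2cc <- h2CaseControl(h2, lia, P)
  sqrt(N * h2cc / (N * h2cc + Me))
}

# correlation between the estimated profile score and the liability:
# the score explains rho^2 of the true genetic score, which explains h2 of
# the liability.
scoreLiabilityCorr <- function(N, h2, me, K, P) {
  sqrt(h2) * accuracyCaseControl(N, h2, me, K, P)
}

#' Expected AUC of a genetic profile score
#'
#' Expected area under the ROC curve when the estimated genetic profile score
#' is used to discriminate cases from controls in an unselected target
#' population. With r the score-liability correlation, i and i2 the mean
#' liabilities of cases and controls, and t the prevalence threshold:
#' AUC = Phi( r (i - i2) / sqrt(2 - r^2 (i(i-t) + i2(i2-t))) ).
#'
#' @inheritParams accuracyCaseControl
#' @return expected AUC in \[0.5, 1).
#' @examples
#' me <- meClosedFormGenome(populationGenome(100, nChr = 30))
#' expectedAUC(3000, 0.5, me, K = 0.1, P = 0.5)   # about 0.85
#' @export
expectedAUC <- function(N, h2, me, K, P) {
  lia <- asLiability(K)
  r <- scoreLiabilityCorr(N, h2, me, lia, P)
  i1 <- lia@iCase; i2 <- lia@iControl; t <- lia@threshold
  varCase <- 1 - r^2 * i1 * (i1 - t)
  varControl <- 1 - r^2 * i2 * (i2 - t)
  stats::pnorm(r * (i1 - i2) / sqrt(varCase + varControl))
}

# P(disease | score stratum with mean iStr and threshold tStr), where the
# score has correlation r with liability: the liability within the stratum is
# normal with mean r*iStr and variance 1 - r^2 * iStr*(iStr - tStr).
stratumRisk <- function(r, iStr, tStr, lia) {
  stats::pnorm((r * iStr - lia@threshold) /
                 sqrt(1 - r^2 * iStr * (iStr - tStr)))
}

#' Expected odds ratio for percentile contrasts of profile scores
#'
#' Expected odds ratio of disease status contrasting the top stratum of
#' ranked genetic profile scores against either the bottom stratum
#' (`"top_vs_bottom"`) or the general population (`"top_vs_population"`,
#' reference odds K/(1-K)). The probability of disease within a stratum uses
#' the truncated-normal stratum mean and variance together with the expected
#' score-liability correlation.
#'
#' @inheritParams accuracyCaseControl
#' @param contrast a [PercentileContrast-class] defining the strata.
#' @param mode `"top_vs_bottom"` or `"top_vs_population"`.
#' @return a list with elements `oddsRatio`, `pTop`, `pRef` and `mode`.
#' @examples
#' me <- meClosedFormGenome(populationGenome(100, nChr = 30))
#' expectedOR(3000, 0.5, me, K = 0.1, P = 0.5,
#'            contrast = percentileContrast(0.2))$oddsRatio     # about 132
#' expectedOR(3000, 0.5, me, K = 0.1, P = 0.5,
#'            contrast = percentileContrast(0.01),
#'            mode = "top_vs_population")$oddsRatio             # about 23
#' @export
expectedOR <- function(N, h2, me, K, P,
                       contrast = percentileContrast(0.2),
                       mode = c("top_vs_bottom", "top_vs_population")) {
  mode <- match.arg(mode)
  stopifnot(is(contrast, "PercentileContrast"))
  lia <- asLiability(K)
  r <- scoreLiabilityCorr(N, h2, me, lia, P)
  pTop <- stratumRisk(r, contrast@iTop, contrast@tTop, lia)
  pRef <- if (mode == "top_vs_population") lia@K
          else stratumRisk(r, contrast@iBottom, contrast@tBottom, lia)
  if (pTop <= 0 || pTop >= 1 || pRef <= 0 || pRef >= 1)
    stop("degenerate stratum risk; odds ratio undefined")
  list(oddsRatio = (pTop / (1 - pTop)) / (pRef / (1 - pRef)),
       pTop = pTop, pRef = pRef, mode = mode)
}
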