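#' Liability threshold quantities for a disease prevalence
#'
#' Computes the standard quantities of the liability threshold model for a
#' disease with population prevalence `K`: the truncation threshold `t` such
#' that P(liability > t) = K, the normal density `z` at `t`, and the mean
#' liabilities of cases (`i = z/K`) and controls (`-z/(1-K)`). The overall
#' mean liability is zero by construction.
#'
#' @param K population prevalence, a single probability in (0, 1).
#' @return a [LiabilityModel-class] object.
#' @examples
#' liabilityModel(0.1)
#' @export
liabilityModel <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0 || K >= 1)
    stop("K must be a single probability in (0, 1)")
  t <- stats::qnorm(K, lower.tail = FALSE)
  z <- stats::dnorm(t)
  new("LiabilityModel", K = K, threshold = t, density = z,
      iCase = z / K, iControl = -z / (1 - K))
}

#' Thresholds and mean scores of profile-score percentile strata
#'
#' For the top `topFraction` and bottom `bottomFraction` of a standardized
#' (unit-variance) score distribution, computes the truncation thresholds and
#' the mean standardized score within each stratum: `iTop = z(tTop)/top` for
#' the upper tail and the symmetric construction for the lower tail. Means are
#' reported in standard-deviation units of the score; callers scale them by
#' the score-liability correlation.
#'
#' @param topFraction fraction of individuals in the top stratum, in (0, 1).
#' @param bottomFraction fraction in the bottom stratum; defaults to
#'   `topFraction`.
#' @return a [PercentileContrast-class] object.
#' @examples
#' percentileContrast(0.2)            # top/bottom quintiles
#' percentileContrast(0.01, 0.2)      # top 1% vs bottom 20%
#' @export
percentileContrast <- function(topFraction, bottomFraction = topFraction) {
  for (f in c(topFraction, bottomFraction))
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f >= 1)
      stop("stratum fractions must be single probabilities in (0, 1)")
  if (topFraction + bottomFraction > 1)
    stop("top and bottom strata overlap: fractions sum to more than 1")
  tTop <- stats::qnorm(topFraction, lower.tail = FALSE)
  tBottom <- stats::qnorm(bottomFraction)
  new("PercentileContrast",
      topFraction = topFraction, bottomFraction = bottomFraction,
      tTop = tTop, tBottom = tBottom,
      iTop = stats::dnorm(tTop) / topFraction,
      iBottom = -stats::dnorm(tBottom) / bottomFraction)
}
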