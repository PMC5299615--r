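#' Observed AUC of a score predicting binary status
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic: the probability that a randomly chosen case outranks a randomly
#' chosen control, with ties counting one half. Invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores numeric vector of profile scores.
#' @param status 0/1 (or logical) case status of the same length.
#' @return AUC in \[0, 1\].
#' @export
observedAUC <- function(scores, status) {
  status <- as.integer(as.logical(status))
  stopifnot(length(scores) == length(status), !anyNA(scores), !anyNA(status))
  nCase <- as.numeric(sum(status == 1L))   # numeric: n^2 overflows int
  nControl <- as.numeric(sum(status == 0L))
  if (nCase == 0 || nControl == 0)
    stop("both cases and controls are required to compute an AUC")
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[status == 1L]) - nCase * (nCase + 1) / 2) / (nCase * nControl)
}

# 2x2 contingency odds ratio with Haldane-Anscombe correction on zero cells
tableOR <- function(tab) {
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  list(oddsRatio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       corrected = corrected,
       logSE = sqrt(sum(1 / tab)))
}

# indices of the top/bottom strata by rank; stable ties (input order)
strataIdx <- function(scores, topFraction, bottomFraction) {
  n <- length(scores)
  nTop <- floor(n * topFraction)
  nBottom <- floor(n * bottomFraction)
  if (nTop < 1 || nBottom < 1)
    stop("strata are empty at this sample size")
  ord <- order(scores)
  list(top = ord[(n - nTop + 1):n], bottom = ord[seq_len(nBottom)])
}

#' Observed odds ratio contrasting score strata
#'
#' Builds the 2x2 stratum-by-status table contrasting the top fraction of
#' ranked scores against either the bottom fraction or the whole sample
#' (`reference = "population"`), and returns the cross-product odds ratio.
#' Zero cells receive the Haldane-Anscombe 0.5 correction and are flagged.
#'
#' @param scores numeric profile scores.
#' @param status 0/1 (or logical) case status.
#' @param topFraction fraction of individuals in the top stratum.
#' @param reference `"bottom"` or `"population"`.
#' @param bottomFraction fraction in the bottom stratum (default
#'   `topFraction`).
#' @return a list with `oddsRatio`, the 2x2 `table` (rows top/reference,
#'   columns case/control), `corrected` flag, `logSE`, and the stratum
#'   definition.
#' @export
observedOR <- function(scores, status, topFraction = 0.2,
                       reference = c("bottom", "population"),
                       bottomFraction = topFraction) {
  reference <- match.arg(reference)
  status <- as.integer(as.logical(status))
  stopifnot(length(scores) == length(status))
  idx <- strataIdx(scores, topFraction, bottomFraction)
  refIdx <- if (reference == "population") seq_along(scores) else idx$bottom
  tab <- rbind(top = c(case = sum(status[idx$top]),
                       control = sum(1L - status[idx$top])),
               reference = c(case = sum(status[refIdx]),
                             control = sum(1L - status[refIdx])))
  c(tableOR(tab),
    list(table = tab, topFraction = topFraction, reference = reference,
         bottomFraction = if (reference == "bottom") bottomFraction else NA))
}

#' Odds-ratio profile across consecutive score bins
#'
#' Partitions the ranked scores into consecutive bins of `binFraction` each
#' (boundaries at floor(n*q)) and reports the odds ratio of each bin against
#' the bottom bin; the bottom-vs-bottom contrast is 1 by definition.
#'
#' @param scores numeric profile scores.
#' @param status 0/1 (or logical) case status.
#' @param binFraction width of each bin as a fraction of the sample.
#' @return a data.frame with one row per bin: `bin`, `nCase`, `nControl`,
#'   `oddsRatio`, `corrected`.
#' @export
decileORProfile <- function(scores, status, binFraction = 0.2) {
  status <- as.integer(as.logical(status))
  stopifnot(length(scores) == length(status), binFraction > 0, binFraction < 1)
  n <- length(scores)
  nBins <- round(1 / binFraction)
  bounds <- floor(n * seq_len(nBins) * binFraction)
  bounds[nBins] <- n
  ord <- order(scores)
  from <- c(1L, utils::head(bounds, -1) + 1L)
  out <- data.frame(bin = seq_len(nBins), nCase = NA_integer_,
                    nControl = NA_integer_, oddsRatio = NA_real_,
                    corrected = NA)
  bottomIdx <- ord[from[1]:bounds[1]]
  for (k in seq_len(nBins)) {
    binIdx <- ord[from[k]:bounds[k]]
    out$nCase[k] <- sum(status[binIdx])
    out$nControl[k] <- length(binIdx) - out$nCase[k]
    if (k == 1L) {
      out$oddsRatio[k] <- 1
      out$corrected[k] <- FALSE
    } else {
      tab <- rbind(c(out$nCase[k], out$nControl[k]),
                   c(sum(status[bottomIdx]),
                     length(bottomIdx) - sum(status[bottomIdx])))
      res <- tableOR(tab)
      out$oddsRatio[k] <- res$oddsRatio
      out$corrected[k] <- res$corrected
    }
  }
  out
}
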