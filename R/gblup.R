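#' GBLUP genetic profile scores for target individuals
#'
#' Best linear unbiased prediction of genetic profile scores using the GRM as
#' the covariance of genetic effects: g_target = G_td (G_dd + lambda I)^-1 y,
#' with lambda = (1 - h2)/h2 the residual-to-genetic variance ratio at the
#' assumed heritability. Phenotypes are centered internally. For case-control
#' data the 0/1 status is used directly as the response.
#'
#' @param grm a [Grm-class] covering discovery and target individuals.
#' @param y named numeric vector of discovery phenotypes (names are ids), or
#'   an unnamed vector aligned with `discoveryIds`.
#' @param discoveryIds,targetIds disjoint id sets present in the GRM.
#' @param h2 assumed heritability in (0, 1), determining the shrinkage.
#' @param jitter diagonal stabilizer added before factorization.
#' @return a data.frame with columns `id` and `score` for the target
#'   individuals, in `targetIds` order.
#' @seealso [snpBlupPredict()], to which this is identical when the GRM is
#'   built from the same standardized genotypes.
#' @export
gblupPredict <- function(grm, y, discoveryIds, targetIds, h2, jitter = 1e-8) {
  stopifnot(is(grm, "Grm"), h2 > 0, h2 < 1)
  discoveryIds <- as.character(discoveryIds)
  targetIds <- as.character(targetIds)
  if (!is.null(names(y))) y <- y[discoveryIds]
  if (length(y) != length(discoveryIds) || anyNA(y))
    stop("y must provide one non-missing phenotype per discovery individual")
  A <- as.matrix(grm)
  missing <- setdiff(c(discoveryIds, targetIds), rownames(A))
  if (length(missing))
    stop("ids absent from the GRM: ", paste(utils::head(missing, 3), collapse = ", "))
  if (length(intersect(discoveryIds, targetIds)))
    stop("discovery and target sets must be disjoint")
  lambda <- (1 - h2) / h2
  Gdd <- A[discoveryIds, discoveryIds, drop = FALSE]
  Gtd <- A[targetIds, discoveryIds, drop = FALSE]
  yc <- as.numeric(y) - mean(y)
  C <- Gdd + diag(lambda + jitter, nrow(Gdd))
  sol <- tryCatch(solve(C, yc), error = function(err)
    stop("GBLUP system is not positive definite after jitter: ",
         conditionMessage(err)))
  data.frame(id = targetIds, score = as.numeric(Gtd %*% sol),
             stringsAsFactors = FALSE)
}

#' SNP-BLUP (ridge) genetic profile scores
#'
#' Estimates standardized-SNP effects jointly by ridge regression,
#' beta = Z_d' (Z_d Z_d'/m + lambda I)^-1 y / m, and projects them onto the
#' target genotypes. Dosages are standardized with allele frequencies
#' computed jointly over discovery and target individuals, so the result is
#' identical to [gblupPredict()] on the GRM built from the same
#' [GenotypeMatrix-class].
#'
#' @param geno a [GenotypeMatrix-class] covering discovery and target
#'   individuals.
#' @param y named numeric vector of discovery phenotypes, or unnamed and
#'   aligned with `discoveryIds`.
#' @inheritParams gblupPredict
#' @return a data.frame with columns `id` and `score`; the estimated SNP
#'   effects are attached as attribute `"beta"`.
#' @export
snpBlupPredict <- function(geno, y, discoveryIds, targetIds, h2, jitter = 1e-8) {
  stopifnot(is(geno, "GenotypeMatrix"), h2 > 0, h2 < 1)
  discoveryIds <- as.character(discoveryIds)
  targetIds <- as.character(targetIds)
  if (!is.null(names(y))) y <- y[discoveryIds]
  if (length(y) != length(discoveryIds) || anyNA(y))
    stop("y must provide one non-missing phenotype per discovery individual")
  Z <- standardizeDosages(geno, warnMono = FALSE)
  missing <- setdiff(c(discoveryIds, targetIds), rownames(Z))
  if (length(missing))
    stop("ids absent from the genotypes: ",
         paste(utils::head(missing, 3), collapse = ", "))
  m <- ncol(Z)
  Zd <- Z[discoveryIds, , drop = FALSE]
  Zt <- Z[targetIds, , drop = FALSE]
  lambda <- (1 - h2) / h2
  yc <- as.numeric(y) - mean(y)
  C <- tcrossprod(Zd) / m + diag(lambda + jitter, length(discoveryIds))
  sol <- tryCatch(solve(C, yc), error = function(err)
    stop("SNP-BLUP system is not positive definite after jitter: ",
         conditionMessage(err)))
  beta <- drop(crossprod(Zd, sol)) / m
  out <- data.frame(id = targetIds, score = as.numeric(Zt %*% beta),
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  out
}
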