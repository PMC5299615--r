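#' Construct a GenotypeMatrix from a dosage matrix
#'
#' Wraps an individuals-by-SNPs matrix of allele dosages (0/1/2, NA allowed)
#' and computes per-SNP counted-allele frequencies from the non-missing
#' entries. Row names are individual ids (generated if absent); column names
#' are SNP ids.
#'
#' @param dosages numeric matrix, individuals x SNPs, entries in \[0, 2\].
#' @return a [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("id", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  p <- colMeans(dosages, na.rm = TRUE) / 2
  new("GenotypeMatrix", dosages = dosages, alleleFreq = p)
}

#' Read a tab-delimited dosage table
#'
#' Reads genotype dosages from a tab-delimited text table. A PLINK-.raw-style
#' header (`FID IID PAT MAT SEX PHENOTYPE snp1 ...`) is accepted, in which
#' case the first six columns are treated as metadata and `IID` supplies the
#' individual ids; otherwise the first two columns are taken as family and
#' individual id.
#'
#' @param path path to the table.
#' @return a [GenotypeMatrix-class].
#' @seealso [writeDosage()]
#' @export
readDosage <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  plinkMeta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plinkMeta %in% names(tab)[1:6])) {
    ids <- as.character(tab$IID)
    geno <- as.matrix(tab[, setdiff(names(tab), plinkMeta), drop = FALSE])
  } else {
    ids <- as.character(tab[[2]])
    geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  }
  rownames(geno) <- ids
  genotypeMatrix(geno)
}

#' Write a tab-delimited dosage table
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output path.
#' @param familyIds optional family ids for the first column (defaults to the
#'   individual ids).
#' @return `path`, invisibly.
#' @export
writeDosage <- function(x, path, familyIds = NULL) {
  stopifnot(is(x, "GenotypeMatrix"))
  ids <- sampleIds(x)
  if (is.null(familyIds)) familyIds <- ids
  tab <- data.frame(FID = familyIds, IID = ids, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(dosages(x), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# column-standardize dosages: subtract 2p, divide by sqrt(2p(1-p));
# missing entries mean-imputed first. Monomorphic SNPs are dropped.
standardizeDosages <- function(x, warnMono = TRUE) {
  d <- dosages(x)
  p <- alleleFreq(x)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic")
  if (warnMono && any(!poly))
    warning(sprintf("dropping %d monomorphic SNP(s)", sum(!poly)))
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  if (anyNA(d)) {
    mu <- rep(2 * p, each = nrow(d))
    d[is.na(d)] <- mu[is.na(d)]
  }
  Z <- sweep(d, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  Z
}

#' Build a genomic relationship matrix
#'
#' Computes the VanRaden/GCTA-style GRM A = Z Z' / m, where Z is the
#' column-standardized dosage matrix (per SNP: subtract twice the allele
#' frequency, divide by sqrt(2p(1-p))) and m the number of polymorphic SNPs.
#' Missing dosages are mean-imputed per SNP; monomorphic SNPs are dropped
#' with a warning.
#'
#' @param x a [GenotypeMatrix-class].
#' @return a [Grm-class].
#' @examples
#' g <- genotypeMatrix(matrix(rbinom(200, 2, 0.5), nrow = 10))
#' buildGRM(g)
#' @export
buildGRM <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  Z <- standardizeDosages(x)
  A <- tcrossprod(Z) / ncol(Z)
  dimnames(A) <- list(sampleIds(x), sampleIds(x))
  new("Grm", values = A, nSnps = ncol(Z))
}

grmBlock <- function(grm, discoveryIds, targetIds) {
  ids <- sampleIds(grm)
  discoveryIds <- as.character(discoveryIds)
  targetIds <- as.character(targetIds)
  if (!length(discoveryIds) || !length(targetIds))
    stop("discovery and target id sets must both be nonempty")
  if (length(shared <- intersect(discoveryIds, targetIds)))
    stop("discovery and target sets must be disjoint (shared: ",
         paste(utils::head(shared, 3), collapse = ", "), " ...)")
  missing <- setdiff(c(discoveryIds, targetIds), ids)
  if (length(missing))
    stop("ids absent from the GRM: ", paste(utils::head(missing, 3), collapse = ", "))
  as.matrix(grm)[targetIds, discoveryIds, drop = FALSE]
}

#' Empirical Me from discovery-by-target genomic relationships
#'
#' Estimates the effective number of chromosome segments as the reciprocal of
#' the variance of the relationships A_ij between each target individual i and
#' each discovery individual j (the off-diagonal block of the GRM). The
#' variance uses the population (1/n) denominator over the pooled block; the
#' per-target-individual variance vector is returned in the details.
#'
#' @param grm a [Grm-class] covering discovery and target individuals.
#' @param discoveryIds,targetIds disjoint, nonempty id sets.
#' @return a [MeEstimate-class] with method `"grm_variance"`; details carry
#'   `perTargetVariance` (named by target id) and the block dimensions.
#' @export
meFromGRM <- function(grm, discoveryIds, targetIds) {
  B <- grmBlock(grm, discoveryIds, targetIds)
  n <- length(B)
  v <- sum((B - mean(B))^2) / n
  if (v <= 0 || n < 2)
    stop("Me undefined: zero variance in the discovery-target relationship block")
  rowMu <- rowMeans(B)
  perTarget <- rowSums((B - rowMu)^2) / ncol(B)
  new("MeEstimate", value = 1 / v, method = "grm_variance",
      details = list(perTargetVariance = perTarget,
                     nTarget = nrow(B), nDiscovery = ncol(B)))
}

#' Rank target individuals by relationship variance with the discovery set
#'
#' Returns the top fraction of target individuals ranked by the variance of
#' their genomic relationships with the discovery individuals. A target
#' individual with close relatives in the discovery set has a high
#' relationship variance and is expected to be predicted more accurately.
#' Ties are broken by id order.
#'
#' @param grm a [Grm-class].
#' @param discoveryIds,targetIds disjoint id sets.
#' @param topFraction fraction of target individuals to keep, in (0, 1\].
#' @return character vector of selected target ids (highest variance first).
#' @export
targetVarianceRanking <- function(grm, discoveryIds, targetIds, topFraction) {
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  B <- grmBlock(grm, discoveryIds, targetIds)
  v <- rowSums((B - rowMeans(B))^2) / ncol(B)
  nKeep <- max(1L, floor(length(v) * topFraction + 1e-9))
  ord <- order(-v, rownames(B))
  sel <- rownames(B)[ord][seq_len(nKeep)]
  if (!length(sel)) stop("empty selection")
  sel
}

#' Greedy relatedness pruning
#'
#' Removes individuals until no pair has a relationship above `threshold`.
#' At each step the individual involved in the most above-threshold pairs is
#' removed (ties broken by id order), so exactly one member of an isolated
#' related pair is dropped and two members of a 3-clique are dropped.
#'
#' @param grm a [Grm-class].
#' @param threshold relationship cut-off (> 0), e.g. 0.025.
#' @return character vector of retained individual ids, in original order.
#' @export
pruneRelatedness <- function(grm, threshold) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  A <- as.matrix(grm)
  ids <- rownames(A)
  adj <- A > threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    worst <- names(deg)[order(-deg, names(deg))][1]
    keep[match(worst, ids)] <- FALSE
  }
  ids[keep]
}

#' Write a GRM in GCTA text format
#'
#' Writes `<prefix>.grm` with one lower-triangle record per line
#' (`i j nSnps A_ij`, 1-based indices, tab-delimited) and `<prefix>.grm.id`
#' with family and individual id columns.
#'
#' @param grm a [Grm-class].
#' @param prefix output path prefix.
#' @param familyIds optional family ids (defaults to individual ids).
#' @return `prefix`, invisibly.
#' @seealso [readGRM()]
#' @export
writeGRM <- function(grm, prefix, familyIds = NULL) {
  stopifnot(is(grm, "Grm"))
  A <- as.matrix(grm)
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(familyIds)) familyIds <- ids
  i <- rep(seq_len(n), times = seq_len(n))
  j <- sequence(seq_len(n))
  rec <- data.frame(i = i, j = j, n = grm@nSnps, a = A[cbind(i, j)])
  utils::write.table(rec, paste0(prefix, ".grm"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(familyIds, ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM in GCTA text format
#'
#' Reads `<prefix>.grm` (lower-triangle `i j nSnps A_ij` records) and
#' `<prefix>.grm.id`. Indices must be 1-based and consistent with the id
#' file; malformed rows raise an error naming the line.
#'
#' @param prefix path prefix (as used by [writeGRM()]).
#' @return a [Grm-class].
#' @export
readGRM <- function(prefix) {
  idTab <- utils::read.table(paste0(prefix, ".grm.id"), sep = "\t",
                             stringsAsFactors = FALSE)
  ids <- as.character(idTab[[2]])
  n <- length(ids)
  lines <- readLines(paste0(prefix, ".grm"))
  fields <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop(sprintf("malformed GRM record at line %d: expected 4 fields, found %d",
                 bad[1], lengths(fields)[bad[1]]))
  rec <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  i <- as.integer(rec[, 1]); j <- as.integer(rec[, 2])
  if (any(i < 1 | i > n | j < 1 | j > i))
    stop("GRM indices inconsistent with the id file (need 1 <= j <= i <= n)")
  if (anyDuplicated(cbind(i, j)))
    stop("duplicate (i, j) records in GRM file")
  if (nrow(rec) != n * (n + 1) / 2)
    stop(sprintf("expected %d lower-triangle records for %d ids, found %d",
                 n * (n + 1) / 2, n, nrow(rec)))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(i, j)] <- rec[, 4]
  A[cbind(j, i)] <- rec[, 4]
  new("Grm", values = A, nSnps = rec[1, 3])
}
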