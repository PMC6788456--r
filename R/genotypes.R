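#' Read genotypes and SNP map from delimited text
#'
#' The genotype file is a delimited matrix of 0/1/2 allele counts with a
#' header of SNP ids and individual ids in the first column. The map file is
#' a TSV with columns `snp`, `chr`, `pos` and optionally `allele` (the
#' counted allele).
#'
#' @param genoPath path to the genotype matrix file.
#' @param mapPath path to the SNP map file.
#' @param sep field separator (default tab).
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(genoPath, mapPath, sep = "\t") {
  g <- utils::read.table(genoPath, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(g[[1]])
  codes <- as.matrix(g[, -1, drop = FALSE])
  map <- utils::read.table(mapPath, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  GenotypeData(codes, map, ids)
}

#' SNP quality control
#'
#' Drops SNPs that (in this order, each SNP counted once under the first
#' filter it fails): map to a sex chromosome; are monomorphic; or have minor
#' allele frequency strictly below `mafMin`. A SNP at exactly `mafMin` is
#' retained.
#'
#' @param geno a [GenotypeData-class].
#' @param sexChromosomes character vector of chromosome labels to exclude
#'   (default `c("X", "Y")`).
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @return list with `geno` (filtered [GenotypeData-class]) and `report`
#'   (named integer vector: `sex`, `mono`, `maf`, `retained`).
#' @export
qcSnps <- function(geno, sexChromosomes = c("X", "Y"), mafMin = 0.01) {
  codes <- genoCodes(geno)
  map <- snpMap(geno)
  p <- colMeans(codes) / 2
  maf <- pmin(p, 1 - p)
  failSex <- map$chr %in% sexChromosomes
  failMono <- !failSex & (maf == 0)
  failMaf <- !failSex & !failMono & (maf < mafMin)
  keep <- !(failSex | failMono | failMaf)
  report <- c(sex = sum(failSex), mono = sum(failMono), maf = sum(failMaf),
              retained = sum(keep))
  out <- GenotypeData(codes[, keep, drop = FALSE],
                      map[keep, , drop = FALSE], sampleIds(geno))
  list(geno = out, report = report)
}

#' Genomic relationship matrix
#'
#' Centred cross-product construction with observed allele frequencies:
#' \eqn{G_{raw} = ZZ' / (2\sum_j p_j(1-p_j))} with \eqn{Z = M - 2p} the
#' column-centred allele counts. To guarantee invertibility inside the
#' single-step system, the returned matrix is blended with the pedigree
#' block, \eqn{G = (1-blend)\,G_{raw} + blend\,A_{22}} (default 0.05).
#'
#' @param geno a [GenotypeData-class] (post-QC).
#' @param A22 a [RelationshipMatrix-class] of kind `"A22"` over the same ids
#'   in the same order; required when `blend > 0`.
#' @param blend blending proportion on A22 (default 0.05). `blend = 0`
#'   returns the raw genomic matrix.
#' @return list with `G` (a [RelationshipMatrix-class] of kind `"G"`) and
#'   `alleleFreq` (the observed frequencies used for centring; carry these
#'   into backsolving).
#' @export
buildG <- function(geno, A22 = NULL, blend = 0.05) {
  codes <- genoCodes(geno)
  if (nrow(codes) < 2) stop("need at least 2 genotyped individuals")
  p <- colMeans(codes) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all SNPs are monomorphic: zero scaling denominator")
  Z <- sweep(codes, 2, 2 * p)
  Graw <- tcrossprod(Z) / denom
  if (blend > 0) {
    if (is.null(A22)) stop("A22 required when blend > 0")
    if (!identical(relIds(A22), sampleIds(geno)))
      stop("A22 ids must match genotype ids in order")
    G <- (1 - blend) * Graw + blend * relValues(A22)
  } else {
    G <- Graw
  }
  list(G = RelationshipMatrix(G, sampleIds(geno), "G"),
       alleleFreq = p)
}
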