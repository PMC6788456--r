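#' @import methods
#' @importClassesFrom Matrix Matrix
NULL

#' Pedigree of animals with topological ordering
#'
#' Holds a renumbered pedigree: animals are coded `1..n` in an order where
#' parents always precede offspring; unknown parents are coded `0`. Construct
#' with [Pedigree()], which accepts arbitrary id labels and sorts/renumbers.
#'
#' @slot animal character vector of original animal labels, in internal order.
#' @slot sire integer vector of sire codes (`0` = unknown).
#' @slot dam integer vector of dam codes (`0` = unknown).
#'
#' @seealso [Pedigree()], [buildAInverse()], [inbreeding()]
#' @export
setClass("Pedigree",
  representation(animal = "character", sire = "integer", dam = "integer"),
  validity = function(object) {
    n <- length(object@animal)
    if (length(object@sire) != n || length(object@dam) != n)
      return("animal, sire and dam must have equal length")
    if (anyDuplicated(object@animal))
      return("duplicated animal ids")
    par <- c(object@sire, object@dam)
    if (any(par < 0L) || any(par > n))
      return("parent codes out of range")
    idx <- seq_len(n)
    if (any(object@sire >= idx) || any(object@dam >= idx))
      return("pedigree not topologically ordered (parent code >= own code)")
    TRUE
  }
)

#' Genotypes with SNP map
#'
#' A matrix of allele counts (0/1/2, the count of the designated counted
#' allele) over individuals, plus a SNP map with chromosome and physical
#' position. Missing calls are rejected: genotypes must be complete.
#'
#' @slot codes integer matrix, individuals x SNPs; entries in \{0,1,2\}.
#' @slot map data.frame with columns `snp`, `chr`, `pos`, `allele`
#'   (the counted allele, informational), one row per SNP, positions sorted
#'   within chromosome.
#' @slot ids character vector of individual ids (rownames of `codes`).
#'
#' @seealso [GenotypeData()], [qcSnps()], [buildG()]
#' @export
setClass("GenotypeData",
  representation(codes = "matrix", map = "data.frame", ids = "character"),
  validity = function(object) {
    if (anyNA(object@codes))
      return("missing genotype calls are not supported; impute or drop upstream")
    if (!all(object@codes %in% c(0L, 1L, 2L)))
      return("genotype codes must be 0, 1 or 2")
    if (nrow(object@codes) != length(object@ids))
      return("ids length must match rows of codes")
    need <- c("snp", "chr", "pos")
    if (!all(need %in% names(object@map)))
      return("map must have columns snp, chr, pos")
    if (nrow(object@map) != ncol(object@codes))
      return("map rows must match columns of codes")
    if (any(object@map$pos < 0))
      return("map positions must be non-negative")
    bychr <- split(object@map$pos, object@map$chr)
    if (!all(vapply(bychr, function(p) !is.unsorted(p), logical(1))))
      return("map positions must be sorted within chromosome")
    TRUE
  }
)

#' Relationship matrix over an ordered id list
#'
#' A symmetric (possibly sparse) relationship or inverse-relationship matrix
#' with its id list and a `kind` tag recording what it is.
#'
#' @slot values a base or Matrix-package matrix, symmetric.
#' @slot ids character vector of ids in matrix order.
#' @slot kind one of `"A"`, `"A_inverse"`, `"A22"`, `"A22_inverse"`, `"G"`,
#'   `"G_inverse"`, `"H_inverse"`.
#'
#' @export
setClass("RelationshipMatrix",
  representation(values = "ANY", ids = "character", kind = "character"),
  validity = function(object) {
    kinds <- c("A", "A_inverse", "A22", "A22_inverse", "G", "G_inverse",
               "H_inverse")
    if (length(object@kind) != 1L || !(object@kind %in% kinds))
      return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (nrow(v) != length(object@ids)) return("ids must match matrix dimension")
    if (nrow(v) > 0) {
      asym <- max(abs(v - Matrix::t(v)))
      if (asym > 1e-8 * max(1, max(abs(v))))
        return(sprintf("matrix not symmetric (max asymmetry %.3g)", asym))
    }
    TRUE
  }
)

#' Variance components of the reaction-norm repeatability model
#'
#' For one yield trait analysed over `nParities` parities: the additive
#' (co)variance matrix `Phi` and permanent-environment matrix `Psi`, both of
#' dimension `2*nParities` over coefficients ordered
#' (intercept parity 1, slope parity 1, intercept parity 2, ...), and the
#' per-parity residual variances `Rdiag`.
#'
#' @slot Phi numeric matrix, additive-genetic (co)variances, 2P x 2P, PD.
#' @slot Psi numeric matrix, permanent-environment (co)variances, 2P x 2P, PD.
#' @slot Rdiag numeric vector of P residual variances, all > 0.
#' @slot nParities integer, number of parities P.
#'
#' @seealso [VarianceComponents()], [gibbsSampler()], [heritabilityAt()]
#' @export
setClass("VarianceComponents",
  representation(Phi = "matrix", Psi = "matrix", Rdiag = "numeric",
                 nParities = "integer"),
  validity = function(object) {
    p2 <- 2L * object@nParities
    if (!all(dim(object@Phi) == p2)) return("Phi must be 2P x 2P")
    if (!all(dim(object@Psi) == p2)) return("Psi must be 2P x 2P")
    if (length(object@Rdiag) != object@nParities)
      return("Rdiag must have one entry per parity")
    if (any(object@Rdiag <= 0)) return("residual variances must be positive")
    for (nm in c("Phi", "Psi")) {
      m <- slot(object, nm)
      if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
        return(sprintf("%s must be symmetric", nm))
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0)
        return(sprintf("%s must be positive definite (min eigenvalue %.3g)",
                       nm, min(ev)))
    }
    TRUE
  }
)

#' Retained draws of a Gibbs variance-component chain
#'
#' @slot samples numeric matrix, one row per retained draw; columns are the
#'   lower triangle (column-major) of Phi, then of Psi, then the per-parity
#'   residual variances. Column names identify each scalar component.
#' @slot meta list with at least `total`, `burnin`, `thin`, `seed`,
#'   `nParities`, `jitter` (count of jittered covariance draws).
#'
#' @seealso [gibbsSampler()], [posteriorSummary()], [chainGeneticParameters()]
#' @export
setClass("PosteriorChain",
  representation(samples = "matrix", meta = "list"),
  validity = function(object) {
    need <- c("total", "burnin", "thin", "nParities")
    if (!all(need %in% names(object@meta)))
      return("meta must contain total, burnin, thin, nParities")
    m <- object@meta
    want <- (m$total - m$burnin) %/% m$thin
    if (nrow(object@samples) != want)
      return(sprintf("retained draws (%d) != (total - burnin)/thin (%d)",
                     nrow(object@samples), want))
    TRUE
  }
)
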