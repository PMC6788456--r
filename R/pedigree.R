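#' Read a pedigree from 3-column delimited text
#'
#' Columns: animal, sire, dam; `0`, empty or `NA` marks an unknown parent.
#' The pedigree is topologically sorted and renumbered internally.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path, sep = "\t") {
  p <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = "character")
  if (ncol(p) < 3) stop("pedigree file must have 3 columns: animal, sire, dam")
  Pedigree(p[[1]], p[[2]], p[[3]])
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F without forming the full
#' relationship matrix, via the L-matrix recursion over each animal's
#' ancestry. Needed both for Henderson's A-inverse rules and for scaling
#' Mendelian-sampling variance when simulating breeding values.
#'
#' @param ped a [Pedigree-class].
#' @return numeric vector of inbreeding coefficients, pedigree order.
#' @export
inbreeding <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire; d <- ped@dam
  f <- numeric(n)       # inbreeding
  dii <- numeric(n)     # within-animal Mendelian variance (diagonal of D)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) f[s[i]] else -1
    fd <- if (d[i] > 0L) f[d[i]] else -1
    dii[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0L || d[i] == 0L) { f[i] <- 0; next }
    # accumulate L-row of animal i over its ancestors
    L <- numeric(i)
    L[i] <- 1
    fi <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      lj <- L[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      fi <- fi + lj * lj * dii[j]
    }
    f[i] <- fi - 1
  }
  stats::setNames(f, animalIds(ped))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules, with Mendelian-sampling
#' variances adjusted for inbreeding (coefficients from [inbreeding()]):
#' each animal contributes \eqn{d_i^{-1} e_i e_i'} with
#' \eqn{e_i = (1, -0.5, -0.5)} on (animal, sire, dam) and
#' \eqn{d_i = 0.5 - 0.25(F_s + F_d)} (0.75 or 1 with one or both parents
#' unknown). Never forms dense A.
#'
#' @param ped a [Pedigree-class].
#' @return a [RelationshipMatrix-class] of kind `"A_inverse"` (sparse).
#' @examples
#' ped <- Pedigree(c("s","d","o"), c(NA,NA,"s"), c(NA,NA,"d"))
#' as.matrix(relValues(buildAInverse(ped)))  # textbook trio closed form
#' @export
buildAInverse <- function(ped) {
  n <- nAnimals(ped)
  f <- unname(inbreeding(ped))
  s <- ped@sire; d <- ped@dam
  fs <- rep(-1, n); fs[s > 0L] <- f[s[s > 0L]]
  fd <- rep(-1, n); fd[d > 0L] <- f[d[d > 0L]]
  dinv <- 1 / (0.5 - 0.25 * (fs + fd))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    mem <- c(i, if (s[i] > 0L) s[i], if (d[i] > 0L) d[i])
    w <- c(1, if (s[i] > 0L) -0.5, if (d[i] > 0L) -0.5)
    k <- length(mem)
    ii <- c(ii, rep(mem, each = k))
    jj <- c(jj, rep(mem, times = k))
    xx <- c(xx, as.vector(outer(w, w)) * dinv[i])
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  RelationshipMatrix(Ainv, animalIds(ped), "A_inverse")
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Recursive tabular construction of A; intended for moderate pedigrees and
#' for extracting blocks such as A22. For model equations use the sparse
#' [buildAInverse()].
#'
#' @param ped a [Pedigree-class].
#' @return a [RelationshipMatrix-class] of kind `"A"` (dense).
#' @export
buildA <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire; d <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                    (if (d[i] > 0L) A[j, d[i]] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  RelationshipMatrix(A, animalIds(ped), "A")
}

#' Pedigree relationship block among genotyped animals
#'
#' Extracts A22, the submatrix of the numerator relationship matrix over the
#' genotyped animals, in the order of `genotypedIds`.
#'
#' @param ped a [Pedigree-class].
#' @param genotypedIds character vector of genotyped animal ids.
#' @return a [RelationshipMatrix-class] of kind `"A22"` (dense).
#' @export
extractA22 <- function(ped, genotypedIds) {
  genotypedIds <- as.character(genotypedIds)
  m <- match(genotypedIds, animalIds(ped))
  if (anyNA(m))
    stop("ids not in pedigree: ",
         paste(genotypedIds[is.na(m)], collapse = ", "))
  A <- relValues(buildA(ped))
  RelationshipMatrix(A[m, m, drop = FALSE], genotypedIds, "A22")
}
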