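#' Single-step combined inverse relationship matrix
#'
#' Assembles the inverse realized relationship matrix of single-step GBLUP:
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
#' \end{bmatrix}}
#' i.e. A-inverse with the correction `G^-1 - A22^-1` added into the block of
#' genotyped animals; all other entries equal those of A-inverse.
#'
#' @param Ainv [RelationshipMatrix-class] of kind `"A_inverse"` over all
#'   animals.
#' @param Ginv [RelationshipMatrix-class] of kind `"G_inverse"` over the
#'   genotyped animals.
#' @param A22inv [RelationshipMatrix-class] of kind `"A22_inverse"` over the
#'   same genotyped animals, same order.
#' @return a [RelationshipMatrix-class] of kind `"H_inverse"` (sparse with a
#'   dense genotyped block).
#' @export
buildHInverse <- function(Ainv, Ginv, A22inv) {
  if (relKind(Ainv) != "A_inverse") stop("Ainv must have kind A_inverse")
  if (!identical(relIds(Ginv), relIds(A22inv)))
    stop("Ginv and A22inv must cover the same ids in the same order")
  idx <- match(relIds(Ginv), relIds(Ainv))
  if (anyNA(idx))
    stop("genotyped ids absent from A-inverse: ",
         paste(relIds(Ginv)[is.na(idx)], collapse = ", "))
  A <- as(as(relValues(Ainv), "generalMatrix"), "CsparseMatrix")
  delta <- as.matrix(relValues(Ginv)) - as.matrix(relValues(A22inv))
  ng <- length(idx)
  D <- Matrix::sparseMatrix(i = rep(idx, times = ng),
                            j = rep(idx, each = ng),
                            x = as.numeric(delta), dims = dim(A))
  H <- A + D
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  RelationshipMatrix(H, relIds(Ainv), "H_inverse")
}

#' Invert a relationship matrix
#'
#' Dense symmetric inversion with the appropriate kind relabel
#' (`A22` to `A22_inverse`, `G` to `G_inverse`).
#'
#' @param rel a [RelationshipMatrix-class] of kind `"A"`, `"A22"` or `"G"`.
#' @return a [RelationshipMatrix-class] of the inverse kind.
#' @export
invertRelationship <- function(rel) {
  kind <- switch(relKind(rel),
                 A = "A_inverse", A22 = "A22_inverse", G = "G_inverse",
                 stop("cannot invert kind ", relKind(rel)))
  V <- as.matrix(relValues(rel))
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e)
    stop(relKind(rel), " is not positive definite: ", conditionMessage(e)))
  Vi <- (Vi + t(Vi)) / 2
  RelationshipMatrix(Vi, relIds(rel), kind)
}
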