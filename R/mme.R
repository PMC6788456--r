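#' Assemble the mixed-model equations
#'
#' Builds the symmetric sparse coefficient matrix and right-hand side of the
#' reaction-norm test-day model for fixed effects (herd-test-day, DIM class),
#' additive reaction-norm pairs per animal (precision
#' \eqn{K^{-1} \otimes \Phi^{-1}}) and permanent-environment pairs per
#' phenotyped cow (precision \eqn{I \otimes \Psi^{-1}}), with residual weight
#' \eqn{1/\sigma^2_{e}} of the record's parity. `K^-1` is A-inverse for a
#' pedigree run or H-inverse for a single-step genomic run.
#'
#' @param design an `rrmDesign` from [buildDesign()].
#' @param vc a [VarianceComponents-class] (must match the design's parities).
#' @param Kinv a [RelationshipMatrix-class] of kind `"A_inverse"` or
#'   `"H_inverse"` over the design's pedigree.
#' @return list with sparse symmetric `C`, right-hand side `rhs`, and the
#'   block index map `blocks` (`htd`, `dim`, `additive`, `permanent`).
#' @export
assembleMME <- function(design, vc, Kinv) {
  stopifnot(inherits(design, "rrmDesign"))
  P <- design$nParities
  if (vc@nParities != P)
    stop("variance components are for ", vc@nParities,
         " parities but design has ", P)
  if (!relKind(Kinv) %in% c("A_inverse", "H_inverse"))
    stop("Kinv must have kind A_inverse or H_inverse")
  N <- nAnimals(design$ped)
  if (length(relIds(Kinv)) != N ||
      !identical(relIds(Kinv), animalIds(design$ped)))
    stop("Kinv ids must match the design pedigree")
  p2 <- 2L * P
  nH <- length(design$htdLevels)
  nD <- length(design$dimLevels)
  nC <- length(design$cowIds)
  nrec <- length(design$y)

  offH <- 0L; offD <- nH; offU <- nH + nD; offW <- offU + p2 * N
  ntot <- offW + p2 * nC

  # record-by-effect incidence (rows = records)
  ri <- seq_len(nrec)
  acol <- (design$animal - 1L) * p2 + 2L * design$parity - 1L
  wcol <- (design$cow - 1L) * p2 + 2L * design$parity - 1L
  i <- c(ri, ri[design$dimcl > 0L], ri, ri, ri, ri)
  j <- c(offH + design$htd,
         offD + design$dimcl[design$dimcl > 0L],
         offU + acol, offU + acol + 1L,
         offW + wcol, offW + wcol + 1L)
  x <- c(rep(1, nrec), rep(1, sum(design$dimcl > 0L)),
         rep(1, nrec), design$f, rep(1, nrec), design$f)
  Z <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrec, ntot))
  wts <- 1 / vc@Rdiag[design$parity]
  C <- Matrix::crossprod(Z, Z * wts)
  rhs <- as.numeric(Matrix::crossprod(Z, design$y * wts))

  PhiInv <- chol2inv(chol(vc@Phi))
  PsiInv <- chol2inv(chol(vc@Psi))
  K <- as(as(relValues(Kinv), "generalMatrix"), "CsparseMatrix")
  Kadd <- Matrix::bdiag(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(nH + nD, nH + nD)),
    Matrix::kronecker(K, Matrix::Matrix(PhiInv)),
    Matrix::kronecker(Matrix::Diagonal(nC), Matrix::Matrix(PsiInv)))
  C <- C + Kadd
  iu <- offU + seq_len(p2 * N)
  iw <- offW + seq_len(p2 * nC)
  C <- Matrix::forceSymmetric((C + Matrix::t(C)) / 2)

  list(C = C, rhs = rhs,
       blocks = list(htd = offH + seq_len(nH), dim = offD + seq_len(nD),
                     additive = iu, permanent = iw),
       design = design, vc = vc)
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky solve of the assembled system, with a residual
#' check. Identifiability is handled at design time (baseline DIM class per
#' parity fixed at zero); any remaining data-dependent confounding among
#' fixed-effect levels is detected by pivoted QR of the fixed incidence and
#' resolved by constraining the dependent levels to zero.
#'
#' @param system output of [assembleMME()].
#' @param tol maximum admissible relative residual (default 1e-8).
#' @return list of class `"effectSolutions"`: `fixed` (data.frame of
#'   herd-test-day and DIM-class estimates), `additive` (animals x 2P matrix
#'   of (intercept, slope) pairs, all pedigree animals), `permanent`
#'   (phenotyped cows x 2P), and `relResidual`.
#' @export
solveMME <- function(system, tol = 1e-8) {
  C <- system$C; rhs <- system$rhs
  trySolve <- function() suppressWarnings(tryCatch(
    as.numeric(Matrix::solve(C, rhs)), error = function(e) e))
  sol <- trySolve()
  if (inherits(sol, "error")) {
    # data-dependent confounding among fixed-effect levels: constrain the
    # dependent columns (found by pivoted QR of the fixed incidence) to zero
    fixedIdx <- c(system$blocks$htd, system$blocks$dim)
    d <- system$design
    nrec <- length(d$y)
    X <- matrix(0, nrec, length(fixedIdx))
    X[cbind(seq_len(nrec), d$htd)] <- 1
    hasD <- d$dimcl > 0L
    X[cbind(which(hasD), length(d$htdLevels) + d$dimcl[hasD])] <- 1
    qrX <- qr(X, LAPACK = TRUE)
    rk <- sum(abs(diag(qr.R(qrX))) > 1e-8 * max(abs(diag(qr.R(qrX)))))
    if (rk < ncol(X)) {
      dep <- fixedIdx[qrX$pivot[(rk + 1):ncol(X)]]
      C[dep, ] <- 0; C[, dep] <- 0
      C[cbind(dep, dep)] <- 1
      rhs[dep] <- 0
      C <- Matrix::forceSymmetric(C)
      sol <- trySolve()
    }
  }
  if (inherits(sol, "error"))
    stop("mixed-model equations could not be solved (singular system?): ",
         conditionMessage(sol))
  rel <- sqrt(sum((as.numeric(C %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (rel > tol)
    stop(sprintf("solver residual %.3g exceeds tolerance %.3g", rel, tol))
  d <- system$design
  P <- d$nParities; p2 <- 2L * P
  b <- system$blocks
  fixed <- data.frame(
    effect = c(rep("htd", length(b$htd)), rep("dim", length(b$dim))),
    level = c(d$htdLevels, d$dimLevels),
    estimate = sol[c(b$htd, b$dim)], stringsAsFactors = FALSE)
  U <- matrix(sol[b$additive], ncol = p2, byrow = TRUE,
              dimnames = list(animalIds(d$ped), coefNames(P)))
  W <- matrix(sol[b$permanent], ncol = p2, byrow = TRUE,
              dimnames = list(d$cowIds, coefNames(P)))
  structure(list(fixed = fixed, additive = U, permanent = W,
                 relResidual = rel), class = "effectSolutions")
}

#' Extract (G)EBV components for a set of animals
#'
#' Pulls the additive intercept ("general", `a`) or slope ("thermotolerance",
#' `v`) solutions of one parity for the requested animals — e.g. the GEBVs of
#' genotyped animals from a single-step solve, ready for SNP-effect
#' backsolving.
#'
#' @param solutions an `effectSolutions` from [solveMME()].
#' @param ids animal ids.
#' @param component `"a"` (intercept) or `"v"` (slope).
#' @param parity parity number (indexing the design's parity list).
#' @return named numeric vector of breeding values.
#' @export
ebvComponent <- function(solutions, ids, component = c("a", "v"), parity = 1) {
  component <- match.arg(component)
  col <- paste0(component, parity)
  U <- solutions$additive
  if (!col %in% colnames(U)) stop("no such coefficient column: ", col)
  m <- match(as.character(ids), rownames(U))
  if (anyNA(m))
    stop("animals not in solutions: ",
         paste(ids[is.na(m)], collapse = ", "))
  stats::setNames(U[m, col], ids)
}
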