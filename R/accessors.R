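#' @rdname Pedigree-class
#' @param animal,sire,dam vectors of animal/sire/dam labels; use `NA` or `"0"`
#'   for unknown parents. Any atomic type; coerced to character.
#' @return `Pedigree()` returns a [Pedigree-class] object, topologically
#'   sorted and renumbered.
#' @examples
#' ped <- Pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' nAnimals(ped)
#' @export
Pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- rep(as.character(sire), length.out = length(animal))
  dam <- rep(as.character(dam), length.out = length(animal))
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (anyDuplicated(animal))
    stop("duplicated animal ids: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  # add parents that appear only as parents (treated as founders)
  onlypar <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(onlypar)) {
    animal <- c(animal, onlypar)
    sire <- c(sire, rep(NA_character_, length(onlypar)))
    dam <- c(dam, rep(NA_character_, length(onlypar)))
  }
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  ord <- topoOrder(si, di, animal)
  rank <- integer(n); rank[ord] <- seq_len(n)
  remap <- function(p) {
    out <- integer(length(p))
    out[p > 0L] <- rank[p[p > 0L]]
    out
  }
  new("Pedigree", animal = animal[ord],
      sire = as.integer(remap(si)[ord]), dam = as.integer(remap(di)[ord]))
}

# Kahn topological sort over the parent -> offspring DAG; errors on cycles
# naming the animals involved.
topoOrder <- function(sire, dam, labels) {
  n <- length(sire)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(sire[i], dam[i])) if (p > 0L) {
    indeg[i] <- indeg[i] + 1L
    kids[[p]] <- c(kids[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(labels[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' @rdname Pedigree-class
#' @param object,x a `Pedigree`.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname Pedigree-class
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@animal))

#' @rdname Pedigree-class
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @rdname Pedigree-class
#' @export
setMethod("animalIds", "Pedigree", function(x) x@animal)

#' @rdname Pedigree-class
#' @export
setGeneric("parents", function(x) standardGeneric("parents"))

#' @rdname Pedigree-class
#' @return `parents()` returns a data.frame (animal, sire, dam) with labels,
#'   `NA` for unknown.
#' @export
setMethod("parents", "Pedigree", function(x) {
  lab <- function(p) {
    out <- rep(NA_character_, length(p))
    out[p > 0L] <- x@animal[p[p > 0L]]
    out
  }
  data.frame(animal = x@animal, sire = lab(x@sire), dam = lab(x@dam),
             stringsAsFactors = FALSE)
})

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d animals (%d founders)\n", nAnimals(object),
              sum(object@sire == 0L & object@dam == 0L)))
})

#' @rdname GenotypeData-class
#' @param codes numeric/integer matrix of allele counts (individuals x SNPs).
#' @param map data.frame with columns `snp`, `chr`, `pos` and optionally
#'   `allele`; reordered to match `codes` columns by `snp` if names disagree.
#' @param ids individual ids; defaults to rownames of `codes`.
#' @export
GenotypeData <- function(codes, map, ids = rownames(codes)) {
  if (is.null(ids)) stop("individual ids required (rownames or ids=)")
  storage.mode(codes) <- "integer"
  if (!is.null(colnames(codes)) && !identical(colnames(codes), as.character(map$snp))) {
    m <- match(colnames(codes), map$snp)
    if (anyNA(m)) stop("map is missing SNPs present in codes: ",
                       paste(colnames(codes)[is.na(m)][1:5], collapse = ", "))
    map <- map[m, , drop = FALSE]
  }
  if (is.null(map$allele)) map$allele <- NA_character_
  map <- map[, c("snp", "chr", "pos", "allele")]
  map$snp <- as.character(map$snp); map$chr <- as.character(map$chr)
  rownames(map) <- NULL
  rownames(codes) <- ids
  colnames(codes) <- map$snp
  new("GenotypeData", codes = codes, map = map, ids = as.character(ids))
}

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@codes))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname GenotypeData-class
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData-class
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname GenotypeData-class
#' @export
setMethod("genoCodes", "GenotypeData", function(x) x@codes)

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@ids)

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d individuals x %d SNPs on %d chromosome(s)\n",
              length(object@ids), ncol(object@codes),
              length(unique(object@map$chr))))
})

#' @rdname RelationshipMatrix-class
#' @param values symmetric matrix (base or Matrix).
#' @param ids ids in matrix order.
#' @param kind matrix kind tag, see slot documentation.
#' @export
RelationshipMatrix <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  new("RelationshipMatrix", values = values, ids = as.character(ids),
      kind = kind)
}

#' @rdname RelationshipMatrix-class
#' @param x a `RelationshipMatrix`.
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' @rdname RelationshipMatrix-class
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' @rdname RelationshipMatrix-class
#' @export
setMethod("relKind", "RelationshipMatrix", function(x) x@kind)

#' @rdname RelationshipMatrix-class
#' @export
setGeneric("relIds", function(x) standardGeneric("relIds"))

#' @rdname RelationshipMatrix-class
#' @export
setMethod("relIds", "RelationshipMatrix", function(x) x@ids)

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix '%s': %d x %d (%s)\n", object@kind,
              nrow(object@values), ncol(object@values),
              if (methods::is(object@values, "sparseMatrix")) "sparse" else "dense"))
})

#' @rdname VarianceComponents-class
#' @param Phi,Psi,Rdiag see slots.
#' @export
VarianceComponents <- function(Phi, Psi, Rdiag) {
  P <- length(Rdiag)
  cf <- coefNames(P)
  dimnames(Phi) <- dimnames(Psi) <- list(cf, cf)
  new("VarianceComponents", Phi = Phi, Psi = Psi, Rdiag = as.numeric(Rdiag),
      nParities = as.integer(P))
}

coefNames <- function(P)
  as.vector(rbind(paste0("a", seq_len(P)), paste0("v", seq_len(P))))

#' @rdname VarianceComponents-class
#' @param x a `VarianceComponents`.
#' @export
setGeneric("vcPhi", function(x) standardGeneric("vcPhi"))
#' @rdname VarianceComponents-class
#' @export
setMethod("vcPhi", "VarianceComponents", function(x) x@Phi)
#' @rdname VarianceComponents-class
#' @export
setGeneric("vcPsi", function(x) standardGeneric("vcPsi"))
#' @rdname VarianceComponents-class
#' @export
setMethod("vcPsi", "VarianceComponents", function(x) x@Psi)
#' @rdname VarianceComponents-class
#' @export
setGeneric("vcResidual", function(x) standardGeneric("vcResidual"))
#' @rdname VarianceComponents-class
#' @export
setMethod("vcResidual", "VarianceComponents", function(x) x@Rdiag)

setMethod("show", "VarianceComponents", function(object) {
  P <- object@nParities
  cat(sprintf("VarianceComponents over %d parit%s\n", P,
              if (P == 1L) "y" else "ies"))
  for (l in seq_len(P))
    cat(sprintf("  parity %d: sigma_a2=%.4g sigma_v2=%.4g sigma_av=%.4g sigma_e2=%.4g\n",
                l, object@Phi[2 * l - 1, 2 * l - 1], object@Phi[2 * l, 2 * l],
                object@Phi[2 * l - 1, 2 * l], object@Rdiag[l]))
})

#' @rdname PosteriorChain-class
#' @param x a `PosteriorChain`.
#' @export
setGeneric("chainSamples", function(x) standardGeneric("chainSamples"))
#' @rdname PosteriorChain-class
#' @export
setMethod("chainSamples", "PosteriorChain", function(x) x@samples)
#' @rdname PosteriorChain-class
#' @export
setGeneric("chainMeta", function(x) standardGeneric("chainMeta"))
#' @rdname PosteriorChain-class
#' @export
setMethod("chainMeta", "PosteriorChain", function(x) x@meta)

setMethod("show", "PosteriorChain", function(object) {
  m <- object@meta
  cat(sprintf("PosteriorChain: %d retained draws (total %d, burn-in %d, thin %d)\n",
              nrow(object@samples), m$total, m$burnin, m$thin))
})
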