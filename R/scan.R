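#' Backsolve SNP effects from genomic breeding values
#'
#' Recovers per-SNP effects from the breeding-value component of genotyped
#' animals via \eqn{\hat{s} = DZ'(ZDZ')^{-}\hat{a}_g}, with Z the centred
#' genotype matrix (`codes - 2p`), D a diagonal SNP weight matrix (equal
#' weights by default) and \eqn{(\cdot)^-} a spectral pseudo-inverse with
#' relative eigenvalue cutoff 1e-10 — with more SNPs than animals, ZDZ' is
#' singular by construction and the pseudo-inverse yields the minimum-norm
#' preimage.
#'
#' @param gebv named numeric vector of breeding values over genotyped ids
#'   (general `a` or thermotolerance `v` component of one parity).
#' @param geno a [GenotypeData-class] covering those ids.
#' @param weights per-SNP weights (default equal).
#' @param alleleFreq centring allele frequencies; defaults to the observed
#'   frequencies (pass the frequencies used in [buildG()] for consistency).
#' @return data.frame of class `"snpEffectTrack"`: `snp`, `chr`, `pos`,
#'   `effect`, with attributes `component`/`parity` if set by the caller.
#' @export
backsolveSnpEffects <- function(gebv, geno, weights = NULL,
                                alleleFreq = NULL) {
  ids <- names(gebv)
  if (is.null(ids)) stop("gebv must be named by animal id")
  m <- match(ids, sampleIds(geno))
  if (anyNA(m))
    stop("gebv ids not genotyped: ", paste(ids[is.na(m)], collapse = ", "))
  codes <- genoCodes(geno)[m, , drop = FALSE]
  p <- if (is.null(alleleFreq)) colMeans(codes) / 2 else alleleFreq
  if (length(p) != ncol(codes)) stop("alleleFreq length mismatch")
  Z <- sweep(codes, 2, 2 * p)
  w <- if (is.null(weights)) rep(1, ncol(Z)) else weights
  if (length(w) != ncol(Z) || any(w <= 0))
    stop("weights must be positive, one per SNP")
  ZD <- sweep(Z, 2, w, `*`)
  ZDZ <- tcrossprod(ZD, Z)
  eg <- eigen((ZDZ + t(ZDZ)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  Vinv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  s <- as.numeric(crossprod(ZD, Vinv %*% gebv))
  map <- snpMap(geno)
  structure(data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                       effect = s, stringsAsFactors = FALSE),
            class = c("snpEffectTrack", "data.frame"))
}

#' Genetic variance explained by 2.0 Mb SNP windows
#'
#' For each window — anchored at every SNP and extending up to `windowBp`
#' rightward on the same chromosome (half-open, `[anchor, anchor +
#' windowBp)`) — computes the percentage of genetic variance explained:
#' \deqn{100 \cdot \mathrm{var}\left(\sum_{j \in window} Z_j \hat{s}_j\right)
#' / \sigma^2_u}
#' where the variance is over genotyped individuals and \eqn{\sigma^2_u} is
#' the variance of the total genomic value \eqn{Z\hat{s}} (per component and
#' parity). Set `tiling = TRUE` for distinct non-overlapping windows
#' instead of per-SNP anchors.
#'
#' @param track a `snpEffectTrack` from [backsolveSnpEffects()].
#' @param geno the matching [GenotypeData-class].
#' @param windowBp window span in bp (default 2e6).
#' @param tiling logical; use non-overlapping tiling windows (default FALSE:
#'   a sliding window anchored at each SNP).
#' @param alleleFreq centring frequencies (default observed).
#' @return data.frame of class `"windowVarianceTrack"`: `chr`, `start`,
#'   `end`, `first_snp`, `last_snp`, `n_snps`, `pct_variance`; attribute
#'   `sigma_u2` is the denominator.
#' @export
windowVariance <- function(track, geno, windowBp = 2e6, tiling = FALSE,
                           alleleFreq = NULL) {
  map <- snpMap(geno)
  if (!identical(as.character(track$snp), map$snp))
    stop("track and genotype map are not aligned")
  codes <- genoCodes(geno)
  p <- if (is.null(alleleFreq)) colMeans(codes) / 2 else alleleFreq
  Z <- sweep(codes, 2, 2 * p)
  g <- as.numeric(Z %*% track$effect)
  su2 <- stats::var(g)
  if (su2 == 0) stop("total genomic variance is zero; nothing to decompose")
  res <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    if (!length(idx)) next
    pos <- map$pos[idx]
    anchors <- if (tiling) {
      idx[!duplicated((pos - min(pos)) %/% windowBp)]
    } else idx
    for (a in anchors) {
      inw <- idx[map$pos[idx] >= map$pos[a] &
                 map$pos[idx] < map$pos[a] + windowBp]
      u <- as.numeric(Z[, inw, drop = FALSE] %*% track$effect[inw])
      res[[length(res) + 1L]] <- data.frame(
        chr = ch, start = map$pos[a], end = map$pos[a] + windowBp,
        first_snp = map$snp[inw[1]], last_snp = map$snp[inw[length(inw)]],
        n_snps = length(inw),
        pct_variance = 100 * stats::var(u) / su2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "sigma_u2") <- su2
  class(out) <- c("windowVarianceTrack", "data.frame")
  out
}

#' Ranked window report across components and parities
#'
#' Stacks window-variance tracks (one per component x parity), ranks windows
#' by explained variance within each track, and extracts the genome-wide top
#' windows for reporting.
#'
#' @param tracks named list of `windowVarianceTrack` objects; names like
#'   `"v_p1"` identify component and parity.
#' @param topK rows to keep per track in the `top` element (default 10).
#' @return list with `windows` (all windows with `track` and `rank` columns)
#'   and `top` (the `topK` leading windows per track).
#' @export
manhattanTable <- function(tracks, topK = 10) {
  if (!length(tracks)) stop("at least one track required")
  if (is.null(names(tracks)))
    names(tracks) <- paste0("track", seq_along(tracks))
  all <- do.call(rbind, lapply(names(tracks), function(nm) {
    t <- as.data.frame(tracks[[nm]])
    t$track <- nm
    t$rank <- rank(-t$pct_variance, ties.method = "first")
    t
  }))
  rownames(all) <- NULL
  top <- all[all$rank <= topK, ]
  top <- top[order(top$track, top$rank), ]
  rownames(top) <- NULL
  list(windows = all, top = top)
}

#' Manhattan-style plot of window variance
#'
#' @param track a `windowVarianceTrack`.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plotManhattan <- function(track, main = "") {
  chr <- factor(track$chr, levels = unique(track$chr))
  off <- c(0, cumsum(tapply(track$end, chr, max)))
  x <- track$start + off[as.integer(chr)]
  graphics::plot(x, track$pct_variance, pch = 16, cex = 0.5,
                 col = as.integer(chr) %% 2 + 1,
                 xlab = "genome position", ylab = "% genetic variance",
                 main = main)
  invisible(NULL)
}

#' Write a SNP-effect or window track as TSV
#'
#' @param track data.frame track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
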