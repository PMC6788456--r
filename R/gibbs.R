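vechNames <- function(prefix, cf) {
  p2 <- length(cf)
  nm <- character(0)
  for (j in seq_len(p2)) for (i in j:p2)
    nm <- c(nm, paste0(prefix, "_", cf[i], "_", cf[j]))
  nm
}

#' Gibbs sampler for reaction-norm variance components
#'
#' Samples the full conditionals of the reaction-norm repeatability model:
#' location effects blockwise (scalar fixed levels; 2P-coefficient blocks
#' per animal and per cow), the additive (co)variance matrix Phi from an
#' inverse-Wishart with scale = prior scale + the K-quadratic cross-product
#' of the animal coefficient vectors, the permanent-environment matrix Psi
#' analogously over cows, and each parity's residual variance from a scaled
#' inverse chi-square. Priors are inverse-Wishart with degrees of freedom
#' `2P + 2` and scale equal to the initial values (so the prior mean is the
#' initial value), and a scaled inverse chi-square with 4 df for residuals;
#' fixed effects have flat priors. Runs are reproducible given `seed`.
#'
#' @param design an `rrmDesign` from [buildDesign()].
#' @param Kinv a [RelationshipMatrix-class] of kind `"A_inverse"` (the usual
#'   choice for variance-component estimation) over the design's pedigree.
#' @param init a [VarianceComponents-class] of starting values (also the
#'   prior location).
#' @param chain list with `total`, `burnin`, `thin` (defaults 20000 / 5000 /
#'   10; the full-scale protocol 500000 / 100000 / 100 is available as
#'   [chainPresetFull()]).
#' @param seed integer seed.
#' @param update named logical list to hold components fixed at `init`
#'   (`phi`, `psi`, `r`; all `TRUE` by default).
#' @return a [PosteriorChain-class]; `chainMeta()` records the protocol,
#'   seed, jitter count (covariance draws needing a diagonal ridge) and the
#'   posterior-mean location effects of the final state are *not* retained —
#'   use [solveMME()] for effect solutions.
#' @seealso [posteriorSummary()], [chainGeneticParameters()]
#' @export
gibbsSampler <- function(design, Kinv, init,
                         chain = list(total = 20000, burnin = 5000, thin = 10),
                         seed = 1,
                         update = list(phi = TRUE, psi = TRUE, r = TRUE)) {
  stopifnot(inherits(design, "rrmDesign"))
  P <- design$nParities
  p2 <- 2L * P
  if (init@nParities != P) stop("init has wrong number of parities")
  if (!relKind(Kinv) %in% c("A_inverse", "H_inverse"))
    stop("Kinv must be A_inverse or H_inverse")
  if (!identical(relIds(Kinv), animalIds(design$ped)))
    stop("Kinv ids must match the design pedigree")
  if (chain$burnin >= chain$total) stop("burnin must be < total")
  if ((chain$total - chain$burnin) %% chain$thin != 0)
    stop("(total - burnin) must be a multiple of thin")
  K <- as(as(relValues(Kinv), "generalMatrix"), "CsparseMatrix")
  upd <- utils::modifyList(list(phi = TRUE, psi = TRUE, r = TRUE), update)

  set.seed(seed)
  res <- gibbs_rrm_cpp(
    design$y, design$parity, design$f,
    design$htd, length(design$htdLevels),
    design$dimcl, length(design$dimLevels),
    design$animal, nAnimals(design$ped),
    design$cow, length(design$cowIds),
    K@i, K@p, K@x,
    init@Phi, init@Psi, init@Rdiag,
    init@Phi, p2 + 2, init@Psi, p2 + 2, init@Rdiag, 4,
    as.integer(chain$total), as.integer(chain$burnin),
    as.integer(chain$thin),
    upd$phi, upd$psi, upd$r)

  cf <- coefNames(P)
  colnames(res$samples) <- c(vechNames("phi", cf), vechNames("psi", cf),
                             paste0("sigma_e2_p", seq_len(P)))
  new("PosteriorChain", samples = res$samples,
      meta = list(total = chain$total, burnin = chain$burnin,
                  thin = chain$thin, seed = seed, nParities = P,
                  jitter = res$jitter, kinv = relKind(Kinv)))
}

#' Full-scale chain protocol
#'
#' The long-run preset: 500,000 total iterations, 100,000 burn-in, every
#' 100th draw retained (4,000 retained samples).
#' @return list with `total`, `burnin`, `thin`.
#' @export
chainPresetFull <- function() list(total = 500000, burnin = 100000, thin = 100)

#' Number of retained draws implied by a chain protocol
#' @param chain list with `total`, `burnin`, `thin`.
#' @return integer count `(total - burnin) / thin`.
#' @export
retainedDraws <- function(chain)
  as.integer((chain$total - chain$burnin) %/% chain$thin)

#' Reconstruct variance components from one retained draw
#'
#' @param chain a [PosteriorChain-class].
#' @param draw row index (default: posterior mean over all draws).
#' @return a [VarianceComponents-class].
#' @export
vcFromChain <- function(chain, draw = NULL) {
  s <- chainSamples(chain)
  x <- if (is.null(draw)) colMeans(s) else s[draw, ]
  P <- chainMeta(chain)$nParities
  p2 <- 2L * P
  nv <- p2 * (p2 + 1) / 2
  unvech <- function(v) {
    M <- matrix(0, p2, p2)
    M[lower.tri(M, diag = TRUE)] <- v
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  }
  VarianceComponents(unvech(x[seq_len(nv)]), unvech(x[nv + seq_len(nv)]),
                     x[2 * nv + seq_len(P)])
}

#' Shortest (highest-posterior-density) empirical interval
#'
#' The narrowest interval among all windows of sorted draws containing the
#' requested probability mass; ties broken toward the smaller lower bound.
#'
#' @param x numeric vector of draws.
#' @param level probability mass (default 0.95).
#' @return numeric length-2 vector (lower, upper).
#' @export
hpdInterval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(x[1], x[1]))
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  lo <- seq_len(n - m + 1)
  width <- x[lo + m - 1] - x[lo]
  i <- which.min(width)
  c(x[i], x[i + m - 1])
}

#' Posterior summary of a chain
#'
#' Per scalar component: sample mean, SD and shortest empirical interval at
#' `level`, plus an advisory Geweke z-score (first 10% vs last 50% of the
#' retained draws) as a convergence screen.
#'
#' @param chain a [PosteriorChain-class] (or plain numeric matrix of draws).
#' @param level interval probability mass (default 0.95).
#' @return data.frame: `component`, `mean`, `sd`, `hpd_lower`, `hpd_upper`,
#'   `geweke_z`.
#' @export
posteriorSummary <- function(chain, level = 0.95) {
  s <- if (methods::is(chain, "PosteriorChain")) chainSamples(chain) else chain
  if (nrow(s) < 100) stop("need at least 100 retained draws")
  hpd <- apply(s, 2, hpdInterval, level = level)
  data.frame(component = colnames(s),
             mean = colMeans(s),
             sd = apply(s, 2, stats::sd),
             hpd_lower = hpd[1, ], hpd_upper = hpd[2, ],
             geweke_z = apply(s, 2, gewekeZ),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Geweke-style z: difference of early (10%) and late (50%) means over the
# sum of their spectral-density-at-zero variance estimates (lag-window).
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  s0 <- function(v) {
    m <- min(length(v) - 1, max(1, floor(sqrt(length(v)))))
    ac <- stats::acf(v, lag.max = m, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    stats::var(v) * (1 + 2 * sum(ac[-1])) / length(v)
  }
  den <- s0(a) + s0(b)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(den)
}

#' Write retained draws as a delimited table
#'
#' One row per retained sample; columns are the lower triangles of Phi and
#' Psi plus the residual variances. A commented header records the protocol
#' and seed.
#'
#' @param chain a [PosteriorChain-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChain <- function(chain, path) {
  m <- chainMeta(chain)
  hdr <- sprintf("# total=%d burnin=%d thin=%d seed=%s parities=%d",
                 m$total, m$burnin, m$thin, as.character(m$seed),
                 m$nParities)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(chainSamples(chain), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Trace plot of selected chain components
#'
#' @param chain a [PosteriorChain-class].
#' @param components column names to plot (default: the per-parity additive
#'   intercept variances).
#' @return invisibly, `NULL`.
#' @export
plotTrace <- function(chain, components = NULL) {
  s <- chainSamples(chain)
  if (is.null(components)) {
    P <- chainMeta(chain)$nParities
    components <- paste0("phi_a", seq_len(P), "_a", seq_len(P))
  }
  components <- intersect(components, colnames(s))
  op <- graphics::par(mfrow = c(length(components), 1),
                      mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (cm in components)
    graphics::plot(s[, cm], type = "l", ylab = cm, xlab = "")
  invisible(NULL)
}
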