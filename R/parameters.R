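#' Reaction-norm heritability at a heat-load level
#'
#' \deqn{h^2(f) = \frac{\sigma^2_a + f^2\sigma^2_v + 2f\sigma_{av}}
#' {\sigma^2_a + f^2\sigma^2_v + 2f\sigma_{av} + \sigma^2_{pe} +
#'  f^2\sigma^2_q + 2f\sigma_{pq} + \sigma^2_e}}
#' A negative genetic numerator (possible with a strongly negative
#' \eqn{\sigma_{av}}) is returned as-is with a warning rather than an error,
#' so per-draw posterior summaries remain robust in chain tails.
#'
#' @param sa2,sv2,sav additive intercept variance, slope variance and their
#'   covariance.
#' @param spe2,sq2,spq permanent-environment analogues.
#' @param se2 residual variance.
#' @param f heat-load level f(THI) at which to evaluate (default 10).
#' @return heritability (vectorised over components).
#' @export
heritabilityAt <- function(sa2, sv2, sav, spe2, sq2, spq, se2, f = 10) {
  num <- sa2 + f^2 * sv2 + 2 * f * sav
  den <- num + spe2 + f^2 * sq2 + 2 * f * spq + se2
  if (any(den <= 0)) stop("implied phenotypic variance must be positive")
  if (any(num < 0))
    warning("negative genetic variance at f = ", paste(unique(f), collapse = ","),
            "; h2 returned as-is")
  num / den
}

#' Correlation between general and thermotolerance additive effects
#'
#' \deqn{corr[a, f v] = \frac{f\,\sigma_{av}}
#' {\sqrt{\sigma^2_a \cdot f^2 \sigma^2_v}}}
#' which algebraically equals \eqn{\sigma_{av}/\sqrt{\sigma^2_a\sigma^2_v}}
#' for any \eqn{f > 0}; `f = 0` is rejected (the defining expression divides by
#' zero).
#'
#' @param sa2,sv2,sav variance components (vectorised).
#' @param f heat-load level, strictly positive (default 10).
#' @return correlation in \[-1, 1\].
#' @examples
#' # published-scale components: sigma_a^2, 100*sigma_v^2, 10*sigma_av
#' generalThermoCorrelation(9.26, 0.94 / 100, -1.21 / 10)  # -0.41
#' @export
generalThermoCorrelation <- function(sa2, sv2, sav, f = 10) {
  if (any(f <= 0)) stop("f must be > 0 (correlation undefined at f = 0)")
  if (any(sa2 <= 0) || any(sv2 <= 0))
    stop("sa2 and sv2 must be positive")
  f * sav / sqrt(sa2 * f^2 * sv2)
}

#' Across-parity correlations of intercept and slope effects
#'
#' From the additive matrix Phi: `cor_gen[i,j]` is the correlation of
#' general (intercept) effects between parities i and j; `cor_ht[i,j]` the
#' analogue for thermotolerance (slope) effects.
#'
#' @param Phi additive (co)variance matrix, 2P x 2P, coefficient order
#'   (a1, v1, a2, v2, ...).
#' @return list with `cor_gen` and `cor_ht`, each P x P.
#' @export
acrossParityCorrelations <- function(Phi) {
  p2 <- nrow(Phi)
  if (p2 %% 2 != 0 || !isTRUE(all.equal(Phi, t(Phi), tolerance = 1e-8)))
    stop("Phi must be a symmetric 2P x 2P matrix")
  P <- p2 / 2
  ai <- 2 * seq_len(P) - 1
  vi <- 2 * seq_len(P)
  corSub <- function(idx) stats::cov2cor(Phi[idx, idx, drop = FALSE])
  g <- corSub(ai); h <- corSub(vi)
  dimnames(g) <- dimnames(h) <- list(paste0("par", seq_len(P)),
                                     paste0("par", seq_len(P)))
  list(cor_gen = g, cor_ht = h)
}

#' Percent change between two variances
#'
#' `100 * (to - from) / from`; e.g. the rise of the thermotolerance additive
#' variance from one parity to the next.
#'
#' @param vFrom,vTo variances; `vFrom` must be positive.
#' @return percentage (vectorised).
#' @examples
#' varianceIncreasePct(0.94, 1.56)  # ~66
#' @export
varianceIncreasePct <- function(vFrom, vTo) {
  if (any(vFrom <= 0)) stop("vFrom must be > 0")
  100 * (vTo - vFrom) / vFrom
}

#' Genetic parameters per posterior draw
#'
#' Evaluates heritability and the general-by-thermotolerance correlation at
#' heat load `f` for every retained draw, per parity, then the across-parity
#' intercept/slope correlations. Summarising the per-draw functionals (not
#' the functional of the posterior-mean components) is deliberate:
#' functionals of means are biased.
#'
#' @param chain a [PosteriorChain-class].
#' @param f heat-load level (default 10).
#' @return matrix of per-draw parameters (columns `h2_p*`, `r_av_p*`,
#'   `cor_gen_*_*`, `cor_ht_*_*`).
#' @export
chainGeneticParameters <- function(chain, f = 10) {
  s <- chainSamples(chain)
  P <- chainMeta(chain)$nParities
  cf <- coefNames(P)
  col <- function(prefix, a, b) {
    nm1 <- paste0(prefix, "_", a, "_", b); nm2 <- paste0(prefix, "_", b, "_", a)
    if (nm1 %in% colnames(s)) s[, nm1] else s[, nm2]
  }
  cols <- list()
  for (l in seq_len(P)) {
    al <- paste0("a", l); vl <- paste0("v", l)
    sa2 <- col("phi", al, al); sv2 <- col("phi", vl, vl)
    sav <- col("phi", al, vl)
    spe2 <- col("psi", al, al); sq2 <- col("psi", vl, vl)
    spq <- col("psi", al, vl)
    se2 <- s[, paste0("sigma_e2_p", l)]
    h2 <- suppressWarnings(
      heritabilityAt(sa2, sv2, sav, spe2, sq2, spq, se2, f = f))
    r <- sav / sqrt(sa2 * sv2)   # equals the f-explicit form for any f > 0
    cols[[paste0("h2_p", l)]] <- h2
    cols[[paste0("r_av_p", l)]] <- r
  }
  if (P > 1) {
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      cols[[paste0("cor_gen_", i, "_", j)]] <-
        col("phi", paste0("a", i), paste0("a", j)) /
        sqrt(col("phi", paste0("a", i), paste0("a", i)) *
             col("phi", paste0("a", j), paste0("a", j)))
      cols[[paste0("cor_ht_", i, "_", j)]] <-
        col("phi", paste0("v", i), paste0("v", j)) /
        sqrt(col("phi", paste0("v", i), paste0("v", i)) *
             col("phi", paste0("v", j), paste0("v", j)))
    }
  }
  do.call(cbind, cols)
}

#' Reference variance-component estimates (Florida Holstein heat stress)
#'
#' Published posterior means of the additive reaction-norm components for
#' milk, fat and protein yield across parities 1-3 in a Florida Holstein
#' heat-stress study, on their published scales: `sigma_a2`, `sigma_v2_x100`
#' (100 x slope variance), `sigma_av_x10` (10 x intercept-slope covariance)
#' and `sigma_e2`. These are the default simulation parameters of
#' [simulationConfig()] and the worked-example inputs of the genetic
#' parameter functions (fat and protein are on the (kg x 100)^2 scale).
#'
#' @return data.frame with one row per trait x parity.
#' @export
referenceVarianceComponents <- function() {
  data.frame(
    trait = rep(c("milk", "fat", "protein"), each = 3),
    parity = rep(1:3, 3),
    sigma_a2 = c(9.26, 10.03, 10.55, 119.76, 205.77, 252.33,
                 55.65, 63.80, 76.01),
    sigma_v2_x100 = c(0.94, 1.56, 1.62, 18.19, 48.61, 33.78,
                      8.57, 9.98, 13.30),
    sigma_av_x10 = c(-1.21, -1.17, -2.31, -11.44, -37.90, -63.03,
                     -6.31, -4.58, -12.81),
    sigma_e2 = c(7.31, 12.97, 15.65, 351.15, 666.04, 840.74,
                 79.92, 127.98, 154.51),
    stringsAsFactors = FALSE)
}

#' Reference across-parity correlations (Florida Holstein heat stress)
#'
#' Published correlations of general (`cor_gen`) and thermotolerance
#' (`cor_ht`) additive effects between parities, per trait; used to fill the
#' cross-parity blocks of the default simulation Phi.
#'
#' @return list per trait, each with `cor_gen` and `cor_ht` 3x3 matrices.
#' @export
referenceParityCorrelations <- function() {
  mk <- function(c12, c13, c23) {
    M <- diag(3)
    M[1, 2] <- M[2, 1] <- c12
    M[1, 3] <- M[3, 1] <- c13
    M[2, 3] <- M[3, 2] <- c23
    M
  }
  list(
    milk = list(cor_gen = mk(0.82, 0.85, 0.92), cor_ht = mk(0.78, 0.65, 0.61)),
    fat = list(cor_gen = mk(0.91, 0.95, 0.95), cor_ht = mk(0.46, 0.34, 0.38)),
    protein = list(cor_gen = mk(0.78, 0.76, 0.96), cor_ht = mk(0.36, 0.55, 0.78)))
}

#' Parameter report across traits and parities
#'
#' Evaluates the general-by-thermotolerance correlation at `f` from a table
#' of published-scale components, mirroring the usual reporting layout
#' (correlations to 2 decimals, percent changes to the nearest integer when
#' requested downstream).
#'
#' @param components data.frame in the layout of
#'   [referenceVarianceComponents()].
#' @param f heat-load level (default 10).
#' @return the input with an `r_av` column appended.
#' @export
parameterReport <- function(components = referenceVarianceComponents(),
                            f = 10) {
  components$r_av <- generalThermoCorrelation(
    components$sigma_a2, components$sigma_v2_x100 / 100,
    components$sigma_av_x10 / 10, f = f)
  components
}
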