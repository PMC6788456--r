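# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most transparent route available (tabular recursion,
# dense assembly, exhaustive enumeration) and share no code with the package
# implementations they check.

# Numerator relationship matrix by direct tabular recursion over a parent
# data.frame (animal/sire/dam labels, NA = unknown), assumed parents-first.
oracleTabularA <- function(pp) {
  n <- nrow(pp)
  idx <- stats::setNames(seq_len(n), pp$animal)
  A <- matrix(0, n, n, dimnames = list(pp$animal, pp$animal))
  for (i in seq_len(n)) {
    s <- if (is.na(pp$sire[i])) 0L else idx[[pp$sire[i]]]
    d <- if (is.na(pp$dam[i])) 0L else idx[[pp$dam[i]]]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) for (j in seq_len(i - 1L)) {
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# Dense mixed-model equations built from explicit dense design matrices.
oracleDenseMME <- function(design, vc, KinvDense) {
  P <- design$nParities
  p2 <- 2L * P
  nrec <- length(design$y)
  N <- length(KinvDense[1, ])
  nH <- length(design$htdLevels)
  nD <- length(design$dimLevels)
  nC <- length(design$cowIds)
  X <- matrix(0, nrec, nH + nD)
  Zu <- matrix(0, nrec, p2 * N)
  Zw <- matrix(0, nrec, p2 * nC)
  for (i in seq_len(nrec)) {
    X[i, design$htd[i]] <- 1
    if (design$dimcl[i] > 0) X[i, nH + design$dimcl[i]] <- 1
    a <- (design$animal[i] - 1) * p2 + 2 * design$parity[i] - 1
    Zu[i, a] <- 1; Zu[i, a + 1] <- design$f[i]
    w <- (design$cow[i] - 1) * p2 + 2 * design$parity[i] - 1
    Zw[i, w] <- 1; Zw[i, w + 1] <- design$f[i]
  }
  Wt <- diag(1 / vc@Rdiag[design$parity], nrec)
  M <- cbind(X, Zu, Zw)
  C <- t(M) %*% Wt %*% M
  iu <- nH + nD + seq_len(p2 * N)
  iw <- nH + nD + p2 * N + seq_len(p2 * nC)
  C[iu, iu] <- C[iu, iu] + kronecker(KinvDense, solve(vc@Phi))
  C[iw, iw] <- C[iw, iw] + kronecker(diag(nC), solve(vc@Psi))
  list(C = C, rhs = as.numeric(t(M) %*% Wt %*% design$y))
}

# Upper-tail hypergeometric probability P(X >= k) by direct enumeration of
# binomial coefficients.
oracleHyperTail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Shortest interval containing `level` of the draws, by exhaustive scan over
# all (i, j) pairs.
oracleHpd <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) for (j in i:n) {
    if ((j - i + 1) / n >= level && (x[j] - x[i]) < diff(best)) {
      best <- c(x[i], x[j])
    }
  }
  best
}

# Brute-force window variance percentages: per anchor SNP, the variance over
# individuals of the summed window genotype value, over the variance of the
# whole genomic value.
oracleWindowPct <- function(Z, effects, map, windowBp = 2e6) {
  g <- as.numeric(Z %*% effects)
  out <- numeric(nrow(map))
  for (a in seq_len(nrow(map))) {
    inw <- which(map$chr == map$chr[a] & map$pos >= map$pos[a] &
                 map$pos < map$pos[a] + windowBp)
    u <- as.numeric(Z[, inw, drop = FALSE] %*% effects[inw])
    out[a] <- 100 * stats::var(u) / stats::var(g)
  }
  out
}

# Small deterministic pedigree used by several relationship tests:
# 2 founder pairs, their two offspring, one grand-offspring.
fixturePedigree <- function() {
  Pedigree(c("s1", "d1", "s2", "d2", "o1", "o2", "g1"),
           c(NA, NA, NA, NA, "s1", "s2", "o1"),
           c(NA, NA, NA, NA, "d1", "d2", "o2"))
}

# Random pedigree with nGen discrete generations for property tests.
randomPedigree <- function(nFounders = 10, nGen = 3, perGen = 15,
                           seed = 1) {
  set.seed(seed)
  animal <- paste0("F", seq_len(nFounders))
  sire <- dam <- rep(NA_character_, nFounders)
  sex <- rep(c("M", "F"), length.out = nFounders)
  prev <- animal; prevSex <- sex
  for (g in seq_len(nGen)) {
    a <- paste0("A", g, "_", seq_len(perGen))
    s <- sample(prev[prevSex == "M"], perGen, replace = TRUE)
    d <- sample(prev[prevSex == "F"], perGen, replace = TRUE)
    sx <- rep(c("M", "F"), length.out = perGen)
    animal <- c(animal, a); sire <- c(sire, s); dam <- c(dam, d)
    prev <- a; prevSex <- sx
  }
  Pedigree(animal, sire, dam)
}

# Small reaction-norm data set (records + design inputs) for model tests.
fixtureRecords <- function(nCows = 8, seed = 2, parities = 1:2) {
  set.seed(seed)
  cows <- paste0("c", seq_len(nCows))
  recs <- expand.grid(cow = cows, parity = parities,
                      t = seq_len(8), stringsAsFactors = FALSE)
  recs$herd <- rep(1:2, length.out = nrow(recs))
  recs$test_date <- as.Date("2015-01-15") + 30 * (recs$t - 1) +
    365 * (recs$parity - min(parities))
  # staggered calving so DIM classes are not collinear with test dates:
  # offsets straddle every 20-day class boundary within each herd
  off <- stats::setNames(rep(c(3, 12, 22), length.out = nCows), cows)
  recs$dim <- pmin(305, 5 + 30 * (recs$t - 1) + off[recs$cow])
  recs$heat_load <- round(pmax(0, stats::rnorm(nrow(recs), 3, 4)), 2)
  recs$yield <- round(25 + stats::rnorm(nrow(recs), 0, 3), 3)
  recs[order(recs$cow, recs$parity, recs$t),
       c("cow", "herd", "test_date", "parity", "dim", "yield", "heat_load")]
}

fixtureVC <- function(P = 2) {
  base <- matrix(c(4, -0.1, -0.1, 0.02), 2, 2)
  Phi <- kronecker(diag(P) * 0.4 + 0.6, base)
  VarianceComponents(Phi, 0.5 * Phi, rep(6, P) + seq_len(P))
}
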