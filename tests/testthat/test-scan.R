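scanGeno <- function(codes, chr = NULL, pos = NULL) {
  m <- ncol(codes)
  map <- data.frame(snp = paste0("s", seq_len(m)),
                    chr = if (is.null(chr)) rep("1", m) else chr,
                    pos = if (is.null(pos)) seq_len(m) * 1e5 else pos,
                    allele = "B", stringsAsFactors = FALSE)
  GenotypeData(codes, map, paste0("i", seq_len(nrow(codes))))
}

test_that("backsolving an identity design returns the input", {
  g <- scanGeno(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  gebv <- c(i1 = 3, i2 = -1)
  tr <- backsolveSnpEffects(gebv, g, alleleFreq = c(0, 0))
  expect_equal(tr$effect, c(3, -1))
})

test_that("backsolve reprojects onto the GEBV within the column space", {
  set.seed(23)
  codes <- matrix(rbinom(12 * 40, 2, 0.4), 12, 40)
  g <- scanGeno(codes)
  p <- colMeans(codes) / 2
  Z <- sweep(codes, 2, 2 * p)
  b <- rnorm(40, 0, 0.1)
  gebv <- stats::setNames(as.numeric(Z %*% b), sampleIds(g))
  tr <- backsolveSnpEffects(gebv, g)
  expect_lt(max(abs(as.numeric(Z %*% tr$effect) - gebv)), 1e-8)
})

test_that("backsolve equals the independent pseudo-inverse oracle", {
  set.seed(31)
  codes <- matrix(rbinom(10 * 30, 2, 0.35), 10, 30)
  g <- scanGeno(codes)
  p <- colMeans(codes) / 2
  Z <- sweep(codes, 2, 2 * p)
  gebv <- stats::setNames(rnorm(10), sampleIds(g))
  tr <- backsolveSnpEffects(gebv, g)
  # oracle: spectral pseudo-inverse assembled from scratch
  sv <- svd(Z)
  keep <- sv$d > 1e-8 * max(sv$d)
  Zplus <- sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  expect_equal(tr$effect, as.numeric(Zplus %*% gebv), tolerance = 1e-8)
})

test_that("whole-genome window explains 100 percent of variance", {
  set.seed(7)
  codes <- matrix(rbinom(8 * 10, 2, 0.5), 8, 10)
  g <- scanGeno(codes, pos = seq(1e5, 1e6, length.out = 10))
  tr <- backsolveSnpEffects(stats::setNames(rnorm(8), sampleIds(g)), g)
  wv <- windowVariance(tr, g)
  expect_equal(wv$pct_variance[1], 100)
  expect_equal(wv$n_snps[1], 10L)
})

test_that("windows of zero-effect SNPs explain nothing", {
  set.seed(8)
  codes <- matrix(rbinom(10 * 6, 2, 0.5), 10, 6)
  g <- scanGeno(codes, chr = rep(c("1", "2"), each = 3),
                pos = rep(c(1e5, 2e5, 3e5), 2))
  tr <- structure(data.frame(snp = snpMap(g)$snp, chr = snpMap(g)$chr,
                             pos = snpMap(g)$pos,
                             effect = c(0, 0, 0, 1, -1, 0.5)),
                  class = c("snpEffectTrack", "data.frame"))
  wv <- windowVariance(tr, g)
  expect_equal(wv$pct_variance[wv$chr == "1"], c(0, 0, 0))
  expect_gt(max(wv$pct_variance[wv$chr == "2"]), 0)
})

test_that("window percentages equal the brute-force variance ratio", {
  set.seed(9)
  codes <- matrix(rbinom(4 * 3, 2, 0.5), 4, 3)
  codes[1, ] <- c(2L, 0L, 1L)           # ensure polymorphism
  g <- scanGeno(codes, pos = c(5e5, 1e6, 3e6))
  tr <- structure(data.frame(snp = snpMap(g)$snp, chr = "1",
                             pos = snpMap(g)$pos,
                             effect = c(0.5, -1, 2)),
                  class = c("snpEffectTrack", "data.frame"))
  wv <- windowVariance(tr, g)
  p <- colMeans(codes) / 2
  Z <- sweep(codes, 2, 2 * p)
  expect_equal(wv$pct_variance,
               oracleWindowPct(Z, tr$effect, snpMap(g)), tolerance = 1e-10)
  # positions 0.5 and 1.0 Mb share a 2 Mb window; 3.0 Mb stands alone
  expect_equal(wv$n_snps, c(2L, 1L, 1L))

  # larger randomised instance against the same oracle
  codes2 <- matrix(rbinom(15 * 25, 2, 0.3), 15, 25)
  g2 <- scanGeno(codes2, chr = rep(c("1", "2"), c(12, 13)),
                 pos = c(sort(sample.int(8e6, 12)),
                         sort(sample.int(8e6, 13))))
  eff <- rnorm(25, 0, 0.2)
  tr2 <- structure(data.frame(snp = snpMap(g2)$snp, chr = snpMap(g2)$chr,
                              pos = snpMap(g2)$pos, effect = eff),
                   class = c("snpEffectTrack", "data.frame"))
  p2 <- colMeans(codes2) / 2
  expect_equal(windowVariance(tr2, g2)$pct_variance,
               oracleWindowPct(sweep(codes2, 2, 2 * p2), eff, snpMap(g2)),
               tolerance = 1e-10)
})

test_that("window percentages ignore a constant shift of the GEBVs", {
  set.seed(12)
  codes <- matrix(rbinom(20 * 15, 2, 0.4), 20, 15)
  g <- scanGeno(codes, pos = sort(sample.int(6e6, 15)))
  p <- colMeans(codes) / 2
  Z <- sweep(codes, 2, 2 * p)
  gebv <- stats::setNames(as.numeric(Z %*% rnorm(15, 0, 0.3)),
                          sampleIds(g))
  w1 <- windowVariance(backsolveSnpEffects(gebv, g), g)
  w2 <- windowVariance(backsolveSnpEffects(gebv + 7.5, g), g)
  expect_equal(w1$pct_variance, w2$pct_variance, tolerance = 1e-6)
})

test_that("with orthogonal SNPs a QTL window converges to its share", {
  set.seed(33)
  n <- 500; m <- 40
  codes <- matrix(rbinom(n * m, 2, 0.5), n, m)
  g <- scanGeno(codes, chr = rep(c("1", "2"), each = m / 2),
                pos = rep(seq(1e5, by = 3e6, length.out = m / 2), 2))
  eff <- rep(0, m); eff[5] <- 0.4; eff[25] <- 0.3
  p <- colMeans(codes) / 2
  Z <- sweep(codes, 2, 2 * p)
  gebv <- stats::setNames(as.numeric(Z %*% eff), sampleIds(g))
  wv <- windowVariance(backsolveSnpEffects(gebv, g), g)
  varQ <- apply(Z[, c(5, 25)], 2, var) * eff[c(5, 25)]^2
  share5 <- 100 * varQ[1] / sum(varQ)
  got5 <- wv$pct_variance[wv$chr == "1"][5]
  expect_lt(abs(got5 - share5), 5)
})

test_that("the ranked report orders windows within each track", {
  w <- function(p) structure(
    data.frame(chr = "1", start = seq_along(p) * 1e6,
               end = seq_along(p) * 1e6 + 2e6,
               first_snp = "a", last_snp = "b", n_snps = 1L,
               pct_variance = p),
    class = c("windowVarianceTrack", "data.frame"))
  mt <- manhattanTable(list(v_p1 = w(c(5.7, 0.6)), a_p1 = w(2)), topK = 1)
  expect_equal(mt$windows$rank[mt$windows$track == "v_p1"], c(1L, 2L))
  expect_equal(mt$top$pct_variance[mt$top$track == "v_p1"], 5.7)
  expect_equal(mt$top$rank, c(1L, 1L))
  expect_error(manhattanTable(list()), "track")
})
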