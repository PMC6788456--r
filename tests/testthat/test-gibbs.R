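smallChainSetup <- function(seed = 6, nCows = 30, parities = 1) {
  cfg <- simulationConfig(seed = seed, nCowsPhenotyped = nCows,
                          nFounders = 16, nGenerations = 2,
                          nPerGeneration = 20, parities = parities,
                          nSnps = 10)
  st <- simulateStudy(cfg)
  spec <- modelSpec(parities = parities)
  des <- buildDesign(validateTestDayRecords(st$records, spec)$records,
                     st$ped, spec)
  list(des = des, Ainv = buildAInverse(st$ped),
       init = VarianceComponents(cfg$Phi, cfg$Psi, cfg$Rdiag), cfg = cfg)
}

test_that("chain bookkeeping retains (total - burnin)/thin draws", {
  expect_equal(retainedDraws(list(total = 500000, burnin = 100000,
                                  thin = 100)), 4000L)
  s <- smallChainSetup()
  ch <- gibbsSampler(s$des, s$Ainv, s$init,
                     chain = list(total = 300, burnin = 100, thin = 4),
                     seed = 2)
  expect_equal(nrow(chainSamples(ch)), 50L)
  expect_error(gibbsSampler(s$des, s$Ainv, s$init,
                            chain = list(total = 100, burnin = 100,
                                         thin = 1), seed = 2), "burnin")
})

test_that("a seeded chain with thin 1 and no burn-in is bitwise stable", {
  s <- smallChainSetup()
  chain <- list(total = 120, burnin = 0, thin = 1)
  a <- gibbsSampler(s$des, s$Ainv, s$init, chain = chain, seed = 99)
  b <- gibbsSampler(s$des, s$Ainv, s$init, chain = chain, seed = 99)
  expect_identical(chainSamples(a), chainSamples(b))
  c2 <- gibbsSampler(s$des, s$Ainv, s$init, chain = chain, seed = 100)
  expect_false(identical(chainSamples(a), chainSamples(c2)))
})

test_that("all retained covariance draws are positive definite", {
  s <- smallChainSetup(parities = 1:2)
  ch <- gibbsSampler(s$des, s$Ainv, s$init,
                     chain = list(total = 400, burnin = 100, thin = 10),
                     seed = 3)
  for (d in seq_len(nrow(chainSamples(ch)))) {
    vc <- vcFromChain(ch, d)
    expect_gt(min(eigen(vcPhi(vc), TRUE, TRUE)$values), 0)
    expect_gt(min(eigen(vcPsi(vc), TRUE, TRUE)$values), 0)
    expect_true(all(vcResidual(vc) > 0))
  }
})

test_that("residual variance matches its conjugate closed form", {
  # hold Phi and Psi fixed at ~0 so the model degenerates to y = mu + e;
  # the marginal posterior of sigma_e2 is then scaled-inv-chi-square with
  # df = nu0 + n - 1 and scale (nu0*s0 + centred SS)/(nu0 + n - 1)
  set.seed(41)
  n <- 200
  y <- rnorm(n, 20, 2.5)
  recs <- data.frame(cow = "c1", herd = 1,
                     test_date = as.Date("2015-06-01"), parity = 1,
                     dim = 50, yield = y, heat_load = 0)
  ped <- Pedigree("c1", NA, NA)
  des <- buildDesign(recs, ped, modelSpec(parities = 1))
  tiny <- matrix(c(1e-10, 0, 0, 1e-10), 2, 2)
  init <- VarianceComponents(tiny, tiny, 5)
  ch <- gibbsSampler(des, buildAInverse(ped), init,
                     chain = list(total = 20000, burnin = 1000, thin = 1),
                     seed = 8,
                     update = list(phi = FALSE, psi = FALSE, r = TRUE))
  nu0 <- 4; s0 <- 5
  post_df <- nu0 + n - 1
  post_scale <- (nu0 * s0 + sum((y - mean(y))^2)) / post_df
  exact_mean <- post_df * post_scale / (post_df - 2)
  got <- mean(chainSamples(ch)[, "sigma_e2_p1"])
  expect_equal(got, exact_mean, tolerance = 0.03)
})

test_that("HPD interval is the shortest window, ties to the left", {
  expect_equal(hpdInterval(rep(3.2, 50)), c(3.2, 3.2))
  expect_equal(hpdInterval(1:1000, 0.95), c(1, 950))
  set.seed(5)
  for (i in 1:5) {
    x <- rgamma(60, shape = 2)
    expect_equal(hpdInterval(x, 0.9), oracleHpd(x, 0.9))
  }
  z <- qnorm((1:50000 - 0.5) / 50000)   # normal scores
  h <- hpdInterval(z, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)
})

test_that("posterior summaries report mean, sd, HPD and Geweke z", {
  s <- smallChainSetup()
  ch <- gibbsSampler(s$des, s$Ainv, s$init,
                     chain = list(total = 1200, burnin = 200, thin = 2),
                     seed = 12)
  ps <- posteriorSummary(ch)
  expect_true(all(c("mean", "sd", "hpd_lower", "hpd_upper", "geweke_z")
                  %in% names(ps)))
  expect_true(all(ps$hpd_lower <= ps$mean & ps$mean <= ps$hpd_upper))
  expect_true(all(is.finite(ps$geweke_z)))
  expect_error(posteriorSummary(chainSamples(ch)[1:50, , drop = FALSE]),
               "100")
})

test_that("chain draws round-trip through the tabular writer", {
  s <- smallChainSetup()
  ch <- gibbsSampler(s$des, s$Ainv, s$init,
                     chain = list(total = 200, burnin = 100, thin = 2),
                     seed = 31)
  f <- tempfile(fileext = ".tsv")
  writeChain(ch, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "total=200 burnin=100 thin=2 seed=31")
  back <- read.table(f, header = TRUE, sep = "\t", skip = 1,
                     check.names = FALSE)
  expect_equal(as.matrix(back), chainSamples(ch), tolerance = 1e-12,
               ignore_attr = TRUE)
})
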