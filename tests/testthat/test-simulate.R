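test_that("generators are seed-deterministic", {
  cfg <- simulationConfig(seed = 42, nCowsPhenotyped = 25, nFounders = 14,
                          nSnps = 40, parities = 1:2)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(parents(a$ped), parents(b$ped))
  expect_identical(genoCodes(a$geno), genoCodes(b$geno))
  expect_identical(a$weather$thi, b$weather$thi)
  expect_identical(a$records$yield, b$records$yield)
  c2 <- simulateStudy(simulationConfig(seed = 43, nCowsPhenotyped = 25,
                                       nFounders = 14, nSnps = 40,
                                       parities = 1:2))
  expect_false(identical(a$records$yield, c2$records$yield))
})

test_that("a zero-generation pedigree contains only founders", {
  cfg <- simulationConfig(seed = 2, nCowsPhenotyped = 10, nFounders = 10,
                          nGenerations = 0, parities = 1, nSnps = 5)
  sim <- simulatePedigree(cfg)
  expect_equal(nAnimals(sim$ped), 10L)
  pp <- parents(sim$ped)
  expect_true(all(is.na(pp$sire)) && all(is.na(pp$dam)))
})

test_that("late-generation inbreeding matches the tabular expectation", {
  cfg <- simulationConfig(seed = 6, nCowsPhenotyped = 50, nFounders = 10,
                          nGenerations = 3, nPerGeneration = 50,
                          parities = 1, nSnps = 5)
  sim <- simulatePedigree(cfg)
  A <- oracleTabularA(parents(sim$ped))
  fTab <- diag(A) - 1
  fPkg <- unname(inbreeding(sim$ped))
  expect_equal(fPkg, unname(fTab), tolerance = 1e-10)
  lastGen <- sim$generation == max(sim$generation)
  expect_gt(mean(fPkg[lastGen]), 0)    # 10 founders for 3 generations
})

test_that("gene drop respects Mendelian constraints and Hardy-Weinberg", {
  cfg <- simulationConfig(seed = 3, nCowsPhenotyped = 500, nFounders = 500,
                          nGenerations = 0, parities = 1, nSnps = 60)
  sim <- simulatePedigree(cfg)
  g <- simulateGenotypes(sim$ped, cfg)
  codes <- genoCodes(g$geno)
  p <- g$founderFreq
  # founder-only: genotype frequencies binomial(2, p) within sampling error
  pHat <- colMeans(codes) / 2
  se <- sqrt(p * (1 - p) / (2 * 500))
  expect_lt(mean(abs(pHat - p) / se > 4), 0.05)
  hetHat <- colMeans(codes == 1L)
  seHet <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / 500)
  expect_lt(mean(abs(hetHat - 2 * p * (1 - p)) / seHet > 4), 0.05)
})

test_that("offspring of 0x0 parents are coded 0", {
  cfg <- simulationConfig(seed = 4, nCowsPhenotyped = 40, nFounders = 10,
                          nGenerations = 2, nPerGeneration = 30,
                          parities = 1, nSnps = 30)
  sim <- simulatePedigree(cfg)
  g <- simulateGenotypes(sim$ped, cfg)
  codes <- genoCodes(g$geno)
  pp <- parents(sim$ped)
  nonf <- which(!is.na(pp$sire))
  for (i in nonf) {
    both0 <- codes[pp$sire[i], ] == 0L & codes[pp$dam[i], ] == 0L
    expect_true(all(codes[i, both0] == 0L))
  }
})

test_that("weather extremes behave as configured", {
  flat <- simulationConfig(seed = 5, nCowsPhenotyped = 5, nFounders = 4,
                           nSnps = 5, parities = 1,
                           weather = list(mean = 60, amplitude = 0,
                                          noiseSd = 0))
  expect_warning(w <- simulateWeather(flat), "never exceeds")
  expect_true(all(heatLoad(w$thi) == 0))
  warm <- simulationConfig(seed = 5, nCowsPhenotyped = 5, nFounders = 4,
                           nSnps = 5, parities = 1,
                           weather = list(mean = 70, amplitude = 0,
                                          noiseSd = 0))
  expect_true(all(heatLoad(simulateWeather(warm)$thi) == 2))
})

test_that("default weather crosses the threshold as the sinusoid predicts", {
  cfg <- simulationConfig(seed = 10, nCowsPhenotyped = 5, nFounders = 4,
                          nSnps = 5, parities = 1)
  w <- simulateWeather(cfg)
  frac <- mean(w$thi > 68)
  doy <- 1:365
  analytic <- mean(stats::pnorm(
    (cfg$weather$mean + cfg$weather$amplitude *
       sin(2 * pi * (doy - 105) / 365) - 68) / cfg$weather$noiseSd))
  expect_lt(abs(frac - analytic), 0.05)
  expect_gt(frac, 0.2)
})

test_that("near-zero variances reduce phenotypes to the fixed effects", {
  eps <- diag(1e-12, 2)
  cfg <- simulationConfig(seed = 7, nCowsPhenotyped = 10, nFounders = 6,
                          parities = 1, nSnps = 5,
                          Phi = eps, Psi = eps, Rdiag = 1e-12)
  st <- simulateStudy(cfg)
  spec <- modelSpec(parities = 1)
  expected <- cfg$baseMean +
    st$truth$htd[paste0(st$records$herd, ":", st$records$test_date, ":",
                        st$records$parity)] +
    st$truth$dimEffects[dimClass(st$records$dim, spec)]
  expect_equal(st$records$yield, unname(expected), tolerance = 1e-4)
})

test_that("true breeding values realise the configured covariance", {
  cfg <- simulationConfig(seed = 8, nCowsPhenotyped = 2000,
                          nFounders = 2000, nGenerations = 0,
                          parities = 1:2, nSnps = 5)
  st <- simulateStudy(cfg)
  U <- st$truth$u
  emp <- cov(U)
  expect_equal(unname(emp), unname(cfg$Phi), tolerance = 0.1)
  # permanent-environment draws likewise
  expect_equal(unname(cov(st$truth$w)), unname(cfg$Psi), tolerance = 0.15)
})

test_that("records respect the edit rules by construction", {
  cfg <- simulationConfig(seed = 9, nCowsPhenotyped = 40, nFounders = 12,
                          parities = 1:3, nSnps = 5)
  st <- simulateStudy(cfg)
  expect_true(all(st$records$dim >= 5 & st$records$dim <= 305))
  tests <- table(st$records$cow, st$records$parity)
  expect_true(all(tests[tests > 0] >= 6))
  expect_true(all(st$records$heat_load >= 0))
})

test_that("a planted QTL contributes its configured variance share", {
  qtl <- data.frame(chr = "1", pos = 5e6, component = "v", effect = NA,
                    var_share = 0.6)
  cfg <- simulationConfig(seed = 12, nCowsPhenotyped = 300,
                          nFounders = 300, nGenerations = 0, parities = 1,
                          nSnps = 50, nChromosomes = 1, qtl = qtl)
  st <- simulateStudy(cfg)
  q <- st$truth$qtl
  expect_false(is.na(q$snp[1]))
  expect_equal(q$var_contrib[1], 0.6 * cfg$Phi[2, 2], tolerance = 1e-9)
})
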