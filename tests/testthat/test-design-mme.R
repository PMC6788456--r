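test_that("DIM classes are 20-day bins anchored at DIM 5", {
  expect_equal(dimClass(c(5, 24, 25, 44, 45, 285, 305)),
               c(1L, 1L, 2L, 2L, 3L, 15L, 15L))
  expect_error(dimClass(4), "range")
  expect_error(dimClass(306), "range")
})

test_that("zero heat load removes the thermotolerance covariate", {
  recs <- fixtureRecords(nCows = 4, parities = 1)
  recs$heat_load <- 0
  ped <- Pedigree(unique(recs$cow), NA, NA)
  des <- buildDesign(recs, ped, modelSpec(parities = 1))
  expect_true(all(des$f == 0))
  # the slope columns of the assembled system then carry no data signal:
  # the additive slope block must equal its pure prior precision
  vc <- fixtureVC(P = 1)
  Ainv <- buildAInverse(ped)
  sys <- assembleMME(des, vc, Ainv)
  slopeIdx <- sys$blocks$additive[seq(2, length(sys$blocks$additive), 2)]
  Cdense <- as.matrix(sys$C)
  prior <- kronecker(as.matrix(relValues(Ainv)), solve(vc@Phi))
  expect_equal(Cdense[slopeIdx, slopeIdx],
               prior[seq(2, nrow(prior), 2), seq(2, nrow(prior), 2)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fixed-effect incidence tallies match per-level record counts", {
  recs <- fixtureRecords(nCows = 5, parities = 1:2, seed = 7)
  ped <- Pedigree(unique(recs$cow), NA, NA)
  des <- buildDesign(recs, ped, modelSpec())
  tallyH <- table(des$htd)
  brute <- table(paste(recs$herd, recs$test_date, recs$parity, sep = ":"))
  expect_equal(sort(as.integer(tallyH)), sort(as.integer(brute)))
  # exactly one HTD level per record
  expect_true(all(des$htd >= 1 & des$htd <= length(des$htdLevels)))
})

test_that("cows missing from the pedigree are reported by id", {
  recs <- fixtureRecords(nCows = 3, parities = 1)
  ped <- Pedigree("c1", NA, NA)
  expect_error(buildDesign(recs, ped, modelSpec(parities = 1)), "c2")
})

test_that("assembled equations equal the dense textbook construction", {
  for (seed in c(2, 13)) {
    recs <- fixtureRecords(nCows = 6, parities = 1:2, seed = seed)
    ped <- randomPedigree(nFounders = 4, nGen = 1, perGen = 6, seed = seed)
    # rename final generation to the cow labels
    recs$cow <- paste0("A1_", match(recs$cow, unique(recs$cow)))
    vc <- fixtureVC(P = 2)
    des <- buildDesign(recs, ped, modelSpec(parities = 1:2))
    expect_lte(nAnimals(ped), 30)
    Ainv <- buildAInverse(ped)
    sys <- assembleMME(des, vc, Ainv)
    oracle <- oracleDenseMME(des, vc, as.matrix(relValues(Ainv)))
    expect_equal(as.matrix(sys$C), oracle$C, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sys$rhs, oracle$rhs, tolerance = 1e-10)
  }
})

test_that("system with no records reduces to the prior precision blocks", {
  recs <- fixtureRecords(nCows = 2, parities = 1)[0, ]
  ped <- Pedigree(c("c1", "c2"), NA, NA)
  des <- buildDesign(recs, ped, modelSpec(parities = 1))
  vc <- fixtureVC(P = 1)
  Ainv <- buildAInverse(ped)
  sys <- assembleMME(des, vc, Ainv)
  iu <- sys$blocks$additive
  expect_equal(as.matrix(sys$C[iu, iu]),
               kronecker(as.matrix(relValues(Ainv)), solve(vc@Phi)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(sys$rhs == 0))
})

test_that("sparse solutions match a dense solve", {
  recs <- fixtureRecords(nCows = 8, parities = 1:2, seed = 4)
  ped <- randomPedigree(nFounders = 6, nGen = 1, perGen = 8, seed = 4)
  recs$cow <- paste0("A1_", match(recs$cow, unique(recs$cow)))
  vc <- fixtureVC(P = 2)
  des <- buildDesign(recs, ped, modelSpec(parities = 1:2))
  Ainv <- buildAInverse(ped)
  sys <- assembleMME(des, vc, Ainv)
  sol <- solveMME(sys)
  dense <- oracleDenseMME(des, vc, as.matrix(relValues(Ainv)))
  # the fixture carries confounded fixed levels; apply the same zero
  # constraints to the dense system before comparing
  zero <- which(sol$fixed$estimate == 0)
  dense$C[zero, ] <- 0; dense$C[, zero] <- 0
  dense$C[cbind(zero, zero)] <- 1
  dense$rhs[zero] <- 0
  ds <- solve(dense$C, dense$rhs)
  got <- c(sol$fixed$estimate, as.vector(t(sol$additive)),
           as.vector(t(sol$permanent)))
  expect_equal(got, as.numeric(ds), tolerance = 1e-6)
  expect_lt(sol$relResidual, 1e-8)
})

test_that("solutions are invariant to record order and re-solve", {
  recs <- fixtureRecords(nCows = 6, parities = 1, seed = 10)
  ped <- Pedigree(unique(recs$cow), NA, NA)
  vc <- fixtureVC(P = 1)
  spec <- modelSpec(parities = 1)
  Ainv <- buildAInverse(ped)
  solA <- solveMME(assembleMME(buildDesign(recs, ped, spec), vc, Ainv))
  perm <- recs[sample(nrow(recs)), ]
  solB <- solveMME(assembleMME(buildDesign(perm, ped, spec), vc, Ainv))
  expect_equal(solA$additive, solB$additive, tolerance = 1e-9)
  expect_equal(solA$permanent, solB$permanent, tolerance = 1e-9)
  solC <- solveMME(assembleMME(buildDesign(recs, ped, spec), vc, Ainv))
  expect_identical(solA$additive, solC$additive)
})

test_that("a single uninformative record yields zero random solutions", {
  # one record in one HTD: the fixed effect absorbs it entirely
  recs <- data.frame(cow = "c1", herd = 1, test_date = as.Date("2015-06-01"),
                     parity = 1, dim = 50, yield = 31.4, heat_load = 0)
  ped <- Pedigree("c1", NA, NA)
  des <- buildDesign(recs, ped, modelSpec(parities = 1))
  sol <- solveMME(assembleMME(des, fixtureVC(P = 1), buildAInverse(ped)))
  expect_equal(unname(sol$additive["c1", ]), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(sol$permanent["c1", ]), c(0, 0), tolerance = 1e-10)
  expect_equal(sol$fixed$estimate[1], 31.4, tolerance = 1e-10)
})
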