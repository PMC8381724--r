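test_that("simulation is bit-identical under a fixed config and seed", {
  cfg <- simulationConfig(nIndividuals = 30, nMarkers = 100, nSubpops = 2,
                          structureStrength = 0.03, seed = 42)
  s1 <- simulateDosages(cfg)
  s2 <- simulateDosages(cfg)
  expect_identical(dosages(s1$dosages), dosages(s2$dosages))
  expect_identical(s1$subpop, s2$subpop)

  rc1 <- simulateReadCounts(s1$dosages, c(10, 40), 0.002, seed = 9)
  rc2 <- simulateReadCounts(s2$dosages, c(10, 40), 0.002, seed = 9)
  expect_identical(refCounts(rc1), refCounts(rc2))

  ph1 <- simulatePhenotypes(s1$dosages, traitSpec(),
                            fieldLayoutSpec(rows = 6, cols = 5), seed = 3)
  ph2 <- simulatePhenotypes(s2$dosages, traitSpec(),
                            fieldLayoutSpec(rows = 6, cols = 5), seed = 3)
  expect_identical(ph1$plots, ph2$plots)
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(nIndividuals = 3, nSubpops = 5), "nSubpops")
  expect_error(simulationConfig(seqError = 0.6))
  expect_error(simulationConfig(depthRange = c(0, 50)))
  expect_error(simulationConfig(alleleFreqRange = c(0, 0.5)))
})

test_that("no drift means no differentiation; dosage means match ancestral frequencies", {
  sim <- makePanel(n = 200, m = 2000, seed = 13, structure = 0, nSubpops = 2)
  fst <- pairwiseFst(sim$dosages, sim$subpop)
  expect_lt(abs(fst$fstRaw[1]), 0.01)

  # fixed ancestral p = 0.5: mean dosage 2.0 within 3 SE of Binomial(4, .5)
  cfg <- simulationConfig(nIndividuals = 500, nMarkers = 1000,
                          alleleFreqRange = c(0.5, 0.5), nSubpops = 1,
                          structureStrength = 0, seed = 14)
  X <- dosages(simulateDosages(cfg)$dosages)
  se <- sqrt(4 * 0.5 * 0.5 / 500)   # SD of a dosage / sqrt(n)
  expect_true(all(abs(colMeans(X) - 2) < 3 * se + 0.15))
  expect_lt(abs(mean(X) - 2), 0.01)
})

test_that("Balding-Nichols drift strength is recovered as realised F_ST", {
  # independent frequency-variance check: for the F-model,
  # Var(p_sub) = F p (1 - p), so F is recoverable from subpop frequencies
  cfg <- simulationConfig(nIndividuals = 200, nMarkers = 5000, nSubpops = 2,
                          structureStrength = 0.05, seed = 15)
  sim <- simulateDosages(cfg)
  fst <- pairwiseFst(sim$dosages, sim$subpop)
  expect_gte(fst$fstRaw[1], 0.02)
  expect_lte(fst$fstRaw[1], 0.09)
})

test_that("read-count generator matches its stated conditional model", {
  X0 <- DosageMatrix(matrix(0L, 5, 10))
  rc0 <- simulateReadCounts(X0, c(30, 30), seqError = 0, seed = 1)
  expect_true(all(altCounts(rc0) == 0))
  expect_true(all(refCounts(rc0) == 30))

  X2 <- DosageMatrix(matrix(2L, 5, 200))
  rc2 <- simulateReadCounts(X2, c(2000, 2000), seqError = 0, seed = 2)
  frac <- altCounts(rc2) / 2000
  expect_lt(abs(mean(frac) - 0.5), 0.005)

  expect_error(simulateReadCounts(DosageMatrix(matrix(c(1, NA), 1)), c(10, 20)))
})

test_that("caller error rate decreases monotonically with depth", {
  sim <- makePanel(n = 60, m = 500, seed = 16)
  truth <- dosages(sim$dosages)
  err <- vapply(c(10, 30, 100), function(d) {
    rc <- simulateReadCounts(sim$dosages, c(d, d), 0.002, seed = 17)
    D <- dosages(callDosages(rc, 0.002, 0.5))
    mean(D != truth, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("phenotype generator honours its variance targets and degenerate cases", {
  sim <- makePanel(n = 100, m = 400, seed = 18)
  # pure additive, no field effects: plot value equals the genotypic value
  ph <- simulatePhenotypes(
    sim$dosages,
    traitSpec(varAdditive = 1, varResidual = 0),
    fieldLayoutSpec(nLocations = 1, nYears = 1, nBlocks = 1,
                    rows = 10, cols = 10,
                    varBlock = 0, varRow = 0, varCol = 0),
    seed = 19)
  g <- ph$truth$geneticValue
  expect_equal(ph$plots$value[match(names(g), ph$plots$genotype)],
               unname(g))
  expect_equal(unname(ph$truth$realizedVarComp["additive"]), 1)
  expect_equal(unname(ph$truth$realizedVarComp[c("dominance", "epistatic")]),
               c(0, 0))

  # no genetic variance at all: flagged, zero-variance genotypic values
  expect_warning(ts0 <- traitSpec(varAdditive = 0, varResidual = 1),
                 "not heritable")
  ph0 <- simulatePhenotypes(sim$dosages, ts0,
                            fieldLayoutSpec(rows = 10, cols = 10), seed = 20)
  expect_equal(var(ph0$truth$geneticValue), 0)

  # layout too small
  expect_error(
    simulatePhenotypes(sim$dosages, traitSpec(),
                       fieldLayoutSpec(rows = 5, cols = 5), seed = 1),
    "too small")
})

test_that("field-trial pipeline recovers the simulated heritability", {
  # var_additive = 1 and a trial-mean error variance of 1 (plot variance 2
  # averaged over two blocks), l = 3, t = 2, no GxE, no field trends:
  # H2 target 1 / (1 + 1/6) = 6/7
  h2s <- vapply(1:8, function(s) {
    sim <- makePanel(n = 80, m = 200, seed = 100 + s)
    ph <- simulatePhenotypes(
      sim$dosages, traitSpec(varAdditive = 1, varResidual = 2),
      fieldLayoutSpec(nLocations = 3, nYears = 2, nBlocks = 2,
                      rows = 8, cols = 10,
                      varBlock = 0, varRow = 0, varCol = 0),
      seed = 200 + s)
    heritability(varCompH2(bluesWithinTrial(ph$plots)))
  }, 0)
  expect_gt(median(h2s), 0.75)
  expect_lt(median(h2s), 0.95)
})

test_that("REML recovers the generator's variance components", {
  rel <- vapply(1:10, function(s) {
    sim <- makePanel(n = 100, m = 200, seed = 300 + s)
    ph <- simulatePhenotypes(
      sim$dosages,
      traitSpec(varAdditive = 1, varGxL = 0.3, varGxT = 0.3,
                varResidual = 1),
      fieldLayoutSpec(nLocations = 3, nYears = 2, nBlocks = 2,
                      rows = 10, cols = 10),
      seed = 400 + s)
    vc <- varCompH2(bluesWithinTrial(ph$plots))$varComp
    vc["g"]
  }, 0)
  expect_lt(abs(median(rel) - 1), 0.3)
})
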