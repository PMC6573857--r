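test_that("community construction honours the mismatch specification", {
  pool <- pool806()
  comm0 <- simulateCommunity(pool, nTaxa = 6, assignedVariant = rep("RPV3", 6),
                             mismatchSpec = rep(0L, 6), seed = 1)
  rpv3 <- as.character(variantSequences(pool)[["RPV3"]])
  sites <- as.character(taxonReverseSites(comm0))
  expect_true(all(sites == revComp(rpv3)))

  comm2 <- simulateCommunity(pool, nTaxa = 6, assignedVariant = rep("RPV3", 6),
                             mismatchSpec = rep(2L, 6), seed = 2)
  mm <- vapply(as.character(taxonReverseSites(comm2)), function(s)
    countMismatches(s, revComp(rpv3)), numeric(1))
  expect_true(all(mm == 2L))

  one <- simulateCommunity(pool, nTaxa = 1, seed = 3)
  expect_equal(unname(taxonAbundance(one)), 1)
  expect_error(simulateCommunity(pool, nTaxa = 2, mismatchSpec = c(25L, 0L)),
               "exceeds the primer length")
})

test_that("variant choice distribution has the stated limiting forms", {
  pool <- pool806()
  site <- revComp(as.character(variantSequences(pool)[["RPV5"]]))
  pTas0 <- variantChoiceDistribution(
    site, pool, tempC = 50,
    model = annealingModel(tasAnnealWeight = 0), mode = "TAS")
  expect_equal(unname(pTas0), rep(1 / 18, 18))
  expect_equal(shannonIndex(pTas0), log(18), tolerance = 1e-12)

  # far below every effective Tm the logistic saturates -> near uniform
  pCold <- variantChoiceDistribution(site, pool, tempC = 0, mode = "DePCR")
  expect_lt(max(pCold) / min(pCold), 1.001)
  expect_equal(sum(pCold), 1, tolerance = 1e-12)

  # Monte-Carlo: drawn variant diversity is lower at 60 than at 40 degC
  p40 <- variantChoiceDistribution(site, pool, tempC = 40, mode = "DePCR")
  p60 <- variantChoiceDistribution(site, pool, tempC = 60, mode = "DePCR")
  set.seed(7)
  h <- vapply(list(p40, p60), function(p) {
    draws <- sample(names(p), 10000, replace = TRUE, prob = p)
    shannonIndex(as.numeric(table(draws)))
  }, numeric(1))
  expect_lt(h[2], h[1])
})

test_that("read simulation produces the declared layout and truth records", {
  sim <- smallSim(chimeraProb = 0, seed = 31)
  expect_equal(sum(simTruth(sim)$isChimera), 0L)
  lens <- nchar(as.character(simReads(sim)))
  expect_true(all(lens >= 400 & lens <= 500))
  # error-free DePCR reads contain the exact reverse-complemented variant
  pool <- pool806()
  reads <- as.character(simReads(sim))
  tr <- simTruth(sim)
  rc <- revComp(as.character(variantSequences(pool)))
  names(rc) <- names(variantSequences(pool))
  hit <- mapply(function(r, v) grepl(rc[[v]], r, fixed = TRUE),
                reads[1:200], tr$variantId[1:200])
  expect_true(all(hit))
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- smallSim(seed = 77, errorRate = 0.001)
  s2 <- smallSim(seed = 77, errorRate = 0.001)
  expect_identical(as.character(simReads(s1)), as.character(simReads(s2)))
  expect_identical(simTruth(s1), simTruth(s2))
  expect_identical(simBarcodes(s1), simBarcodes(s2))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  writeSimulatedReads(s1, d1); writeSimulatedReads(s2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("expected depth scales linearly with input DNA mass", {
  pool <- pool806()
  comm <- smallCommunity()
  bcs <- designBarcodes(25, 10, 3, seed = 12)
  levels <- c(1.25, 2.5, 5, 10, 20)
  cfg <- simulationConfig(mode = "DePCR", nSamples = 25L,
                          inputNg = rep(levels, each = 5),
                          readsPerNg = 60, depthNoiseSd = 0.3,
                          errorRate = 0, seed = 91)
  sim <- simulateReads(comm, pool, bcs, cfg)
  depth <- simSamples(sim)$depth
  input <- simSamples(sim)$inputNg
  fit <- linearFit(input, depth)
  expect_gt(regressionCoefficients(fit)["x"], 0)
  # doubling input roughly doubles the mean depth
  ratio <- mean(depth[input == 20]) / mean(depth[input == 10])
  expect_gt(ratio, 1.3)
})

test_that("realized chimera fraction tracks the configured probability", {
  sim <- smallSim(mode = "TAS", chimeraProb = 0.06, seed = 13,
                  nSamples = 3, readsPerNg = 200)
  n <- length(sim)
  frac <- mean(simTruth(sim)$isChimera)
  expect_lt(abs(frac - 0.06), 3 * sqrt(0.06 * 0.94 / n))
  # truth-record consistency: parents and breakpoint set iff chimeric
  tr <- simTruth(sim)
  expect_true(all(tr$isChimera == (!is.na(tr$parentA) & !is.na(tr$parentB))))
  bp <- tr$breakpoint[tr$isChimera]
  expect_true(all(bp > 0 & bp < nchar(as.character(simReads(sim)))[tr$isChimera]))
})
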