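randSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("match profiles agree with Hamming and alignment oracles", {
  ref <- randSeq(120, 1)
  expect_equal(matchProfile(ref, ref), rep(1L, 120))

  # three substitutions: exactly length - 3 ones, zeros at the mutated sites
  q <- ref
  for (p in c(10, 60, 110))
    substr(q, p, p) <- chartr("ACGT", "CATG", substr(ref, p, p))
  mutated <- which(strsplit(q, "")[[1]] != strsplit(ref, "")[[1]])
  prof <- matchProfile(q, ref)
  expect_equal(sum(prof), 120L - length(mutated))
  expect_true(all(prof[mutated] == 0L))

  # internal 2-base deletion: remaining bases still align as matches
  qDel <- paste0(substr(ref, 1, 50), substr(ref, 53, 120))
  profDel <- matchProfile(qDel, ref)
  expect_equal(sum(profDel), nchar(qDel))
})

test_that("chimera detection flags constructed hybrids with correct parents", {
  set.seed(3)
  refs <- setNames(vapply(1:4, function(i) randSeq(300, 100 + i),
                          character(1)), paste0("t", 1:4))
  params <- chimeraParams(minGain = 4L, minSegment = 50L)

  pure <- detectChimeras(refs["t2"], refs, params)
  expect_false(pure$isChimera)
  expect_equal(pure$closestReference, "t2")

  hybrid <- paste0(substr(refs["t1"], 1, 150), substr(refs["t3"], 151, 300))
  resH <- detectChimeras(c(hy = hybrid), refs, params)
  expect_true(resH$isChimera)
  expect_setequal(c(resH$parentA, resH$parentB), c("t1", "t3"))
  # breakpoint within the interval between flanking parent differences
  d13 <- which(strsplit(refs[["t1"]], "")[[1]] !=
                 strsplit(refs[["t3"]], "")[[1]])
  lastLeft <- max(d13[d13 <= 150])
  firstRight <- min(d13[d13 > 150])
  expect_gte(resH$breakpoint, lastLeft)
  expect_lte(resH$breakpoint, firstRight)
  expect_gte(resH$bestChimericMatches, resH$bestSingleMatches + 4L)

  # reads shorter than two segments are never called
  short <- detectChimeras(DNAStringSet(c(s = substr(hybrid, 1, 80))), refs,
                          params)
  expect_false(short$isChimera)
  expect_true(short$tooShort)
})

test_that("prefix/suffix maximization equals the brute-force pair search", {
  set.seed(17)
  refs <- setNames(vapply(1:5, function(i) randSeq(300, 200 + i),
                          character(1)), paste0("r", 1:5))
  queries <- c(
    refs[["r1"]],                                             # pure
    paste0(substr(refs[["r2"]], 1, 90), substr(refs[["r4"]], 91, 300)),
    paste0(substr(refs[["r5"]], 1, 200), substr(refs[["r1"]], 201, 300)),
    randSeq(300, 999),                                        # unrelated
    paste0(substr(refs[["r3"]], 1, 60), substr(refs[["r2"]], 61, 300)))
  params <- chimeraParams(minGain = 4L, minSegment = 50L)
  res <- detectChimeras(queries, refs, params)
  for (i in seq_along(queries)) {
    oracle <- bruteChimeraScore(queries[i], unname(refs), 50L)
    expect_equal(res$bestSingleMatches[i], oracle$bestSingle)
    expect_equal(res$bestChimericMatches[i], oracle$bestChimeric)
    expect_equal(res$isChimera[i],
                 oracle$bestChimeric - oracle$bestSingle >= 4L)
  }
})

test_that("chimera rates and intervals behave as fractions", {
  v0 <- data.frame(isChimera = rep(FALSE, 1000))
  r0 <- chimeraRate(v0)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ciLower, 0)
  v60 <- data.frame(isChimera = rep(c(TRUE, FALSE), c(60, 940)))
  r60 <- chimeraRate(v60)
  expect_equal(r60$rate, 0.06)
  expect_lt(r60$ciLower, 0.06)
  expect_gt(r60$ciUpper, 0.06)
})

test_that("detector is sensitive and specific on simulated data", {
  sim <- smallSim(mode = "TAS", chimeraProb = 0.06, errorRate = 0.001,
                  seed = 19, nSamples = 2, readsPerNg = 150)
  v <- detectChimeras(simReads(sim), simTemplates(sim))
  tr <- simTruth(sim)
  sens <- mean(v$isChimera[tr$isChimera])
  fpr <- mean(v$isChimera[!tr$isChimera])
  expect_gte(sens, 0.90)
  expect_lte(fpr, 0.001)
  # detected rate brackets the truth-table rate
  rate <- chimeraRate(v)$rate
  truthRate <- mean(tr$isChimera)
  expect_gte(rate, 0.8 * truthRate)
  expect_lte(rate, 1.1 * truthRate)
})

test_that("detected rate is monotone in the simulated chimera probability", {
  rates <- vapply(c(0, 0.01, 0.06), function(cp) {
    sim <- smallSim(mode = "TAS", chimeraProb = cp, errorRate = 0.001,
                    seed = 23, nSamples = 1, readsPerNg = 120)
    chimeraRate(detectChimeras(simReads(sim), simTemplates(sim)))$rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
})
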