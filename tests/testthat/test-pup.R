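library(Biostrings)

test_that("sliding-window quality trimming matches a positionwise oracle", {
  params <- filterParams(window = 4L, qualityThreshold = 20)
  mkq <- function(phreds) intToUtf8(phreds + 33L)
  reads <- DNAStringSet(c(a = strrep("A", 100), b = strrep("C", 100),
                          c = strrep("G", 80)))
  quals <- c(mkq(rep(30L, 100)),
             mkq(c(rep(30L, 50), rep(10L, 50))),
             mkq(rep(2L, 80)))
  out <- qualityTrim(reads, quals, params)
  # independent oracle: first window with mean below threshold
  oracle <- function(q, w, thr) {
    for (i in seq_len(length(q) - w + 1L))
      if (mean(q[i:(i + w - 1L)]) < thr) return(i - 1L)
    length(q)
  }
  expect_equal(unname(Biostrings::width(out$reads["a"])), 100L)  # untouched
  cutB <- oracle(c(rep(30L, 50), rep(10L, 50)), 4L, 20)
  expect_equal(unname(Biostrings::width(out$reads["b"])), cutB)
  expect_gte(100L - cutB, 50L - 4L + 1L)  # tail removal lower bound
  expect_equal(out$discarded, 1L)         # the all-Q2 read
  expect_false("c" %in% names(out$reads))

  # malformed record (length mismatch) is skipped and counted
  expect_message(
    out2 <- qualityTrim(DNAStringSet(c(x = "ACGT", y = "ACGT")),
                        c("III", "IIII"), params),
    "malformed")
  expect_equal(out2$malformed, 1L)
  expect_equal(names(out2$reads), "y")
})

test_that("length filter uses inclusive bounds", {
  reads <- DNAStringSet(setNames(
    vapply(c(399, 400, 500, 501), strrep, character(1), x = "A"),
    paste0("L", c(399, 400, 500, 501))))
  out <- lengthFilter(reads)
  expect_setequal(names(out$reads), c("L400", "L500"))
  expect_equal(out$kept, 2L)
  expect_equal(out$tooShort, 1L)
  expect_equal(out$tooLong, 1L)

  empty <- lengthFilter(DNAStringSet())
  expect_equal(length(empty$reads), 0L)
  expect_equal(empty$kept + empty$tooShort + empty$tooLong, 0L)

  sim <- smallSim(seed = 41)
  simOut <- lengthFilter(simReads(sim))
  expect_gte(simOut$kept / length(sim), 0.99)
})

test_that("exact variant counting reproduces the simulation ground truth", {
  pool <- pool806()
  sim <- smallSim(seed = 55, chimeraProb = 0, nSamples = 2, readsPerNg = 100)
  dm <- demultiplexSimulation(sim)
  pe <- buildPupExperiment(dm$readsBySample, pool)
  tr <- simTruth(sim)
  truthTab <- table(factor(tr$variantId, levels = rownames(pupCounts(pe))),
                    tr$sampleId)
  expect_equal(unname(as.matrix(pupCounts(pe))),
               unname(as.matrix(truthTab[, colnames(pupCounts(pe))])))
  expect_true(all(sampleData(pe)$unassigned == 0L))
  # conservation: counts + unassigned = reads per sample
  perSample <- colSums(pupCounts(pe)) + sampleData(pe)$unassigned
  expect_equal(unname(perSample),
               unname(vapply(dm$readsBySample, length, integer(1))))
})

test_that("single substitutions in the primer region unassign the read", {
  pool <- pool806()
  rpv1 <- as.character(variantSequences(pool)[["RPV1"]])
  insert <- strrep("AC", 180)
  clean <- paste0("ACACTGACGACATGGTTCTACA", "CCTACGGGAGGCAGCAG",
                  insert, revComp(rpv1), "AGACCAAGTCTCTGCTACCGTA")
  mut <- sub("^G", "A", rpv1)  # position-1 substitution: matches no variant
  broken <- paste0("ACACTGACGACATGGTTCTACA", "CCTACGGGAGGCAGCAG",
                   insert, revComp(mut), "AGACCAAGTCTCTGCTACCGTA")
  fwd <- paste0(insert, rpv1, insert)  # forward-strand orientation
  res <- extractPup(DNAStringSet(c(clean, broken, fwd)), pool)
  expect_equal(sum(res$counts), 2L)
  expect_equal(unname(res$counts["RPV1"]), 2L)
  expect_equal(res$unassigned, 1L)
})

test_that("substitution errors unassign reads at the predicted rate", {
  e <- 0.005
  sim <- smallSim(seed = 66, errorRate = e, chimeraProb = 0, nSamples = 3,
                  readsPerNg = 250)
  res <- extractPup(simReads(sim), pool806())
  n <- length(sim)
  L <- 20
  # an error in the 20-base primer region unassigns the read unless it
  # lands on a degenerate position and recreates another valid variant:
  # positions 8 and 9 admit 2 of 3 alternative bases, position 14 admits 1
  pRescue <- (2 / 3 + 2 / 3 + 1 / 3) / L
  pUn <- (1 - (1 - e)^L) - L * e * (1 - e)^(L - 1) * pRescue
  obs <- res$unassigned / n
  expect_lt(abs(obs - pUn), 3 * sqrt(pUn * (1 - pUn) / n))
})

test_that("rarefaction subsamples exactly and matches the hypergeometric mean", {
  x <- c(a = 30L, b = 70L)
  expect_equal(rarefyCounts(x, depth = 100L, seed = 1), x)
  r <- rarefyCounts(x, depth = 40L, seed = 1)
  expect_equal(sum(r), 40L)
  expect_true(all(r <= x))
  set.seed(9)
  draws <- replicate(1000, .rarefied <- rarefyCounts(x, 40L)["a"])
  mu <- 40 * 30 / 100                      # hypergeometric expectation
  se <- sqrt(40 * 0.3 * 0.7 * (100 - 40) / (100 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - mu), 3 * se)
  expect_error(rarefyCounts(x, depth = 0L), "depth")

  # container method drops shallow samples and rarefies the rest
  m <- matrix(c(50L, 50L, 10L, 5L, 200L, 300L), nrow = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  pe <- PupExperiment(m)
  expect_message(pr <- rarefyCounts(pe, depth = 90L, seed = 4), "dropping")
  expect_equal(colnames(pupCounts(pr)), c("s1", "s3"))
  expect_true(all(colSums(pupCounts(pr)) == 90L))
  expect_true(all(pupCounts(pr) <= pupCounts(pe)[, c("s1", "s3")]))
  # deterministic under a fixed seed
  expect_identical(pupCounts(rarefyCounts(pe, 90L, seed = 4)), pupCounts(pr))
})
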