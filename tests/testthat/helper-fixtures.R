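# Shared fixtures, built in code at test time.

.fixtureEnv <- new.env()

pool806 <- function() {
  if (is.null(.fixtureEnv$pool))
    .fixtureEnv$pool <- expandDegenerate("GGACTACHVGGGTWTCTAAT", name = "806R")
  .fixtureEnv$pool
}

smallBarcodes <- function(n = 8) designBarcodes(n, 10, 3, seed = 404)

smallCommunity <- function(nTaxa = 15, seed = 99, ...)
  simulateCommunity(pool806(), nTaxa = nTaxa, seed = seed, ...)

smallSim <- function(mode = "DePCR", nSamples = 2, seed = 21,
                     errorRate = 0, chimeraProb = NULL, nTaxa = 15,
                     readsPerNg = 150, ...) {
  cfg <- simulationConfig(mode = mode, nSamples = nSamples, seed = seed,
                          errorRate = errorRate, chimeraProb = chimeraProb,
                          readsPerNg = readsPerNg, ...)
  simulateReads(smallCommunity(nTaxa), pool806(), smallBarcodes(nSamples),
                cfg)
}

# independent brute-force two-parent chimera scorer used as oracle
bruteChimeraScore <- function(q, refs, minSegment) {
  L <- nchar(q)
  qc <- strsplit(q, "")[[1]]
  profs <- lapply(refs, function(r) {
    rc <- strsplit(r, "")[[1]]
    M <- length(rc)
    k <- min(L, M)
    left <- rep(FALSE, L); left[seq_len(k)] <- qc[seq_len(k)] == rc[seq_len(k)]
    right <- rep(FALSE, L)
    right[(L - k + 1):L] <- qc[(L - k + 1):L] == rc[(M - k + 1):M]
    list(cumLeft = cumsum(left), cumRight = cumsum(right),
         totRight = sum(right), tot = sum(left))
  })
  s1 <- max(vapply(profs, `[[`, numeric(1), "tot"))
  best <- -Inf
  if (L >= 2 * minSegment) {
    for (a in seq_along(refs)) for (b in seq_along(refs)) {
      if (a == b) next
      for (bp in minSegment:(L - minSegment)) {
        sc <- profs[[a]]$cumLeft[bp] +
          (profs[[b]]$totRight - profs[[b]]$cumRight[bp])
        if (sc > best) best <- sc
      }
    }
  }
  list(bestSingle = s1, bestChimeric = if (is.finite(best)) best else NA)
}

# direct (formula) ANOSIM R, independent of the package implementation
directAnosimR <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pairs <- t(combn(n, 2))
  vals <- dm[pairs]
  rk <- rank(vals)
  within <- groups[pairs[, 1]] == groups[pairs[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
}
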