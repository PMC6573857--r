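#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject PhredQuality quality QualityScaledDNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IntegerList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom stats rlnorm rpois rbinom runif lm coef qf kruskal.test p.adjust
#'   prop.test cmdscale dist cov var quantile setNames complete.cases
#' @importFrom utils write.table read.table head combn
#' @importFrom Rcpp sourceCpp
#' @useDynLib depcr, .registration = TRUE
NULL

#' Solution conditions for melting-temperature prediction
#'
#' Holds the strand and ion concentrations (molar) under which
#' nearest-neighbor melting temperatures are computed. Defaults follow common
#' amplicon PCR conditions: 250 nM total oligo, 2 mM Mg2+, 0.2 mM dNTPs and a
#' 50 mM monovalent-cation baseline.
#'
#' @slot oligoConcM total oligonucleotide strand concentration (M)
#' @slot mgConcM divalent (Mg2+) cation concentration (M)
#' @slot dntpConcM total dNTP concentration (M); dNTPs chelate Mg2+, so the
#'   free divalent concentration is \code{max(0, mgConcM - dntpConcM)}
#' @slot monovalentConcM monovalent cation concentration (M)
#' @export
setClass("TmConditions", representation(
  oligoConcM = "numeric", mgConcM = "numeric",
  dntpConcM = "numeric", monovalentConcM = "numeric"
))

setValidity("TmConditions", function(object) {
  v <- c(object@oligoConcM, object@mgConcM, object@dntpConcM,
         object@monovalentConcM)
  if (length(v) != 4L || anyNA(v) || any(v < 0))
    return("all concentrations must be single non-negative numbers")
  if (object@oligoConcM <= 0)
    return("oligoConcM must be positive")
  TRUE
})

#' An expanded degenerate primer pool
#'
#' Stores a degenerate IUPAC primer together with its full expansion into
#' non-degenerate variants and their predicted melting temperatures. Variant
#' identifiers RPV1, RPV2, ... are assigned in canonical expansion order: the
#' leftmost degenerate position varies slowest and bases are ordered
#' A < C < G < T at each degenerate position.
#'
#' @slot primerName short primer label, e.g. "806R"
#' @slot iupac the degenerate primer sequence (IUPAC codes allowed), 5'->3'
#' @slot variants \code{DNAStringSet} of non-degenerate variants, named by
#'   variant id
#' @slot tm named numeric vector of predicted melting temperatures (deg C),
#'   parallel to \code{variants}
#' @slot conditions the \linkS4class{TmConditions} used for \code{tm}
#' @export
setClass("PrimerPool", representation(
  primerName = "character", iupac = "character",
  variants = "DNAStringSet", tm = "numeric", conditions = "TmConditions"
))

setValidity("PrimerPool", function(object) {
  n <- length(object@variants)
  if (n < 1L) return("pool must contain at least one variant")
  if (anyDuplicated(names(object@variants)))
    return("variant ids must be unique")
  if (length(unique(Biostrings::width(object@variants))) != 1L)
    return("all variants must have the parent primer length")
  if (length(object@tm) && length(object@tm) != n)
    return("tm must be empty or parallel to variants")
  TRUE
})

#' A designed sample-barcode set
#'
#' Fixed-length nucleotide barcodes with a guaranteed minimum pairwise
#' Hamming distance, as used to tag samples in pooled amplicon libraries.
#'
#' @slot barcodes character vector of barcode sequences
#' @slot width barcode length (bases)
#' @slot minDistance guaranteed minimum pairwise Hamming distance
#' @export
setClass("BarcodeSet", representation(
  barcodes = "character", width = "integer", minDistance = "integer"
))

setValidity("BarcodeSet", function(object) {
  b <- object@barcodes
  if (length(b) < 1L) return("empty barcode set")
  if (any(nchar(b) != object@width))
    return("all barcodes must have the declared width")
  if (anyDuplicated(b)) return("barcodes must be distinct")
  if (length(b) > 1L) {
    dmin <- minPairwiseHamming(b)
    if (dmin < object@minDistance)
      return(sprintf("min pairwise Hamming distance %d < declared %d",
                     dmin, object@minDistance))
  }
  TRUE
})

#' A synthetic template community
#'
#' The set of template "taxa" from which reads are simulated. Each taxon has
#' a relative abundance, an insert sequence (the region between the forward
#' primer site and the reverse primer site) and a 20-base reverse-primer site
#' to which reverse-primer variants anneal (possibly with mismatches).
#'
#' @slot abundance named numeric vector of relative abundances (sums to 1)
#' @slot inserts \code{DNAStringSet} of insert sequences, named by taxon id
#' @slot reverseSites \code{DNAStringSet} of reverse-primer template sites
#'   (read-strand orientation), named by taxon id
#' @export
setClass("Community", representation(
  abundance = "numeric", inserts = "DNAStringSet", reverseSites = "DNAStringSet"
))

setValidity("Community", function(object) {
  n <- length(object@abundance)
  if (n < 1L) return("community must contain at least one taxon")
  if (abs(sum(object@abundance) - 1) > 1e-9)
    return("relative abundances must sum to 1")
  if (any(object@abundance <= 0)) return("abundances must be positive")
  if (length(object@inserts) != n || length(object@reverseSites) != n)
    return("inserts and reverseSites must be parallel to abundance")
  ids <- names(object@abundance)
  if (is.null(ids) || !identical(ids, names(object@inserts)) ||
      !identical(ids, names(object@reverseSites)))
    return("taxon ids must name all three slots consistently")
  TRUE
})

#' Annealing model for primer-variant choice
#'
#' Phenomenological model of which variant from a degenerate pool is used to
#' copy a given template at a given annealing temperature. In DePCR mode the
#' probability of variant v is proportional to
#' \code{plogis((Tm(v) - mismatchPenaltyC * mm(v) - T) / softnessC)}, where
#' \code{mm(v)} is the number of primer-template mismatches. In TAS mode the
#' distribution is a mixture \code{(1 - w) * uniform + w * DePCR} with
#' \code{w = tasAnnealWeight}, reflecting the near-uniform "scrambled" primer
#' utilization that exponential amplification with locus primers produces.
#'
#' @slot mismatchPenaltyC deg C of effective Tm lost per primer-template
#'   mismatch
#' @slot softnessC logistic transition width (deg C)
#' @slot tasAnnealWeight weight in [0,1] of the annealing-driven component in
#'   TAS mode (0 = exactly uniform)
#' @export
setClass("AnnealingModel", representation(
  mismatchPenaltyC = "numeric", softnessC = "numeric",
  tasAnnealWeight = "numeric"
))

setValidity("AnnealingModel", function(object) {
  if (object@mismatchPenaltyC < 0) return("mismatchPenaltyC must be >= 0")
  if (object@softnessC <= 0) return("softnessC must be > 0")
  w <- object@tasAnnealWeight
  if (w < 0 || w > 1) return("tasAnnealWeight must lie in [0,1]")
  TRUE
})

#' Simulation configuration
#'
#' Parameters of one simulated sequencing condition. Per-sample read depth is
#' drawn as Poisson(inputNg * readsPerNg * lognormal(0, depthNoiseSd)), so
#' expected yield is proportional to input DNA mass. Chimeric reads are
#' produced at \code{chimeraProb}; the default depends on the mode (0.06 for
#' TAS, 0.0005 for DePCR), matching the orders of magnitude observed for the
#' two workflows.
#'
#' @slot mode "DePCR" or "TAS"
#' @slot annealingTempC first-stage annealing temperature (deg C)
#' @slot nSamples number of samples (technical replicates) to simulate
#' @slot inputNg input gDNA mass per sample (ng); recycled to nSamples
#' @slot readsPerNg expected reads generated per ng of input
#' @slot depthNoiseSd sd (log scale) of the lognormal depth noise
#' @slot chimeraProb per-read probability of a two-parent chimeric insert
#' @slot errorRate per-base substitution error probability
#' @slot annealing the \linkS4class{AnnealingModel}
#' @slot seed integer seed driving all randomness of the simulation
#' @export
setClass("SimulationConfig", representation(
  mode = "character", annealingTempC = "numeric", nSamples = "integer",
  inputNg = "numeric", readsPerNg = "numeric", depthNoiseSd = "numeric",
  chimeraProb = "numeric", errorRate = "numeric",
  annealing = "AnnealingModel", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  if (!object@mode %in% c("DePCR", "TAS"))
    return("mode must be 'DePCR' or 'TAS'")
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (object@chimeraProb < 0 || object@chimeraProb >= 1)
    return("chimeraProb must lie in [0,1)")
  if (object@errorRate < 0 || object@errorRate > 0.05)
    return("errorRate must lie in [0, 0.05]")
  if (any(object@inputNg <= 0)) return("inputNg must be positive")
  if (object@readsPerNg <= 0) return("readsPerNg must be positive")
  TRUE
})

#' Simulated reads with ground truth
#'
#' Result of \code{\link{simulateReads}}: pooled merged reads, the observed
#' (possibly error-containing) barcode of every read, the per-read truth
#' records and per-sample metadata, plus the full-length template amplicons
#' used as chimera-detection references.
#'
#' @slot reads \code{DNAStringSet} of merged reads, named by read id
#' @slot qualities \code{PhredQuality} per-read quality strings
#' @slot barcodes character vector of observed barcodes, parallel to reads
#' @slot truth data.frame with columns readId, sampleId, taxonId, variantId,
#'   isChimera, parentA, parentB, breakpoint (read coordinate)
#' @slot samples data.frame with columns sampleId, barcode, mode,
#'   annealingTempC, inputNg, depth
#' @slot templates \code{DNAStringSet} of full-length template amplicons,
#'   named by taxon id
#' @slot config the \linkS4class{SimulationConfig} used
#' @export
setClass("SimulatedReads", representation(
  reads = "DNAStringSet", qualities = "PhredQuality", barcodes = "character",
  truth = "data.frame", samples = "data.frame", templates = "DNAStringSet",
  config = "SimulationConfig"
))

setValidity("SimulatedReads", function(object) {
  n <- length(object@reads)
  if (nrow(object@truth) != n || length(object@barcodes) != n)
    return("truth and barcodes must be parallel to reads")
  ch <- object@truth$isChimera
  par_ok <- !is.na(object@truth$parentA) & !is.na(object@truth$parentB) &
    !is.na(object@truth$breakpoint)
  if (any(ch != par_ok))
    return("isChimera must hold exactly when parents and breakpoint are set")
  TRUE
})

#' Primer utilization count container
#'
#' A \code{SummarizedExperiment} with features (primer variants or taxa) as
#' rows and samples as columns; assay \code{"counts"} holds non-negative
#' integer counts. Per-sample metadata (method, annealing temperature, input
#' mass, unassigned read count, ...) lives in \code{colData}.
#'
#' @export
setClass("PupExperiment", contains = "SummarizedExperiment")

setValidity("PupExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integers")
  if (anyDuplicated(rownames(m))) return("feature ids must be unique")
  TRUE
})

#' ANOSIM permutation-test result
#'
#' @slot statistic the ANOSIM R statistic in [-1, 1]
#' @slot pValue permutation p-value, computed with the +1 correction
#'   \code{(1 + #(permuted R >= observed)) / (1 + permutations)}
#' @slot permutations number of label permutations used
#' @slot design "one-way" or "two-way-crossed"
#' @slot permStats the permuted R statistics (for diagnostics)
#' @export
setClass("AnosimResult", representation(
  statistic = "numeric", pValue = "numeric", permutations = "integer",
  design = "character", permStats = "numeric"
))

setValidity("AnosimResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  if (object@pValue < 1 / (object@permutations + 1) - 1e-12)
    return("pValue below the permutation lower bound")
  TRUE
})

#' Ordination result (classical MDS)
#'
#' @slot points samples x k coordinate matrix
#' @slot eig all eigenvalues of the doubly-centered matrix, non-increasing
#' @slot propExplained proportion of the positive-eigenvalue total captured
#'   by each retained axis
#' @export
setClass("OrdinationResult", representation(
  points = "matrix", eig = "numeric", propExplained = "numeric"
))

#' Least-squares regression result
#'
#' @slot coefficients named coefficient vector (intercept, linear and, for a
#'   quadratic fit, quadratic term)
#' @slot rSquared coefficient of determination in [0, 1]
#' @slot residualSd residual standard deviation
#' @slot model "linear" or "quadratic"
#' @export
setClass("RegressionResult", representation(
  coefficients = "numeric", rSquared = "numeric", residualSd = "numeric",
  model = "character"
))

setValidity("RegressionResult", function(object) {
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' Thresholds of the reference-based chimera detector
#'
#' @slot minGain minimum improvement, in absolute aligned matches, of the
#'   best two-parent split over the best single reference for a read to be
#'   called chimeric
#' @slot minSegment minimum length (bases) of each parental segment
#' @slot maxReferences cap on the number of candidate references considered
#'   per read (top references by total matches); \code{Inf} disables the cap
#' @export
setClass("ChimeraParams", representation(
  minGain = "integer", minSegment = "integer", maxReferences = "numeric"
))

setValidity("ChimeraParams", function(object) {
  if (object@minGain < 1L) return("minGain must be >= 1")
  if (object@minSegment < 1L) return("minSegment must be >= 1")
  TRUE
})

#' Read filtering parameters
#'
#' @slot minLen minimum retained read length (bases), inclusive
#' @slot maxLen maximum retained read length (bases), inclusive
#' @slot qualityThreshold Phred score below which a 3' sliding window
#'   triggers truncation
#' @slot window sliding-window width (bases)
#' @export
setClass("FilterParams", representation(
  minLen = "integer", maxLen = "integer",
  qualityThreshold = "numeric", window = "integer"
))

setValidity("FilterParams", function(object) {
  if (object@minLen <= 0L || object@minLen > object@maxLen)
    return("need 0 < minLen <= maxLen")
  if (object@qualityThreshold < 0) return("qualityThreshold must be >= 0")
  if (object@window < 1L) return("window must be >= 1")
  TRUE
})
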