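# Synthetic merged-read generator emulating DePCR vs standard (TAS)
# amplicon library preparation on a template community.

# Constant linker / locus-primer sequences of the simulated read layout.
# CS1 is the published common-sequence-1 linker; CS2 is a fixed 22-mer
# placeholder for the second linker (configurable in simulateReads).
CS1_LINKER <- "ACACTGACGACATGGTTCTACA"
CS2_LINKER <- "TACGGTAGCAGAGACTTGGTCT"
FWD_341F <- "CCTACGGGAGGCAGCAG"
IUPAC_806R <- "GGACTACHVGGGTWTCTAAT"

#' Construct an annealing model
#'
#' @param mismatchPenaltyC effective-Tm penalty per primer-template mismatch
#'   (deg C); default 3
#' @param softnessC logistic transition width (deg C); default 3, so that
#'   utilization narrows smoothly across a 40-60 degC annealing gradient
#' @param tasAnnealWeight weight of the annealing-driven component in TAS
#'   mode; default 0.05 (near-uniform utilization)
#' @return an \linkS4class{AnnealingModel}
#' @export
annealingModel <- function(mismatchPenaltyC = 3, softnessC = 3,
                           tasAnnealWeight = 0.05) {
  new("AnnealingModel", mismatchPenaltyC = mismatchPenaltyC,
      softnessC = softnessC, tasAnnealWeight = tasAnnealWeight)
}

#' Construct a simulation configuration
#'
#' @param mode "DePCR" or "TAS"
#' @param annealingTempC annealing temperature (deg C); default 50
#' @param nSamples number of samples; default 5
#' @param inputNg input gDNA per sample (ng), recycled to nSamples; default 10
#' @param readsPerNg expected reads per ng input; default 300
#' @param depthNoiseSd lognormal depth-noise sd; default 0.4
#' @param chimeraProb per-read chimera probability; \code{NULL} selects the
#'   mode default (0.06 for TAS, 0.0005 for DePCR)
#' @param errorRate per-base substitution probability; default 0.001
#' @param annealing an \linkS4class{AnnealingModel}
#' @param seed integer seed
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(mode = c("DePCR", "TAS"), annealingTempC = 50,
                             nSamples = 5L, inputNg = 10, readsPerNg = 300,
                             depthNoiseSd = 0.4, chimeraProb = NULL,
                             errorRate = 0.001, annealing = annealingModel(),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(chimeraProb))
    chimeraProb <- if (mode == "TAS") 0.06 else 0.0005
  new("SimulationConfig", mode = mode, annealingTempC = annealingTempC,
      nSamples = as.integer(nSamples),
      inputNg = rep_len(inputNg, nSamples), readsPerNg = readsPerNg,
      depthNoiseSd = depthNoiseSd, chimeraProb = chimeraProb,
      errorRate = errorRate, annealing = annealing, seed = as.integer(seed))
}

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s mode, %d samples, annealing %.0f degC\n",
    object@mode, object@nSamples, object@annealingTempC))
  cat(sprintf("  chimeraProb %.4g, errorRate %.4g, seed %d\n",
              object@chimeraProb, object@errorRate, object@seed))
})

.substitute <- function(sequence, positions) {
  chars <- strsplit(sequence, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a template community
#'
#' Builds \code{nTaxa} template taxa with lognormal relative abundances.
#' Each taxon is assigned one variant from \code{pool}; its reverse-primer
#' template site is the reverse complement of that variant with exactly
#' \code{mismatchSpec[i]} random substitutions, giving controlled
#' primer-template mismatch structure. Insert lengths are drawn so that the
#' simulated merged reads (linkers + primers + insert) fall inside the
#' 400-500 base window used downstream.
#'
#' @param pool a \linkS4class{PrimerPool} of reverse-primer variants
#' @param nTaxa number of taxa; default 40
#' @param abundanceMeanlog,abundanceSdlog lognormal abundance parameters;
#'   defaults 0 and 1
#' @param assignedVariant per-taxon variant ids; default random
#' @param mismatchSpec per-taxon substitution counts between the template
#'   site and the reverse complement of the assigned variant; default drawn
#'   from {0,1,2} with probabilities (0.5, 0.3, 0.2)
#' @param insertLengthRange inclusive range of insert lengths; default
#'   c(355, 395)
#' @param seed integer seed
#' @return a \linkS4class{Community}
#' @export
simulateCommunity <- function(pool, nTaxa = 40L, abundanceMeanlog = 0,
                              abundanceSdlog = 1, assignedVariant = NULL,
                              mismatchSpec = NULL,
                              insertLengthRange = c(355L, 395L),
                              seed = NULL) {
  if (nTaxa < 1L) stop("nTaxa must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("taxon%02d", seq_len(nTaxa))
  ab <- rlnorm(nTaxa, abundanceMeanlog, abundanceSdlog)
  ab <- setNames(ab / sum(ab), ids)
  vid <- names(variantSequences(pool))
  if (is.null(assignedVariant))
    assignedVariant <- sample(vid, nTaxa, replace = TRUE)
  if (is.null(mismatchSpec))
    mismatchSpec <- sample(0:2, nTaxa, replace = TRUE,
                           prob = c(0.5, 0.3, 0.2))
  mismatchSpec <- rep_len(as.integer(mismatchSpec), nTaxa)
  primerLen <- nchar(as.character(variantSequences(pool)[[1]]))
  if (any(mismatchSpec > primerLen))
    stop("mismatch count exceeds the primer length")
  sites <- character(nTaxa)
  for (i in seq_len(nTaxa)) {
    base <- revComp(as.character(variantSequences(pool)[[assignedVariant[i]]]))
    pos <- if (mismatchSpec[i] > 0L)
      sample(primerLen, mismatchSpec[i]) else integer(0)
    sites[i] <- .substitute(base, pos)
  }
  lens <- sample(seq(insertLengthRange[1L], insertLengthRange[2L]),
                 nTaxa, replace = TRUE)
  inserts <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  new("Community", abundance = ab,
      inserts = DNAStringSet(setNames(inserts, ids)),
      reverseSites = DNAStringSet(setNames(sites, ids)))
}

#' @export
setMethod("length", "Community", function(x) length(x@abundance))

#' @export
setMethod("show", "Community", function(object) {
  cat(sprintf("Community: %d taxa, insert lengths %d-%d\n",
              length(object@abundance),
              min(Biostrings::width(object@inserts)),
              max(Biostrings::width(object@inserts))))
})

#' Accessors for Community objects
#'
#' @param x a \linkS4class{Community}
#' @rdname Community-accessors
#' @export
taxonAbundance <- function(x) x@abundance

#' @rdname Community-accessors
#' @export
taxonInserts <- function(x) x@inserts

#' @rdname Community-accessors
#' @export
taxonReverseSites <- function(x) x@reverseSites

#' Primer-variant choice distribution for one template
#'
#' Probability with which each variant of a degenerate pool is used to copy
#' a template whose reverse-primer site is \code{site}, at annealing
#' temperature \code{tempC}. In DePCR mode the weight of variant v is
#' \code{plogis((Tm(v) - penalty * mm(v) - T) / softness)} where
#' \code{mm(v)} is the Hamming distance between the reverse complement of v
#' and the site. In TAS mode the DePCR distribution is mixed with the
#' uniform distribution: \code{(1 - w) * uniform + w * DePCR}.
#'
#' @param site template reverse-primer site (read-strand orientation), same
#'   length as the pool's variants
#' @param pool a \linkS4class{PrimerPool} with computed Tm values
#' @param tempC annealing temperature (deg C)
#' @param model an \linkS4class{AnnealingModel}
#' @param mode "DePCR" or "TAS"
#' @return named probability vector over variants (sums to 1)
#' @export
variantChoiceDistribution <- function(site, pool, tempC,
                                      model = annealingModel(),
                                      mode = c("DePCR", "TAS")) {
  mode <- match.arg(mode)
  vs <- as.character(variantSequences(pool))
  if (!length(vs)) stop("empty variant pool")
  tm <- variantTm(pool)
  if (!length(tm))
    stop("pool has no melting temperatures; expand with Tm conditions first")
  mm <- vapply(vs, function(v) countMismatches(revComp(v), site), numeric(1))
  eff <- tm - model@mismatchPenaltyC * mm
  w <- stats::plogis((eff - tempC) / model@softnessC)
  if (all(w == 0)) {
    warning("all annealing weights are zero; falling back to uniform")
    w <- rep(1, length(vs))
  }
  p <- w / sum(w)
  if (mode == "TAS") {
    a <- model@tasAnnealWeight
    p <- (1 - a) / length(p) + a * p
  }
  setNames(p, names(vs))
}

# per-taxon variant choice matrix: taxa x variants
.variantChoiceMatrix <- function(community, pool, tempC, model, mode) {
  sites <- as.character(taxonReverseSites(community))
  t(vapply(sites, variantChoiceDistribution, numeric(length(pool)),
           pool = pool, tempC = tempC, model = model, mode = mode))
}

# vectorized per-base substitution errors
.applyErrors <- function(seqs, errorRate) {
  if (errorRate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, errorRate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    seqs[i] <- .substitute(seqs[i], sample(lens[i], nerr[i]))
  }
  seqs
}

#' Simulate merged amplicon reads with ground truth
#'
#' Generates pooled, pre-merged reads for \code{nSamples} samples. Per
#' sample, depth is Poisson(inputNg * readsPerNg * lognormal(0,
#' depthNoiseSd)). Each read is
#' \code{CS1 + 341F + insert + revcomp(variant) + revcomp(CS2)}: the taxon
#' is drawn by relative abundance, the reverse-primer variant by
#' \code{\link{variantChoiceDistribution}}. With probability
#' \code{chimeraProb} the insert is a two-parent hybrid (parents drawn
#' abundance-weighted without replacement, breakpoint uniform over the
#' shorter insert's interior); the truth table records parents and the
#' breakpoint in read coordinates, and the primer-proximal parent also
#' supplies the variant choice. Substitution errors are applied to the read
#' and to the observed barcode at \code{errorRate}; qualities are constant
#' Q30.
#'
#' @param community a \linkS4class{Community}
#' @param pool a \linkS4class{PrimerPool}
#' @param barcodeSet a \linkS4class{BarcodeSet} with at least
#'   \code{nSamples} barcodes
#' @param config a \linkS4class{SimulationConfig}
#' @param cs1,cs2 linker sequences flanking the amplicon
#' @param sampleIds optional sample identifiers
#' @return a \linkS4class{SimulatedReads}
#' @export
simulateReads <- function(community, pool, barcodeSet,
                          config = simulationConfig(),
                          cs1 = CS1_LINKER, cs2 = CS2_LINKER,
                          sampleIds = NULL) {
  if (length(community) < 1L) stop("empty community")
  ns <- config@nSamples
  if (length(barcodeSet) < ns)
    stop("barcodeSet has fewer barcodes than samples")
  set.seed(config@seed)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%02d", seq_len(ns))
  bcs <- barcodes(barcodeSet)[seq_len(ns)]
  depth <- rpois(ns, config@inputNg * config@readsPerNg *
                   rlnorm(ns, 0, config@depthNoiseSd))
  if (all(depth == 0L)) stop("simulated depth is zero for every sample")
  choice <- .variantChoiceMatrix(community, pool, config@annealingTempC,
                                 config@annealing, config@mode)
  ab <- taxonAbundance(community)
  taxa <- names(ab)
  ins <- as.character(taxonInserts(community))
  sites <- as.character(taxonReverseSites(community))
  vseq <- as.character(variantSequences(pool))
  vrc <- revComp(vseq)
  names(vrc) <- names(vseq)
  cs2rc <- revComp(cs2)
  prefix <- paste0(cs1, FWD_341F)
  prefLen <- nchar(prefix)

  allSeq <- allBc <- allId <- character(0)
  truthList <- vector("list", ns)
  for (s in seq_len(ns)) {
    n <- depth[s]
    if (n == 0L) {
      truthList[[s]] <- NULL
      next
    }
    tx <- sample(taxa, n, replace = TRUE, prob = ab)
    isCh <- runif(n) < config@chimeraProb & length(taxa) >= 2L
    vch <- character(n)
    insert <- ins[tx]
    parentA <- parentB <- rep(NA_character_, n)
    breakpoint <- rep(NA_integer_, n)
    for (i in which(isCh)) {
      par <- sample(taxa, 2L, prob = ab)
      parentA[i] <- par[1L]
      parentB[i] <- par[2L]
      la <- nchar(ins[par[1L]]); lb <- nchar(ins[par[2L]])
      b <- sample(seq(2L, min(la, lb) - 1L), 1L)
      insert[i] <- paste0(substr(ins[par[1L]], 1L, b),
                          substr(ins[par[2L]], b + 1L, lb))
      breakpoint[i] <- prefLen + b
      tx[i] <- par[2L]  # primer-proximal parent supplies the variant choice
    }
    for (t in unique(tx)) {
      idx <- which(tx == t)
      vch[idx] <- sample(colnames(choice), length(idx), replace = TRUE,
                         prob = choice[t, ])
    }
    reads <- paste0(prefix, insert, vrc[vch], cs2rc)
    reads <- .applyErrors(reads, config@errorRate)
    obsBc <- .applyErrors(rep(bcs[s], n), config@errorRate)
    rid <- sprintf("%s:read%06d", sampleIds[s], seq_len(n))
    allSeq <- c(allSeq, reads)
    allBc <- c(allBc, obsBc)
    allId <- c(allId, rid)
    truthList[[s]] <- data.frame(
      readId = rid, sampleId = sampleIds[s], taxonId = tx, variantId = vch,
      isChimera = isCh, parentA = parentA, parentB = parentB,
      breakpoint = breakpoint, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truthList)
  rownames(truth) <- NULL
  readSet <- DNAStringSet(setNames(allSeq, allId))
  qual <- PhredQuality(vapply(nchar(allSeq), function(L)
    strrep("?", L), character(1)))  # "?" is Phred+33 Q30
  templates <- DNAStringSet(setNames(
    paste0(prefix, ins, sites, cs2rc), taxa))
  samples <- data.frame(
    sampleId = sampleIds, barcode = bcs, mode = config@mode,
    annealingTempC = config@annealingTempC,
    inputNg = config@inputNg, depth = depth, stringsAsFactors = FALSE)
  new("SimulatedReads", reads = readSet, qualities = qual, barcodes = allBc,
      truth = truth, samples = samples, templates = templates,
      config = config)
}

#' @export
setMethod("length", "SimulatedReads", function(x) length(x@reads))

#' @export
setMethod("show", "SimulatedReads", function(object) {
  cat(sprintf(
    "SimulatedReads: %d reads across %d samples (%s mode, %.0f degC)\n",
    length(object@reads), nrow(object@samples), object@config@mode,
    object@config@annealingTempC))
  cat(sprintf("  chimeras in truth: %d\n", sum(object@truth$isChimera)))
})

#' Accessors for SimulatedReads
#'
#' @param x a \linkS4class{SimulatedReads}
#' @rdname SimulatedReads-accessors
#' @export
simReads <- function(x) x@reads

#' @rdname SimulatedReads-accessors
#' @export
simQualities <- function(x) x@qualities

#' @rdname SimulatedReads-accessors
#' @export
simTruth <- function(x) x@truth

#' @rdname SimulatedReads-accessors
#' @export
simSamples <- function(x) x@samples

#' @rdname SimulatedReads-accessors
#' @export
simTemplates <- function(x) x@templates

#' @rdname SimulatedReads-accessors
#' @export
simBarcodes <- function(x) x@barcodes

#' Write a simulation to disk
#'
#' Writes per-sample FASTQ files (Phred+33), the truth table and sample
#' metadata as TSV, and the template amplicons as 80-column FASTA.
#'
#' @param sim a \linkS4class{SimulatedReads}
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
writeSimulatedReads <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  byS <- split(seq_along(sim@reads), sim@truth$sampleId)
  for (s in names(byS)) {
    f <- file.path(dir, paste0(s, ".fastq"))
    idx <- byS[[s]]
    writeFastqFile(sim@reads[idx], as.character(sim@qualities)[idx], f)
    files <- c(files, f)
  }
  tf <- file.path(dir, "truth.tsv")
  write.table(sim@truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- file.path(dir, "samples.tsv")
  write.table(sim@samples, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  ff <- file.path(dir, "templates.fasta")
  writeXStringSet(sim@templates, filepath = ff, width = 80L)
  invisible(c(files, tf, mf, ff))
}
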