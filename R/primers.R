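# Degenerate primer expansion, nearest-neighbor melting temperatures,
# mismatch counting and barcode design.

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct melting-temperature conditions
#'
#' @param oligoConcM total oligo strand concentration (M); default 250 nM
#' @param mgConcM Mg2+ concentration (M); default 2 mM
#' @param dntpConcM dNTP concentration (M); default 0.2 mM
#' @param monovalentConcM monovalent cation concentration (M); default 50 mM
#' @return a \linkS4class{TmConditions} object
#' @examples
#' tmConditions()
#' @export
tmConditions <- function(oligoConcM = 250e-9, mgConcM = 2e-3,
                         dntpConcM = 0.2e-3, monovalentConcM = 50e-3) {
  new("TmConditions", oligoConcM = oligoConcM, mgConcM = mgConcM,
      dntpConcM = dntpConcM, monovalentConcM = monovalentConcM)
}

#' @describeIn tmConditions display method
#' @param object a TmConditions object
#' @export
setMethod("show", "TmConditions", function(object) {
  cat(sprintf(
    "TmConditions: oligo %.3g M, Mg2+ %.3g M, dNTP %.3g M, monovalent %.3g M\n",
    object@oligoConcM, object@mgConcM, object@dntpConcM,
    object@monovalentConcM))
})

.checkIupac <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_BASES))
  if (nchar(sequence) == 0L)
    stop("primer sequence is empty")
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  chars
}

#' Degeneracy of an IUPAC primer
#'
#' Product of the per-position IUPAC code sizes.
#'
#' @param sequence IUPAC nucleotide string
#' @return integer degeneracy (>= 1)
#' @examples
#' degeneracy("GGACTACHVGGGTWTCTAAT")  # 18
#' @export
degeneracy <- function(sequence) {
  chars <- .checkIupac(sequence)
  prod(vapply(IUPAC_BASES[chars], length, integer(1)))
}

#' Expand a degenerate primer into its non-degenerate variants
#'
#' Enumerates every non-degenerate sequence compatible with an IUPAC primer.
#' The order is canonical: the leftmost degenerate position varies slowest
#' and bases at each degenerate position are taken in A < C < G < T order.
#' Variant ids "RPV1", "RPV2", ... are assigned in that order, so the
#' numbering is reproducible from the primer sequence alone.
#'
#' @param sequence IUPAC nucleotide string, 5'->3'
#' @param name primer label (default "primer")
#' @param conditions \linkS4class{TmConditions} under which variant melting
#'   temperatures are predicted; \code{NULL} skips Tm computation
#' @param variantPrefix prefix for variant ids (default "RPV")
#' @return a \linkS4class{PrimerPool}
#' @examples
#' pool <- expandDegenerate("GGACTACHVGGGTWTCTAAT", name = "806R")
#' length(variantSequences(pool))  # 18
#' @export
expandDegenerate <- function(sequence, name = "primer",
                             conditions = tmConditions(),
                             variantPrefix = "RPV") {
  chars <- .checkIupac(sequence)
  sets <- IUPAC_BASES[chars]
  # expand.grid varies the first factor fastest; feed positions reversed so
  # the leftmost degenerate position varies slowest
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  seqs <- unique(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste,
                       collapse = ""))
  ids <- paste0(variantPrefix, seq_along(seqs))
  variants <- DNAStringSet(setNames(seqs, ids))
  tm <- numeric(0)
  if (!is.null(conditions))
    tm <- setNames(vapply(seqs, meltingTemperature, numeric(1),
                          conditions = conditions), ids)
  new("PrimerPool", primerName = name, iupac = toupper(sequence),
      variants = variants, tm = tm,
      conditions = if (is.null(conditions)) tmConditions() else conditions)
}

#' @rdname PrimerPool-accessors
#' @aliases variantSequences
#' @param pool a \linkS4class{PrimerPool}
#' @export
variantSequences <- function(pool) pool@variants

#' Accessors for PrimerPool objects
#'
#' \code{variantSequences} returns the named \code{DNAStringSet} of
#' non-degenerate variants; \code{variantTm} the named vector of predicted
#' melting temperatures; \code{primerIupac} the parent IUPAC sequence.
#'
#' @name PrimerPool-accessors
#' @rdname PrimerPool-accessors
#' @aliases variantTm
#' @export
variantTm <- function(pool) pool@tm

#' @rdname PrimerPool-accessors
#' @aliases primerIupac
#' @export
primerIupac <- function(pool) pool@iupac

#' @export
setMethod("length", "PrimerPool", function(x) length(x@variants))

#' @export
setMethod("show", "PrimerPool", function(object) {
  cat(sprintf("PrimerPool '%s': %s (%d-fold degenerate)\n",
              object@primerName, object@iupac, length(object@variants)))
  if (length(object@tm))
    cat(sprintf("  predicted Tm: %.1f-%.1f degC\n",
                min(object@tm), max(object@tm)))
})

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keyed by the 5'->3' dinucleotide of one
# strand (the complementary-strand entries are the same duplex).
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# duplex initiation terms for terminal base pairs
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
GAS_CONSTANT <- 1.9872  # cal/(mol K)

#' Nearest-neighbor enthalpy/entropy sums
#'
#' Total duplex formation dH (kcal/mol) and dS (cal/mol/K) for a
#' non-degenerate sequence under the unified nearest-neighbor parameter set,
#' including both terminal initiation terms.
#'
#' @param sequence non-degenerate nucleotide string
#' @return named numeric vector \code{c(dH = , dS = )}
#' @export
nnThermodynamics <- function(sequence) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("sequence contains degenerate or invalid codes; expand first")
  steps <- paste0(chars[-length(chars)], chars[-1L])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in chars[c(1L, length(chars))]) {
    init <- if (term %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  c(dH = dH, dS = dS)
}

#' Predict an oligonucleotide melting temperature
#'
#' Nearest-neighbor prediction \code{Tm(K) = dH / (dS + R ln(CT / f))} with
#' the unified parameter set and duplex initiation terms, followed by the
#' Owczarzy divalent/monovalent salt correction computed at free
#' \code{Mg2+ = max(0, Mg - dNTP)}. By default the primer strand is assumed
#' to be in large excess over its template (\code{excessStrand = TRUE}, so
#' \code{f = 1}); with \code{excessStrand = FALSE} the equimolar
#' non-self-complementary factor \code{f = 4} is used instead.
#'
#' @param sequence non-degenerate nucleotide string, length >= 8
#' @param conditions a \linkS4class{TmConditions} object
#' @param excessStrand logical; assume the oligo strand is in excess
#' @param saltCorrection "auto" applies the divalent (or, when free Mg2+ is
#'   negligible relative to monovalent ions, the monovalent) correction;
#'   "none" returns the uncorrected 1 M Na+ value
#' @return predicted melting temperature in deg C
#' @examples
#' meltingTemperature("GGACTACAAGGGTATCTAAT")
#' @export
meltingTemperature <- function(sequence, conditions = tmConditions(),
                               excessStrand = TRUE,
                               saltCorrection = c("auto", "none")) {
  saltCorrection <- match.arg(saltCorrection)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8L)
    stop("sequence shorter than 8 bases; nearest-neighbor prediction refused")
  th <- nnThermodynamics(sequence)
  ctFactor <- if (excessStrand) 1 else 4
  ct <- conditions@oligoConcM / ctFactor
  tm1 <- th[["dH"]] * 1000 / (th[["dS"]] + GAS_CONSTANT * log(ct))
  if (saltCorrection == "none")
    return(tm1 - 273.15)
  chars <- strsplit(sequence, "")[[1]]
  fGC <- mean(chars %in% c("G", "C"))
  nbp <- length(chars)
  mono <- conditions@monovalentConcM
  mgFree <- max(0, conditions@mgConcM - conditions@dntpConcM)

  monovalentInv <- function() {
    # Owczarzy (2004) monovalent correction
    1 / tm1 + (4.29 * fGC - 3.95) * 1e-5 * log(mono) +
      9.40e-6 * log(mono)^2
  }
  if (mgFree <= 0) {
    if (mono <= 0) stop("no cations: supply monovalent or Mg2+ concentration")
    return(1 / monovalentInv() - 273.15)
  }
  # Owczarzy (2008) divalent correction, with competition regimes set by
  # sqrt([Mg2+]) / [monovalent]
  a <- 3.92e-5; b <- 9.11e-6; cc <- 6.26e-5; d <- 1.42e-5
  e <- -4.82e-4; f <- 5.25e-4; g <- 8.31e-5
  if (mono > 0) {
    ratio <- sqrt(mgFree) / mono
    if (ratio < 0.22)
      return(1 / monovalentInv() - 273.15)
    if (ratio < 6) {
      lnM <- log(mono)
      a <- a * (0.843 - 0.352 * sqrt(mono) * lnM)
      d <- d * (1.279 - 4.03e-3 * lnM - 8.03e-3 * lnM^2)
      g <- g * (0.486 - 0.258 * lnM + 5.25e-3 * lnM^3)
    }
  }
  lnMg <- log(mgFree)
  inv <- 1 / tm1 + a - b * lnMg + fGC * (cc + d * lnMg) +
    (e + f * lnMg + g * lnMg^2) / (2 * (nbp - 1))
  1 / inv - 273.15
}

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around
#' \code{Biostrings::reverseComplement}.
#'
#' @param x character vector of nucleotide sequences (IUPAC allowed)
#' @return character vector of reverse complements
#' @examples
#' revComp("ACGT")
#' @export
revComp <- function(x) {
  out <- as.character(reverseComplement(DNAStringSet(x)))
  unname(out)
}

#' Count mismatches between two equal-length sequences
#'
#' Hamming distance. With \code{iupac = TRUE} two positions match whenever
#' their IUPAC base sets intersect (so \code{N} matches everything).
#'
#' @param a,b nucleotide strings of equal length
#' @param iupac treat IUPAC codes as compatible base sets
#' @return integer number of mismatching positions
#' @examples
#' countMismatches("ACGT", "ACGA")  # 1
#' @export
countMismatches <- function(a, b, iupac = FALSE) {
  ca <- .checkIupac(a)
  cb <- .checkIupac(b)
  if (length(ca) != length(cb))
    stop("sequences have unequal lengths (", length(ca), " vs ",
         length(cb), ")")
  if (!iupac)
    return(sum(ca != cb))
  hit <- mapply(function(x, y) {
    length(intersect(IUPAC_BASES[[x]], IUPAC_BASES[[y]])) > 0L
  }, ca, cb)
  sum(!hit)
}

# minimum pairwise Hamming distance over a character vector of equal-length
# strings; exhaustive
minPairwiseHamming <- function(x) {
  m <- do.call(rbind, strsplit(x, ""))
  n <- nrow(m)
  dmin <- nchar(x[1L])
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      dmin <- min(dmin, sum(m[i, ] != m[j, ]))
  dmin
}

.maxHomopolymerRun <- function(s) {
  r <- rle(strsplit(s, "")[[1]])
  max(r$lengths)
}

#' Design a Hamming-separated barcode set
#'
#' Greedy rejection sampling: random candidates are accepted when they keep
#' the minimum pairwise Hamming distance at or above \code{minDistance}, are
#' not the reverse complement of an accepted barcode, and contain no
#' homopolymer run longer than \code{maxHomopolymer} (a practical sequencing
#' constraint; disable with \code{maxHomopolymer = Inf}). Fails with an
#' explicit error after a bounded number of attempts when the request is
#' infeasible or too tight.
#'
#' @param n number of barcodes
#' @param width barcode length in bases (default 10)
#' @param minDistance minimum pairwise Hamming distance (default 3)
#' @param seed integer seed for reproducibility
#' @param maxHomopolymer longest allowed single-base run
#' @param maxAttempts total candidate draws before giving up
#' @return a \linkS4class{BarcodeSet}
#' @examples
#' bc <- designBarcodes(8, width = 10, minDistance = 3, seed = 1)
#' @export
designBarcodes <- function(n, width = 10L, minDistance = 3L, seed = NULL,
                           maxHomopolymer = 3L, maxAttempts = 2000L * n) {
  if (n < 1L) stop("n must be >= 1")
  if (minDistance > width)
    stop("minDistance cannot exceed the barcode width")
  if (4^width < n)
    stop(sprintf("infeasible: only %d sequences of length %d exist",
                 4^width, width))
  # Singleton-bound sanity check for the Hamming sphere packing
  if (minDistance >= 3L && width <= 12L) {
    sphere <- 1 + 3 * width
    if (n > 4^width / sphere * 4)  # loose screen; true bound attempt-limited
      stop("infeasible: request exceeds the approximate packing capacity")
  }
  if (!is.null(seed)) set.seed(seed)
  accepted <- character(0)
  acceptedMat <- NULL
  attempts <- 0L
  while (length(accepted) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(
        "barcode design failed: %d/%d accepted after %d attempts",
        length(accepted), n, maxAttempts))
    cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                  collapse = "")
    if (is.finite(maxHomopolymer) && .maxHomopolymerRun(cand) > maxHomopolymer)
      next
    cv <- strsplit(cand, "")[[1]]
    if (!is.null(acceptedMat)) {
      dists <- rowSums(acceptedMat != matrix(cv, nrow(acceptedMat), width,
                                             byrow = TRUE))
      if (min(dists) < minDistance) next
      if (revComp(cand) %in% accepted || cand %in% vapply(
            accepted, revComp, character(1))) next
    }
    accepted <- c(accepted, cand)
    acceptedMat <- rbind(acceptedMat, cv)
  }
  new("BarcodeSet", barcodes = accepted, width = as.integer(width),
      minDistance = as.integer(minDistance))
}

#' @export
setMethod("length", "BarcodeSet", function(x) length(x@barcodes))

#' @rdname designBarcodes
#' @aliases barcodes
#' @param x a \linkS4class{BarcodeSet}
#' @export
barcodes <- function(x) x@barcodes

#' @export
setMethod("show", "BarcodeSet", function(object) {
  cat(sprintf("BarcodeSet: %d barcodes of width %d, min Hamming distance %d\n",
              length(object@barcodes), object@width, object@minDistance))
})

#' Write and read primer pools
#'
#' \code{writeVariantsFasta} writes the expanded variants as FASTA with
#' variant-id headers; \code{writeVariantsTsv} writes a table of
#' (variantId, sequence, tmCelsius); \code{readPrimerFasta} reads (possibly
#' IUPAC-degenerate) primers from FASTA.
#'
#' @param pool a \linkS4class{PrimerPool}
#' @param path output/input file path
#' @return \code{readPrimerFasta} returns a named character vector
#' @rdname primer-io
#' @export
writeVariantsFasta <- function(pool, path) {
  writeXStringSet(pool@variants, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname primer-io
#' @export
writeVariantsTsv <- function(pool, path) {
  df <- data.frame(variantId = names(pool@variants),
                   sequence = as.character(pool@variants),
                   tmCelsius = if (length(pool@tm)) unname(pool@tm) else NA_real_)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname primer-io
#' @export
readPrimerFasta <- function(path) {
  x <- readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
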