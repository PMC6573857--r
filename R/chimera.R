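# Reference-based two-parent chimera detection. This detector is
# deliberately not a UCHIME/USEARCH reimplementation: it assumes a known
# reference set (as available for simulated data), has no de novo mode and
# no abundance heuristic, and scores splits in absolute aligned matches so
# results remain integer and oracle-checkable. Rates it reports should not
# be compared numerically with USEARCH outputs on real data.

#' Construct chimera-detector thresholds
#'
#' @param minGain minimum match-count improvement of the best two-parent
#'   split over the best single reference; default 4
#' @param minSegment minimum parental segment length (bases); default 50
#' @param maxReferences per-read cap on candidate references (top by total
#'   matches); default Inf (no cap)
#' @return a \linkS4class{ChimeraParams}
#' @export
chimeraParams <- function(minGain = 4L, minSegment = 50L,
                          maxReferences = Inf) {
  new("ChimeraParams", minGain = as.integer(minGain),
      minSegment = as.integer(minSegment),
      maxReferences = as.numeric(maxReferences))
}

#' Per-position match profile of a read against a reference
#'
#' Globally aligns query and reference with free end gaps (match +1,
#' mismatch and gap -1) and returns a 0/1 indicator over query positions
#' marking which query bases are aligned to an identical reference base.
#'
#' @param query,reference nucleotide strings (or \code{DNAString})
#' @return integer vector of 0/1, one entry per query position
#' @export
matchProfile <- function(query, reference) {
  query <- as.character(query)
  reference <- as.character(reference)
  if (!nchar(query) || !nchar(reference))
    stop("query and reference must be non-empty")
  sm <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = TRUE)
  aln <- pairwiseAlignment(query, reference, type = "overlap",
                           substitutionMatrix = sm,
                           gapOpening = 0, gapExtension = 1)
  pat <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  prof <- integer(nchar(query))
  qpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  for (i in seq_along(pat)) {
    if (pat[i] != "-") {
      qpos <- qpos + 1L
      if (sub[i] != "-" && pat[i] == sub[i]) prof[qpos] <- 1L
    }
  }
  prof
}

#' Detect two-parent chimeras against a reference set
#'
#' For each read, computes cumulative match profiles against every
#' reference in shared-prefix (left-aligned) and shared-suffix
#' (right-aligned) coordinates, then maximizes over breakpoints the best
#' prefix score plus the best suffix score taken from two distinct
#' references, requiring both segments to span at least
#' \code{minSegment} bases. A read is called chimeric when this best split
#' beats the best single reference by at least \code{minGain} matches.
#' Reads shorter than \code{2 * minSegment} are never called and are
#' flagged in the \code{tooShort} column. References are processed in
#' lexicographic id order, so score ties resolve to the lexicographically
#' smallest parent pair; breakpoint ties resolve to the smallest position.
#'
#' @param reads \code{DNAStringSet} (or character vector) of query reads
#' @param references named \code{DNAStringSet} (or character vector) of
#'   template sequences; at least 2
#' @param params a \linkS4class{ChimeraParams}
#' @return data.frame with one row per read: readId, isChimera, parentA,
#'   parentB, breakpoint, bestSingleMatches, bestChimericMatches, tooShort
#' @export
detectChimeras <- function(reads, references, params = chimeraParams()) {
  qs <- setNames(as.character(reads), names(reads))
  refs <- setNames(as.character(references), names(references))
  if (length(refs) < 2L) stop("need at least 2 references")
  if (is.null(names(refs)))
    names(refs) <- paste0("ref", seq_along(refs))
  refs <- refs[order(names(refs))]
  if (is.finite(params@maxReferences) &&
      length(refs) > params@maxReferences) {
    # keep globally most-matching references (cheap screen on shared prefix)
    tot <- vapply(refs, function(r) {
      sc <- vapply(qs[seq_len(min(200L, length(qs)))], function(q) {
        n <- min(nchar(q), nchar(r))
        sum(strsplit(substr(q, 1, n), "")[[1]] ==
              strsplit(substr(r, 1, n), "")[[1]])
      }, numeric(1))
      sum(sc)
    }, numeric(1))
    refs <- refs[order(-tot)[seq_len(params@maxReferences)]]
    refs <- refs[order(names(refs))]
  }
  res <- chimeraScanC(qs, unname(refs), params@minSegment, params@minGain)
  ids <- if (!is.null(names(qs))) names(qs) else paste0("read", seq_along(qs))
  data.frame(
    readId = ids,
    isChimera = res$isChimera,
    parentA = ifelse(is.na(res$parentA), NA_character_,
                     names(refs)[res$parentA]),
    parentB = ifelse(is.na(res$parentB), NA_character_,
                     names(refs)[res$parentB]),
    breakpoint = res$breakpoint,
    bestSingleMatches = res$bestSingle,
    bestChimericMatches = res$bestChimeric,
    closestReference = names(refs)[res$singleRef],
    tooShort = res$tooShort,
    stringsAsFactors = FALSE)
}

#' Chimera rate with a Wilson confidence interval
#'
#' @param verdicts data.frame from \code{\link{detectChimeras}} (or any
#'   data.frame with a logical \code{isChimera} column)
#' @param level confidence level; default 0.95
#' @return list with \code{rate}, \code{flagged}, \code{n}, \code{ciLower},
#'   \code{ciUpper}
#' @export
chimeraRate <- function(verdicts, level = 0.95) {
  if (!nrow(verdicts)) stop("no verdicts")
  x <- sum(verdicts$isChimera)
  n <- nrow(verdicts)
  ci <- if (x == 0L && n > 0L) {
    c(0, prop.test(0, n, conf.level = level, correct = FALSE)$conf.int[2L])
  } else {
    as.numeric(prop.test(x, n, conf.level = level,
                         correct = FALSE)$conf.int)
  }
  list(rate = x / n, flagged = x, n = n, ciLower = ci[1L], ciUpper = ci[2L])
}
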