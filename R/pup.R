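# Primer utilization profiles: quality trimming, length filtering, exact
# variant counting, the PupExperiment container and rarefaction.

#' Construct read filtering parameters
#'
#' @param minLen,maxLen inclusive retained length bounds; defaults 400/500
#' @param qualityThreshold Phred threshold for the 3' sliding-window trim;
#'   default 20
#' @param window sliding-window width; default 4
#' @return a \linkS4class{FilterParams}
#' @export
filterParams <- function(minLen = 400L, maxLen = 500L,
                         qualityThreshold = 20, window = 4L) {
  new("FilterParams", minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      qualityThreshold = qualityThreshold, window = as.integer(window))
}

# integer Phred scores from a Phred+33 quality string
.phredInts <- function(qual) utf8ToInt(qual) - 33L

# 3' sliding-window truncation point for one quality vector: the read is cut
# just before the first window (scanning 5'->3') whose mean quality drops
# below the threshold; returns the retained length (0 = discard)
.trimPoint <- function(q, threshold, window) {
  n <- length(q)
  if (n == 0L) return(0L)
  w <- min(window, n)
  means <- as.numeric(stats::filter(q, rep(1 / w, w), sides = 1))
  means <- means[w:n]  # means[i] covers positions (i):(i+w-1), i = 1..n-w+1
  bad <- which(means < threshold)
  if (!length(bad)) return(n)
  bad[1L] - 1L
}

#' Sliding-window quality trimming
#'
#' Truncates each read at the first window (moving 5' to 3') whose mean
#' Phred quality falls below the threshold; reads that become empty are
#' discarded. Records whose sequence and quality lengths disagree are
#' skipped and counted as malformed.
#'
#' @param reads \code{DNAStringSet} of reads
#' @param qualities character vector of Phred+33 quality strings (or a
#'   \code{PhredQuality}), parallel to \code{reads}
#' @param params a \linkS4class{FilterParams}
#' @return list with \code{reads} (trimmed \code{DNAStringSet}),
#'   \code{qualities}, and counts \code{discarded} and \code{malformed}
#' @export
qualityTrim <- function(reads, qualities, params = filterParams()) {
  qualities <- as.character(qualities)
  if (length(qualities) != length(reads))
    stop("qualities must be parallel to reads")
  lens <- Biostrings::width(reads)
  malformed <- which(nchar(qualities) != lens)
  if (length(malformed)) {
    message(length(malformed), " malformed record(s) skipped")
    keep0 <- setdiff(seq_along(reads), malformed)
    reads <- reads[keep0]
    qualities <- qualities[keep0]
    lens <- lens[keep0]
  }
  # fast path: reads whose minimum quality clears the threshold are untouched
  qInts <- lapply(qualities, .phredInts)
  minQ <- vapply(qInts, function(q) if (length(q)) min(q) else 0L, integer(1))
  cut <- lens
  recheck <- which(minQ < params@qualityThreshold)
  for (i in recheck)
    cut[i] <- .trimPoint(qInts[[i]], params@qualityThreshold, params@window)
  keep <- which(cut > 0L)
  out <- Biostrings::subseq(reads[keep], start = 1L, end = cut[keep])
  list(reads = out,
       qualities = substr(qualities[keep], 1L, cut[keep]),
       discarded = sum(cut == 0L),
       malformed = length(malformed))
}

#' Length filtering of trimmed reads
#'
#' Retains reads whose length lies inside the inclusive
#' \code{[minLen, maxLen]} window.
#'
#' @param reads \code{DNAStringSet}
#' @param params a \linkS4class{FilterParams}
#' @return list with \code{reads} and counts \code{kept}, \code{tooShort},
#'   \code{tooLong}
#' @export
lengthFilter <- function(reads, params = filterParams()) {
  lens <- Biostrings::width(reads)
  keep <- lens >= params@minLen & lens <= params@maxLen
  list(reads = reads[keep], kept = sum(keep),
       tooShort = sum(lens < params@minLen),
       tooLong = sum(lens > params@maxLen))
}

#' Count exact primer-variant occurrences in reads
#'
#' Searches every read for an exact substring match to any variant sequence
#' of the pool or its reverse complement. Each read increments exactly one
#' variant: when several positions match (e.g. a spurious internal hit), the
#' match closest to the read's 3' end wins, since that is where the reverse
#' primer sits in merged orientation. Reads with no exact match are counted
#' as unassigned.
#'
#' @param reads \code{DNAStringSet} of trimmed, filtered reads
#' @param pool a \linkS4class{PrimerPool}
#' @return list with \code{counts} (named integer vector over variant ids)
#'   and \code{unassigned}
#' @export
extractPup <- function(reads, pool) {
  vs <- as.character(variantSequences(pool))
  if (!length(vs)) stop("empty variant list")
  n <- length(reads)
  ids <- names(vs)
  counts <- setNames(integer(length(vs)), ids)
  if (n == 0L)
    return(list(counts = counts, unassigned = 0L))
  bestEnd <- integer(n)     # rightmost match end seen so far, 0 = none
  bestVar <- rep(NA_character_, n)
  for (v in ids) {
    for (pat in c(vs[[v]], revComp(vs[[v]]))) {
      m <- Biostrings::vmatchPattern(pat, reads)
      ei <- Biostrings::endIndex(m)
      nh <- lengths(ei)
      if (!any(nh > 0L)) next
      endsAll <- unlist(ei, use.names = FALSE)
      ridx <- rep.int(seq_along(reads), nh)
      endsBy <- vapply(split(endsAll, ridx), max, integer(1))
      hits <- as.integer(names(endsBy))
      ends <- unname(endsBy)
      better <- ends > bestEnd[hits]
      upd <- hits[better]
      bestEnd[upd] <- ends[better]
      bestVar[upd] <- v
    }
  }
  tab <- table(factor(bestVar, levels = ids))
  counts[ids] <- as.integer(tab)
  list(counts = counts, unassigned = sum(is.na(bestVar)))
}

#' Construct a PupExperiment
#'
#' @param counts features x samples matrix of non-negative integers
#' @param sampleData data.frame of per-sample metadata (rownames or a
#'   \code{sampleId} column matching \code{colnames(counts)})
#' @return a \linkS4class{PupExperiment}
#' @export
PupExperiment <- function(counts, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(counts))
  else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if ("sampleId" %in% colnames(sampleData))
      rownames(sampleData) <- sampleData$sampleId
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = sampleData)
  new("PupExperiment", se)
}

#' @rdname PupExperiment
#' @aliases pupCounts
#' @param x a \linkS4class{PupExperiment}
#' @export
pupCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname PupExperiment
#' @aliases sampleData
#' @export
sampleData <- function(x) SummarizedExperiment::colData(x)

#' Build a primer-utilization experiment from per-sample reads
#'
#' Runs \code{\link{extractPup}} on each sample's reads and assembles the
#' counts into a \linkS4class{PupExperiment}; the per-sample unassigned
#' counts are stored in \code{colData(x)$unassigned}.
#'
#' @param readsBySample named list of \code{DNAStringSet}, one per sample
#' @param pool a \linkS4class{PrimerPool}
#' @param sampleData optional data.frame of per-sample metadata
#' @return a \linkS4class{PupExperiment}
#' @export
buildPupExperiment <- function(readsBySample, pool, sampleData = NULL) {
  res <- lapply(readsBySample, extractPup, pool = pool)
  counts <- vapply(res, `[[`, integer(length(pool)), "counts")
  counts <- matrix(counts, nrow = length(pool),
                   dimnames = list(names(variantSequences(pool)),
                                   names(readsBySample)))
  un <- vapply(res, `[[`, integer(1), "unassigned")
  sd <- if (is.null(sampleData))
    data.frame(unassigned = un, row.names = names(readsBySample))
  else
    cbind(sampleData, unassigned = un)
  PupExperiment(counts, sd)
}

#' @export
setMethod("show", "PupExperiment", function(object) {
  m <- pupCounts(object)
  cat(sprintf("PupExperiment: %d features x %d samples\n",
              nrow(m), ncol(m)))
  cat(sprintf("  total counts per sample: %s\n",
              paste(utils::head(colSums(m), 6L), collapse = ", ")))
})

#' Rarefy counts to a fixed depth
#'
#' Subsamples counts without replacement so that every retained sample has
#' exactly \code{depth} total counts; samples with fewer than \code{depth}
#' counts are dropped with a message. With a numeric vector, a single
#' sample's counts are rarefied and returned as a vector.
#'
#' @param x a \linkS4class{PupExperiment} or a non-negative count vector
#' @param depth target depth (>= 1); default 1800
#' @param seed integer seed; fixed seed gives identical output
#' @return object of the same kind as \code{x}
#' @export
setGeneric("rarefyCounts", function(x, depth = 1800L, seed = NULL)
  standardGeneric("rarefyCounts"))

.rarefyVector <- function(counts, depth) {
  total <- sum(counts)
  if (total < depth) stop("sample total below the rarefaction depth")
  if (total == depth) return(counts)
  drawn <- sample(rep.int(seq_along(counts), counts), depth)
  out <- tabulate(drawn, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' @rdname rarefyCounts
#' @export
setMethod("rarefyCounts", "numeric", function(x, depth = 1800L, seed = NULL) {
  if (depth <= 0L) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  .rarefyVector(x, depth)
})

#' @rdname rarefyCounts
#' @export
setMethod("rarefyCounts", "PupExperiment",
          function(x, depth = 1800L, seed = NULL) {
  if (depth <= 0L) stop("depth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- pupCounts(x)
  totals <- colSums(m)
  drop <- which(totals < depth)
  if (length(drop)) {
    message("dropping ", length(drop), " sample(s) below depth ", depth,
            ": ", paste(colnames(m)[drop], collapse = ", "))
    x <- x[, -drop]
    m <- pupCounts(x)
  }
  if (ncol(m) == 0L) stop("no sample reaches the rarefaction depth")
  out <- apply(m, 2L, .rarefyVector, depth = depth)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(as.integer(out), nrow(m),
                                  dimnames = dimnames(m))),
    colData = SummarizedExperiment::colData(x))
  new("PupExperiment", se)
})
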