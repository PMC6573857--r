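# FASTQ/FASTA/TSV readers and writers, and barcode demultiplexing.
# FASTQ records are validated line-by-line (so parse errors carry line
# numbers) and held in Biostrings containers.

#' Read a FASTQ file
#'
#' Reads Phred+33 FASTQ. Malformed records (truncated record, missing '@'
#' or '+' marker, sequence/quality length mismatch) raise an error naming
#' the offending line.
#'
#' @param path FASTQ file path
#' @return list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{qualities} (character vector of quality strings)
#' @export
readFastqFile <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (near line %d)",
                 n, n))
  idx <- seq(1L, n, by = 4L)
  for (i in idx) {
    if (!startsWith(lines[i], "@"))
      stop(sprintf("malformed FASTQ header at line %d", i))
    if (!startsWith(lines[i + 2L], "+"))
      stop(sprintf("malformed FASTQ separator at line %d", i + 2L))
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop(sprintf("sequence/quality length mismatch at line %d", i + 3L))
  }
  ids <- sub("^@", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  reads <- DNAStringSet(setNames(lines[idx + 1L], ids))
  list(reads = reads, qualities = lines[idx + 3L])
}

#' Write a FASTQ file
#'
#' Phred+33, one four-line record per read.
#'
#' @param reads named \code{DNAStringSet} (names become record ids)
#' @param qualities character vector of quality strings (or a
#'   \code{PhredQuality}), parallel to \code{reads}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeFastqFile <- function(reads, qualities, path) {
  qualities <- as.character(qualities)
  if (length(qualities) != length(reads))
    stop("qualities must be parallel to reads")
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  out <- character(4L * length(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", ids)
  out[seq(2L, length(out), 4L)] <- as.character(reads)
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- qualities
  writeLines(out, path)
  invisible(path)
}

#' Write sequences as 80-column FASTA
#'
#' @param seqs named \code{DNAStringSet} or character vector
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeFastaFile <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read and write count tables
#'
#' TSV layout: header row of feature ids, first column \code{sampleId},
#' one row per sample. \code{writeCountTable} accepts a
#' \linkS4class{PupExperiment} (sample metadata is written alongside as
#' additional leading columns only via \code{writeSampleData}; the count
#' table itself stays purely numeric).
#'
#' @param x a \linkS4class{PupExperiment} or samples x features matrix
#' @param path file path
#' @rdname count-table-io
#' @return \code{readCountTable} returns a samples x features integer
#'   matrix with sample ids as rownames
#' @export
writeCountTable <- function(x, path) {
  m <- if (is(x, "PupExperiment")) t(pupCounts(x)) else as.matrix(x)
  df <- data.frame(sampleId = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname count-table-io
#' @export
readCountTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "sampleId")
    stop("count table must have 'sampleId' as its first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sampleId
  m
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique sample whose barcode lies within
#' \code{maxMismatch} of the read's observed barcode; reads matching no
#' barcode, or more than one, are unassigned. Requires
#' \code{maxMismatch < minDistance / 2} so assignments are unambiguous by
#' construction.
#'
#' @param observedBarcodes character vector of observed per-read barcodes
#' @param barcodeMap named character vector, sample id -> barcode
#' @param maxMismatch maximum Hamming distance tolerated; default 1
#' @return character vector of sample ids (NA = unassigned), parallel to
#'   \code{observedBarcodes}
#' @export
demultiplexReads <- function(observedBarcodes, barcodeMap, maxMismatch = 1L) {
  bl <- unique(nchar(barcodeMap))
  if (length(bl) != 1L) stop("barcodes must share one length")
  if (length(barcodeMap) > 1L) {
    dmin <- minPairwiseHamming(unname(barcodeMap))
    if (maxMismatch >= dmin / 2)
      stop(sprintf(
        "maxMismatch %d is not below half the minimum barcode distance %d",
        maxMismatch, dmin))
  }
  if (any(nchar(observedBarcodes) != bl))
    stop("observed barcodes must match the barcode length")
  bcMat <- do.call(rbind, strsplit(unname(barcodeMap), ""))
  obs <- strsplit(observedBarcodes, "")
  assign <- vapply(obs, function(ov) {
    d <- rowSums(bcMat != matrix(ov, nrow(bcMat), bl, byrow = TRUE))
    hit <- which(d <= maxMismatch)
    if (length(hit) == 1L) names(barcodeMap)[hit] else NA_character_
  }, character(1))
  assign
}

#' Split simulated reads by demultiplexed sample
#'
#' Runs \code{\link{demultiplexReads}} on a \linkS4class{SimulatedReads}
#' pool and returns per-sample \code{DNAStringSet}s plus the unassigned
#' count; assigned + unassigned equals the input read count.
#'
#' @param sim a \linkS4class{SimulatedReads}
#' @param maxMismatch maximum barcode Hamming distance; default 1
#' @return list with \code{readsBySample} (named list of
#'   \code{DNAStringSet}), \code{qualitiesBySample},
#'   \code{assignments} and \code{unassigned}
#' @export
demultiplexSimulation <- function(sim, maxMismatch = 1L) {
  bm <- setNames(sim@samples$barcode, sim@samples$sampleId)
  assign <- demultiplexReads(sim@barcodes, bm, maxMismatch)
  keep <- !is.na(assign)
  quals <- as.character(sim@qualities)
  readsBySample <- lapply(split(which(keep), assign[keep]),
                          function(i) sim@reads[i])
  qualsBySample <- lapply(split(which(keep), assign[keep]),
                          function(i) quals[i])
  list(readsBySample = readsBySample, qualitiesBySample = qualsBySample,
       assignments = assign, unassigned = sum(!keep))
}
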