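# Alpha diversity (Shannon, richness, Pielou evenness) and Bray-Curtis
# dissimilarity. The index computations are delegated to vegan; these
# wrappers add the container methods and input checking.

.checkCountVector <- function(x) {
  if (any(x < 0)) stop("negative counts")
  if (sum(x) <= 0) stop("all-zero count vector")
  x
}

#' Shannon diversity index
#'
#' \code{H = -sum(p_i * log(p_i))} over positive entries, natural log by
#' default.
#'
#' @param x non-negative count (or relative abundance) vector, or a
#'   \linkS4class{PupExperiment} (one value per sample)
#' @param base logarithm base; default \code{exp(1)}
#' @return numeric value, or a named vector for a \code{PupExperiment}
#' @examples
#' shannonIndex(rep(1, 18))  # log(18) = 2.890
#' @export
setGeneric("shannonIndex", function(x, base = exp(1))
  standardGeneric("shannonIndex"))

#' @rdname shannonIndex
#' @export
setMethod("shannonIndex", "numeric", function(x, base = exp(1)) {
  .checkCountVector(x)
  unname(vegan::diversity(x, index = "shannon", base = base))
})

#' @rdname shannonIndex
#' @export
setMethod("shannonIndex", "PupExperiment", function(x, base = exp(1)) {
  apply(pupCounts(x), 2L, shannonIndex, base = base)
})

#' Feature richness
#'
#' Number of features with positive counts.
#'
#' @param x count vector or \linkS4class{PupExperiment}
#' @return integer, or named integer vector per sample
#' @export
setGeneric("richness", function(x) standardGeneric("richness"))

#' @rdname richness
#' @export
setMethod("richness", "numeric", function(x) {
  .checkCountVector(x)
  as.integer(vegan::specnumber(x))
})

#' @rdname richness
#' @export
setMethod("richness", "PupExperiment", function(x) {
  apply(pupCounts(x), 2L, function(v) as.integer(vegan::specnumber(v)))
})

#' Pielou evenness
#'
#' \code{J = H / log(richness)}; defined as 1 for a single-feature sample.
#'
#' @param x count vector or \linkS4class{PupExperiment}
#' @param base logarithm base used for both H and the ceiling
#' @return numeric value(s) in (0, 1]
#' @export
setGeneric("pielouEvenness", function(x, base = exp(1))
  standardGeneric("pielouEvenness"))

#' @rdname pielouEvenness
#' @export
setMethod("pielouEvenness", "numeric", function(x, base = exp(1)) {
  s <- richness(x)
  if (s == 1L) return(1)
  shannonIndex(x, base = base) / log(s, base = base)
})

#' @rdname pielouEvenness
#' @export
setMethod("pielouEvenness", "PupExperiment", function(x, base = exp(1)) {
  apply(pupCounts(x), 2L, pielouEvenness, base = base)
})

#' Bray-Curtis dissimilarity matrix
#'
#' \code{BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)}, optionally after an
#' elementwise square-root transform (as used for community-level ANOSIM).
#' Computed with \code{vegan::vegdist}.
#'
#' @param x a \linkS4class{PupExperiment} (samples = columns) or a numeric
#'   matrix with samples as rows
#' @param sqrtTransform apply an elementwise square root first; default
#'   FALSE
#' @return a \code{dist} with sample labels; entries in [0, 1], zero
#'   diagonal, symmetric
#' @examples
#' brayCurtis(rbind(a = c(2, 1), b = c(1, 1)))  # 0.2
#' @export
setGeneric("brayCurtis", function(x, sqrtTransform = FALSE)
  standardGeneric("brayCurtis"))

.brayCurtisMatrix <- function(m, sqrtTransform) {
  zero <- rowSums(m) <= 0
  if (any(zero))
    stop("zero total count for sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  if (sqrtTransform) m <- sqrt(m)
  vegan::vegdist(m, method = "bray")
}

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "matrix", function(x, sqrtTransform = FALSE) {
  if (nrow(x) < 2L) stop("need at least 2 samples")
  .brayCurtisMatrix(x, sqrtTransform)
})

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "PupExperiment", function(x, sqrtTransform = FALSE) {
  m <- t(pupCounts(x))
  if (nrow(m) < 2L) stop("need at least 2 samples")
  .brayCurtisMatrix(m, sqrtTransform)
})
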