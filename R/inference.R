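# Ordination, ANOSIM permutation tests, per-feature Kruskal-Wallis testing,
# regression helpers and robust confidence ellipses.

#' Classical (metric) multidimensional scaling
#'
#' Wraps \code{stats::cmdscale}: the squared dissimilarities are doubly
#' centered and eigendecomposed; coordinates are the top-k eigenvectors
#' scaled by the square roots of their eigenvalues. Proportion explained is
#' reported over the positive eigenvalues only; negative eigenvalues (from
#' non-Euclidean dissimilarities such as Bray-Curtis) are retained in
#' \code{eig} for inspection.
#'
#' @param d a \code{dist} (e.g. from \code{\link{brayCurtis}})
#' @param k number of ordination axes; reduced with a warning when fewer
#'   positive eigenvalues exist
#' @return an \linkS4class{OrdinationResult}
#' @export
classicalMds <- function(d, k = 2L) {
  if (k < 1L) stop("k must be >= 1")
  n <- attr(d, "Size")
  res <- suppressWarnings(cmdscale(d, k = min(k, n - 1L), eig = TRUE))
  npos <- sum(res$eig > sqrt(.Machine$double.eps) * max(abs(res$eig)))
  if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); reducing k")
    k <- npos
  }
  pts <- res$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("MDS", seq_len(k))
  posSum <- sum(res$eig[res$eig > 0])
  new("OrdinationResult", points = pts, eig = res$eig,
      propExplained = res$eig[seq_len(k)] / posSum)
}

#' @export
setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples x %d axes\n",
              nrow(object@points), ncol(object@points)))
  cat(sprintf("  proportion explained: %s\n",
              paste(sprintf("%.1f%%", 100 * object@propExplained),
                    collapse = ", ")))
})

#' @rdname classicalMds
#' @aliases ordinationPoints
#' @param x an \linkS4class{OrdinationResult}
#' @export
ordinationPoints <- function(x) x@points

# Clarke's ANOSIM R on a rank vector: (rB - rW) / (M / 2), with M the number
# of pairwise dissimilarities and mid-ranks on ties
.anosimR <- function(rankVec, withinMask) {
  (mean(rankVec[!withinMask]) - mean(rankVec[withinMask])) /
    (length(rankVec) / 2)
}

.pairWithinMask <- function(groups) {
  n <- length(groups)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  groups[idx[, 1L]] == groups[idx[, 2L]]
}

#' One-way ANOSIM
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. R is Clarke's statistic in [-1, 1];
#' the p-value uses the +1 correction
#' \code{(1 + #(permuted R >= observed)) / (1 + permutations)}.
#'
#' @param d a \code{dist}
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples)
#' @param permutations number of label permutations; default 9999
#' @param seed integer seed for the permutations
#' @return an \linkS4class{AnosimResult}
#' @export
anosimOneWay <- function(d, groups, permutations = 9999L, seed = NULL) {
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups must have one label per sample")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("singleton group(s): ",
                          paste(names(tab)[tab < 2L], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rk <- rank(as.vector(d))
  obs <- .anosimR(rk, .pairWithinMask(groups))
  perm <- vapply(seq_len(permutations), function(i)
    .anosimR(rk, .pairWithinMask(sample(groups))), numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + permutations)
  new("AnosimResult", statistic = obs, pValue = p,
      permutations = as.integer(permutations), design = "one-way",
      permStats = perm)
}

# average one-way R of `groups` computed separately inside each block, using
# ranks local to the block's sub-dissimilarity-matrix
.blockAveragedR <- function(dm, groups, blocks) {
  rs <- vapply(unique(blocks), function(b) {
    idx <- which(blocks == b)
    sub <- dm[idx, idx]
    rk <- rank(sub[lower.tri(sub)])
    .anosimR(rk, .pairWithinMask(groups[idx]))
  }, numeric(1))
  mean(rs)
}

#' Two-way crossed ANOSIM
#'
#' Tests factor A in a crossed design by averaging the one-way ANOSIM R for
#' A computed within each level of the blocking factor B, with permutations
#' of A labels restricted to occur within B levels (Clarke's two-way
#' crossed scheme). Call with the factors swapped to test B.
#'
#' @param d a \code{dist}
#' @param factorA factor under test
#' @param factorB blocking factor
#' @param permutations number of restricted permutations; default 9999
#' @param seed integer seed
#' @return an \linkS4class{AnosimResult}
#' @export
anosimTwoWayCrossed <- function(d, factorA, factorB, permutations = 9999L,
                                seed = NULL) {
  factorA <- as.character(factorA)
  factorB <- as.character(factorB)
  n <- attr(d, "Size")
  if (length(factorA) != n || length(factorB) != n)
    stop("factors must have one label per sample")
  for (b in unique(factorB)) {
    inb <- factorA[factorB == b]
    if (length(unique(inb)) < 2L || any(table(inb) < 2L))
      stop("factor A is confounded or has singleton cells within block ", b)
  }
  if (!is.null(seed)) set.seed(seed)
  dm <- as.matrix(d)
  obs <- .blockAveragedR(dm, factorA, factorB)
  perm <- vapply(seq_len(permutations), function(i) {
    ga <- factorA
    for (b in unique(factorB)) {
      idx <- which(factorB == b)
      ga[idx] <- ga[idx][sample(length(idx))]
    }
    .blockAveragedR(dm, ga, factorB)
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + permutations)
  new("AnosimResult", statistic = obs, pValue = p,
      permutations = as.integer(permutations), design = "two-way-crossed",
      permStats = perm)
}

#' @export
setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM (%s): R = %.3f, p = %.4g (%d permutations)\n",
              object@design, object@statistic, object@pValue,
              object@permutations))
})

#' Accessors for AnosimResult
#'
#' @param x an \linkS4class{AnosimResult}
#' @rdname AnosimResult-accessors
#' @export
anosimR <- function(x) x@statistic

#' @rdname AnosimResult-accessors
#' @export
anosimP <- function(x) x@pValue

#' Per-feature Kruskal-Wallis group testing
#'
#' Applies \code{stats::kruskal.test} to every feature whose mean relative
#' abundance across samples is at least \code{minMeanFraction} (features
#' below 1 percent of the dataset are excluded by default), and reports
#' Benjamini-Hochberg and Bonferroni adjusted p-values.
#'
#' @param x a \linkS4class{PupExperiment} or features x samples count matrix
#' @param groups group labels, one per sample
#' @param minMeanFraction mean relative-abundance inclusion threshold;
#'   default 0.01
#' @return data.frame with featureId, meanFraction, H, p, pBH, pBonferroni
#' @export
kruskalWallisFeatures <- function(x, groups, minMeanFraction = 0.01) {
  m <- if (is(x, "PupExperiment")) pupCounts(x) else as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("groups must have one label per sample")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  rel <- sweep(m, 2L, pmax(colSums(m), 1L), "/")
  mf <- rowMeans(rel)
  keep <- which(mf >= minMeanFraction)
  if (!length(keep)) {
    warning("no feature passes the abundance threshold")
    return(data.frame(featureId = character(0), meanFraction = numeric(0),
                      H = numeric(0), p = numeric(0), pBH = numeric(0),
                      pBonferroni = numeric(0)))
  }
  res <- t(vapply(keep, function(i) {
    v <- rel[i, ]
    if (length(unique(v)) == 1L)  # constant feature: no group effect
      return(c(0, 1))
    kt <- kruskal.test(v, factor(groups))
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2)))
  data.frame(featureId = rownames(m)[keep], meanFraction = mf[keep],
             H = res[, 1L], p = res[, 2L],
             pBH = p.adjust(res[, 2L], "BH"),
             pBonferroni = p.adjust(res[, 2L], "bonferroni"),
             row.names = NULL)
}

.olsResult <- function(fit, model) {
  s <- suppressWarnings(summary(fit))  # silence the exact-fit notice
  new("RegressionResult",
      coefficients = coef(fit), rSquared = s$r.squared,
      residualSd = s$sigma, model = model)
}

#' Least-squares fits
#'
#' \code{linearFit} fits \code{y ~ x}; \code{quadraticFit} fits
#' \code{y ~ x + x^2}. Both are exact on noise-free polynomial input and
#' refuse rank-deficient designs (too few distinct x values).
#'
#' @param x,y numeric vectors
#' @return a \linkS4class{RegressionResult}
#' @rdname regression-fits
#' @export
linearFit <- function(x, y) {
  if (length(unique(x)) < 2L) stop("need >= 2 distinct x values")
  .olsResult(lm(y ~ x), "linear")
}

#' @rdname regression-fits
#' @export
quadraticFit <- function(x, y) {
  if (length(unique(x)) < 3L)
    stop("need >= 3 distinct x values for a quadratic fit")
  fit <- lm(y ~ x + I(x^2))
  out <- .olsResult(fit, "quadratic")
  names(out@coefficients) <- c("(Intercept)", "linear", "quadratic")
  out
}

#' @rdname regression-fits
#' @aliases regressionCoefficients
#' @param object a \linkS4class{RegressionResult}
#' @export
regressionCoefficients <- function(object) object@coefficients

#' @rdname regression-fits
#' @aliases rSquared
#' @export
rSquared <- function(object) object@rSquared

#' @export
setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult (%s): R^2 = %.3f, residual sd = %.3g\n",
              object@model, object@rSquared, object@residualSd))
  print(round(object@coefficients, 6))
})

#' Robust t-distribution confidence ellipse
#'
#' Centroid confidence ellipse for a 2-D point cloud assuming a multivariate
#' t distribution: location and shape come from the iteratively reweighted
#' t-covariance fit (\code{MASS::cov.trob}), and the radius from the
#' \code{F(2, n - 2)} quantile at the requested level.
#'
#' @param points n x 2 coordinate matrix, n >= 3
#' @param level confidence level; default 0.95
#' @param df t degrees of freedom for the robust covariance; default 4
#' @return list with \code{center}, \code{semiAxes} (major, minor),
#'   \code{angle} (radians, major axis vs x-axis) and \code{shape} (the 2x2
#'   covariance)
#' @export
confidenceEllipse <- function(points, level = 0.95, df = 4) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (ncol(points) != 2L) stop("points must be n x 2")
  fit <- MASS::cov.trob(points, nu = df)
  r2 <- 2 * qf(level, 2, nrow(points) - 2L)
  ed <- eigen(fit$cov, symmetric = TRUE)
  list(center = fit$center,
       semiAxes = sqrt(pmax(ed$values, 0) * r2),
       angle = atan2(ed$vectors[2L, 1L], ed$vectors[1L, 1L]),
       shape = fit$cov)
}
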