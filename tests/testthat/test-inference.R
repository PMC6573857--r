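test_that("classical MDS reconstructs Euclidean configurations", {
  # collinear points 0, 1, 2
  d <- dist(matrix(c(0, 1, 2), ncol = 1))
  ord <- classicalMds(d, k = 1L)
  rec <- dist(ordinationPoints(ord))
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)

  # equilateral triangle, all pairwise distances 1
  dEq <- as.dist(matrix(1, 3, 3) - diag(3))
  ordEq <- classicalMds(dEq, k = 2L)
  expect_equal(as.numeric(dist(ordinationPoints(ordEq))), rep(1, 3),
               tolerance = 1e-9)

  # random 2-D configuration is reproduced exactly at k = 2
  set.seed(8)
  pts <- matrix(rnorm(24), ncol = 2)
  d2 <- dist(pts)
  ord2 <- classicalMds(d2, k = 2L)
  expect_equal(as.numeric(dist(ordinationPoints(ord2))), as.numeric(d2),
               tolerance = 1e-9)
  expect_true(all(diff(ord2@eig) <= 1e-9))      # non-increasing eigenvalues
  expect_lte(sum(ord2@propExplained), 1 + 1e-9)
  expect_warning(classicalMds(d2, k = 10L), "reducing k")
})

test_that("one-way ANOSIM matches oracles and is rank-invariant", {
  # perfect separation: all within < all between
  pts <- rbind(matrix(rnorm(8, 0, 0.05), ncol = 2),
               matrix(rnorm(8, 5, 0.05), ncol = 2))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  res <- anosimOneWay(d, g, permutations = 199, seed = 1)
  expect_equal(anosimR(res), 1)
  expect_gte(anosimP(res), 1 / 200)

  # statistic equals the direct-formula oracle and vegan's implementation
  set.seed(33)
  pts2 <- matrix(rnorm(12), ncol = 2)
  d2 <- dist(pts2)
  g2 <- rep(c("a", "b"), each = 3)
  mine <- anosimOneWay(d2, g2, permutations = 99, seed = 2)
  expect_equal(anosimR(mine), directAnosimR(d2, g2), tolerance = 1e-12)
  veg <- vegan::anosim(d2, g2, permutations = 9)
  expect_equal(anosimR(mine), unname(veg$statistic), tolerance = 1e-12)

  # exhaustive 6-sample oracle: permutation distribution and p-value
  allPerms <- unique(combinat <- t(apply(
    expand.grid(rep(list(c("a", "b")), 6)), 1, as.character)))
  valid <- allPerms[apply(allPerms, 1, function(v) sum(v == "a") == 3), ]
  exhaustR <- apply(valid, 1, function(v) directAnosimR(d2, v))
  pExact <- mean(exhaustR >= directAnosimR(d2, g2))
  big <- anosimOneWay(d2, g2, permutations = 4999, seed = 3)
  expect_lt(abs(anosimP(big) - pExact), 0.05)
  # permuted statistics live inside the exhaustively enumerated set
  expect_true(all(vapply(big@permStats, function(r)
    any(abs(exhaustR - r) < 1e-9), logical(1))))

  # invariance under monotone transforms of the dissimilarities
  dSq <- d2^2
  expect_equal(anosimR(anosimOneWay(dSq, g2, permutations = 9, seed = 1)),
               anosimR(mine), tolerance = 1e-12)
  expect_error(anosimOneWay(d2, c("a", "a", "a", "a", "a", "b")), "singleton")
})

test_that("one-way ANOSIM p-values are calibrated under the null", {
  set.seed(41)
  rejections <- vapply(1:200, function(i) {
    d <- dist(matrix(rnorm(20), ncol = 2))
    g <- sample(rep(c("a", "b"), each = 5))
    anosimP(anosimOneWay(d, g, permutations = 99)) <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("two-way crossed ANOSIM averages within-block statistics", {
  # factor A separates perfectly inside every level of B
  set.seed(52)
  centers <- c(a = 0, b = 10)
  pts <- NULL; fa <- fb <- character(0)
  for (b in c("b1", "b2")) {
    off <- if (b == "b1") 0 else 100
    for (a in c("a", "b")) {
      pts <- rbind(pts, matrix(rnorm(6, centers[a] + off, 0.01), ncol = 2))
      fa <- c(fa, rep(a, 3)); fb <- c(fb, rep(b, 3))
    }
  }
  d <- dist(pts)
  res <- anosimTwoWayCrossed(d, fa, fb, permutations = 199, seed = 5)
  expect_equal(anosimR(res), 1)
  expect_lte(anosimP(res), 0.05)

  # observed statistic equals the brute-force within-block average
  blockR <- mean(vapply(c("b1", "b2"), function(b) {
    idx <- fb == b
    directAnosimR(as.dist(as.matrix(d)[idx, idx]), fa[idx])
  }, numeric(1)))
  expect_equal(anosimR(res), blockR, tolerance = 1e-12)

  # shuffling A within blocks destroys the signal
  set.seed(6)
  faNull <- fa
  for (b in c("b1", "b2")) {
    idx <- which(fb == b)
    faNull[idx] <- sample(fa[idx])
  }
  dNull <- dist(matrix(rnorm(24), ncol = 2))
  resNull <- anosimTwoWayCrossed(dNull, faNull, fb, permutations = 199,
                                 seed = 7)
  expect_gt(anosimP(resNull), 0.05)
  expect_lt(abs(anosimR(resNull)), 0.5)
  expect_error(anosimTwoWayCrossed(d, rep("a", 12), fb), "confounded")
})

test_that("per-feature Kruskal-Wallis testing matches hand computation", {
  # identical group distributions give H = 0, p = 1
  mSame <- rbind(f1 = c(3, 7, 3, 7), f2 = c(7, 3, 7, 3))
  resSame <- kruskalWallisFeatures(mSame, c("a", "a", "b", "b"),
                                   minMeanFraction = 0)
  expect_equal(resSame$H, c(0, 0))
  expect_equal(resSame$p, c(1, 1))

  # hand-computed rank statistic: relative abundances .1 .2 | .5 .6 | .8 .9
  # give ranks 1,2 | 3,4 | 5,6 and H = 12/(6*7) * sum(Rk^2/2) - 3*7 = 32/7
  m <- rbind(f1 = c(1, 2, 5, 6, 8, 9), f2 = c(9, 8, 5, 4, 2, 1))
  g <- rep(c("a", "b", "c"), each = 2)
  res <- kruskalWallisFeatures(m, g, minMeanFraction = 0)
  expect_equal(res$H[res$featureId == "f1"], 32 / 7, tolerance = 1e-12)

  # BH adjustment is monotone in raw-p order; Bonferroni >= BH
  set.seed(71)
  mr <- matrix(rpois(200, 20), nrow = 10,
               dimnames = list(paste0("f", 1:10), NULL))
  gr <- rep(c("x", "y"), each = 10)
  rr <- kruskalWallisFeatures(mr, gr, minMeanFraction = 0)
  o <- order(rr$p)
  expect_true(all(diff(rr$pBH[o]) >= -1e-12))
  expect_true(all(rr$pBonferroni >= rr$pBH - 1e-12))

  # abundance threshold removes rare features
  mThr <- rbind(common = c(99, 99), rare = c(1, 1))
  resThr <- kruskalWallisFeatures(mThr, c("a", "b"), minMeanFraction = 0.05)
  expect_equal(resThr$featureId, "common")
})

test_that("least-squares fits are exact on polynomial input", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- 1 + 2 * x - 0.03 * x^2
  fit <- quadraticFit(x, y)
  expect_equal(unname(regressionCoefficients(fit)), c(1, 2, -0.03),
               tolerance = 1e-9)
  expect_equal(rSquared(fit), 1, tolerance = 1e-9)
  lin <- linearFit(x, x)
  expect_equal(rSquared(lin), 1, tolerance = 1e-12)
  expect_error(quadraticFit(c(1, 1, 2), c(1, 2, 3)), "distinct")
  expect_error(linearFit(c(2, 2), c(1, 2)), "distinct")
})

test_that("robust confidence ellipses are centred and equivariant", {
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  circle <- cbind(cos(theta), sin(theta))
  ell <- confidenceEllipse(circle)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 1e-6)

  set.seed(81)
  iso <- matrix(rnorm(1000), ncol = 2)
  eIso <- confidenceEllipse(iso)
  expect_lt(abs(eIso$semiAxes[1] / eIso$semiAxes[2] - 1), 0.10)

  # rotating the points rotates the ellipse
  set.seed(82)
  pts <- cbind(rnorm(60, sd = 3), rnorm(60, sd = 1))
  e0 <- confidenceEllipse(pts)
  phi <- pi / 5
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  e1 <- confidenceEllipse(pts %*% t(rot))
  angDiff <- (e1$angle - e0$angle - phi) %% pi
  expect_lt(min(angDiff, pi - angDiff), 1e-6)
  expect_equal(e0$semiAxes, e1$semiAxes, tolerance = 1e-6)
  expect_error(confidenceEllipse(pts[1:2, ]), "at least 3")
})
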