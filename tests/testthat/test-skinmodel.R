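test_that("single-Gaussian fit uses the biased 1/T covariance", {
  x <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  p <- fitSGM(x)
  expect_equal(p@mu, c(1, 1))
  expect_equal(p@sigma, diag(2))
  # identical points: mean at the point, ridge keeps sigma usable
  expect_warning(p0 <- fitSGM(matrix(rep(c(3, 4), 5), 5, 2, byrow = TRUE)),
                 "regularised")
  expect_equal(p0@mu, c(3, 4))
  expect_true(all(eigen(p0@sigma)$values > 0))
})

test_that("single-Gaussian fit recovers known parameters from large samples", {
  set.seed(21)
  S <- rbind(c(2, 0.8), c(0.8, 1))
  x <- MASS::mvrnorm(10000, c(-1, 3), S)
  p <- fitSGM(x)
  se <- sqrt(diag(S) / 10000)
  expect_true(all(abs(p@mu - c(-1, 3)) < 3 * se))
  expect_true(max(abs(p@sigma - S)) < 3 * max(S) / sqrt(10000) * 2)
})

test_that("squared Mahalanobis distance matches the closed-form 2x2 inverse", {
  p <- fitSGM(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))  # mu (1,1), sigma I
  expect_equal(mahalanobisSq(c(1, 1), p), 0)
  expect_equal(mahalanobisSq(c(4, 5), p), 25)  # identity: squared Euclidean
  set.seed(5)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    S <- crossprod(A) + diag(0.1, 2)
    mu <- rnorm(2)
    q <- new("SGMParams", mu = mu, sigma = S, space = "lab", peak = 0)
    x <- rnorm(2)
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) /
      (S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1])
    expect_equal(mahalanobisSq(x, q),
                 as.numeric((x - mu) %*% inv %*% (x - mu)),
                 tolerance = 1e-10)
  }
})

test_that("Gaussian density peaks at 1/(2 pi det^1/2) and integrates to one", {
  p <- new("SGMParams", mu = c(0, 0), sigma = diag(2), space = "lab", peak = 0)
  expect_equal(sgmDensity(c(0, 0), p), 1 / (2 * pi), tolerance = 1e-12)
  # quadrature over +-6 sigma
  g <- seq(-6, 6, length.out = 301)
  h <- g[2] - g[1]
  grid <- as.matrix(expand.grid(g, g))
  expect_equal(sum(sgmDensity(grid, p)) * h^2, 1, tolerance = 1e-3)
  # scaling sigma by 4 divides the 2-D peak by 4 (det factor)
  p4 <- new("SGMParams", mu = c(0, 0), sigma = 4 * diag(2), space = "lab",
            peak = 0)
  expect_equal(sgmDensity(c(0, 0), p4), sgmDensity(c(0, 0), p) / 4,
               tolerance = 1e-12)
})

test_that("mixture density collapses, dominates components, and integrates to one", {
  p <- fitSGM(rbind(c(0, 1), c(2, 1), c(1, 0), c(1, 2)))
  g1 <- gmmParams(1, matrix(p@mu, 1), p@sigma)
  set.seed(8)
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(gmmDensity(x, g1), sgmDensity(x, p), tolerance = 1e-12)
  g2 <- twoClusterTruth()
  # at a component mean the far component contributes < 1e-10
  expect_equal(gmmDensity(c(0, 0), g2), 0.5 / (2 * pi), tolerance = 1e-9)
  for (j in 1:2) {
    comp <- gmmParams(1, g2@means[j, , drop = FALSE],
                      g2@covariances[, , j])
    expect_true(all(gmmDensity(x, g2) >=
                    g2@priors[j] * gmmDensity(x, comp) - 1e-14))
  }
  gr <- seq(-8, 13, length.out = 351)
  h <- gr[2] - gr[1]
  grid <- as.matrix(expand.grid(gr, gr))
  expect_equal(sum(gmmDensity(grid, g2)) * h^2, 1, tolerance = 1e-3)
})

test_that("histogram initialisation finds distant modes deterministically", {
  x <- sampleMixture(twoClusterTruth(), 4000, seed = 12)
  gi <- initGMM(x, 2, seed = 1)
  # each initial mean within one (smoothed) bin neighbourhood of a true mode
  d <- apply(gi@means, 1, function(m)
    min(sqrt(colSums((t(twoClusterTruth()@means) - m)^2))))
  binw <- max(diff(range(x[, 1])), diff(range(x[, 2]))) / 64
  expect_true(all(d < 5 * binw))
  expect_equal(sort(apply(gi@means, 1, sum)),
               sort(apply(initGMM(x, 2, seed = 1)@means, 1, sum)))
  expect_equal(gi@priors, c(0.5, 0.5))
  expect_error(initGMM(x[1:9, ], 200), "J")
})

test_that("E-step responsibilities are proper posteriors", {
  x <- sampleMixture(twoClusterTruth(), 500, seed = 3)
  g1 <- gmmParams(1, matrix(c(1, 1), 1), diag(2))
  expect_equal(as.numeric(emEStep(x, g1)), rep(1, 500))
  # identical components split evenly by symmetry
  gid <- gmmParams(c(0.5, 0.5), rbind(c(1, 1), c(1, 1)), diag(2))
  h <- emEStep(x, gid)
  expect_equal(as.numeric(h), rep(0.5, 1000))
  # rows always sum to one, even for outlying points (log-domain path)
  gfar <- gmmParams(c(0.5, 0.5), rbind(c(500, 500), c(-500, -500)),
                    0.0001 * diag(2))
  h <- emEStep(x, gfar)
  expect_true(all(abs(rowSums(h) - 1) < 1e-9))
  expect_true(all(h >= 0 & h <= 1))
  # tiny-covariance component dominates at its own mean
  gdom <- gmmParams(c(0.5, 0.5), rbind(c(0, 0), c(0.5, 0.5)),
                    array(c(1e-6 * diag(2), diag(2)), c(2, 2, 2)))
  h <- emEStep(matrix(c(0, 0), 1), gdom)
  expect_gt(h[1, 1], 1 - 1e-6)
})

test_that("M-step reduces to per-class ML fits for hard responsibilities", {
  x <- sampleMixture(twoClusterTruth(), 600, seed = 4)
  # all-ones single column reproduces the single-Gaussian fit exactly
  g <- emMStep(x, matrix(1, nrow(x), 1))
  p <- fitSGM(x)
  expect_equal(g@means[1, ], p@mu, tolerance = 1e-12)
  expect_equal(g@covariances[, , 1], p@sigma, tolerance = 1e-12)
  expect_equal(g@priors, 1)
  # hard 0/1 split: partition-and-fit oracle
  lab <- attr(x, "component")
  h <- cbind(lab == 1, lab == 2) * 1
  g <- emMStep(x, h)
  for (j in 1:2) {
    pj <- fitSGM(x[lab == j, ])
    expect_equal(g@means[j, ], pj@mu, tolerance = 1e-12)
    expect_equal(g@covariances[, , j], pj@sigma, tolerance = 1e-12)
    expect_equal(g@priors[j], mean(lab == j), tolerance = 1e-12)
  }
  expect_equal(sum(g@priors), 1, tolerance = 1e-12)
})

test_that("EM increases the likelihood and stops at the iteration cap", {
  x <- sampleMixture(twoClusterTruth(), 2000, seed = 5)
  fit <- fitGMM(x, J = 2, seed = 2)
  expect_true(all(diff(fit@logLik) > -1e-8))
  # cap honoured when tolerance can never fire
  fit5 <- fitGMM(x, J = 2, maxIter = 5, tol = 0, seed = 2)
  expect_identical(length(fit5@logLik), 5L)
})

test_that("a single-component mixture fit equals the single-Gaussian fit", {
  x <- sampleMixture(twoClusterTruth(), 1500, seed = 6)
  p <- fitSGM(x)
  g <- fitGMM(x, J = 1, seed = 1)
  expect_equal(g@means[1, ], p@mu, tolerance = 1e-9)
  expect_equal(g@covariances[, , 1], p@sigma, tolerance = 1e-9)
  expect_equal(g@priors, 1, tolerance = 1e-12)
})

test_that("EM recovers a separated two-component mixture", {
  truth <- twoClusterTruth()
  x <- sampleMixture(truth, 5000, seed = 31)
  fit <- suppressWarnings(fitGMM(x, J = 2, seed = 31))
  p <- matchComponents(fit, truth)
  expect_lt(max(sqrt(rowSums((fit@means[p, ] - truth@means)^2))), 0.15)
  expect_lt(max(abs(fit@priors[p] - truth@priors)), 0.05)
})

test_that("probability maps are normalised, ordered, and tag-checked", {
  skin <- gmmParams(1, matrix(c(10, 10), 1), diag(2), space = "lab")
  # an image sitting at the model mean maps to the maximal value 1
  img <- ChromImage(array(10, dim = c(3, 4, 2)), "lab")
  pm <- probabilityMap(img, skin)
  expect_equal(as.numeric(pm), rep(1, 12))
  # separable two-region image: mean skin score above mean background score
  a <- array(0, dim = c(10, 10, 2))
  a[, 1:5, ] <- 10           # skin region at the model mean
  a[, 6:10, ] <- -10         # background far away
  img <- ChromImage(a, "lab")
  pm <- probabilityMap(img, skin)
  expect_gt(mean(pm[, 1:5]), mean(pm[, 6:10]))
  # posterior variant is a proper probability
  bg <- gmmParams(1, matrix(c(-10, -10), 1), diag(2), space = "lab")
  pp <- probabilityMap(img, skin, bg)
  expect_true(all(pp >= 0 & pp <= 1))
  expect_gt(mean(pp[, 1:5]), 0.99)
  expect_lt(mean(pp[, 6:10]), 0.01)
  wrong <- gmmParams(1, matrix(c(0, 0), 1), diag(2), space = "hsv")
  expect_error(probabilityMap(img, wrong), "hsv")
})

test_that("thresholding keeps exactly the pixels at or above tau", {
  pm <- matrix(c(0.5, 0.6, 0.2, 0.9), 2)
  expect_equal(sum(thresholdMap(pm, 0)), 4)
  expect_equal(sum(thresholdMap(pm, 0.95)), 0)
  expect_identical(thresholdMap(pm, 0.55), pm >= 0.55)
  expect_identical(sum(thresholdMap(matrix(c(0.5, 0.6), 1), 0.55)), 1L)
  expect_error(thresholdMap(pm, 1.5), "tau")
})
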