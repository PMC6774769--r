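test_that("initialisation places two prototypes on samples with no edges", {
  pts <- unitSquareCloud(100, seed = 2)
  g <- gngInit(pts, gngConfig(), seed = 3)
  expect_identical(nrow(nodePositions(g)), 2L)
  expect_identical(nrow(graphEdges(g)), 0L)
  g2 <- gngInit(pts, gngConfig(), seed = 3)
  expect_identical(nodePositions(g), nodePositions(g2))
  # a 2-point distribution pins the prototypes to those points
  two <- rbind(c(0, 0), c(1, 1))
  g3 <- gngInit(two, gngConfig(), seed = 1)
  expect_true(setequal(asplit(nodePositions(g3), 1), asplit(two, 1)))
  expect_error(gngInit(two[1, , drop = FALSE], gngConfig()), "2")
})

test_that("one adaptation step moves, links and accumulates as specified", {
  cfg <- gngConfig(epsB = 0.2, epsN = 0.01)
  g <- newGNGForTest(rbind(c(0, 0), c(1, 1)), cfg)
  # signal exactly on the winner: nothing moves, no error accrues
  g1 <- gngAdapt(g, c(0, 0))
  expect_equal(nodePositions(g1)[1, ], c(0, 0))
  expect_equal(nodeErrors(g1)[1], 0)
  # winner and runner-up get linked with age zero
  expect_identical(nrow(graphEdges(g1)), 1L)
  expect_identical(edgeAges(g1), 0L)
  # general signal: winner moves by epsB, neighbour by epsN, error by d^2
  g2 <- gngAdapt(g1, c(0.2, 0))
  expect_equal(nodePositions(g2)[1, ], c(0.04, 0))
  expect_equal(nodePositions(g2)[2, ], c(1, 1) + 0.01 * (c(0.2, 0) - c(1, 1)))
  expect_equal(nodeErrors(g2)[1], 0.04)
})

test_that("insertion splits the worst edge at its midpoint", {
  cfg <- gngConfig(alpha = 0.5)
  g <- newGNGForTest(rbind(c(0, 0), c(2, 2)), cfg,
                     edges = rbind(c(1L, 2L)), ages = 0L,
                     errors = c(4, 1))
  g2 <- gngInsert(g)
  expect_identical(nrow(nodePositions(g2)), 3L)
  expect_equal(nodePositions(g2)[3, ], c(1, 1))
  keys <- paste(graphEdges(g2)[, 1], graphEdges(g2)[, 2])
  expect_true(setequal(keys, c("1 3", "2 3")))  # q-f replaced by q-r, f-r
  expect_equal(nodeErrors(g2), c(2, 0.5, 2))
})

test_that("the insertion schedule yields 2 + floor(signals/lambda) nodes", {
  pts <- unitSquareCloud(1000, seed = 4)
  g <- gngLearn(pts, gngConfig(maxNodes = 7, lambda = 100), nSignals = 500,
                seed = 1)
  expect_identical(nrow(nodePositions(g)), 7L)  # 2 + 5 insertions
  g <- gngLearn(pts, gngConfig(maxNodes = 50, lambda = 100,
                               ageMax = 100000L), nSignals = 930, seed = 1)
  expect_identical(nrow(nodePositions(g)), 2L + 9L)
})

test_that("compiled learning matches the pure-R reference step for step", {
  set.seed(9)
  pts <- cbind(runif(300), runif(300))
  cols <- matrix(runif(900), 300, 3)
  cfg <- gngConfig(maxNodes = 15, lambda = 50, ageMax = 100000L)
  a <- gngLearn(pts, cfg, nSignals = 700, colours = cols, seed = 5)
  b <- SkinGNG:::gngLearnR(pts, cfg, 700, colours = cols, seed = 5)
  expect_identical(nodePositions(a), nodePositions(b))
  expect_identical(nodeErrors(a), nodeErrors(b))
  expect_identical(nodeColours(a), nodeColours(b))
  expect_setequal(paste(graphEdges(a)[, 1], graphEdges(a)[, 2], edgeAges(a)),
                  paste(graphEdges(b)[, 1], graphEdges(b)[, 2], edgeAges(b)))
})

test_that("learning is bit-reproducible under a fixed seed", {
  pts <- unitSquareCloud(500, seed = 6)
  cfg <- gngConfig(maxNodes = 30)
  a <- gngLearn(pts, cfg, nSignals = 3000, seed = 11)
  b <- gngLearn(pts, cfg, nSignals = 3000, seed = 11)
  expect_identical(nodePositions(a), nodePositions(b))
  expect_identical(graphEdges(a), graphEdges(b))
  expect_identical(edgeAges(a), edgeAges(b))
  c <- gngLearn(pts, cfg, nSignals = 3000, seed = 12)
  expect_false(identical(nodePositions(a), nodePositions(c)))
})

test_that("graph validity holds throughout learning and capacity binds", {
  pts <- unitSquareCloud(1000, seed = 7)
  g <- gngLearn(pts, gngConfig(maxNodes = 40), nSignals = 8000, seed = 2,
                checkInvariants = TRUE)
  expect_identical(attr(g, "violations"), 0)
  expect_true(validObject(g))
  expect_lte(nrow(nodePositions(g)), 40L)
  expect_true(all(edgeAges(g) <= g@config$ageMax))
})

test_that("more capacity strictly lowers quantisation error", {
  pts <- unitSquareCloud(2000, seed = 8)
  mqe <- vapply(c(10, 25, 50, 100), function(mn) {
    g <- gngLearn(pts, gngConfig(maxNodes = mn), nSignals = 15000, seed = 3)
    gngQuantisationError(g, pts)
  }, numeric(1))
  expect_true(all(diff(mqe) < 0))
})

test_that("a constant signal contracts all surviving neurons onto it", {
  pts <- matrix(rep(c(0.4, 0.6), 50), 50, 2, byrow = TRUE)
  g <- gngLearn(pts, gngConfig(maxNodes = 5), nSignals = 4000, seed = 1)
  d <- sqrt(colSums((t(nodePositions(g)) - c(0.4, 0.6))^2))
  expect_true(all(d < 1e-3))
})

test_that("mask learning covers the support and separates distant blobs", {
  mask <- discMask(80, 80, 40, 40, 22)
  g <- learnFromMask(mask, gngConfig(maxNodes = 60), nSignals = 10000, seed = 2)
  pos <- nodePositions(g)
  # neuron positions live inside the disc dilated by a typical edge length
  ctr <- c(40 - 0.5, 40 - 0.5) / 80
  el <- graphEdges(g)
  elen <- sqrt(rowSums((pos[el[, 1], ] - pos[el[, 2], ])^2))
  dil <- (22 / 80) + stats::quantile(elen, 0.95)
  d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  expect_gte(mean(d <= dil), 0.95)
  # two well-separated discs give at least two graph components
  m2 <- discMask(60, 120, 30, 25, 14) | discMask(60, 120, 30, 95, 14)
  g2 <- learnFromMask(m2, gngConfig(maxNodes = 60), nSignals = 12000, seed = 3)
  expect_gte(max(gngComponents(g2)), 2)
  expect_error(learnFromMask(matrix(FALSE, 5, 5)), "foreground")
})

test_that("point-cloud learning adheres to the surface and averages colour", {
  sp <- sampleShape3D("sphere", n = 2000, seed = 13)
  mesh <- learnPointCloud(sp$points, sp$colours,
                          gngConfig(maxNodes = 200), nSignals = 20000,
                          seed = 4)
  g <- attr(mesh, "gng")
  dev <- mean(abs(sqrt(rowSums(nodePositions(g)^2)) - 1))
  expect_lt(dev, 0.05)
  # every face's edges exist in the graph (validity method enforces it)
  expect_true(validObject(mesh))
  # a uniformly red cloud yields uniformly red neurons
  red <- matrix(rep(c(1, 0, 0), each = 2000), 2000, 3)
  meshR <- learnPointCloud(sp$points, red, gngConfig(maxNodes = 50),
                           nSignals = 5000, seed = 1)
  expect_true(all(abs(nodeColours(meshR) -
                      matrix(rep(c(1, 0, 0), each = nrow(nodeColours(meshR))),
                             ncol = 3)) < 1e-12))
})

test_that("disparity normalisation follows d = (d_off - kd)/8", {
  expect_equal(normaliseDisparity(1090, dOff = 1090), 0)
  expect_equal(normaliseDisparity(600, dOff = 1090), 61.25)
  expect_equal(normaliseDisparity(400, dOff = 1090),
               2 * normaliseDisparity(745, dOff = 1090))
})

test_that("pinhole back-projection is geometric and mask-aware", {
  K <- list(fx = 100, fy = 100, cx = 5, cy = 4)
  depth <- matrix(0, 8, 10)
  depth[4, 5] <- 2.5  # principal point
  pc <- depthToPointCloud(depth, K)
  expect_equal(as.numeric(pc$points), c(0, 0, 2.5))
  # constant-depth image back-projects to a plane
  depth <- matrix(2, 8, 10)
  pc <- depthToPointCloud(depth, K)
  expect_equal(as.numeric(stats::sd(pc$points[, 3])), 0)
  fit <- stats::lm.fit(cbind(1, pc$points[, 1:2]), pc$points[, 3])
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # masked projection keeps exactly the masked non-zero pixels
  mask <- matrix(FALSE, 8, 10); mask[1:2, 1:3] <- TRUE
  pc <- depthToPointCloud(depth, K, mask = mask)
  expect_identical(nrow(pc$points), 6L)
  expect_warning(depthToPointCloud(matrix(0, 3, 3), K), "empty")
})
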