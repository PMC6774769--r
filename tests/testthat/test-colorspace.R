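onePixel <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))

test_that("normalised RGB removes intensity and handles zero pixels", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(0.5, 0.5, 0.5)
  img[1, 2, ] <- c(1, 0, 0)
  img[2, 1, ] <- c(0.2, 0.3, 0.5)
  img[2, 2, ] <- c(0, 0, 0)  # zero intensity: neutral fallback
  ci <- rgbToNrgb(img)
  a <- chromData(ci)
  expect_equal(a[1, 1, ], c(1 / 3, 1 / 3))
  expect_equal(a[1, 2, ], c(1, 0))
  expect_equal(a[2, 1, ], c(0.2, 0.3))
  expect_equal(a[2, 2, ], c(1 / 3, 1 / 3))
  expect_identical(spaceTag(ci), "nrgb")
})

test_that("HSV hue/saturation follow the hexcone with H scaled to [0,1]", {
  a <- chromData(rgbToHsv(onePixel(1, 0, 0)))
  expect_equal(a[1, 1, ], c(0, 1))
  a <- chromData(rgbToHsv(onePixel(0.5, 0.5, 0.5)))
  expect_equal(a[1, 1, 2], 0)   # grey is unsaturated
  expect_equal(a[1, 1, 1], 0)   # achromatic convention H = 0
  a <- chromData(rgbToHsv(onePixel(0, 1, 0)))
  expect_equal(a[1, 1, ], c(1 / 3, 1))
})

test_that("the linear RGB-to-XYZ map reproduces its matrix columns and row sums", {
  xyz <- rgbToXyzRaw(onePixel(1, 1, 1))
  expect_equal(as.numeric(xyz[1, 1, ]), c(0.99999, 1.000000, 1.000149),
               tolerance = 1e-12)
  xyz <- rgbToXyzRaw(onePixel(1, 0, 0))
  expect_equal(as.numeric(xyz[1, 1, ]), c(0.433910, 0.212649, 0.017756),
               tolerance = 1e-12)
  xyz <- rgbToXyzRaw(onePixel(0, 0, 0))
  expect_equal(as.numeric(xyz[1, 1, ]), c(0, 0, 0))
  # black maps to the neutral chromaticity, not a division error
  expect_equal(chromData(rgbToXyz(onePixel(0, 0, 0)))[1, 1, ], c(1 / 3, 1 / 3))
})

test_that("Lab transform hits (100, 0, 0) at the white point and is continuous", {
  wp <- whitePointD65()
  lab <- xyzToLab(wp[1], wp[2], wp[3], wp)
  expect_equal(lab$L, 100, tolerance = 1e-9)
  expect_equal(lab$a, 0, tolerance = 1e-9)
  expect_equal(lab$b, 0, tolerance = 1e-9)
  # the two branches of the lightness function agree at the knee
  r0 <- 0.008856
  expect_lt(abs(r0^(1 / 3) - (7.7867 * r0 + 16 / 116)), 1e-4)
  # L* of black comes from the linear branch at r = 0
  expect_equal(xyzToLab(0, 0, 0, wp)$L, 0)
  # monotone increasing on a dense grid
  grid <- seq(0, 1, length.out = 5000)
  f <- ifelse(grid > 0.008856, grid^(1 / 3), 7.7867 * grid + 16 / 116)
  expect_true(all(diff(f) > 0))
  expect_error(xyzToLab(0.5, 0.5, 0.5, c(1, 0, 1)), "positive")
})

test_that("grey images are chromatically neutral in a*b* under the matrix row-sum white point", {
  rowSums <- c(0.99999, 1.000000, 1.000149)
  for (c0 in c(0.1, 0.5, 0.9)) {
    ci <- rgbToLab(onePixel(c0, c0, c0), wp = rowSums)
    expect_equal(as.numeric(chromData(ci)[1, 1, ]), c(0, 0), tolerance = 1e-9)
  }
})

test_that("rgbToLab matches an independent scalar re-implementation", {
  # scalar-loop oracle written independently of the vectorised path
  oracle <- function(rgb, wp) {
    M <- rbind(c(0.433910, 0.376220, 0.189860),
               c(0.212649, 0.715169, 0.072182),
               c(0.017756, 0.109478, 0.872915))
    xyz <- as.numeric(M %*% rgb)
    f <- function(r) if (r > 0.008856) r^(1 / 3) else 7.7867 * r + 16 / 116
    fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
    unname(c(500 * (fx - fy), 200 * (fy - fz)))
  }
  wp <- whitePointD65()
  set.seed(42)
  for (i in 1:10) {
    rgb <- runif(3)
    got <- as.numeric(chromData(rgbToLab(onePixel(rgb[1], rgb[2], rgb[3]), wp))[1, 1, ])
    expect_equal(got, oracle(rgb, wp), tolerance = 1e-12)
  }
})

test_that("convertColorSpace dispatches and rejects unknown tags", {
  set.seed(7)
  img <- array(runif(5 * 4 * 3), dim = c(4, 5, 3))
  expect_identical(chromData(convertColorSpace(img, "lab")),
                   chromData(rgbToLab(img)))
  expect_identical(chromData(convertColorSpace(img, "hsv")),
                   chromData(rgbToHsv(img)))
  expect_identical(chromData(convertColorSpace(img, "nrgb")),
                   chromData(rgbToNrgb(img)))
  expect_identical(chromData(convertColorSpace(img, "xyz")),
                   chromData(rgbToXyz(img)))
  expect_error(convertColorSpace(img, "ycgcr"))
})

test_that("chromaticities stay in the simplex and conversions are pixel-wise", {
  set.seed(11)
  img <- array(runif(8 * 6 * 3), dim = c(6, 8, 3))
  for (space in c("nrgb", "xyz")) {
    a <- chromData(convertColorSpace(img, space))
    expect_true(all(a >= -1e-12))
    expect_true(all(a[, , 1] + a[, , 2] <= 1 + 1e-12))
  }
  # permuting pixels commutes with converting
  perm <- sample(6 * 8)
  for (space in c("nrgb", "hsv", "xyz", "lab")) {
    a <- convertColorSpace(img, space)
    flat <- cbind(as.vector(chromData(a)[, , 1]), as.vector(chromData(a)[, , 2]))
    imgP <- array(c(matrix(img[, , 1])[perm], matrix(img[, , 2])[perm],
                    matrix(img[, , 3])[perm]), dim = c(6, 8, 3))
    b <- convertColorSpace(imgP, space)
    flatP <- cbind(as.vector(chromData(b)[, , 1]), as.vector(chromData(b)[, , 2]))
    expect_equal(flatP, flat[perm, ], tolerance = 1e-12)
  }
})

test_that("lifting chrominance back to RGB inverts the forward transform in gamut", {
  set.seed(3)
  ab <- cbind(runif(50, -20, 25), runif(50, -20, 25))
  rgb <- chromToRGB(ab, "lab", intensity = 65)
  img <- array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = c(50, 1, 3))
  back <- chromData(rgbToLab(img))
  got <- cbind(as.vector(back[, , 1]), as.vector(back[, , 2]))
  inGamut <- apply(rgb, 1, function(v) all(v > 1e-6 & v < 1 - 1e-6))
  expect_gt(sum(inGamut), 10)
  expect_equal(got[inGamut, ], ab[inGamut, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})
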