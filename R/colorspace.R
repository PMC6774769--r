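# RGB -> XYZ linear map. Row sums are ~1 so unit-range RGB is assumed:
# 8-bit input must be divided by 255 before conversion.
RGB_TO_XYZ_MATRIX <- matrix(c(
  0.433910, 0.376220, 0.189860,
  0.212649, 0.715169, 0.072182,
  0.017756, 0.109478, 0.872915), nrow = 3, byrow = TRUE)

LAB_F_THRESHOLD <- 0.008856
LAB_F_SLOPE <- 7.7867

#' D65 reference white point
#'
#' Standard daylight tristimulus reference (Xn, Yn, Zn) used by default for
#' the CIE L*a*b* transform. Any strictly positive triple can be supplied
#' instead wherever a white point is accepted.
#' @return named numeric vector c(Xn, Yn, Zn).
#' @export
whitePointD65 <- function() c(Xn = 0.95047, Yn = 1.0, Zn = 1.08883)

checkWhitePoint <- function(wp) {
  if (length(wp) != 3L || anyNA(wp) || any(wp <= 0))
    stop("white point must be three strictly positive tristimulus values")
  unname(wp)
}

checkRGB <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (anyNA(img) || min(img) < 0 || max(img) > 1 + 1e-9)
    stop("RGB channel values must lie in [0, 1]; divide 8-bit input by 255")
  img
}

#' Convert an RGB image to normalised-RGB chrominance
#'
#' Removes intensity by dividing each channel by the channel sum:
#' r = R/(R+G+B), g = G/(R+G+B). Pixels with zero intensity are mapped to the
#' neutral chromaticity (1/3, 1/3) so they stay defined but uninformative.
#'
#' @param img H x W x 3 RGB array with values in [0, 1].
#' @return a \code{\link{ChromImage}} with channels (r, g).
#' @export
rgbToNrgb <- function(img) {
  img <- checkRGB(img)
  s <- img[, , 1] + img[, , 2] + img[, , 3]
  zero <- s <= 0
  s[zero] <- 1
  r <- img[, , 1] / s
  g <- img[, , 2] / s
  r[zero] <- 1 / 3
  g[zero] <- 1 / 3
  ChromImage(array(c(r, g), dim = c(dim(img)[1:2], 2L)), "nrgb")
}

#' Convert an RGB image to HSV chrominance
#'
#' Standard hexcone HSV with hue scaled to [0, 1] (degrees/360) so both
#' channels share the unit range used by the covariance fits. Achromatic
#' pixels take H = 0 by convention; their S = 0 already marks them.
#'
#' @inheritParams rgbToNrgb
#' @return a \code{\link{ChromImage}} with channels (H, S).
#' @export
rgbToHsv <- function(img) {
  img <- checkRGB(img)
  hw <- dim(img)[1:2]
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  ChromImage(array(c(hsv[1, ], hsv[2, ]), dim = c(hw, 2L)), "hsv")
}

#' Convert an RGB image to raw CIE XYZ tristimulus values
#'
#' Applies the fixed linear RGB-to-XYZ matrix to each pixel of a unit-range
#' RGB image; no gamma handling is performed.
#'
#' @inheritParams rgbToNrgb
#' @return H x W x 3 array of (X, Y, Z).
#' @export
rgbToXyzRaw <- function(img) {
  img <- checkRGB(img)
  hw <- dim(img)[1:2]
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  xyz <- RGB_TO_XYZ_MATRIX %*% m
  array(c(xyz[1, ], xyz[2, ], xyz[3, ]), dim = c(hw, 3L))
}

#' Convert an RGB image to CIE xy chromaticity
#'
#' Projects the raw tristimulus values to the chromaticity plane
#' x = X/(X+Y+Z), y = Y/(X+Y+Z), removing intensity as the d = 2 models
#' require. Zero-tristimulus pixels map to the neutral point (1/3, 1/3).
#'
#' @inheritParams rgbToNrgb
#' @return a \code{\link{ChromImage}} with channels (x, y).
#' @export
rgbToXyz <- function(img) {
  xyz <- rgbToXyzRaw(img)
  s <- xyz[, , 1] + xyz[, , 2] + xyz[, , 3]
  zero <- s <= 0
  s[zero] <- 1
  x <- xyz[, , 1] / s
  y <- xyz[, , 2] / s
  x[zero] <- 1 / 3
  y[zero] <- 1 / 3
  ChromImage(array(c(x, y), dim = c(dim(xyz)[1:2], 2L)), "xyz")
}

# Piecewise lightness function: cube root above the threshold, linear with
# intercept 16/116 below; continuous at the join to ~1e-5.
labF <- function(r) {
  ifelse(r > LAB_F_THRESHOLD, r^(1 / 3), LAB_F_SLOPE * r + 16 / 116)
}

labFInv <- function(t) {
  knee <- LAB_F_THRESHOLD^(1 / 3)
  ifelse(t > knee, t^3, (t - 16 / 116) / LAB_F_SLOPE)
}

#' CIE XYZ to CIE L*a*b*
#'
#' Nonlinear transform relative to a white point:
#' L* = 116 f(Y/Yn) - 16, a* = 500 (f(X/Xn) - f(Y/Yn)),
#' b* = 200 (f(Y/Yn) - f(Z/Zn)).
#'
#' @param X,Y,Z non-negative tristimulus values (vectors or arrays of equal
#'   shape).
#' @param wp white point c(Xn, Yn, Zn), all components positive.
#' @return list with components \code{L}, \code{a}, \code{b} of the input
#'   shape.
#' @export
xyzToLab <- function(X, Y, Z, wp = whitePointD65()) {
  wp <- checkWhitePoint(wp)
  X <- unname(X); Y <- unname(Y); Z <- unname(Z)
  fx <- labF(X / wp[1])
  fy <- labF(Y / wp[2])
  fz <- labF(Z / wp[3])
  list(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convert an RGB image to CIE a*b* chrominance
#'
#' Composition of the linear RGB-to-XYZ map and the L*a*b* transform; the
#' lightness channel L* is dropped and the chrominance pair (a*, b*) kept.
#'
#' @inheritParams rgbToNrgb
#' @param wp white point c(Xn, Yn, Zn).
#' @return a \code{\link{ChromImage}} with channels (a, b).
#' @export
rgbToLab <- function(img, wp = whitePointD65()) {
  xyz <- rgbToXyzRaw(img)
  lab <- xyzToLab(xyz[, , 1], xyz[, , 2], xyz[, , 3], wp)
  ChromImage(array(c(lab$a, lab$b), dim = c(dim(xyz)[1:2], 2L)), "lab")
}

#' Convert an RGB image to a chosen chrominance representation
#'
#' Dispatch wrapper over \code{\link{rgbToNrgb}}, \code{\link{rgbToHsv}},
#' \code{\link{rgbToXyz}} and \code{\link{rgbToLab}}.
#'
#' @inheritParams rgbToLab
#' @param space one of \code{"nrgb"}, \code{"hsv"}, \code{"xyz"},
#'   \code{"lab"}.
#' @return a \code{\link{ChromImage}}.
#' @export
convertColorSpace <- function(img, space, wp = whitePointD65()) {
  switch(match.arg(space, CHROM_SPACES),
    nrgb = rgbToNrgb(img),
    hsv  = rgbToHsv(img),
    xyz  = rgbToXyz(img),
    lab  = rgbToLab(img, wp))
}

#' Lift chrominance samples back to RGB
#'
#' Inverse mapping used by the synthetic-scene generator: given 2-column
#' chrominance samples and a fixed value for the removed intensity channel,
#' reconstruct RGB triples (clipped to [0, 1]).
#'
#' @param xy n x 2 matrix of chrominance samples.
#' @param space source colour space of the samples.
#' @param intensity the fixed removed component: channel sum R+G+B for nrgb,
#'   V for hsv, luminance Y for xyz, lightness L* for lab.
#' @param wp white point (lab only).
#' @return n x 3 RGB matrix in [0, 1].
#' @export
chromToRGB <- function(xy, space, intensity = NULL, wp = whitePointD65()) {
  xy <- as.matrix(xy)
  space <- match.arg(space, CHROM_SPACES)
  n <- nrow(xy)
  rgb <- switch(space,
    nrgb = {
      s <- if (is.null(intensity)) 1.5 else intensity
      b <- pmax(0, 1 - xy[, 1] - xy[, 2])
      cbind(xy[, 1], xy[, 2], b) * s
    },
    hsv = {
      v <- if (is.null(intensity)) 0.85 else intensity
      h <- pmin(pmax(xy[, 1], 0), 1) * 360
      s <- pmin(pmax(xy[, 2], 0), 1)
      hsvToRgb(h, s, rep(v, length.out = n))
    },
    xyz = {
      Y <- if (is.null(intensity)) 0.5 else intensity
      y <- pmax(xy[, 2], 1e-6)
      X <- xy[, 1] * Y / y
      Z <- pmax(0, 1 - xy[, 1] - xy[, 2]) * Y / y
      t(solve(RGB_TO_XYZ_MATRIX) %*% rbind(X, rep(Y, n), Z))
    },
    lab = {
      wp <- checkWhitePoint(wp)
      L <- if (is.null(intensity)) 65 else intensity
      fy <- (L + 16) / 116
      fx <- fy + xy[, 1] / 500
      fz <- fy - xy[, 2] / 200
      X <- labFInv(fx) * wp[1]
      Y <- labFInv(rep(fy, n)) * wp[2]
      Z <- labFInv(fz) * wp[3]
      t(solve(RGB_TO_XYZ_MATRIX) %*% rbind(X, Y, Z))
    })
  rgb <- pmin(pmax(rgb, 0), 1)
  dimnames(rgb) <- NULL
  rgb
}

# hexcone HSV -> RGB, h in degrees
hsvToRgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}
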