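#' Construct a Gaussian-mixture parameter object
#'
#' Convenience constructor used to specify ground-truth mixtures for the
#' synthetic generators and to assemble models by hand.
#'
#' @param priors component priors (rescaled to sum to one).
#' @param means J x 2 matrix of component means.
#' @param covariances 2 x 2 x J array, or a single 2 x 2 matrix recycled.
#' @param space colour-space tag.
#' @return a \code{\link{GMMParams}} object.
#' @export
gmmParams <- function(priors, means, covariances, space = "lab") {
  means <- as.matrix(means)
  J <- length(priors)
  if (is.matrix(covariances))
    covariances <- array(rep(covariances, J), dim = c(2, 2, J))
  g <- new("GMMParams", priors = priors / sum(priors), means = means,
           covariances = covariances, space = space,
           logLik = numeric(0), peak = 0)
  g@peak <- gmmPeak(g)
  g
}

#' Draw chrominance samples from a known mixture
#'
#' @param g a \code{\link{GMMParams}} ground-truth mixture.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return n x 2 matrix; the generating component of each row is attached
#'   as integer attribute \code{"component"} for recovery oracles.
#' @export
sampleMixture <- function(g, n, seed = 1L) {
  set.seed(seed)
  J <- length(g@priors)
  z <- sample.int(J, n, replace = TRUE, prob = g@priors)
  x <- matrix(0, n, 2)
  for (j in seq_len(J)) {
    k <- sum(z == j)
    if (k > 0)
      x[z == j, ] <- MASS::mvrnorm(k, g@means[j, ], g@covariances[, , j])
  }
  attr(x, "component") <- z
  x
}

#' Default chrominance mixtures for synthetic scenes
#'
#' Plausible skin and background chrominance clusters per colour space,
#' widely separated so that scenes built from them are separable by
#' construction. Values approximate where typical skin tones fall in each
#' plane (e.g. positive a*/b* in CIE L*a*b*, red-dominant r in nRGB).
#'
#' @param space colour-space tag.
#' @param class \code{"skin"} or \code{"background"}.
#' @return a \code{\link{GMMParams}}.
#' @export
defaultMixture <- function(space = "lab", class = c("skin", "background")) {
  class <- match.arg(class)
  space <- match.arg(space, CHROM_SPACES)
  p <- switch(space,
    lab = if (class == "skin")
      list(m = rbind(c(16, 20), c(24, 27)), s = diag(c(7, 7)))
    else
      list(m = rbind(c(-18, -22), c(-28, 8)), s = diag(c(12, 12))),
    nrgb = if (class == "skin")
      list(m = rbind(c(0.46, 0.31), c(0.50, 0.30)), s = diag(c(4e-4, 4e-4)))
    else
      list(m = rbind(c(0.26, 0.40), c(0.30, 0.25)), s = diag(c(8e-4, 8e-4))),
    hsv = if (class == "skin")
      list(m = rbind(c(0.045, 0.42), c(0.08, 0.50)), s = diag(c(4e-4, 1e-3)))
    else
      list(m = rbind(c(0.55, 0.55), c(0.35, 0.40)), s = diag(c(2e-3, 2e-3))),
    xyz = if (class == "skin")
      list(m = rbind(c(0.40, 0.335), c(0.42, 0.34)), s = diag(c(2e-4, 1e-4)))
    else
      list(m = rbind(c(0.28, 0.33), c(0.31, 0.40)), s = diag(c(4e-4, 4e-4))))
  gmmParams(c(0.5, 0.5), p$m, p$s, space = space)
}

ellipseShape <- function(cx, cy, rx, ry, angle = 0) {
  list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry, angle = angle)
}

# Five-finger hand: palm disc plus five elongated finger ellipses fanned
# around `angle`. A stylised silhouette, not an anatomical claim - it gives
# the elongated multi-branch topology a 2D graph should trace.
handShape <- function(cx, cy, r, angle = -pi / 2) {
  shapes <- list(ellipseShape(cx, cy, r, r))
  spread <- pi / 2.2
  for (k in 1:5) {
    th <- angle + spread * ((k - 3) / 4)
    fl <- r * ifelse(k == 1 || k == 5, 0.9, 1.3)
    fc <- c(cx + cos(th) * (r + fl * 0.45), cy + sin(th) * (r + fl * 0.45))
    shapes <- c(shapes, list(ellipseShape(fc[1], fc[2], fl * 0.55, r * 0.22,
                                          angle = th)))
  }
  shapes
}

shapeMask <- function(shapes, width, height) {
  X <- matrix(rep(seq_len(width), each = height), height, width)
  Y <- matrix(rep(seq_len(height), times = width), height, width)
  m <- matrix(FALSE, height, width)
  for (s in shapes) {
    dx <- X - s$cx; dy <- Y - s$cy
    u <- cos(s$angle) * dx + sin(s$angle) * dy
    v <- -sin(s$angle) * dx + cos(s$angle) * dy
    m <- m | ((u / s$rx)^2 + (v / s$ry)^2 <= 1)
  }
  m
}

#' Specify a synthetic face/hand scene
#'
#' Describes a scene with an elliptical "face", optionally a five-finger
#' "hand", a chosen number of non-skin clutter blobs, and the chrominance
#' mixtures the two pixel classes are drawn from. Foreground shapes must lie
#' within the image bounds.
#'
#' @param width,height image size in pixels.
#' @param shapes list of foreground shapes; default one face ellipse and one
#'   hand in the left and right halves.
#' @param skin,background ground-truth \code{\link{GMMParams}} in the same
#'   colour space.
#' @param clutter number of flat-coloured distractor blobs drawn from the
#'   background mixture (0 = plain background, 2+ = cluttered).
#' @param noiseSd RGB noise standard deviation added after lifting.
#' @param intensity fixed value of the removed intensity channel used to
#'   lift chrominance back to RGB (see \code{\link{chromToRGB}}).
#' @param seed RNG seed.
#' @return a list of class \code{"sceneSpec"}.
#' @export
sceneSpec <- function(width = 160L, height = 120L, shapes = NULL,
                      skin = defaultMixture("lab", "skin"),
                      background = defaultMixture("lab", "background"),
                      clutter = 0L, noiseSd = 0.01, intensity = NULL,
                      seed = 1L) {
  if (is.null(shapes))
    shapes <- c(list(ellipseShape(width * 0.26, height * 0.45,
                                  width * 0.13, height * 0.3)),
                handShape(width * 0.72, height * 0.62, height * 0.14))
  if (!identical(spaceTag(skin), spaceTag(background)))
    stop("skin and background mixtures must share a colour space")
  for (s in shapes)
    if (s$cx - s$rx < 0 || s$cx + s$rx > width + 1 ||
        s$cy - s$ry < 0 || s$cy + s$ry > height + 1)
      stop("foreground shape extends beyond the image bounds")
  structure(list(width = as.integer(width), height = as.integer(height),
                 shapes = shapes, skin = skin, background = background,
                 clutter = as.integer(clutter), noiseSd = noiseSd,
                 intensity = intensity, seed = seed), class = "sceneSpec")
}

#' Render a synthetic scene with its exact ground-truth mask
#'
#' Foreground pixels receive chrominance draws from the skin mixture and
#' background pixels from the background mixture; clutter blobs are flat
#' patches of background-mixture colour at jittered intensity. Chrominance
#' is lifted to RGB at a fixed intensity, noise added, channels clipped to
#' [0, 1]. The mask marks exactly the analytic foreground shapes.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @return list with \code{image} (H x W x 3 RGB), \code{mask} (logical
#'   H x W) and \code{spec}.
#' @export
renderScene <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"))
  W <- spec$width; H <- spec$height
  space <- spaceTag(spec$skin)
  mask <- shapeMask(spec$shapes, W, H)
  set.seed(spec$seed)
  nFg <- sum(mask); nBg <- H * W - nFg
  chrom <- matrix(0, H * W, 2)
  if (nFg > 0)
    chrom[as.vector(mask), ] <- sampleMixture(spec$skin, nFg,
                                              seed = spec$seed + 1L)
  chrom[!as.vector(mask), ] <- sampleMixture(spec$background, nBg,
                                             seed = spec$seed + 2L)
  inten <- rep(if (is.null(spec$intensity))
    switch(space, lab = 65, hsv = 0.85, nrgb = 1.5, xyz = 0.5)
    else spec$intensity, H * W)
  set.seed(spec$seed + 3L)
  if (spec$clutter > 0) {
    for (k in seq_len(spec$clutter)) {
      blob <- ellipseShape(runif(1, W * 0.1, W * 0.9), runif(1, H * 0.1, H * 0.9),
                           runif(1, W * 0.03, W * 0.1), runif(1, H * 0.03, H * 0.12),
                           runif(1, 0, pi))
      bm <- shapeMask(list(blob), W, H) & !mask
      if (!any(bm)) next
      flat <- sampleMixture(spec$background, 1, seed = spec$seed + 10L + k)
      chrom[as.vector(bm), 1] <- flat[1]
      chrom[as.vector(bm), 2] <- flat[2]
      inten[as.vector(bm)] <- inten[as.vector(bm)] * runif(1, 0.7, 1.3)
    }
  }
  # clutter jitters the lift intensity; recompute per distinct value
  if (length(unique(inten)) > 1L) {
    rgb <- matrix(0, H * W, 3)
    for (iv in unique(inten)) {
      sel <- inten == iv
      rgb[sel, ] <- chromToRGB(chrom[sel, , drop = FALSE], space, intensity = iv)
    }
  } else {
    rgb <- chromToRGB(chrom, space, intensity = inten[1])
  }
  if (spec$noiseSd > 0)
    rgb <- rgb + matrix(rnorm(length(rgb), 0, spec$noiseSd), nrow(rgb))
  rgb <- pmin(pmax(rgb, 0), 1)
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- rgb[, 1]; img[, , 2] <- rgb[, 2]; img[, , 3] <- rgb[, 3]
  list(image = img, mask = mask, spec = spec)
}

#' Sample a noisy coloured point cloud of known geometry
#'
#' Points lie on an analytic surface (unit-style sphere, face-like
#' ellipsoid, or a palm-and-fingers cylinder union) with Gaussian noise
#' along the surface normal and an optional fraction of uniform-box
#' outliers. The analytic surface distance is returned so reconstruction
#' error can be measured exactly.
#'
#' @param shape \code{"sphere"}, \code{"ellipsoid"} or \code{"hand"}.
#' @param n number of points (>= 10).
#' @param noiseSd normal-direction noise standard deviation.
#' @param outlierFrac fraction in [0, 0.5) replaced by box outliers.
#' @param radius sphere radius / overall scale.
#' @param colour either an RGB triple applied to all inliers, or
#'   \code{"height"} for a z-graded colouring; outliers are coloured grey.
#' @param seed RNG seed.
#' @return list with \code{points} (n x 3), \code{colours} (n x 3),
#'   \code{outlier} (logical), and \code{surfaceDistance}, a function
#'   mapping an m x 3 matrix to distances from the clean surface.
#' @export
sampleShape3D <- function(shape = c("sphere", "ellipsoid", "hand"), n = 2000L,
                          noiseSd = 0, outlierFrac = 0, radius = 1,
                          colour = c(0.91, 0.76, 0.65), seed = 1L) {
  shape <- match.arg(shape)
  if (n < 10L) stop("need at least 10 points")
  if (outlierFrac < 0 || outlierFrac >= 0.5)
    stop("outlier fraction must lie in [0, 0.5)")
  set.seed(seed)
  if (shape == "sphere") {
    axes <- c(radius, radius, radius)
  } else if (shape == "ellipsoid") {
    axes <- radius * c(0.8, 1.1, 0.7)
  }
  if (shape %in% c("sphere", "ellipsoid")) {
    dirs <- matrix(rnorm(3 * n), n, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs, 2, axes, `*`)
    if (noiseSd > 0) {
      grad <- sweep(pts, 2, axes^2, `/`)
      nrm <- grad / sqrt(rowSums(grad^2))
      pts <- pts + nrm * rnorm(n, 0, noiseSd)
    }
    surfaceDistance <- if (shape == "sphere") {
      function(p) abs(sqrt(rowSums(as.matrix(p)^2)) - radius)
    } else {
      # first-order implicit-surface distance |f| / |grad f|,
      # f(p) = sum((p/axes)^2) - 1
      function(p) {
        p <- as.matrix(p)
        f <- rowSums(sweep(p, 2, axes, `/`)^2) - 1
        g <- sqrt(rowSums((2 * sweep(p, 2, axes^2, `/`))^2))
        abs(f) / pmax(g, 1e-12)
      }
    }
  } else {
    # palm: vertical cylinder; fingers: five thin slanted cylinders on top
    cyl <- list(list(base = c(0, 0, 0), axis = c(0, 0, 1),
                     len = radius, r = radius * 0.35))
    for (k in 1:5) {
      th <- pi / 2 + (k - 3) * pi / 10
      ax <- c(cos(th) * 0.25, sin(th) * 0.25, 1)
      ax <- ax / sqrt(sum(ax^2))
      cyl <- c(cyl, list(list(base = c(cos(th), sin(th), 0) * radius * 0.25 +
                                c(0, 0, radius),
                              axis = ax, len = radius * 0.8, r = radius * 0.08)))
    }
    weights <- vapply(cyl, function(cc) cc$r * cc$len, numeric(1))
    pick <- sample.int(length(cyl), n, replace = TRUE, prob = weights)
    pts <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      cc <- cyl[[pick[i]]]
      t0 <- runif(1, 0, cc$len)
      phi <- runif(1, 0, 2 * pi)
      u <- if (abs(cc$axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- u - sum(u * cc$axis) * cc$axis
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(cc$axis[2] * e1[3] - cc$axis[3] * e1[2],
              cc$axis[3] * e1[1] - cc$axis[1] * e1[3],
              cc$axis[1] * e1[2] - cc$axis[2] * e1[1])
      rr <- cc$r + if (noiseSd > 0) rnorm(1, 0, noiseSd) else 0
      pts[i, ] <- cc$base + t0 * cc$axis + rr * (cos(phi) * e1 + sin(phi) * e2)
    }
    surfaceDistance <- function(p) {
      p <- as.matrix(p)
      dmin <- rep(Inf, nrow(p))
      for (cc in cyl) {
        rel <- sweep(p, 2, cc$base)
        t0 <- pmin(pmax(rel %*% cc$axis, 0), cc$len)
        ax <- outer(as.vector(t0), cc$axis)
        rad <- sqrt(rowSums((rel - ax)^2))
        dmin <- pmin(dmin, abs(rad - cc$r))
      }
      dmin
    }
  }
  out <- rep(FALSE, n)
  nOut <- round(n * outlierFrac)
  if (nOut > 0) {
    out[sample.int(n, nOut)] <- TRUE
    lim <- 2 * (radius + max(abs(pts)))
    pts[out, ] <- matrix(runif(3 * nOut, -lim / 2, lim / 2), nOut, 3)
  }
  cols <- if (identical(colour, "height")) {
    z <- (pts[, 3] - min(pts[, 3])) / max(diff(range(pts[, 3])), 1e-12)
    cbind(z, 0.4 + 0.2 * z, 1 - z)
  } else {
    matrix(rep(colour, each = n), n, 3)
  }
  cols[out, ] <- 0.5
  list(points = pts, colours = cols, outlier = out,
       surfaceDistance = surfaceDistance,
       spec = list(shape = shape, n = n, noiseSd = noiseSd,
                   outlierFrac = outlierFrac, radius = radius, seed = seed))
}
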