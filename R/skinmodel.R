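# Covariance floor: Eq-7-style densities need full-rank covariances, so a
# scaled identity ridge is added whenever the smallest eigenvalue degenerates.
regulariseCov <- function(S, warn = TRUE) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    eps <- 1e-6 * sum(diag(S)) / 2
    if (eps <= 0) eps <- 1e-10  # all-identical samples: absolute floor
    S <- S + diag(eps, 2)
    if (warn) warning("singular covariance regularised with a small ridge")
  }
  S
}

# (2s+1) x (2s+1) box mean filter with zero padding
boxSmooth <- function(m, s = 2L) {
  out <- matrix(0, nrow(m), ncol(m))
  for (di in -s:s) for (dj in -s:s) {
    src <- m[max(1, 1 - di):min(nrow(m), nrow(m) - di),
             max(1, 1 - dj):min(ncol(m), ncol(m) - dj), drop = FALSE]
    out[max(1, 1 + di):min(nrow(m), nrow(m) + di),
        max(1, 1 + dj):min(ncol(m), ncol(m) + dj)] <-
      out[max(1, 1 + di):min(nrow(m), nrow(m) + di),
          max(1, 1 + dj):min(ncol(m), ncol(m) + dj)] + src
  }
  out / (2 * s + 1)^2
}

asSamples <- function(x) {
  if (is(x, "ChromImage")) x <- chromPixels(x)
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("chrominance samples must have exactly 2 columns")
  if (anyNA(x) || any(!is.finite(x))) stop("samples must be finite")
  x
}

#' Flatten a chrominance image to a sample matrix
#'
#' Extracts the per-pixel 2-vectors as model-fitting observations, optionally
#' restricted to a mask and subsampled to a cap (half a million pixels is
#' plenty for a 2-D Gaussian mixture and keeps EM fast).
#'
#' @param img a \code{\link{ChromImage}}.
#' @param mask optional logical/0-1 matrix of the image size selecting pixels.
#' @param cap maximum number of samples retained (seeded subsampling beyond).
#' @param seed RNG seed for the subsampling draw.
#' @return T x 2 numeric matrix of observations.
#' @export
chromPixels <- function(img, mask = NULL, cap = 5e5, seed = 1L) {
  a <- chromData(img)
  m <- cbind(as.vector(a[, , 1]), as.vector(a[, , 2]))
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(a)[1:2])) stop("mask dimensions must match image")
    m <- m[as.logical(as.vector(mask)), , drop = FALSE]
  }
  if (nrow(m) > cap) {
    set.seed(seed)
    m <- m[sample.int(nrow(m), cap), , drop = FALSE]
  }
  m
}

#' Fit a single-Gaussian chrominance model
#'
#' Maximum-likelihood estimates: the sample mean and the biased (1/T)
#' covariance of the observations. Degenerate covariances are ridged.
#'
#' @param x T x 2 sample matrix (rows are chrominance observations) or a
#'   \code{ChromImage}.
#' @param space colour-space tag recorded on the model (taken from \code{x}
#'   when it is a \code{ChromImage}).
#' @return an \code{\link{SGMParams}} object.
#' @export
fitSGM <- function(x, space = if (is(x, "ChromImage")) spaceTag(x) else "lab") {
  x <- asSamples(x)
  T <- nrow(x)
  if (T < 3L) stop("need at least 3 observations (d + 1) to estimate a covariance")
  mu <- colMeans(x)
  d <- sweep(x, 2, mu)
  sigma <- crossprod(d) / T
  sigma <- regulariseCov(sigma)
  p <- new("SGMParams", mu = mu, sigma = sigma, space = space, peak = 0)
  p@peak <- sgmDensity(matrix(mu, 1), p)
  p
}

#' Squared Mahalanobis distance to a single-Gaussian model
#'
#' @param x length-2 vector or n x 2 matrix of observations.
#' @param p an \code{\link{SGMParams}} object.
#' @return non-negative numeric vector of squared distances.
#' @export
mahalanobisSq <- function(x, p) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  stats::mahalanobis(x, p@mu, p@sigma)
}

logGaussDensity <- function(x, mu, sigma) {
  d2 <- stats::mahalanobis(x, mu, sigma)
  det <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  -log(2 * pi) - 0.5 * log(det) - 0.5 * d2
}

#' Bivariate normal density of a single-Gaussian model
#'
#' @inheritParams mahalanobisSq
#' @return density values (2-D normal, so the peak is
#'   \eqn{(2\pi)^{-1}\det(\Sigma)^{-1/2}}).
#' @export
sgmDensity <- function(x, p) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  exp(logGaussDensity(x, p@mu, p@sigma))
}

gmmLogComponents <- function(x, g) {
  J <- length(g@priors)
  out <- matrix(0, nrow(x), J)
  for (j in seq_len(J))
    out[, j] <- logGaussDensity(x, g@means[j, ], g@covariances[, , j]) +
      log(g@priors[j])
  out
}

logSumExpRows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Gaussian-mixture density
#'
#' Weighted sum of the component normal densities, evaluated in the log
#' domain so outlying observations never underflow to an undefined posterior.
#'
#' @param x length-2 vector or n x 2 matrix of observations.
#' @param g a \code{\link{GMMParams}} object.
#' @return density values.
#' @export
gmmDensity <- function(x, g) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  exp(logSumExpRows(gmmLogComponents(x, g)))
}

#' Histogram-seeded initial mixture
#'
#' Builds a 2-D chrominance histogram, smooths it with a small box filter to
#' tame bin-count noise, and seeds component means at the J strongest modes
#' that are at least \code{minSep} bins apart (Chebyshev distance). When the
#' data carry fewer separated modes than J, the separation is halved until
#' enough are found; only truly coincident data fail. Priors start equal and
#' every covariance starts at the global sample covariance divided by J.
#'
#' @param x T x 2 sample matrix or \code{ChromImage}.
#' @param J number of mixture components.
#' @param space colour-space tag for the model.
#' @param bins histogram resolution per axis.
#' @param minSep preferred minimum mode separation in bins; a strong
#'   separation keeps the seeds from landing in one noisy cluster.
#' @param seed RNG seed (initialisation is deterministic; the seed is set for
#'   parity with the stochastic fitters).
#' @return a \code{\link{GMMParams}} object (untrained: empty likelihood
#'   trace).
#' @export
initGMM <- function(x, J, space = if (is(x, "ChromImage")) spaceTag(x) else "lab",
                    bins = 64L, minSep = 8L, seed = 1L) {
  x <- asSamples(x)
  if (nrow(x) < 3L * J) stop("need at least 3*J observations")
  set.seed(seed)
  rng1 <- range(x[, 1]); rng2 <- range(x[, 2])
  if (diff(rng1) == 0) rng1 <- rng1 + c(-0.5, 0.5)
  if (diff(rng2) == 0) rng2 <- rng2 + c(-0.5, 0.5)
  b1 <- pmin(pmax(findInterval(x[, 1], seq(rng1[1], rng1[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  b2 <- pmin(pmax(findInterval(x[, 2], seq(rng2[1], rng2[2], length.out = bins + 1),
                               rightmost.closed = TRUE), 1L), bins)
  counts <- unclass(table(factor(b1, levels = 1:bins), factor(b2, levels = 1:bins)))
  smooth <- boxSmooth(counts, 2L)
  smooth[counts == 0] <- 0  # only occupied bins are mode candidates
  occ <- which(smooth > 0, arr.ind = TRUE)
  occ <- occ[order(smooth[occ], decreasing = TRUE), , drop = FALSE]
  chosen <- matrix(0L, 0, 2)
  sep <- as.integer(minSep)
  while (sep >= 1L) {
    chosen <- matrix(0L, 0, 2)
    for (r in seq_len(nrow(occ))) {
      if (nrow(chosen) == J) break
      cand <- occ[r, ]
      if (nrow(chosen) == 0 ||
          all(pmax(abs(chosen[, 1] - cand[1]), abs(chosen[, 2] - cand[2])) >= sep))
        chosen <- rbind(chosen, cand)
    }
    if (nrow(chosen) == J) break
    sep <- sep %/% 2L
  }
  if (nrow(chosen) < J)
    stop(sprintf("only %d separated occupied histogram modes; choose J <= %d",
                 nrow(chosen), nrow(chosen)))
  ctr1 <- rng1[1] + (chosen[, 1] - 0.5) * diff(rng1) / bins
  ctr2 <- rng2[1] + (chosen[, 2] - 0.5) * diff(rng2) / bins
  globalS <- regulariseCov(stats::cov(x) * (nrow(x) - 1) / nrow(x), warn = FALSE)
  covs <- array(0, dim = c(2, 2, J))
  for (j in seq_len(J)) covs[, , j] <- regulariseCov(globalS / J, warn = FALSE)
  new("GMMParams", priors = rep(1 / J, J),
      means = cbind(ctr1, ctr2, deparse.level = 0),
      covariances = covs, space = space, logLik = numeric(0), peak = 0)
}

#' EM expectation step
#'
#' Posterior component memberships for each observation under the current
#' mixture, computed with log-sum-exp so no row can divide by zero.
#'
#' @param x T x 2 sample matrix or \code{ChromImage}.
#' @param g current \code{\link{GMMParams}}.
#' @return T x J responsibility matrix; rows sum to one. The total data
#'   log-likelihood is attached as attribute \code{"logLik"}.
#' @export
emEStep <- function(x, g) {
  x <- asSamples(x)
  lc <- gmmLogComponents(x, g)
  lse <- logSumExpRows(lc)
  h <- exp(lc - lse)
  attr(h, "logLik") <- sum(lse)
  h
}

#' EM maximisation step
#'
#' Closed-form updates: responsibility-weighted means, weighted scatter about
#' the new means, and priors equal to mean responsibility. A component whose
#' total responsibility collapses below 1e-6 T is re-seeded at the worst
#' explained observation.
#'
#' @param x T x 2 sample matrix or \code{ChromImage}.
#' @param h T x J responsibility matrix (rows summing to one).
#' @param space colour-space tag for the updated model.
#' @param current optional current \code{GMMParams}; enables the
#'   lowest-likelihood re-seed rule for empty components.
#' @return updated \code{\link{GMMParams}}.
#' @export
emMStep <- function(x, h, space = "lab", current = NULL) {
  x <- asSamples(x)
  h <- as.matrix(h)
  T <- nrow(x)
  J <- ncol(h)
  if (any(abs(rowSums(h) - 1) > 1e-6)) stop("responsibility rows must sum to 1")
  tot <- colSums(h)
  empty <- tot < 1e-6 * T
  means <- matrix(0, J, 2)
  covs <- array(0, dim = c(2, 2, J))
  priors <- tot / T
  globalS <- regulariseCov(stats::cov(x) * (T - 1) / T, warn = FALSE)
  for (j in seq_len(J)) {
    if (empty[j]) next
    means[j, ] <- colSums(h[, j] * x) / tot[j]
    d <- sweep(x, 2, means[j, ])
    covs[, , j] <- regulariseCov(crossprod(d * h[, j], d) / tot[j], warn = FALSE)
  }
  if (any(empty)) {
    warning(sprintf("%d empty mixture component(s) re-seeded", sum(empty)))
    ll <- if (!is.null(current)) logSumExpRows(gmmLogComponents(x, current))
          else -apply(h, 1, max)  # fall back: least decisively assigned
    for (j in which(empty)) {
      worst <- which.min(ll)
      means[j, ] <- x[worst, ]
      covs[, , j] <- globalS
      priors[j] <- 1 / J
      ll[worst] <- Inf
    }
    priors <- priors / sum(priors)
  }
  new("GMMParams", priors = priors, means = means, covariances = covs,
      space = space, logLik = numeric(0), peak = 0)
}

gmmPeak <- function(g) {
  max(gmmDensity(g@means, g))
}

#' Fit a Gaussian mixture by expectation-maximisation
#'
#' Histogram initialisation followed by alternating E and M steps until the
#' relative log-likelihood change drops below \code{tol} or \code{maxIter}
#' iterations have run. The per-iteration log-likelihood trace is kept on the
#' returned model; EM guarantees it is non-decreasing.
#'
#' @param x T x 2 sample matrix or \code{ChromImage}.
#' @param J number of components (single-component fits reproduce
#'   \code{\link{fitSGM}} exactly).
#' @param space colour-space tag.
#' @param maxIter iteration cap (the quick-look preset in the literature is
#'   5; the default 100 lets small mixtures converge fully).
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed RNG seed passed to the initialiser.
#' @return a fitted \code{\link{GMMParams}} with \code{logLik} trace.
#' @export
fitGMM <- function(x, J = 3L, space = if (is(x, "ChromImage")) spaceTag(x) else "lab",
                   maxIter = 100L, tol = 1e-6, seed = 1L) {
  x <- asSamples(x)
  g <- initGMM(x, J, space = space, seed = seed)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    h <- emEStep(x, g)
    ll <- attr(h, "logLik")
    g <- emMStep(x, h, space = space, current = g)
    trace <- c(trace, ll)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <
          tol * max(abs(trace[it - 1]), 1e-12)) break
  }
  g@logLik <- trace
  g@peak <- gmmPeak(g)
  g
}

modelDensity <- function(model, x) {
  if (is(model, "SGMParams")) sgmDensity(x, model) else gmmDensity(x, model)
}

modelPeak <- function(model) {
  if (model@peak > 0) model@peak
  else if (is(model, "SGMParams")) sgmDensity(matrix(model@mu, 1), model)
  else gmmPeak(model)
}

#' Per-pixel skin probability map
#'
#' With only a skin model, the map is the skin density divided by the model's
#' peak density (clipped to 1) so that the conventional fixed threshold 0.55
#' operates on a [0, 1] scale. With a background model as well, the map is
#' the equal-prior class posterior p_skin / (p_skin + p_background).
#'
#' @param img a \code{\link{ChromImage}}.
#' @param skin fitted \code{SGMParams} or \code{GMMParams} for skin.
#' @param background optional model of the non-skin class.
#' @return H x W numeric matrix of scores in [0, 1].
#' @export
probabilityMap <- function(img, skin, background = NULL) {
  if (!identical(spaceTag(img), spaceTag(skin)))
    stop(sprintf("image is in '%s' but the skin model was fitted in '%s'",
                 spaceTag(img), spaceTag(skin)))
  a <- chromData(img)
  x <- cbind(as.vector(a[, , 1]), as.vector(a[, , 2]))
  ps <- modelDensity(skin, x)
  if (is.null(background)) {
    v <- pmin(ps / modelPeak(skin), 1)
  } else {
    if (!identical(spaceTag(img), spaceTag(background)))
      stop("background model colour space does not match the image")
    pb <- modelDensity(background, x)
    denom <- ps + pb
    v <- ifelse(denom > 0, ps / denom, 0.5)
  }
  matrix(v, dim(a)[1], dim(a)[2])
}

#' Threshold a probability map into a binary mask
#'
#' @param pm H x W probability map in [0, 1].
#' @param tau threshold in [0, 1]; pixels with score >= tau become skin. The
#'   default 0.55 is the conventional mid-range operating point.
#' @return logical H x W mask.
#' @export
thresholdMap <- function(pm, tau = 0.55) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  pm >= tau
}
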