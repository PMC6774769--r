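#' Growing-neural-gas learning parameters
#'
#' All parameters are constant during learning. Defaults are the widely used
#' values for incremental topology learning; every one is exposed because the
#' right capacity and insertion cadence depend on the input distribution.
#'
#' @param maxNodes capacity: learning inserts no neuron beyond this count.
#' @param lambda number of processed signals between insertions.
#' @param epsB winner adaptation step size.
#' @param epsN topological-neighbour adaptation step size.
#' @param alpha error decay applied to the two anchor neurons at insertion.
#' @param beta global per-signal error decay.
#' @param ageMax edges older than this are removed.
#' @return validated list of class \code{"gngConfig"}.
#' @export
gngConfig <- function(maxNodes = 200L, lambda = 100L, epsB = 0.1,
                      epsN = 0.005, alpha = 0.5, beta = 0.0005, ageMax = 50L) {
  stopifnot(maxNodes >= 2, lambda >= 1, ageMax >= 1,
            epsB > 0, epsB < 1, epsN > 0, epsN <= epsB,
            alpha > 0, alpha < 1, beta > 0, beta < 1)
  structure(list(maxNodes = as.integer(maxNodes), lambda = as.integer(lambda),
                 epsB = epsB, epsN = epsN, alpha = alpha, beta = beta,
                 ageMax = as.integer(ageMax)), class = "gngConfig")
}

asCloud <- function(samples) {
  samples <- as.matrix(samples)
  if (anyNA(samples) || any(!is.finite(samples))) stop("samples must be finite")
  samples
}

newGNG <- function(positions, errors, colours, edges, ages, nSignals, cfg) {
  if (length(edges) == 0) edges <- matrix(integer(0), 0, 2)
  new("GNG", positions = positions, errors = as.numeric(errors),
      colours = if (is.null(colours) || nrow(colours) == 0)
        matrix(numeric(0), 0, 3) else colours,
      edges = matrix(as.integer(edges), ncol = 2),
      ages = as.integer(ages), nSignals = nSignals, config = unclass(cfg))
}

#' Initialise a two-neuron topology graph
#'
#' Places the two starting prototypes at seeded-random positions drawn from
#' the input samples, with an empty edge set.
#'
#' @param samples n x d matrix of input vectors (rows), n >= 2.
#' @param cfg a \code{\link{gngConfig}}.
#' @param colours optional n x 3 RGB per sample; enables colour tracking.
#' @param seed RNG seed.
#' @return a \code{\link{GNG}} with 2 neurons and no edges.
#' @export
gngInit <- function(samples, cfg = gngConfig(), colours = NULL, seed = 1L) {
  samples <- asCloud(samples)
  if (nrow(samples) < 2L) stop("need at least 2 input samples")
  set.seed(seed)
  idx <- sample.int(nrow(samples), 2L)
  newGNG(samples[idx, , drop = FALSE], c(0, 0),
         if (is.null(colours)) NULL else colours[idx, , drop = FALSE],
         matrix(integer(0), 0, 2), integer(0), 0, cfg)
}

edgeIndex <- function(g, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  which(pmin(g@edges[, 1], g@edges[, 2]) == lo &
        pmax(g@edges[, 1], g@edges[, 2]) == hi)
}

neighboursOf <- function(g, i) {
  if (nrow(g@edges) == 0) return(integer(0))
  sort(unique(c(g@edges[g@edges[, 2] == i, 1], g@edges[g@edges[, 1] == i, 2])))
}

#' One competitive-Hebbian adaptation step
#'
#' Processes a single input signal: accumulates the winner's squared error,
#' moves the winner (step \code{epsB}) and its topological neighbours
#' (step \code{epsN}) towards the signal, refreshes/creates the
#' winner-runner-up edge, ages the winner's other edges, removes stale edges,
#' and drops neurons left without edges. Equidistant candidates resolve to
#' the lowest neuron index for determinism.
#'
#' @param g a \code{\link{GNG}} graph with at least two neurons.
#' @param signal input vector of the graph's dimension.
#' @param colour optional RGB triple blended into the winner's colour.
#' @return the updated \code{\link{GNG}}.
#' @export
gngAdapt <- function(g, signal, colour = NULL) {
  cfg <- g@config
  d2 <- colSums((t(g@positions) - signal)^2)
  s1 <- which.min(d2)
  d1 <- d2[s1]
  d2[s1] <- Inf
  s2 <- which.min(d2)
  g@errors[s1] <- g@errors[s1] + d1
  nb <- neighboursOf(g, s1)
  for (j in nb)
    g@positions[j, ] <- g@positions[j, ] + cfg$epsN * (signal - g@positions[j, ])
  g@positions[s1, ] <- g@positions[s1, ] + cfg$epsB * (signal - g@positions[s1, ])
  if (!is.null(colour) && nrow(g@colours) > 0)
    g@colours[s1, ] <- g@colours[s1, ] + cfg$epsB * (colour - g@colours[s1, ])
  # age other incident edges, then refresh winner-runner-up
  inc <- setdiff(nb, s2)
  drop <- integer(0)
  for (j in inc) {
    e <- edgeIndex(g, s1, j)
    g@ages[e] <- g@ages[e] + 1L
    if (g@ages[e] > cfg$ageMax) drop <- c(drop, e)
  }
  touched <- integer(0)
  if (length(drop)) {
    touched <- setdiff(as.vector(g@edges[drop, , drop = FALSE]), s1)
    g@edges <- g@edges[-drop, , drop = FALSE]
    g@ages <- g@ages[-drop]
  }
  e <- edgeIndex(g, s1, s2)
  if (length(e)) g@ages[e] <- 0L
  else {
    g@edges <- rbind(g@edges, c(min(s1, s2), max(s1, s2)))
    g@ages <- c(g@ages, 0L)
  }
  dead <- touched[vapply(touched, function(j) length(neighboursOf(g, j)) == 0L,
                         logical(1))]
  if (length(dead)) g <- removeNodes(g, dead)
  g@nSignals <- g@nSignals + 1
  g
}

removeNodes <- function(g, dead) {
  keep <- setdiff(seq_len(nrow(g@positions)), dead)
  remap <- integer(nrow(g@positions))
  remap[keep] <- seq_along(keep)
  g@positions <- g@positions[keep, , drop = FALSE]
  g@errors <- g@errors[keep]
  if (nrow(g@colours) > 0) g@colours <- g@colours[keep, , drop = FALSE]
  if (nrow(g@edges) > 0) {
    g@edges <- matrix(remap[g@edges], ncol = 2)
    g@ages <- g@ages
  }
  g
}

#' Insert a neuron near the highest-error region
#'
#' The new prototype lands midway between the maximal-error neuron q and its
#' maximal-error neighbour f; the q-f edge is replaced by q-r and f-r, the
#' anchor errors decay by \code{alpha}, and the newcomer inherits q's decayed
#' error. An isolated q pairs with the globally next-highest-error neuron.
#'
#' @param g a \code{\link{GNG}} graph.
#' @return the updated \code{\link{GNG}} with one more neuron.
#' @export
gngInsert <- function(g) {
  cfg <- g@config
  if (nrow(g@positions) >= cfg$maxNodes) return(g)
  q <- which.max(g@errors)
  nb <- neighboursOf(g, q)
  f <- if (length(nb)) nb[which.max(g@errors[nb])]
       else {
         others <- setdiff(seq_len(nrow(g@positions)), q)
         others[which.max(g@errors[others])]
       }
  r <- nrow(g@positions) + 1L
  g@positions <- rbind(g@positions, (g@positions[q, ] + g@positions[f, ]) / 2)
  if (nrow(g@colours) > 0)
    g@colours <- rbind(g@colours, (g@colours[q, ] + g@colours[f, ]) / 2)
  e <- edgeIndex(g, q, f)
  if (length(e)) {
    g@edges <- g@edges[-e, , drop = FALSE]
    g@ages <- g@ages[-e]
  }
  g@edges <- rbind(g@edges, c(min(q, r), max(q, r)), c(min(f, r), max(f, r)))
  g@ages <- c(g@ages, 0L, 0L)
  g@errors[q] <- g@errors[q] * cfg$alpha
  g@errors[f] <- g@errors[f] * cfg$alpha
  g@errors <- c(g@errors, g@errors[q])
  g
}

#' Learn a topology-preserving graph from an input distribution
#'
#' Repeats \code{\link{gngAdapt}} over seeded with-replacement draws from the
#' sample set, inserting a neuron every \code{lambda} signals while below
#' \code{maxNodes} and decaying all errors by \code{1 - beta} after every
#' signal. Runs in compiled code; a fixed seed gives a bit-identical graph.
#'
#' @param samples n x d input matrix (d = 2 or 3).
#' @param cfg a \code{\link{gngConfig}}.
#' @param nSignals total number of signals to process.
#' @param colours optional n x 3 RGB per sample, tracked per neuron as an
#'   exponential running average with the winner step size.
#' @param seed RNG seed controlling initial prototypes and signal order.
#' @param checkInvariants verify graph validity after every signal (testing
#'   aid); any violation count is attached as attribute
#'   \code{"violations"}.
#' @return a learned \code{\link{GNG}}.
#' @export
gngLearn <- function(samples, cfg = gngConfig(), nSignals = 10000L,
                     colours = NULL, seed = 1L, checkInvariants = FALSE) {
  samples <- asCloud(samples)
  if (nrow(samples) < 2L) stop("need at least 2 input samples")
  if (!is.null(colours)) {
    colours <- as.matrix(colours)
    stopifnot(nrow(colours) == nrow(samples), ncol(colours) == 3L)
  }
  set.seed(seed)
  initIdx <- sample.int(nrow(samples), 2L)
  ord <- sample.int(nrow(samples), nSignals, replace = TRUE)
  res <- gng_core(samples, ord, initIdx, colours,
                  cfg$maxNodes, cfg$lambda, cfg$epsB, cfg$epsN,
                  cfg$alpha, cfg$beta, cfg$ageMax, checkInvariants)
  g <- newGNG(res$positions, res$errors,
              if (is.null(colours)) NULL else res$colours,
              res$edges, res$ages, res$nSignals, cfg)
  if (checkInvariants) attr(g, "violations") <- res$violations
  g
}

# Pure-R reference learner mirroring the compiled loop exactly (same draws,
# same update order); kept internal as the oracle for the C++ core.
gngLearnR <- function(samples, cfg, nSignals, colours = NULL, seed = 1L) {
  samples <- asCloud(samples)
  set.seed(seed)
  idx <- sample.int(nrow(samples), 2L)
  ord <- sample.int(nrow(samples), nSignals, replace = TRUE)
  g <- newGNG(samples[idx, , drop = FALSE], c(0, 0),
              if (is.null(colours)) NULL else colours[idx, , drop = FALSE],
              matrix(integer(0), 0, 2), integer(0), 0, cfg)
  for (t in seq_len(nSignals)) {
    s <- ord[t]
    g <- gngAdapt(g, samples[s, ],
                  if (is.null(colours)) NULL else colours[s, ])
    if (t %% cfg$lambda == 0 && nrow(g@positions) < cfg$maxNodes)
      g <- gngInsert(g)
    g@errors <- g@errors * (1 - cfg$beta)
  }
  g
}

#' Mean quantisation error of a graph over samples
#'
#' Mean squared Euclidean distance from each sample to its nearest neuron;
#' the quantity whose local accumulation drives insertion.
#'
#' @param g a \code{\link{GNG}}.
#' @param samples n x d matrix.
#' @return non-negative scalar.
#' @export
gngQuantisationError <- function(g, samples) {
  samples <- asCloud(samples)
  p <- g@positions
  mins <- rep(Inf, nrow(samples))
  for (i in seq_len(nrow(p)))
    mins <- pmin(mins, colSums((t(samples) - p[i, ])^2))
  mean(mins)
}

#' Connected components of a topology graph
#'
#' @param g a \code{\link{GNG}}.
#' @return integer vector of component labels (1-based), one per neuron;
#'   the number of components is \code{max} of the labels.
#' @export
gngComponents <- function(g) {
  n <- nrow(g@positions)
  adj <- vector("list", n)
  if (nrow(g@edges) > 0)
    for (r in seq_len(nrow(g@edges))) {
      a <- g@edges[r, 1]; b <- g@edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  lab <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    comp <- comp + 1L
    queue <- i
    lab[i] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!lab[u]) { lab[u] <- comp; queue <- c(queue, u) }
    }
  }
  lab
}

#' Learn the 2D topology of a binary mask
#'
#' Treats the foreground pixels as a uniform distribution over their centre
#' coordinates, normalised to the unit square, and learns a graph over it.
#' Well-separated blobs end up as separate connected components because
#' edges only ever form between a winner and its runner-up.
#'
#' @param mask logical/0-1 matrix; needs at least 2 foreground pixels.
#' @param cfg a \code{\link{gngConfig}} (2D default capacity).
#' @param nSignals signals to process.
#' @param seed RNG seed.
#' @return a \code{\link{GNG}} in [0, 1]^2 (x = column, y = row fraction).
#' @export
learnFromMask <- function(mask, cfg = gngConfig(maxNodes = 200L),
                          nSignals = 20000L, seed = 1L) {
  mask <- as.matrix(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) stop("mask needs at least 2 foreground pixels")
  pts <- cbind((idx[, 2] - 0.5) / ncol(mask), (idx[, 1] - 0.5) / nrow(mask))
  gngLearn(pts, cfg, nSignals = nSignals, seed = seed)
}

#' Triangulate a learned graph into a coloured mesh
#'
#' Faces are exactly the 3-cliques of the edge set: triangles are completed
#' where three neurons are mutually connected and nowhere else, so meshes of
#' partial views stay open rather than being hallucinated shut.
#'
#' @param g a 3D \code{\link{GNG}}.
#' @return a \code{\link{ColouredMesh}}.
#' @export
gngMesh <- function(g) {
  n <- nrow(g@positions)
  adj <- vector("list", n)
  if (nrow(g@edges) > 0)
    for (r in seq_len(nrow(g@edges))) {
      a <- g@edges[r, 1]; b <- g@edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  faces <- matrix(integer(0), 0, 3)
  if (nrow(g@edges) > 0)
    for (r in seq_len(nrow(g@edges))) {
      a <- g@edges[r, 1]; b <- g@edges[r, 2]
      common <- intersect(adj[[a]], adj[[b]])
      common <- common[common > b]  # each triangle reported once (a < b < c)
      if (a < b) for (cc in common) faces <- rbind(faces, c(a, b, cc))
    }
  cols <- if (nrow(g@colours) > 0) g@colours else matrix(0.5, n, 3)
  new("ColouredMesh", vertices = g@positions, colours = cols,
      edges = g@edges, faces = matrix(as.integer(faces), ncol = 3))
}

#' Reconstruct a coloured mesh from a 3D point cloud
#'
#' Learns a 3D topology graph over the points, tracking per-neuron colour as
#' a running average of the colours of the signals each neuron wins, then
#' completes triangles among mutually connected triples. Sparse outliers
#' attract few or no prototypes, so the reconstruction adheres to the dense
#' surface.
#'
#' @param points n x 3 matrix.
#' @param colours optional n x 3 RGB in [0, 1].
#' @param cfg a \code{\link{gngConfig}} (3D capacity, e.g. 500-1000 nodes).
#' @param nSignals signals to process; needs about
#'   \code{lambda * maxNodes} to reach full capacity.
#' @param seed RNG seed.
#' @return a \code{\link{ColouredMesh}}; the underlying graph is attached as
#'   attribute \code{"gng"}.
#' @export
learnPointCloud <- function(points, colours = NULL,
                            cfg = gngConfig(maxNodes = 1000L),
                            nSignals = NULL, seed = 1L) {
  points <- asCloud(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (is.null(nSignals)) nSignals <- cfg$lambda * cfg$maxNodes
  g <- gngLearn(points, cfg, nSignals = nSignals, colours = colours, seed = seed)
  m <- gngMesh(g)
  attr(m, "gng") <- g
  m
}

#' Normalise a structured-light sensor disparity value
#'
#' Maps the device's raw disparity kd to the normalised disparity
#' d = (d_off - kd) / 8, where d_off is a per-device calibration offset.
#'
#' @param kd raw disparity value(s).
#' @param dOff device offset (calibration-dependent; 1090 is a common value).
#' @return normalised disparity, same shape as \code{kd}.
#' @export
normaliseDisparity <- function(kd, dOff = 1090) {
  (dOff - kd) / 8
}

#' Back-project a depth image to a 3D point cloud
#'
#' Standard pinhole geometry: a pixel (row, col) with depth z maps to
#' x = (col - cx) z / fx, y = (row - cy) z / fy. Zero-depth pixels are
#' dropped; colours are attached from an aligned RGB image when given.
#'
#' @param depth H x W matrix of depths (zero = missing).
#' @param intrinsics list with fx, fy, cx, cy (pixels, 1-based centre).
#' @param rgb optional H x W x 3 RGB array aligned with \code{depth}.
#' @param mask optional H x W logical mask restricting the projection.
#' @return list with \code{points} (n x 3) and \code{colours} (n x 3 or
#'   NULL).
#' @export
depthToPointCloud <- function(depth, intrinsics, rgb = NULL, mask = NULL) {
  depth <- as.matrix(depth)
  stopifnot(all(c("fx", "fy", "cx", "cy") %in% names(intrinsics)))
  if (any(intrinsics$fx <= 0, intrinsics$fy <= 0))
    stop("focal lengths must be positive")
  keep <- depth > 0
  if (!is.null(mask)) keep <- keep & (as.matrix(mask) != 0)
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no pixels with positive depth; empty point cloud")
    return(list(points = matrix(numeric(0), 0, 3), colours = NULL))
  }
  z <- depth[keep]
  x <- (idx[, 2] - intrinsics$cx) * z / intrinsics$fx
  y <- (idx[, 1] - intrinsics$cy) * z / intrinsics$fy
  cols <- NULL
  if (!is.null(rgb)) {
    rgb <- checkRGB(rgb)
    cols <- cbind(rgb[, , 1][keep], rgb[, , 2][keep], rgb[, , 3][keep])
  }
  list(points = cbind(x = x, y = y, z = z), colours = cols)
}
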