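#' @import methods
#' @importFrom stats rnorm runif quantile median cov
#' @importFrom Rcpp sourceCpp
#' @useDynLib SkinGNG, .registration = TRUE
NULL

CHROM_SPACES <- c("nrgb", "hsv", "xyz", "lab")

CHROM_CHANNELS <- list(
  nrgb = c("r", "g"),
  hsv  = c("H", "S"),
  xyz  = c("x", "y"),
  lab  = c("a", "b")
)

#' Two-channel chrominance image
#'
#' Holds the two intensity-free colour channels a skin model is fitted on:
#' (r, g) for normalised RGB, (H, S) for HSV, chromaticities (x, y) for CIE
#' XYZ, and (a*, b*) for CIE L*a*b*. The observation at each pixel is the
#' 2-vector the Gaussian models treat as one sample.
#'
#' @slot data numeric H x W x 2 array of channel values.
#' @slot space one of \code{"nrgb"}, \code{"hsv"}, \code{"xyz"}, \code{"lab"}.
#' @slot channels the pair of channel labels implied by \code{space}.
#' @export
setClass("ChromImage",
  representation(data = "array", space = "character", channels = "character"))

setValidity("ChromImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 2L)
    return("data must be an H x W x 2 array (exactly two chrominance channels)")
  if (d[1] < 1L || d[2] < 1L) return("image dimensions must be positive")
  if (!(object@space %in% CHROM_SPACES))
    return(sprintf("space must be one of %s", paste(CHROM_SPACES, collapse = ", ")))
  if (!identical(object@channels, CHROM_CHANNELS[[object@space]]))
    return("channels do not match the colour space tag")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("chrominance values must be finite")
  TRUE
})

ChromImage <- function(data, space) {
  new("ChromImage", data = data, space = space,
      channels = CHROM_CHANNELS[[space]])
}

setMethod("show", "ChromImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChromImage %d x %d, space '%s' (channels %s, %s)\n",
              d[1], d[2], object@space,
              object@channels[1], object@channels[2]))
})

#' Single-Gaussian skin model
#'
#' Maximum-likelihood bivariate normal fitted to chrominance samples of one
#' class: mean vector and (biased, 1/T) covariance.
#'
#' @slot mu length-2 mean vector.
#' @slot sigma 2 x 2 symmetric positive-definite covariance.
#' @slot space colour-space tag the model was fitted in.
#' @slot peak density value at the mode, used to normalise probability maps.
#' @export
setClass("SGMParams",
  representation(mu = "numeric", sigma = "matrix", space = "character",
                 peak = "numeric"))

setValidity("SGMParams", function(object) {
  if (length(object@mu) != 2L) return("mu must have length 2")
  if (!all(dim(object@sigma) == c(2L, 2L))) return("sigma must be 2 x 2")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
    return("sigma must be symmetric")
  ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("sigma must be positive definite")
  if (!(object@space %in% CHROM_SPACES)) return("unknown colour space tag")
  TRUE
})

setMethod("show", "SGMParams", function(object) {
  cat(sprintf("SGMParams (space '%s')\n  mu    = (%.5f, %.5f)\n", object@space,
              object@mu[1], object@mu[2]))
  cat(sprintf("  sigma = [%.3g %.3g; %.3g %.3g]\n", object@sigma[1, 1],
              object@sigma[1, 2], object@sigma[2, 1], object@sigma[2, 2]))
})

#' Gaussian-mixture skin model
#'
#' @slot priors component priors, non-negative, summing to one.
#' @slot means J x 2 matrix of component means.
#' @slot covariances 2 x 2 x J array of component covariances.
#' @slot space colour-space tag.
#' @slot logLik per-iteration log-likelihood trace from EM (empty until fitted).
#' @slot peak reference density used to normalise probability maps.
#' @export
setClass("GMMParams",
  representation(priors = "numeric", means = "matrix", covariances = "array",
                 space = "character", logLik = "numeric", peak = "numeric"))

setValidity("GMMParams", function(object) {
  J <- length(object@priors)
  if (J < 1L) return("at least one component required")
  if (any(object@priors < -1e-12)) return("priors must be non-negative")
  if (abs(sum(object@priors) - 1) > 1e-9) return("priors must sum to 1")
  if (!all(dim(object@means) == c(J, 2L))) return("means must be J x 2")
  if (!all(dim(object@covariances) == c(2L, 2L, J)))
    return("covariances must be 2 x 2 x J")
  for (j in seq_len(J)) {
    S <- object@covariances[, , j]
    if (max(abs(S - t(S))) > 1e-8) return("covariances must be symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("covariances must be positive definite")
  }
  if (!(object@space %in% CHROM_SPACES)) return("unknown colour space tag")
  TRUE
})

setMethod("show", "GMMParams", function(object) {
  J <- length(object@priors)
  cat(sprintf("GMMParams (space '%s'), J = %d\n", object@space, J))
  for (j in seq_len(J))
    cat(sprintf("  [%d] pi = %.4f, mu = (%.5f, %.5f)\n", j, object@priors[j],
                object@means[j, 1], object@means[j, 2]))
  if (length(object@logLik))
    cat(sprintf("  EM: %d iterations, logLik %.4f -> %.4f\n",
                length(object@logLik), object@logLik[1],
                object@logLik[length(object@logLik)]))
})

#' Topology-preserving graph learned by growing neural gas
#'
#' Vertex set of neurons (reference vectors in R^d with accumulated error and,
#' in 3D colour mode, an RGB attribute) plus an unweighted aged edge set.
#'
#' @slot positions n x d matrix of neuron reference vectors (d = 2 or 3).
#' @slot errors accumulated squared-distance error per neuron.
#' @slot colours n x 3 RGB per neuron, or a 0 x 3 matrix when untracked.
#' @slot edges m x 2 matrix of neuron index pairs (each row i < j).
#' @slot ages integer edge ages, one per edge row.
#' @slot nSignals number of input signals processed so far.
#' @slot config the learning parameters used (list from \code{gngConfig}).
#' @export
setClass("GNG",
  representation(positions = "matrix", errors = "numeric", colours = "matrix",
                 edges = "matrix", ages = "integer", nSignals = "numeric",
                 config = "list"))

setValidity("GNG", function(object) {
  n <- nrow(object@positions)
  if (n < 2L) return("a GNG graph keeps at least two neurons")
  if (length(object@errors) != n) return("one error value per neuron required")
  if (any(object@errors < 0)) return("accumulated errors must be non-negative")
  if (any(!is.finite(object@positions))) return("reference vectors must be finite")
  m <- nrow(object@edges)
  if (length(object@ages) != m) return("one age per edge required")
  if (m > 0) {
    if (any(object@edges[, 1] == object@edges[, 2])) return("self-loop edge")
    if (any(object@edges < 1L) || any(object@edges > n))
      return("edge endpoint outside neuron set")
    key <- paste(pmin(object@edges[, 1], object@edges[, 2]),
                 pmax(object@edges[, 1], object@edges[, 2]))
    if (anyDuplicated(key)) return("duplicate edge")
    if (any(object@ages < 0L)) return("edge ages must be non-negative")
  }
  ncol_col <- ncol(object@colours)
  if (nrow(object@colours) > 0 && (nrow(object@colours) != n || ncol_col != 3L))
    return("colours must be n x 3 when present")
  TRUE
})

setMethod("show", "GNG", function(object) {
  cat(sprintf("GNG graph: %d neurons (d = %d), %d edges, %g signals processed\n",
              nrow(object@positions), ncol(object@positions),
              nrow(object@edges), object@nSignals))
  if (nrow(object@colours) > 0) cat("  per-neuron RGB colours attached\n")
})

#' Coloured mesh reconstructed from a point cloud
#'
#' Vertices are the neuron reference vectors of a learned 3D GNG graph; faces
#' are the triangles completed among mutually connected neuron triples. The
#' mesh can be open: triangles are never invented where the graph has none.
#'
#' @slot vertices n x 3 vertex positions.
#' @slot colours n x 3 RGB vertex colours in [0, 1].
#' @slot edges m x 2 vertex index pairs.
#' @slot faces k x 3 vertex index triples (3-cliques of the edge graph).
#' @export
setClass("ColouredMesh",
  representation(vertices = "matrix", colours = "matrix", edges = "matrix",
                 faces = "matrix"))

setValidity("ColouredMesh", function(object) {
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (nrow(object@colours) != n || ncol(object@colours) != 3L)
    return("colours must be n x 3")
  if (nrow(object@faces) > 0) {
    if (ncol(object@faces) != 3L) return("faces must be k x 3")
    if (any(object@faces < 1L) || any(object@faces > n))
      return("face vertex index out of range")
    ek <- edgeKeys(object@edges)
    for (r in seq_len(nrow(object@faces))) {
      f <- object@faces[r, ]
      need <- edgeKeys(rbind(f[c(1, 2)], f[c(1, 3)], f[c(2, 3)]))
      if (!all(need %in% ek)) return("face uses an edge absent from the graph")
    }
  }
  TRUE
})

edgeKeys <- function(e) {
  if (nrow(e) == 0) return(character(0))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

setMethod("show", "ColouredMesh", function(object) {
  cat(sprintf("ColouredMesh: %d vertices, %d edges, %d faces\n",
              nrow(object@vertices), nrow(object@edges), nrow(object@faces)))
})

# ---- accessors ----

#' @export
setGeneric("chromData", function(x) standardGeneric("chromData"))
#' Chrominance pixel array of a ChromImage
#' @param x a \code{ChromImage}.
#' @return the H x W x 2 numeric array.
#' @export
setMethod("chromData", "ChromImage", function(x) x@data)

#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))
#' Colour-space tag of an object
#' @param x a \code{ChromImage}, \code{SGMParams} or \code{GMMParams}.
#' @return character tag, one of "nrgb", "hsv", "xyz", "lab".
#' @export
setMethod("spaceTag", "ChromImage", function(x) x@space)
#' @rdname spaceTag-ChromImage-method
#' @export
setMethod("spaceTag", "SGMParams", function(x) x@space)
#' @rdname spaceTag-ChromImage-method
#' @export
setMethod("spaceTag", "GMMParams", function(x) x@space)

#' @export
setGeneric("nodePositions", function(x) standardGeneric("nodePositions"))
#' Neuron reference vectors of a GNG graph
#' @param x a \code{GNG} object.
#' @return n x d numeric matrix.
#' @export
setMethod("nodePositions", "GNG", function(x) x@positions)

#' @export
setGeneric("nodeErrors", function(x) standardGeneric("nodeErrors"))
#' Accumulated neuron errors of a GNG graph
#' @param x a \code{GNG} object.
#' @return numeric vector.
#' @export
setMethod("nodeErrors", "GNG", function(x) x@errors)

#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' Edge list of a GNG graph or mesh
#' @param x a \code{GNG} or \code{ColouredMesh}.
#' @return m x 2 integer matrix of neuron index pairs.
#' @export
setMethod("graphEdges", "GNG", function(x) x@edges)
#' @rdname graphEdges-GNG-method
#' @export
setMethod("graphEdges", "ColouredMesh", function(x) x@edges)

#' @export
setGeneric("edgeAges", function(x) standardGeneric("edgeAges"))
#' Edge ages of a GNG graph
#' @param x a \code{GNG} object.
#' @return integer vector parallel to \code{graphEdges(x)} rows.
#' @export
setMethod("edgeAges", "GNG", function(x) x@ages)

#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' Triangle list of a coloured mesh
#' @param x a \code{ColouredMesh}.
#' @return k x 3 integer matrix.
#' @export
setMethod("meshFaces", "ColouredMesh", function(x) x@faces)

#' @export
setGeneric("nodeColours", function(x) standardGeneric("nodeColours"))
#' Per-neuron RGB colours
#' @param x a \code{GNG} or \code{ColouredMesh}.
#' @return n x 3 matrix in [0, 1] (0 x 3 when colours were not tracked).
#' @export
setMethod("nodeColours", "GNG", function(x) x@colours)
#' @rdname nodeColours-GNG-method
#' @export
setMethod("nodeColours", "ColouredMesh", function(x) x@colours)
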