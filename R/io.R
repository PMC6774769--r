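#' Read an RGB image (PNG or PPM)
#'
#' 8-bit (or 16-bit PNG) input is returned normalised to [0, 1]. Greyscale
#' input is replicated to three channels; an alpha channel is dropped.
#'
#' @param path file path ending in .png, .ppm or .pnm.
#' @return H x W x 3 numeric array in [0, 1].
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop(sprintf("image not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("ppm", "pnm")) {
    img <- readPPM(path)
  } else stop(sprintf("unsupported image format: .%s", ext))
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

# Minimal binary (P6) and ASCII (P3) PPM reader, 8-bit maxval.
readPPM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with #-comments allowed
  while (length(tokens) < 4L) {
    line <- readBin(con, "raw", 1L)
    chunk <- character(0)
    repeat {
      ch <- rawToChar(line)
      if (ch %in% c(" ", "\t", "\n", "\r")) break
      chunk <- c(chunk, ch)
      line <- readBin(con, "raw", 1L)
      if (length(line) == 0) break
    }
    tok <- paste(chunk, collapse = "")
    if (tok == "") next
    if (startsWith(tok, "#")) {  # consume to end of line
      repeat {
        b <- readBin(con, "raw", 1L)
        if (length(b) == 0 || rawToChar(b) == "\n") break
      }
      next
    }
    tokens <- c(tokens, tok)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxv <- as.integer(tokens[4])
  if (!(magic %in% c("P3", "P6"))) stop("not a PPM (P3/P6) file")
  npx <- w * h * 3L
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", npx))
  } else {
    as.integer(scan(con, what = integer(), n = npx, quiet = TRUE))
  }
  a <- array(0, dim = c(h, w, 3))
  v <- matrix(vals, nrow = 3)  # pixel-interleaved, row-major
  for (ch in 1:3)
    a[, , ch] <- matrix(v[ch, ], nrow = h, byrow = TRUE)
  a / maxv
}

#' Write a binary mask as an 8-bit PNG
#'
#' Background pixels are written as 0 and skin pixels as 255.
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(asMask(mask) * 1, path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' @param path PNG path; any non-zero pixel counts as skin.
#' @return logical matrix.
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a probability map as a 32-bit float TIFF
#'
#' @param pm numeric matrix in [0, 1].
#' @param path output path (.tif/.tiff).
#' @export
writeMapTIFF <- function(pm, path) {
  tiff::writeTIFF(pmin(pmax(pm, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a probability map written by \code{\link{writeMapTIFF}}
#'
#' @param path TIFF path.
#' @return numeric matrix in [0, 1].
#' @export
readMapTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write a coloured point cloud or mesh as ASCII PLY
#'
#' Vertices carry x, y, z and 8-bit red, green, blue; faces (when present)
#' are triangles.
#'
#' @param x a \code{\link{ColouredMesh}}, or a list with \code{points} and
#'   optional \code{colours} as produced by \code{\link{depthToPointCloud}}.
#' @param path output .ply path.
#' @export
writePLY <- function(x, path) {
  if (is(x, "ColouredMesh")) {
    v <- x@vertices; cols <- x@colours; faces <- x@faces
  } else {
    v <- x$points
    cols <- if (is.null(x$colours)) matrix(0.5, nrow(v), 3) else x$colours
    faces <- matrix(integer(0), 0, 3)
  }
  cols8 <- round(pmin(pmax(cols, 0), 1) * 255)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           sprintf("element face %d", nrow(faces)),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.8g %.8g %.8g %d %d %d", v[, 1], v[, 2], v[, 3],
                cols8[, 1], cols8[, 2], cols8[, 3])
  fl <- if (nrow(faces) > 0)
    sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L)
  else character(0)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' Supports the vertex/face layout written by \code{\link{writePLY}}
#' (x y z [red green blue], triangular faces).
#'
#' @param path .ply path.
#' @return list with \code{points} (n x 3), \code{colours} (n x 3 in [0, 1]
#'   or NULL) and \code{faces} (k x 3, 1-based).
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  endHdr <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(endHdr)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nfLine <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nfLine)) as.integer(sub("element face ", "", nfLine)) else 0L
  # count vertex properties to know the column layout
  elemStarts <- grep("^element ", hdr)
  vStart <- grep("^element vertex", hdr)
  vEnd <- min(c(elemStarts[elemStarts > vStart], endHdr)) - 1L
  nProp <- sum(grepl("^property ", hdr[vStart:vEnd]))
  vdat <- matrix(scan(text = lines[endHdr + seq_len(nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  points <- vdat[, 1:3, drop = FALSE]
  colours <- if (nProp >= 6) vdat[, 4:6, drop = FALSE] / 255 else NULL
  faces <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    fdat <- matrix(scan(text = lines[endHdr + nv + seq_len(nf)], quiet = TRUE),
                   nrow = nf, byrow = TRUE)
    faces <- fdat[, 2:4, drop = FALSE] + 1L
  }
  list(points = points, colours = colours, faces = faces)
}

#' Write a coloured mesh as Wavefront OBJ
#'
#' Vertex colours are written as the nonstandard-but-common x y z r g b
#' extension of the \code{v} record.
#'
#' @param mesh a \code{\link{ColouredMesh}}.
#' @param path output .obj path.
#' @export
writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; cols <- mesh@colours
  lines <- c(sprintf("v %.8g %.8g %.8g %.6g %.6g %.6g",
                     v[, 1], v[, 2], v[, 3], cols[, 1], cols[, 2], cols[, 3]),
             if (nrow(mesh@faces) > 0)
               sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
                       mesh@faces[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise a fitted skin model to YAML
#'
#' Stores the colour-space tag, the parameters (mean/covariance for a single
#' Gaussian; priors/means/covariances for a mixture) and the map
#' normalisation constant.
#'
#' @param model an \code{\link{SGMParams}} or \code{\link{GMMParams}}.
#' @param path output .yaml path.
#' @export
saveModelYAML <- function(model, path) {
  doc <- if (is(model, "SGMParams")) {
    list(kind = "sgm", space = model@space, mu = as.numeric(model@mu),
         sigma = lapply(seq_len(2), function(i) as.numeric(model@sigma[i, ])),
         peak = model@peak)
  } else {
    J <- length(model@priors)
    list(kind = "gmm", space = model@space, J = J,
         priors = as.numeric(model@priors),
         means = lapply(seq_len(J), function(j) as.numeric(model@means[j, ])),
         covariances = lapply(seq_len(J), function(j)
           lapply(1:2, function(i) as.numeric(model@covariances[i, , j]))),
         logLik = as.numeric(model@logLik), peak = model@peak)
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load a skin model saved by \code{\link{saveModelYAML}}
#'
#' @param path .yaml path.
#' @return an \code{\link{SGMParams}} or \code{\link{GMMParams}}.
#' @export
loadModelYAML <- function(path) {
  doc <- yaml::read_yaml(path)
  if (identical(doc$kind, "sgm")) {
    new("SGMParams", mu = as.numeric(doc$mu),
        sigma = do.call(rbind, lapply(doc$sigma, as.numeric)),
        space = doc$space, peak = as.numeric(doc$peak))
  } else if (identical(doc$kind, "gmm")) {
    J <- doc$J
    covs <- array(0, dim = c(2, 2, J))
    for (j in seq_len(J))
      covs[, , j] <- do.call(rbind, lapply(doc$covariances[[j]], as.numeric))
    new("GMMParams", priors = as.numeric(doc$priors),
        means = do.call(rbind, lapply(doc$means, as.numeric)),
        covariances = covs, space = doc$space,
        logLik = as.numeric(doc$logLik), peak = as.numeric(doc$peak))
  } else stop("unrecognised model file")
}

#' Serialise a topology graph to JSON
#'
#' @param g a \code{\link{GNG}}.
#' @param path output .json path.
#' @export
saveGraphJSON <- function(g, path) {
  doc <- list(
    d = ncol(g@positions),
    nSignals = g@nSignals,
    config = g@config,
    nodes = lapply(seq_len(nrow(g@positions)), function(i) {
      nd <- list(position = as.numeric(g@positions[i, ]),
                 error = g@errors[i])
      if (nrow(g@colours) > 0) nd$colour <- as.numeric(g@colours[i, ])
      nd
    }),
    edges = lapply(seq_len(nrow(g@edges)), function(r)
      list(a = g@edges[r, 1], b = g@edges[r, 2], age = g@ages[r])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a topology graph saved by \code{\link{saveGraphJSON}}
#'
#' @param path .json path.
#' @return a \code{\link{GNG}}.
#' @export
loadGraphJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  pos <- do.call(rbind, lapply(doc$nodes, function(nd) as.numeric(nd$position)))
  errs <- vapply(doc$nodes, function(nd) as.numeric(nd$error), numeric(1))
  cols <- if (!is.null(doc$nodes[[1]]$colour))
    do.call(rbind, lapply(doc$nodes, function(nd) as.numeric(nd$colour)))
  else matrix(numeric(0), 0, 3)
  edges <- if (length(doc$edges))
    do.call(rbind, lapply(doc$edges, function(e) c(e$a, e$b)))
  else matrix(integer(0), 0, 2)
  ages <- vapply(doc$edges, function(e) as.integer(e$age), integer(1))
  cfg <- doc$config
  cfg <- gngConfig(cfg$maxNodes, cfg$lambda, cfg$epsB, cfg$epsN,
                   cfg$alpha, cfg$beta, cfg$ageMax)
  newGNG(pos, errs, cols, edges, ages, doc$nSignals, cfg)
}
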