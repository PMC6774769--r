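stageRecord <- function(stage, ...) {
  rec <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              ...)
  message(sprintf("[%s] %s", stage,
                  paste(names(rec)[-(1:2)], unlist(lapply(rec[-(1:2)], function(v)
                    paste(format(v, digits = 6), collapse = ","))),
                    sep = "=", collapse = " ")))
  rec
}

#' Fit a skin (or background) model from image files
#'
#' Reads one or more images with matching masks, converts them to the chosen
#' chrominance space, pools the masked pixels (capped with seeded
#' subsampling) and fits either a single Gaussian or an EM mixture. The
#' fitted model is written as YAML.
#'
#' @param imagePaths character vector of PNG/PPM images.
#' @param maskPaths matching mask PNGs selecting the training pixels (NULL =
#'   use every pixel).
#' @param modelPath output .yaml path.
#' @param space chrominance space tag.
#' @param kind \code{"gmm"} or \code{"sgm"}.
#' @param J mixture components (gmm only).
#' @param maxIter,tol EM controls.
#' @param seed RNG seed.
#' @param wp white point for the lab conversion.
#' @return the fitted model, invisibly; the run log is attached as
#'   attribute \code{"log"}.
#' @export
runFit <- function(imagePaths, maskPaths = NULL, modelPath, space = "lab",
                   kind = c("gmm", "sgm"), J = 3L, maxIter = 100L,
                   tol = 1e-6, seed = 1L, wp = whitePointD65()) {
  kind <- match.arg(kind)
  log <- list()
  pixels <- NULL
  for (i in seq_along(imagePaths)) {
    img <- readImageRGB(imagePaths[i])
    ci <- convertColorSpace(img, space, wp)
    mask <- if (is.null(maskPaths)) NULL else readMaskPNG(maskPaths[i])
    px <- chromPixels(ci, mask, seed = seed)
    pixels <- rbind(pixels, px)
    log <- c(log, list(stageRecord("load", image = imagePaths[i],
                                   pixels = nrow(px))))
  }
  if (nrow(pixels) > 5e5) {
    set.seed(seed)
    pixels <- pixels[sample.int(nrow(pixels), 5e5), ]
  }
  minNeeded <- if (kind == "sgm") 3L else 3L * J
  if (nrow(pixels) < minNeeded)
    stop(sprintf("need at least %d training pixels, got %d", minNeeded,
                 nrow(pixels)))
  model <- if (kind == "sgm") fitSGM(pixels, space = space)
           else fitGMM(pixels, J = J, space = space, maxIter = maxIter,
                       tol = tol, seed = seed)
  saveModelYAML(model, modelPath)
  log <- c(log, list(stageRecord("fit", kind = kind, space = space,
                                 samples = nrow(pixels),
                                 iterations = if (kind == "gmm")
                                   length(model@logLik) else 1L)))
  attr(model, "log") <- log
  invisible(model)
}

#' Segment an image with a fitted skin model
#'
#' Converts the image to the model's colour space, computes the probability
#' map (posterior when a background model is supplied), writes the map
#' (float TIFF) and the thresholded mask (8-bit PNG).
#'
#' @param imagePath input PNG/PPM image.
#' @param modelPath skin model YAML from \code{\link{runFit}}.
#' @param mapPath,maskPath output map (.tiff) and mask (.png) paths.
#' @param backgroundModelPath optional background model YAML; switches the
#'   map to the equal-prior class posterior.
#' @param tau threshold (default 0.55).
#' @param wp white point for the lab conversion.
#' @return list with \code{map} and \code{mask}, invisibly; run log
#'   attached as attribute \code{"log"}.
#' @export
runSegment <- function(imagePath, modelPath, mapPath, maskPath,
                       backgroundModelPath = NULL, tau = 0.55,
                       wp = whitePointD65()) {
  skin <- loadModelYAML(modelPath)
  bg <- if (is.null(backgroundModelPath)) NULL
        else loadModelYAML(backgroundModelPath)
  img <- readImageRGB(imagePath)
  ci <- convertColorSpace(img, spaceTag(skin), wp)
  pm <- probabilityMap(ci, skin, bg)
  mask <- thresholdMap(pm, tau)
  writeMapTIFF(pm, mapPath)
  writeMaskPNG(mask, maskPath)
  log <- list(stageRecord("segment", image = imagePath, space = spaceTag(skin),
                          tau = tau, skinPixels = sum(mask),
                          totalPixels = length(mask)))
  out <- list(map = pm, mask = mask)
  attr(out, "log") <- log
  invisible(out)
}

#' Reconstruct topology from a mask or a point cloud
#'
#' For a mask PNG, learns the 2D topology graph of the foreground and writes
#' it as JSON. For a PLY point cloud, learns a coloured 3D mesh and writes
#' it as PLY (or OBJ if the output path says so).
#'
#' @param inputPath mask .png or cloud .ply.
#' @param outputPath graph .json (2D) or mesh .ply/.obj (3D).
#' @param cfg a \code{\link{gngConfig}}.
#' @param nSignals signals to process (default: enough to reach capacity).
#' @param seed RNG seed.
#' @return the learned \code{GNG} or \code{ColouredMesh}, invisibly; run
#'   log attached as attribute \code{"log"}.
#' @export
runReconstruct <- function(inputPath, outputPath, cfg = NULL,
                           nSignals = NULL, seed = 1L) {
  ext <- tolower(tools::file_ext(inputPath))
  if (ext == "png") {
    if (is.null(cfg)) cfg <- gngConfig(maxNodes = 200L)
    if (is.null(nSignals)) nSignals <- cfg$lambda * cfg$maxNodes
    mask <- readMaskPNG(inputPath)
    g <- learnFromMask(mask, cfg, nSignals = nSignals, seed = seed)
    saveGraphJSON(g, outputPath)
    log <- list(stageRecord("reconstruct2d", input = inputPath,
                            nodes = nrow(nodePositions(g)),
                            edges = nrow(graphEdges(g)),
                            components = max(gngComponents(g))))
    attr(g, "log") <- log
    return(invisible(g))
  }
  if (ext == "ply") {
    if (is.null(cfg)) cfg <- gngConfig(maxNodes = 1000L)
    cloud <- readPLY(inputPath)
    mesh <- learnPointCloud(cloud$points, cloud$colours, cfg,
                            nSignals = nSignals, seed = seed)
    if (tolower(tools::file_ext(outputPath)) == "obj") writeOBJ(mesh, outputPath)
    else writePLY(mesh, outputPath)
    g <- attr(mesh, "gng")
    log <- list(stageRecord("reconstruct3d", input = inputPath,
                            nodes = nrow(mesh@vertices),
                            edges = nrow(mesh@edges),
                            faces = nrow(mesh@faces),
                            mqe = gngQuantisationError(g, cloud$points)))
    attr(mesh, "log") <- log
    return(invisible(mesh))
  }
  stop(sprintf("unsupported reconstruction input: .%s", ext))
}

#' Batch-evaluate predictions against ground truth
#'
#' Pairs predicted masks or probability maps with truth masks by file name,
#' computes TPR/FPR/IoU/Dice at the fixed threshold for each pair, writes a
#' CSV report, and (for probability maps) a ROC CSV per image.
#'
#' @param predPaths predicted mask PNGs or probability-map TIFFs.
#' @param truthPaths matching ground-truth mask PNGs.
#' @param reportPath output CSV path.
#' @param tau threshold applied to probability maps (default 0.55).
#' @param rocDir optional directory for per-image ROC CSVs.
#' @param thresholds ROC threshold grid.
#' @return the report data.frame, invisibly.
#' @export
runEvaluate <- function(predPaths, truthPaths, reportPath, tau = 0.55,
                        rocDir = NULL, thresholds = seq(0, 1, length.out = 101)) {
  if (length(predPaths) != length(truthPaths))
    stop(sprintf("unmatched inputs: %d predictions vs %d truths",
                 length(predPaths), length(truthPaths)))
  rows <- NULL
  for (i in seq_along(predPaths)) {
    ext <- tolower(tools::file_ext(predPaths[i]))
    truth <- readMaskPNG(truthPaths[i])
    if (ext %in% c("tif", "tiff")) {
      pm <- readMapTIFF(predPaths[i])
      pred <- thresholdMap(pm, tau)
      if (!is.null(rocDir)) {
        dir.create(rocDir, showWarnings = FALSE, recursive = TRUE)
        roc <- rocCurve(pm, truth, thresholds)
        utils::write.csv(roc, file.path(rocDir, paste0(
          tools::file_path_sans_ext(basename(predPaths[i])), "_roc.csv")),
          row.names = FALSE)
      }
    } else {
      pred <- readMaskPNG(predPaths[i])
    }
    r <- evaluateMask(pred, truth)
    r <- cbind(data.frame(image = basename(predPaths[i])), r)
    rows <- rbind(rows, r)
  }
  utils::write.csv(rows, reportPath, row.names = FALSE)
  invisible(rows)
}
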