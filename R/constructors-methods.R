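#' Construct an ShgImage
#'
#' @param intensities numeric matrix (y, x) or 3D array (y, x, z) of
#'   non-negative intensities.
#' @param pixelSizeUm in-plane pixel size in micrometres.
#' @param zStepUm slice spacing in micrometres (3D stacks).
#' @return an [ShgImage-class].
#' @examples
#' img <- ShgImage(matrix(runif(64, 0, 100), 8, 8))
#' pixelSize(img)
#' @export
ShgImage <- function(intensities, pixelSizeUm = 0.497, zStepUm = 3.0) {
  if (is.matrix(intensities) || (is.array(intensities) &&
      length(dim(intensities)) %in% c(2L, 3L))) {
    storage.mode(intensities) <- "double"
  } else {
    stop("'intensities' must be a 2D or 3D numeric array")
  }
  new("ShgImage", intensities = intensities,
      pixelSizeUm = as.numeric(pixelSizeUm), zStepUm = as.numeric(zStepUm))
}

#' Construct a FiberMask
#'
#' @param mask logical matrix or 3D array.
#' @param pixelSizeUm in-plane pixel size in micrometres.
#' @return a [FiberMask-class].
#' @export
FiberMask <- function(mask, pixelSizeUm = 0.497) {
  if (!is.array(mask) && !is.matrix(mask))
    stop("'mask' must be a 2D or 3D array")
  if (!is.logical(mask)) {
    m <- mask > 0
    dim(m) <- dim(mask)
    mask <- m
  }
  new("FiberMask", mask = mask, pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Construct an FcmConfig
#'
#' @param nClusters number of clusters (>= 2).
#' @param fuzziness fuzzifier m (> 1).
#' @param tol convergence tolerance, as a fraction of the intensity range.
#' @param maxIter iteration cap.
#' @param init "quantile", "range" or "random".
#' @param seed RNG seed for random initialization.
#' @return an [FcmConfig-class].
#' @export
FcmConfig <- function(nClusters = 2L, fuzziness = 2.0, tol = 1e-5,
                      maxIter = 300L, init = "quantile", seed = 1L) {
  new("FcmConfig", nClusters = as.integer(nClusters),
      fuzziness = as.numeric(fuzziness), tol = as.numeric(tol),
      maxIter = as.integer(maxIter), init = match.arg(init,
      c("quantile", "range", "random")), seed = as.integer(seed))
}

#' Construct a ShapeFilterConfig
#'
#' @param minLengthUm minimum skeleton length (um).
#' @param maxWidthUm maximum mean ridge width (um).
#' @param minAspect minimum length/width aspect ratio.
#' @param connectivity 4 or 8.
#' @return a [ShapeFilterConfig-class].
#' @export
ShapeFilterConfig <- function(minLengthUm = 10.0, maxWidthUm = 10.0,
                              minAspect = 2.0, connectivity = 8L) {
  new("ShapeFilterConfig", minLengthUm = as.numeric(minLengthUm),
      maxWidthUm = as.numeric(maxWidthUm), minAspect = as.numeric(minAspect),
      connectivity = as.integer(connectivity))
}

#' Construct FiberImageParams
#'
#' See [FiberImageParams-class] for the meaning of each parameter.
#'
#' @param shape,pixelSizeUm,nFibers,targetFraction,fiberWidthPx,fiberLengthPx
#'   see class documentation.
#' @param persistence,nBlobs,blobRadiusPx,fiberIntensity,backgroundLevel
#'   see class documentation.
#' @param gaussianSigma,poissonScale,seed see class documentation.
#' @return a [FiberImageParams-class].
#' @export
FiberImageParams <- function(shape = c(512L, 512L), pixelSizeUm = 0.497,
                             nFibers = 2000L, targetFraction = 0.10,
                             fiberWidthPx = 3, fiberLengthPx = 80,
                             persistence = 0.9, nBlobs = 10L,
                             blobRadiusPx = 6, fiberIntensity = 200,
                             backgroundLevel = 10, gaussianSigma = 5,
                             poissonScale = 1, seed = 1L) {
  new("FiberImageParams", shape = as.integer(shape),
      pixelSizeUm = as.numeric(pixelSizeUm), nFibers = as.integer(nFibers),
      targetFraction = as.numeric(targetFraction),
      fiberWidthPx = as.numeric(fiberWidthPx),
      fiberLengthPx = as.numeric(fiberLengthPx),
      persistence = as.numeric(persistence), nBlobs = as.integer(nBlobs),
      blobRadiusPx = as.numeric(blobRadiusPx),
      fiberIntensity = as.numeric(fiberIntensity),
      backgroundLevel = as.numeric(backgroundLevel),
      gaussianSigma = as.numeric(gaussianSigma),
      poissonScale = as.numeric(poissonScale), seed = as.integer(seed))
}

#' Construct CohortParams
#'
#' See [CohortParams-class] for the generative model.
#'
#' @param nPatientsPerGroup,fovsMin,fovsMax,muLog,groupEffectLog see class
#'   documentation.
#' @param sdBetween,sdWithin,trueHr,baselineHazard,censorRate,seed see class
#'   documentation.
#' @return a [CohortParams-class].
#' @export
CohortParams <- function(nPatientsPerGroup = c(12L, 14L), fovsMin = 6L,
                         fovsMax = 18L, muLog = 1.5, groupEffectLog = 0.5,
                         sdBetween = 0.5, sdWithin = 0.6, trueHr = 2.71,
                         baselineHazard = 0.08, censorRate = 0.04,
                         seed = 1L) {
  new("CohortParams", nPatientsPerGroup = as.integer(nPatientsPerGroup),
      fovsMin = as.integer(fovsMin), fovsMax = as.integer(fovsMax),
      muLog = as.numeric(muLog), groupEffectLog = as.numeric(groupEffectLog),
      sdBetween = as.numeric(sdBetween), sdWithin = as.numeric(sdWithin),
      trueHr = as.numeric(trueHr),
      baselineHazard = as.numeric(baselineHazard),
      censorRate = as.numeric(censorRate), seed = as.integer(seed))
}

#' Construct a TileLayout
#'
#' @param tiles list of tiles; each a list with `image` (numeric matrix) and
#'   `origin` (numeric (y, x), 0-based pixels).
#' @param pixelSizeUm shared pixel size (um).
#' @param overlapUm nominal overlap between adjacent tiles (um).
#' @return a [TileLayout-class].
#' @export
TileLayout <- function(tiles, pixelSizeUm = 0.53, overlapUm = 300) {
  tiles <- lapply(tiles, function(tl) {
    tl$image <- `storage.mode<-`(tl$image, "double")
    tl$origin <- as.numeric(tl$origin)
    tl
  })
  new("TileLayout", tiles = tiles, pixelSizeUm = as.numeric(pixelSizeUm),
      overlapUm = as.numeric(overlapUm))
}

#' @rdname ShgImage-class
#' @export
setMethod("intensities", "ShgImage", function(object) object@intensities)

#' @rdname ShgImage-class
#' @export
setMethod("pixelSize", "ShgImage", function(object) object@pixelSizeUm)

#' @rdname FiberMask-class
#' @export
setMethod("pixelSize", "FiberMask", function(object) object@pixelSizeUm)

#' @rdname ShgImage-class
#' @export
setMethod("zStep", "ShgImage", function(object) object@zStepUm)

#' @rdname FiberMask-class
#' @export
setMethod("maskArray", "FiberMask", function(object) object@mask)

#' @rdname FcmResult-class
#' @export
setMethod("centroids", "FcmResult", function(object) object@centroids)

#' @rdname FcmResult-class
#' @export
setMethod("membership", "FcmResult", function(object) object@membership)

#' @rdname ShgImage-class
#' @export
setMethod("dim", "ShgImage", function(x) dim(x@intensities))

#' @rdname FiberMask-class
#' @export
setMethod("dim", "FiberMask", function(x) dim(x@mask))

#' @rdname maxProject
#' @export
setMethod("maxProject", "ShgImage", function(object) {
  d <- dim(object@intensities)
  if (length(d) == 2L) return(object)
  proj <- apply(object@intensities, c(1L, 2L), max)
  ShgImage(proj, pixelSizeUm = object@pixelSizeUm, zStepUm = object@zStepUm)
})

#' @rdname maxProject
#' @export
setMethod("maxProject", "FiberMask", function(object) {
  d <- dim(object@mask)
  if (length(d) == 2L) return(object)
  proj <- apply(object@mask, c(1L, 2L), any)
  FiberMask(proj, pixelSizeUm = object@pixelSizeUm)
})

setMethod("show", "ShgImage", function(object) {
  d <- dim(object@intensities)
  kind <- if (length(d) == 2L) "FOV" else sprintf("stack (%d slices)", d[3])
  cat(sprintf("ShgImage %s: %d x %d px at %.3f um/px\n", kind, d[1], d[2],
              object@pixelSizeUm))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@intensities), max(object@intensities)))
  invisible(NULL)
})

setMethod("show", "FiberMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("FiberMask: %s px at %.3f um/px, %.2f%% fiber\n",
              paste(d, collapse = " x "), object@pixelSizeUm,
              100 * mean(object@mask)))
  invisible(NULL)
})

setMethod("show", "FcmResult", function(object) {
  cat(sprintf(
    "FcmResult: %d clusters, %d values, %d iterations, objective %.6g\n",
    length(object@centroids), nrow(object@membership), object@nIter,
    object@objective))
  cat("  centroids:", paste(signif(object@centroids, 6), collapse = ", "),
      "\n")
  invisible(NULL)
})
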