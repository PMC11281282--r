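#' @import methods
NULL

#' SHG intensity image
#'
#' Container for a second harmonic generation (SHG) micrograph: a 2D field of
#' view (y, x) or a 3D z-stack (y, x, z) of non-negative intensities together
#' with the physical sampling of the acquisition. The in-plane pixel size
#' defaults to 0.497 um, a typical voxel resolution for multiphoton SHG
#' imaging of collagen with a 25x objective; z-stacks carry the slice
#' spacing (default 3 um).
#'
#' @slot intensities numeric array, 2D (y, x) or 3D (y, x, z); finite, >= 0.
#' @slot pixelSizeUm in-plane pixel size in micrometres.
#' @slot zStepUm slice spacing in micrometres (only meaningful for stacks).
#'
#' @seealso [ShgImage()] for construction, [segmentFibers()],
#'   [preprocessShg()]
#' @exportClass ShgImage
setClass("ShgImage",
  representation(
    intensities = "array",
    pixelSizeUm = "numeric",
    zStepUm = "numeric"
  ),
  prototype(
    intensities = array(0, dim = c(1L, 1L)),
    pixelSizeUm = 0.497,
    zStepUm = 3.0
  )
)

setValidity("ShgImage", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    msg <- c(msg, "'intensities' must be a 2D or 3D array")
  if (!is.null(d) && any(d < 1L))
    msg <- c(msg, "all image dimensions must be positive")
  v <- object@intensities
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "intensities must be finite and non-missing")
  else if (any(v < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(object@zStepUm) != 1L || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    msg <- c(msg, "'zStepUm' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Binary fiber mask
#'
#' Boolean grid aligned to an [ShgImage-class]: `TRUE` marks voxels classified
#' as fibrillar collagen. Carries the pixel size so downstream morphometry can
#' report physical units.
#'
#' @slot mask logical array, same orientation as the source image.
#' @slot pixelSizeUm in-plane pixel size in micrometres.
#'
#' @seealso [FiberMask()], [percentFiberVolume()], [labelFiberComponents()]
#' @exportClass FiberMask
setClass("FiberMask",
  representation(mask = "array", pixelSizeUm = "numeric"),
  prototype(mask = array(FALSE, dim = c(1L, 1L)), pixelSizeUm = 0.497)
)

setValidity("FiberMask", function(object) {
  msg <- character()
  d <- dim(object@mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    msg <- c(msg, "'mask' must be a 2D or 3D array")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (anyNA(object@mask))
    msg <- c(msg, "'mask' must not contain NA")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means clustering result
#'
#' Holds the converged state of fuzzy c-means on a set of intensities: the `c`
#' cluster centroids (sorted ascending), the n-by-c membership matrix `u`
#' (rows sum to 1), the iteration count, the final value of the objective
#' `J = sum_i sum_k u_ik^m (x_i - v_k)^2`, and the per-iteration objective
#' trace (non-increasing by construction of the alternating updates).
#'
#' @slot centroids numeric vector of cluster centres, ascending.
#' @slot membership numeric matrix, one row per value, one column per cluster.
#' @slot nIter iterations used.
#' @slot objective final objective value.
#' @slot objectiveTrace objective after each iteration.
#'
#' @seealso [fuzzyCMeans()]
#' @exportClass FcmResult
setClass("FcmResult",
  representation(
    centroids = "numeric",
    membership = "matrix",
    nIter = "integer",
    objective = "numeric",
    objectiveTrace = "numeric"
  )
)

setValidity("FcmResult", function(object) {
  msg <- character()
  if (ncol(object@membership) != length(object@centroids))
    msg <- c(msg, "membership columns must match number of centroids")
  if (is.unsorted(object@centroids))
    msg <- c(msg, "centroids must be sorted ascending")
  u <- object@membership
  if (nrow(u) > 0) {
    if (any(u < -1e-12) || any(u > 1 + 1e-12))
      msg <- c(msg, "memberships must lie in [0, 1]")
    if (max(abs(rowSums(u) - 1)) > 1e-8)
      msg <- c(msg, "membership rows must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means configuration
#'
#' @slot nClusters number of clusters `c` (>= 2); 2 separates background from
#'   fiber, 3 adds a diffuse intermediate class (the brightest cluster is
#'   always taken as fiber downstream).
#' @slot fuzziness exponent `m` > 1; 2 is the conventional choice.
#' @slot tol convergence tolerance on maximum centroid movement, expressed as
#'   a fraction of the intensity range.
#' @slot maxIter iteration cap.
#' @slot init `"quantile"` (deterministic: centroids at evenly spaced
#'   intensity quantiles), `"range"` (deterministic: centroids evenly spaced
#'   over the intensity range) or `"random"` (seeded draw of distinct
#'   values).
#' @slot seed RNG seed for random initialization (ignored by the
#'   deterministic inits).
#'
#' @seealso [FcmConfig()], [fuzzyCMeans()], [segmentFibers()]
#' @exportClass FcmConfig
setClass("FcmConfig",
  representation(
    nClusters = "integer",
    fuzziness = "numeric",
    tol = "numeric",
    maxIter = "integer",
    init = "character",
    seed = "integer"
  ),
  prototype(
    nClusters = 2L,
    fuzziness = 2.0,
    tol = 1e-5,
    maxIter = 300L,
    init = "quantile",
    seed = 1L
  )
)

setValidity("FcmConfig", function(object) {
  msg <- character()
  if (object@nClusters < 2L)
    msg <- c(msg, "'nClusters' must be >= 2")
  if (object@fuzziness <= 1)
    msg <- c(msg, "'fuzziness' must be > 1")
  if (object@tol <= 0)
    msg <- c(msg, "'tol' must be > 0")
  if (object@maxIter < 1L)
    msg <- c(msg, "'maxIter' must be >= 1")
  if (!object@init %in% c("quantile", "range", "random"))
    msg <- c(msg, "'init' must be \"quantile\", \"range\" or \"random\"")
  if (length(msg)) msg else TRUE
})

#' Shape filter configuration
#'
#' Thresholds for the fibrillar shape filter that removes stray, non-fibrillar
#' signal from a candidate fiber mask. A connected component survives iff its
#' skeleton length is at least `minLengthUm`, its mean ridge width is at most
#' `maxWidthUm`, and its length/width aspect ratio is at least `minAspect`.
#'
#' @slot minLengthUm minimum skeleton length, micrometres (default 10).
#' @slot maxWidthUm maximum mean width, micrometres (default 10).
#' @slot minAspect minimum length/width ratio (default 2).
#' @slot connectivity pixel connectivity for component labeling: 4 or 8.
#'
#' @seealso [ShapeFilterConfig()], [shapeFilter()], [labelFiberComponents()]
#' @exportClass ShapeFilterConfig
setClass("ShapeFilterConfig",
  representation(
    minLengthUm = "numeric",
    maxWidthUm = "numeric",
    minAspect = "numeric",
    connectivity = "integer"
  ),
  prototype(
    minLengthUm = 10.0,
    maxWidthUm = 10.0,
    minAspect = 2.0,
    connectivity = 8L
  )
)

setValidity("ShapeFilterConfig", function(object) {
  msg <- character()
  if (object@minLengthUm <= 0 || object@maxWidthUm <= 0 ||
      object@minAspect <= 0)
    msg <- c(msg, "all shape thresholds must be > 0")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' Synthetic fiber image parameters
#'
#' Controls the SHG-like image generator: curvilinear bright fibers drawn as
#' persistent random walks dilated to a sampled width, circular non-fibrillar
#' blob confounders, and a Gaussian-plus-scaled-Poisson noise model over a
#' flat background. Fibers are added until the ground-truth mask reaches
#' `targetFraction` of the grid (with `nFibers` as a hard cap); set
#' `targetFraction = NA` to draw exactly `nFibers` fibers.
#'
#' @slot shape image dimensions in pixels, length 2 (y, x).
#' @slot pixelSizeUm pixel size in micrometres (default 0.497).
#' @slot nFibers maximum number of fibers drawn.
#' @slot targetFraction desired fiber volume fraction in \[0, 1), or `NA`.
#' @slot fiberWidthPx mean fiber width, pixels.
#' @slot fiberLengthPx mean fiber length, pixels.
#' @slot persistence directional persistence of the fiber walk in \[0, 1\];
#'   1 gives straight fibers, 0 a diffusive tangle.
#' @slot nBlobs number of circular confounders (not in the truth mask).
#' @slot blobRadiusPx mean blob radius, pixels.
#' @slot fiberIntensity,backgroundLevel mean signal on fiber / background.
#' @slot gaussianSigma read-noise standard deviation.
#' @slot poissonScale photon-count scaling of the shot-noise term; 0 disables
#'   shot noise.
#' @slot seed integer RNG seed; fixing it fixes every output bit.
#'
#' @seealso [FiberImageParams()], [simulateFiberImage()]
#' @exportClass FiberImageParams
setClass("FiberImageParams",
  representation(
    shape = "integer",
    pixelSizeUm = "numeric",
    nFibers = "integer",
    targetFraction = "numeric",
    fiberWidthPx = "numeric",
    fiberLengthPx = "numeric",
    persistence = "numeric",
    nBlobs = "integer",
    blobRadiusPx = "numeric",
    fiberIntensity = "numeric",
    backgroundLevel = "numeric",
    gaussianSigma = "numeric",
    poissonScale = "numeric",
    seed = "integer"
  ),
  prototype(
    shape = c(512L, 512L),
    pixelSizeUm = 0.497,
    nFibers = 2000L,
    targetFraction = 0.10,
    fiberWidthPx = 3,
    fiberLengthPx = 80,
    persistence = 0.9,
    nBlobs = 10L,
    blobRadiusPx = 6,
    fiberIntensity = 200,
    backgroundLevel = 10,
    gaussianSigma = 5,
    poissonScale = 1,
    seed = 1L
  )
)

setValidity("FiberImageParams", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 1L))
    msg <- c(msg, "'shape' must be two positive integers")
  tf <- object@targetFraction
  if (!is.na(tf) && (tf < 0 || tf >= 1))
    msg <- c(msg, "'targetFraction' must be in [0, 1) or NA")
  if (object@nFibers < 0L || object@nBlobs < 0L)
    msg <- c(msg, "fiber and blob counts must be >= 0")
  if (object@persistence < 0 || object@persistence > 1)
    msg <- c(msg, "'persistence' must be in [0, 1]")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be > 0")
  if (object@fiberWidthPx >= min(object@shape))
    msg <- c(msg, "impossible geometry: fiber width exceeds image size")
  if (object@fiberWidthPx < 1 || object@fiberLengthPx < 1)
    msg <- c(msg, "fiber width and length must be >= 1 pixel")
  if (object@gaussianSigma < 0 || object@poissonScale < 0 ||
      object@backgroundLevel < 0 || object@fiberIntensity < 0)
    msg <- c(msg, "noise and intensity parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort parameters
#'
#' Defines a two-group (non-recurrent vs recurrent) patient cohort with 6-18
#' fields of view per patient and log-scale variance components. The log
#' percent fiber volume of FOV j in patient i is
#' `muLog + groupEffectLog * 1(recurrent) + b_i + e_ij` with
#' `b_i ~ N(0, sdBetween^2)` and `e_ij ~ N(0, sdWithin^2)`. Survival times are
#' exponential; patients whose true mean log volume exceeds the cohort median
#' have their event hazard multiplied by `trueHr`, and censoring is an
#' independent exponential clock.
#'
#' @slot nPatientsPerGroup patients per group; either one integer for both
#'   groups or two integers (non-recurrent, recurrent). Default c(12, 14),
#'   the design of a typical small exploratory recurrence cohort.
#' @slot fovsMin,fovsMax range of FOV counts per patient (defaults 6 and 18).
#' @slot muLog baseline mean of log percent fiber volume.
#' @slot groupEffectLog additive recurrent-group effect on the log scale.
#' @slot sdBetween,sdWithin between-patient and within-patient SDs (log
#'   scale).
#' @slot trueHr hazard ratio of the high-fiber (above true-median) group.
#' @slot baselineHazard event hazard of the low-fiber group.
#' @slot censorRate rate of the independent exponential censoring clock;
#'   0 disables censoring.
#' @slot seed integer RNG seed.
#'
#' @seealso [CohortParams()], [simulateCohort()]
#' @exportClass CohortParams
setClass("CohortParams",
  representation(
    nPatientsPerGroup = "integer",
    fovsMin = "integer",
    fovsMax = "integer",
    muLog = "numeric",
    groupEffectLog = "numeric",
    sdBetween = "numeric",
    sdWithin = "numeric",
    trueHr = "numeric",
    baselineHazard = "numeric",
    censorRate = "numeric",
    seed = "integer"
  ),
  prototype(
    nPatientsPerGroup = c(12L, 14L),
    fovsMin = 6L,
    fovsMax = 18L,
    muLog = 1.5,
    groupEffectLog = 0.5,
    sdBetween = 0.5,
    sdWithin = 0.6,
    trueHr = 2.71,
    baselineHazard = 0.08,
    censorRate = 0.04,
    seed = 1L
  )
)

setValidity("CohortParams", function(object) {
  msg <- character()
  n <- object@nPatientsPerGroup
  if (!length(n) %in% c(1L, 2L))
    msg <- c(msg, "'nPatientsPerGroup' must have length 1 or 2")
  if (any(n < 2L))
    msg <- c(msg, "at least 2 patients per group are required")
  if (object@fovsMin < 1L)
    msg <- c(msg, "'fovsMin' must be >= 1")
  if (object@fovsMin > object@fovsMax)
    msg <- c(msg, "'fovsMin' must be <= 'fovsMax'")
  if (object@sdBetween < 0 || object@sdWithin < 0)
    msg <- c(msg, "variance components must be >= 0")
  if (object@trueHr <= 0)
    msg <- c(msg, "'trueHr' must be > 0")
  if (object@baselineHazard <= 0)
    msg <- c(msg, "'baselineHazard' must be > 0")
  if (object@censorRate < 0)
    msg <- c(msg, "'censorRate' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Tile layout for mosaic stitching
#'
#' Describes a tiled SHG acquisition: a list of tiles, each an image matrix
#' with a nominal origin (stage position) in pixels, 0-based, row-major with
#' the origin at the top-left. Quadrant scans are typically acquired with a
#' ~300 um overlap between neighbours at 0.53 um/pixel.
#'
#' @slot tiles list; each element a list with components `image` (numeric
#'   matrix) and `origin` (numeric length-2, (y, x) in pixels, 0-based).
#' @slot pixelSizeUm shared pixel size of all tiles.
#' @slot overlapUm nominal overlap between adjacent tiles, micrometres.
#'
#' @seealso [TileLayout()], [stitchTiles()], [refineOffset()]
#' @exportClass TileLayout
setClass("TileLayout",
  representation(
    tiles = "list",
    pixelSizeUm = "numeric",
    overlapUm = "numeric"
  ),
  prototype(tiles = list(), pixelSizeUm = 0.53, overlapUm = 300)
)

setValidity("TileLayout", function(object) {
  msg <- character()
  for (i in seq_along(object@tiles)) {
    tl <- object@tiles[[i]]
    if (!is.list(tl) || !all(c("image", "origin") %in% names(tl))) {
      msg <- c(msg, sprintf("tile %d must have 'image' and 'origin'", i))
      next
    }
    if (!is.matrix(tl$image))
      msg <- c(msg, sprintf("tile %d image must be a matrix", i))
    if (length(tl$origin) != 2L || anyNA(tl$origin))
      msg <- c(msg, sprintf("tile %d origin must be (y, x)", i))
  }
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be > 0")
  if (length(msg)) msg else TRUE
})
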