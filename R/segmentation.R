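#' Preprocess an SHG image
#'
#' Noise suppression before segmentation: a median filter removes impulse
#' noise, then a global background percentile is subtracted and the result is
#' clipped at zero. Shape and physical metadata are preserved. With
#' `medianRadiusPx = 0` and `backgroundPercentile = 0` the image is returned
#' unchanged.
#'
#' @param image an [ShgImage-class]. 3D stacks are filtered slice by slice.
#' @param medianRadiusPx radius of the median filter window in pixels
#'   (0 disables filtering).
#' @param backgroundPercentile percentile of the (filtered) intensities to
#'   subtract, in [0, 100); 0 disables subtraction.
#' @return an [ShgImage-class] of the same shape.
#' @examples
#' img <- ShgImage(matrix(c(rep(10, 80), rep(200, 1)), 9, 9))
#' out <- preprocessShg(img, medianRadiusPx = 1, backgroundPercentile = 0)
#' max(intensities(out))  # hot pixel removed
#' @export
preprocessShg <- function(image, medianRadiusPx = 2L,
                          backgroundPercentile = 50) {
  stopifnot(is(image, "ShgImage"))
  medianRadiusPx <- as.integer(medianRadiusPx)
  if (medianRadiusPx < 0L)
    stop("'medianRadiusPx' must be >= 0")
  if (backgroundPercentile < 0 || backgroundPercentile >= 100)
    stop("'backgroundPercentile' must be in [0, 100)")
  x <- intensities(image)
  d <- dim(x)
  if (medianRadiusPx > 0L) {
    filt2d <- function(m) {
      hi <- max(m)
      if (hi <= 0) return(m)
      # EBImage's constant-time median filter requires values in [0, 1]
      EBImage::medianFilter(m / hi, size = medianRadiusPx) * hi
    }
    if (length(d) == 2L) {
      x <- filt2d(x)
    } else {
      for (k in seq_len(d[3])) x[, , k] <- filt2d(x[, , k])
    }
  }
  if (backgroundPercentile > 0) {
    bg <- stats::quantile(x, probs = backgroundPercentile / 100, names = FALSE)
    x <- pmax(x - bg, 0)
    dim(x) <- d
  }
  ShgImage(x, pixelSizeUm = pixelSize(image), zStepUm = zStep(image))
}

#' Fuzzy c-means clustering of intensities
#'
#' Soft clustering of scalar intensities into `c` clusters by alternating
#' minimization of `J = sum_i sum_k u_ik^m (x_i - v_k)^2`:
#' centroid update `v_k = sum_i u_ik^m x_i / sum_i u_ik^m` and membership
#' update `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))` with `d` the Euclidean
#' distance on intensity. A value coinciding with a centroid gets membership
#' 1 there and 0 elsewhere. Iteration stops when the maximum centroid
#' movement falls below `tol * diff(range(values))` or `maxIter` is reached.
#' Centroids are returned sorted ascending with membership columns reordered
#' to match.
#'
#' @param values numeric vector of intensities; needs at least `nClusters`
#'   distinct values.
#' @param config an [FcmConfig-class].
#' @return an [FcmResult-class].
#' @examples
#' res <- fuzzyCMeans(c(0, 0, 0, 10, 10, 10), FcmConfig(nClusters = 2))
#' centroids(res)
#' @export
fuzzyCMeans <- function(values, config = FcmConfig()) {
  validObject(config)
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'values' must be finite and non-missing")
  cc <- config@nClusters
  m <- config@fuzziness
  ux <- unique(x)
  if (length(ux) < cc)
    stop(sprintf(
      "degenerate input: %d distinct values, but %d clusters requested",
      length(ux), cc))
  rng <- diff(range(x))
  tolAbs <- config@tol * rng

  v <- if (config@init == "quantile") {
    q <- stats::quantile(x, probs = (seq_len(cc) - 0.5) / cc, names = FALSE)
    # evenly spaced quantiles can coincide on discrete data; spread to the
    # nearest distinct observed values
    while (anyDuplicated(q)) {
      dup <- which(duplicated(q))
      q[dup] <- q[dup] + rng * 1e-6 * dup
    }
    sort(q)
  } else if (config@init == "range") {
    seq(min(x), max(x), length.out = cc)
  } else {
    sort(withr::with_seed(config@seed, sample(ux, cc)))
  }

  expo <- 2 / (m - 1)
  n <- length(x)
  trace <- numeric(0)
  u <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    zero <- d2 <= 0
    anyZero <- rowSums(zero) > 0
    w <- d2^(-expo / 2)           # (1/d)^(2/(m-1))
    u <- w / rowSums(w)
    if (any(anyZero)) {
      zr <- which(anyZero)
      u[zr, ] <- 0
      # first zero-distance cluster takes full membership
      kz <- max.col(zero[zr, , drop = FALSE], ties.method = "first")
      u[cbind(zr, kz)] <- 1
    }
    um <- u^m
    trace[iter] <- sum(um * d2)
    vNew <- colSums(um * x) / colSums(um)
    moved <- max(abs(vNew - v))
    v <- vNew
    if (moved < tolAbs || iter >= config@maxIter) break
  }
  ord <- order(v)
  new("FcmResult", centroids = v[ord], membership = u[, ord, drop = FALSE],
      nIter = iter, objective = trace[iter], objectiveTrace = trace)
}

#' Segment collagen fibers by fuzzy c-means
#'
#' Runs [fuzzyCMeans()] on all voxel intensities and defuzzifies: the fiber
#' class is the cluster with the highest centroid, and a voxel enters the
#' mask iff its membership in that cluster is strictly the maximum over all
#' clusters (ties are background). A constant image yields an empty mask with
#' a warning. 3D stacks are maximum-intensity projected to 2D by default;
#' `projection = "slice"` instead segments each slice independently and
#' returns a 3D mask.
#'
#' Fiber pixels are typically a small minority of an SHG field of view, and
#' with such unbalanced classes fuzzy c-means has a well-known poor local
#' optimum in which all centroids settle inside the dominant background
#' mode. When the configured initialization is deterministic, segmentation
#' therefore runs the clustering from both the quantile and the
#' intensity-range starts and keeps the solution with the lower objective -
#' still fully deterministic and reproducible. A `"random"` init is honoured
#' as a single seeded run.
#'
#' @param image an [ShgImage-class].
#' @param config an [FcmConfig-class].
#' @param projection `"max"` (default) or `"slice"`, for 3D stacks.
#' @return a [FiberMask-class] aligned to the (projected) image.
#' @examples
#' img <- ShgImage(matrix(rep(c(10, 200), each = 50), 10, 10))
#' mask <- segmentFibers(img)
#' sum(maskArray(mask))  # the bright plateau
#' @export
segmentFibers <- function(image, config = FcmConfig(),
                          projection = c("max", "slice")) {
  stopifnot(is(image, "ShgImage"))
  projection <- match.arg(projection)
  d <- dim(image)
  if (length(d) == 3L && projection == "slice") {
    out <- vapply(seq_len(d[3]), function(k) {
      sl <- ShgImage(image@intensities[, , k], pixelSizeUm = pixelSize(image))
      maskArray(segmentFibers(sl, config))
    }, matrix(TRUE, d[1], d[2]))
    return(FiberMask(out, pixelSizeUm = pixelSize(image)))
  }
  if (length(d) == 3L) image <- maxProject(image)
  x <- as.vector(intensities(image))
  if (length(unique(x)) < config@nClusters) {
    warning("image has too few distinct intensities to cluster; ",
            "returning an empty mask")
    return(FiberMask(array(FALSE, dim(image)),
                     pixelSizeUm = pixelSize(image)))
  }
  res <- if (config@init == "random") {
    fuzzyCMeans(x, config)
  } else {
    starts <- lapply(c("quantile", "range"), function(ini) {
      cfg <- config
      cfg@init <- ini
      fuzzyCMeans(x, cfg)
    })
    starts[[which.min(vapply(starts, function(r) r@objective, numeric(1)))]]
  }
  u <- membership(res)
  top <- ncol(u)                       # highest centroid after sorting
  mx <- do.call(pmax, lapply(seq_len(ncol(u)), function(k) u[, k]))
  sel <- (u[, top] == mx) & (rowSums(u == mx) == 1L)
  FiberMask(array(sel, dim(image)), pixelSizeUm = pixelSize(image))
}
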