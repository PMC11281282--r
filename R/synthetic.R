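# Disk offsets of a given diameter, used to stamp fiber cross-sections and
# blobs.
.diskOffsets <- function(widthPx) {
  r <- widthPx / 2
  s <- floor(r)
  dy <- rep(-s:s, times = 2 * s + 1)
  dx <- rep(-s:s, each = 2 * s + 1)
  keep <- dy^2 + dx^2 <= r^2 + 1e-9
  cbind(dy = dy[keep], dx = dx[keep])
}

# Stamp TRUE at (rows + dy, cols + dx) for every disk offset, clipped to the
# grid.
.stampDisks <- function(mask, rows, cols, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  py <- rep(rows, each = nrow(offsets)) + offsets[, "dy"]
  px <- rep(cols, each = nrow(offsets)) + offsets[, "dx"]
  ok <- py >= 1L & py <= nr & px >= 1L & px <= nc
  mask[cbind(py[ok], px[ok])] <- TRUE
  mask
}

# One fiber as a persistent random walk; returns integer path coordinates.
.fiberPath <- function(shape, lengthPx, persistence) {
  y <- stats::runif(1, 1, shape[1])
  x <- stats::runif(1, 1, shape[2])
  theta <- stats::runif(1, 0, 2 * pi)
  sdTurn <- (1 - persistence) * 0.9
  ys <- numeric(lengthPx); xs <- numeric(lengthPx)
  n <- 0L
  for (i in seq_len(lengthPx)) {
    ys[i] <- y; xs[i] <- x
    n <- i
    theta <- theta + stats::rnorm(1, 0, sdTurn)
    y <- y + sin(theta)
    x <- x + cos(theta)
    if (y < 1 || y > shape[1] || x < 1 || x > shape[2]) break
  }
  cbind(round(ys[seq_len(n)]), round(xs[seq_len(n)]))
}

#' Simulate an SHG-like fiber image with ground truth
#'
#' Draws curvilinear bright fibers (persistent random walks dilated to a
#' sampled width) and circular non-fibrillar blob confounders on a flat
#' background, then applies scaled-Poisson shot noise and Gaussian read
#' noise. Fibers are added until the ground-truth fraction reaches
#' `targetFraction` (capped at `nFibers`); blobs are never part of the truth
#' mask. The same seed reproduces the output bit for bit.
#'
#' @param params a [FiberImageParams-class].
#' @return list with `image` (an [ShgImage-class]) and `truth`
#'   (a [FiberMask-class] of the true fiber voxels).
#' @examples
#' out <- simulateFiberImage(FiberImageParams(shape = c(128L, 128L),
#'                                            targetFraction = 0.05))
#' percentFiberVolume(out$truth)
#' @export
simulateFiberImage <- function(params = FiberImageParams()) {
  validObject(params)
  withr::with_seed(params@seed, {
    shape <- params@shape
    truth <- matrix(FALSE, shape[1], shape[2])
    total <- prod(shape)
    target <- params@targetFraction
    if (params@nFibers > 0L && (is.na(target) || target > 0)) {
      for (i in seq_len(params@nFibers)) {
        w <- max(1, round(stats::rnorm(1, params@fiberWidthPx,
                                       params@fiberWidthPx / 4)))
        w <- min(w, min(shape) - 1L)
        len <- max(2L, round(stats::rnorm(1, params@fiberLengthPx,
                                          params@fiberLengthPx / 4)))
        path <- .fiberPath(shape, len, params@persistence)
        truth <- .stampDisks(truth, path[, 1], path[, 2], .diskOffsets(w))
        if (!is.na(target) && sum(truth) / total >= target) break
      }
    }
    blobs <- matrix(FALSE, shape[1], shape[2])
    if (params@nBlobs > 0L) {
      for (i in seq_len(params@nBlobs)) {
        r <- max(1, round(stats::rnorm(1, params@blobRadiusPx,
                                       params@blobRadiusPx / 4)))
        cy <- round(stats::runif(1, 1, shape[1]))
        cx <- round(stats::runif(1, 1, shape[2]))
        blobs <- .stampDisks(blobs, cy, cx, .diskOffsets(2 * r))
      }
    }
    base <- params@backgroundLevel +
      params@fiberIntensity * ((truth | blobs) * 1)
    img <- if (params@poissonScale > 0) {
      stats::rpois(total, as.vector(base) * params@poissonScale) /
        params@poissonScale
    } else {
      as.vector(base)
    }
    if (params@gaussianSigma > 0)
      img <- img + stats::rnorm(total, 0, params@gaussianSigma)
    img <- pmax(img, 0)
    dim(img) <- shape
    list(image = ShgImage(img, pixelSizeUm = params@pixelSizeUm),
         truth = FiberMask(truth, pixelSizeUm = params@pixelSizeUm))
  })
}

#' Simulate a two-group FOV cohort with survival
#'
#' Generates the hierarchical data structure the downstream statistics
#' assume. Each patient i gets a uniform number of FOVs in
#' `\[fovsMin, fovsMax\]`; FOV j carries
#' `log(volume_ij) = muLog + groupEffectLog * 1(recurrent) + b_i + e_ij`
#' with `b_i ~ N(0, sdBetween^2)` and `e_ij ~ N(0, sdWithin^2)`, so percent
#' volumes are log-normal and strictly positive (capped at 100). Survival
#' times are exponential: patients whose true mean log volume `mu_i` exceeds
#' the cohort median have hazard `baselineHazard * trueHr`; an independent
#' exponential censoring clock at `censorRate` right-censors. Using the true
#' mean (not the estimated one) to assign the high-hazard group makes
#' hazard-ratio recovery a clean parameter-recovery exercise.
#'
#' @param params a [CohortParams-class].
#' @return list with `fovs` (columns `patient_id`, `group`, `fov_id`,
#'   `percent_fiber_volume`) and `patients` (columns `patient_id`, `group`,
#'   `mean_volume`, `n_fov`, `time`, `event`, `true_log_mean`,
#'   `high_hazard`).
#' @export
simulateCohort <- function(params = CohortParams()) {
  validObject(params)
  n <- params@nPatientsPerGroup
  if (length(n) == 1L) n <- c(n, n)
  withr::with_seed(params@seed, {
    nTot <- sum(n)
    group <- rep(c("non_recurrent", "recurrent"), n)
    ids <- sprintf("P%03d", seq_len(nTot))
    b <- stats::rnorm(nTot, 0, params@sdBetween)
    muI <- params@muLog + params@groupEffectLog * (group == "recurrent") + b
    nFov <- sample(params@fovsMin:params@fovsMax, nTot, replace = TRUE)
    fovs <- do.call(rbind, lapply(seq_len(nTot), function(i) {
      lv <- muI[i] + stats::rnorm(nFov[i], 0, params@sdWithin)
      data.frame(patient_id = ids[i], group = group[i],
                 fov_id = sprintf("%s_F%02d", ids[i], seq_len(nFov[i])),
                 percent_fiber_volume = pmin(exp(lv), 100))
    }))
    highHazard <- muI > stats::median(muI)
    hazard <- params@baselineHazard * ifelse(highHazard, params@trueHr, 1)
    eventTime <- stats::rexp(nTot, hazard)
    censTime <- if (params@censorRate > 0) {
      stats::rexp(nTot, params@censorRate)
    } else {
      rep(Inf, nTot)
    }
    patients <- data.frame(
      patient_id = ids, group = group,
      mean_volume = vapply(split(fovs$percent_fiber_volume,
                                 fovs$patient_id)[ids], mean, numeric(1)),
      n_fov = nFov,
      time = pmin(eventTime, censTime),
      event = as.integer(eventTime <= censTime),
      true_log_mean = muI,
      high_hazard = highHazard)
    rownames(patients) <- NULL
    list(fovs = fovs, patients = patients)
  })
}

#' Simulate a differential-expression table
#'
#' Null genes get `log2fc ~ N(0, nullSd)` and uniform p-values; planted
#' effect genes carry their stated log2 fold change plus a small jitter and
#' very small p-values. The `padj` column is the Benjamini-Hochberg
#' adjustment of the p-values (see [benjaminiHochberg()]).
#'
#' @param nGenes total number of rows (>= number of planted genes).
#' @param planted named numeric vector of log2 fold changes, e.g.
#'   `c(COL1A1 = 2.63)`; names must be unique.
#' @param nullSd standard deviation of the null log2 fold changes.
#' @param seed integer RNG seed.
#' @return data.frame with columns `symbol`, `gene_id`, `log2fc`, `pvalue`,
#'   `padj`.
#' @export
simulateDeTable <- function(nGenes, planted = numeric(0), nullSd = 0.2,
                            seed = 1L) {
  nGenes <- as.integer(nGenes)
  nP <- length(planted)
  if (nP > 0 && (is.null(names(planted)) || any(names(planted) == "")))
    stop("'planted' must be a named numeric vector of log2 fold changes")
  if (anyDuplicated(names(planted)))
    stop("duplicate planted gene symbols")
  if (nGenes < nP)
    stop("'nGenes' must be at least the number of planted genes")
  withr::with_seed(as.integer(seed), {
    nNull <- nGenes - nP
    symbol <- c(names(planted), sprintf("GENE%05d", seq_len(nNull)))
    log2fc <- c(planted + stats::rnorm(nP, 0, 0.02),
                stats::rnorm(nNull, 0, nullSd))
    pvalue <- c(10^-stats::runif(nP, 8, 15), stats::runif(nNull))
    out <- data.frame(symbol = symbol, gene_id = seq_len(nGenes),
                      log2fc = log2fc, pvalue = pvalue)
    out$padj <- benjaminiHochberg(out$pvalue)
    out
  })
}
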